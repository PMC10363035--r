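#' Biexponential tumor-size model
#'
#' Structural tumor growth inhibition (TGI) model for the sum of longest
#' diameters. Before treatment start the tumor grows exponentially at rate
#' `kg`; from treatment start the size is the sum of a shrinking component
#' (rate `ks`) and a regrowing component (rate `kg`):
#' \deqn{TS(t) = TS_0 e^{K_G t} \quad (t < 0)}
#' \deqn{TS(t) = TS_0 [e^{-K_S t} + e^{K_G t} - 1] \quad (t \ge 0)}
#' Both branches equal `ts0` at `t = 0`. For `ks > kg > 0` the on-treatment
#' curve has its nadir at `t* = log(ks/kg) / (ks + kg)`.
#'
#' @param t time in weeks relative to treatment start (vectorized; may be
#'   negative for screening assessments).
#' @param ts0 model tumor size at time 0, mm (> 0).
#' @param kg tumor growth rate constant, week^-1 (> 0).
#' @param ks tumor shrinkage rate constant, week^-1 (> 0).
#' @return predicted tumor size in mm.
#' @examples
#' ts_model(8, ts0 = 57, kg = 0.00196, ks = 0.0342)
#' @export
ts_model <- function(t, ts0, kg, ks) {
  stopifnot(all(ts0 > 0), all(kg > 0), all(ks > 0))
  ifelse(t < 0,
         ts0 * exp(kg * t),
         ts0 * (exp(-ks * t) + exp(kg * t) - 1))
}

#' Time of the on-treatment nadir of the biexponential curve
#'
#' Closed form `log(ks/kg) / (ks + kg)`, valid when `ks > kg > 0`
#' (otherwise the on-treatment curve is non-decreasing and the nadir is 0).
#'
#' @inheritParams ts_model
#' @return nadir time in weeks.
#' @export
ts_nadir_time <- function(kg, ks) {
  ifelse(ks > kg, log(ks / kg) / (ks + kg), 0)
}

THETA_NAMES <- c("kg_treatment", "ks_treatment", "kg_control", "ks_control", "ts0")

#' Estimation settings for the population TGI fit
#'
#' @param n_starts number of jittered restarts tried on non-convergence.
#' @param jitter_sd log-scale SD of the restart jitter.
#' @param iter_max,eval_max outer optimizer (nlminb) budgets.
#' @param rel_tol relative objective convergence tolerance.
#' @param include_prebaseline include screening assessments at `t < 0`
#'   (they inform `kg` through the pre-treatment branch). When `FALSE`,
#'   records at negative times are dropped before fitting.
#' @param iiv fit inter-individual variability. `FALSE` fixes all random
#'   effects at zero (and the variances at their initial values), reducing
#'   the fit to nonlinear least squares on the typical parameters.
#' @param init optional named list overriding initial values: `theta`
#'   (named as `r paste(THETA_NAMES, collapse=", ")`), `omega2`, `sigma2`.
#' @param seed seed for the restart jitter.
#' @return list of class `tgi_control`.
#' @export
tgi_control <- function(n_starts = 6, jitter_sd = 0.4, iter_max = 500,
                        eval_max = 2000, rel_tol = 1e-8,
                        include_prebaseline = TRUE, iiv = TRUE,
                        init = NULL, seed = 1L) {
  structure(list(n_starts = n_starts, jitter_sd = jitter_sd,
                 iter_max = iter_max, eval_max = eval_max, rel_tol = rel_tol,
                 include_prebaseline = include_prebaseline, iiv = iiv,
                 init = init, seed = seed),
            class = "tgi_control")
}

# Internal: assemble TMB data/parameter lists from a tumor table.
# `for_fit = FALSE` skips the subjects-per-arm precondition (likelihood
# evaluation at fixed parameters is well-defined for any number of subjects).
tgi_tmb_input <- function(tumor, control, for_fit = TRUE) {
  if (!control$include_prebaseline) {
    tumor <- tumor[tumor$time_weeks >= 0, , drop = FALSE]
  }
  tumor <- tumor[order(tumor$subject_id, tumor$time_weeks), , drop = FALSE]
  ids <- unique(tumor$subject_id)
  subj_idx <- match(tumor$subject_id, ids) - 1L
  arm_by_subj <- arm_of(tumor)[ids]
  n_obs <- tabulate(subj_idx + 1L, nbins = length(ids))
  if (any(n_obs < 2)) {
    stop("every subject needs >= 2 tumor-size records to be fitted; ",
         sum(n_obs < 2), " subject(s) have fewer (run filter_evaluable first)")
  }
  if (stats::var(tumor$sld_mm) == 0) {
    stop("degenerate data: all SLD values identical")
  }
  arms_present <- ARM_LEVELS %in% arm_by_subj
  if (for_fit && control$iiv) {
    per_arm <- table(factor(arm_by_subj, levels = ARM_LEVELS))
    if (any(per_arm[arms_present] < 2)) {
      stop("need >= 2 subjects in every fitted arm for a population fit")
    }
  }
  list(
    data = list(
      t = tumor$time_weeks, y = tumor$sld_mm, subj = subj_idx,
      pre = as.integer(tumor$time_weeks < 0),
      arm = as.integer(arm_by_subj == "control")
    ),
    ids = ids, arm_by_subj = arm_by_subj, arms_present = arms_present,
    tumor = tumor
  )
}

# Data-driven starting values: per-subject log-linear heuristics pooled by
# arm. ks from the initial decline (baseline to first post-baseline scan),
# kg from the regrowth slope between the observed nadir and the last scan.
# Good starts matter here: the Laplace objective can hold spurious basins
# where a subject's inner Hessian degenerates.
tgi_default_init <- function(tumor) {
  base <- baseline_sld_of(tumor)
  ts0 <- max(stats::median(base, na.rm = TRUE), 1)
  heur <- function(d) {
    d <- d[order(d$time_weeks), , drop = FALSE]
    ib <- which(d$time_weeks <= 0)
    if (!length(ib)) return(c(NA_real_, NA_real_))
    b <- d$sld_mm[max(ib)]
    post <- d[d$time_weeks > 0, , drop = FALSE]
    if (!nrow(post)) return(c(NA_real_, NA_real_))
    ks <- if (post$sld_mm[1] < b && post$sld_mm[1] > 0) {
      log(b / post$sld_mm[1]) / post$time_weeks[1]
    } else NA_real_
    iN <- which.min(d$sld_mm)
    nlast <- nrow(d)
    kg <- if (nlast > iN && d$sld_mm[nlast] > d$sld_mm[iN] &&
              d$sld_mm[iN] > 0 && d$time_weeks[nlast] > d$time_weeks[iN]) {
      log(d$sld_mm[nlast] / d$sld_mm[iN]) /
        (d$time_weeks[nlast] - d$time_weeks[iN])
    } else NA_real_
    c(kg, ks)
  }
  hs <- t(vapply(split(tumor, tumor$subject_id), heur, numeric(2)))
  arm1 <- vapply(split(tumor$arm, tumor$subject_id), function(a) a[1], "")
  pooled <- function(x) {
    x <- x[is.finite(x) & x > 1e-5 & x < 1]
    if (length(x) >= 3) stats::median(x) else NA_real_
  }
  pick <- function(arm, col, fallback) {
    v <- pooled(hs[arm1 == arm, col])
    if (is.finite(v)) v else fallback
  }
  theta <- c(kg_treatment = pick("treatment", 1, 0.004),
             ks_treatment = pick("treatment", 2, 0.03),
             kg_control = pick("control", 1, 0.004),
             ks_control = pick("control", 2, 0.03),
             ts0 = ts0)
  list(theta = theta,
       omega2 = setNames(rep(0.5, 5), THETA_NAMES),
       sigma2 = 25)
}

#' Fit the population TGI model by Laplace-approximated maximum likelihood
#'
#' Nonlinear mixed-effects fit of the biexponential model [ts_model()] to
#' longitudinal SLD data. `kg` and `ks` have arm-specific typical values and
#' log-normal inter-individual variability; `ts0` has a single typical value
#' and log-normal variability common to both arms; residual error is
#' additive normal. Random-effect variances are diagonal (no eta
#' correlations). All parameters are estimated on the log scale; the
#' marginal likelihood is the Laplace approximation over the per-subject
#' random effects, maximized with `nlminb` using exact (automatic)
#' derivatives. Jittered restarts are attempted on non-convergence.
#'
#' @param data a [trial_dataset()] or a tumor-record data.frame with columns
#'   `subject_id`, `arm`, `time_weeks`, `sld_mm`. Subjects must be
#'   TGI-evaluable (see [filter_evaluable()]).
#' @param control a [tgi_control()].
#' @return object of class `tgi_fit` with elements
#'   \describe{
#'     \item{theta}{typical values (week^-1 for rates, mm for `ts0`).}
#'     \item{omega2}{random-effect variances on the log scale.}
#'     \item{sigma2}{additive residual variance, mm^2.}
#'     \item{rse}{relative standard errors (%) for all reported estimates.}
#'     \item{shrinkage}{eta shrinkage (%) per random effect.}
#'     \item{ebes}{per-subject empirical Bayes estimates: `ts0`, `kg`, `ks`,
#'       `log_kg`, and the underlying etas.}
#'     \item{loglik}{Laplace marginal log-likelihood at the optimum.}
#'   }
#' @export
fit_tgi <- function(data, control = tgi_control()) {
  tumor <- if (inherits(data, "trial_dataset")) data$tumor else data
  inp <- tgi_tmb_input(tumor, control)
  init <- tgi_default_init(inp$tumor)
  if (!is.null(control$init)) {
    for (nm in names(control$init)) init[[nm]] <- control$init[[nm]]
  }
  n_sub <- length(inp$ids)

  theta_map <- seq_along(THETA_NAMES)
  fit_arm <- rep(inp$arms_present, each = 2) # kg/ks pair per arm
  theta_map[1:4][!fit_arm] <- NA
  omega_map <- theta_map
  if (!control$iiv) omega_map[] <- NA
  map <- list(log_theta = factor(theta_map), log_omega2 = factor(omega_map))
  if (!control$iiv) map$eta <- factor(matrix(NA, 3, n_sub))

  pars <- list(
    log_theta = log(unname(init$theta[THETA_NAMES])),
    log_omega2 = log(unname(init$omega2[THETA_NAMES])),
    log_sigma2 = log(unname(init$sigma2)),
    eta = matrix(0, 3, n_sub)
  )

  make_obj <- function(p) {
    TMB::MakeADFun(data = inp$data, parameters = p, map = map,
                   random = if (control$iiv) "eta" else NULL,
                   DLL = "tgios", silent = TRUE)
  }

  set.seed(control$seed)
  best <- NULL
  trace <- list()
  for (s in seq_len(control$n_starts)) {
    p <- pars
    if (s > 1) {
      p$log_theta <- p$log_theta + rnorm(5, 0, control$jitter_sd)
      p$log_sigma2 <- p$log_sigma2 + rnorm(1, 0, control$jitter_sd)
    }
    obj <- make_obj(p)
    # transient NA/NaN objective values during line search are expected and
    # handled by nlminb itself; keep them out of user-facing output
    quiet_nlminb <- function(start) {
      withCallingHandlers(
        nlminb(start, obj$fn, obj$gr,
               control = list(iter.max = control$iter_max,
                              eval.max = control$eval_max,
                              rel.tol = control$rel_tol)),
        warning = function(w) {
          if (grepl("NA/NaN function evaluation", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
    opt <- try({
      o1 <- quiet_nlminb(obj$par)
      # warm restart: clears spurious "false convergence" stops and usually
      # lands on a point with a positive-definite Hessian
      o2 <- quiet_nlminb(o1$par)
      if (is.finite(o2$objective) && o2$objective <= o1$objective) o2 else o1
    }, silent = TRUE)
    ok <- !inherits(opt, "try-error") && is.finite(opt$objective)
    trace[[s]] <- if (ok) {
      list(start = s, objective = opt$objective, convergence = opt$convergence,
           message = opt$message)
    } else list(start = s, objective = NA_real_, convergence = NA_integer_,
                message = "optimizer failure")
    if (ok) {
      # A usable optimum needs a positive-definite Hessian (finite standard
      # errors on both the estimation and the reporting scale), not just a
      # small gradient: the Laplace objective is unbounded below where a
      # subject's inner Hessian turns singular, and an optimizer can stall
      # near that spurious region with a seemingly better objective.
      rp <- tryCatch(suppressWarnings(
        TMB::sdreport(obj, getReportCovariance = FALSE)), error = function(e) NULL)
      se_ok <- !is.null(rp) &&
        all(is.finite(summary(rp, select = "fixed")[, "Std. Error"])) &&
        all(is.finite(summary(rp, select = "report")[, "Std. Error"]))
      cand <- list(obj = obj, opt = opt, rep = rp, se_ok = se_ok,
                   rank = 2 * se_ok + (opt$convergence == 0))
      better <- is.null(best) || cand$rank > best$rank ||
        (cand$rank == best$rank && opt$objective < best$opt$objective)
      if (better) best <- cand
      if (cand$rank == 3) break
    }
  }
  if (is.null(best)) {
    stop("TGI fit failed to converge after ", control$n_starts,
         " start(s); trace: ",
         paste(vapply(trace, function(x) x$message, ""), collapse = " | "))
  }
  obj <- best$obj
  opt <- best$opt
  if (!best$se_ok) {
    warning("Hessian not positive definite at the reported optimum; ",
            "standard errors are unreliable")
  }

  rep <- if (!is.null(best$rep)) best$rep else
    TMB::sdreport(obj, getReportCovariance = FALSE)
  sm <- summary(rep, select = "report")
  nat <- data.frame(name = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], row.names = NULL)
  nat$name <- c(THETA_NAMES, paste0("omega2_", THETA_NAMES), "sigma2")
  fitted_idx <- c(which(!is.na(theta_map)),
                  5 + which(!is.na(omega_map)), 11)
  nat <- nat[fitted_idx, , drop = FALSE]
  rse <- setNames(100 * nat$se / nat$estimate, nat$name)

  pl <- obj$env$parList(opt$par, obj$env$last.par.best)
  theta <- setNames(exp(pl$log_theta), THETA_NAMES)
  omega2 <- setNames(exp(pl$log_omega2), THETA_NAMES)
  sigma2 <- exp(pl$log_sigma2)
  eta <- pl$eta
  kg_typ <- ifelse(inp$arm_by_subj == "treatment", theta["kg_treatment"], theta["kg_control"])
  ks_typ <- ifelse(inp$arm_by_subj == "treatment", theta["ks_treatment"], theta["ks_control"])
  ebes <- data.frame(
    subject_id = inp$ids,
    arm = unname(inp$arm_by_subj),
    ts0 = unname(theta["ts0"] * exp(eta[3, ])),
    kg = unname(kg_typ * exp(eta[1, ])),
    ks = unname(ks_typ * exp(eta[2, ])),
    eta_kg = eta[1, ], eta_ks = eta[2, ], eta_ts0 = eta[3, ],
    stringsAsFactors = FALSE
  )
  ebes$log_kg <- log(ebes$kg)

  shrink <- c(
    kg_treatment = eta_shrinkage(ebes$eta_kg[ebes$arm == "treatment"], omega2[["kg_treatment"]]),
    ks_treatment = eta_shrinkage(ebes$eta_ks[ebes$arm == "treatment"], omega2[["ks_treatment"]]),
    kg_control = eta_shrinkage(ebes$eta_kg[ebes$arm == "control"], omega2[["kg_control"]]),
    ks_control = eta_shrinkage(ebes$eta_ks[ebes$arm == "control"], omega2[["ks_control"]]),
    ts0 = eta_shrinkage(ebes$eta_ts0, omega2[["ts0"]])
  )
  shrink <- shrink[is.finite(shrink)]

  structure(list(
    theta = theta[c(which(!is.na(theta_map[1:4])), 5)],
    omega2 = if (control$iiv) omega2[c(which(!is.na(theta_map[1:4])), 5)] else NULL,
    sigma2 = sigma2,
    rse = rse,
    shrinkage = if (control$iiv) shrink else NULL,
    ebes = ebes,
    loglik = -opt$objective,
    convergence = opt$convergence,
    trace = trace,
    n_subjects = n_sub,
    n_obs = length(inp$data$y),
    control = control,
    tumor = inp$tumor
  ), class = "tgi_fit")
}

#' @export
print.tgi_fit <- function(x, ...) {
  cat("<tgi_fit> biexponential TGI population model (Laplace NLME)\n")
  cat(sprintf("  %d subjects, %d observations, logLik %.2f\n",
              x$n_subjects, x$n_obs, x$loglik))
  est <- data.frame(
    estimate = signif(x$theta, 3),
    rse_pct = signif(x$rse[names(x$theta)], 3)
  )
  if (!is.null(x$omega2)) {
    est$omega2 <- signif(x$omega2[names(x$theta)], 3)
    est$iiv_cv_pct <- signif(cv_percent(x$omega2[names(x$theta)]), 3)
    est$shrinkage_pct <- signif(x$shrinkage[names(x$theta)], 3)
  }
  print(est)
  cat(sprintf("  sigma2 (residual variance): %.3g mm^2\n", x$sigma2))
  invisible(x)
}

#' @export
logLik.tgi_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$rse), class = "logLik")
}

#' Laplace marginal log-likelihood at given population parameters
#'
#' Evaluates (without optimizing the fixed effects) the Laplace approximation
#' of the marginal log-likelihood of a tumor-record table at the supplied
#' typical values, variances, and residual variance. The inner modes of the
#' random effects are found by TMB's inner Newton optimizer. Used to compare
#' the Laplace approximation against direct quadrature on small instances.
#'
#' @param tumor tumor-record data.frame (see [fit_tgi()]).
#' @param theta named typical values (`r paste(THETA_NAMES, collapse=", ")`);
#'   arms absent from the data may be omitted.
#' @param omega2 named random-effect variances, same names.
#' @param sigma2 residual variance, mm^2.
#' @return log-likelihood (scalar).
#' @export
tgi_marginal_loglik <- function(tumor, theta, omega2, sigma2) {
  control <- tgi_control()
  inp <- tgi_tmb_input(tumor, control, for_fit = FALSE)
  full <- function(x, default) {
    out <- setNames(rep(default, 5), THETA_NAMES)
    out[names(x)] <- x
    out
  }
  pars <- list(
    log_theta = log(unname(full(theta, 0.01))),
    log_omega2 = log(unname(full(omega2, 0.5))),
    log_sigma2 = log(sigma2),
    eta = matrix(0, 3, length(inp$ids))
  )
  obj <- TMB::MakeADFun(data = inp$data, parameters = pars, random = "eta",
                        DLL = "tgios", silent = TRUE)
  -as.numeric(obj$fn(obj$par))
}

#' Eta shrinkage
#'
#' Shrinkage of empirical Bayes random-effect estimates toward zero,
#' `100 * (1 - sd(eta) / sqrt(omega2))` (percent). High shrinkage means the
#' individual estimates carry little individual information and mostly
#' reflect the population value.
#'
#' @param eta numeric vector of per-subject empirical Bayes eta estimates
#'   (>= 2 values).
#' @param omega2 estimated population variance of that random effect (> 0).
#' @return shrinkage in percent.
#' @export
eta_shrinkage <- function(eta, omega2) {
  if (length(eta) < 2) return(NA_real_)
  if (!is.finite(omega2) || omega2 <= 0) {
    stop("eta shrinkage is undefined for omega2 <= 0")
  }
  100 * (1 - stats::sd(eta) / sqrt(omega2))
}

#' Coefficient of variation implied by a log-scale variance
#'
#' Reporting convention for inter-individual variability: a log-normal
#' random effect with log-scale variance `omega2` is reported as
#' `CV% = 100 * sqrt(omega2)`.
#'
#' @param omega2 log-scale variance(s).
#' @return CV in percent.
#' @export
cv_percent <- function(omega2) 100 * sqrt(omega2)

#' Goodness-of-fit table for a population TGI fit
#'
#' Per-observation population predictions (typical parameters, etas at 0),
#' individual predictions (empirical Bayes parameters), and residuals,
#' plus the observed-vs-individual-predicted correlation.
#'
#' @param fit a [fit_tgi()] result.
#' @return data.frame of class `tgi_gof` with one row per observation and
#'   attributes `cor_ipred` (observed vs individual predicted correlation)
#'   and `resid_sd` (SD of individual residuals).
#' @export
gof_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "tgi_fit"))
  tum <- fit$tumor
  i <- match(tum$subject_id, fit$ebes$subject_id)
  theta <- fit$theta
  kg_typ <- ifelse(tum$arm == "treatment", theta[["kg_treatment"]], theta[["kg_control"]])
  ks_typ <- ifelse(tum$arm == "treatment", theta[["ks_treatment"]], theta[["ks_control"]])
  ppred <- ts_model(tum$time_weeks, theta[["ts0"]], kg_typ, ks_typ)
  ipred <- ts_model(tum$time_weeks, fit$ebes$ts0[i], fit$ebes$kg[i], fit$ebes$ks[i])
  out <- data.frame(
    subject_id = tum$subject_id, arm = tum$arm, time_weeks = tum$time_weeks,
    observed = tum$sld_mm, pred_population = ppred, pred_individual = ipred,
    resid_individual = tum$sld_mm - ipred,
    stringsAsFactors = FALSE
  )
  attr(out, "cor_ipred") <- stats::cor(out$observed, out$pred_individual)
  attr(out, "resid_sd") <- stats::sd(out$resid_individual)
  class(out) <- c("tgi_gof", "data.frame")
  out
}

#' Serialize a TGI fit
#'
#' Writes the population estimates as JSON and, optionally, the per-subject
#' empirical Bayes estimates as CSV.
#'
#' @param fit a [fit_tgi()] result.
#' @param json_path output JSON path.
#' @param ebe_csv_path optional CSV path for the EBE table
#'   (`subject_id, arm, ts0, kg, ks, log_kg`).
#' @return `json_path`, invisibly.
#' @export
write_tgi_fit <- function(fit, json_path, ebe_csv_path = NULL) {
  stopifnot(inherits(fit, "tgi_fit"))
  doc <- list(
    model = "biexponential TGI, log-normal IIV, additive residual",
    theta = as.list(fit$theta),
    omega2 = as.list(fit$omega2),
    sigma2 = fit$sigma2,
    rse_percent = as.list(fit$rse),
    shrinkage_percent = as.list(fit$shrinkage),
    loglik = fit$loglik,
    n_subjects = fit$n_subjects,
    n_obs = fit$n_obs
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ebe_csv_path)) {
    write.csv(fit$ebes[, c("subject_id", "arm", "ts0", "kg", "ks", "log_kg")],
              ebe_csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
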