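DAYS_PER_MONTH <- 30.4375

#' Configuration for replicate virtual-trial simulation
#'
#' @param n_replicates number of simulated study replicates (default 1000).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @param censor_bounds length-2 numeric, days: per-patient study duration is
#'   drawn Uniform(low, high) and censors the simulated death time. Choose
#'   from the observed censoring-time range of the study being emulated.
#' @param landmark_times days at which landmark survival rates are reported
#'   (default 730 = 2 years).
#' @param uncertainty how OS-model parameters vary across replicates:
#'   `"diagonal"` (independent normal draws per coefficient using its SE,
#'   the default since published tables carry no covariance), `"none"`
#'   (point estimates), or `"full"` (multivariate normal from the fitted
#'   covariance).
#' @param time_grid_months common output grid for curve aggregation
#'   (months; default 0..60).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_replicates = 1000, seed = NULL,
                       censor_bounds = c(365, 1825), landmark_times = 730,
                       uncertainty = c("diagonal", "none", "full"),
                       time_grid_months = 0:60) {
  uncertainty <- match.arg(uncertainty)
  stopifnot(n_replicates >= 1, length(censor_bounds) == 2,
            censor_bounds[1] >= 0, censor_bounds[1] < censor_bounds[2],
            all(is.finite(censor_bounds)))
  structure(list(n_replicates = n_replicates, seed = seed,
                 censor_bounds = censor_bounds,
                 landmark_times = landmark_times, uncertainty = uncertainty,
                 time_grid_days = time_grid_months * DAYS_PER_MONTH),
            class = "sim_config")
}

#' Draw one OS-parameter vector from estimation uncertainty
#'
#' One draw of the full coefficient vector (including `log_scale`) used for
#' a single simulated study replicate. `"none"` returns the point estimates;
#' `"diagonal"` draws each coefficient independently from
#' Normal(estimate, se^2); `"full"` draws from the multivariate normal with
#' the model's covariance.
#'
#' @param model an `os_model` (SEs required unless mode is `"none"`;
#'   covariance required for `"full"`).
#' @param mode `"none"`, `"diagonal"`, or `"full"`.
#' @return named numeric vector of coefficients.
#' @export
sample_parameters <- function(model, mode = c("diagonal", "none", "full")) {
  mode <- match.arg(mode)
  est <- os_coef_vector(model)
  if (mode == "none") return(est)
  if (mode == "full") {
    if (is.null(model$vcov)) stop("full-covariance sampling needs a fitted covariance matrix")
    L <- chol(model$vcov)
    return(est + drop(rnorm(length(est)) %*% L))
  }
  se <- setNames(model$coefficients$se, model$coefficients$term)
  if (anyNA(se)) stop("diagonal sampling needs a standard error for every coefficient")
  est + rnorm(length(est), 0, se[names(est)])
}

#' Simulate one patient's observed survival time under uniform censoring
#'
#' Death time `T ~ LogNormal(mu, scale)`; study duration
#' `C ~ Uniform(censor_bounds)`. The observed time is `min(T, C)` with event
#' indicator `T <= C`. Vectorized over `mu`.
#'
#' @param mu location(s) on the log-day scale.
#' @param scale SD of log OS.
#' @param censor_bounds length-2 days.
#' @return data.frame with `time` (days) and `event` (0/1).
#' @export
simulate_patient <- function(mu, scale, censor_bounds) {
  n <- length(mu)
  T <- rlnorm(n, meanlog = mu, sdlog = scale)
  C <- runif(n, censor_bounds[1], censor_bounds[2])
  data.frame(time = pmin(T, C), event = as.integer(T <= C))
}

#' Kaplan-Meier estimate as an evaluable step function
#'
#' Product-limit estimator (via [survival::survfit()]) returned as a
#' right-continuous step function representation.
#'
#' @param time observed times, days.
#' @param event 1 = event, 0 = censored.
#' @return object of class `km_curve`: `time` (sorted unique times) and
#'   `surv` (survival just after each time).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = sf$time, surv = sf$surv), class = "km_curve")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a [km_estimate()] result.
#' @param t times (days) at which to evaluate; survival is 1 before the
#'   first observed time and constant after the last.
#' @return survival probabilities.
#' @export
km_eval <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$time) + 1]
}

#' Cox proportional-hazards hazard ratio, treatment vs control
#'
#' `exp(beta)` from the Cox partial likelihood with Efron tie handling for a
#' binary treatment indicator. Returns `NA` (with a `reason` attribute) when
#' the partial likelihood is monotone, i.e. an arm has no events.
#'
#' @param time observed times, days.
#' @param event 1 = event, 0 = censored.
#' @param arm character ("treatment"/"control") or 0/1 indicator
#'   (1 = treatment).
#' @return hazard ratio (scalar), or `NA` when not estimable.
#' @export
cox_hr <- function(time, event, arm) {
  x <- if (is.numeric(arm)) arm else as.numeric(arm == "treatment")
  if (length(unique(x)) < 2) stop("both arms must be represented")
  if (sum(event) < 1) stop("at least one event is required")
  ev_by_arm <- tapply(event, x, sum)
  if (any(ev_by_arm == 0)) {
    return(structure(NA_real_, reason = "no events in one arm"))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  unname(exp(stats::coef(fit)))
}

#' Simulate replicate virtual trials and aggregate OS predictions
#'
#' For each replicate: draw one OS-parameter vector from estimation
#' uncertainty, compute each subject's location `mu` from their baseline
#' covariates and individual log(KG), simulate death and uniform censoring
#' times, then summarize the replicate by per-arm Kaplan-Meier curves on a
#' common time grid, landmark survival rates, and the Cox hazard ratio of
#' treatment vs control. Replicate summaries are aggregated to medians and
#' 2.5/97.5 percentiles (95% prediction intervals).
#'
#' @param model an `os_model`.
#' @param subjects data.frame with columns `arm`
#'   ("treatment"/"control") and every design term of the model (from
#'   [os_design()], joined with the arm).
#' @param cfg a [sim_config()].
#' @return object of class `sim_summary`: `curves` (arm, time_days, median,
#'   lo, hi), `landmarks` (arm, time_days, median, lo, hi, in percent),
#'   `hr` (median, lo, hi), `hr_replicates`, `n_hr_failed`, `config`.
#' @export
run_simulation <- function(model, subjects, cfg = sim_config()) {
  stopifnot(inherits(model, "os_model"), inherits(cfg, "sim_config"))
  if (!"arm" %in% names(subjects)) stop("subjects needs an 'arm' column")
  bad_arm <- setdiff(unique(subjects$arm), ARM_LEVELS)
  if (length(bad_arm)) stop("unknown arm level(s): ", paste(bad_arm, collapse = ", "))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  grid <- cfg$time_grid_days
  arms <- ARM_LEVELS[ARM_LEVELS %in% unique(subjects$arm)]
  R <- cfg$n_replicates
  curve_acc <- lapply(arms, function(a) matrix(NA_real_, R, length(grid)))
  names(curve_acc) <- arms
  lm_acc <- lapply(arms, function(a) matrix(NA_real_, R, length(cfg$landmark_times)))
  names(lm_acc) <- arms
  hrs <- rep(NA_real_, R)
  hr_reasons <- character()

  base_design <- subjects[, setdiff(names(subjects), "arm"), drop = FALSE]
  for (r in seq_len(R)) {
    co <- sample_parameters(model, cfg$uncertainty)
    terms <- setdiff(names(co), c("(Intercept)", "log_scale"))
    X <- design_matrix(base_design, terms)
    mu <- drop(co[["(Intercept)"]] + X %*% co[terms])
    scale_r <- exp(co[["log_scale"]])
    sim <- simulate_patient(mu, scale_r, cfg$censor_bounds)
    for (a in arms) {
      sel <- subjects$arm == a
      km <- km_estimate(sim$time[sel], sim$event[sel])
      curve_acc[[a]][r, ] <- km_eval(km, grid)
      lm_acc[[a]][r, ] <- km_eval(km, cfg$landmark_times)
    }
    if (length(arms) == 2) {
      hr <- if (sum(sim$event) == 0) {
        structure(NA_real_, reason = "no events in replicate")
      } else {
        cox_hr(sim$time, sim$event, subjects$arm)
      }
      if (is.na(hr)) hr_reasons <- c(hr_reasons, attr(hr, "reason")) else hrs[r] <- hr
    }
  }

  qs <- function(m) apply(m, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  curves <- do.call(rbind, lapply(arms, function(a) {
    q <- qs(curve_acc[[a]])
    data.frame(arm = a, time_days = grid, median = q[1, ], lo = q[2, ],
               hi = q[3, ], stringsAsFactors = FALSE)
  }))
  landmarks <- do.call(rbind, lapply(arms, function(a) {
    q <- qs(lm_acc[[a]]) * 100
    data.frame(arm = a, time_days = cfg$landmark_times, median = q[1, ],
               lo = q[2, ], hi = q[3, ], stringsAsFactors = FALSE)
  }))
  hr_sum <- if (length(arms) == 2) {
    ok <- hrs[!is.na(hrs)]
    if (length(ok)) setNames(quantile(ok, c(0.5, 0.025, 0.975), names = FALSE),
                             c("median", "lo", "hi"))
    else c(median = NA_real_, lo = NA_real_, hi = NA_real_)
  } else NULL

  structure(list(curves = curves, landmarks = landmarks, hr = hr_sum,
                 hr_replicates = hrs, n_hr_failed = length(hr_reasons),
                 hr_failure_reasons = table(hr_reasons), config = cfg),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("<sim_summary>", x$config$n_replicates, "replicate virtual trials\n")
  if (!is.null(x$hr)) {
    cat(sprintf("  HR treatment vs control: %.3f (95%% PI %.3f-%.3f)",
                x$hr[["median"]], x$hr[["lo"]], x$hr[["hi"]]))
    if (x$n_hr_failed > 0) cat(sprintf("  [%d replicate(s) not estimable]", x$n_hr_failed))
    cat("\n")
  }
  cat("  landmark survival (%):\n")
  lm <- x$landmarks
  lm$median <- round(lm$median, 1); lm$lo <- round(lm$lo, 1); lm$hi <- round(lm$hi, 1)
  print(lm, row.names = FALSE)
  invisible(x)
}

#' Export a simulation summary
#'
#' Writes the aggregated curves/landmarks/HR as JSON, the curve grid as a
#' tidy CSV (arm, time_days, median, lo, hi), and optionally the
#' per-replicate hazard ratios for audit.
#'
#' @param x a `sim_summary`.
#' @param json_path,curves_csv_path,hr_csv_path output paths (`NULL` skips).
#' @return `json_path`, invisibly.
#' @export
write_sim_summary <- function(x, json_path, curves_csv_path = NULL,
                              hr_csv_path = NULL) {
  stopifnot(inherits(x, "sim_summary"))
  doc <- list(
    n_replicates = x$config$n_replicates,
    uncertainty = x$config$uncertainty,
    censor_bounds_days = x$config$censor_bounds,
    hr = as.list(x$hr),
    n_hr_failed = x$n_hr_failed,
    landmarks = x$landmarks,
    curves = x$curves
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(curves_csv_path)) write.csv(x$curves, curves_csv_path, row.names = FALSE)
  if (!is.null(hr_csv_path)) {
    write.csv(data.frame(replicate = seq_along(x$hr_replicates), hr = x$hr_replicates),
              hr_csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
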