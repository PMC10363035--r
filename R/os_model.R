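OS_TERMS <- c("log_kg", "albumin", "ecog_ge1", "race_asian", "n_met_sites",
              "nlr", "liver_met", "baseline_sld", "line_2plus", "sex_female")

#' Build the OS design table from baseline covariates and individual log(KG)
#'
#' Translates a covariate table (see [trial_dataset()]) plus per-subject
#' natural-log tumor growth rate constants into the numeric design used by
#' the TGI-OS survival model. Reference coding: ECOG >= 1 vs 0, Asian vs
#' non-Asian, liver metastasis yes vs no, line of therapy 2+ vs 1, female vs
#' male. The number of metastatic sites is capped at 5 ([cap_met_sites()]).
#'
#' @param covariates covariate data.frame (one row per subject).
#' @param log_kg named numeric vector (names = subject_id) or a data.frame
#'   with columns `subject_id` and `log_kg`; `kg` is in week^-1 and the log
#'   is natural.
#' @return data.frame with `subject_id` and numeric columns
#'   `r paste(OS_TERMS, collapse=", ")`. Subjects with any missing value are
#'   kept (rows with `NA`); drop them explicitly before fitting.
#' @export
os_design <- function(covariates, log_kg) {
  validate_covariates(covariates)
  if (is.data.frame(log_kg)) {
    log_kg <- setNames(log_kg$log_kg, log_kg$subject_id)
  }
  lk <- unname(log_kg[covariates$subject_id])
  data.frame(
    subject_id = covariates$subject_id,
    log_kg = lk,
    albumin = covariates$albumin,
    ecog_ge1 = as.numeric(covariates$ecog >= 1),
    race_asian = as.numeric(covariates$race == "Asian"),
    n_met_sites = cap_met_sites(covariates$n_met_sites),
    nlr = covariates$nlr,
    liver_met = as.numeric(covariates$liver_met == "yes"),
    baseline_sld = covariates$baseline_sld,
    line_2plus = as.numeric(covariates$line_of_therapy == "2+"),
    sex_female = as.numeric(covariates$sex == "female"),
    stringsAsFactors = FALSE
  )
}

design_matrix <- function(design, terms) {
  miss <- setdiff(terms, names(design))
  if (length(miss)) stop("design is missing covariate(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(design[, terms, drop = FALSE])
  if (anyNA(X)) {
    bad <- terms[colSums(is.na(X)) > 0]
    stop("missing covariate value(s) in: ", paste(bad, collapse = ", "))
  }
  storage.mode(X) <- "double"
  X
}

#' Log-likelihood of the log-normal AFT model
#'
#' Censored log-normal likelihood on the day scale: with location
#' `mu = intercept + X beta` and scale `s` (SD of log OS), a death at `t`
#' contributes `log(dnorm(log t, mu, s)) - log t` and a censored time
#' contributes `log(1 - pnorm((log t - mu)/s))`.
#'
#' @param coef named numeric vector: `(Intercept)`, the covariate
#'   coefficients (a subset of `r paste(OS_TERMS, collapse=", ")`), and
#'   `log_scale`.
#' @param time survival/censoring times in days (> 0).
#' @param event 1 = death, 0 = censored.
#' @param design design data.frame from [os_design()].
#' @return scalar log-likelihood.
#' @export
os_loglik <- function(coef, time, event, design) {
  terms <- setdiff(names(coef), c("(Intercept)", "log_scale"))
  X <- design_matrix(design, terms)
  mu <- coef[["(Intercept)"]] + drop(X %*% coef[terms])
  s <- exp(coef[["log_scale"]])
  z <- (log(time) - mu) / s
  ll_event <- dnorm(z, log = TRUE) - log(s) - log(time)
  ll_cens <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  sum(ifelse(event == 1, ll_event, ll_cens))
}

#' Fit the log-normal accelerated failure time OS model
#'
#' Censored maximum-likelihood fit of log(OS in days) ~ Normal(mu, scale^2)
#' with `mu` linear in log(KG) and baseline prognostic factors. Standard
#' errors come from the inverse observed information at the MLE; `z` is the
#' Wald statistic `beta/se` with two-sided normal p-values. The scale is
#' estimated as `log_scale` for positivity.
#'
#' @param time survival/censoring times in days (> 0).
#' @param event 1 = death, 0 = censored; at least one event required.
#' @param design design data.frame from [os_design()] (the `subject_id`
#'   column, if present, is ignored for fitting).
#' @param terms covariate columns to include; default all of
#'   `r paste(OS_TERMS, collapse=", ")` that are present in `design`.
#' @return object of class `os_model`: `coefficients` data.frame
#'   (term, estimate, se, z, p), `scale`, `loglik`, `vcov`, `n`, `n_events`.
#' @export
fit_os <- function(time, event, design, terms = NULL) {
  stopifnot(length(time) == nrow(design), length(event) == length(time))
  if (any(time <= 0)) stop("OS times must be > 0 days")
  if (sum(event) == 0) stop("cannot fit the OS model with zero events")
  if (is.null(terms)) terms <- intersect(OS_TERMS, names(design))
  X <- design_matrix(design, terms)
  Xi <- cbind("(Intercept)" = 1, X)
  qr_rank <- qr(Xi)$rank
  if (qr_rank < ncol(Xi)) {
    drop_candidates <- colnames(Xi)[qr(Xi)$pivot[-seq_len(qr_rank)]]
    stop("singular design; collinear column(s): ",
         paste(drop_candidates, collapse = ", "))
  }
  lt <- log(time)
  start <- c(mean(lt), rep(0, length(terms)), log(max(stats::sd(lt), 1e-3)))
  nll <- function(par) {
    mu <- drop(Xi %*% par[seq_len(ncol(Xi))])
    s <- exp(par[length(par)])
    z <- (lt - mu) / s
    ll <- ifelse(event == 1,
                 dnorm(z, log = TRUE) - log(s) - lt,
                 pnorm(z, lower.tail = FALSE, log.p = TRUE))
    -sum(ll)
  }
  ngr <- function(par) {
    mu <- drop(Xi %*% par[seq_len(ncol(Xi))])
    s <- exp(par[length(par)])
    z <- (lt - mu) / s
    # censored subjects contribute through the hazard of the normal on log t
    h <- exp(dnorm(z, log = TRUE) - pnorm(z, lower.tail = FALSE, log.p = TRUE))
    g_mu <- ifelse(event == 1, -z / s, -h / s)
    g_ls <- ifelse(event == 1, 1 - z^2, -z * h)
    c(drop(crossprod(Xi, g_mu)), sum(g_ls))
  }
  opt <- optim(start, nll, gr = ngr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    stop("OS model did not converge (optim code ", opt$convergence, ")")
  }
  # gradient-based polish: BFGS can stall slightly short on a flat ridge
  pol <- nlminb(opt$par, nll, ngr,
                control = list(iter.max = 500, rel.tol = 1e-15, x.tol = 1e-12))
  if (is.finite(pol$objective) && pol$objective <= opt$value) {
    opt$par <- pol$par
    opt$value <- pol$objective
  }
  H <- optimHess(opt$par, nll)
  V <- tryCatch(solve(H), error = function(e) {
    stop("observed information is singular at the optimum")
  })
  nm <- c("(Intercept)", terms, "log_scale")
  est <- setNames(opt$par, nm)
  se <- setNames(sqrt(pmax(diag(V), 0)), nm)
  z <- est / se
  coefs <- data.frame(
    term = nm, estimate = unname(est), se = unname(se), z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    scale = exp(est[["log_scale"]]),
    loglik = -opt$value,
    vcov = structure(V, dimnames = list(nm, nm)),
    terms = terms,
    n = length(time),
    n_events = sum(event)
  ), class = "os_model")
}

#' @export
print.os_model <- function(x, ...) {
  cat("<os_model> log-normal AFT for overall survival (days)\n")
  cat(sprintf("  n = %d (%d events), logLik %.2f, scale %.4f\n",
              x$n, x$n_events, x$loglik, x$scale))
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 3)
  co$se <- signif(co$se, 3)
  co$z <- round(co$z, 2)
  co$p <- signif(co$p, 2)
  print(co, row.names = FALSE)
  invisible(x)
}

os_coef_vector <- function(model) {
  setNames(model$coefficients$estimate, model$coefficients$term)
}

#' Location of log(OS) for given subjects under an OS model
#'
#' Computes `mu = intercept + sum(beta * x)` per subject, on the log-day
#' scale. The median predicted OS of a subject is `exp(mu)` days.
#'
#' @param model an `os_model` (from [fit_os()] or [os_model_from_table()]).
#' @param design design data.frame from [os_design()] containing every term
#'   of the model.
#' @return numeric vector of locations, one per design row.
#' @export
linear_predictor <- function(model, design) {
  stopifnot(inherits(model, "os_model"))
  co <- os_coef_vector(model)
  terms <- setdiff(names(co), c("(Intercept)", "log_scale"))
  X <- design_matrix(design, terms)
  drop(co[["(Intercept)"]] + X %*% co[terms])
}

#' Log-normal survival function
#'
#' `S(t) = 1 - Phi((log t - mu) / scale)` for OS time `t` in days.
#'
#' @param t time in days (> 0; vectorized over `t` or `mu`).
#' @param mu location on the log-day scale.
#' @param scale SD of log OS (> 0).
#' @return survival probability.
#' @export
survival_function <- function(t, mu, scale) {
  stopifnot(all(t > 0), scale > 0)
  pnorm((log(t) - mu) / scale, lower.tail = FALSE)
}

#' Backward covariate elimination for the OS model
#'
#' Repeatedly refits the AFT model, dropping the least significant covariate
#' (largest Wald p) while any droppable p exceeds `alpha`. `log_kg` is the
#' model's core tumor-dynamics term and is never dropped; nor are the
#' intercept and scale.
#'
#' @inheritParams fit_os
#' @param alpha Wald p-value retention threshold (default 0.01).
#' @return the final `os_model`, with an `elimination` attribute recording
#'   each dropped term and its p-value at removal.
#' @export
select_covariates <- function(time, event, design, terms = NULL, alpha = 0.01) {
  if (is.null(terms)) terms <- intersect(OS_TERMS, names(design))
  if (!"log_kg" %in% terms) stop("candidate set must include log_kg")
  trace <- list()
  repeat {
    model <- fit_os(time, event, design, terms)
    co <- model$coefficients
    droppable <- co[!co$term %in% c("(Intercept)", "log_scale", "log_kg"), ]
    if (nrow(droppable) == 0 || max(droppable$p) <= alpha) break
    worst <- droppable$term[which.max(droppable$p)]
    trace[[length(trace) + 1]] <- data.frame(term = worst,
                                             p = max(droppable$p))
    terms <- setdiff(terms, worst)
  }
  attr(model, "elimination") <- if (length(trace)) do.call(rbind, trace) else
    data.frame(term = character(), p = numeric())
  model
}

#' Construct an OS model from a typed-in coefficient table
#'
#' Builds an `os_model` directly from a published coefficient table
#' (term, estimate, SE) so simulations can run without refitting. Terms must
#' use the canonical names (`(Intercept)`, `r paste(OS_TERMS, collapse=", ")`,
#' `log_scale`); a subset of covariate terms is allowed.
#'
#' @param table data.frame with columns `term`, `estimate`, and optionally
#'   `se` (required for parameter-uncertainty simulation).
#' @return an `os_model` (without `loglik`/`vcov`; SEs diagonal if given).
#' @export
os_model_from_table <- function(table) {
  need <- c("term", "estimate")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("coefficient table missing column(s): ", paste(miss, collapse = ", "))
  if (!"(Intercept)" %in% table$term) stop("coefficient table needs an (Intercept) row")
  if (!"log_scale" %in% table$term) stop("coefficient table needs a log_scale row")
  unknown <- setdiff(table$term, c("(Intercept)", OS_TERMS, "log_scale"))
  if (length(unknown)) stop("unknown term(s): ", paste(unknown, collapse = ", "))
  se <- if ("se" %in% names(table)) table$se else rep(NA_real_, nrow(table))
  z <- table$estimate / se
  coefs <- data.frame(term = table$term, estimate = table$estimate, se = se,
                      z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  ord <- order(match(coefs$term, c("(Intercept)", OS_TERMS, "log_scale")))
  coefs <- coefs[ord, , drop = FALSE]
  rownames(coefs) <- NULL
  structure(list(
    coefficients = coefs,
    scale = exp(coefs$estimate[coefs$term == "log_scale"]),
    loglik = NA_real_,
    vcov = NULL,
    terms = setdiff(coefs$term, c("(Intercept)", "log_scale")),
    n = NA_integer_, n_events = NA_integer_
  ), class = "os_model")
}

#' Read/write an OS model as JSON or CSV
#'
#' `write_os_model` serializes the coefficient table (term, estimate, se, z,
#' p), the scale, and — for fitted models — the coefficient covariance
#' matrix as JSON; `read_os_model_json` restores it (enabling
#' full-covariance parameter sampling). `read_os_model_csv` rebuilds a model
#' from a plain CSV coefficient table via [os_model_from_table()], e.g. a
#' published table typed in directly.
#'
#' @param model an `os_model`.
#' @param path file path.
#' @return `path` (write) or an `os_model` (read).
#' @export
write_os_model <- function(model, path) {
  stopifnot(inherits(model, "os_model"))
  doc <- list(model = "log-normal AFT, OS in days",
              coefficients = model$coefficients,
              scale = model$scale, loglik = model$loglik,
              n = model$n, n_events = model$n_events,
              vcov = model$vcov)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_os_model
#' @export
read_os_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- os_model_from_table(doc$coefficients)
  model$coefficients <- doc$coefficients
  model$loglik <- doc$loglik
  model$n <- doc$n
  model$n_events <- doc$n_events
  if (!is.null(doc$vcov)) {
    v <- as.matrix(doc$vcov)
    dimnames(v) <- list(model$coefficients$term, model$coefficients$term)
    model$vcov <- v
  }
  model
}

#' @rdname write_os_model
#' @export
read_os_model_csv <- function(path) {
  os_model_from_table(read.csv(path, stringsAsFactors = FALSE))
}
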