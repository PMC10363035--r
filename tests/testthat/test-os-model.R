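# design row builder with reference-level covariates
ref_design <- function(log_kg = 0, albumin = 0, ecog_ge1 = 0, race_asian = 0,
                       n_met_sites = 0, nlr = 0, liver_met = 0, baseline_sld = 0,
                       line_2plus = 0, sex_female = 0) {
  data.frame(log_kg = log_kg, albumin = albumin, ecog_ge1 = ecog_ge1,
             race_asian = race_asian, n_met_sites = n_met_sites, nlr = nlr,
             liver_met = liver_met, baseline_sld = baseline_sld,
             line_2plus = line_2plus, sex_female = sex_female)
}

test_that("linear predictor reproduces hand arithmetic over the coefficients", {
  m <- default_os_truth()
  # all covariates zero and log_kg = 0: mu equals the intercept
  expect_equal(linear_predictor(m, ref_design()), 2.87)
  # typical first-line male non-Asian patient; independent hand computation
  d <- ref_design(log_kg = log(0.00438), albumin = 40, n_met_sites = 2,
                  nlr = 4, baseline_sld = 57)
  by_hand <- 2.87 + (-0.642) * log(0.00438) + 0.0262 * 40 +
    (-0.0733) * 2 + (-0.0138) * 4 + (-0.00122) * 57
  expect_equal(linear_predictor(m, d), by_hand, tolerance = 1e-12)
  expect_equal(linear_predictor(m, d), 7.13319, tolerance = 1e-5)
  # exp(mu) is a plausible first-line median OS (around 41 months)
  expect_equal(exp(by_hand) / 30.4375, 41.2, tolerance = 0.01)
  # slower growth means longer predicted survival, all else equal
  d_slow <- d; d_slow$log_kg <- log(0.00196)
  expect_gt(linear_predictor(m, d_slow), linear_predictor(m, d))
})

test_that("missing covariates are reported by name", {
  m <- default_os_truth()
  d <- ref_design(); d$nlr <- NULL
  expect_error(linear_predictor(m, d), "nlr")
  d2 <- ref_design(); d2$albumin <- NA
  expect_error(linear_predictor(m, d2), "albumin")
})

test_that("survival function is the log-normal tail with the fitted scale", {
  # median: S(exp(mu)) = 1/2
  expect_equal(survival_function(exp(7.2), 7.2, 0.8), 0.5)
  # limit at t -> 0+
  expect_equal(survival_function(1e-12, 7.2, 0.8), 1)
  # frozen value from an independent normal-CDF evaluation
  expect_equal(survival_function(730, 7.0, exp(-0.225)),
               pnorm((log(730) - 7.0) / exp(-0.225), lower.tail = FALSE))
  expect_equal(survival_function(730, 7.0, 0.7985), 0.694852, tolerance = 1e-5)
  # monotone decreasing in t
  tt <- c(1, 10, 100, 1000, 5000)
  expect_true(all(diff(survival_function(tt, 7, 0.8)) < 0))
})

test_that("AFT log-likelihood equals term-by-term summation on a 5-subject toy", {
  d <- do.call(rbind, lapply(1:5, function(i) ref_design()))
  d$log_kg <- c(-6.2, -5.4, -4.8, -5.9, -5.1)
  d$albumin <- c(35, 40, 42, 38, 44)
  time <- c(400, 800, 150, 1200, 600)
  event <- c(1, 0, 1, 0, 1)
  coef <- c("(Intercept)" = 2.9, log_kg = -0.6, albumin = 0.03,
            log_scale = -0.2)
  s <- exp(-0.2)
  mu <- 2.9 - 0.6 * d$log_kg + 0.03 * d$albumin
  by_hand <- 0
  for (i in 1:5) {
    by_hand <- by_hand + if (event[i] == 1) {
      log(dnorm((log(time[i]) - mu[i]) / s) / (s * time[i]))
    } else {
      log(1 - pnorm((log(time[i]) - mu[i]) / s))
    }
  }
  expect_equal(os_loglik(coef, time, event, d[c("log_kg", "albumin")]),
               by_hand, tolerance = 1e-12)
})

test_that("uncensored intercept-only fit matches the closed-form MLE", {
  set.seed(5)
  time <- rlnorm(400, 6.5, 0.7)
  event <- rep(1, 400)
  m <- fit_os(time, event, data.frame(row.names = seq_along(time)),
              terms = character(0))
  lt <- log(time)
  expect_equal(m$coefficients$estimate[m$coefficients$term == "(Intercept)"],
               mean(lt), tolerance = 1e-6)
  # ML scale uses the n denominator
  expect_equal(m$scale, sqrt(mean((lt - mean(lt))^2)), tolerance = 1e-6)
})

test_that("censored ML fit agrees with an independent AFT implementation", {
  set.seed(12)
  n <- 400
  d <- ref_design(log_kg = rnorm(n, -5.5, 1), albumin = rnorm(n, 40, 4),
                  ecog_ge1 = rbinom(n, 1, 0.5), sex_female = rbinom(n, 1, 0.5))
  mu <- 2.9 - 0.6 * d$log_kg + 0.026 * d$albumin - 0.27 * d$ecog_ge1 +
    0.08 * d$sex_female
  death <- rlnorm(n, mu, 0.8)
  cens <- runif(n, 300, 3000)
  time <- pmin(death, cens); event <- as.integer(death <= cens)
  terms <- c("log_kg", "albumin", "ecog_ge1", "sex_female")
  m <- fit_os(time, event, d, terms)
  sr <- survival::survreg(
    survival::Surv(time, event) ~ log_kg + albumin + ecog_ge1 + sex_female,
    data = d, dist = "lognormal",
    control = survival::survreg.control(rel.tolerance = 1e-12))
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  # the likelihood ridge is flat in (intercept, albumin); allow survreg's
  # looser stopping rule a little coefficient slop
  expect_equal(unname(est[c("(Intercept)", terms)]), unname(coef(sr)),
               tolerance = 0.01)
  expect_equal(m$scale, sr$scale, tolerance = 1e-4)
  expect_gte(m$loglik, sr$loglik[2] - 1e-6)
  expect_gte(m$loglik, sr$loglik[2] - 1e-4)
  # Wald machinery: z = beta/se, SEs close to survreg's
  expect_equal(m$coefficients$z, m$coefficients$estimate / m$coefficients$se)
  expect_equal(unname(m$coefficients$se[match(terms, m$coefficients$term)]),
               unname(sqrt(diag(sr$var))[2:5]), tolerance = 0.02)
})

test_that("location-family invariance: rescaling time shifts only the intercept", {
  set.seed(21)
  n <- 300
  d <- ref_design(log_kg = rnorm(n, -5.5, 1), albumin = rnorm(n, 40, 4))
  mu <- 2.9 - 0.6 * d$log_kg + 0.026 * d$albumin
  death <- rlnorm(n, mu, 0.8)
  cens <- runif(n, 300, 3000)
  time <- pmin(death, cens); event <- as.integer(death <= cens)
  terms <- c("log_kg", "albumin")
  m1 <- fit_os(time, event, d, terms)
  m2 <- fit_os(time * 3, event, d, terms)
  e1 <- setNames(m1$coefficients$estimate, m1$coefficients$term)
  e2 <- setNames(m2$coefficients$estimate, m2$coefficients$term)
  expect_equal(e2[["(Intercept)"]] - e1[["(Intercept)"]], log(3), tolerance = 1e-5)
  expect_equal(e1[c(terms, "log_scale")], e2[c(terms, "log_scale")],
               tolerance = 1e-5)
})

test_that("recovered fits reproduce the published effect directions", {
  set.seed(77)
  n <- 1500
  arm <- rep(c("treatment", "control"), each = n / 2)
  cov <- sample_covariates(n, covariate_config(p_line2 = 0.25),
                           ids = sprintf("S%05d", seq_len(n)))
  par <- sample_tgi_params(arm)
  cov$baseline_sld <- par$ts0
  des <- os_design(cov, setNames(par$log_kg, cov$subject_id))
  osim <- generate_os(des, censor_bounds = c(700, 4000))
  m <- fit_os(osim$os$os_days, osim$os$event, des)
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_true(all(est[c("albumin", "race_asian", "sex_female")] > 0))
  expect_true(all(est[c("log_kg", "ecog_ge1", "n_met_sites", "nlr",
                        "liver_met", "baseline_sld", "line_2plus")] < 0))
})

test_that("backward elimination drops noise covariates and never log_kg", {
  set.seed(33)
  n <- 800
  d <- ref_design(log_kg = rnorm(n, -5.5, 1), albumin = rnorm(n, 40, 4))
  d$noise <- rnorm(n)
  mu <- 0.74 - 0.6 * d$log_kg + 0.08 * d$albumin
  death <- rlnorm(n, mu, 0.8)
  cens <- runif(n, 300, 4000)
  time <- pmin(death, cens); event <- as.integer(death <= cens)
  # pure-noise covariate is eliminated at alpha = 0.01
  m <- select_covariates(time, event, d, terms = c("log_kg", "albumin", "noise"))
  expect_false("noise" %in% m$coefficients$term)
  expect_true(all(c("log_kg", "albumin") %in% m$coefficients$term))
  expect_equal(attr(m, "elimination")$term, "noise")
  # alpha = 1 keeps the full model
  m_full <- select_covariates(time, event, d,
                              terms = c("log_kg", "albumin", "noise"), alpha = 1)
  expect_true("noise" %in% m_full$coefficients$term)
  expect_equal(nrow(attr(m_full, "elimination")), 0)
  # log_kg is retained even when it carries no signal
  d2 <- d; d2$log_kg <- rnorm(n)
  death2 <- rlnorm(n, 6.5, 0.8)
  m2 <- select_covariates(pmin(death2, cens), as.integer(death2 <= cens),
                          d2, terms = c("log_kg", "albumin"))
  expect_true("log_kg" %in% m2$coefficients$term)
})

test_that("degenerate fits fail loudly", {
  d <- ref_design(log_kg = rnorm(20))
  expect_error(fit_os(rlnorm(20, 6, 1), rep(0, 20), d, "log_kg"), "zero events")
  d$dup <- d$log_kg
  expect_error(fit_os(rlnorm(20, 6, 1), rep(1, 20), d, c("log_kg", "dup")),
               "collinear")
})

test_that("a typed-in coefficient table round-trips through CSV", {
  m <- default_os_truth()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "os_model.csv")
  write.csv(m$coefficients[, c("term", "estimate", "se")], path, row.names = FALSE)
  back <- read_os_model_csv(path)
  expect_equal(back$coefficients$estimate, m$coefficients$estimate)
  expect_equal(back$scale, exp(-0.225))
  expect_equal(back$coefficients$z, back$coefficients$estimate / back$coefficients$se)
  # full published table has 10 covariate rows plus intercept and log(scale)
  expect_equal(nrow(m$coefficients), 12)
})
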