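test_that("parameter draws respect the requested uncertainty mode", {
  m <- default_os_truth()
  expect_equal(sample_parameters(m, "none"),
               setNames(m$coefficients$estimate, m$coefficients$term))
  set.seed(4)
  draws <- t(replicate(10000, sample_parameters(m, "diagonal")))
  se_hat <- apply(draws, 2, sd)
  se <- setNames(m$coefficients$se, m$coefficients$term)
  expect_equal(unname(se_hat), unname(se[colnames(draws)]), tolerance = 0.05)
  expect_equal(unname(colMeans(draws)),
               unname(setNames(m$coefficients$estimate, m$coefficients$term)[colnames(draws)]),
               tolerance = 0.05)
  # a zero-SE coefficient stays fixed across draws
  tab <- m$coefficients[, c("term", "estimate", "se")]
  tab$se[tab$term == "log_kg"] <- 0
  m0 <- os_model_from_table(tab)
  d0 <- t(replicate(50, sample_parameters(m0, "diagonal")))
  expect_equal(unname(d0[, "log_kg"]), rep(-0.642, 50))
  # full mode without a covariance matrix is an error
  expect_error(sample_parameters(m, "full"), "covariance")
})

test_that("patient simulation reproduces the censoring integral", {
  set.seed(9)
  # effectively no censoring: every patient dies on study
  s1 <- simulate_patient(rep(7, 500), 0.8, c(1e7, 1e8))
  expect_true(all(s1$event == 1))
  # immediate cutoff: everyone censored
  s2 <- simulate_patient(rep(7, 500), 0.8, c(0, 1e-9))
  expect_true(all(s2$event == 0))
  # event fraction matches the 1-D integral P(T <= C)
  n <- 1e5
  s3 <- simulate_patient(rep(7, n), 0.8, c(0, 1825))
  p_event <- integrate(function(c) plnorm(c, 7, 0.8) / 1825, 0, 1825)$value
  expect_equal(mean(s3$event), p_event, tolerance = 3 * sqrt(p_event * (1 - p_event) / n) / p_event)
})

test_that("Kaplan-Meier estimator matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_eval(km, c(0.5, 1, 2, 3, 10)), c(1, 2/3, 1/3, 0, 0))
  # 5-subject table with censoring, product-limit by hand:
  # risk sets 5,4,3 at event times 10,20,40 (censored at 15, 50)
  km2 <- km_estimate(c(10, 15, 20, 40, 50), c(1, 0, 1, 1, 0))
  expect_equal(km_eval(km2, c(10, 20, 40, 60)),
               c(4/5, 4/5 * 2/3, 4/5 * 2/3 * 1/2, 4/5 * 2/3 * 1/2))
  # all censored: survival stays at 1
  km3 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_equal(km_eval(km3, c(1, 10)), c(1, 1))
  # single event drops to 0
  km4 <- km_estimate(3, 1)
  expect_equal(km_eval(km4, c(2.9, 3.1)), c(1, 0))
})

test_that("Cox hazard ratio matches brute-force partial-likelihood maximization", {
  time <- c(5, 8, 12, 20, 25, 33)
  event <- c(1, 1, 1, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  hr <- cox_hr(time, event, x)
  expect_equal(hr, cox_brute_force_hr(time, event, x), tolerance = 1e-5)
  # label swap inverts the ratio
  expect_equal(cox_hr(time, event, 1 - x), 1 / hr, tolerance = 1e-8)
  # exchangeable arms: duplicating the same outcomes in both arms gives HR 1
  hr_null <- cox_hr(rep(time, 2), rep(event, 2), rep(c(1, 0), each = 6))
  expect_equal(hr_null, 1, tolerance = 1e-6)
  # an arm without events is flagged as not estimable
  hr_na <- cox_hr(c(5, 6, 7, 8), c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_true(is.na(hr_na))
  expect_match(attr(hr_na, "reason"), "no events")
})

sim_subjects <- function(n_per_arm = 40, seed = 15, identical_mu = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_arm
  arm <- rep(c("treatment", "control"), each = n_per_arm)
  cov <- sample_covariates(n, ids = sprintf("P%04d", seq_len(n)))
  par <- sample_tgi_params(if (identical_mu) rep("control", n) else arm)
  cov$baseline_sld <- par$ts0
  cbind(arm = arm, os_design(cov, setNames(par$log_kg, cov$subject_id)))
}

test_that("a degenerate single-replicate simulation behaves analytically", {
  subj <- sim_subjects(20, seed = 3, identical_mu = TRUE)
  cfg <- sim_config(n_replicates = 1, seed = 11, censor_bounds = c(1e7, 1e8),
                    uncertainty = "none")
  sim <- run_simulation(default_os_truth(), subj, cfg)
  # degenerate prediction interval
  expect_equal(sim$hr[["lo"]], sim$hr[["median"]])
  expect_equal(sim$hr[["hi"]], sim$hr[["median"]])
  # arm labels are exchangeable here, so the HR is near 1
  expect_gt(sim$hr[["median"]], 0.4)
  expect_lt(sim$hr[["median"]], 2.5)
  # replicate internals reconstructed: landmark equals the replicate KM
  set.seed(11)
  co <- sample_parameters(default_os_truth(), "none")
  terms <- setdiff(names(co), c("(Intercept)", "log_scale"))
  mu <- co[["(Intercept)"]] +
    drop(as.matrix(subj[, terms]) %*% co[terms])
  rep1 <- simulate_patient(mu, exp(co[["log_scale"]]), cfg$censor_bounds)
  for (a in c("treatment", "control")) {
    km <- km_estimate(rep1$time[subj$arm == a], rep1$event[subj$arm == a])
    expect_equal(sim$landmarks$median[sim$landmarks$arm == a],
                 100 * km_eval(km, 730))
  }
})

test_that("simulation is reproducible and prediction intervals are ordered", {
  subj <- sim_subjects(25, seed = 8)
  cfg <- sim_config(n_replicates = 40, seed = 5)
  s1 <- run_simulation(default_os_truth(), subj, cfg)
  s2 <- run_simulation(default_os_truth(), subj, cfg)
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$hr, s2$hr)
  expect_true(all(s1$curves$lo <= s1$curves$median + 1e-12))
  expect_true(all(s1$curves$median <= s1$curves$hi + 1e-12))
  expect_true(all(s1$landmarks$lo <= s1$landmarks$median))
  # KM curves start at 1 and are non-increasing for every quantile band
  for (a in unique(s1$curves$arm)) {
    cc <- s1$curves[s1$curves$arm == a, ]
    expect_equal(cc$median[cc$time_days == 0], 1)
    expect_true(all(diff(cc$median) <= 1e-12))
  }
})

test_that("without parameter uncertainty the mean KM approaches the analytic mixture", {
  subj <- sim_subjects(30, seed = 19)
  cfg <- sim_config(n_replicates = 250, seed = 21, censor_bounds = c(1e7, 1e8),
                    uncertainty = "none")
  sim <- run_simulation(default_os_truth(), subj, cfg)
  m <- default_os_truth()
  mu <- linear_predictor(m, subj[, setdiff(names(subj), "arm")])
  for (a in c("treatment", "control")) {
    sbar <- mean(survival_function(730, mu[subj$arm == a], m$scale))
    # mean across replicates at the landmark (median ~ mean for many replicates)
    got <- sim$landmarks$median[sim$landmarks$arm == a] / 100
    expect_equal(got, sbar, tolerance = 0.08)
  }
})

test_that("parameter uncertainty widens the HR prediction interval", {
  subj <- sim_subjects(30, seed = 23)
  s_none <- run_simulation(default_os_truth(), subj,
                           sim_config(n_replicates = 120, seed = 2, uncertainty = "none"))
  s_diag <- run_simulation(default_os_truth(), subj,
                           sim_config(n_replicates = 120, seed = 2, uncertainty = "diagonal"))
  w_none <- s_none$hr[["hi"]] - s_none$hr[["lo"]]
  w_diag <- s_diag$hr[["hi"]] - s_diag$hr[["lo"]]
  expect_lt(w_none, w_diag)
})

test_that("simulation summaries export to JSON and tidy CSV", {
  subj <- sim_subjects(15, seed = 4)
  sim <- run_simulation(default_os_truth(), subj,
                        sim_config(n_replicates = 10, seed = 6))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "sim.json"); cp <- file.path(dir, "curves.csv")
  hp <- file.path(dir, "hr.csv")
  write_sim_summary(sim, jp, cp, hp)
  doc <- jsonlite::read_json(jp)
  expect_equal(doc$n_replicates, 10)
  expect_equal(doc$hr$median, unname(sim$hr[["median"]]), tolerance = 1e-12)
  curves <- read.csv(cp)
  expect_named(curves, c("arm", "time_days", "median", "lo", "hi"))
  hr <- read.csv(hp)
  expect_equal(nrow(hr), 10)
})
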