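sim_for_fit <- function(seed = 21, bouts = 40) {
  cfg <- simulation_config(
    groups = tibble::tibble(name = "G1", n_adult_f = 2, n_adult_m = 1,
                            n_juv_f = 1, n_juv_m = 1),
    n_sessions = 3, bouts_per_session = bouts, session_length_min = 45,
    true_params = list(lambda = 5, phi = 0.1, gamma = 0.2, beta_pay = 1),
    spec = ewa_spec("payoff_bias"), seed = seed)
  simulate_diffusion(cfg)
}

test_that("link functions keep prior-predictive parameters in bounds", {
  set.seed(2)
  pp <- prior_predictive(ewa_spec("global"), n = 2000)
  expect_true(all(pp$phi > 0 & pp$phi < 1))
  expect_true(all(pp$gamma > 0 & pp$gamma < 1))
  expect_true(all(pp$lambda > 0))
  expect_true(all(pp$fc > 0))
  expect_true(any(pp$beta_pay < 0) && any(pp$beta_pay > 0))
  # inverse-link identities at the origin of the link scale
  expect_equal(ewalearn:::inv_link(0, "logit"), 0.5)
  expect_equal(ewalearn:::inv_link(0, "log"), 1)
})

test_that("the design bundle indexes individuals, groups and events", {
  sim <- sim_for_fit()
  design <- build_design(sim$log, ewa_spec("payoff_bias"))
  expect_equal(length(design$actor), nrow(sim$log$events))
  expect_true(all(design$actor %in% seq_len(nrow(design$individuals))))
  expect_equal(sort(unique(design$grp)),
               seq_along(unique(design$individuals$group)))
  # events with an empty window are flagged for the individual-only path
  expect_true(any(!design$social_defined))
  expect_equal(design$social_defined, rowSums(design$cues$n) > 0)
  # the hierarchical layout matches the spec's free parameters
  expect_equal(design$hier, c("lambda", "phi", "gamma", "beta_pay"))
  expect_equal(ewalearn:::hier_params(ewa_spec("global")),
               c("lambda", "phi", "gamma", "fc", "beta_pay", "beta_rank",
                 "beta_kin", "beta_fem", "beta_sex"))
})

test_that("individuals with no events are excluded with a warning", {
  log <- toy_log()
  # D never acts in the toy log
  expect_warning(design <- build_design(log, ewa_spec("individual")),
                 "zero events")
  expect_false("D" %in% design$individuals$id)
  expect_equal(length(design$actor), nrow(log$events))
})

test_that("fits are reproducible under a fixed seed and chain count", {
  sim <- sim_for_fit()
  f1 <- fit_ewa(sim$log, ewa_spec("payoff_bias"), chains = 2, iter = 40,
                warmup = 40, seed = 5)
  f2 <- fit_ewa(sim$log, ewa_spec("payoff_bias"), chains = 2, iter = 40,
                warmup = 40, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)
  f3 <- fit_ewa(sim$log, ewa_spec("payoff_bias"), chains = 2, iter = 40,
                warmup = 40, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the hierarchical likelihood agrees with the sequence likelihood", {
  # the pointwise log-likelihood stored at each draw must equal an
  # independent forward replay at that draw's natural-scale parameters
  sim <- sim_for_fit(seed = 22)
  fit <- fit_ewa(sim$log, ewa_spec("payoff_bias"), chains = 2, iter = 30,
                 warmup = 30, seed = 1)
  for (draw in c(1, 17, 60)) {
    prm <- fitted_params(fit, draw)
    sl <- sequence_loglik(sim$log, prm, ewa_spec("payoff_bias"))
    expect_equal(unname(fit$pointwise_loglik[draw, ]), sl$loglik,
                 tolerance = 1e-10)
  }
})

test_that("natural-scale summaries respect selectors and links", {
  sim <- sim_for_fit(seed = 23)
  fit <- fit_ewa(sim$log, ewa_spec("payoff_bias"), chains = 2, iter = 40,
                 warmup = 40, seed = 2)
  ns <- natural_scale(fit, "population")
  expect_equal(ns$parameter, c("lambda", "phi", "gamma", "beta_pay"))
  expect_true(all(ns$mean[ns$parameter %in% c("phi", "gamma")] > 0 &
                    ns$mean[ns$parameter %in% c("phi", "gamma")] < 1))
  expect_true(ns$mean[ns$parameter == "lambda"] > 0)
  expect_true(all(ns$lower <= ns$mean & ns$mean <= ns$upper))
  for (who in c("age:juvenile", "sex:F",
                paste0("individual:", fit$design$individuals$id[1]),
                paste0("group:", fit$design$group_names[1]))) {
    expect_s3_class(natural_scale(fit, who), "tbl_df")
  }
  expect_error(natural_scale(fit, "individual:nobody"), "unknown")
  expect_error(natural_scale(fit, "planet:mars"), "unknown selector")
  # broom-style accessors
  td <- tidy(fit, by = "population")
  expect_true(all(c("term", "estimate", "conf.low", "conf.high")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.finite(gl$waic))
})
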