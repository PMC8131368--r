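test_that("WAIC has the right degenerate and additive behaviour", {
  # one event, identical log-likelihood across draws: no effective
  # parameters, waic = -2 * loglik
  ll <- matrix(-1.3, nrow = 4, ncol = 1)
  w <- compute_waic(ll)
  expect_equal(w$waic, 2.6)
  expect_equal(w$p_waic, 0)
  # appending a zero-variance event adds exactly -2 * loglik
  ll2 <- cbind(matrix(rnorm(8, -1), 4, 2), -0.7)
  w_base <- compute_waic(ll2[, 1:2])
  w_full <- compute_waic(ll2)
  expect_equal(w_full$waic, w_base$waic + 1.4)
  expect_error(compute_waic(matrix(-1, 1, 3)), "at least 2")
})

test_that("WAIC matches a hand evaluation on a 2x2 fixture", {
  ll <- matrix(c(-1, -2, -0.5, -1.5), nrow = 2) # draws x events
  lppd <- log(mean(exp(ll[, 1]))) + log(mean(exp(ll[, 2])))
  p <- var(ll[, 1]) + var(ll[, 2])
  w <- compute_waic(ll)
  expect_equal(w$waic, -2 * (lppd - p))
  expect_equal(w$p_waic, p)
})

test_that("WAIC agrees with an independent textbook implementation", {
  # straight transcription of the estimator, kept free of package code
  waic_oracle <- function(ll) {
    lppd_e <- apply(ll, 2, function(x) log(mean(exp(x))))
    p_e <- apply(ll, 2, var)
    elpd_e <- lppd_e - p_e
    list(waic = -2 * sum(elpd_e),
         se = sqrt(ncol(ll) * var(-2 * elpd_e)),
         p_waic = sum(p_e))
  }
  set.seed(31)
  for (i in 1:10) {
    ll <- matrix(rnorm(40 * 25, mean = -1.5, sd = 0.4), nrow = 40)
    o <- waic_oracle(ll)
    w <- compute_waic(ll)
    expect_equal(w$waic, o$waic, tolerance = 1e-8)
    expect_equal(w$se, o$se, tolerance = 1e-8)
    expect_equal(w$p_waic, o$p_waic, tolerance = 1e-8)
  }
})

fake_waic <- function(waic, n_events = 100) {
  out <- tibble::tibble(waic = waic, se = 1, p_waic = 5, lppd = -waic / 2,
                        n_events = n_events)
  class(out) <- c("ewa_waic", class(out))
  out
}

test_that("model weights follow the exponential WAIC-difference rule", {
  # equal scores split the weight evenly
  cmp <- compare_models(a = fake_waic(100), b = fake_waic(100))
  expect_equal(cmp$weight, c(0.5, 0.5))
  # a 49.18-point gap leaves essentially no weight on the worse model
  cmp <- compare_models(best = fake_waic(4707.71),
                        worse = fake_waic(4756.90))
  # scores printed to 2 decimals pin the difference only to ~0.01
  expect_equal(cmp$dwaic, c(0, 49.18), tolerance = 3e-4)
  expect_equal(cmp$weight[1], 1, tolerance = 1e-4)
  expect_equal(cmp$weight[2], 0, tolerance = 1e-4)
  # three models with hand-set scores
  cmp <- compare_models(m1 = fake_waic(10), m2 = fake_waic(12),
                        m3 = fake_waic(14))
  z <- exp(-c(0, 1, 2))
  expect_equal(cmp$weight, z / sum(z), tolerance = 1e-12)
  expect_equal(round(cmp$weight, 3), c(0.665, 0.245, 0.090))
  # ordering by waic equals ordering by weight, weights sum to 1
  expect_equal(cmp$model, c("m1", "m2", "m3"))
  expect_equal(order(-cmp$weight), order(cmp$waic))
  expect_equal(sum(cmp$weight), 1)
  expect_error(compare_models(a = fake_waic(1)), "at least 2")
  expect_error(compare_models(a = fake_waic(1, 100), b = fake_waic(2, 90)),
               "not comparable")
})

test_that("the HPDI is the narrowest interval holding the requested mass", {
  expect_equal(hpdi(rep(3, 10)), c(3, 3))
  # draws 1..100: all width-88 intervals tie; take the lowest lower bound
  expect_equal(hpdi(1:100, 0.89), c(1, 89))
  # an asymmetric sample: the interval hugs the dense region
  x <- c(seq(0, 1, length.out = 95), 50, 60, 70, 80, 90)
  h <- hpdi(x, 0.89)
  expect_true(h[2] <= 1)
  expect_error(hpdi(1:10, 1), "between 0 and 1")
  expect_error(hpdi(1:10, 0), "between 0 and 1")
  expect_equal(hpdi(1:10, 0.9999), c(1, 10))
  # exhaustive-scan oracle on random draws
  set.seed(41)
  for (i in 1:20) {
    x <- sort(rnorm(50))
    m <- ceiling(0.89 * 50)
    cand <- vapply(seq_len(50 - m + 1),
                   function(j) x[j + m - 1] - x[j], numeric(1))
    j <- which.min(cand)
    expect_equal(hpdi(x, 0.89), c(x[j], x[j + m - 1]))
  }
})

test_that("posterior predictions are normalised and consistent with the forward model", {
  cfg <- simulation_config(
    groups = tibble::tibble(name = "G1", n_adult_f = 2, n_adult_m = 1,
                            n_juv_f = 1, n_juv_m = 1),
    n_sessions = 3, bouts_per_session = 30, session_length_min = 45,
    true_params = list(lambda = 5, phi = 0.1, gamma = 0.2, beta_pay = 1),
    spec = ewa_spec("payoff_bias"), seed = 33)
  sim <- simulate_diffusion(cfg)
  fit <- fit_ewa(sim$log, ewa_spec("payoff_bias"), chains = 2, iter = 40,
                 warmup = 40, seed = 3)
  pred <- posterior_predict(fit, "population-daily")
  sums <- pred |>
    dplyr::group_by(.data$group, .data$date) |>
    dplyr::summarise(s = sum(.data$mean), sraw = sum(.data$raw),
                     .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(abs(sums$sraw - 1) < 1e-9))
  # with a single draw the per-bout prediction is exactly the forward
  # probability at that draw's parameters
  pred1 <- posterior_predict(fit, "per-bout", n_draws = 1)
  prm <- fitted_params(fit, 1)
  sl <- sequence_loglik(sim$log, prm, ewa_spec("payoff_bias"))
  chosen <- pred1 |>
    dplyr::inner_join(
      dplyr::mutate(fit$design$events, event = dplyr::row_number()),
      by = c("session_id", "time_min", "actor_id", "technique")
    ) |>
    dplyr::arrange(.data$event)
  expect_equal(chosen$mean, sl$prob, tolerance = 1e-10)
  # individual-daily resolution returns one block per actor and day
  pred_i <- posterior_predict(fit, "individual-daily", n_draws = 20)
  expect_true(all(c("actor_id", "date") %in% names(pred_i)))
  expect_error(posterior_predict(fit, "weekly"), "unknown resolution")
})
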