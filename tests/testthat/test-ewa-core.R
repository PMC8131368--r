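test_that("attraction updates follow the convex memory rule", {
  expect_equal(update_attraction(0.5, 0.1, 1), 0.55)
  # phi = 0: pure memory, experience ignored
  expect_equal(update_attraction(0.3, 0, 1), 0.3)
  # phi = 1: only the newest payoff matters
  expect_equal(update_attraction(0.9, 1, 0), 0)
  expect_error(update_attraction(0.5, 1.2, 1), "\\[0, 1\\]")
  # attractions stay in [0, 1] under binary payoffs from A0 = 0
  set.seed(1)
  A <- 0
  for (i in 1:200) {
    A <- update_attraction(A, runif(1), rbinom(1, 1, 0.5))
    expect_true(A >= 0 && A <= 1)
  }
})

test_that("individual choice is softmax over attractions", {
  expect_equal(individual_choice_probs(c(2, -1, 5), 0), rep(1 / 3, 3))
  p <- individual_choice_probs(c(1, 0, 0), 1)
  expect_equal(p, c(exp(1), 1, 1) / (exp(1) + 2))
  expect_equal(sum(p), 1, tolerance = 1e-15)
  # large scores do not overflow
  p <- individual_choice_probs(c(50, 0, 0), 10)
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  # higher sensitivity concentrates on the argmax technique
  p1 <- individual_choice_probs(c(0.6, 0.2, 0.1), 2)
  p2 <- individual_choice_probs(c(0.6, 0.2, 0.1), 4)
  expect_true(p2[1] > p1[1])
  expect_error(individual_choice_probs(c(1, 0), -1), ">= 0")
})

cue_row <- function(n, paybar = NA, rank = NA, kin = NA, fem = NA,
                    samesex = NA) {
  tibble::tibble(technique = c("CMS", "CMT", "CH"), n = n,
                 paybar = paybar, rank = rank, kin = kin, fem = fem,
                 samesex = samesex)
}

test_that("the social kernel weights techniques by frequency and cues", {
  prm <- list(fc = 1, beta_pay = 1)
  # unbiased imitation: proportional to counts
  s <- social_choice_probs(cue_row(c(2, 1, 1)), list(fc = 1),
                           ewa_spec("freq_dep"))
  expect_equal(s, c(0.5, 0.25, 0.25))
  # conformist exponent overweights the majority
  s <- social_choice_probs(cue_row(c(2, 1, 1)), list(fc = 2),
                           ewa_spec("freq_dep"))
  expect_equal(s, c(4, 1, 1) / 6)
  # payoff bias: observed success rates tilt the kernel; unobserved
  # techniques get zero weight
  s <- social_choice_probs(cue_row(c(1, 1, 0), paybar = c(1, 0, NA)),
                           list(fc = 1, beta_pay = 1),
                           ewa_spec("payoff_bias"))
  expect_equal(s, c(exp(1), 1, 0) / (exp(1) + 1))
  # nothing observed: kernel undefined
  expect_null(social_choice_probs(cue_row(c(0, 0, 0)), list(fc = 1),
                                  ewa_spec("freq_dep")))
  expect_error(social_choice_probs(cue_row(c(1, 0, 0)), list(fc = -1),
                                   ewa_spec("freq_dep")), "fc")
  expect_error(social_choice_probs(cue_row(c(1, 0, 0)), list(fc = 1),
                                   ewa_spec("individual")), "no social")
})

test_that("choice combines individual and social parts convexly", {
  I <- c(0.5, 0.25, 0.25)
  S <- c(0.8, 0.1, 0.1)
  expect_identical(combined_choice_probs(I, S, 0), I)
  expect_identical(combined_choice_probs(I, S, 1), S)
  expect_equal(combined_choice_probs(I, S, 0.5), c(0.65, 0.175, 0.175))
  # undefined social info falls back to individual choice
  expect_identical(combined_choice_probs(I, NULL, 0.7), I)
  expect_error(combined_choice_probs(I, S, 1.5), "\\[0, 1\\]")
  # normalisation holds across random convex combinations
  set.seed(3)
  for (i in 1:50) {
    I <- individual_choice_probs(rnorm(3), runif(1, 0, 5))
    S <- social_choice_probs(cue_row(rpois(3, 2) + c(1, 0, 0),
                                     paybar = runif(3)),
                             list(fc = runif(1, 0.3, 3),
                                  beta_pay = rnorm(1)),
                             ewa_spec("payoff_bias"))
    P <- combined_choice_probs(I, S, runif(1))
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
})

test_that("a two-event sequence log-likelihood matches the hand recursion", {
  ev <- tibble::tibble(
    session_id = "s1", date = "2018-05-01", time_min = c(1, 2),
    actor_id = "A", technique = c("CMS", "CMS"),
    outcome = c("success", "failure"), observers = ""
  )
  inds <- tibble::tibble(id = "A", group = "G1", sex = "F",
                         age_class = "adult", rank = 1, matriline = NA)
  log <- ewa_log(ev, inds)
  prm <- ewa_params("A", lambda = 2, phi = 0.3)
  sl <- sequence_loglik(log, prm, ewa_spec("individual"))
  # bout 1: A = (0,0,0) -> uniform; bout 2: A_CMS = 0.3
  p1 <- 1 / 3
  p2 <- exp(2 * 0.3) / (exp(2 * 0.3) + 2)
  expect_equal(sl$loglik, c(log(p1), log(p2)), tolerance = 1e-12)
})

test_that("zero social weight reduces the global model to individual learning", {
  set.seed(9)
  log <- random_log(n_events = 15, n_ind = 4)
  prm <- random_params(log)
  prm$gamma <- 0
  a <- sequence_loglik(log, prm, ewa_spec("global"))
  b <- sequence_loglik(log, prm, ewa_spec("individual"))
  expect_identical(a$loglik, b$loglik)
})

test_that("both likelihood engines match an independent brute-force recursion", {
  set.seed(17)
  specs <- c("individual", "freq_dep", "payoff_bias", "rank_bias",
             "kin_bias", "female_bias", "sex_bias", "global")
  for (i in 1:24) {
    log <- random_log(n_events = rpois(1, 6) + 2, n_ind = 3)
    prm <- random_params(log)
    spec <- ewa_spec(specs[(i - 1) %% length(specs) + 1])
    oracle <- brute_force_loglik(log, prm, spec)
    r_eng <- sequence_loglik(log, prm, spec, engine = "R")
    cpp_eng <- sequence_loglik(log, prm, spec, engine = "cpp")
    expect_equal(r_eng$loglik, oracle, tolerance = 1e-10)
    expect_equal(cpp_eng$loglik, oracle, tolerance = 1e-10)
  }
})
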