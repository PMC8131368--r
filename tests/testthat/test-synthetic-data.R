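small_cfg <- function(seed = 1, ...) {
  simulation_config(
    groups = tibble::tibble(name = "G1", n_adult_f = 2, n_adult_m = 1,
                            n_juv_f = 1, n_juv_m = 1),
    n_sessions = 3, bouts_per_session = 40, session_length_min = 45,
    true_params = list(lambda = 5, phi = 0.1, gamma = 0.2, beta_pay = 1),
    spec = ewa_spec("payoff_bias"), seed = seed, ...)
}

test_that("the synthetic pedigree follows the matriline relatedness rules", {
  cfg <- simulation_config(
    groups = tibble::tibble(name = "G1", n_adult_f = 1, n_adult_m = 0,
                            n_juv_f = 1, n_juv_m = 0),
    seed = 4)
  pop <- generate_population(cfg)
  mother <- pop$individuals$id[pop$individuals$age_class == "adult"]
  juv <- pop$individuals$id[pop$individuals$age_class == "juvenile"]
  expect_equal(pop$kin[mother, juv], 0.5)
  expect_equal(pop$kin[mother, mother], 1)
  # two-group population: zero relatedness across groups, 0.25 between
  # non-mother matriline members, distinct ranks spanning [0, 1]
  cfg2 <- simulation_config(seed = 5)
  pop2 <- generate_population(cfg2)
  inds <- pop2$individuals
  cross <- pop2$kin[inds$group == "NH", inds$group == "KB"]
  expect_true(all(cross == 0))
  sibs <- which(!is.na(inds$mother))
  if (length(sibs) >= 2) {
    a <- sibs[1]
    b <- sibs[which(inds$mother[sibs] == inds$mother[a])[2]]
    if (!is.na(b)) expect_equal(pop2$kin[a, b], 0.25)
  }
  for (g in unique(inds$group)) {
    r <- sort(inds$rank[inds$group == g])
    expect_equal(length(unique(r)), length(r))
    expect_equal(range(r), c(0, 1))
  }
})

test_that("population and diffusion generation are deterministic under a seed", {
  pop1 <- generate_population(small_cfg(seed = 6))
  pop2 <- generate_population(small_cfg(seed = 6))
  expect_identical(pop1, pop2)
  sim1 <- simulate_diffusion(small_cfg(seed = 6))
  sim2 <- simulate_diffusion(small_cfg(seed = 6))
  expect_identical(sim1$log$events, sim2$log$events)
  expect_identical(sim1$ledger, sim2$ledger)
  sim3 <- simulate_diffusion(small_cfg(seed = 7))
  expect_false(identical(sim1$log$events, sim3$log$events))
})

test_that("a lone asocial learner fixates on the only rewarding technique", {
  cfg <- simulation_config(
    groups = tibble::tibble(name = "G1", n_adult_f = 1, n_adult_m = 0,
                            n_juv_f = 0, n_juv_m = 0),
    n_sessions = 1, bouts_per_session = 50, session_length_min = 500,
    technique_success_probs = c(CMS = 1, CMT = 0, CH = 0),
    true_params = list(lambda = 10, phi = 0.3, gamma = 0),
    spec = ewa_spec("individual"), seed = 3)
  sim <- simulate_diffusion(cfg)
  tech <- sim$log$events$technique
  n <- length(tech)
  expect_true(n >= 30)
  # after exploration the agent settles on the high-payoff technique
  expect_true(all(tail(tech, 20) == "CMS"))
})

test_that("with zero social weight attendance never influences choice", {
  cfg <- small_cfg(seed = 8)
  cfg$true_params$gamma <- 0
  sim <- simulate_diffusion(cfg)
  # the ledger's probabilities coincide with a purely individual model
  ind <- sequence_loglik(sim$log, sim$truth$params, ewa_spec("individual"))
  expect_identical(sim$ledger$prob, ind$prob)
})

test_that("realised success rates converge to the configured probabilities", {
  cfg <- simulation_config(
    groups = tibble::tibble(name = "G1", n_adult_f = 1, n_adult_m = 0,
                            n_juv_f = 0, n_juv_m = 0),
    n_sessions = 10, bouts_per_session = 500, session_length_min = 5000,
    technique_success_probs = c(CMS = 0.47, CMT = 0.08, CH = 0.05),
    true_params = list(lambda = 0, phi = 0.05, gamma = 0),
    spec = ewa_spec("individual"), seed = 10)
  sim <- simulate_diffusion(cfg)
  ev <- sim$log$events
  expect_true(nrow(ev) >= 4000)
  for (tech in names(cfg$technique_success_probs)) {
    sel <- ev$technique == tech
    p_hat <- mean(ev$outcome[sel] == "success")
    p <- cfg$technique_success_probs[[tech]]
    # within three binomial standard errors
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / sum(sel)))
  }
})

test_that("ledger probabilities equal likelihood recomputation with truth", {
  sim <- simulate_diffusion(small_cfg(seed = 11))
  sl <- sequence_loglik(sim$log, sim$truth$params, sim$truth$spec)
  expect_identical(sl$prob, sim$ledger$prob)
})

test_that("payoff-biased worlds converge on the high-payoff technique", {
  for (seed in 1:3) {
    cfg <- simulation_config(
      groups = tibble::tibble(name = "G1", n_adult_f = 8, n_adult_m = 7,
                              n_juv_f = 8, n_juv_m = 7),
      n_sessions = 10, bouts_per_session = 200, session_length_min = 46.8,
      true_params = list(lambda = 8, phi = 0.06, gamma = 0.25,
                         beta_pay = 1),
      spec = ewa_spec("payoff_bias"), seed = seed)
    sim <- simulate_diffusion(cfg)
    ev <- sim$log$events
    final <- ev$technique[ev$session_id == max(ev$session_id)]
    modal <- names(which.max(table(final)))
    expect_equal(modal, "CMS")
  }
})

test_that("simulated datasets serialise with their ground truth", {
  sim <- simulate_diffusion(small_cfg(seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$spec, "payoff_bias")
  expect_equal(truth$seed, 12)
  log2 <- read_event_log(paths[["events"]], paths[["individuals"]],
                         paths[["kin"]])
  expect_equal(log2$events$technique, sim$log$events$technique)
})
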