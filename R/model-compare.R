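#' Widely applicable information criterion from pointwise log-likelihood
#'
#' Deviance-scale WAIC: `lppd = sum_e log(mean_d exp(ll_de))`,
#' `p_waic = sum_e var_d(ll_de)`, `waic = -2 (lppd - p_waic)`. The standard
#' error uses the pointwise-variance estimator
#' `se = sqrt(E * var_e(-2 (lppd_e - p_e)))`.
#'
#' @param pointwise A draws x events matrix of pointwise log-likelihood, or
#'   an `ewa_fit` (its stored matrix is used).
#' @return A one-row tibble of class `ewa_waic` with columns `waic`, `se`,
#'   `p_waic`, `lppd` and `n_events`.
#' @export
compute_waic <- function(pointwise) {
  if (inherits(pointwise, "ewa_fit")) pointwise <- pointwise$pointwise_loglik
  pointwise <- as.matrix(pointwise)
  if (nrow(pointwise) < 2) {
    stop("WAIC needs at least 2 posterior draws (p_waic is a variance)",
         call. = FALSE)
  }
  S <- nrow(pointwise)
  # log of the draw-averaged likelihood, computed stably per event
  mx <- apply(pointwise, 2, max)
  lppd_e <- mx + log(colMeans(exp(sweep(pointwise, 2, mx))))
  p_e <- apply(pointwise, 2, var)
  elpd_e <- lppd_e - p_e
  out <- tibble::tibble(
    waic = -2 * sum(elpd_e),
    se = sqrt(ncol(pointwise) * var(-2 * elpd_e)),
    p_waic = sum(p_e),
    lppd = sum(lppd_e),
    n_events = ncol(pointwise)
  )
  class(out) <- c("ewa_waic", class(out))
  out
}

#' Compare fitted models by WAIC
#'
#' Builds the standard comparison table: models sorted by ascending WAIC,
#' differences from the best model, and Akaike-style weights
#' `w_i = exp(-dwaic_i / 2) / sum exp(-dwaic / 2)`.
#'
#' @param ... Named `ewa_fit` or `ewa_waic` objects (or a single named list
#'   of them). At least two, all fitted to the same events.
#' @return A tibble of class `ewa_comparison` with columns `model`, `waic`,
#'   `se`, `p_waic`, `dwaic`, `weight`.
#' @export
compare_models <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) &&
      !inherits(args[[1]], c("ewa_fit", "ewa_waic", "data.frame"))) {
    args <- args[[1]]
  }
  if (length(args) < 2) {
    stop("at least 2 models are required for comparison", call. = FALSE)
  }
  if (is.null(names(args)) || any(!nzchar(names(args)))) {
    stop("models must be named", call. = FALSE)
  }
  ws <- purrr::map(args, function(a) {
    if (inherits(a, "ewa_waic")) a else compute_waic(a)
  })
  n_events <- vapply(ws, function(w) w$n_events, numeric(1))
  if (length(unique(n_events)) != 1) {
    stop("models were fit to different event sets (event counts differ); ",
         "WAIC values are not comparable", call. = FALSE)
  }
  out <- purrr::map2_dfr(names(ws), ws, function(nm, w) {
    tibble::tibble(model = nm, waic = w$waic, se = w$se, p_waic = w$p_waic)
  }) |>
    dplyr::arrange(.data$waic) |>
    dplyr::mutate(dwaic = .data$waic - min(.data$waic),
                  weight = exp(-.data$dwaic / 2) /
                    sum(exp(-.data$dwaic / 2)))
  class(out) <- c("ewa_comparison", class(out))
  out
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval of sorted draws containing
#' `ceiling(mass * n)` draws; ties are broken towards the lowest lower
#' bound.
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @param mass Probability mass in (0, 1); default 0.89.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.89) {
  stopifnot(length(draws) >= 2)
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("mass must lie strictly between 0 and 1", call. = FALSE)
  }
  x <- sort(draws)
  n <- length(x)
  m <- min(ceiling(mass * n), n)
  widths <- x[m:n] - x[seq_len(n - m + 1)]
  i <- which.min(widths)  # which.min takes the first (lowest lower bound)
  c(x[i], x[i + m - 1])
}

#' Posterior predictions along the observed sequences
#'
#' For each posterior draw, replays the forward model along every
#' individual's observed behavioural sequence (attractions updated with the
#' realised outcomes, social cues as observed) and records the per-bout
#' technique probabilities; these one-step-ahead predictions are then
#' aggregated at the requested resolution with posterior means and 89\%
#' HPDIs, alongside the raw technique frequencies for overlay.
#'
#' @param object An `ewa_fit`.
#' @param resolution `"population-daily"` (mean over all events of a group
#'   and day), `"individual-daily"` or `"per-bout"`.
#' @param n_draws Number of (evenly spaced) posterior draws to use.
#' @param mass HPDI mass.
#' @param free_running If `TRUE`, instead of conditioning on the observed
#'   choices the replay samples each choice from the model and draws its
#'   payoff from the actor's empirical success rate for the sampled
#'   technique (population rate when the actor never used it); an
#'   approximation useful to visualise model-implied trajectories.
#' @param seed Seed used only by the free-running replay.
#' @param ... Unused.
#' @return A tibble of class `ewa_prediction`: one row per unit x technique
#'   with `mean`, `lower`, `upper` and the raw frequency `raw` (observed
#'   proportion of that technique in the unit).
#' @export
posterior_predict <- function(object, ...) UseMethod("posterior_predict")

#' @rdname posterior_predict
#' @export
posterior_predict.ewa_fit <- function(object, resolution = "population-daily",
                                      n_draws = 200, mass = 0.89,
                                      free_running = FALSE, seed = 1, ...) {
  fit <- object
  if (!resolution %in% c("population-daily", "individual-daily", "per-bout")) {
    stop("unknown resolution '", resolution, "'", call. = FALSE)
  }
  design <- fit$design
  E <- length(design$actor)
  K <- length(design$techniques)
  nd_all <- nrow(fit$draws)
  idx <- unique(round(seq(1, nd_all, length.out = min(n_draws, nd_all))))
  probs <- array(NA_real_, c(length(idx), E, K))
  if (free_running) set.seed(seed)
  for (i in seq_along(idx)) {
    P <- assemble_draw(fit$draws[idx[i], ], design)
    if (!free_running) {
      res <- ewa_loglik_cpp(design$actor, design$tech, design$payoff,
                            design$cues$n, design$cues$paybar,
                            design$cues$rank, design$cues$kin,
                            design$cues$fem, design$cues$samesex,
                            P, design$spec$social, TRUE)
      probs[i, , ] <- res$probs
    } else {
      probs[i, , ] <- free_run_probs(design, P)
    }
  }
  ev <- design$events
  obs_mat <- matrix(0, E, K)
  obs_mat[cbind(seq_len(E), design$tech)] <- 1
  group_of <- design$individuals$group[design$actor]

  unit <- switch(resolution,
    "per-bout" = tibble::tibble(unit = seq_len(E), group = group_of,
                                date = ev$date, actor_id = ev$actor_id,
                                session_id = ev$session_id,
                                time_min = ev$time_min),
    "population-daily" = tibble::tibble(
      unit = as.integer(factor(paste(group_of, ev$date))),
      group = group_of, date = ev$date),
    "individual-daily" = tibble::tibble(
      unit = as.integer(factor(paste(ev$actor_id, ev$date))),
      group = group_of, date = ev$date, actor_id = ev$actor_id)
  )
  fac <- unit$unit
  nunits <- max(fac)
  counts <- tabulate(fac, nunits)
  agg <- array(NA_real_, c(length(idx), nunits, K))
  for (i in seq_along(idx)) {
    agg[i, , ] <- rowsum(probs[i, , ], fac) / counts
  }
  raw <- rowsum(obs_mat, fac) / counts
  meta <- unit[!duplicated(fac), , drop = FALSE]
  meta <- meta[order(meta$unit), , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nunits), function(u) {
    purrr::map_dfr(seq_len(K), function(k) {
      h <- if (length(idx) < 2) rep(agg[, u, k], 2)
           else hpdi(agg[, u, k], mass)
      dplyr::bind_cols(
        meta[u, setdiff(names(meta), "unit"), drop = FALSE],
        tibble::tibble(technique = design$techniques[k],
                       mean = mean(agg[, u, k]),
                       lower = h[1], upper = h[2], raw = raw[u, k],
                       n_events = counts[u])
      )
    })
  })
  attr(out, "resolution") <- resolution
  class(out) <- c("ewa_prediction", class(out))
  out
}

# free-running replay for one draw: choices sampled from the model,
# payoffs from empirical per-technique success rates, cues as observed
free_run_probs <- function(design, P) {
  E <- length(design$actor)
  K <- ncol(design$cues$n)
  J <- nrow(design$individuals)
  succ <- matrix(NA_real_, J, K)
  pay_obs <- design$payoff
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      sel <- design$actor == j & design$tech == k
      succ[j, k] <- if (any(sel)) mean(pay_obs[sel]) else NA_real_
    }
  }
  pop_rate <- vapply(seq_len(K), function(k) {
    mean(pay_obs[design$tech == k])
  }, numeric(1))
  pop_rate[is.na(pop_rate)] <- mean(pay_obs)
  A <- matrix(0, J, K)
  out <- matrix(NA_real_, E, K)
  for (e in seq_len(E)) {
    j <- design$actor[e]
    I <- individual_choice_probs(A[j, ], P[j, "lambda"])
    pr <- I
    if (design$spec$social && any(design$cues$n[e, ] > 0)) {
      N <- design$cues$n[e, ]
      B <- P[j, "beta_pay"] * design$cues$paybar[e, ] +
        P[j, "beta_rank"] * design$cues$rank[e, ] +
        P[j, "beta_kin"] * design$cues$kin[e, ] +
        P[j, "beta_fem"] * design$cues$fem[e, ] +
        P[j, "beta_sex"] * design$cues$samesex[e, ]
      logw <- ifelse(N > 0, P[j, "fc"] * log(N) + B, -Inf)
      S <- exp(logw - max(logw)); S <- S / sum(S)
      pr <- (1 - P[j, "gamma"]) * I + P[j, "gamma"] * S
    }
    out[e, ] <- pr
    k <- sample.int(K, 1, prob = pr)
    p_succ <- succ[j, k]
    if (is.na(p_succ)) p_succ <- pop_rate[k]
    pay <- rbinom(1, 1, p_succ)
    A[j, k] <- (1 - P[j, "phi"]) * A[j, k] + P[j, "phi"] * pay
  }
  out
}

#' @export
print.ewa_comparison <- function(x, ...) {
  cat("WAIC model comparison (", nrow(x), " models, ",
      x$waic[1] |> round(1), " best)\n", sep = "")
  NextMethod()
}
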