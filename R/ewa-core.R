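#' Learning-strategy model specifications
#'
#' The eight model variants differ only in which social cues enter the
#' social choice kernel and whether the frequency-dependence exponent `f_c`
#' is free. `individual` has no social component at all; the single-bias
#' models activate exactly one demonstrator/behaviour cue with `f_c` fixed
#' at 1; `freq_dep` frees `f_c` with no trait cues; `global` activates all
#' five cues and frees `f_c`.
#'
#' @param name One of `"individual"`, `"freq_dep"`, `"female_bias"`,
#'   `"kin_bias"`, `"payoff_bias"`, `"rank_bias"`, `"sex_bias"`, `"global"`.
#' @return An object of class `ewa_spec` with elements `name`, `social`,
#'   `active_betas` (subset of `pay, rank, kin, fem, sex`) and `fc_free`.
#' @examples
#' ewa_spec("payoff_bias")
#' @export
ewa_spec <- function(name) {
  specs <- list(
    individual  = list(social = FALSE, active_betas = character(), fc_free = FALSE),
    freq_dep    = list(social = TRUE,  active_betas = character(), fc_free = TRUE),
    female_bias = list(social = TRUE,  active_betas = "fem",  fc_free = FALSE),
    kin_bias    = list(social = TRUE,  active_betas = "kin",  fc_free = FALSE),
    payoff_bias = list(social = TRUE,  active_betas = "pay",  fc_free = FALSE),
    rank_bias   = list(social = TRUE,  active_betas = "rank", fc_free = FALSE),
    sex_bias    = list(social = TRUE,  active_betas = "sex",  fc_free = FALSE),
    global      = list(social = TRUE,
                       active_betas = c("pay", "rank", "kin", "fem", "sex"),
                       fc_free = TRUE)
  )
  if (!name %in% names(specs)) {
    stop("unknown model spec '", name, "'; valid names: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  }
  structure(c(list(name = name), specs[[name]]), class = "ewa_spec")
}

#' @export
print.ewa_spec <- function(x, ...) {
  cat("<ewa_spec> ", x$name,
      if (x$social) paste0(" (social; betas: ",
                           if (length(x$active_betas))
                             paste(x$active_betas, collapse = ",") else "none",
                           if (x$fc_free) "; f_c free" else "; f_c = 1", ")")
      else " (individual learning only)", "\n", sep = "")
  invisible(x)
}

#' All eight spec names in canonical order
#' @return Character vector of valid [ewa_spec()] names.
#' @export
ewa_spec_names <- function() {
  c("individual", "freq_dep", "female_bias", "kin_bias", "payoff_bias",
    "rank_bias", "sex_bias", "global")
}

#' Per-individual learning parameters
#'
#' Builds the tidy per-individual parameter table consumed by the forward
#' model: the attraction sensitivity `lambda` (>= 0), the recent-experience
#' weight `phi` in \[0, 1\], the social-information weight `gamma` in
#' \[0, 1\], the frequency-dependence exponent `fc` (> 0; 1 means unbiased,
#' proportional imitation) and the cue coefficients `beta_*` (unconstrained).
#' Scalars are recycled over ids.
#'
#' @param id Character vector of individual ids.
#' @param lambda,phi,gamma,fc,beta_pay,beta_rank,beta_kin,beta_fem,beta_sex
#'   Numeric, length 1 or `length(id)`.
#' @return A tibble with one row per individual.
#' @export
ewa_params <- function(id, lambda = 1, phi = 0.1, gamma = 0, fc = 1,
                       beta_pay = 0, beta_rank = 0, beta_kin = 0,
                       beta_fem = 0, beta_sex = 0) {
  out <- tibble::tibble(
    id = as.character(id), lambda = lambda, phi = phi, gamma = gamma,
    fc = fc, beta_pay = beta_pay, beta_rank = beta_rank,
    beta_kin = beta_kin, beta_fem = beta_fem, beta_sex = beta_sex
  )
  check_params(out)
  out
}

check_params <- function(p) {
  if (any(p$lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (any(p$phi < 0 | p$phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  if (any(p$gamma < 0 | p$gamma > 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (any(p$fc <= 0)) stop("fc must be > 0", call. = FALSE)
  invisible(p)
}

#' Attraction-score update
#'
#' One bout's worth of experience for the chosen technique:
#' `A' = (1 - phi) A + phi * payoff`. Only the chosen technique's attraction
#' changes at a bout; unchosen techniques retain their scores.
#'
#' @param A_prev Previous attraction score(s).
#' @param phi Recent-experience weight in \[0, 1\]; high `phi` discounts old
#'   experience quickly.
#' @param payoff Realised payoff, 1 for a success and 0 for a failure.
#' @return Updated attraction score(s).
#' @export
update_attraction <- function(A_prev, phi, payoff) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  (1 - phi) * A_prev + phi * payoff
}

#' Individual (asocial) choice probabilities
#'
#' Multinomial logistic choice over attraction scores:
#' `I_i = exp(lambda A_i) / sum_k exp(lambda A_k)`, computed with
#' max-subtraction so large `lambda * A` cannot overflow. `lambda = 0`
#' yields uniform choice.
#'
#' @param A_row Numeric vector of attraction scores (one per technique).
#' @param lambda Sensitivity to attraction differences, >= 0.
#' @return Probability vector summing to 1.
#' @export
individual_choice_probs <- function(A_row, lambda) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  z <- lambda * A_row
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

#' Social choice probabilities from windowed cues
#'
#' The social kernel `S_i` is proportional to `N_i^fc * exp(B_i)` where `N_i`
#' counts attended demonstrations of technique `i` in the window and
#' `B_i = sum_k beta_k * kappa_{k,i}` over the spec's active cues. Techniques
#' never observed in the window get probability 0 (`0^fc = 0` for `fc > 0`);
#' if nothing was observed at all the social kernel is undefined and `NULL`
#' is returned — the caller then falls back to purely individual choice.
#'
#' @param cues A cue tibble as returned by [compute_cues()] (columns `n`,
#'   `paybar`, `rank`, `kin`, `fem`, `samesex`).
#' @param params A single-row parameter table ([ewa_params()]) or named list
#'   with `fc` and the `beta_*` entries.
#' @param spec An [ewa_spec()] with a social component.
#' @return Probability vector over techniques summing to 1, or `NULL` when
#'   no demonstration was observed.
#' @export
social_choice_probs <- function(cues, params, spec) {
  stopifnot(inherits(spec, "ewa_spec"))
  if (!spec$social) {
    stop("spec '", spec$name, "' has no social component", call. = FALSE)
  }
  fc <- if (spec$fc_free) params$fc else 1
  if (fc <= 0) stop("fc must be > 0", call. = FALSE)
  N <- cues$n
  if (all(N == 0)) return(NULL)
  cue_cols <- c(pay = "paybar", rank = "rank", kin = "kin",
                fem = "fem", sex = "samesex")
  B <- numeric(length(N))
  for (k in spec$active_betas) {
    kap <- cues[[cue_cols[[k]]]]
    kap[is.na(kap)] <- 0  # only multiplies into techniques with N = 0
    B <- B + params[[paste0("beta_", k)]] * kap
  }
  logw <- ifelse(N > 0, fc * log(N) + B, -Inf)
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

#' Convex combination of individual and social choice
#'
#' `Pr = (1 - gamma) I + gamma S`. When the social kernel is undefined
#' (`S = NULL`, nothing observed in the window) the bout is modelled as a
#' purely individual choice and `I` is returned.
#'
#' @param I Individual choice probability vector.
#' @param S Social choice probability vector, or `NULL` when undefined.
#' @param gamma Social-information weight in \[0, 1\].
#' @return Probability vector summing to 1.
#' @export
combined_choice_probs <- function(I, S, gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (is.null(S)) return(I)
  (1 - gamma) * I + gamma * S
}

# Internal single-bout step shared verbatim by the simulator and the R
# likelihood engine, so simulated choice probabilities and recomputed
# likelihood probabilities agree bitwise.
choice_step <- function(A_row, cues, params_row, spec) {
  I <- individual_choice_probs(A_row, params_row$lambda)
  S <- if (spec$social) social_choice_probs(cues, params_row, spec) else NULL
  combined_choice_probs(I, S, params_row$gamma)
}

#' Pointwise log-likelihood of an observed behavioural sequence
#'
#' Replays the log in time order: for each manipulation event the actor's
#' current attraction scores and windowed social cues give a choice
#' probability for the observed technique; its log is recorded, and then the
#' actor's attraction for the chosen technique is updated with the realised
#' payoff. Attractions start at 0 for every technique and evolve
#' independently per individual.
#'
#' @param log An [ewa_log].
#' @param params An [ewa_params()] table covering every actor in the log.
#' @param spec An [ewa_spec()].
#' @param window A [cue_window_config()].
#' @param engine `"R"` (reference implementation, shared step-for-step with
#'   the simulator) or `"cpp"` (fast path used by the sampler); both return
#'   the same values to floating-point accuracy.
#' @return A tibble with one row per event: `event`, `session_id`,
#'   `time_min`, `actor_id`, `technique`, `prob` (probability assigned to
#'   the observed technique) and `loglik`.
#' @export
sequence_loglik <- function(log, params, spec, window = cue_window_config(),
                            engine = c("R", "cpp")) {
  stopifnot(inherits(log, "ewa_log"), inherits(spec, "ewa_spec"))
  engine <- match.arg(engine)
  check_params(params)
  ev <- log$events
  missing_ids <- setdiff(unique(ev$actor_id), params$id)
  if (length(missing_ids)) {
    stop("params missing for individual(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    event = seq_len(nrow(ev)), session_id = ev$session_id,
    time_min = ev$time_min, actor_id = ev$actor_id,
    technique = ev$technique, prob = NA_real_, loglik = NA_real_
  )
  if (!nrow(ev)) return(out)
  if (engine == "cpp") {
    arrs <- cue_arrays(log, window)
    pm <- apply_spec(params_matrix(params, log$individuals$id), spec)
    res <- ewa_loglik_cpp(
      match(ev$actor_id, log$individuals$id),
      match(ev$technique, log$techniques),
      as.numeric(ev$outcome == "success"),
      arrs$n, arrs$paybar, arrs$rank, arrs$kin, arrs$fem, arrs$samesex,
      pm, spec$social, FALSE
    )
    out$prob <- res$prob
    out$loglik <- res$loglik
    return(out)
  }
  K <- length(log$techniques)
  A <- matrix(0, nrow(log$individuals), K,
              dimnames = list(log$individuals$id, log$techniques))
  prow <- params[match(log$individuals$id, params$id), ]
  for (e in seq_len(nrow(ev))) {
    j <- ev$actor_id[e]
    cues <- NULL
    if (spec$social) {
      att <- attended_events(log, j, ev$time_min[e], ev$session_id[e], window)
      cues <- compute_cues(att, log, j)
    }
    pr <- unname(choice_step(A[j, ], cues,
                             prow[match(j, log$individuals$id), ], spec))
    k <- match(ev$technique[e], log$techniques)
    out$prob[e] <- pr[k]
    out$loglik[e] <- log(pr[k])
    pay <- as.numeric(ev$outcome[e] == "success")
    A[j, k] <- update_attraction(A[j, k], prow$phi[match(j, log$individuals$id)], pay)
  }
  out
}

# Internal: params tibble -> J x 9 matrix in the fixed column layout the C++
# likelihood expects (lambda, phi, gamma, fc, beta pay/rank/kin/fem/sex),
# rows ordered like `ids`.
params_matrix <- function(params, ids) {
  i <- match(ids, params$id)
  if (anyNA(i)) stop("params missing for some individuals", call. = FALSE)
  m <- as.matrix(params[i, c("lambda", "phi", "gamma", "fc", "beta_pay",
                             "beta_rank", "beta_kin", "beta_fem", "beta_sex")])
  rownames(m) <- ids
  m
}

# Enforce a spec's structural constraints on a full parameter matrix:
# fixed f_c = 1 unless free, inactive cue coefficients zeroed, and no
# social weight without a social component.
apply_spec <- function(pm, spec) {
  if (!spec$social) pm[, "gamma"] <- 0
  if (!spec$fc_free) pm[, "fc"] <- 1
  for (k in c("pay", "rank", "kin", "fem", "sex")) {
    if (!k %in% spec$active_betas) pm[, paste0("beta_", k)] <- 0
  }
  pm
}
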