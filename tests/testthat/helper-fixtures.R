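# Shared fixture builders. All data is generated in code.

toy_individuals <- function() {
  tibble::tibble(
    id = c("A", "B", "C", "D"),
    group = c("G1", "G1", "G1", "G1"),
    sex = c("F", "M", "F", "M"),
    age_class = c("adult", "adult", "juvenile", "infant"),
    rank = c(1, 2 / 3, 1 / 3, 0),
    matriline = c("A", NA, "A", "A")
  )
}

toy_kin <- function(ids = c("A", "B", "C", "D")) {
  k <- diag(length(ids))
  dimnames(k) <- list(ids, ids)
  k["A", "C"] <- k["C", "A"] <- 0.5
  k["A", "D"] <- k["D", "A"] <- 0.5
  k["C", "D"] <- k["D", "C"] <- 0.25
  k
}

toy_events <- function() {
  tibble::tibble(
    session_id = "s1",
    date = "2018-05-01",
    time_min = c(1, 2, 3.5, 5),
    actor_id = c("A", "A", "B", "C"),
    technique = c("CMS", "CMS", "CMT", "CH"),
    outcome = c("success", "failure", "failure", "success"),
    observers = c("B;C", "C", "A", "")
  )
}

toy_log <- function() ewa_log(toy_events(), toy_individuals(), toy_kin())

# random small event log with attendance, for property-style tests
random_log <- function(n_events = 8, n_ind = 3, n_sessions = 1,
                       techniques = c("CMS", "CMT", "CH")) {
  ids <- LETTERS[seq_len(n_ind)]
  inds <- tibble::tibble(
    id = ids, group = "G1",
    sex = sample(c("F", "M"), n_ind, replace = TRUE),
    age_class = sample(c("adult", "juvenile"), n_ind, replace = TRUE),
    rank = (sample(n_ind) - 1) / max(1, n_ind - 1),
    matriline = "m1"
  )
  kin <- diag(n_ind)
  dimnames(kin) <- list(ids, ids)
  for (a in seq_len(n_ind - 1)) {
    for (b in (a + 1):n_ind) {
      kin[a, b] <- kin[b, a] <- sample(c(0, 0.25, 0.5), 1)
    }
  }
  rows <- lapply(seq_len(n_sessions), function(s) {
    k <- max(1, rpois(1, n_events / n_sessions))
    actor <- sample(ids, k, replace = TRUE)
    obs <- vapply(actor, function(a) {
      others <- setdiff(ids, a)
      paste(others[runif(length(others)) < 0.6], collapse = ";")
    }, character(1))
    tibble::tibble(
      session_id = paste0("s", s), date = "2018-05-01",
      time_min = sort(runif(k, 0, 45)), actor_id = actor,
      technique = sample(techniques, k, replace = TRUE),
      outcome = sample(c("success", "failure"), k, replace = TRUE),
      observers = obs
    )
  })
  ewa_log(dplyr::bind_rows(rows), inds, kin, techniques = techniques)
}

random_params <- function(log) {
  n <- nrow(log$individuals)
  ewa_params(
    id = log$individuals$id,
    lambda = runif(n, 0, 6), phi = runif(n, 0.02, 0.6),
    gamma = runif(n, 0, 0.8), fc = runif(n, 0.5, 2.5),
    beta_pay = rnorm(n), beta_rank = rnorm(n), beta_kin = rnorm(n),
    beta_fem = rnorm(n), beta_sex = rnorm(n)
  )
}

# Independent brute-force recursion over a log: plain base-R re-derivation
# of the forward model, written without any package internals, used as the
# oracle for sequence_loglik. Window logic, cue means, softmax and the
# convex combination are all recomputed from first principles.
brute_force_loglik <- function(log, params, spec, width = 20) {
  ev <- log$events
  ind <- log$individuals
  techs <- log$techniques
  A <- matrix(0, nrow(ind), length(techs),
              dimnames = list(ind$id, techs))
  out <- numeric(nrow(ev))
  for (e in seq_len(nrow(ev))) {
    j <- ev$actor_id[e]
    prow <- params[params$id == j, ]
    # individual part
    z <- prow$lambda * A[j, ]
    I <- exp(z - max(z)); I <- I / sum(I)
    P <- I
    if (spec$name != "individual") {
      # window scan
      sel <- which(ev$session_id == ev$session_id[e] &
                     ev$time_min >= ev$time_min[e] - width &
                     ev$time_min < ev$time_min[e])
      sel <- sel[vapply(sel, function(i) {
        j %in% ev$observers[[i]] && ev$actor_id[i] != j
      }, logical(1))]
      if (length(sel)) {
        N <- sapply(techs, function(tk) sum(ev$technique[sel] == tk))
        if (sum(N) > 0) {
          fc <- if (spec$fc_free) prow$fc else 1
          w <- numeric(length(techs))
          for (ki in seq_along(techs)) {
            if (N[ki] == 0) { w[ki] <- 0; next }
            si <- sel[ev$technique[sel] == techs[ki]]
            demo <- match(ev$actor_id[si], ind$id)
            B <- 0
            if ("pay" %in% spec$active_betas)
              B <- B + prow$beta_pay * mean(ev$outcome[si] == "success")
            if ("rank" %in% spec$active_betas)
              B <- B + prow$beta_rank * mean(ind$rank[demo])
            if ("kin" %in% spec$active_betas)
              B <- B + prow$beta_kin * mean(log$kin[j, ind$id[demo]])
            if ("fem" %in% spec$active_betas)
              B <- B + prow$beta_fem *
                mean(ind$sex[demo] == "F" & ind$age_class[demo] == "adult")
            if ("sex" %in% spec$active_betas)
              B <- B + prow$beta_sex *
                mean(ind$sex[demo] == ind$sex[match(j, ind$id)])
            w[ki] <- N[ki]^fc * exp(B)
          }
          S <- w / sum(w)
          P <- (1 - prow$gamma) * I + prow$gamma * S
        }
      }
    }
    k <- match(ev$technique[e], techs)
    out[e] <- log(P[k])
    pay <- as.numeric(ev$outcome[e] == "success")
    A[j, k] <- (1 - prow$phi) * A[j, k] + prow$phi * pay
  }
  out
}
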