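#' Prior configuration for hierarchical EWA fits
#'
#' Regularising priors on the link scale: normal means and age/sex offsets,
#' exponential scales for the varying-effect standard deviations, and an
#' LKJ prior on the varying-effect correlation matrices.
#'
#' @param mean_sd Standard deviation of the normal prior on population means.
#' @param offset_sd Standard deviation of the normal prior on age/sex offsets.
#' @param sigma_rate Rate of the exponential prior on varying-effect scales.
#' @param lkj_eta Concentration of the LKJ correlation prior (> 0; larger
#'   values concentrate mass near the identity).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(mean_sd = 1, offset_sd = 1, sigma_rate = 1,
                         lkj_eta = 4) {
  stopifnot(mean_sd > 0, offset_sd > 0, sigma_rate > 0, lkj_eta > 0)
  structure(list(mean_sd = mean_sd, offset_sd = offset_sd,
                 sigma_rate = sigma_rate, lkj_eta = lkj_eta),
            class = "prior_config")
}

# canonical hierarchical parameter bookkeeping ------------------------------

.param_slots <- c(lambda = 1, phi = 2, gamma = 3, fc = 4, beta_pay = 5,
                  beta_rank = 6, beta_kin = 7, beta_fem = 8, beta_sex = 9)
.param_links <- c(lambda = "log", phi = "logit", gamma = "logit", fc = "log",
                  beta_pay = "identity", beta_rank = "identity",
                  beta_kin = "identity", beta_fem = "identity",
                  beta_sex = "identity")
.link_codes <- c(identity = 0L, log = 1L, logit = 2L)

hier_params <- function(spec) {
  out <- c("lambda", "phi")
  if (spec$social) out <- c(out, "gamma")
  if (spec$fc_free) out <- c(out, "fc")
  if (length(spec$active_betas)) {
    ord <- c("pay", "rank", "kin", "fem", "sex")
    out <- c(out, paste0("beta_", ord[ord %in% spec$active_betas]))
  }
  out
}

inv_link <- function(x, link) {
  switch(link, log = exp(x), logit = plogis(x), x)
}

#' Build a fitting-ready design bundle from a log
#'
#' Precomputes everything the sampler needs: integer-indexed individuals and
#' groups, event arrays aligned to the log, the windowed cue arrays, and the
#' hierarchical parameter layout implied by the model spec. Individuals with
#' no events carry no information about their varying effects and are
#' excluded (with a warning).
#'
#' @param log An [ewa_log].
#' @param spec An [ewa_spec()].
#' @param window A [cue_window_config()].
#' @return A list of class `ewa_design`.
#' @export
build_design <- function(log, spec, window = cue_window_config()) {
  stopifnot(inherits(log, "ewa_log"), inherits(spec, "ewa_spec"))
  ev <- log$events
  active_ids <- unique(ev$actor_id)
  inactive <- setdiff(log$individuals$id, active_ids)
  if (length(inactive)) {
    warning(length(inactive), " individual(s) with zero events excluded ",
            "from varying effects: ", paste(inactive, collapse = ", "),
            call. = FALSE)
  }
  ind <- log$individuals[log$individuals$id %in% active_ids, ]
  arrs <- cue_arrays(log, window)
  hp <- hier_params(spec)
  design <- list(
    actor = match(ev$actor_id, ind$id),
    tech = match(ev$technique, log$techniques),
    payoff = as.numeric(ev$outcome == "success"),
    cues = arrs,
    social_defined = rowSums(arrs$n) > 0,
    individuals = ind,
    juv = as.integer(ind$age_class == "juvenile"),
    male = as.integer(ind$sex == "M"),
    grp = match(ind$group, unique(ind$group)),
    group_names = unique(ind$group),
    hier = hp,
    slots = unname(.param_slots[hp]),
    links = unname(.param_links[hp]),
    spec = spec, window = window,
    techniques = log$techniques,
    events = ev[, c("session_id", "date", "time_min", "actor_id",
                    "technique", "outcome")]
  )
  class(design) <- "ewa_design"
  design
}

hyper_layout <- function(design) {
  p <- length(design$hier)
  q <- p * (p - 1) / 2
  J <- nrow(design$individuals)
  G <- length(design$group_names)
  nm <- c(paste0("mu_", design$hier),
          paste0("b_juv_", design$hier),
          paste0("b_male_", design$hier),
          paste0("log_sigma_ind_", design$hier),
          if (q) paste0("y_ind_", seq_len(q)),
          paste0("log_sigma_grp_", design$hier),
          if (q) paste0("y_grp_", seq_len(q)),
          paste0("z_ind_", rep(design$individuals$id, each = p), "_",
                 rep(design$hier, J)),
          paste0("z_grp_", rep(design$group_names, each = p), "_",
                 rep(design$hier, G)))
  list(p = p, q = q, J = J, G = G, n = length(nm), names = nm,
       i_mu = 0L, i_bj = p, i_bm = 2L * p, i_lsi = 3L * p, i_yi = 4L * p,
       i_lsg = 4L * p + q, i_yg = 5L * p + q, i_zi = 5L * p + 2L * q,
       i_zg = 5L * p + 2L * q + p * J)
}

# R mirror of the C++ partial-correlation Cholesky transform
chol_from_y <- function(p, y) {
  L <- diag(p)
  cidx <- 1
  for (i in seq_len(p)[-1]) {
    sumsq <- 0
    for (j in seq_len(i - 1)) {
      z <- tanh(y[cidx])
      L[i, j] <- z * sqrt(1 - sumsq)
      sumsq <- sumsq + L[i, j]^2
      cidx <- cidx + 1
    }
    L[i, i] <- sqrt(max(1 - sumsq, 0))
  }
  L
}

# R mirror of the C++ natural-parameter assembly (J x 9 matrix)
assemble_draw <- function(theta, design) {
  lay <- hyper_layout(design)
  p <- lay$p
  Li <- chol_from_y(p, theta[lay$i_yi + seq_len(lay$q)])
  Lg <- chol_from_y(p, theta[lay$i_yg + seq_len(lay$q)])
  si <- exp(theta[lay$i_lsi + seq_len(p)])
  sg <- exp(theta[lay$i_lsg + seq_len(p)])
  Zi <- matrix(theta[lay$i_zi + seq_len(p * lay$J)], nrow = p)
  Zg <- matrix(theta[lay$i_zg + seq_len(p * lay$G)], nrow = p)
  Ui <- (si * Li) %*% Zi   # p x J
  Ug <- (sg * Lg) %*% Zg   # p x G
  P <- matrix(rep(c(1, 0, 0, 1, 0, 0, 0, 0, 0), each = lay$J), lay$J, 9)
  for (r in seq_len(p)) {
    eta <- theta[lay$i_mu + r] + theta[lay$i_bj + r] * design$juv +
      theta[lay$i_bm + r] * design$male + Ui[r, ] + Ug[r, design$grp]
    P[, design$slots[r]] <- inv_link(eta, design$links[r])
  }
  colnames(P) <- names(.param_slots)
  rownames(P) <- design$individuals$id
  P
}

# link-scale MAP of the homogeneous model (shared parameters, no varying
# effects); used to start the chains in the likelihood's high-density region
homogeneous_map <- function(design, priors) {
  p <- length(design$hier)
  J <- nrow(design$individuals)
  obj <- function(eta) {
    P <- matrix(rep(c(1, 0, 0, 1, 0, 0, 0, 0, 0), each = J), J, 9)
    for (r in seq_len(p)) {
      P[, design$slots[r]] <- inv_link(eta[r], design$links[r])
    }
    ll <- sum(ewa_loglik_cpp(design$actor, design$tech, design$payoff,
                             design$cues$n, design$cues$paybar,
                             design$cues$rank, design$cues$kin,
                             design$cues$fem, design$cues$samesex,
                             P, design$spec$social, FALSE)$loglik)
    -(ll - 0.5 * sum((eta / priors$mean_sd)^2))
  }
  fit <- stats::optim(rep(0, p), obj, method = "BFGS",
                      control = list(maxit = 200))
  fit$par
}

#' Fit a hierarchical EWA model
#'
#' Samples the posterior of a learning-strategy model with fixed effects of
#' age class and sex and correlated varying effects of individual and group
#' on every hierarchical parameter (log link for `lambda` and `fc`, logit
#' link for `phi` and `gamma`, identity for the cue coefficients). Sampling
#' is by adaptive Metropolis-within-Gibbs on a non-centred parameterisation;
#' runs are reproducible under a fixed seed and chain count.
#'
#' @param log An [ewa_log] (or a prebuilt `ewa_design`).
#' @param spec An [ewa_spec()]; ignored when `log` is already a design.
#' @param window A [cue_window_config()]; ignored for a design.
#' @param priors A [prior_config()].
#' @param chains Number of chains (>= 2 for split-Rhat diagnostics).
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup (adaptation) iterations per chain.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param max_init_tries Reinitialisation attempts if the likelihood is not
#'   finite at the starting point.
#' @return An object of class `ewa_fit` with posterior draws on the link
#'   scale, pointwise log-likelihood (draws x events) for WAIC, and
#'   split-Rhat/effective-sample-size diagnostics.
#' @seealso [natural_scale()], [compute_waic()], [posterior_predict()]
#' @export
fit_ewa <- function(log, spec, window = cue_window_config(),
                    priors = prior_config(), chains = 2, iter = 500,
                    warmup = iter, seed = 1, max_init_tries = 20) {
  design <- if (inherits(log, "ewa_design")) log
            else build_design(log, spec, window)
  lay <- hyper_layout(design)
  E <- length(design$actor)
  chain_draws <- vector("list", chains)
  chain_pw <- vector("list", chains)
  accept <- matrix(NA_real_, chains, 2,
                   dimnames = list(NULL, c("scalar", "block")))
  map_eta <- homogeneous_map(design, priors)
  p <- lay$p
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    res <- NULL
    for (try in seq_len(max_init_tries)) {
      init <- rnorm(lay$n, 0, 0.1)
      init[lay$i_mu + seq_len(p)] <- map_eta + rnorm(p, 0, 0.2)
      init[lay$i_lsi + seq_len(p)] <- log(0.2) + rnorm(p, 0, 0.2)
      init[lay$i_lsg + seq_len(p)] <- log(0.2) + rnorm(p, 0, 0.2)
      if (lay$G == 1) {
        # single group: the group level is confounded with the population
        # mean and is frozen at zero inside the sampler
        init[lay$i_lsg + seq_len(p)] <- 0
        init[lay$i_yg + seq_len(lay$q)] <- 0
        init[lay$i_zg + seq_len(p * lay$G)] <- 0
      }
      res <- tryCatch(
        ewa_mcmc_cpp(design$actor, design$tech, design$payoff,
                     design$cues$n, design$cues$paybar, design$cues$rank,
                     design$cues$kin, design$cues$fem, design$cues$samesex,
                     design$spec$social,
                     design$juv, design$male, design$grp,
                     as.integer(design$slots),
                     unname(.link_codes[design$links]),
                     priors$mean_sd, priors$offset_sd, priors$sigma_rate,
                     priors$lkj_eta, init, as.integer(warmup),
                     as.integer(iter)),
        error = function(e) {
          if (grepl("non-finite initial", conditionMessage(e))) NULL
          else stop(e)
        })
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop("could not find a finite starting point after ", max_init_tries,
           " tries", call. = FALSE)
    }
    colnames(res$draws) <- lay$names
    chain_draws[[ch]] <- res$draws
    chain_pw[[ch]] <- res$pointwise
    accept[ch, ] <- c(res$accept_scalar, res$accept_block)
  }
  fit <- structure(
    list(chain_draws = chain_draws,
         draws = do.call(rbind, chain_draws),
         pointwise_loglik = do.call(rbind, chain_pw),
         accept = accept,
         design = design, spec = design$spec, priors = priors,
         chains = chains, iter = iter, warmup = warmup, seed = seed,
         hyper_names = lay$names),
    class = "ewa_fit"
  )
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

split_rhat <- function(mats) {
  # mats: list of iter x 1 chains for one parameter -> split each in half
  halves <- unlist(lapply(mats, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(mats) {
  # effective sample size from pooled within-chain autocorrelations
  # (initial positive sequence estimator)
  n <- length(mats[[1]]); m <- length(mats)
  if (n < 4) return(NA_real_)
  centred <- lapply(mats, function(x) x - mean(x))
  v <- mean(vapply(centred, function(x) sum(x^2) / n, numeric(1)))
  if (v == 0) return(NA_real_)
  rho_sum <- 0
  for (lag in seq_len(min(n - 2, 200))) {
    rho <- mean(vapply(centred, function(x) {
      sum(x[seq_len(n - lag)] * x[(lag + 1):n]) / n
    }, numeric(1))) / v
    if (rho < 0.01) break
    rho_sum <- rho_sum + rho
  }
  m * n / (1 + 2 * rho_sum)
}

fit_diagnostics <- function(fit) {
  nm <- fit$hyper_names
  out <- tibble::tibble(
    parameter = nm,
    rhat = vapply(seq_along(nm), function(i) {
      split_rhat(lapply(fit$chain_draws, function(d) d[, i]))
    }, numeric(1)),
    ess = vapply(seq_along(nm), function(i) {
      ess_basic(lapply(fit$chain_draws, function(d) d[, i]))
    }, numeric(1))
  )
  out
}

#' @export
print.ewa_fit <- function(x, ...) {
  cat("<ewa_fit> spec '", x$spec$name, "': ", x$chains, " chains x ",
      x$iter, " draws, ", length(x$design$actor), " events, ",
      nrow(x$design$individuals), " individuals\n", sep = "")
  hyper <- grepl("^(mu|b_juv|b_male|log_sigma)", x$hyper_names)
  cat("  max split-Rhat (hierarchy): ",
      round(max(x$diagnostics$rhat[hyper], na.rm = TRUE), 3),
      "; mean acceptance (scalar/block): ",
      paste(round(colMeans(x$accept), 2), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Natural-scale posterior summaries
#'
#' Applies the inverse links to the assembled linear predictor for a
#' selector and summarises the draws (posterior mean and 89\% HPDI).
#' Marginal age-class summaries average over the empirical sex distribution
#' of that class and vice versa; `"population"` averages over the empirical
#' joint age/sex distribution.
#'
#' @param fit An [fit_ewa()] result.
#' @param who One of `"population"`, `"age:adult"`, `"age:juvenile"`,
#'   `"sex:F"`, `"sex:M"`, `"group:<name>"`, `"individual:<id>"`.
#' @param mass HPDI mass (default 0.89).
#' @return A tibble with columns `selector`, `parameter`, `mean`, `lower`,
#'   `upper`.
#' @export
natural_scale <- function(fit, who = "population", mass = 0.89) {
  stopifnot(inherits(fit, "ewa_fit"))
  design <- fit$design
  lay <- hyper_layout(design)
  draws <- fit$draws
  nd <- nrow(draws)
  p <- lay$p
  ind <- design$individuals

  sel <- strsplit(who, ":", fixed = TRUE)[[1]]
  kind <- sel[1]
  level <- if (length(sel) > 1) sel[2] else NA_character_

  if (kind == "individual") {
    j <- match(level, ind$id)
    if (is.na(j)) stop("unknown individual '", level, "'", call. = FALSE)
    vals <- matrix(NA_real_, nd, p)
    for (dix in seq_len(nd)) {
      P <- assemble_draw(draws[dix, ], design)
      vals[dix, ] <- P[j, design$slots]
    }
  } else {
    # population-level cells weighted by the empirical age/sex distribution
    cells <- switch(kind,
      population = ind[, c("age_class", "sex")],
      age = {
        if (!level %in% c("adult", "juvenile"))
          stop("unknown age class '", level, "'", call. = FALSE)
        ind[ind$age_class == level, c("age_class", "sex")]
      },
      sex = {
        if (!level %in% c("F", "M"))
          stop("unknown sex '", level, "'", call. = FALSE)
        ind[ind$sex == level, c("age_class", "sex")]
      },
      group = {
        g <- match(level, design$group_names)
        if (is.na(g)) stop("unknown group '", level, "'", call. = FALSE)
        ind[ind$group == level, c("age_class", "sex")]
      },
      stop("unknown selector '", who, "'", call. = FALSE)
    )
    juv_w <- as.numeric(cells$age_class == "juvenile")
    male_w <- as.numeric(cells$sex == "M")
    g_eff <- kind == "group"
    g_idx <- if (g_eff) match(level, design$group_names) else NA
    vals <- matrix(NA_real_, nd, p)
    for (dix in seq_len(nd)) {
      th <- draws[dix, ]
      for (r in seq_len(p)) {
        eta <- th[lay$i_mu + r] + th[lay$i_bj + r] * juv_w +
          th[lay$i_bm + r] * male_w
        if (g_eff) {
          Lg <- chol_from_y(p, th[lay$i_yg + seq_len(lay$q)])
          sg <- exp(th[lay$i_lsg + seq_len(p)])
          zg <- th[lay$i_zg + (g_idx - 1) * p + seq_len(p)]
          eta <- eta + ((sg * Lg) %*% zg)[r]
        }
        vals[dix, r] <- mean(inv_link(eta, design$links[r]))
      }
    }
  }
  purrr::map_dfr(seq_len(p), function(r) {
    h <- hpdi(vals[, r], mass)
    tibble::tibble(selector = who, parameter = design$hier[r],
                   mean = mean(vals[, r]), lower = h[1], upper = h[2])
  })
}

#' Per-individual natural-scale parameters at one posterior draw
#'
#' @param fit An `ewa_fit`.
#' @param draw Draw index (row of the pooled draw matrix).
#' @return An [ewa_params()] tibble for the design's individuals.
#' @export
fitted_params <- function(fit, draw = 1) {
  stopifnot(inherits(fit, "ewa_fit"))
  P <- assemble_draw(fit$draws[draw, ], fit$design)
  tibble::as_tibble(cbind(tibble::tibble(id = rownames(P)),
                          as.data.frame(P)))
}

#' Prior-predictive draws of the population-level natural parameters
#'
#' Samples population means from the priors and maps them through the
#' links; used to check that the link functions enforce the declared
#' parameter bounds.
#'
#' @param spec An [ewa_spec()].
#' @param priors A [prior_config()].
#' @param n Number of draws.
#' @return A tibble of natural-scale population parameter draws.
#' @export
prior_predictive <- function(spec, priors = prior_config(), n = 1000) {
  hp <- hier_params(spec)
  out <- purrr::map(hp, function(pn) {
    inv_link(rnorm(n, 0, priors$mean_sd), .param_links[[pn]])
  })
  names(out) <- hp
  tibble::as_tibble(out)
}

#' @export
tidy.ewa_fit <- function(x, by = "age_sex", mass = 0.89, ...) {
  sels <- switch(by,
    population = "population",
    age_sex = c("sex:F", "sex:M", "age:juvenile", "age:adult"),
    group = paste0("group:", x$design$group_names),
    individual = paste0("individual:", x$design$individuals$id),
    by
  )
  purrr::map_dfr(sels, function(s) natural_scale(x, s, mass)) |>
    dplyr::rename(term = "parameter", estimate = "mean",
                  conf.low = "lower", conf.high = "upper")
}

#' @export
glance.ewa_fit <- function(x, ...) {
  w <- compute_waic(x$pointwise_loglik)
  hyper <- grepl("^(mu|b_juv|b_male|log_sigma)", x$hyper_names)
  tibble::tibble(
    spec = x$spec$name,
    n_events = length(x$design$actor),
    n_individuals = nrow(x$design$individuals),
    chains = x$chains, iter = x$iter,
    waic = w$waic, p_waic = w$p_waic,
    max_rhat = max(x$diagnostics$rhat[hyper], na.rm = TRUE),
    min_ess = min(x$diagnostics$ess[hyper], na.rm = TRUE),
    accept_scalar = mean(x$accept[, "scalar"]),
    accept_block = mean(x$accept[, "block"])
  )
}
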