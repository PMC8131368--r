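#' Configuration of the social-information window
#'
#' Social information available to an actor at a choice is everything it
#' attended in a fixed window of time immediately before the choice, within
#' the same session. The default width is 20 minutes; 5, 10 and 30 minutes
#' are the usual robustness settings.
#'
#' @param width_min Window width in minutes (> 0).
#' @param include_own_events Should an individual's own past manipulations
#'   count as social information for itself? Defaults to `FALSE`: personal
#'   experience acts through attraction scores instead.
#' @return A list of class `cue_window_config`.
#' @export
cue_window_config <- function(width_min = 20, include_own_events = FALSE) {
  stopifnot(is.numeric(width_min), length(width_min) == 1, width_min > 0)
  structure(list(width_min = width_min,
                 include_own_events = isTRUE(include_own_events)),
            class = "cue_window_config")
}

#' Events an observer attended in the window before a time point
#'
#' Returns the manipulation events of the same session with time in the
#' half-open interval `[t - width, t)` whose attendance set contains
#' `observer`. The half-open bound means an event at exactly `t` never
#' informs a choice at `t`, and by default the observer's own manipulations
#' are excluded.
#'
#' @param log An [ewa_log].
#' @param observer Individual id.
#' @param t Time in minutes since session start.
#' @param session Session id.
#' @param cfg A [cue_window_config()].
#' @return A tibble of events (possibly zero rows) in time order.
#' @export
attended_events <- function(log, observer, t, session,
                            cfg = cue_window_config()) {
  stopifnot(inherits(log, "ewa_log"), inherits(cfg, "cue_window_config"))
  ev <- log$events
  keep <- ev$session_id == session &
    ev$time_min >= t - cfg$width_min & ev$time_min < t
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev)) {
    # an actor is never in its own attendance set, so own events only
    # enter when explicitly requested
    saw <- vapply(ev$observers, function(o) observer %in% o, logical(1))
    if (cfg$include_own_events) saw <- saw | ev$actor_id == observer
    ev <- ev[saw, , drop = FALSE]
  }
  ev
}

#' Social cues carried by a set of attended events
#'
#' Reduces the events an observer attended to the per-technique cue set of
#' the learning model: the observation count `n`, the mean observed payoff
#' `paybar` (proportion of attended demonstrations of the technique that
#' succeeded), and the mean demonstrator-trait cues `rank` (normalised
#' dominance rank), `kin` (relatedness to the observer), `fem` (proportion of
#' demonstrations by adult females) and `samesex` (proportion by
#' demonstrators of the observer's sex). Cue means of techniques never
#' observed in the window are undefined (`NA`).
#'
#' @param events A tibble of events as returned by [attended_events()] (all
#'   attended by `observer`).
#' @param log The [ewa_log] supplying demonstrator attributes and kinship.
#' @param observer The observing individual's id.
#' @return A tibble with one row per technique of the log's alphabet, columns
#'   `technique`, `n`, `paybar`, `rank`, `kin`, `fem`, `samesex`.
#' @export
compute_cues <- function(events, log, observer) {
  stopifnot(inherits(log, "ewa_log"))
  ind <- log$individuals
  obs_row <- match(observer, ind$id)
  if (is.na(obs_row)) stop("unknown observer id '", observer, "'", call. = FALSE)
  out <- tibble::tibble(
    technique = log$techniques, n = 0L,
    paybar = NA_real_, rank = NA_real_, kin = NA_real_,
    fem = NA_real_, samesex = NA_real_
  )
  if (!nrow(events)) return(out)
  demo <- match(events$actor_id, ind$id)
  pay <- as.numeric(events$outcome == "success")
  rnk <- ind$rank[demo]
  kin <- log$kin[obs_row, ][ind$id[demo]]
  fem <- as.numeric(ind$sex[demo] == "F" & ind$age_class[demo] == "adult")
  same <- as.numeric(ind$sex[demo] == ind$sex[obs_row])
  for (k in seq_along(log$techniques)) {
    sel <- events$technique == log$techniques[k]
    nk <- sum(sel)
    out$n[k] <- nk
    if (nk > 0) {
      out$paybar[k] <- mean(pay[sel])
      out$rank[k] <- mean(rnk[sel])
      out$kin[k] <- mean(kin[sel])
      out$fem[k] <- mean(fem[sel])
      out$samesex[k] <- mean(same[sel])
    }
  }
  out
}

#' Cue table for every choice in a log
#'
#' Computes, for each manipulation event, the social cues its actor had
#' available at the moment of choice (one row per event x technique), in a
#' tidy layout suitable for export and audit.
#'
#' @param log An [ewa_log].
#' @param cfg A [cue_window_config()].
#' @return A tibble with columns `event`, `session_id`, `time_min`,
#'   `actor_id` and the [compute_cues()] columns.
#' @export
build_cue_table <- function(log, cfg = cue_window_config()) {
  stopifnot(inherits(log, "ewa_log"))
  ev <- log$events
  rows <- purrr::map(seq_len(nrow(ev)), function(e) {
    att <- attended_events(log, ev$actor_id[e], ev$time_min[e],
                           ev$session_id[e], cfg)
    cues <- compute_cues(att, log, ev$actor_id[e])
    dplyr::bind_cols(
      tibble::tibble(event = e, session_id = ev$session_id[e],
                     time_min = ev$time_min[e], actor_id = ev$actor_id[e]),
      cues
    )
  })
  dplyr::bind_rows(rows)
}

# Internal: cue arrays aligned to events, as E x K matrices, for the fast
# likelihood path. Undefined cue means are stored as 0; they are only ever
# multiplied into the social kernel where n > 0.
cue_arrays <- function(log, cfg = cue_window_config()) {
  ev <- log$events
  K <- length(log$techniques)
  E <- nrow(ev)
  mats <- list(n = matrix(0, E, K), paybar = matrix(0, E, K),
               rank = matrix(0, E, K), kin = matrix(0, E, K),
               fem = matrix(0, E, K), samesex = matrix(0, E, K))
  for (e in seq_len(E)) {
    att <- attended_events(log, ev$actor_id[e], ev$time_min[e],
                           ev$session_id[e], cfg)
    if (!nrow(att)) next
    cues <- compute_cues(att, log, ev$actor_id[e])
    mats$n[e, ] <- cues$n
    for (nm in c("paybar", "rank", "kin", "fem", "samesex")) {
      v <- cues[[nm]]
      v[is.na(v)] <- 0
      mats[[nm]][e, ] <- v
    }
  }
  mats
}
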