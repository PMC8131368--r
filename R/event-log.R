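#' Assemble a validated open-diffusion event log
#'
#' Bundles time-stamped manipulation events, the individual attribute table
#' and an optional pairwise relatedness matrix into a validated `ewa_log`
#' object, the unit of analysis for all downstream EWA modelling.
#'
#' @param events A data frame with one row per manipulation event and columns
#'   `session_id`, `date` (ISO-8601 string or `Date`), `time_min` (minutes
#'   since session start, fractional allowed), `actor_id`, `technique`,
#'   `outcome` (`"success"` or `"failure"`), and `observers` (either a
#'   list-column of character vectors or a semicolon-separated string of ids,
#'   possibly empty).
#' @param individuals A data frame with columns `id`, `group`, `sex`
#'   (`"F"`/`"M"`), `age_class` (`"adult"`, `"juvenile"` or `"infant"`;
#'   infants are merged into the juvenile class for modelling, the raw coding
#'   is preserved in `age_class_raw`), `rank` (normalised dominance rank in
#'   \[0, 1\], 1 = highest) and `matriline` (label or `NA`).
#' @param kin Optional square numeric matrix of relatedness coefficients in
#'   \[0, 1\] with row/column names matching `individuals$id`; must be
#'   symmetric with unit diagonal. Defaults to the identity (no relatedness
#'   information).
#' @param techniques Character vector giving the technique alphabet
#'   (at least two); defaults to the three peanut-processing techniques
#'   `c("CMS", "CMT", "CH")`.
#'
#' @return An object of class `ewa_log`: a list with elements `events`
#'   (tibble, sorted by session and time, `observers` as a list-column),
#'   `individuals` (tibble), `kin` (matrix) and `techniques`.
#'
#' @details Events are sorted non-decreasing in time within session; out of
#'   order input is repaired with a warning. An actor may not appear in its
#'   own attendance set. Every actor and observer id must resolve to a row of
#'   `individuals`.
#'
#' @examples
#' inds <- tibble::tibble(
#'   id = c("A", "B"), group = "G1", sex = c("F", "M"),
#'   age_class = c("adult", "juvenile"), rank = c(1, 0), matriline = "m1"
#' )
#' ev <- tibble::tibble(
#'   session_id = "s1", date = "2018-05-01", time_min = c(1, 2.5),
#'   actor_id = c("A", "B"), technique = c("CMS", "CH"),
#'   outcome = c("success", "failure"), observers = c("B", "")
#' )
#' log <- ewa_log(ev, inds)
#' summarize_log(log)
#' @export
ewa_log <- function(events, individuals, kin = NULL,
                    techniques = .default_techniques) {
  stopifnot(is.data.frame(events), is.data.frame(individuals))
  if (length(techniques) < 2) {
    stop("technique alphabet must contain at least two techniques", call. = FALSE)
  }
  individuals <- tibble::as_tibble(individuals)
  req_ind <- c("id", "group", "sex", "age_class", "rank", "matriline")
  missing_cols <- setdiff(req_ind, names(individuals))
  if (length(missing_cols)) {
    stop("individuals table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id)) {
    stop("individual ids must be unique", call. = FALSE)
  }
  if (any(!is.finite(individuals$rank)) ||
      any(individuals$rank < 0 | individuals$rank > 1)) {
    stop("ranks must lie in [0, 1]", call. = FALSE)
  }
  if (!all(individuals$sex %in% c("F", "M"))) {
    stop("sex must be coded F or M", call. = FALSE)
  }
  if (!all(individuals$age_class %in% c("adult", "juvenile", "infant"))) {
    stop("age_class must be adult, juvenile or infant", call. = FALSE)
  }
  # infants are modelled as juveniles; keep the raw coding for provenance
  if (!"age_class_raw" %in% names(individuals)) {
    individuals$age_class_raw <- individuals$age_class
  }
  individuals$age_class <- ifelse(individuals$age_class == "infant",
                                  "juvenile", individuals$age_class)

  events <- tibble::as_tibble(events)
  req_ev <- c("session_id", "date", "time_min", "actor_id", "technique",
              "outcome", "observers")
  missing_cols <- setdiff(req_ev, names(events))
  if (length(missing_cols)) {
    stop("events table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events$session_id <- as.character(events$session_id)
  events$date <- as.Date(events$date)
  events$actor_id <- as.character(events$actor_id)
  if (!is.list(events$observers)) {
    events$observers <- parse_observers(events$observers)
  }
  events$observers <- lapply(events$observers, function(x) {
    x <- as.character(x)
    x[nzchar(x)]
  })
  if (nrow(events)) {
    if (any(!is.finite(events$time_min)) || any(events$time_min < 0)) {
      stop("event times must be finite and non-negative", call. = FALSE)
    }
    bad_tech <- setdiff(unique(events$technique), techniques)
    if (length(bad_tech)) {
      stop("unknown technique(s): ", paste(bad_tech, collapse = ", "),
           call. = FALSE)
    }
    if (!all(events$outcome %in% c("success", "failure"))) {
      stop("outcome must be 'success' or 'failure'", call. = FALSE)
    }
    ids <- individuals$id
    bad_actor <- which(!(events$actor_id %in% ids))
    if (length(bad_actor)) {
      stop("event row ", bad_actor[1], ": unknown actor id '",
           events$actor_id[bad_actor[1]], "'", call. = FALSE)
    }
    all_obs <- unique(unlist(events$observers))
    bad_obs <- setdiff(all_obs, ids)
    if (length(bad_obs)) {
      row <- which(vapply(events$observers,
                          function(o) any(o %in% bad_obs), logical(1)))[1]
      stop("event row ", row, ": unknown observer id '", bad_obs[1], "'",
           call. = FALSE)
    }
    self_obs <- mapply(function(a, o) a %in% o,
                       events$actor_id, events$observers)
    if (any(self_obs)) {
      stop("event row ", which(self_obs)[1],
           ": actor appears in its own attendance set", call. = FALSE)
    }
    # sessions ordered by first date then label; events non-decreasing in time
    sess_order <- events |>
      dplyr::group_by(.data$session_id) |>
      dplyr::summarise(first_date = min(.data$date), .groups = "drop") |>
      dplyr::arrange(.data$first_date, .data$session_id)
    events$session_id <- factor(events$session_id,
                                levels = sess_order$session_id)
    resorted <- events |> dplyr::arrange(.data$session_id, .data$time_min)
    if (!identical(resorted$time_min, events$time_min) ||
        !identical(as.character(resorted$session_id),
                   as.character(events$session_id))) {
      warning("events were not sorted by (session, time); repaired",
              call. = FALSE)
    }
    events <- resorted
    events$session_id <- as.character(events$session_id)
  }

  if (is.null(kin)) {
    kin <- diag(nrow(individuals))
    dimnames(kin) <- list(individuals$id, individuals$id)
  }
  kin <- as.matrix(kin)
  if (is.null(rownames(kin)) || is.null(colnames(kin))) {
    stop("kin matrix must carry id row and column names", call. = FALSE)
  }
  missing_ids <- setdiff(individuals$id, rownames(kin))
  if (length(missing_ids)) {
    stop("kin matrix lacks individual(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  kin <- kin[individuals$id, individuals$id, drop = FALSE]
  if (!isTRUE(all.equal(kin, t(kin), tolerance = 1e-8))) {
    stop("kin matrix must be symmetric", call. = FALSE)
  }
  if (!isTRUE(all.equal(unname(diag(kin)), rep(1, nrow(kin))))) {
    stop("kin matrix must have unit diagonal", call. = FALSE)
  }
  if (any(kin < 0 | kin > 1)) {
    stop("relatedness coefficients must lie in [0, 1]", call. = FALSE)
  }

  structure(
    list(events = events, individuals = individuals, kin = kin,
         techniques = techniques),
    class = "ewa_log"
  )
}

parse_observers <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(trimws(x), "\\s*;\\s*")
}

#' @export
print.ewa_log <- function(x, ...) {
  cat("<ewa_log> ", nrow(x$events), " events, ",
      nrow(x$individuals), " individuals, ",
      length(unique(x$events$session_id)), " sessions, techniques: ",
      paste(x$techniques, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Read an event log from its three CSV components
#'
#' Reads `events.csv`, `individuals.csv` and (optionally) `kin.csv` in the
#' documented schema and returns a validated [ewa_log].
#'
#' @param events_path Path to the events CSV (`session_id, date, time_min,
#'   actor_id, technique, outcome, observers`), observers as a
#'   semicolon-separated id string (possibly empty).
#' @param individuals_path Path to the individuals CSV (`id, group, sex,
#'   age_class, rank, matriline`).
#' @param kin_path Optional path to a square relatedness matrix CSV whose
#'   first column holds ids and whose header row repeats them.
#' @param techniques Technique alphabet passed to [ewa_log()].
#' @return An [ewa_log] object.
#' @seealso [write_event_log()]
#' @export
read_event_log <- function(events_path, individuals_path, kin_path = NULL,
                           techniques = .default_techniques) {
  events <- readr::read_csv(events_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              session_id = "c", date = "D", time_min = "d",
                              actor_id = "c", technique = "c", outcome = "c",
                              observers = "c"))
  individuals <- readr::read_csv(individuals_path, show_col_types = FALSE,
                                 col_types = readr::cols(.default = "c",
                                                         rank = "d"))
  kin <- NULL
  if (!is.null(kin_path)) {
    kin_df <- readr::read_csv(kin_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = "d",
                                                      id = "c"))
    kin <- as.matrix(kin_df[, -1])
    rownames(kin) <- kin_df[[1]]
  }
  ewa_log(events, individuals, kin, techniques = techniques)
}

#' Write an event log to CSV files
#'
#' Emits `events.csv`, `individuals.csv` and `kin.csv` into `dir` in the
#' schema read back by [read_event_log()]; the round trip is lossless.
#'
#' @param log An [ewa_log].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_event_log <- function(log, dir) {
  stopifnot(inherits(log, "ewa_log"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- log$events
  ev$observers <- vapply(ev$observers, paste, collapse = ";",
                         FUN.VALUE = character(1))
  paths <- c(events = file.path(dir, "events.csv"),
             individuals = file.path(dir, "individuals.csv"),
             kin = file.path(dir, "kin.csv"))
  readr::write_csv(ev, paths[["events"]])
  ind <- log$individuals
  # raw age coding is written back so the round trip preserves provenance
  ind$age_class <- ind$age_class_raw
  ind$age_class_raw <- NULL
  readr::write_csv(ind, paths[["individuals"]])
  kin_df <- tibble::as_tibble(log$kin)
  kin_df <- dplyr::bind_cols(tibble::tibble(id = rownames(log$kin)), kin_df)
  readr::write_csv(kin_df, paths[["kin"]])
  invisible(paths)
}

#' Per-individual participation summary
#'
#' Counts successes, failed attempts and total manipulations per individual,
#' the cumulative-exposure latency to first success, and per-technique
#' success proportions.
#'
#' @param log An [ewa_log].
#' @return A tibble with one row per individual: `id`, `group`, `n_success`,
#'   `n_attempt`, `n_manipulation`, `latency_first_success` (minutes of
#'   cumulative session exposure before the first success, `NA` if never
#'   successful) and one `succ_<technique>` column per technique, giving that
#'   individual's successes with the technique as a proportion of all its
#'   manipulations (`NA` when the individual never manipulated).
#'
#' @details Latency accumulates exposure across sessions: the elapsed time of
#'   each completed earlier session (taken as its last event time) plus the
#'   event time of the first success within its session. Individuals with no
#'   events are retained with zero counts. An empty log yields an empty
#'   tibble.
#' @export
summarize_log <- function(log) {
  stopifnot(inherits(log, "ewa_log"))
  ev <- log$events
  if (!nrow(ev)) return(tibble::tibble())
  sess <- ev |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(duration = max(.data$time_min), .groups = "drop")
  sess$prior_exposure <- cumsum(dplyr::lag(sess$duration, default = 0))
  ev2 <- dplyr::left_join(ev, sess[, c("session_id", "prior_exposure")],
                          by = "session_id")
  ev2$exposure <- ev2$prior_exposure + ev2$time_min

  counts <- ev2 |>
    dplyr::group_by(id = .data$actor_id) |>
    dplyr::summarise(
      n_success = sum(.data$outcome == "success"),
      n_attempt = sum(.data$outcome == "failure"),
      n_manipulation = dplyr::n(),
      latency_first_success = if (any(.data$outcome == "success")) {
        min(.data$exposure[.data$outcome == "success"])
      } else NA_real_,
      .groups = "drop"
    )
  tech_prop <- ev2 |>
    dplyr::group_by(id = .data$actor_id, .data$technique) |>
    dplyr::summarise(n_succ_tech = sum(.data$outcome == "success"),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "technique", values_from = "n_succ_tech",
                       values_fill = 0)
  for (tech in setdiff(log$techniques, names(tech_prop))) {
    tech_prop[[tech]] <- 0
  }
  out <- log$individuals[, c("id", "group")] |>
    dplyr::left_join(counts, by = "id") |>
    dplyr::left_join(tech_prop, by = "id") |>
    dplyr::mutate(dplyr::across(
      c("n_success", "n_attempt", "n_manipulation"),
      ~ tidyr::replace_na(.x, 0L)
    ))
  for (tech in log$techniques) {
    out[[paste0("succ_", tech)]] <-
      ifelse(out$n_manipulation > 0,
             tidyr::replace_na(out[[tech]], 0) / out$n_manipulation,
             NA_real_)
    out[[tech]] <- NULL
  }
  out
}

#' Technique success rates over all manipulations
#'
#' For each group (or the whole population) and technique, the number of
#' successful events with that technique divided by the group's total
#' manipulations — the convention in which the three techniques' rates sum to
#' the group's overall success proportion.
#'
#' @param log An [ewa_log].
#' @param by `"group"` (default) or `"population"`.
#' @return A tibble with columns `group` (unless `by = "population"`),
#'   `technique`, `n_success`, `n_manipulation` and `rate` (percent).
#' @export
technique_success_rates <- function(log, by = c("group", "population")) {
  stopifnot(inherits(log, "ewa_log"))
  by <- match.arg(by)
  ev <- log$events
  if (!nrow(ev)) return(tibble::tibble())
  ev <- dplyr::left_join(ev,
                         log$individuals[, c("id", "group")],
                         by = c(actor_id = "id"))
  if (by == "population") ev$group <- "all"
  totals <- ev |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_manipulation = dplyr::n(), .groups = "drop")
  out <- tidyr::expand_grid(group = unique(ev$group),
                            technique = log$techniques) |>
    dplyr::left_join(
      ev |>
        dplyr::group_by(.data$group, .data$technique) |>
        dplyr::summarise(n_success = sum(.data$outcome == "success"),
                         .groups = "drop"),
      by = c("group", "technique")
    ) |>
    dplyr::mutate(n_success = tidyr::replace_na(.data$n_success, 0L)) |>
    dplyr::left_join(totals, by = "group") |>
    dplyr::mutate(rate = 100 * .data$n_success / .data$n_manipulation)
  if (by == "population") out$group <- NULL
  out
}
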