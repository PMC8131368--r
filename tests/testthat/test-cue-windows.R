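make_window_log <- function() {
  ev <- tibble::tibble(
    session_id = "s1", date = "2018-05-01",
    time_min = c(100, 105, 118, 120),
    actor_id = c("A", "B", "A", "C"),
    technique = c("CMS", "CMS", "CH", "CMT"),
    outcome = c("success", "failure", "success", "failure"),
    observers = c("C;B", "C;A", "C", "")
  )
  inds <- tibble::tibble(
    id = c("A", "B", "C"), group = "G1", sex = c("F", "M", "F"),
    age_class = c("adult", "adult", "juvenile"),
    rank = c(1, 0.5, 0.2), matriline = "m1"
  )
  ewa_log(ev, inds)
}

test_that("the half-open window collects exactly the attended events", {
  log <- make_window_log()
  # C attended events at 100, 105, 118; query at t = 120, width 20
  att <- attended_events(log, "C", 120, "s1")
  expect_equal(att$time_min, c(100, 105, 118))
  # the event at exactly t is excluded (half-open boundary)
  att <- attended_events(log, "C", 118, "s1")
  expect_equal(att$time_min, c(100, 105))
  # an observer attending nothing gets an empty window
  att <- attended_events(log, "B", 60, "s1")
  expect_equal(nrow(att), 0L)
  # narrower windows drop older events
  att <- attended_events(log, "C", 120, "s1", cue_window_config(5))
  expect_equal(att$time_min, 118)
})

test_that("own manipulations are excluded from social cues by default", {
  log <- make_window_log()
  att <- attended_events(log, "A", 120, "s1")
  expect_equal(att$actor_id, "B") # A's own events at 100, 118 dropped
  att_own <- attended_events(log, "A", 120, "s1",
                             cue_window_config(include_own_events = TRUE))
  expect_equal(att_own$actor_id, c("A", "B", "A"))
})

test_that("cue means reproduce hand arithmetic over a three-event window", {
  log <- make_window_log()
  # C saw (CMS success by A rank 1), (CMS failure by B rank .5),
  # (CH success by A rank 1)
  att <- attended_events(log, "C", 120, "s1")
  cues <- compute_cues(att, log, "C")
  expect_equal(cues$n[cues$technique == "CMS"], 2L)
  expect_equal(cues$n[cues$technique == "CH"], 1L)
  expect_equal(cues$n[cues$technique == "CMT"], 0L)
  expect_equal(cues$paybar[cues$technique == "CMS"], 0.5)
  expect_equal(cues$paybar[cues$technique == "CH"], 1)
  expect_equal(cues$rank[cues$technique == "CMS"], 0.75)
  expect_equal(cues$rank[cues$technique == "CH"], 1)
  # adult-female cue: A is adult F, B is adult M
  expect_equal(cues$fem[cues$technique == "CMS"], 0.5)
  # same-sex cue for female observer C
  expect_equal(cues$samesex[cues$technique == "CMS"], 0.5)
  # unobserved technique carries undefined cue means
  expect_true(is.na(cues$paybar[cues$technique == "CMT"]))
  # empty window: all counts zero, all means undefined
  empty <- compute_cues(att[0, ], log, "C")
  expect_equal(empty$n, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$paybar)))
})

test_that("a constant demonstrator kinship yields a constant kin cue", {
  log <- make_window_log()
  log$kin["C", c("A", "B")] <- 0.5
  log$kin[c("A", "B"), "C"] <- 0.5
  att <- attended_events(log, "C", 120, "s1")
  cues <- compute_cues(att, log, "C")
  expect_equal(cues$kin[cues$n > 0], c(0.5, 0.5))
})

test_that("cue-window invariants hold on random logs", {
  set.seed(42)
  for (i in 1:20) {
    log <- random_log(n_events = 12, n_ind = 4)
    ev <- log$events
    e <- sample(nrow(ev), 1)
    widths <- c(5, 10, 20, 30)
    n_prev <- NULL
    for (w in widths) {
      att <- attended_events(log, ev$actor_id[e], ev$time_min[e],
                             ev$session_id[e], cue_window_config(w))
      cues <- compute_cues(att, log, ev$actor_id[e])
      # counts sum to the attended events in the window
      expect_equal(sum(cues$n), nrow(att))
      # widening the window never loses events
      if (!is.null(n_prev)) expect_true(all(cues$n >= n_prev))
      n_prev <- cues$n
      # defined cue means live on their natural [0, 1] scales
      for (col in c("paybar", "rank", "kin", "fem", "samesex")) {
        v <- cues[[col]][!is.na(cues[[col]])]
        expect_true(all(v >= 0 & v <= 1))
      }
    }
  }
})

test_that("the tidy cue table aligns one row per event and technique", {
  log <- make_window_log()
  tab <- build_cue_table(log)
  expect_equal(nrow(tab), nrow(log$events) * length(log$techniques))
  expect_equal(unique(tab$event), seq_len(nrow(log$events)))
  # the final event's row matches compute_cues directly
  last <- tab[tab$event == 4, ]
  direct <- compute_cues(attended_events(log, "C", 120, "s1"), log, "C")
  expect_equal(last$n, direct$n)
  expect_equal(last$paybar, direct$paybar)
})
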