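# Cached simulation fixtures shared across test files. Everything is built
# in code at test time; the cache avoids re-synthesizing the same recording.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small recording for module-level tests
small_sim <- function() {
  cached("small", function() {
    cfg <- sim_config(duration_s = 600, seed = 7)
    sim <- simulate_recording(cfg)
    sim$cfg <- cfg
    sim
  })
}

# the full-scale study-conditions recording used by the acceptance tests:
# 30 min, 4 cortical + 2 thalamic channels, default coupling
acceptance_sim <- function() {
  cached("acceptance", function() {
    cfg <- sim_config(duration_s = 1800, seed = 42)
    sim <- simulate_recording(cfg)
    sim$cfg <- cfg
    sim
  })
}

acceptance_downstates <- function() {
  cached("acceptance_ds", function() {
    suppressWarnings(detect_downstates(acceptance_sim()$recording))
  })
}

# marks = ground-truth spindles in the 20 min marked period (10 min N2 +
# 10 min N3, the four leading 5-min stage blocks)
mark_periods <- data.frame(onset_s = c(0, 300, 600, 900),
                           offset_s = c(300, 600, 900, 1200))

marks_for <- function(sim, ch) {
  tru <- sim$truth[sim$truth$channel == ch & sim$truth$type == "spindle", ]
  tru[tru$onset_s >= 0 & tru$offset_s <= 1200, c("onset_s", "offset_s")]
}

acceptance_classifiers <- function() {
  cached("acceptance_clf", function() {
    sim <- acceptance_sim()
    lapply(stats::setNames(nm = sim$recording$channels), function(ch) {
      suppressWarnings(spindle_classifier(sim$recording, ch,
                                          marks_for(sim, ch), mark_periods))
    })
  })
}

acceptance_spindles <- function() {
  cached("acceptance_sp", function() {
    sim <- acceptance_sim()
    clfs <- acceptance_classifiers()
    lapply(clfs, function(clf)
      suppressWarnings(apply_classifier(clf, sim$recording)))
  })
}

# drop events/times within `margin` seconds of an exclusion interval
drop_near_exclusions <- function(ev, exclusions, margin = 0) {
  if (is.null(dim(ev))) {
    keep <- rep(TRUE, length(ev))
    for (i in seq_len(nrow(exclusions))) {
      keep <- keep & !(ev - margin <= exclusions$offset_s[i] &
                         ev + margin >= exclusions$onset_s[i])
    }
    return(ev[keep])
  }
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(exclusions))) {
    keep <- keep & !(ev$onset_s - margin <= exclusions$offset_s[i] &
                       ev$offset_s + margin >= exclusions$onset_s[i])
  }
  ev[keep, , drop = FALSE]
}

truth_events <- function(sim, ch, type) {
  sim$truth[sim$truth$channel == ch & sim$truth$type == type, , drop = FALSE]
}
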