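# Cued color-recall task paradigm: trial structure, stimulus geometry, and the
# circular error metric.
#
# Geometry of a set-size-3 display: two "close" hues 20 deg apart in color
# space (10 deg either side of their midpoint; one clockwise, CW, one
# counter-clockwise, CCW) plus a "unique" hue 170 deg from each close hue.
# Items sit on an invisible circle, with pairwise polar-angle separations of
# at least 80 deg.  Hues are drawn from 180 values in 2-degree steps.  The
# response wheel is rotated randomly per trial and mirrored on half of the
# trials.

#' Signed circular difference in degrees
#'
#' `signed_error(reported, target)` is the recall error: reported minus target,
#' wrapped to (-180, 180].  Positive values are clockwise in color space, so
#' repulsion yields positive errors for CW targets and negative for CCW.
#'
#' @param reported,target hues in degrees on the 360-degree circle.
#' @export
#' @examples
#' signed_error(83, 90)   # -7
#' signed_error(1, 359)   # +2 (wraps)
signed_error <- function(reported, target) {
  wrap180(reported - target)
}

#' Absolute circular distance in degrees
#' @keywords internal
circ_dist <- function(a, b) abs(wrap180(a - b))

wrap360 <- function(x) x %% 360

#' Hue under the response-wheel mapping
#'
#' The wheel maps polar angle `s` (deg) on the screen to a hue: identity
#' diagonal plus a per-trial rotation offset, optionally mirror-reversed.
#'
#' @param s polar angle(s) in degrees.
#' @param rotation wheel rotation offset in degrees.
#' @param mirrored logical; if `TRUE` the wheel runs counter-clockwise.
#' @export
wheel_hue <- function(s, rotation, mirrored) {
  if (mirrored) wrap360(rotation - s) else wrap360(rotation + s)
}

#' Inverse wheel mapping: polar angle at which the wheel shows `hue`
#' @inheritParams wheel_hue
#' @param hue hue in degrees.
#' @export
wheel_angle <- function(hue, rotation, mirrored) {
  if (mirrored) wrap360(rotation - hue) else wrap360(hue - rotation)
}

hue_lattice <- function() seq(0, 358, by = 2)

# rejection-sample `k` polar angles pairwise >= 80 deg apart; optionally keep
# every (hue, location) pair off the wheel diagonal by `diag_margin` degrees
sample_locations <- function(k, hues, rotation, mirrored, diag_margin = 0) {
  repeat {
    locs <- runif(k, 0, 360)
    ok <- TRUE
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
        if (circ_dist(locs[i], locs[j]) < 80) ok <- FALSE
    }
    if (ok && diag_margin > 0) {
      for (i in seq_len(k))
        if (circ_dist(locs[i], wheel_angle(hues[i], rotation, mirrored)) <
            diag_margin) ok <- FALSE
    }
    if (ok) return(locs)
  }
}

new_trial_spec <- function(condition, set_size, hues, locations, roles,
                           probed_index, rotation, mirrored) {
  structure(list(condition = condition, set_size = set_size, hues = hues,
                 locations = locations, roles = roles,
                 probed_index = probed_index,
                 rotation = rotation, mirrored = mirrored,
                 timings = trial_timings(condition)),
            class = "trial_spec")
}

#' Phase timings (ms) for a trial condition
#'
#' DELAY: 500 ms fixation, 800 ms sample, 1000 ms delay, then the test
#' display.  CONTROL: identical except the wheel appears 500 ms into the
#' sample and overlaps it for the remaining 300 ms, with no delay.
#'
#' @param condition `"DELAY"` or `"CONTROL"`.
#' @return list with stimulus on/off and test-onset times in ms.
#' @export
trial_timings <- function(condition = c("DELAY", "CONTROL")) {
  condition <- match.arg(condition)
  if (condition == "DELAY")
    list(fixation_on = 0, stim_on = 500, stim_off = 1300, test_on = 2300)
  else
    list(fixation_on = 0, stim_on = 500, stim_off = 1300, test_on = 1000)
}

make_ss3_trial <- function(condition, probed_role, diag_margin = 0) {
  mid <- sample(hue_lattice(), 1)
  cw <- wrap360(mid + 10)
  ccw <- wrap360(mid - 10)
  # 170 deg from BOTH close hues pins the unique hue to the antipode of the
  # pair midpoint: the only point at distance 170 from mid+10 and mid-10
  unique_hue <- wrap360(mid + 180)
  roles <- c("CW", "CCW", "UNIQUE")
  hues <- c(cw, ccw, unique_hue)
  rotation <- runif(1, 0, 360)
  mirrored <- runif(1) < 0.5
  locs <- sample_locations(3, hues, rotation, mirrored, diag_margin)
  new_trial_spec(condition, 3L, hues, locs, roles,
                 which(roles == probed_role), rotation, mirrored)
}

make_ss1_trial <- function(condition) {
  hue <- sample(hue_lattice(), 1)
  rotation <- runif(1, 0, 360)
  mirrored <- runif(1) < 0.5
  locs <- sample_locations(1, hue, rotation, mirrored, 0)
  new_trial_spec(condition, 1L, hue, locs, "SINGLE", 1L, rotation, mirrored)
}

#' Generate the full trial set for one experimental session
#'
#' DELAY sessions comprise 800 trials: 160 set-size-1 trials and 640
#' set-size-3 trials, 320 probing the unique color and 320 probing one of the
#' two close colors (160 CW + 160 CCW).  CONTROL sessions comprise 640
#' set-size-3 trials: 320 unique, 160 CW, 160 CCW.  Probe counts are exact
#' (pre-allocated, then shuffled).
#'
#' @param condition `"DELAY"` or `"CONTROL"`.
#' @param n_trials optional downscaled total; counts are scaled proportionally
#'   (rounded to keep the CW/CCW split even).
#' @param diag_margin for CONTROL trials, minimum distance (deg) between every
#'   item and the wheel diagonal in the color-space field, so that visible
#'   stimulus peaks stay clear of the response corridor.
#' @return list of `trial_spec` objects in randomized order.
#' @export
generate_trials <- function(condition = c("DELAY", "CONTROL"),
                            n_trials = NULL, diag_margin = 45) {
  condition <- match.arg(condition)
  if (condition == "DELAY") {
    full <- c(SINGLE = 160, UNIQUE = 320, CW = 160, CCW = 160)
  } else {
    full <- c(SINGLE = 0, UNIQUE = 320, CW = 160, CCW = 160)
  }
  counts <- full
  if (!is.null(n_trials)) {
    scale <- n_trials / sum(full)
    counts <- round(full * scale)
  }
  margin <- if (condition == "CONTROL") diag_margin else 0
  trials <- list()
  for (role in names(counts)) {
    k <- counts[[role]]
    if (k == 0) next
    for (i in seq_len(k)) {
      trials[[length(trials) + 1L]] <-
        if (role == "SINGLE") make_ss1_trial(condition)
        else make_ss3_trial(condition, role, margin)
    }
  }
  trials[sample.int(length(trials))]
}

#' Piecewise-constant stimulus schedule for the color-space field
#'
#' Expands a trial into the phase segments the simulator integrates over:
#' which Gaussian item inputs and whether the wheel ridge are present in each
#' interval, plus per-item gain (CONTROL attenuates the uncued items while
#' sample display and wheel overlap).
#'
#' @param trial a `trial_spec`.
#' @param uncued_attenuation multiplicative gain on uncued item inputs during
#'   the CONTROL overlap interval.
#' @return list of segments `(t0, t1, items, item_gain, wheel, test)`.
#' @export
make_stimulus_inputs <- function(trial, uncued_attenuation = 0.5) {
  tm <- trial$timings
  segs <- list()
  add <- function(t0, t1, items, gain, wheel, test) {
    if (t1 > t0)
      segs[[length(segs) + 1L]] <<- list(t0 = t0, t1 = t1, items = items,
                                         item_gain = gain, wheel = wheel,
                                         test = test)
  }
  k <- trial$set_size
  ones <- rep(1, k)
  if (tm$stim_off <= tm$stim_on) return(segs)
  if (trial$condition == "DELAY") {
    add(0, tm$stim_on, integer(0), numeric(0), FALSE, FALSE)
    add(tm$stim_on, tm$stim_off, seq_len(k), ones, FALSE, FALSE)
    add(tm$stim_off, tm$test_on, integer(0), numeric(0), FALSE, FALSE)
    add(tm$test_on, Inf, integer(0), numeric(0), TRUE, TRUE)
  } else {
    gain <- rep(uncued_attenuation, k)
    gain[trial$probed_index] <- 1
    add(0, tm$stim_on, integer(0), numeric(0), FALSE, FALSE)
    add(tm$stim_on, tm$test_on, seq_len(k), ones, FALSE, FALSE)
    add(tm$test_on, tm$stim_off, seq_len(k), gain, TRUE, TRUE)
    add(tm$stim_off, Inf, integer(0), numeric(0), TRUE, TRUE)
  }
  segs
}

#' Flatten trial specs to a data frame (one row per trial) for replay/export
#' @param trials list of `trial_spec` objects.
#' @export
trials_to_table <- function(trials) {
  do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial = i, condition = tr$condition, set_size = tr$set_size,
               probed_role = tr$roles[tr$probed_index],
               probed_index = tr$probed_index,
               hues = paste(round(tr$hues, 3), collapse = ";"),
               locations = paste(round(tr$locations, 3), collapse = ";"),
               rotation = tr$rotation, mirrored = tr$mirrored)
  }))
}

#' Rebuild trial specs from a table written by [trials_to_table()]
#' @param tab data frame in the `trials_to_table` layout.
#' @export
trials_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    hues <- as.numeric(strsplit(row$hues, ";")[[1]])
    locs <- as.numeric(strsplit(row$locations, ";")[[1]])
    roles <- if (row$set_size == 1) "SINGLE" else c("CW", "CCW", "UNIQUE")
    new_trial_spec(row$condition, as.integer(row$set_size), hues, locs, roles,
                   as.integer(row$probed_index), row$rotation,
                   as.logical(row$mirrored))
  })
}
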