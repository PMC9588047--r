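# Trial generation, stimulus geometry, timings, and the circular error metric.

test_that("signed error is the wrapped circular difference", {
  expect_equal(signed_error(83, 90), -7)
  expect_equal(signed_error(42, 42), 0)
  expect_equal(signed_error(1, 359), 2)
  expect_equal(signed_error(359, 1), -2)
  expect_equal(signed_error(270, 90), 180)  # antipode maps to +180
})

test_that("wheel mapping inverts correctly with rotation and mirror", {
  for (mir in c(FALSE, TRUE)) {
    s <- wheel_angle(137, rotation = 52.3, mirrored = mir)
    expect_equal(wheel_hue(s, 52.3, mir), 137)
  }
})

test_that("session composition matches the design exactly for any seed", {
  for (seed in c(1, 99)) {
    set.seed(seed)
    tr <- generate_trials("DELAY")
    expect_length(tr, 800)
    roles <- vapply(tr, function(t) t$roles[t$probed_index], character(1))
    expect_equal(sum(roles == "SINGLE"), 160)
    expect_equal(sum(roles == "UNIQUE"), 320)
    expect_equal(sum(roles == "CW"), 160)
    expect_equal(sum(roles == "CCW"), 160)
  }
  set.seed(3)
  ctl <- generate_trials("CONTROL")
  expect_length(ctl, 640)
  roles <- vapply(ctl, function(t) t$roles[t$probed_index], character(1))
  expect_equal(as.integer(table(roles)[c("UNIQUE", "CW", "CCW")]),
               c(320L, 160L, 160L))
  expect_true(all(vapply(ctl, function(t) t$set_size == 3L, logical(1))))
  # downscaled sessions keep proportions
  set.seed(4)
  small <- generate_trials("DELAY", n_trials = 200)
  roles <- vapply(small, function(t) t$roles[t$probed_index], character(1))
  expect_equal(sum(roles == "SINGLE"), 40)
  expect_equal(sum(roles == "UNIQUE"), 80)
})

test_that("set-size-3 geometry invariants hold by construction", {
  set.seed(5)
  for (i in 1:300) {
    t <- dfwm:::make_ss3_trial("DELAY", sample(c("CW", "CCW", "UNIQUE"), 1))
    cw <- t$hues[t$roles == "CW"]; ccw <- t$hues[t$roles == "CCW"]
    un <- t$hues[t$roles == "UNIQUE"]
    expect_equal(dfwm:::circ_dist(cw, ccw), 20)
    expect_equal(dfwm:::circ_dist(cw, un), 170)
    expect_equal(dfwm:::circ_dist(ccw, un), 170)
    d <- outer(t$locations, t$locations, dfwm:::circ_dist)
    expect_true(all(d[upper.tri(d)] >= 80))
    # close-pair midpoint (and thus all hues) on the 2-degree lattice
    expect_true(all(round(t$hues) %% 2 == 0))
  }
  # control layout keeps items off the wheel diagonal
  set.seed(6)
  for (i in 1:50) {
    t <- dfwm:::make_ss3_trial("CONTROL", "CW", diag_margin = 45)
    for (j in 1:3) {
      sj <- wheel_angle(t$hues[j], t$rotation, t$mirrored)
      expect_gte(dfwm:::circ_dist(t$locations[j], sj), 45)
    }
  }
})

test_that("stimulus schedules follow the condition timings", {
  set.seed(7)
  d <- dfwm:::make_ss3_trial("DELAY", "CW")
  segs <- make_stimulus_inputs(d)
  stim <- Filter(function(s) length(s$items) > 0, segs)
  expect_equal(range(vapply(stim, function(s) c(s$t0, s$t1), numeric(2))),
               c(500, 1300))
  test_seg <- Filter(function(s) s$wheel, segs)
  expect_equal(test_seg[[1]]$t0, 2300)
  expect_false(any(vapply(stim, function(s) s$wheel, logical(1))))

  ctl <- dfwm:::make_ss3_trial("CONTROL", "CW")
  segs <- make_stimulus_inputs(ctl, uncued_attenuation = 0.3)
  overlap <- Filter(function(s) s$wheel && length(s$items) > 0, segs)
  expect_equal(overlap[[1]]$t0, 1000)
  expect_equal(overlap[[1]]$t1, 1300)
  gain <- overlap[[1]]$item_gain
  expect_equal(gain[ctl$probed_index], 1)
  expect_equal(sort(unique(gain[-ctl$probed_index])), 0.3)

  # zero-duration sample degenerates to an empty schedule
  z <- d; z$timings$stim_off <- z$timings$stim_on
  expect_length(make_stimulus_inputs(z), 0)
})

test_that("trial tables round-trip through export and import", {
  set.seed(8)
  tr <- generate_trials("DELAY", n_trials = 20)
  tab <- trials_to_table(tr)
  back <- trials_from_table(tab)
  expect_equal(length(back), length(tr))
  for (i in seq_along(tr)) {
    expect_equal(back[[i]]$hues, round(tr[[i]]$hues, 3))
    expect_equal(back[[i]]$condition, tr[[i]]$condition)
    expect_equal(back[[i]]$probed_index, tr[[i]]$probed_index)
  }
})
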