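# Model construction and single-trial behavior of both architectures.

test_that("model graphs match the adjacency fixtures", {
  for (v in 1:2) {
    m <- if (v == 1) build_model1() else build_model2()
    fix <- model_adjacency_fixture(v)
    got <- m$couplings[, c("source", "target", "sign")]
    key <- function(d) sort(paste(d$source, d$target, d$sign))
    expect_equal(key(got), key(fix))
  }
})

test_that("missing parameters fail with a named error", {
  p <- default_params(1)
  p$couplings$fc_fwm <- NULL
  expect_error(build_model1(p), "fc_fwm")
  p2 <- default_params(2)
  p2$fields$sla <- NULL
  expect_error(build_model2(p2), "sla")
  expect_error(build_model1(default_params(2)), "variant")
})

test_that("zero-gain couplings decouple the fields", {
  p <- default_params(1)
  for (nm in names(p$couplings))
    p$couplings[[nm]] <- if (length(p$couplings[[nm]]) == 1) 0 else
      replace(p$couplings[[nm]], "gain", 0)
  for (f in names(p$fields)) p$fields[[f]]$q <- 0
  m <- build_model1(p)
  tr <- dfwm:::new_trial_spec("DELAY", 1L, 90, 180, "SINGLE", 1L, 0, FALSE)
  res <- simulate_trial(m, tr, keep_state = TRUE)
  st <- attr(res, "state")
  # the stimulus drives the sensory field, but nothing propagates: the
  # contrast field never moves, attention only sees its test-phase resting
  # boost, and working memory sits at its gated resting level
  expect_lt(max(abs(st$fc - p$fields$fc$h)), 1e-6)
  expect_equal(max(st$fa), p$fields$fa$h + p$task$fa_hboost, tolerance = 1e-3)
  base <- p$fields$fwm$h + p$task$fwm_h_test
  expect_equal(min(st$fwm), base, tolerance = 1e-3)
  expect_equal(max(st$fwm), base + p$task$cue_boost_amp, tolerance = 1e-3)
  expect_true(res$guess)  # no response can form without couplings
})

test_that("a noise-free single-item trial is recalled almost exactly", {
  p <- default_params(1)
  for (f in names(p$fields)) p$fields[[f]]$q <- 0
  m <- build_model1(p)
  tr <- dfwm:::new_trial_spec("DELAY", 1L, 90, 45, "SINGLE", 1L,
                              rotation = 10, mirrored = FALSE)
  res <- simulate_trial(m, tr)
  expect_false(res$guess)
  expect_lt(abs(res$signed_error), 2)
  # mirrored wheel: the same memory maps through the mirrored lookup
  tr$mirrored <- TRUE
  res2 <- simulate_trial(m, tr)
  expect_false(res2$guess)
  expect_lt(abs(res2$signed_error), 2)
})

test_that("noise-free close peaks repel and far peaks do not interact", {
  p <- default_params(1)
  for (f in names(p$fields)) p$fields[[f]]$q <- 0
  m <- build_model1(p)
  # run encoding+delay directly and track the pair separation over the delay
  tr <- dfwm:::new_trial_spec("DELAY", 3L, c(100, 80, 270), c(0, 120, 240),
                              c("CW", "CCW", "UNIQUE"), 1L, 0, FALSE)
  seps <- sapply(c(1400, 1800, 2300), function(until) {
    st <- dfwm:::init_state(m, tr)
    segs <- make_stimulus_inputs(tr)
    for (seg in segs) {
      if (seg$test) break
      t1 <- min(seg$t1, until)
      if (t1 <= seg$t0) next
      cs_in <- matrix(0, m$nc, m$ns)
      if (length(seg$items)) cs_in <- dfwm:::stimulus_matrix(m, tr, rep(1, 3))
      st <- dfwm:::advance(st, m$par_encode, list(cs_input = cs_in,
             readout = 0, step_offset = 0), round((t1 - seg$t0) / 2), 2)
      if (t1 >= until) break
    }
    pk <- detect_peaks(df_field("fwm", n_sites = m$nc, u = st$fwm), 0)
    cw <- pk$location[which.min(dfwm:::circ_dist(pk$location, 100))]
    ccw <- pk$location[which.min(dfwm:::circ_dist(pk$location, 80))]
    dfwm:::circ_dist(cw, ccw)
  })
  expect_gte(seps[1], 20 - 0.5)          # repulsion, never attraction
  expect_true(all(diff(seps) >= -1e-9))  # non-decreasing over the delay
  expect_gt(seps[3], 21)                 # measurably repelled by test time
})

test_that("far peaks 170 degrees apart stay put without noise", {
  p <- default_params(1)
  for (f in names(p$fields)) p$fields[[f]]$q <- 0
  m <- build_model1(p)
  tr <- dfwm:::new_trial_spec("DELAY", 2L, c(90, 260), c(0, 180),
                              c("CW", "UNIQUE"), 1L, 0, FALSE)
  st <- dfwm:::init_state(m, tr)
  segs <- make_stimulus_inputs(tr)
  dist_at <- c()
  for (until in c(1400, 2300)) {
    st <- dfwm:::init_state(m, tr)
    for (seg in segs) {
      if (seg$test) break
      t1 <- min(seg$t1, until)
      if (t1 <= seg$t0) next
      cs_in <- matrix(0, m$nc, m$ns)
      if (length(seg$items)) cs_in <- dfwm:::stimulus_matrix(m, tr, rep(1, 2))
      st <- dfwm:::advance(st, m$par_encode, list(cs_input = cs_in,
             readout = 0, step_offset = 0), round((t1 - seg$t0) / 2), 2)
      if (t1 >= until) break
    }
    pk <- detect_peaks(df_field("fwm", n_sites = m$nc, u = st$fwm), 0)
    a <- pk$location[which.min(dfwm:::circ_dist(pk$location, 90))]
    b <- pk$location[which.min(dfwm:::circ_dist(pk$location, 260))]
    dist_at <- c(dist_at, dfwm:::circ_dist(a, b))
  }
  expect_lt(abs(dist_at[2] - dist_at[1]), 1)
})

test_that("cue boost has the documented flat local geometry", {
  m <- build_model1()
  b <- cue_boost(m, 90)
  x <- dfwm:::site_degrees(m$nc)
  inside <- dfwm:::circ_dist(x, 90) <= 20
  expect_true(all(b[inside] > 0))
  expect_true(all(b[!inside] == 0))
  expect_equal(length(unique(b[inside])), 1)  # flat profile
  # a boost at the unique item 170 degrees from the pair overlaps neither
  b2 <- cue_boost(m, 270)
  expect_equal(b2[which.min(dfwm:::circ_dist(x, 100))], 0)
  expect_equal(b2[which.min(dfwm:::circ_dist(x, 80))], 0)
})

test_that("disabling the condition-of-satisfaction loop stops the attention cycle", {
  p <- default_params(2)
  p$couplings$pd_cos <- 0
  m <- build_model2(p)
  set.seed(61)
  consolidated <- vapply(1:4, function(i) {
    tr <- dfwm:::make_ss3_trial("DELAY", "CW")
    sum(!is.na(consolidation_times(m, tr)))
  }, numeric(1))
  # without disengagement at most one item is ever consolidated
  expect_true(all(consolidated <= 1))
})

test_that("the extended model consolidates sequentially", {
  m <- build_model2()
  set.seed(62)
  ok <- 0
  for (i in 1:6) {
    tr <- dfwm:::make_ss3_trial("DELAY", "CW")
    ct <- consolidation_times(m, tr)
    if (all(!is.na(ct)) && min(diff(sort(ct))) > 20) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("readout_response maps sensory peaks through the wheel", {
  m <- build_model1()
  tr <- dfwm:::new_trial_spec("DELAY", 1L, 83, 200, "SINGLE", 1L,
                              rotation = 0, mirrored = FALSE)
  # flat field: no response
  flat <- matrix(-5, m$nc, m$ns)
  expect_true(is.na(readout_response(m, tr, flat)))
  # peak at the spatial site whose wheel color is 83 reads out as 83
  s_idx <- round(wheel_angle(83, 0, FALSE) / (360 / m$ns)) + 1
  c_idx <- round(83 / (360 / m$nc)) + 1
  cs <- flat; cs[c_idx, s_idx] <- 6
  expect_equal(readout_response(m, tr, cs), 83, tolerance = 2)
  # the mirrored wheel maps the same spatial site to the mirrored hue
  tr2 <- tr; tr2$mirrored <- TRUE
  cs2 <- flat
  s2 <- round(wheel_angle(83, 0, TRUE) / (360 / m$ns)) + 1
  cs2[c_idx, s2] <- 6
  expect_equal(readout_response(m, tr2, cs2), 83, tolerance = 2)
})
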