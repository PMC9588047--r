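# Model architectures and end-to-end trial simulation.
#
# Model 1 (five fields): a 2D color-space sensory field (CS) feeding a feature
# attention field (FA) and a three-layer working-memory core -- feature
# contrast (FC) and feature working memory (FWM), both reciprocally coupled to
# a shared inhibitory field (Inhib).  Encoding is parallel; the spatial cue is
# modeled as a flat local boost of the cued hue region in FWM.
#
# Model 2 adds a spatial pathway (spatial attention SA, inhibition-of-return
# IOR), a scene-level attention field (SLA), and peak-detector (PD) /
# condition-of-satisfaction (CoS) nodes.  Attention fields run winner-takes-
# all; the PD-CoS loop stamps attended locations into IOR and disengages
# attention, producing autonomous sequential consolidation.  The spatial cue
# boosts SLA instead of FWM.
#
# Couplings active only in the response phase (FWM->FA, and SLA->FWM in Model
# 2) implement the attentional routing engaged by the recall prompt; the
# consolidation loop (SLA->PD->CoS) is disengaged during the response phase.

required_couplings <- function(variant) {
  core <- c("cs_fa", "cs_fc", "cs_fwm", "fa_fc", "fc_fwm", "fc_inh",
            "fwm_inh", "inh_fc", "inh_fwm", "fwm_fa", "fa_cs")
  if (variant == 1) return(core)
  c(core, "fc_fa", "cs_sa", "sa_cs", "ior_sa", "sa_ior", "fwm_sla",
    "fa_sla", "sla_fwm", "sla_pd", "pd_cos", "cos_fa", "cos_sa", "cos_sla",
    "cos_ior")
}

required_fields <- function(variant) {
  if (variant == 1) c("cs", "fa", "fc", "inh", "fwm")
  else c("cs", "fa", "fc", "inh", "fwm", "sa", "ior", "sla")
}

coupling_graph <- function(params) {
  nm <- required_couplings(params$variant)
  ends <- list(
    cs_fa = c("CS", "FA"), cs_fc = c("CS", "FC"), cs_fwm = c("CS", "FWM"),
    fa_fc = c("FA", "FC"), fc_fwm = c("FC", "FWM"), fc_inh = c("FC", "Inhib"),
    fwm_inh = c("FWM", "Inhib"), inh_fc = c("Inhib", "FC"),
    inh_fwm = c("Inhib", "FWM"), fwm_fa = c("FWM", "FA"),
    fa_cs = c("FA", "CS"), fc_fa = c("FC", "FA"), cs_sa = c("CS", "SA"),
    sa_cs = c("SA", "CS"), ior_sa = c("IOR", "SA"), sa_ior = c("SA", "IOR"),
    fwm_sla = c("FWM", "SLA"), fa_sla = c("FA", "SLA"),
    sla_fwm = c("SLA", "FWM"), sla_pd = c("SLA", "PD"),
    pd_cos = c("PD", "CoS"), cos_fa = c("CoS", "FA"), cos_sa = c("CoS", "SA"),
    cos_sla = c("CoS", "SLA"), cos_ior = c("CoS", "IOR"))
  suppressive <- c("cos_fa", "cos_sa", "cos_sla")  # subtracted scalar gains
  do.call(rbind, lapply(nm, function(n) {
    cpl <- params$couplings[[n]]
    gain <- if (length(cpl) > 1) cpl[["gain"]] else as.numeric(cpl)
    sign <- if (n %in% suppressive || gain < 0) "inhibitory" else "excitatory"
    data.frame(source = ends[[n]][1], target = ends[[n]][2],
               coupling = n, gain = gain, sign = sign)
  }))
}

build_model <- function(params) {
  variant <- params$variant
  miss <- setdiff(required_fields(variant), names(params$fields))
  if (length(miss)) stop("missing field parameters: ", paste(miss, collapse = ", "))
  miss <- setdiff(required_couplings(variant), names(params$couplings))
  if (length(miss)) stop("missing couplings: ", paste(miss, collapse = ", "))
  par <- build_engine_par(params)
  # encode/delay phases: response-only couplings off
  par_enc <- par
  par_enc$cp$fwm_fa <- numeric(0)
  if (variant == 2) par_enc$cp$sla_fwm <- numeric(0)
  # response phase: consolidation loop disengaged, attention fully selective
  par_test <- par
  if (!is.null(params$task$fa_ginh_test))
    par_test$fa$ginh <- params$task$fa_ginh_test
  if (!is.null(params$task$fa_cs_test))
    par_test$cp$fa_cs <- params$task$fa_cs_test
  if (variant == 2) { par_test$cp$sla_pd <- 0; par_test$cp$pd_cos <- 0 }
  # zero-delay control response phase: the implicit reference-frame shift
  # onto the wheel detaches the spatial pathway from the display frame, so
  # the still-visible items cannot capture spatial attention
  par_test_ctl <- par_test
  if (variant == 2) {
    par_test_ctl$cp$cs_sa <- numeric(0)
    par_test_ctl$cp$sa_cs <- 0
  }
  structure(list(variant = variant, params = params,
                 nc = params$grid$nc, ns = params$grid$ns,
                 par_encode = par_enc, par_test = par_test,
                 par_test_control = par_test_ctl,
                 couplings = coupling_graph(params)),
            class = "df_model")
}

#' Assemble the five-field recall model (parallel encoding)
#'
#' @param params parameter list from [default_params()] (variant 1).
#' @return a `df_model` ready for [simulate_trial()].
#' @export
build_model1 <- function(params = default_params(1)) {
  if (params$variant != 1) stop("params are not for variant 1")
  build_model(params)
}

#' Assemble the extended model with spatial pathway and sequential consolidation
#'
#' @param params parameter list from [default_params()] (variant 2).
#' @export
build_model2 <- function(params = default_params(2)) {
  if (params$variant != 2) stop("params are not for variant 2")
  build_model(params)
}

#' @export
print.df_model <- function(x, ...) {
  cat(sprintf("Dynamic field model, variant %d (%d couplings, grid %dx%d)\n",
              x$variant, nrow(x$couplings), x$nc, x$ns))
  invisible(x)
}

site_degrees <- function(n) (seq_len(n) - 1) * 360 / n

circ_gauss <- function(x, center, sigma) {
  d <- wrap180(x - center)
  exp(-d^2 / (2 * sigma^2))
}

# sum of 2D Gaussian item inputs, nc x ns
stimulus_matrix <- function(model, trial, gains) {
  tk <- model$params$task
  cdeg <- site_degrees(model$nc); sdeg <- site_degrees(model$ns)
  m <- matrix(0, model$nc, model$ns)
  for (j in seq_len(trial$set_size)) {
    if (gains[j] == 0) next
    gc <- circ_gauss(cdeg, trial$hues[j], tk$stim_sigma_c)
    gs <- circ_gauss(sdeg, trial$locations[j], tk$stim_sigma_s)
    m <- m + tk$stim_amp * gains[j] * outer(gc, gs)
  }
  m
}

# 0/1 mask of sites within `margin` degrees of the wheel diagonal
wheel_mask <- function(model, trial, margin = 15) {
  cdeg <- site_degrees(model$nc); sdeg <- site_degrees(model$ns)
  hue_s <- wheel_hue(sdeg, trial$rotation, trial$mirrored)
  d <- abs(wrap180(outer(cdeg, hue_s, "-")))
  (d <= margin) + 0
}

# sub-threshold diagonal wheel ridge: color wheel_hue(s) at each polar angle s
wheel_matrix <- function(model, trial) {
  tk <- model$params$task
  cdeg <- site_degrees(model$nc); sdeg <- site_degrees(model$ns)
  hue_s <- wheel_hue(sdeg, trial$rotation, trial$mirrored)
  d <- wrap180(outer(cdeg, hue_s, "-"))
  tk$wheel_amp * exp(-d^2 / (2 * tk$wheel_sigma^2))
}

#' Spatial-cue boost input
#'
#' A flat local boost of configured width and amplitude centered on the cued
#' item's true hue; applied to FWM in Model 1 and to the scene-level
#' attention field in Model 2.
#'
#' @param model a `df_model`.
#' @param cued_hue hue (degrees) of the cued item.
#' @return input vector over color sites.
#' @export
cue_boost <- function(model, cued_hue) {
  tk <- model$params$task
  cdeg <- site_degrees(model$nc)
  tk$cue_boost_amp * (circ_dist(cdeg, cued_hue) <= tk$cue_boost_width / 2)
}

init_state <- function(model, trial) {
  f <- model$params$fields
  st <- list(cs = matrix(f$cs$h, model$nc, model$ns),
             fa = rep(f$fa$h, model$nc), fc = rep(f$fc$h, model$nc),
             inh = rep(f$inh$h, model$nc), fwm = rep(f$fwm$h, model$nc),
             item_sites = as.integer(round(trial$hues / (360 / model$nc)) %% model$nc),
             cons_step = rep(-1, trial$set_size))
  if (model$variant == 2) {
    st$sa <- rep(f$sa$h, model$ns); st$ior <- rep(f$ior$h, model$ns)
    st$sla <- rep(f$sla$h, model$nc)
    st$pd <- model$params$nodes$pd$h; st$cos <- model$params$nodes$cos$h
  }
  st
}

advance <- function(state, par, ext, nsteps, dt) {
  out <- cpp_run_phase(state, par, ext, as.integer(nsteps), dt)
  for (nm in c("cs", "fa", "fc", "inh", "fwm", "sa", "ior", "sla", "pd",
               "cos", "cons_step"))
    if (!is.null(out[[nm]])) state[[nm]] <- out[[nm]]
  state$diag <- out[c("resp_step", "resp_space", "resp_color")]
  state
}

#' Simulate one cued color-recall trial
#'
#' Runs the model through fixation, sample, delay (condition permitting) and
#' test phases and reads out the recall response from the first stable
#' above-threshold peak in the sensory field.  If no response forms before
#' the deadline, the reported hue is drawn uniformly and flagged as a guess
#' (a response is required on every trial, as in the task).
#'
#' @param model a `df_model`.
#' @param trial a `trial_spec`.
#' @param keep_state if `TRUE`, attach the final field state.
#' @return a one-row data frame: condition, probed role, target and reported
#'   hues, signed error (degrees), response time (ms), guess flag, and the
#'   consolidation times (ms, semicolon-joined, `NA` for unconsolidated
#'   items).
#' @export
simulate_trial <- function(model, trial, keep_state = FALSE, verbose = FALSE) {
  tk <- model$params$task
  dt <- model$params$dt
  segs <- make_stimulus_inputs(trial, tk$uncued_attenuation)
  # split the first response segment at the readout grace boundary: responses
  # are only accepted once the attention cascade has re-oriented to the wheel
  grace <- trial$timings$test_on + tk$read_delay_ms
  split_segs <- list()
  for (seg in segs) {
    if (seg$test && seg$t0 < grace && seg$t1 > grace) {
      pre <- seg; pre$t1 <- grace; pre$no_read <- TRUE
      post <- seg; post$t0 <- grace
      split_segs <- c(split_segs, list(pre), list(post))
    } else {
      seg$no_read <- seg$test && seg$t1 <= grace
      split_segs <- c(split_segs, list(seg))
    }
  }
  segs <- split_segs
  deadline <- trial$timings$test_on + tk$deadline_ms
  state <- init_state(model, trial)
  cued_hue <- trial$hues[trial$probed_index]
  boost <- cue_boost(model, cued_hue)
  hold_steps <- max(1L, round(tk$hold_ms / dt))
  responded <- FALSE
  resp_time <- NA_real_; resp_space <- NA_real_
  test_started <- FALSE
  t_abs <- 0
  final_state <- NULL
  for (seg in segs) {
    t1 <- min(seg$t1, deadline)
    nsteps <- round((t1 - seg$t0) / dt)
    if (nsteps <= 0) next
    if (seg$test && !test_started) {
      test_started <- TRUE
      if (model$variant == 2) {
        # the response cue re-orients attention: attention fields reset, and
        # the spatial frame shifts onto the wheel.  In the zero-delay control
        # the IOR traces of already-attended item locations are kept so the
        # still-visible display cannot recapture spatial attention
        state$sa[] <- model$params$fields$sa$h
        state$fa[] <- model$params$fields$fa$h
        state$fc[] <- model$params$fields$fc$h
        state$sla[] <- model$params$fields$sla$h
        if (trial$condition == "DELAY")
          state$ior[] <- model$params$fields$ior$h
      }
    }
    cs_in <- matrix(0, model$nc, model$ns)
    if (length(seg$items))
      cs_in <- cs_in + stimulus_matrix(model, trial, {
        g <- rep(0, trial$set_size); g[seg$items] <- seg$item_gain; g
      })
    if (seg$wheel) cs_in <- cs_in + wheel_matrix(model, trial)
    ext <- list(cs_input = cs_in, step_offset = round(seg$t0 / dt))
    if (seg$test) {
      ext$readout <- if (isTRUE(seg$no_read)) 0 else 1
      ext$read_mask <- wheel_mask(model, trial)
      ext$read_threshold <- tk$read_threshold
      ext$hold_steps <- hold_steps
      ext$fa_hboost <- tk$fa_hboost
      # response-phase attentional gating: uniform resting drop in FWM with
      # the cued region rescued by the spatial-cue boost (via FWM in Model 1,
      # via scene-level attention in Model 2).  In the zero-delay control the
      # response is driven by the still-visible cued stimulus (the recall
      # prompt arrives with no delay), so memory peaks are gated out entirely
      gamp <- if (trial$condition == "CONTROL") tk$fwm_h_test_control
              else tk$fwm_h_test
      gate <- rep(gamp, model$nc)
      if (model$variant == 1) {
        ext$fwm_input <- gate + boost
      } else {
        ext$fwm_input <- gate
        ext$sla_input <- boost
      }
    } else {
      ext$readout <- 0
    }
    par <- if (!seg$test) model$par_encode
           else if (trial$condition == "CONTROL") model$par_test_control
           else model$par_test
    if (verbose) {
      t0c <- seg$t0
      while (t0c < t1) {
        tc <- min(t0c + 100, t1)
        ext$step_offset <- round(t0c / dt)
        state <- advance(state, par, ext, round((tc - t0c) / dt), dt)
        fmax <- function(v) sprintf("%+6.1f", max(v))
        cat(sprintf("t=%5.0f cs %s fa %s fc %s fwm %s", tc, fmax(state$cs),
                    fmax(state$fa), fmax(state$fc), fmax(state$fwm)))
        if (model$variant == 2)
          cat(sprintf(" sa %s ior %s sla %s", fmax(state$sa), fmax(state$ior),
                      fmax(state$sla)))
        if (seg$test && !is.null(ext$read_mask))
          cat(sprintf(" wheelmax %+6.1f", max(state$cs[ext$read_mask == 1])))
        cat("\n")
        t0c <- tc
        if (seg$test && state$diag$resp_step >= 0) break
      }
    } else {
      state <- advance(state, par, ext, nsteps, dt)
    }
    t_abs <- t1
    if (seg$test && is.null(attr(state, "cons_frozen"))) {
      # consolidation bookkeeping ends when the response phase begins
      attr(state, "cons_frozen") <- TRUE
      cons_at_test <- state$cons_step
    }
    if (seg$test && state$diag$resp_step >= 0) {
      resp_time <- seg$t0 + state$diag$resp_step * dt - trial$timings$test_on
      resp_space <- state$diag$resp_space
      responded <- TRUE
      break
    }
    if (t_abs >= deadline) break
  }
  if (keep_state) final_state <- state
  if (exists("cons_at_test", inherits = FALSE)) state$cons_step <- cons_at_test
  guess <- !responded
  reported <- if (responded) wheel_hue(resp_space, trial$rotation,
                                       trial$mirrored) else runif(1, 0, 360)
  cons_ms <- ifelse(state$cons_step > 0, state$cons_step * dt, NA_real_)
  res <- data.frame(
    condition = trial$condition, set_size = trial$set_size,
    probed_role = trial$roles[trial$probed_index],
    target_hue = cued_hue, reported_hue = reported,
    signed_error = signed_error(reported, cued_hue),
    response_time = if (responded) resp_time else NA_real_,
    guess = guess,
    consolidation_ms = paste(round(cons_ms, 1), collapse = ";"))
  if (keep_state) attr(res, "state") <- final_state
  res
}

#' Simulate a list of trials into a tidy results table
#'
#' @param model a `df_model`.
#' @param trials list of `trial_spec` objects.
#' @param progress print a dot every 25 trials.
#' @return data frame with one row per trial (see [simulate_trial()]) plus a
#'   `trial` index column.
#' @export
run_trials <- function(model, trials, progress = FALSE) {
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    rows[[i]] <- cbind(trial = i, simulate_trial(model, trials[[i]]))
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, rows)
}

#' Consolidation times of the display items
#'
#' Runs encoding (fixation, sample, and the early delay) without a response
#' phase and returns, per item, the first time working memory crossed
#' threshold near the item's hue.
#'
#' @param model a `df_model`.
#' @param trial a `trial_spec`.
#' @param until end of the simulated window (ms from trial onset).
#' @return numeric vector (ms, `NA` for unconsolidated items) in item order.
#' @export
consolidation_times <- function(model, trial, until = 1600) {
  tk <- model$params$task
  dt <- model$params$dt
  segs <- make_stimulus_inputs(trial, tk$uncued_attenuation)
  state <- init_state(model, trial)
  for (seg in segs) {
    if (seg$test) break
    t1 <- min(seg$t1, until)
    nsteps <- round((t1 - seg$t0) / dt)
    if (nsteps <= 0) next
    cs_in <- matrix(0, model$nc, model$ns)
    if (length(seg$items))
      cs_in <- cs_in + stimulus_matrix(model, trial, {
        g <- rep(0, trial$set_size); g[seg$items] <- seg$item_gain; g
      })
    state <- advance(state, model$par_encode,
                     list(cs_input = cs_in, readout = 0,
                          step_offset = round(seg$t0 / dt)), nsteps, dt)
    if (t1 >= until) break
  }
  ifelse(state$cons_step > 0, state$cons_step * dt, NA_real_)
}

#' Read a recall response out of a sensory-field state
#'
#' Finds the strongest above-threshold peak within the wheel corridor of the
#' color-space field and returns the wheel color at its spatial position
#' (rotation and mirroring applied).  `simulate_trial()` additionally
#' requires the peak to be stable for a hold window; this function reads a
#' single snapshot.
#'
#' @param model a `df_model`.
#' @param trial the `trial_spec` providing the wheel mapping.
#' @param cs sensory-field activation matrix (color x space).
#' @param threshold activation threshold (defaults to the model's readout
#'   threshold).
#' @return the reported hue in degrees, or `NA` if no above-threshold peak
#'   lies on the wheel.
#' @export
readout_response <- function(model, trial, cs,
                             threshold = model$params$task$read_threshold) {
  mask <- wheel_mask(model, trial)
  vals <- ifelse(mask == 1, cs, -Inf)
  if (max(vals) <= threshold) return(NA_real_)
  ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  s <- ix[["col"]]
  ns <- model$ns
  colmax <- function(j) {
    j <- ((j - 1) %% ns) + 1
    m <- max(vals[, j])
    if (is.finite(m)) m else min(cs)
  }
  a <- colmax(s - 1); b <- colmax(s); c <- colmax(s + 1)
  denom <- a - 2 * b + c
  off <- if (denom < 0) 0.5 * (a - c) / denom else 0
  wheel_hue(wrap360((s - 1 + off) * 360 / ns), trial$rotation, trial$mirrored)
}
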