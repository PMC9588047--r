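# Default model parameters and translation into engine form.
#
# Parameters are expressed in field units: kernel and projection amplitudes
# are per-degree weights (the convolution multiplies by the grid spacing, so
# behavior is resolution-invariant), widths are degrees, time constants ms.
# A projection is either a Gaussian tube (gain + sigma) or, with sigma = 0, a
# plain scalar gain.

#' Default parameter set for a model variant
#'
#' Returns the nested parameter list (fields, couplings, task/readout
#' settings) for the five-field architecture (`variant = 1`) or the extended
#' architecture with spatial pathway and sequential consolidation
#' (`variant = 2`).  Values were hand-tuned to the study conditions; see the
#' methods vignette for the tuning rationale.
#'
#' @param variant 1 or 2.
#' @param overrides named list of replacement values, merged recursively.
#' @export
default_params <- function(variant = 1, overrides = NULL) {
  base <- list(
    variant = as.integer(variant),
    dt = 2,                       # ms, fixed-step Euler
    grid = list(nc = 120, ns = 120),  # sites over 360 deg (3 deg spacing)
    fields = list(
      cs  = list(h = -5, tau = 20, q = 0.12, beta = 4,
                 c_exc = 4, sigma_exc_c = 4, sigma_exc_s = 4,
                 c_inh = 0, sigma_inh_c = 10, sigma_inh_s = 10,
                 g_inh = 0.003),
      fa  = list(h = -5, tau = 20, q = 0.12, beta = 4,
                 c_exc = 3.5, sigma_exc = 3, c_inh = 0, sigma_inh = 12,
                 g_inh = 0.05),
      fc  = list(h = -5, tau = 20, q = 0.12, beta = 4,
                 c_exc = 2, sigma_exc = 3, c_inh = 0, sigma_inh = 10,
                 g_inh = 0.1),
      inh = list(h = -5, tau = 10, q = 0.12, beta = 4,
                 c_exc = 0, sigma_exc = 5, c_inh = 0, sigma_inh = 10,
                 g_inh = 0),
      fwm = list(h = -3.8, tau = 20, q = 0.3, beta = 4,
                 c_exc = 13, sigma_exc = 3, c_inh = 0, sigma_inh = 10,
                 g_inh = 0.02)
    ),
    couplings = list(
      cs_fa   = c(gain = 0.8, sigma = 3),
      cs_fc   = c(gain = 1.2, sigma = 3),
      cs_fwm  = c(gain = 0.25, sigma = 3),
      fa_fc   = c(gain = 0.8, sigma = 3),
      fc_fwm  = c(gain = 3.5, sigma = 3),
      fc_inh  = c(gain = 4.0, sigma = 5),
      fwm_inh = c(gain = 8.0, sigma = 4),
      inh_fc  = c(gain = -4.0, sigma = 9),
      inh_fwm = c(gain = -8.0, sigma = 16),
      fwm_fa  = c(gain = 3.5, sigma = 3),   # response phase only
      fa_cs   = 3.0
    ),
    task = list(
      stim_amp = 8, stim_sigma_c = 5, stim_sigma_s = 5,
      wheel_amp = 3, wheel_sigma = 4,
      cue_boost_amp = 4.5, cue_boost_width = 40,
      fwm_h_test = -4, fwm_h_test_control = -15,
      fa_hboost = 2, fa_ginh_test = 0.3,
      uncued_attenuation = 0.3,
      read_threshold = 3.0, hold_ms = 50, read_delay_ms = 250,
      deadline_ms = 2000,
      cons_threshold = 0, cons_halfwidth = 12
    )
  )
  if (variant == 2) {
    # attention fields run winner-takes-all; consolidation is attention-gated
    # (FC crosses threshold only under the attended item's FA boost), and the
    # PD/CoS loop stamps attended locations into IOR to disengage attention
    base$fields$cs$c_exc <- 5.5     # slower sensory decay extends encoding
    base$fields$fwm$h <- -4.1
    base$fields$fwm$q <- 0.24
    base$fields$fa$g_inh <- 0.8
    base$fields$fa$tau <- 20
    base$fields$fc$tau <- 15
    base$fields$fc$c_exc <- 1.5
    base$fields$sa <- list(h = -5, tau = 10, q = 0.12, beta = 4,
                           c_exc = 3.5, sigma_exc = 6, c_inh = 0,
                           sigma_inh = 12, g_inh = 0.8)
    base$fields$ior <- list(h = -4, tau = 80, q = 0.03, beta = 4,
                            c_exc = 9, sigma_exc = 6, c_inh = 0,
                            sigma_inh = 12, g_inh = 0.03)
    base$fields$sla <- list(h = -5, tau = 12, q = 0.12, beta = 4,
                            c_exc = 3.0, sigma_exc = 4, c_inh = 0,
                            sigma_inh = 10, g_inh = 0.4)
    base$nodes <- list(
      pd  = list(h = -4.5, tau = 8, q = 0, beta = 4, self_exc = 2),
      cos = list(h = -2.8, tau = 20, q = 0, beta = 4, self_exc = 3)
    )
    # narrow component resolves the close pair; wide component implements the
    # overlap bias that favors attending the close pair before the unique item
    base$couplings$cs_fa  <- c(gain = 0.5, sigma = 4, gain2 = 0.62, sigma2 = 14)
    base$couplings$cs_fc  <- c(gain = 0.5, sigma = 3)
    base$couplings$fa_fc  <- c(gain = 4, sigma = 2.5)
    base$couplings$fc_fwm <- c(gain = 5.5, sigma = 3)
    base$couplings$cs_fwm <- c(gain = 0.1, sigma = 3)
    base$couplings$inh_fc <- c(gain = -5, sigma = 7)
    base$couplings$fc_fa  <- c(gain = 2.5, sigma = 4)
    base$couplings$cs_sa  <- c(gain = 1.6, sigma = 6)
    base$couplings$sa_cs  <- 3.0
    base$couplings$ior_sa <- c(gain = -6, sigma = 8)
    base$couplings$sa_ior <- c(gain = 5.5, sigma = 5)
    base$couplings$cos_ior <- 4.5
    base$couplings$fwm_sla <- c(gain = 4, sigma = 4)
    base$couplings$fa_sla  <- c(gain = 4, sigma = 4)
    base$couplings$sla_fwm <- c(gain = 5, sigma = 5)  # response phase only
    base$couplings$sla_pd  <- 1.2
    base$couplings$pd_cos  <- 10
    base$couplings$cos_fa  <- 10
    base$couplings$cos_sa  <- 10
    base$couplings$cos_sla <- 10
    base$task$fa_cs_test <- 4.0   # stronger response ridge at recall only
    base$task$wheel_amp <- 4
    base$task$read_threshold <- 3.5
    base$task$cue_boost_amp <- 5.5
    base$task$fa_ginh_test <- 0.3
    base$task$cons_threshold <- 2
    base$task$cons_halfwidth <- 6
  }
  if (!is.null(overrides)) base <- merge_params(base, overrides)
  base
}

merge_params <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_params(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

# centered normalized-Gaussian tap vector: gain * N(d; sigma) * dx truncated
# at `cut` sigmas, so `gain` is the integrated connection strength; sigma = 0
# yields the scalar gain
gauss_taps <- function(gain, sigma, n, extent = 360, cut = 4) {
  if (gain == 0) return(numeric(0))
  dx <- extent / n
  if (sigma <= 0) return(gain)
  w <- min(floor(n / 2) - 1L, ceiling(cut * sigma / dx))
  d <- (-w:w) * dx
  gain * exp(-d^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma) * dx
}

# difference-of-Gaussians lateral taps for a 1D field
lateral_taps <- function(f, n, extent = 360) {
  tp <- gauss_taps(f$c_exc, f$sigma_exc, n, extent)
  tn <- gauss_taps(f$c_inh, f$sigma_inh, n, extent)
  if (length(tp) == 0 && length(tn) == 0) return(numeric(0))
  w <- max(length(tp), length(tn))
  pad <- function(x) {
    if (length(x) == 0) return(rep(0, w))
    c(rep(0, (w - length(x)) / 2), x, rep(0, (w - length(x)) / 2))
  }
  pad(tp) - pad(tn)
}

# correlated-noise taps: Gaussian smoothing rescaled so the marginal
# per-site variance stays 1 (q keeps its meaning as per-site amplitude)
noise_taps <- function(sigma, n, extent = 360) {
  tp <- gauss_taps(1, sigma, n, extent)
  tp / sqrt(sum(tp^2))
}

# sum tap vectors of different (odd) lengths, center-aligned
add_taps <- function(a, b) {
  w <- max(length(a), length(b))
  pad <- function(x) {
    if (length(x) == 0) return(rep(0, w))
    c(rep(0, (w - length(x)) / 2), x, rep(0, (w - length(x)) / 2))
  }
  pad(a) + pad(b)
}

# a coupling is a scalar gain, a (gain, sigma) Gaussian tube, or a
# (gain, sigma, gain2, sigma2) sum of two Gaussians
cp_taps <- function(cpl, n) {
  if (is.null(cpl)) return(numeric(0))
  if (length(cpl) == 1) return(as.numeric(cpl))
  tp <- gauss_taps(cpl[["gain"]], cpl[["sigma"]], n)
  if (length(cpl) >= 4)
    tp <- add_taps(tp, gauss_taps(cpl[["gain2"]], cpl[["sigma2"]], n))
  tp
}

# translate the human-readable parameter list into the flat engine form
build_engine_par <- function(params) {
  nc <- params$grid$nc; ns <- params$grid$ns
  f <- params$fields
  field1d <- function(ff, n) {
    out <- list(h = ff$h, tau = ff$tau, q = ff$q, beta = ff$beta,
                lat_taps = lateral_taps(ff, n), ginh = ff$g_inh)
    ns <- ff$noise_sigma
    if (!is.null(ns) && ns > 0) out$noise_taps <- noise_taps(ns, n)
    out
  }
  par <- list(
    variant = params$variant, nc = nc, ns = ns,
    cs = list(h = f$cs$h, tau = f$cs$tau, q = f$cs$q, beta = f$cs$beta,
              exc_c = gauss_taps(f$cs$c_exc, f$cs$sigma_exc_c, nc),
              exc_s = gauss_taps(1, f$cs$sigma_exc_s, ns),
              inh_c = gauss_taps(f$cs$c_inh, f$cs$sigma_inh_c, nc),
              inh_s = gauss_taps(if (f$cs$c_inh > 0) 1 else 0,
                                 f$cs$sigma_inh_s, ns),
              ginh = f$cs$g_inh),
    fa = field1d(f$fa, nc), fc = field1d(f$fc, nc),
    inh = field1d(f$inh, nc), fwm = field1d(f$fwm, nc),
    cons_threshold = params$task$cons_threshold,
    cons_halfwidth = round(params$task$cons_halfwidth / (360 / nc))
  )
  if (params$variant == 2) {
    par$sa <- field1d(f$sa, ns); par$ior <- field1d(f$ior, ns)
    par$sla <- field1d(f$sla, nc)
    par$pd <- params$nodes$pd; par$cos <- params$nodes$cos
  }
  cpl <- params$couplings
  cn <- function(nm, n) cp_taps(cpl[[nm]], n)
  par$cp <- list(
    cs_fa = cn("cs_fa", nc), cs_fc = cn("cs_fc", nc),
    inh_fa = cn("inh_fa", nc),
    cs_fwm = cn("cs_fwm", nc), fa_fc = cn("fa_fc", nc),
    fc_fwm = cn("fc_fwm", nc), fc_inh = cn("fc_inh", nc),
    fwm_inh = cn("fwm_inh", nc), inh_fc = cn("inh_fc", nc),
    inh_fwm = cn("inh_fwm", nc), fwm_fa = cn("fwm_fa", nc),
    fa_cs = if (is.null(cpl$fa_cs)) 0 else cpl$fa_cs
  )
  if (params$variant == 2) {
    par$cp$fc_fa <- cn("fc_fa", nc)
    par$cp$cs_sa <- cn("cs_sa", ns)
    par$cp$sa_cs <- cpl$sa_cs
    par$cp$ior_sa <- cn("ior_sa", ns)
    par$cp$sa_ior <- cn("sa_ior", ns)
    par$cp$fwm_sla <- cn("fwm_sla", nc)
    par$cp$fa_sla <- cn("fa_sla", nc)
    par$cp$sla_fwm <- cn("sla_fwm", nc)
    for (nm in c("sla_pd", "pd_cos", "cos_fa", "cos_sa", "cos_sla",
                 "cos_ior"))
      par$cp[[nm]] <- cpl[[nm]]
  }
  par
}

#' Write a parameter set to a YAML (or JSON) file for provenance
#'
#' Every simulation run can dump its full configuration alongside its
#' outputs; [read_params()] restores it.
#'
#' @param params a parameter list as returned by [default_params()].
#' @param path output file; extension `.yaml`/`.yml` selects YAML (requires
#'   the yaml package), anything else JSON.
#' @export
write_params <- function(params, path) {
  if (grepl("[.]ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    yaml::write_yaml(params, path)
  else
    jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#' @param path file path.
#' @export
read_params <- function(path) {
  p <- if (grepl("[.]ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  # coupling entries arrive as named lists/vectors; normalize to numeric
  p$couplings <- lapply(p$couplings, function(x) unlist(x))
  p$variant <- as.integer(p$variant)
  p
}
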