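# Generic dynamic-field integrator.
#
# A field is a population of feature-tuned units over one or two circular
# dimensions (extent 360 deg each), evolving as
#   tau * du/dt = -u + h + s(x,t) + integral k(x - x') g(u(x')) dx' + q xi
# with g a logistic output nonlinearity and k a difference-of-Gaussians
# lateral-interaction kernel with optional constant global inhibition.
# Kernel amplitudes are per-degree weights: the convolution multiplies by the
# grid spacing so results are resolution-invariant.

#' Logistic output nonlinearity
#'
#' @param u activation (any shape).
#' @param beta steepness (1 / activation units).
#' @param theta threshold (activation units); `df_sigmoid(theta) == 0.5`.
#' @return values in (0, 1), shape preserved.
#' @export
df_sigmoid <- function(u, beta = 4, theta = 0) {
  if (any(!is.finite(u))) stop("non-finite activation")
  1 / (1 + exp(-beta * (u - theta)))
}

#' Difference-of-Gaussians lateral-interaction kernel
#'
#' Evaluated at circular distance d:
#' `c_exc * exp(-d^2 / (2 sigma_exc^2)) - c_inh * exp(-d^2 / (2 sigma_inh^2)) - g_inh`.
#'
#' @param c_exc,sigma_exc excitatory amplitude and width (degrees).
#' @param c_inh,sigma_inh surround-inhibition amplitude and width (degrees).
#' @param g_inh constant global-inhibition offset (>= 0).
#' @export
interaction_kernel <- function(c_exc = 0, sigma_exc = 5, c_inh = 0,
                               sigma_inh = 10, g_inh = 0) {
  if (g_inh < 0) stop("g_inh must be >= 0")
  if (c_exc != 0 && c_inh != 0 && sigma_inh <= sigma_exc)
    stop("surround structure requires sigma_inh > sigma_exc")
  structure(list(c_exc = c_exc, sigma_exc = sigma_exc, c_inh = c_inh,
                 sigma_inh = sigma_inh, g_inh = g_inh),
            class = "interaction_kernel")
}

# kernel values (excluding g_inh) at each site's circular distance from site 1
kernel_profile <- function(kernel, n_sites, extent = 360) {
  dx <- extent / n_sites
  d <- dx * pmin(0:(n_sites - 1), n_sites - (0:(n_sites - 1)))
  kernel$c_exc * exp(-d^2 / (2 * kernel$sigma_exc^2)) -
    kernel$c_inh * exp(-d^2 / (2 * kernel$sigma_inh^2))
}

#' Construct a 1D circular dynamic field
#'
#' @param label field name.
#' @param n_sites number of sampling points over the 360-degree extent.
#' @param h resting level (activation units).
#' @param tau time constant (ms).
#' @param q noise amplitude (activation units).
#' @param kernel an [interaction_kernel()] or `NULL` for no lateral coupling.
#' @param beta,theta sigmoid steepness and threshold.
#' @param u optional initial activation (defaults to `h`).
#' @export
df_field <- function(label, n_sites = 180, h = -5, tau = 20, q = 0,
                     kernel = NULL, beta = 4, theta = 0, u = NULL) {
  if (is.null(u)) u <- rep(h, n_sites)
  stopifnot(length(u) == n_sites)
  structure(list(label = label, n_sites = as.integer(n_sites), u = u, h = h,
                 tau = tau, q = q, kernel = kernel, beta = beta,
                 theta = theta, extent = 360),
            class = "df_field")
}

#' Site coordinates (degrees) of a field
#' @param field a `df_field`.
#' @export
field_sites <- function(field) {
  (seq_len(field$n_sites) - 1) * field$extent / field$n_sites
}

#' Lateral interaction input of a field
#'
#' Circular convolution of the field output with its kernel (per-degree
#' weights times grid spacing), minus `g_inh` times the integral of the
#' output.
#'
#' @param field a `df_field` with a kernel.
#' @return activation contribution per site.
#' @export
lateral_input <- function(field) {
  if (is.null(field$kernel)) stop("field has no interaction kernel")
  k <- field$kernel
  if (min(k$sigma_exc, k$sigma_inh) * 2 > field$extent)
    stop("kernel wider than the field extent")
  g <- df_sigmoid(field$u, field$beta, field$theta)
  dx <- field$extent / field$n_sites
  kv <- kernel_profile(k, field$n_sites, field$extent)
  conv <- Re(fft(fft(kv) * fft(g), inverse = TRUE)) / field$n_sites
  conv * dx - k$g_inh * sum(g) * dx
}

#' One Euler(-Maruyama) integration step of a field
#'
#' `u <- u + (dt / tau) * (-u + h + s + lateral) + q * sqrt(dt) * xi` with
#' `xi` i.i.d. standard normal per site (drawn from the R RNG, so runs are
#' reproducible under `set.seed`); deterministic when `q = 0`.
#'
#' @param field a `df_field`.
#' @param external_input input `s` per site (scalar or vector).
#' @param dt time step (ms), strictly less than `tau`.
#' @export
euler_step <- function(field, external_input = 0, dt = 2) {
  if (dt <= 0 || dt >= field$tau) stop("require 0 < dt < tau for stable integration")
  lat <- if (is.null(field$kernel)) 0 else lateral_input(field)
  du <- (-field$u + field$h + external_input + lat) * (dt / field$tau)
  if (field$q > 0) du <- du + field$q * sqrt(dt) * rnorm(field$n_sites)
  field$u <- field$u + du
  field
}

#' Run a field forward for a fixed duration under constant input
#' @inheritParams euler_step
#' @param duration total simulated time (ms).
#' @export
run_field <- function(field, external_input = 0, duration, dt = 2) {
  for (i in seq_len(round(duration / dt)))
    field <- euler_step(field, external_input, dt)
  field
}

#' Above-threshold local maxima of a 1D field
#'
#' Circular local maxima with activation above `threshold`, positions refined
#' by three-point parabolic interpolation, sorted by descending activation;
#' ties broken by the lower location index.
#'
#' @param field a `df_field`.
#' @param threshold activation threshold.
#' @return data frame with columns `location` (degrees) and `activation`.
#' @export
detect_peaks <- function(field, threshold = 0) {
  u <- field$u
  n <- length(u)
  up <- u[c(2:n, 1)]
  um <- u[c(n, 1:(n - 1))]
  is_peak <- u > threshold & u >= um & u > up
  idx <- which(is_peak)
  if (!length(idx))
    return(data.frame(location = numeric(0), activation = numeric(0)))
  dx <- field$extent / n
  loc <- vapply(idx, function(i) {
    a <- um[i]; b <- u[i]; c <- up[i]
    denom <- a - 2 * b + c
    offset <- if (denom < 0) 0.5 * (a - c) / denom else 0
    ((i - 1) + offset) * dx
  }, numeric(1))
  ord <- order(-u[idx], idx)
  data.frame(location = wrap360(loc[ord]), activation = u[idx][ord])
}

#' Construct a scalar dynamic node
#'
#' Same relaxation contract as a one-site field without a spatial kernel, plus
#' a self-excitation term `self_exc * g(u)`.
#'
#' @inheritParams df_field
#' @param self_exc self-excitation gain.
#' @export
df_node <- function(label, h = -5, tau = 20, self_exc = 0, q = 0, beta = 4,
                    theta = 0, u = NULL) {
  if (is.null(u)) u <- h
  structure(list(label = label, u = u, h = h, tau = tau, self_exc = self_exc,
                 q = q, beta = beta, theta = theta),
            class = "df_node")
}

#' One Euler step of a dynamic node
#'
#' @param node a `df_node`.
#' @param drive summed external input (scalar).
#' @param dt time step (ms), strictly less than `tau`.
#' @export
node_step <- function(node, drive = 0, dt = 2) {
  if (dt <= 0 || dt >= node$tau) stop("require 0 < dt < tau for stable integration")
  self <- node$self_exc * df_sigmoid(node$u, node$beta, node$theta)
  du <- (-node$u + node$h + drive + self) * (dt / node$tau)
  if (node$q > 0) du <- du + node$q * sqrt(dt) * rnorm(1)
  node$u <- node$u + du
  node
}

#' Node output (sigmoided activation)
#' @param node a `df_node`.
#' @export
node_output <- function(node) df_sigmoid(node$u, node$beta, node$theta)
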