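# Circular mixture models for continuous-report recall errors.
#
# The standard model describes the error distribution as a weighted sum of a
# von Mises component centered on the (possibly biased) target value and a
# uniform component capturing random guesses:
#   f(e) = (1 - p_u) * VM(e; mu, kappa) + p_u / 360
# with errors in degrees on the full circle.  The swap variant adds von Mises
# components centered on the non-probed items' values.  Concentration kappa is
# reported as a circular standard deviation in degrees.

DEG <- pi / 180

#' Von Mises density on the 360-degree circle
#'
#' @param x angles in degrees.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return density per degree (integrates to 1 over any 360-degree window).
#' @export
dvonmises_deg <- function(x, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  # exponential scaling keeps the ratio finite for large kappa
  exp(kappa * (cos((x - mu) * DEG) - 1)) /
    (360 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Circular standard deviation (degrees) implied by a von Mises concentration
#'
#' Uses the standard mapping sd = sqrt(-2 log R) with R = I1(kappa)/I0(kappa).
#' @param kappa concentration parameter.
#' @export
sd_from_kappa <- function(kappa) {
  # for very large concentrations the Bessel ratio underflows; use the
  # asymptotic expansion A1(kappa) ~ 1 - 1/(2 kappa)
  r <- if (kappa > 1e6) 1 - 1 / (2 * kappa) else
    besselI(kappa, 1, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-2 * log(r)) / DEG
}

#' Concentration implied by a circular standard deviation in degrees
#'
#' Numerical inverse of [sd_from_kappa()]; round-trips to high precision over
#' the range of standard deviations seen in recall data.
#' @param sd_deg circular standard deviation in degrees (> 0).
#' @export
kappa_from_sd <- function(sd_deg) {
  if (!is.finite(sd_deg) || sd_deg <= 0) stop("sd must be a positive number")
  f <- function(lk) sd_from_kappa(exp(lk)) - sd_deg
  # kappa is monotonically decreasing in sd; bracket on log scale
  exp(uniroot(f, c(-15, 20), tol = 1e-12)$root)
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

check_errors <- function(errors) {
  if (!is.numeric(errors) || any(!is.finite(errors)))
    stop("errors must be finite numeric degrees")
  wrap180(errors)
}

#' Log-likelihood of the standard mixture model (with bias)
#'
#' @param errors recall errors in degrees, wrapped to (-180, 180].
#' @param mu mean bias (degrees).
#' @param sd circular standard deviation of the target component (degrees).
#' @param p_uniform probability of a uniform (guess) response.
#' @return total log-likelihood in nats.
#' @export
loglik_standard <- function(errors, mu, sd, p_uniform) {
  errors <- check_errors(errors)
  if (sd <= 0) stop("sd must be > 0")
  if (p_uniform < 0 || p_uniform > 1) stop("p_uniform must lie in [0, 1]")
  kappa <- kappa_from_sd(sd)
  sum(log((1 - p_uniform) * dvonmises_deg(errors, mu, kappa) + p_uniform / 360))
}

#' Log-likelihood of the three-component swap model
#'
#' Non-target components share the target component's concentration and bias;
#' the non-target probability is split equally over the supplied offsets.
#'
#' @param errors recall errors (degrees).
#' @param offsets matrix (n x m) of non-target minus target feature values per
#'   trial, in degrees.
#' @inheritParams loglik_standard
#' @param p_nontarget probability of reporting a non-probed item.
#' @export
loglik_swap <- function(errors, offsets, mu, sd, p_uniform, p_nontarget) {
  errors <- check_errors(errors)
  offsets <- as.matrix(offsets)
  if (nrow(offsets) != length(errors)) stop("one row of offsets per error required")
  if (sd <= 0) stop("sd must be > 0")
  if (min(p_uniform, p_nontarget) < 0 || p_uniform + p_nontarget > 1)
    stop("mixture probabilities must be valid")
  kappa <- kappa_from_sd(sd)
  target <- dvonmises_deg(errors, mu, kappa)
  nt <- rowMeans(dvonmises_deg(errors - offsets, mu, kappa))
  sum(log((1 - p_uniform - p_nontarget) * target +
            p_nontarget * nt + p_uniform / 360))
}

mixture_fit <- function(mu, sd, p_uniform, p_nontarget, loglik, converged, n) {
  structure(list(mu = wrap180(mu), sd = sd, p_uniform = p_uniform,
                 p_m = 1 - p_uniform - p_nontarget,
                 p_nontarget = p_nontarget,
                 loglik = loglik, converged = converged, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Circular mixture fit (n = %d)\n  mu = %.2f deg, sd = %.2f deg, p_m = %.3f, p_uniform = %.3f%s\n  loglik = %.2f, converged = %s\n",
    x$n, x$mu, x$sd, x$p_m, x$p_uniform,
    if (x$p_nontarget > 0) sprintf(", p_nontarget = %.3f", x$p_nontarget) else "",
    x$loglik, x$converged))
  invisible(x)
}

#' Maximum-likelihood fit of the standard mixture model (with bias)
#'
#' Bounded multi-start optimization over (mu, sd, p_uniform).  The start grid
#' is fixed, so the fit is deterministic given the data.
#'
#' @param errors recall errors in degrees (at least 20 values).
#' @return a `mixture_fit` with elements mu, sd, p_uniform, p_m, loglik,
#'   converged and n.
#' @export
fit_standard_mixture <- function(errors) {
  errors <- check_errors(errors)
  n <- length(errors)
  if (n < 20) stop("at least 20 errors required for a stable fit")
  if (length(unique(errors)) == 1L)
    warning("all errors identical; fit lies on the parameter boundary")
  nll <- function(par) {
    val <- tryCatch(-loglik_standard(errors, par[1], par[2], par[3]),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  starts <- expand.grid(mu = c(-20, 0, 20), sd = c(10, 25, 50),
                        p_u = c(0.05, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- suppressWarnings(
      optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
            lower = c(-180, 0.5, 0), upper = c(180, 150, 1),
            control = list(maxit = 500)))
    if (is.null(best) || res$value < best$value) best <- res
  }
  mixture_fit(best$par[1], best$par[2], best$par[3], 0,
              -best$value, best$convergence == 0, n)
}

#' Maximum-likelihood fit of the three-component swap model
#'
#' @inheritParams loglik_swap
#' @param fix_p_nontarget if not `NULL`, the non-target probability is held at
#'   this value (0 recovers the standard model exactly).
#' @export
fit_swap_mixture <- function(errors, nontarget_offsets, fix_p_nontarget = NULL) {
  errors <- check_errors(errors)
  if (missing(nontarget_offsets) || is.null(nontarget_offsets))
    stop("per-trial non-target offsets are required for the swap model")
  offsets <- as.matrix(nontarget_offsets)
  n <- length(errors)
  if (n < 20) stop("at least 20 errors required for a stable fit")
  fixed <- !is.null(fix_p_nontarget)
  # mixture weights parameterized as total non-von-Mises-target mass `a` and
  # its non-target share `w`, keeping p_uniform + p_nontarget <= 1 by box bounds
  nll <- function(par) {
    a <- par[3]; w <- if (fixed) 0 else par[4]
    pn <- if (fixed) fix_p_nontarget else a * w
    pu <- if (fixed) a else a * (1 - w)
    val <- tryCatch(-loglik_swap(errors, offsets, par[1], par[2], pu, pn),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  starts <- expand.grid(mu = c(-20, 0, 20), sd = c(10, 25, 50),
                        a = c(0.05, 0.3), w = if (fixed) 0 else c(0.1, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- as.numeric(starts[i, seq_len(if (fixed) 3 else 4)])
    res <- suppressWarnings(
      optim(par0, nll, method = "L-BFGS-B",
            lower = c(-180, 0.5, 0, 0)[seq_along(par0)],
            upper = c(180, 150, 1, 1)[seq_along(par0)],
            control = list(maxit = 500)))
    if (is.null(best) || res$value < best$value) best <- res
  }
  a <- best$par[3]; w <- if (fixed) 0 else best$par[4]
  pn <- if (fixed) fix_p_nontarget else a * w
  pu <- if (fixed) a else a * (1 - w)
  mixture_fit(best$par[1], best$par[2], pu, pn, -best$value,
              best$convergence == 0, n)
}

#' Draw von Mises samples (degrees) by Best-Fisher rejection sampling
#' @keywords internal
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -180, 180) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f) / DEG + mu
        break
      }
    }
  }
  out
}

#' Simulate recall errors from the generative mixture
#'
#' @param n number of samples.
#' @param mu,sd target-component bias and circular s.d. (degrees).
#' @param p_m probability the probed item is in memory (target component).
#' @param p_nontarget probability of a response centered on a non-target.
#' @param offsets vector or n x m matrix of non-target offsets (degrees);
#'   required when `p_nontarget > 0`.
#' @return errors in degrees wrapped to (-180, 180].
#' @export
simulate_errors <- function(n, mu, sd, p_m, p_nontarget = 0, offsets = NULL) {
  if (min(p_m, p_nontarget) < 0 || p_m + p_nontarget > 1)
    stop("mixture probabilities must be valid")
  if (p_nontarget > 0 && is.null(offsets))
    stop("offsets required when p_nontarget > 0")
  kappa <- kappa_from_sd(sd)
  comp <- sample(c("target", "nontarget", "uniform"), n, replace = TRUE,
                 prob = c(p_m, p_nontarget, 1 - p_m - p_nontarget))
  out <- numeric(n)
  nt <- comp == "nontarget"
  if (any(nt)) {
    offsets <- as.matrix(offsets)
    om <- if (nrow(offsets) == 1) offsets[rep(1, n), , drop = FALSE] else offsets
    pick <- om[cbind(which(nt), sample.int(ncol(om), sum(nt), replace = TRUE))]
    out[nt] <- rvonmises_deg(sum(nt), mu, kappa) + pick
  }
  tg <- comp == "target"
  if (any(tg)) out[tg] <- rvonmises_deg(sum(tg), mu, kappa)
  un <- comp == "uniform"
  if (any(un)) out[un] <- runif(sum(un), -180, 180)
  wrap180(out)
}
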