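# Experiment-level orchestration: simulated participants, condition-wise
# mixture fits, RMSE against behavioral reference values, and AIC model
# comparison.

#' Behavioral reference values from the cued color-recall experiments
#'
#' Mixture-model parameter estimates (means over twelve participants) for the
#' delayed-estimation experiment (1000-ms delay) and its zero-delay control.
#' Only values reported numerically are included; entries not available are
#' `NA`.  Each value carries a citation tag in the `citations` attribute.
#'
#' @return data frame with columns experiment, condition, mu, sd, p_m.
#' @export
behavioral_reference <- function() {
  ref <- data.frame(
    experiment = c(rep("DELAY", 4), rep("CONTROL", 3)),
    condition  = c("SINGLE", "UNIQUE", "CW", "CCW", "UNIQUE", "CW", "CCW"),
    mu  = c(NA, NA, NA, NA, -1.10, -0.10, -1.66),
    sd  = c(NA, 18.66, 21.63, 20.44, 10.66, 11.15, 10.79),
    p_m = c(NA, NA, NA, NA, 0.96, 0.97, 0.96)
  )
  attr(ref, "citations") <- c(
    "delay sd: reported group means (Unique = 18.66; CW = 21.63; CCW = 20.44)",
    "control mu: reported group means (Unique = -1.10; CW = -0.11; CCW = -1.66); the CW value is also quoted as -0.10 in the discussion",
    "control sd: reported group means (Unique = 10.66; CW = 11.15; CCW = 10.79)",
    "control p_m: reported group means (Unique = 0.96; CW = 0.97; CCW = 0.96)")
  ref
}

#' Published root-mean-squared errors between simulations and behavior
#'
#' The RMSE rows (mean color bias mu, s.d., and p_m, each across the four
#' conditions) reported for the two simulation experiments and the control
#' simulation.  These are inputs to the AIC comparison.
#'
#' @return data frame with columns simulation, rmse_mu, rmse_sd, rmse_pm, k.
#' @export
reference_rmse_table <- function() {
  data.frame(
    simulation = c("model1_delay", "model2_delay", "model2_control"),
    rmse_mu = c(1.77, 1.70, 1.16),
    rmse_sd = c(6.91, 3.61, 2.40),
    rmse_pm = c(0.07, 0.03, 0.03),
    k = c(49, 56, NA)
  )
}

#' Fit the standard mixture model to each condition of a results table
#'
#' @param results trial results from [run_trials()].
#' @param min_n conditions with fewer responses are skipped with a warning.
#' @return data frame with one row per condition: n, mu, sd, p_m, p_uniform,
#'   loglik, converged.
#' @export
fit_conditions <- function(results, min_n = 20) {
  out <- list()
  for (cond in unique(results$probed_role)) {
    err <- results$signed_error[results$probed_role == cond]
    if (length(err) < min_n) {
      warning("condition ", cond, " has fewer than ", min_n,
              " responses; skipped")
      next
    }
    f <- fit_standard_mixture(err)
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, n = f$n, mu = f$mu, sd = f$sd, p_m = f$p_m,
      p_uniform = f$p_uniform, loglik = f$loglik, converged = f$converged)
  }
  do.call(rbind, out)
}

#' Run a set of simulated participants through the task
#'
#' Each run generates a fresh trial set, simulates every trial, and fits the
#' standard mixture model per condition, mirroring how each human participant
#' contributes one session.  The full-scale session is 800 trials (delay) or
#' 640 (control); `n_trials` scales the session down proportionally.
#'
#' @param variant model variant (1 or 2).
#' @param condition `"DELAY"` or `"CONTROL"`.
#' @param n_runs number of simulated participants.
#' @param n_trials trials per run (`NULL` = the full session).
#' @param seed base seed; run r uses `seed + r`.
#' @param params optional parameter overrides (see [default_params()]).
#' @param progress print one line per completed run.
#' @return list with elements `fits` (per-run condition fits), `summary`
#'   (mean and standard error per condition across runs) and `results`
#'   (trial-level table).
#' @export
run_simulated_participants <- function(variant, condition = "DELAY",
                                       n_runs = 12, n_trials = NULL,
                                       seed = 1, params = NULL,
                                       progress = FALSE) {
  p <- default_params(variant, params)
  model <- if (variant == 1) build_model1(p) else build_model2(p)
  fits <- list(); all_res <- list()
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    trials <- generate_trials(condition, n_trials = n_trials)
    res <- run_trials(model, trials)
    res$run <- r
    all_res[[r]] <- res
    f <- fit_conditions(res)
    f$run <- r
    fits[[r]] <- f
    if (progress) cat(sprintf("run %d/%d done (%d trials)\n", r, n_runs,
                              nrow(res)))
  }
  fits <- do.call(rbind, fits)
  agg <- do.call(rbind, lapply(split(fits, fits$condition), function(d) {
    data.frame(condition = d$condition[1], n_runs = nrow(d),
               mu = mean(d$mu), mu_se = sd(d$mu) / sqrt(nrow(d)),
               sd = mean(d$sd), sd_se = sd(d$sd) / sqrt(nrow(d)),
               p_m = mean(d$p_m), p_m_se = sd(d$p_m) / sqrt(nrow(d)))
  }))
  rownames(agg) <- NULL
  list(fits = fits, summary = agg, results = do.call(rbind, all_res))
}

#' Root-mean-squared error between simulated and reference mixture parameters
#'
#' For each mixture parameter, the square root of the mean squared deviation
#' between simulation means and reference values over the conditions present
#' in both tables (reference entries that are `NA` are skipped).
#'
#' @param sim_summary the `summary` element of
#'   [run_simulated_participants()] (columns condition, mu, sd, p_m).
#' @param reference data frame with columns condition, mu, sd, p_m.
#' @return one-row data frame with rmse_mu, rmse_sd, rmse_pm and the number
#'   of conditions entering each.
#' @export
rmse_table <- function(sim_summary, reference) {
  m <- merge(sim_summary, reference, by = "condition",
             suffixes = c("_sim", "_ref"))
  if (nrow(m) == 0) stop("no overlapping conditions between simulation and reference")
  one <- function(par) {
    d <- m[[paste0(par, "_sim")]] - m[[paste0(par, "_ref")]]
    d <- d[!is.na(d)]
    if (!length(d)) return(c(NA_real_, 0L))
    c(sqrt(mean(d^2)), length(d))
  }
  mu <- one("mu"); sdv <- one("sd"); pm <- one("p_m")
  data.frame(rmse_mu = mu[1], n_mu = mu[2], rmse_sd = sdv[1], n_sd = sdv[2],
             rmse_pm = pm[1], n_pm = pm[2])
}

#' AIC model-comparison score from per-parameter RMSEs
#'
#' `AIC = N * ln(MSE) + 2k` (Gaussian likelihood), where the mean squared
#' error pools the squared deviations behind the three per-parameter RMSEs
#' over `N = n_conditions * 3` data points.
#'
#' @param rmse_mu,rmse_sd,rmse_pm per-parameter RMSEs (each across
#'   `n_conditions` conditions).
#' @param k number of free model parameters.
#' @param n_conditions number of conditions behind each RMSE (default 4).
#' @return the AIC value (natural logarithm).
#' @export
aic_from_rmse <- function(rmse_mu, rmse_sd, rmse_pm, k, n_conditions = 4) {
  if (min(rmse_mu, rmse_sd, rmse_pm) < 0) stop("RMSEs must be >= 0")
  if (k <= 0) stop("k must be positive")
  n <- 3 * n_conditions
  mse <- n_conditions * (rmse_mu^2 + rmse_sd^2 + rmse_pm^2) / n
  if (mse == 0) stop("MSE is zero; AIC undefined")
  n * log(mse) + 2 * k
}
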