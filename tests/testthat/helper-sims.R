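# Shared simulation batches for the heavier tests.  Results are cached for
# the session so several test blocks can analyze the same runs.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (!exists(key, envir = .sim_cache)) assign(key, fun(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# simulate trials for each probed role (n_per: scalar or named per-role
# counts); returns the trial table
role_batch <- function(variant, roles, n_per, condition = "DELAY", seed = 1) {
  model <- if (variant == 1) build_model1() else build_model2()
  set.seed(seed)
  if (length(n_per) == 1) n_per <- setNames(rep(n_per, length(roles)), roles)
  out <- list()
  for (role in roles) {
    for (i in seq_len(n_per[[role]])) {
      tr <- if (role == "SINGLE") dfwm:::make_ss1_trial(condition)
            else dfwm:::make_ss3_trial(condition, role,
                   if (condition == "CONTROL") 45 else 0)
      out[[length(out) + 1L]] <- cbind(simulate_trial(model, tr), role = role)
    }
  }
  do.call(rbind, out)
}

delay_batch_m1 <- function()
  cached("m1_delay", function()
    role_batch(1, c("SINGLE", "UNIQUE", "CW", "CCW"),
               c(SINGLE = 20, UNIQUE = 20, CW = 26, CCW = 26), "DELAY",
               seed = 11))

delay_batch_m2 <- function()
  cached("m2_delay", function()
    role_batch(2, c("SINGLE", "UNIQUE", "CW", "CCW"),
               c(SINGLE = 24, UNIQUE = 24, CW = 40, CCW = 40), "DELAY",
               seed = 12))

control_batch_m2 <- function()
  cached("m2_control", function()
    role_batch(2, c("CW", "CCW"), 22, "CONTROL", seed = 13))

# consolidation-time table over seeded set-size-3 trials (encoding only)
consolidation_batch <- function(n = 90, seed = 14) {
  cached("m2_consolidation", function() {
    model <- build_model2()
    set.seed(seed)
    t(vapply(seq_len(n), function(i) {
      tr <- dfwm:::make_ss3_trial("DELAY", "CW", 0)
      consolidation_times(model, tr)
    }, numeric(3)))
  })
}

role_mean <- function(tab, role) {
  r <- tab[tab$role == role & !tab$guess, ]
  mean(r$signed_error)
}
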