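#' Nested model variants
#'
#' Restricts the full model to one of its published nested variants:
#' `"fixed_attitudes"` freezes attitudes by setting the adjustment speed
#' `s = 0`; `"no_attitudes"` additionally removes every attitude-coupled
#' force by setting `v = k2 = alpha = beta2 = 0` for all agents. The
#' remaining weights are deliberately *not* renormalised — the variant
#' zeroes terms only, so the value difference reduces to
#' `k1 (2p - 1) + k3`. `"full"` returns the configuration unchanged.
#'
#' `model_variant()` adjusts the configuration-level pieces (`s`);
#' the per-agent zeroing is applied to a generated population by
#' [simulate_adoption()] when its `variant` argument is set.
#'
#' @param config An [adoption_config()] object.
#' @param variant One of `"full"`, `"fixed_attitudes"`, `"no_attitudes"`.
#' @return The (possibly modified) configuration.
#' @examples
#' cfg <- model_variant(adoption_config(), "fixed_attitudes")
#' cfg$global$s  # 0
#' @export
model_variant <- function(config, variant = c("full", "fixed_attitudes",
                                              "no_attitudes")) {
  stopifnot(inherits(config, "adoption_config"))
  variant <- match.arg(variant)
  if (variant %in% c("fixed_attitudes", "no_attitudes"))
    config$global$s <- 0
  if (variant == "no_attitudes" && !is.null(config$population$weights)) {
    w <- config$population$weights
    w$util[c(1L, 3L)] <- 0   # v, k2
    w$att[c(1L, 3L)] <- 0    # alpha, beta2
    config$population$weights <- w
  }
  config
}

# Zero the attitude-coupled weights of an already generated population.
apply_variant_population <- function(population, variant) {
  if (variant == "no_attitudes") {
    population$params$v <- 0
    population$params$k2 <- 0
    population$params$alpha <- 0
    population$params$beta2 <- 0
  }
  population
}

#' Run independent replicate simulations
#'
#' Runs `n_runs` independent simulations of a configuration (one RNG
#' substream per run, derived from `seed` via [derive_seeds()]) and records
#' the adopter frequency and class-wise mean attitudes at each observation
#' time. Attitude means of an empty class are reported as `NA`.
#'
#' @param config An [adoption_config()] object.
#' @param n_runs Number of replicates (>= 1).
#' @param T_obs Observation times (positive integers); the simulation runs
#'   to `max(T_obs)`.
#' @param seed Master seed.
#' @param variant Model variant passed to [simulate_adoption()].
#' @return A data frame with one row per `(run, T)`: columns `run, seed, T,
#'   p, mean_y_adopters, mean_y_nonadopters, mean_b`.
#' @examples
#' cfg <- adoption_config(global = global_params(N = 100))
#' head(run_replicates(cfg, n_runs = 3, T_obs = c(25, 50), seed = 1))
#' @export
run_replicates <- function(config, n_runs, T_obs = c(50, 100, 200),
                           seed = 1, variant = "full") {
  stopifnot(n_runs >= 1, all(T_obs >= 1))
  seeds <- derive_seeds(seed, n_runs)
  T_max <- max(T_obs)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sim <- simulate_adoption(config, T = T_max, seed = seeds[r],
                             variant = variant)
    tr <- sim$trajectory[sim$trajectory$t %in% T_obs, , drop = FALSE]
    rows[[r]] <- data.frame(run = r, seed = seeds[r], T = tr$t, p = tr$p,
                            mean_y_adopters = tr$mean_y_adopters,
                            mean_y_nonadopters = tr$mean_y_nonadopters,
                            mean_b = tr$mean_b)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Set a sweep parameter inside the right configuration block.
set_sweep_parameter <- function(config, name, value) {
  global_fields <- c("b0", "b_min", "b_max", "a0", "c", "s", "nu", "lam", "N")
  pop_fields <- c("a1_mean", "a1_sd", "omega_mean", "omega_sd",
                  "eps_mean", "eps_sd", "y0_mean", "y0_sd")
  int_fields <- c("p0", "b_s", "subsidy_window", "f0", "f1", "f2", "f3")
  if (name %in% global_fields) {
    config$global[[name]] <- if (name == "N") as.integer(value) else value
    validate_global_params(config$global)
  } else if (name %in% pop_fields) {
    config$population[[name]] <- value
    validate_population_config(config$population)
  } else if (name %in% int_fields) {
    config$intervention[[name]] <- value
    validate_intervention_config(config$intervention)
  } else {
    stop("unknown sweep parameter '", name, "'", call. = FALSE)
  }
  config
}

#' Sweep a parameter across a value grid
#'
#' Repeats [run_replicates()] for every value of one parameter, reusing the
#' *same* replicate seeds at every grid value (matched seeds), so that
#' grid-to-grid differences are not confounded by sampling noise. Returns
#' long-format results suitable for monotonicity tests and plotting.
#'
#' @param config Base [adoption_config()].
#' @param parameter Name of the swept parameter: one of the global fields
#'   (`b_max`, `b_min`, `a0`, ...), population hyperparameters
#'   (`omega_mean`, `eps_mean`, `a1_mean`, ...) or intervention controls
#'   (`p0`, `b_s`, `f0`..`f3`).
#' @param values Non-empty numeric grid.
#' @param n_runs Replicates per grid value.
#' @param T_obs Observation times.
#' @param seed Master seed (shared across grid values).
#' @param variant Model variant.
#' @return A data frame: columns `parameter, value, run, seed, T, p,
#'   mean_y_adopters, mean_y_nonadopters, mean_b`.
#' @examples
#' cfg <- adoption_config(global = global_params(N = 100))
#' sw <- sweep_parameter(cfg, "b_max", c(1.5, 2), n_runs = 2, T_obs = 50, seed = 1)
#' aggregate(p ~ value, sw, mean)
#' @export
sweep_parameter <- function(config, parameter, values, n_runs = 20,
                            T_obs = c(50, 100, 200), seed = 1,
                            variant = "full") {
  if (length(values) < 1) stop("'values' must be non-empty", call. = FALSE)
  out <- lapply(values, function(val) {
    cfg <- set_sweep_parameter(config, parameter, val)
    res <- run_replicates(cfg, n_runs = n_runs, T_obs = T_obs, seed = seed,
                          variant = variant)
    cbind(parameter = parameter, value = val, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Per-agent composite psychological characteristics.
agent_characteristics <- function(params) {
  data.frame(D = (params$v + params$alpha) / 2,
             K1 = (params$k1 + params$beta1) / 2,
             K2 = (params$k2 + params$beta2) / 2,
             K3 = (params$k3 + params$beta3) / 2,
             omega = params$omega,
             epsilon = params$epsilon)
}

#' Per-run psychological profiles of adopters and non-adopters
#'
#' For one finished simulation, computes the class means of the composite
#' characteristics `D = (v + alpha)/2`, `K1 = (k1 + beta1)/2`,
#' `K2 = (k2 + beta2)/2`, `K3 = (k3 + beta3)/2` and of `omega` and
#' `epsilon`, among adopters (`x = 1` at the end of the run) and
#' non-adopters.
#'
#' @param sim An `adoption_sim` object.
#' @return A two-row data frame (`class` = "adopter"/"nonadopter") of class
#'   means; `NA` for an empty class.
#' @export
adopter_profiles <- function(sim) {
  stopifnot(inherits(sim, "adoption_sim"))
  ch <- agent_characteristics(sim$population$params)
  adopt <- sim$population$state$x == 1L
  class_mean <- function(keep)
    if (any(keep)) colMeans(ch[keep, , drop = FALSE]) else
      stats::setNames(rep(NA_real_, ncol(ch)), names(ch))
  out <- rbind(class_mean(adopt), class_mean(!adopt))
  data.frame(class = c("adopter", "nonadopter"),
             n = c(sum(adopt), sum(!adopt)), out)
}

#' Compare early adopters with non-adopters across replicate runs
#'
#' Aggregates per-run class-mean profiles (see [adopter_profiles()]) across
#' independent runs and tests, for each characteristic, whether adopters
#' and non-adopters differ: a Welch two-sample t-test on the per-run class
#' means, with 95% confidence intervals for the difference
#' (adopter minus non-adopter). Runs in which a class is empty contribute
#' no mean for that class; if a class is empty in every run the comparison
#' is impossible and an informative error is raised.
#'
#' @param profiles Either a list of per-run profile data frames (as
#'   returned by [adopter_profiles()]) or a list of `adoption_sim` objects.
#' @param level Significance level for flagging differences (default 0.05).
#' @return An object of class `profile_comparison`: a data frame with one
#'   row per characteristic (`D, K1, K2, K3, omega, epsilon`) and columns
#'   `mean_adopter, mean_nonadopter, diff, ci_lo, ci_hi, p_value,
#'   significant`, plus attributes `n_runs` and `level`.
#' @examples
#' cfg <- adoption_config(global = global_params(N = 200),
#'                        intervention = intervention_config(f3 = 2))
#' sims <- lapply(derive_seeds(1, 5), function(s)
#'   simulate_adoption(cfg, T = 10, seed = s))
#' compare_adopter_profiles(sims)
#' @export
compare_adopter_profiles <- function(profiles, level = 0.05) {
  if (length(profiles) < 2) stop("need at least 2 runs", call. = FALSE)
  if (inherits(profiles[[1]], "adoption_sim"))
    profiles <- lapply(profiles, adopter_profiles)
  chars <- c("D", "K1", "K2", "K3", "omega", "epsilon")
  pull <- function(cls) {
    m <- t(vapply(profiles, function(pr) {
      row <- pr[pr$class == cls, chars]
      if (nrow(row) == 0L || pr$n[pr$class == cls] == 0L)
        rep(NA_real_, length(chars)) else as.numeric(row)
    }, numeric(length(chars))))
    colnames(m) <- chars
    m
  }
  ad <- pull("adopter")
  non <- pull("nonadopter")
  if (all(is.na(ad)))
    stop("no run contains any adopter; profile comparison impossible", call. = FALSE)
  if (all(is.na(non)))
    stop("no run contains any non-adopter; profile comparison impossible", call. = FALSE)

  rows <- lapply(chars, function(ch) {
    a <- ad[, ch][!is.na(ad[, ch])]
    b <- non[, ch][!is.na(non[, ch])]
    tt <- stats::t.test(a, b, conf.level = 1 - level)
    data.frame(characteristic = ch,
               mean_adopter = mean(a), mean_nonadopter = mean(b),
               diff = mean(a) - mean(b),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               p_value = tt$p.value,
               significant = tt$p.value < level)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_runs") <- length(profiles)
  attr(out, "level") <- level
  class(out) <- c("profile_comparison", class(out))
  out
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Adopter vs non-adopter profiles (%d runs, %g%% level)\n",
              attr(x, "n_runs"), 100 * attr(x, "level")))
  df <- as.data.frame(x)
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
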