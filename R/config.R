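#' Population-wide model constants
#'
#' Bundles the global parameters shared by every agent: the benefit of the
#' old technology, the benefit bounds of the new one, the learning and
#' depreciation rates, the attitude adjustment speed, the per-step revision
#' probability, the decision precision and the population size.
#'
#' Defaults are the baseline constants used throughout the simulation study:
#' `c = 0.1`, `b0 = 1`, `nu = 0.1`, `s = 0.1`, `N = 1000`, `lam = 15`,
#' `a0 = 0.05`, with benefit bounds `b_min = 0.5`, `b_max = 1.5`.
#'
#' @param b0 Benefit per step of the old technology (currency/step).
#' @param b_min,b_max Benefit of the new technology for a novice and for a
#'   complete master; `b_min <= b0 <= b_max` is required.
#' @param a0 Baseline learning rate in `[0, 1]` (per step).
#' @param c Knowledge depreciation rate in `[0, 1]` (per step).
#' @param s Attitude adjustment speed in `[0, 1]`.
#' @param nu Probability that an agent revises its technology choice in a
#'   given step, in `[0, 1]`.
#' @param lam Decision precision of the logit choice rule; `0` means purely
#'   random choice, `Inf` means deterministic utility maximisation.
#' @param N Number of agents (at least 2).
#' @return An object of class `global_params` (a validated list).
#' @seealso [population_config()], [intervention_config()],
#'   [adoption_config()]
#' @examples
#' gp <- global_params(b_max = 2.4, lam = Inf)
#' gp$b_max
#' @export
global_params <- function(b0 = 1, b_min = 0.5, b_max = 1.5,
                          a0 = 0.05, c = 0.1, s = 0.1, nu = 0.1,
                          lam = 15, N = 1000) {
  gp <- list(b0 = b0, b_min = b_min, b_max = b_max, a0 = a0, c = c,
             s = s, nu = nu, lam = lam, N = as.integer(N))
  validate_global_params(gp)
  class(gp) <- "global_params"
  gp
}

validate_global_params <- function(gp) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in c("b0", "b_min", "b_max", "a0", "c", "s", "nu", "lam"))
    if (!num1(gp[[f]])) stop("global parameter '", f, "' must be a single number", call. = FALSE)
  if (!(gp$b_min <= gp$b0 && gp$b0 <= gp$b_max))
    stop("benefit ordering violated: need b_min <= b0 <= b_max, got b_min = ",
         gp$b_min, ", b0 = ", gp$b0, ", b_max = ", gp$b_max, call. = FALSE)
  for (f in c("a0", "c", "s", "nu"))
    if (gp[[f]] < 0 || gp[[f]] > 1)
      stop("global parameter '", f, "' must lie in [0, 1]", call. = FALSE)
  if (gp$lam < 0) stop("precision 'lam' must be >= 0 (Inf allowed)", call. = FALSE)
  if (is.na(gp$N) || gp$N < 2) stop("population size 'N' must be at least 2", call. = FALSE)
  invisible(gp)
}

#' Population heterogeneity configuration
#'
#' Hyperparameters of the distributions that individual psychological and
#' economic traits are drawn from: truncated normals for the learning
#' sensitivity `a1`, the foresight weight `omega` and the normative strength
#' `epsilon`, and a beta law (parameterised by its mean and standard
#' deviation) for initial attitudes. The four utility-side weights
#' `(v, k1, k2, k3)` and the four attitude-side weights
#' `(alpha, beta1, beta2, beta3)` are always drawn from parameter-free
#' broken-stick distributions and need no hyperparameters.
#'
#' `weights`, if supplied, switches off the broken-stick draw and gives every
#' agent the same two weight vectors — the symmetric (no-heterogeneity) case
#' used by the analytic results.
#'
#' @param a1_mean,a1_sd Mean and sd of the learning-rate sensitivity `a1`
#'   (truncated to `[0, 1 - a0]`).
#' @param omega_mean,omega_sd Mean and sd of the foresight weight (truncated
#'   to `[0, 1]`).
#' @param eps_mean,eps_sd Mean and sd of the normative-strength weight
#'   (truncated to `[0, 1]`).
#' @param y0_mean,y0_sd Mean and sd of the beta-distributed initial
#'   attitudes; must satisfy `y0_sd^2 < y0_mean * (1 - y0_mean)`.
#' @param weights Optional list with components `util` (`c(v, k1, k2, k3)`)
#'   and `att` (`c(alpha, beta1, beta2, beta3)`), each summing to 1, applied
#'   identically to all agents.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `population_config`.
#' @examples
#' population_config(omega_mean = 0.3)
#' @export
population_config <- function(a1_mean = 0.05, a1_sd = 0.005,
                              omega_mean = 0.25, omega_sd = 0.025,
                              eps_mean = 0.5, eps_sd = 0.05,
                              y0_mean = 0.1, y0_sd = 0.2,
                              weights = NULL, seed = NULL) {
  pc <- list(a1_mean = a1_mean, a1_sd = a1_sd,
             omega_mean = omega_mean, omega_sd = omega_sd,
             eps_mean = eps_mean, eps_sd = eps_sd,
             y0_mean = y0_mean, y0_sd = y0_sd,
             weights = weights, seed = seed)
  validate_population_config(pc)
  class(pc) <- "population_config"
  pc
}

validate_population_config <- function(pc) {
  for (f in c("a1_sd", "omega_sd", "eps_sd", "y0_sd"))
    if (pc[[f]] < 0) stop("'", f, "' must be >= 0", call. = FALSE)
  if (pc$y0_mean <= 0 || pc$y0_mean >= 1)
    stop("'y0_mean' must lie strictly inside (0, 1)", call. = FALSE)
  if (pc$y0_sd > 0 && pc$y0_sd^2 >= pc$y0_mean * (1 - pc$y0_mean))
    stop("infeasible beta moments: need y0_sd^2 < y0_mean * (1 - y0_mean)", call. = FALSE)
  if (!is.null(pc$weights)) {
    w <- pc$weights
    if (!is.list(w) || !all(c("util", "att") %in% names(w)))
      stop("'weights' must be a list with components 'util' and 'att'", call. = FALSE)
    for (nm in c("util", "att")) {
      ww <- w[[nm]]
      # sum < 1 is allowed: nested model variants zero individual terms
      # without renormalising the rest
      if (length(ww) != 4L || any(ww < 0) || sum(ww) > 1 + 1e-8)
        stop("'weights$", nm, "' must be 4 non-negative values with sum <= 1",
             call. = FALSE)
    }
  }
  invisible(pc)
}

#' Policy intervention configuration
#'
#' Control variables for the five intervention levers: training an initial
#' fraction `p0` of agents, a one-time subsidy `b_s` for adopting within the
#' first `subsidy_window` steps, and the global factors `f0`..`f3` scaling
#' cognitive dissonance, the visibility of peers' actions, the exchange of
#' peers' attitudes, and the effort of the external authority. `f0`..`f3`
#' multiply the matching `k_i`/`v` terms of the utility difference and the
#' matching `beta_i`/`alpha` terms of the attitude update.
#'
#' Defaults (`p0 = 0`, `b_s = 0`, all factors `1`) leave the baseline model
#' untouched.
#'
#' @param p0 Fraction of agents trained at time 0 (skills `b_max`, action 1,
#'   attitude 1), in `[0, 1]`.
#' @param b_s One-time subsidy (currency) added to the perceived pay-off of
#'   adopting, for agents that have never adopted, during the first
#'   `subsidy_window` steps.
#' @param subsidy_window Number of initial steps during which the subsidy is
#'   on offer.
#' @param f0,f1,f2,f3 Non-negative scaling factors for dissonance, peer
#'   action visibility, peer attitude exchange and authority effort.
#' @return An object of class `intervention_config`.
#' @examples
#' intervention_config(p0 = 0.05, f3 = 2)
#' @export
intervention_config <- function(p0 = 0, b_s = 0, subsidy_window = 10,
                                f0 = 1, f1 = 1, f2 = 1, f3 = 1) {
  ic <- list(p0 = p0, b_s = b_s, subsidy_window = as.integer(subsidy_window),
             f0 = f0, f1 = f1, f2 = f2, f3 = f3)
  validate_intervention_config(ic)
  class(ic) <- "intervention_config"
  ic
}

validate_intervention_config <- function(ic) {
  if (ic$p0 < 0 || ic$p0 > 1) stop("'p0' must lie in [0, 1]", call. = FALSE)
  if (ic$b_s < 0) stop("'b_s' must be >= 0", call. = FALSE)
  if (ic$subsidy_window < 0) stop("'subsidy_window' must be >= 0", call. = FALSE)
  for (f in c("f0", "f1", "f2", "f3"))
    if (ic[[f]] < 0) stop("'", f, "' must be >= 0", call. = FALSE)
  invisible(ic)
}

#' Full model configuration
#'
#' Combines the three configuration blocks into the single object consumed
#' by [simulate_adoption()], [run_replicates()] and [sweep_parameter()].
#'
#' @param global A [global_params()] object.
#' @param population A [population_config()] object.
#' @param intervention An [intervention_config()] object.
#' @return An object of class `adoption_config`.
#' @examples
#' cfg <- adoption_config(global = global_params(N = 100))
#' cfg$global$N
#' @export
adoption_config <- function(global = global_params(),
                            population = population_config(),
                            intervention = intervention_config()) {
  stopifnot(inherits(global, "global_params"),
            inherits(population, "population_config"),
            inherits(intervention, "intervention_config"))
  structure(list(global = global, population = population,
                 intervention = intervention),
            class = "adoption_config")
}

#' Symmetric (no-heterogeneity) configuration
#'
#' Convenience constructor for the analytically tractable case: every agent
#' shares the same parameters (all hyperparameter sds are 0, the two weight
#' vectors are fixed rather than drawn) and decisions are error-free
#' (`lam = Inf` by default). This is the regime in which the closed-form
#' equilibrium results of [attitude_at_extinction()], [extinction_unstable()]
#' and [coexistence_range()] apply.
#'
#' @param util Shared utility-side weights `c(v, k1, k2, k3)` summing to 1.
#' @param att Shared attitude-side weights `c(alpha, beta1, beta2, beta3)`
#'   summing to 1.
#' @param omega,epsilon,a1 Shared foresight, normative strength and learning
#'   sensitivity.
#' @param y0_mean,y0_sd Beta moments of the initial attitudes (heterogeneous
#'   starting attitudes are retained; only parameters are symmetric).
#' @param global A [global_params()] object; its `lam` is kept as given.
#' @return An `adoption_config` object.
#' @examples
#' cfg <- symmetric_config(omega = 0.9, global = global_params(b_max = 2.4, lam = Inf))
#' @export
symmetric_config <- function(util = rep(0.25, 4), att = rep(0.25, 4),
                             omega = 0.25, epsilon = 0.5, a1 = 0.05,
                             y0_mean = 0.5, y0_sd = 0.2,
                             global = global_params(lam = Inf)) {
  adoption_config(
    global = global,
    population = population_config(
      a1_mean = a1, a1_sd = 0,
      omega_mean = omega, omega_sd = 0,
      eps_mean = epsilon, eps_sd = 0,
      y0_mean = y0_mean, y0_sd = y0_sd,
      weights = list(util = util, att = att)),
    intervention = intervention_config())
}

#' @export
print.adoption_config <- function(x, ...) {
  g <- x$global
  cat("Technology-adoption model configuration\n")
  cat(sprintf("  benefits: b0 = %g, b_min = %g, b_max = %g\n", g$b0, g$b_min, g$b_max))
  cat(sprintf("  rates: a0 = %g, c = %g, s = %g, nu = %g\n", g$a0, g$c, g$s, g$nu))
  cat(sprintf("  precision lam = %g, N = %d\n", g$lam, g$N))
  p <- x$population
  cat(sprintf("  traits: a1 ~ TN(%g, %g), omega ~ TN(%g, %g), eps ~ TN(%g, %g)\n",
              p$a1_mean, p$a1_sd, p$omega_mean, p$omega_sd, p$eps_mean, p$eps_sd))
  cat(sprintf("  initial attitudes ~ Beta(mean %g, sd %g)%s\n", p$y0_mean, p$y0_sd,
              if (is.null(p$weights)) "; weights ~ broken stick" else "; fixed weights"))
  i <- x$intervention
  if (i$p0 > 0 || i$b_s > 0 || any(c(i$f0, i$f1, i$f2, i$f3) != 1))
    cat(sprintf("  interventions: p0 = %g, b_s = %g (window %d), f = (%g, %g, %g, %g)\n",
                i$p0, i$b_s, i$subsidy_window, i$f0, i$f1, i$f2, i$f3))
  invisible(x)
}
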