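#' Frequency-dependent learning rate
#'
#' The per-step learning-by-doing rate `a = a0 + a1 * p`: agents learn
#' faster when more peers use the new technology (guides, forums and
#' courses multiply with adoption). The generator constrains
#' `a1 <= 1 - a0`, so the rate never exceeds 1.
#'
#' @param a0 Baseline learning rate.
#' @param a1 Sensitivity of the learning rate to adopter frequency
#'   (vectorised over agents).
#' @param p Current adopter frequency in `[0, 1]`.
#' @return Learning rate(s) in `[0, 1]`.
#' @export
learning_rate <- function(a0, a1, p) a0 + a1 * p

#' One-step benefit/skill update
#'
#' Learning by doing pulls the benefit geometrically towards `b_max` while
#' the technology is used (`x = 1`); knowledge depreciation pulls it towards
#' `b_min` while it is not (`x = 0`):
#' `b' = b + a (b_max - b)` or `b' = b - c (b - b_min)`.
#'
#' @param b Current benefit/skill, in `[b_min, b_max]` (vectorised).
#' @param x Action, 0 or 1 (vectorised).
#' @param a Learning rate(s) in `[0, 1]`.
#' @param c Depreciation rate in `[0, 1]`.
#' @param b_min,b_max Benefit bounds.
#' @return Updated benefit(s), guaranteed to stay in `[b_min, b_max]`.
#' @export
update_benefit <- function(b, x, a, c, b_min, b_max) {
  ifelse(x == 1, b + a * (b_max - b), b - c * (b - b_min))
}

#' Perceived material pay-off difference
#'
#' Difference in perceived material pay-off between adopting and staying
#' with the old technology. An adopter weighs the current benefit against
#' the maximal future benefit with foresight `omega`; a one-time subsidy
#' (when on offer) adds to the adoption side:
#' `dPi = (1 - omega) b + omega b_max + bonus - b0`.
#'
#' @param b Current benefit/skill (vectorised).
#' @param omega Foresight weight(s) in `[0, 1]`.
#' @param b_max Maximal benefit of the new technology.
#' @param b0 Benefit of the old technology.
#' @param bonus Subsidy credited to subsidy-eligible agents inside the
#'   subsidy window; 0 otherwise.
#' @return Pay-off difference(s).
#' @export
payoff_diff <- function(b, omega, b_max, b0, bonus = 0) {
  (1 - omega) * b + omega * b_max + bonus - b0
}

#' Normative value difference
#'
#' Difference in psychological value between adopting and not, combining
#' cognitive dissonance, conformity with peers' actions, conformity with
#' peers' attitudes and conformity with the external authority:
#' `dV = f0 v (2y - 1) + f1 k1 (2p - 1) + f2 k2 (2 ybar - 1) + f3 k3`.
#' The intervention factors `f0..f3` rescale the four forces globally.
#'
#' @param y Own attitude(s) in `[0, 1]`.
#' @param p Adopter frequency.
#' @param y_bar Population mean attitude.
#' @param params Data frame (or list) with columns/components
#'   `v, k1, k2, k3`.
#' @param factors An [intervention_config()] (only `f0..f3` are used).
#' @return Value difference(s).
#' @export
value_diff <- function(y, p, y_bar, params, factors = intervention_config()) {
  factors$f0 * params$v * (2 * y - 1) +
    factors$f1 * params$k1 * (2 * p - 1) +
    factors$f2 * params$k2 * (2 * y_bar - 1) +
    factors$f3 * params$k3
}

#' Utility difference
#'
#' `dU = dPi + epsilon * dV`: the material pay-off difference plus the
#' normative value difference weighted by the agent's normative strength.
#'
#' @param dPi Material pay-off difference(s).
#' @param dV Normative value difference(s).
#' @param epsilon Normative strength(s), `>= 0`.
#' @return Utility difference(s).
#' @export
utility_diff <- function(dPi, dV, epsilon) dPi + epsilon * dV

#' Logit adoption probability
#'
#' Myopic best response with errors: the probability of choosing the new
#' technology is `1 / (1 + exp(-lam * dU))`. `lam = 0` is pure
#' randomisation (probability 1/2 whatever the utilities); `lam = Inf` is
#' the deterministic rule "adopt iff `dU >= 0`" — the tie `dU = 0` resolves
#' to adoption.
#'
#' @param dU Utility difference(s).
#' @param lam Precision, `>= 0` or `Inf`.
#' @return Adoption probability(ies) in `[0, 1]`.
#' @export
adoption_probability <- function(dU, lam) {
  if (is.infinite(lam)) return(as.numeric(dU >= 0))
  if (lam == 0) return(rep(0.5, length(dU)))
  stats::plogis(lam * dU)
}

#' One-step attitude update
#'
#' Linear social-influence revision of the attitude after acting:
#' `y' = y + s [f0 alpha (x - y) + f1 beta1 (p - y) + f2 beta2 (ybar - y)
#' + f3 beta3 (1 - y)]`. The four terms pull the attitude towards the own
#' action, the peers' average action, the peers' average attitude and the
#' authority's message (`x = 1`). The result is clipped to `[0, 1]`; with
#' all factors `<= 1` the update is a convex combination and clipping never
#' binds.
#'
#' @param y Current attitude(s).
#' @param x Action(s) just taken.
#' @param p Adopter frequency the agent observes.
#' @param y_bar Mean attitude the agent observes.
#' @param params Data frame (or list) with `alpha, beta1, beta2, beta3`.
#' @param factors An [intervention_config()] (only `f0..f3` are used).
#' @param s Attitude adjustment speed.
#' @return Updated attitude(s) in `[0, 1]`.
#' @export
update_attitude <- function(y, x, p, y_bar, params,
                            factors = intervention_config(), s) {
  dy <- factors$f0 * params$alpha * (x - y) +
    factors$f1 * params$beta1 * (p - y) +
    factors$f2 * params$beta2 * (y_bar - y) +
    factors$f3 * params$beta3 * (1 - y)
  pmin(pmax(y + s * dy, 0), 1)
}

#' Advance the model one time step
#'
#' Synchronous update scheme. Writing `p_t`, `ybar_t` for the adopter
#' frequency and mean attitude of the incoming state:
#' \enumerate{
#'   \item each agent independently revises its action with probability
#'     `nu`, adopting with [adoption_probability()] evaluated at its current
#'     `y`, `b` and the observed `p_t`, `ybar_t` (plus the subsidy bonus if
#'     the agent is still entitled and `t < subsidy_window`);
#'   \item an entitled agent that adopts consumes its subsidy;
#'   \item the post-revision frequency `p_new` is computed;
#'   \item every agent's benefit updates by [update_benefit()] at learning
#'     rate `a0 + a1 * p_t`, using the action just taken;
#'   \item every agent's attitude updates by [update_attitude()] with its
#'     new action, `p_new` and `ybar_t`.
#' }
#'
#' @param population An `adoption_population` (params + state).
#' @param global A [global_params()] object.
#' @param intervention An [intervention_config()] object.
#' @param t Current step index (0-based; governs the subsidy window).
#' @param u_revise,u_adopt Optional length-`N` uniform draws for the
#'   revision and adoption decisions; drawn internally when `NULL`.
#'   Supplying them makes the step a deterministic function, which the test
#'   suite uses to compare against a scalar reference implementation.
#' @return The population with updated state.
#' @export
step_population <- function(population, global,
                            intervention = intervention_config(), t = 0,
                            u_revise = NULL, u_adopt = NULL) {
  params <- population$params
  state <- population$state
  N <- nrow(params)
  if (nrow(state) != N)
    stop("params and state describe different numbers of agents", call. = FALSE)
  if (is.null(u_revise)) u_revise <- stats::runif(N)
  if (is.null(u_adopt)) u_adopt <- stats::runif(N)
  if (length(u_revise) != N || length(u_adopt) != N)
    stop("uniform draws must have one entry per agent", call. = FALSE)

  p_t <- mean(state$x)
  ybar_t <- mean(state$y)

  bonus <- ifelse(state$subsidy_pending & t < intervention$subsidy_window,
                  intervention$b_s, 0)
  dPi <- payoff_diff(state$b, params$omega, global$b_max, global$b0, bonus)
  dV <- value_diff(state$y, p_t, ybar_t, params, intervention)
  dU <- utility_diff(dPi, dV, params$epsilon)
  prob <- adoption_probability(dU, global$lam)

  revise <- u_revise < global$nu
  x_new <- ifelse(revise, as.integer(u_adopt < prob), state$x)
  subsidy_pending <- state$subsidy_pending & x_new == 0L

  p_new <- mean(x_new)
  a <- learning_rate(global$a0, params$a1, p_t)
  b_new <- update_benefit(state$b, x_new, a, global$c, global$b_min, global$b_max)
  y_new <- update_attitude(state$y, x_new, p_new, ybar_t, params,
                           intervention, global$s)

  population$state <- data.frame(x = as.integer(x_new), y = y_new, b = b_new,
                                 subsidy_pending = subsidy_pending)
  population
}

state_summary <- function(state) {
  adopt <- state$x == 1L
  c(p = mean(state$x),
    y_bar = mean(state$y),
    mean_y_adopters = if (any(adopt)) mean(state$y[adopt]) else NA_real_,
    mean_y_nonadopters = if (any(!adopt)) mean(state$y[!adopt]) else NA_real_,
    mean_b = mean(state$b))
}

#' Simulate an adoption trajectory
#'
#' Generates a population from `config` (unless one is supplied), applies
#' the training intervention, and advances the model `T` steps, recording
#' the adopter frequency, the mean attitudes of adopters and non-adopters,
#' and the mean benefit at every step.
#'
#' Model variants: `"fixed_attitudes"` freezes attitudes (`s = 0`);
#' `"no_attitudes"` additionally removes every attitude-coupled force
#' (`v = k2 = alpha = beta2 = 0` for all agents, without renormalising the
#' remaining weights). See [model_variant()].
#'
#' @param config An [adoption_config()] object.
#' @param T Number of steps (>= 1).
#' @param seed Optional integer seed making the whole run (population and
#'   dynamics) reproducible.
#' @param population Optional pre-built `adoption_population`; when given,
#'   population synthesis and training are skipped.
#' @param init Optional list with any of `x`, `y`, `b`, `subsidy_pending`
#'   overriding the initial state (used e.g. to start at an analytic
#'   equilibrium).
#' @param variant One of `"full"`, `"fixed_attitudes"`, `"no_attitudes"`.
#' @return An object of class `adoption_sim`: a list with `trajectory`
#'   (data frame with columns `t, p, y_bar, mean_y_adopters,
#'   mean_y_nonadopters, mean_b`, rows `t = 0..T`), `population` (final
#'   state), `config`, `variant`, `seed` and `T`.
#' @examples
#' cfg <- adoption_config(global = global_params(N = 100))
#' sim <- simulate_adoption(cfg, T = 50, seed = 1)
#' sim
#' @export
simulate_adoption <- function(config, T = 100, seed = NULL,
                              population = NULL, init = NULL,
                              variant = c("full", "fixed_attitudes",
                                          "no_attitudes")) {
  stopifnot(inherits(config, "adoption_config"))
  variant <- match.arg(variant)
  if (T < 1) stop("'T' must be >= 1", call. = FALSE)
  local_seed(seed)

  config <- model_variant(config, variant)
  if (is.null(population)) {
    population <- generate_population(config$population, config$global)
    if (config$intervention$p0 > 0)
      population <- apply_training(population, config$intervention$p0,
                                   config$global)
  }
  population <- apply_variant_population(population, variant)
  if (!is.null(init)) {
    for (f in intersect(names(init), c("x", "y", "b", "subsidy_pending"))) {
      stopifnot(length(init[[f]]) %in% c(1L, nrow(population$state)))
      population$state[[f]] <- init[[f]]
    }
    population$state$x <- as.integer(population$state$x)
  }

  traj <- matrix(NA_real_, nrow = T + 1L, ncol = 5L)
  traj[1L, ] <- state_summary(population$state)
  for (t in seq_len(T)) {
    population <- step_population(population, config$global,
                                  config$intervention, t = t - 1L)
    traj[t + 1L, ] <- state_summary(population$state)
  }
  trajectory <- data.frame(t = 0:T, traj)
  names(trajectory) <- c("t", "p", "y_bar", "mean_y_adopters",
                         "mean_y_nonadopters", "mean_b")
  structure(list(trajectory = trajectory, population = population,
                 config = config, variant = variant, seed = seed, T = T),
            class = "adoption_sim")
}

#' @export
print.adoption_sim <- function(x, ...) {
  final <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("Adoption simulation: N = %d agents, T = %d steps%s\n",
              x$config$global$N, x$T,
              if (x$variant != "full") paste0(" (variant: ", x$variant, ")") else ""))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  final adopter frequency p = %.3f\n", final$p))
  cat(sprintf("  final mean attitude      = %.3f\n", final$y_bar))
  cat(sprintf("  final mean benefit       = %.3f\n", final$mean_b))
  invisible(x)
}

#' @export
summary.adoption_sim <- function(object, ...) {
  tr <- object$trajectory
  final <- tr[nrow(tr), ]
  half <- tr$t[which(tr$p >= 0.5)[1L]]
  out <- list(N = object$config$global$N, T = object$T,
              variant = object$variant, seed = object$seed,
              p_final = final$p, y_bar_final = final$y_bar,
              mean_b_final = final$mean_b,
              y_adopters_final = final$mean_y_adopters,
              y_nonadopters_final = final$mean_y_nonadopters,
              attitude_gap_final = final$mean_y_adopters - final$mean_y_nonadopters,
              t_half = if (is.na(half)) NA_integer_ else half)
  class(out) <- "summary.adoption_sim"
  out
}

#' @export
print.summary.adoption_sim <- function(x, ...) {
  cat(sprintf("Adoption simulation summary (N = %d, T = %d, variant = %s)\n",
              x$N, x$T, x$variant))
  cat(sprintf("  p(T) = %.4f   ybar(T) = %.4f   mean b(T) = %.4f\n",
              x$p_final, x$y_bar_final, x$mean_b_final))
  if (!is.na(x$attitude_gap_final))
    cat(sprintf("  attitudes at T: adopters %.4f, non-adopters %.4f (gap %.4f)\n",
                x$y_adopters_final, x$y_nonadopters_final, x$attitude_gap_final))
  if (!is.na(x$t_half)) cat(sprintf("  first step with p >= 1/2: t = %d\n", x$t_half))
  invisible(x)
}

#' Plot an adoption trajectory
#'
#' Adopter frequency and class-wise mean attitudes against time.
#'
#' @param x An `adoption_sim` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.adoption_sim <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$t, tr$p, type = "l", ylim = c(0, 1), lwd = 2,
                 xlab = "time step", ylab = "frequency / attitude", ...)
  graphics::lines(tr$t, tr$mean_y_adopters, col = "red")
  graphics::lines(tr$t, tr$mean_y_nonadopters, col = "blue")
  graphics::legend("topleft", bty = "n", lwd = c(2, 1, 1),
                   col = c("black", "red", "blue"),
                   legend = c("adopter frequency p", "mean y, adopters",
                              "mean y, non-adopters"))
  invisible(x)
}

#' @export
as.data.frame.adoption_sim <- function(x, ...) x$trajectory
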