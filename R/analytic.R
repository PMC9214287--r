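#' Equilibrium attitude when the innovation dies out
#'
#' In the symmetric error-free model, at the equilibrium where nobody uses
#' the new technology (`p* = 0`) attitudes do not fall to zero: the
#' authority's message keeps them at `y* = beta3 / (1 - beta2)`. The value
#' increases with both the trust in the authority `beta3` and the strength
#' of attitude exchange among peers `beta2`.
#'
#' @param beta2 Attitude-side weight of conformity with peers' attitudes
#'   (`< 1`).
#' @param beta3 Attitude-side weight of conformity with the authority.
#' @return The limiting attitude `y*`.
#' @examples
#' attitude_at_extinction(0.25, 0.25)  # 1/3
#' @export
attitude_at_extinction <- function(beta2, beta3) {
  if (any(beta2 >= 1)) stop("'beta2' must be < 1", call. = FALSE)
  beta3 / (1 - beta2)
}

#' Sufficient condition for instability of the extinction equilibrium
#'
#' The no-adoption equilibrium is unstable — the new technology gets some
#' use — whenever the perceived material gain from first use plus the
#' authority's pull exceeds the combined opposing normative forces:
#' `dPi(b_min) + epsilon * k3 > epsilon * (v + k1 + k2)` with
#' `dPi(b_min) = (1 - omega) b_min + omega b_max - b0`. The condition is
#' sufficient only: the equilibrium can also be unstable when it fails
#' (it is evaluated at the most hostile attitude `y = 0`).
#'
#' @param pars Named list (or data frame row) with `v, k1, k2, k3, omega,
#'   epsilon` — the shared agent parameters of the symmetric model.
#' @param global A [global_params()] object.
#' @return `TRUE` if the printed inequality holds strictly.
#' @examples
#' pars <- list(v = 0.25, k1 = 0.25, k2 = 0.25, k3 = 0.25,
#'              omega = 0.8, epsilon = 0.5)
#' extinction_unstable(pars, global_params())
#' @export
extinction_unstable <- function(pars, global) {
  dPi_min <- payoff_diff(global$b_min, pars$omega, global$b_max, global$b0)
  dPi_min + pars$epsilon * pars$k3 >
    pars$epsilon * (pars$v + pars$k1 + pars$k2)
}

#' Stationary attitudes along the coexistence line
#'
#' At a heterogeneous equilibrium with adopter frequency `p*`, the attitude
#' update has a unique fixed point per class. Solving the linear system
#' (adopters experience dissonance towards `x = 1`, non-adopters towards
#' `x = 0`, both conform to `p*`, the population mean attitude and the
#' authority) gives
#' `y_n = (beta1 p* + beta2 alpha p* + beta3) / (1 - beta2)` and
#' `y_a = y_n + alpha`: the two classes' attitudes always differ by exactly
#' the dissonance weight `alpha`. With `beta2 = 0` this reduces to
#' `y_a = alpha + (1 - alpha - beta3) p* + beta3`,
#' `y_n = (1 - alpha - beta3) p* + beta3`.
#'
#' @param p_star Equilibrium adopter frequency in `[0, 1]`.
#' @param alpha,beta1,beta2,beta3 Shared attitude-side weights (sum 1,
#'   `beta2 < 1`). `beta1` defaults to `1 - alpha - beta2 - beta3`.
#' @return Named vector `c(y_a, y_n)`.
#' @examples
#' coexistence_attitudes(0.5, alpha = 0.25, beta2 = 0, beta3 = 0.25)
#' @export
coexistence_attitudes <- function(p_star, alpha, beta1 = NULL, beta2 = 0,
                                  beta3 = 0) {
  if (any(p_star < 0 | p_star > 1)) stop("'p_star' must lie in [0, 1]", call. = FALSE)
  if (is.null(beta1)) beta1 <- 1 - alpha - beta2 - beta3
  if (any(beta1 < -1e-12)) stop("weights exceed the simplex", call. = FALSE)
  if (any(beta2 >= 1)) stop("'beta2' must be < 1", call. = FALSE)
  y_n <- (beta1 * p_star + beta2 * alpha * p_star + beta3) / (1 - beta2)
  c(y_a = y_n + alpha, y_n = y_n)
}

# dU of a stationary adopter (b = b_max, y = y_a(p)) and non-adopter
# (b = b_min, y = y_n(p)) in the symmetric model, as functions of p.
coexistence_dU <- function(p, pars, global) {
  ys <- coexistence_attitudes(p, pars$alpha, pars$beta1, pars$beta2, pars$beta3)
  y_bar <- p * ys[["y_a"]] + (1 - p) * ys[["y_n"]]
  dU_a <- payoff_diff(global$b_max, pars$omega, global$b_max, global$b0) +
    pars$epsilon * value_diff(ys[["y_a"]], p, y_bar, pars)
  dU_n <- payoff_diff(global$b_min, pars$omega, global$b_max, global$b0) +
    pars$epsilon * value_diff(ys[["y_n"]], p, y_bar, pars)
  c(dU_a = dU_a, dU_n = dU_n)
}

#' Coexistence band of the symmetric model
#'
#' Heterogeneous (coexistence) equilibria form a line `p_low < p* < p_high`:
#' the set of frequencies at which a stationary adopter (skill `b_max`,
#' attitude `y_a(p)`) weakly prefers the new technology while a stationary
#' non-adopter (skill `b_min`, attitude `y_n(p)`) strictly prefers the old
#' one. Both utility differences are affine in `p` (the stationary
#' attitudes are themselves affine in `p`), so the boundaries are obtained
#' exactly from the two linear conditions; an empty band is possible and is
#' reported as `NULL`.
#'
#' @param pars Named list with the shared weights `v, k1, k2, k3, alpha,
#'   beta1, beta2, beta3` and `omega, epsilon`.
#' @param global A [global_params()] object.
#' @return Named vector `c(p_low, p_high)` (a sub-interval of `[0, 1]`),
#'   or `NULL` when no frequency satisfies both conditions.
#' @examples
#' pars <- list(v = 0.25, k1 = 0.25, k2 = 0.25, k3 = 0.25,
#'              alpha = 0.25, beta1 = 0.25, beta2 = 0.25, beta3 = 0.25,
#'              omega = 0.25, epsilon = 0.5)
#' coexistence_range(pars, global_params(b_max = 2.4, lam = Inf))
#' @export
coexistence_range <- function(pars, global) {
  g0 <- coexistence_dU(0, pars, global)
  g1 <- coexistence_dU(1, pars, global)

  # Affine in p: g(p) = g(0) + (g(1) - g(0)) p. Feasible set:
  # {p : dU_a(p) >= 0} intersect {p : dU_n(p) < 0} intersect [0, 1].
  interval_where <- function(a0, a1, geq) {
    slope <- a1 - a0
    if (abs(slope) < 1e-14) {
      ok <- if (geq) a0 >= 0 else a0 < 0
      return(if (ok) c(0, 1) else NULL)
    }
    root <- -a0 / slope
    if (geq) {
      if (slope > 0) c(max(0, root), 1) else c(0, min(1, root))
    } else {
      if (slope > 0) c(0, min(1, root)) else c(max(0, root), 1)
    }
  }
  ia <- interval_where(g0[["dU_a"]], g1[["dU_a"]], geq = TRUE)
  inn <- interval_where(g0[["dU_n"]], g1[["dU_n"]], geq = FALSE)
  if (is.null(ia) || is.null(inn)) return(NULL)
  lo <- max(ia[1], inn[1])
  hi <- min(ia[2], inn[2])
  if (lo > hi) return(NULL)
  c(p_low = lo, p_high = hi)
}

#' Equilibrium diagnostics for a symmetric configuration
#'
#' Convenience report combining the closed-form results: the extinction
#' attitude, the instability flag, the coexistence band, and (optionally)
#' the stationary class attitudes at a requested `p*`.
#'
#' @param config An [adoption_config()] whose population block carries fixed
#'   `weights` (see [symmetric_config()]).
#' @param p_star Optional frequency at which to report the stationary class
#'   attitudes.
#' @return A list with `y_extinction`, `extinction_unstable`,
#'   `coexistence`, and (if `p_star` given) `attitudes_at_p`.
#' @examples
#' equilibrium_report(symmetric_config(omega = 0.25,
#'   global = global_params(b_max = 2.4, lam = Inf)), p_star = 0.1)
#' @export
equilibrium_report <- function(config, p_star = NULL) {
  stopifnot(inherits(config, "adoption_config"))
  pars <- symmetric_pars(config)
  out <- list(
    y_extinction = attitude_at_extinction(pars$beta2, pars$beta3),
    extinction_unstable = extinction_unstable(pars, config$global),
    coexistence = coexistence_range(pars, config$global))
  if (!is.null(p_star))
    out$attitudes_at_p <- coexistence_attitudes(p_star, pars$alpha,
                                                pars$beta1, pars$beta2,
                                                pars$beta3)
  out
}

# Extract the shared agent parameters of a symmetric configuration.
symmetric_pars <- function(config) {
  w <- config$population$weights
  if (is.null(w))
    stop("analytic results need a symmetric configuration (fixed 'weights'); ",
         "see symmetric_config()", call. = FALSE)
  list(v = w$util[1], k1 = w$util[2], k2 = w$util[3], k3 = w$util[4],
       alpha = w$att[1], beta1 = w$att[2], beta2 = w$att[3], beta3 = w$att[4],
       omega = config$population$omega_mean,
       epsilon = config$population$eps_mean)
}
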