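#' Broken-stick weight samples
#'
#' Breaks the unit interval at `n_parts - 1` uniform points and returns the
#' segment lengths: `n_parts` non-negative weights summing to 1. The law of
#' the spacings is a flat Dirichlet, so each component has marginal mean
#' `1 / n_parts`. The distribution has no free parameters, which is why it
#' is used for the four-way psychological weight vectors.
#'
#' @param n_parts Number of segments (>= 1).
#' @param n Number of independent sticks to draw.
#' @return If `n == 1` a numeric vector of length `n_parts`; otherwise an
#'   `n x n_parts` matrix with one stick per row.
#' @examples
#' set.seed(1)
#' w <- sample_broken_stick(4)
#' sum(w)
#' @export
sample_broken_stick <- function(n_parts, n = 1) {
  if (!is.numeric(n_parts) || length(n_parts) != 1L || is.na(n_parts) || n_parts < 1)
    stop("'n_parts' must be a positive integer", call. = FALSE)
  n_parts <- as.integer(n_parts)
  n <- as.integer(n)
  if (n_parts == 1L) {
    out <- matrix(1, nrow = n, ncol = 1L)
  } else {
    cuts <- matrix(stats::runif(n * (n_parts - 1L)), nrow = n)
    # row-wise sorted cut points, padded with the interval ends
    cuts <- t(apply(cuts, 1L, sort))
    out <- cbind(cuts, 1) - cbind(0, cuts)
  }
  if (n == 1L) drop(out) else out
}

#' Truncated-normal samples
#'
#' Draws from a normal law with the given location and scale restricted to
#' `[lo, hi]`, by inverse-CDF sampling. A zero `sd` gives the degenerate
#' distribution at `mean` clamped into the interval.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal (`sd >= 0`).
#' @param lo,hi Truncation bounds, `lo < hi`.
#' @return Numeric vector of length `n` with all values in `[lo, hi]`.
#' @examples
#' set.seed(1)
#' range(sample_truncated_normal(100, 0.25, 0.1, 0, 1))
#' @export
sample_truncated_normal <- function(n, mean, sd, lo, hi) {
  if (!(lo < hi)) stop("truncation bounds must satisfy lo < hi", call. = FALSE)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)  # guard against round-off at extreme truncation
}

#' Beta shapes from mean and standard deviation
#'
#' Moment-matches a beta distribution: returns the shape pair `(s1, s2)`
#' whose mean and standard deviation equal the inputs,
#' `s1 = m * (m(1-m)/sd^2 - 1)`, `s2 = (1-m) * (m(1-m)/sd^2 - 1)`.
#'
#' @param mean Target mean in `(0, 1)`.
#' @param sd Target standard deviation; must satisfy
#'   `sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_params_from_moments(0.5, 0.2)  # c(2.625, 2.625)
#' @export
beta_params_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1)
    stop("'mean' must lie strictly inside (0, 1)", call. = FALSE)
  if (sd <= 0 || sd^2 >= mean * (1 - mean))
    stop("infeasible beta moments: need 0 < sd^2 < mean * (1 - mean)", call. = FALSE)
  k <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Synthesize a heterogeneous agent population
#'
#' Draws the per-agent parameters and the initial state. Each agent gets two
#' independent four-part broken sticks — the utility-side weights
#' `(v, k1, k2, k3)` and the attitude-side weights
#' `(alpha, beta1, beta2, beta3)` — plus truncated-normal draws of `a1` (on
#' `[0, 1 - a0]`, so the learning rate `a0 + a1 * p` can never exceed 1),
#' `omega` and `epsilon` (both on `[0, 1]`). Initially no one has adopted:
#' every agent starts with action `x = 0`, minimal skill `b = b_min`, a
#' beta-distributed attitude, and an unconsumed subsidy entitlement.
#'
#' If `config$weights` is set, every agent receives those fixed weight
#' vectors instead of broken-stick draws (the symmetric case).
#'
#' @param config A [population_config()] object.
#' @param global A [global_params()] object (supplies `N`, `a0`, `b_min`).
#' @param seed Optional integer seed; defaults to `config$seed`. When
#'   non-`NULL` it seeds the RNG so the draw is reproducible; when `NULL`
#'   the current RNG stream is consumed (useful inside seeded replicates).
#' @return An object of class `adoption_population`: a list with data frames
#'   `params` (columns `v, k1, k2, k3, alpha, beta1, beta2, beta3, a1,
#'   omega, epsilon`) and `state` (columns `x, y, b, subsidy_pending`).
#' @examples
#' pop <- generate_population(population_config(), global_params(N = 50), seed = 1)
#' colMeans(pop$params[, c("v", "k1", "k2", "k3")])
#' @export
generate_population <- function(config, global, seed = NULL) {
  validate_population_config(config)
  validate_global_params(global)
  if (is.null(seed)) seed <- config$seed
  local_seed(seed)
  N <- global$N

  if (is.null(config$weights)) {
    util <- sample_broken_stick(4L, N)
    att <- sample_broken_stick(4L, N)
  } else {
    util <- matrix(config$weights$util, nrow = N, ncol = 4L, byrow = TRUE)
    att <- matrix(config$weights$att, nrow = N, ncol = 4L, byrow = TRUE)
  }
  a1 <- sample_truncated_normal(N, config$a1_mean, config$a1_sd, 0, 1 - global$a0)
  omega <- sample_truncated_normal(N, config$omega_mean, config$omega_sd, 0, 1)
  epsilon <- sample_truncated_normal(N, config$eps_mean, config$eps_sd, 0, 1)
  if (config$y0_sd == 0) {
    y0 <- rep(config$y0_mean, N)
  } else {
    sh <- beta_params_from_moments(config$y0_mean, config$y0_sd)
    y0 <- stats::rbeta(N, sh[["shape1"]], sh[["shape2"]])
  }

  params <- data.frame(v = util[, 1L], k1 = util[, 2L], k2 = util[, 3L], k3 = util[, 4L],
                       alpha = att[, 1L], beta1 = att[, 2L], beta2 = att[, 3L],
                       beta3 = att[, 4L],
                       a1 = a1, omega = omega, epsilon = epsilon)
  state <- data.frame(x = integer(N), y = y0, b = rep(global$b_min, N),
                      subsidy_pending = rep(TRUE, N))
  structure(list(params = params, state = state), class = "adoption_population")
}

#' Train a random fraction of the population
#'
#' Implements the training intervention: a uniformly chosen subset of
#' `round(p0 * N)` agents starts out fully skilled (`b = b_max`), using the
#' new technology (`x = 1`) and maximally convinced (`y = 1`). Trained
#' agents count as adopters from the start, so they carry no pending
#' subsidy. All other agents are untouched.
#'
#' @param population An `adoption_population` object.
#' @param p0 Fraction to train, in `[0, 1]`.
#' @param global A [global_params()] object (supplies `b_max`).
#' @return The modified `adoption_population`.
#' @examples
#' pop <- generate_population(population_config(), global_params(N = 50), seed = 1)
#' pop <- apply_training(pop, 0.1, global_params(N = 50))
#' sum(pop$state$x)  # 5 trained adopters
#' @export
apply_training <- function(population, p0, global) {
  stopifnot(inherits(population, "adoption_population"))
  if (p0 < 0 || p0 > 1) stop("'p0' must lie in [0, 1]", call. = FALSE)
  N <- nrow(population$state)
  n_train <- round(p0 * N)
  if (n_train == 0) return(population)
  idx <- sample.int(N, n_train)
  population$state$x[idx] <- 1L
  population$state$y[idx] <- 1
  population$state$b[idx] <- global$b_max
  population$state$subsidy_pending[idx] <- FALSE
  population
}

#' @export
print.adoption_population <- function(x, ...) {
  N <- nrow(x$params)
  cat(sprintf("Agent population: %d agents\n", N))
  cat(sprintf("  adopters at t: %d (p = %.3f); mean attitude %.3f; mean skill %.3f\n",
              sum(x$state$x), mean(x$state$x), mean(x$state$y), mean(x$state$b)))
  invisible(x)
}

#' Write or read an agent population as CSV
#'
#' Plain-text round trip of a population (one row per agent; columns
#' `v, k1, k2, k3, alpha, beta1, beta2, beta3, a1, omega, epsilon, x0, y0,
#' b0_skill`), used for regression fixtures and provenance.
#'
#' @param population An `adoption_population` object.
#' @param path File path.
#' @return `write_population_csv()` returns `path` invisibly;
#'   `read_population_csv()` returns an `adoption_population`.
#' @export
write_population_csv <- function(population, path) {
  stopifnot(inherits(population, "adoption_population"))
  df <- cbind(population$params,
              x0 = population$state$x, y0 = population$state$y,
              b0_skill = population$state$b)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  par_cols <- c("v", "k1", "k2", "k3", "alpha", "beta1", "beta2", "beta3",
                "a1", "omega", "epsilon")
  missing <- setdiff(c(par_cols, "x0", "y0", "b0_skill"), names(df))
  if (length(missing))
    stop("population file lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  structure(list(params = df[par_cols],
                 state = data.frame(x = as.integer(df$x0), y = df$y0,
                                    b = df$b0_skill,
                                    subsidy_pending = df$x0 == 0)),
            class = "adoption_population")
}
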