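# Scalar, loop-based reference implementation of one model step, written
# directly from the update equations term by term. Deliberately independent
# of the vectorised production code: plain arithmetic, one agent at a time.
oracle_step <- function(params, state, global, intervention, t,
                        u_revise, u_adopt) {
  N <- nrow(params)
  p_t <- sum(state$x) / N
  ybar_t <- sum(state$y) / N

  x_new <- state$x
  pend <- state$subsidy_pending
  for (i in seq_len(N)) {
    if (u_revise[i] < global$nu) {
      bonus <- if (state$subsidy_pending[i] && t < intervention$subsidy_window)
        intervention$b_s else 0
      dPi <- (1 - params$omega[i]) * state$b[i] +
        params$omega[i] * global$b_max + bonus - global$b0
      dV <- intervention$f0 * params$v[i] * (2 * state$y[i] - 1) +
        intervention$f1 * params$k1[i] * (2 * p_t - 1) +
        intervention$f2 * params$k2[i] * (2 * ybar_t - 1) +
        intervention$f3 * params$k3[i]
      dU <- dPi + params$epsilon[i] * dV
      pr <- if (is.infinite(global$lam)) {
        if (dU >= 0) 1 else 0
      } else if (global$lam == 0) 0.5 else 1 / (1 + exp(-global$lam * dU))
      x_new[i] <- if (u_adopt[i] < pr) 1L else 0L
    }
    if (x_new[i] == 1L) pend[i] <- FALSE
  }

  p_new <- sum(x_new) / N
  b_new <- numeric(N)
  y_new <- numeric(N)
  for (i in seq_len(N)) {
    a <- global$a0 + params$a1[i] * p_t
    b_new[i] <- if (x_new[i] == 1L)
      state$b[i] + a * (global$b_max - state$b[i])
    else
      state$b[i] - global$c * (state$b[i] - global$b_min)
    dy <- intervention$f0 * params$alpha[i] * (x_new[i] - state$y[i]) +
      intervention$f1 * params$beta1[i] * (p_new - state$y[i]) +
      intervention$f2 * params$beta2[i] * (ybar_t - state$y[i]) +
      intervention$f3 * params$beta3[i] * (1 - state$y[i])
    y_new[i] <- min(max(state$y[i] + global$s * dy, 0), 1)
  }
  data.frame(x = x_new, y = y_new, b = b_new, subsidy_pending = pend)
}

# Random small population for oracle comparisons.
random_small_population <- function(N, global) {
  util <- sample_broken_stick(4L, N)
  att <- sample_broken_stick(4L, N)
  params <- data.frame(v = util[, 1], k1 = util[, 2], k2 = util[, 3],
                       k3 = util[, 4], alpha = att[, 1], beta1 = att[, 2],
                       beta2 = att[, 3], beta3 = att[, 4],
                       a1 = runif(N, 0, 1 - global$a0),
                       omega = runif(N), epsilon = runif(N))
  state <- data.frame(x = sample(0:1, N, replace = TRUE), y = runif(N),
                      b = runif(N, global$b_min, global$b_max),
                      subsidy_pending = FALSE)
  state$subsidy_pending <- state$x == 0L
  structure(list(params = params, state = state),
            class = "adoption_population")
}
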