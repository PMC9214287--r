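test_that("primitive update formulas match hand arithmetic", {
  # learning rate
  expect_equal(learning_rate(0.05, 0.05, 0), 0.05)
  expect_equal(learning_rate(0.05, 0.05, 1), 0.10)
  expect_equal(learning_rate(0, 0, 0.7), 0)
  # benefit fixed points and direct substitution
  expect_equal(update_benefit(1.5, 1, 0.1, 0.1, 0.5, 1.5), 1.5)
  expect_equal(update_benefit(0.5, 0, 0.1, 0.1, 0.5, 1.5), 0.5)
  expect_equal(update_benefit(0.5, 1, 0.1, 0.1, 0.5, 1.5), 0.6)
  # pay-off difference
  expect_equal(payoff_diff(1, 0, 1.5, 1), 0)
  expect_equal(payoff_diff(0.7, 1, 1.5, 1), 0.5)
  expect_equal(payoff_diff(0.5, 0.25, 1.5, 1), -0.25)
  # value difference
  w <- list(v = 0.25, k1 = 0.25, k2 = 0.25, k3 = 0.25)
  expect_equal(value_diff(0.5, 0.5, 0.5, w), 0.25)  # symmetry leaves only k3
  off <- intervention_config(f0 = 0, f1 = 0, f2 = 0, f3 = 0)
  expect_equal(value_diff(0.9, 0.2, 0.4, w, off), 0)
  expect_equal(value_diff(1, 1, 1, w), 1)           # simplex sum
  # utility difference
  expect_equal(utility_diff(-0.3, 0.9, 0), -0.3)
  expect_equal(utility_diff(-0.125, 0.25, 0.5), 0)
})

test_that("logit choice covers the random, tied and deterministic regimes", {
  expect_equal(adoption_probability(c(-5, 0, 3), 0), rep(0.5, 3))
  expect_equal(adoption_probability(0, 15), 0.5)
  expect_equal(adoption_probability(c(-1, 0, 1e-9), Inf), c(0, 1, 1))
  # non-decreasing in dU and pointwise convergence to the threshold rule
  # (away from the discontinuity at dU = 0)
  dU <- setdiff(seq(-0.5, 0.5, length.out = 101), 0)
  for (lam in c(0, 1, 15, 200)) {
    pr <- adoption_probability(dU, lam)
    expect_true(all(diff(pr) >= 0))
  }
  expect_equal(adoption_probability(dU, 1e4), as.numeric(dU >= 0),
               tolerance = 1e-3)
})

test_that("attitude update obeys its fixed points, arithmetic and clipping", {
  w <- list(alpha = 0.25, beta1 = 0.25, beta2 = 0.25, beta3 = 0.25)
  expect_equal(update_attitude(0.3, 1, 0.2, 0.6, w, s = 0), 0.3)
  expect_equal(update_attitude(1, 1, 1, 1, w, s = 0.1), 1)
  # only the authority term active: s * beta3 * (1 - y) = 0.1 * 0.25
  expect_equal(update_attitude(0, 0, 0, 0, w, s = 0.1), 0.025)
  # with all factors <= 1 the update is already inside [0, 1]
  set.seed(13)
  for (i in 1:50) {
    att <- sample_broken_stick(4)
    wi <- list(alpha = att[1], beta1 = att[2], beta2 = att[3], beta3 = att[4])
    y <- runif(1); x <- sample(0:1, 1); p <- runif(1); yb <- runif(1)
    raw <- y + 1 * (wi$alpha * (x - y) + wi$beta1 * (p - y) +
                      wi$beta2 * (yb - y) + wi$beta3 * (1 - y))
    expect_true(raw >= 0 && raw <= 1)
    expect_equal(update_attitude(y, x, p, yb, wi, s = 1), raw)
  }
  # an amplified authority factor overshoots and is clipped
  boost <- intervention_config(f3 = 8)
  expect_equal(update_attitude(0.95, 1, 1, 1, w, boost, s = 1), 1)
})

test_that("continuous use follows the closed-form learning curve exactly", {
  a <- 0.07; b_max <- 1.5; b0_skill <- 0.5
  b <- b0_skill
  for (t in 1:60) {
    b <- update_benefit(b, 1, a, 0.1, 0.5, b_max)
    expect_equal(b, b_max - (1 - a)^t * (b_max - b0_skill), tolerance = 1e-12)
  }
})

test_that("a step with nu = 0 freezes actions but not benefits and attitudes", {
  gp <- global_params(N = 40, nu = 0)
  pop <- generate_population(population_config(), gp, seed = 4)
  pop$state$b <- runif(40, gp$b_min, gp$b_max)
  out <- step_population(pop, gp, t = 0)
  expect_identical(out$state$x, pop$state$x)
  expect_false(all(out$state$b == pop$state$b))
  expect_false(all(out$state$y == pop$state$y))
})

test_that("the full-adoption consensus state is absorbing", {
  gp <- global_params(N = 30, lam = Inf)
  pop <- generate_population(population_config(), gp, seed = 6)
  pop$state$x <- rep(1L, 30)
  pop$state$y <- rep(1, 30)
  pop$state$b <- rep(gp$b_max, 30)
  pop$state$subsidy_pending <- rep(FALSE, 30)
  out <- pop
  for (t in 0:4) out <- step_population(out, gp, t = t)
  expect_identical(out$state, pop$state)
})

test_that("state bounds hold along heterogeneous trajectories", {
  cfg <- adoption_config(global = global_params(N = 80),
                         intervention = intervention_config(p0 = 0.05,
                                                            b_s = 0.5))
  sim <- simulate_adoption(cfg, T = 60, seed = 8)
  st <- sim$population$state
  expect_true(all(st$x %in% c(0L, 1L)))
  expect_true(all(st$y >= 0 & st$y <= 1))
  expect_true(all(st$b >= cfg$global$b_min & st$b <= cfg$global$b_max))
  tr <- sim$trajectory
  expect_equal(tr$p[nrow(tr)], mean(st$x))
  expect_equal(tr$y_bar[nrow(tr)], mean(st$y))
})

test_that("purely material agents never adopt without foresight or subsidy", {
  # epsilon = 0, nu = 1, lam = Inf, omega = 0: dU = b - b0 <= b_min - b0 < 0
  cfg <- adoption_config(
    global = global_params(N = 60, nu = 1, lam = Inf),
    population = population_config(eps_mean = 0, eps_sd = 0,
                                   omega_mean = 0, omega_sd = 0))
  sim <- simulate_adoption(cfg, T = 30, seed = 10)
  expect_true(all(sim$trajectory$p == 0))
})

test_that("the vectorised step agrees with the scalar oracle", {
  set.seed(99)
  for (i in 1:100) {
    N <- sample(2:10, 1)
    gp <- global_params(N = N,
                        b_min = 0.5, b0 = 1, b_max = runif(1, 1, 2.5),
                        nu = runif(1), lam = sample(c(0, 1, 15, Inf), 1))
    ic <- intervention_config(b_s = runif(1, 0, 0.5),
                              subsidy_window = sample(0:5, 1),
                              f0 = runif(1, 0, 2), f1 = runif(1, 0, 2),
                              f2 = runif(1, 0, 2), f3 = runif(1, 0, 2))
    pop <- random_small_population(N, gp)
    t <- sample(0:6, 1)
    u_rev <- runif(N); u_ad <- runif(N)
    prod <- step_population(pop, gp, ic, t, u_revise = u_rev, u_adopt = u_ad)
    ref <- oracle_step(pop$params, pop$state, gp, ic, t, u_rev, u_ad)
    expect_equal(prod$state$x, ref$x)
    expect_equal(prod$state$y, ref$y, tolerance = 1e-12)
    expect_equal(prod$state$b, ref$b, tolerance = 1e-12)
    expect_identical(prod$state$subsidy_pending, ref$subsidy_pending)
  }
})

test_that("simulations are reproducible from their seed", {
  cfg <- adoption_config(global = global_params(N = 60))
  a <- simulate_adoption(cfg, T = 40, seed = 123)
  b <- simulate_adoption(cfg, T = 40, seed = 123)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$population, b$population)
  # T = 1 equals a single step at the same seed
  set.seed(123)
  pop <- generate_population(cfg$population, cfg$global)
  one <- step_population(pop, cfg$global, cfg$intervention, t = 0)
  c1 <- simulate_adoption(cfg, T = 1, seed = 123)
  expect_equal(c1$population$state, one$state)
})

test_that("subsidised first adoption consumes the entitlement", {
  gp <- global_params(N = 20, nu = 1, lam = Inf)
  pop <- generate_population(population_config(omega_mean = 0, omega_sd = 0),
                             gp, seed = 15)
  ic <- intervention_config(b_s = 5, subsidy_window = 3)  # irresistible
  out <- step_population(pop, gp, ic, t = 0)
  expect_true(all(out$state$x == 1L))
  expect_true(all(!out$state$subsidy_pending))
  # outside the window the bonus is gone: nobody adopts on material grounds
  out2 <- step_population(pop, gp, ic, t = 3)
  expect_true(all(out2$state$x == 0L))
})
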