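test_that("extinction attitude matches the closed form and the iterated update", {
  expect_equal(attitude_at_extinction(0.25, 0), 0)
  expect_equal(attitude_at_extinction(0, 0.25), 0.25)
  expect_equal(attitude_at_extinction(0.25, 0.25), 1 / 3)
  expect_error(attitude_at_extinction(1, 0.2), "beta2")
  # fixed point of the attitude recursion with x = p = 0 and ybar = y
  set.seed(17)
  for (i in 1:10) {
    att <- sample_broken_stick(4)
    w <- list(alpha = att[1], beta1 = att[2], beta2 = att[3], beta3 = att[4])
    y <- runif(1)
    for (t in 1:4000) y <- update_attitude(y, 0, 0, y, w, s = 0.1)
    expect_equal(y, attitude_at_extinction(w$beta2, w$beta3), tolerance = 1e-10)
  }
})

test_that("the instability condition reproduces its boundary cases", {
  gp_eq <- global_params(b_min = 1, b0 = 1, b_max = 1.5)
  base <- list(v = 0.25, k1 = 0.25, k2 = 0.25, k3 = 0.25, epsilon = 0)
  # all terms zero: the strict inequality fails at the boundary
  expect_false(extinction_unstable(c(base, omega = 0), gp_eq))
  # pure material gain with full foresight
  expect_true(extinction_unstable(c(base, omega = 1), global_params()))
  # symmetric baseline flips exactly at omega = 0.75
  gp <- global_params(b_min = 0.5, b0 = 1, b_max = 1.5)
  pars <- function(om) list(v = 0.25, k1 = 0.25, k2 = 0.25, k3 = 0.25,
                            omega = om, epsilon = 0.5)
  expect_false(extinction_unstable(pars(0.75 - 1e-9), gp))
  expect_false(extinction_unstable(pars(0.75), gp))  # strict inequality
  expect_true(extinction_unstable(pars(0.75 + 1e-9), gp))
})

test_that("coexistence attitudes keep a gap of exactly alpha", {
  expect_equal(coexistence_attitudes(0, alpha = 0.25, beta2 = 0, beta3 = 0.25),
               c(y_a = 0.5, y_n = 0.25))
  expect_equal(coexistence_attitudes(1, alpha = 0.25, beta2 = 0, beta3 = 0.25),
               c(y_a = 1, y_n = 0.75))
  expect_equal(coexistence_attitudes(0.5, alpha = 0.25, beta2 = 0, beta3 = 0.25),
               c(y_a = 0.75, y_n = 0.5))
  set.seed(23)
  for (i in 1:25) {
    att <- sample_broken_stick(4)
    p <- runif(1)
    ys <- coexistence_attitudes(p, att[1], att[2], att[3], att[4])
    expect_equal(ys[["y_a"]] - ys[["y_n"]], att[1], tolerance = 1e-12)
    expect_true(all(ys >= 0 & ys <= 1 + 1e-12))
    # each class attitude is stationary under the update it experiences
    ybar <- p * ys[["y_a"]] + (1 - p) * ys[["y_n"]]
    w <- list(alpha = att[1], beta1 = att[2], beta2 = att[3], beta3 = att[4])
    expect_equal(update_attitude(ys[["y_a"]], 1, p, ybar, w, s = 0.1),
                 ys[["y_a"]], tolerance = 1e-12)
    expect_equal(update_attitude(ys[["y_n"]], 0, p, ybar, w, s = 0.1),
                 ys[["y_n"]], tolerance = 1e-12)
  }
})

sym_pars <- function(omega, epsilon = 0.5)
  list(v = 0.25, k1 = 0.25, k2 = 0.25, k3 = 0.25,
       alpha = 0.25, beta1 = 0.25, beta2 = 0.25, beta3 = 0.25,
       omega = omega, epsilon = epsilon)

test_that("without normative forces the coexistence band degenerates", {
  # epsilon = 0: both utility conditions are independent of p, and with
  # dPi(b_max), dPi(b_min) of the same sign no band can exist
  gp <- global_params(b_min = 0.5, b0 = 1, b_max = 1.5)
  expect_null(coexistence_range(sym_pars(1, epsilon = 0), gp))  # both gains > 0
  gp2 <- global_params(b_min = 1, b0 = 1, b_max = 1)
  expect_null(coexistence_range(sym_pars(0, epsilon = 0), gp2)) # exact parity
})

test_that("interior band endpoints solve the defining utility equalities", {
  gp <- global_params(b_min = 0.5, b0 = 1, b_max = 1.02, lam = Inf)
  pars <- sym_pars(0.25)
  band <- coexistence_range(pars, gp)
  expect_false(is.null(band))
  expect_true(band[["p_low"]] > 0 && band[["p_high"]] < 1)
  dU_lo <- techadopt:::coexistence_dU(band[["p_low"]], pars, gp)
  dU_hi <- techadopt:::coexistence_dU(band[["p_high"]], pars, gp)
  expect_equal(dU_lo[["dU_a"]], 0, tolerance = 1e-10)
  expect_equal(dU_hi[["dU_n"]], 0, tolerance = 1e-10)
})

test_that("an analytic coexistence point is stationary under simulation", {
  gp <- global_params(b_max = 2.4, lam = Inf, N = 200)
  cfg <- symmetric_config(omega = 0.25,
                          global = gp)
  band <- equilibrium_report(cfg)$coexistence
  expect_false(is.null(band))
  n_a <- round(mean(band) * gp$N)
  p_star <- n_a / gp$N
  ys <- coexistence_attitudes(p_star, 0.25, 0.25, 0.25, 0.25)
  init <- list(x = rep(c(1L, 0L), c(n_a, gp$N - n_a)),
               y = rep(c(ys[["y_a"]], ys[["y_n"]]), c(n_a, gp$N - n_a)),
               b = rep(c(gp$b_max, gp$b_min), c(n_a, gp$N - n_a)),
               subsidy_pending = rep(FALSE, gp$N))
  sim <- simulate_adoption(cfg, T = 50, seed = 19, init = init)
  expect_true(all(sim$trajectory$p == p_star))
  final <- sim$trajectory[nrow(sim$trajectory), ]
  expect_equal(final$mean_y_adopters, ys[["y_a"]], tolerance = 1e-10)
  expect_equal(final$mean_y_nonadopters, ys[["y_n"]], tolerance = 1e-10)
})

test_that("full adoption is locally attracting under attitude perturbations", {
  gp <- global_params(b_max = 2.4, lam = Inf, N = 150)
  cfg <- symmetric_config(omega = 0.25, global = gp)
  set.seed(29)
  init <- list(x = rep(1L, gp$N), y = pmin(pmax(1 - runif(gp$N, 0, 0.05), 0), 1),
               b = rep(gp$b_max, gp$N), subsidy_pending = rep(FALSE, gp$N))
  sim <- simulate_adoption(cfg, T = 300, seed = 31, init = init)
  expect_true(all(sim$trajectory$p == 1))
  expect_equal(sim$population$state$y, rep(1, gp$N), tolerance = 1e-6)
})

test_that("wherever the sufficient condition holds, p leaves zero", {
  gp <- global_params(b_max = 1.5, lam = Inf, N = 200)
  set.seed(37)
  for (om in c(0.8, 0.9)) {
    pars <- sym_pars(om)
    expect_true(extinction_unstable(pars, gp))
    cfg <- symmetric_config(omega = om, y0_mean = 1 / 3, y0_sd = 0, global = gp)
    sim <- simulate_adoption(cfg, T = 30, seed = om * 100)
    expect_gt(max(sim$trajectory$p), 0)
  }
})

test_that("equilibrium_report needs a symmetric configuration", {
  expect_error(equilibrium_report(adoption_config()), "symmetric")
})
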