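# Analytic coexistence theory and the numeric root-finding oracle.

sp <- function(eta = 0.005, alpha = 1e-4, kappa = 1e-2, b = 100, r = 1, ...) {
  single_spacer_params(f0 = 1, r = r, K = 1e5, kappa = kappa, g = 1e-5,
                       eta = eta, alpha = alpha, mu = 1, b = b, ...)
}

test_that("unused capacity formula matches hand-evaluated values", {
  # alpha = 0, eta = 0: the (b(1-alpha)-1)/(b-1) factor collapses to 1
  expect_equal(unused_capacity_single(sp(eta = 0, alpha = 0)), 0.01)
  # no spacer loss: bacteria reach capacity
  expect_equal(unused_capacity_single(sp(kappa = 0)), 0)
  # generic point: 0.01 * 98.99 / (99 * 0.5)
  expect_equal(unused_capacity_single(sp()),
               0.01 * (100 * (1 - 1e-4) - 1) / (99 * 0.5))
  expect_equal(unused_capacity_single(sp()), 0.0199979798, tolerance = 1e-8)
  expect_error(unused_capacity_single(sp(r = 1.1)), "steady_state_numeric")
  expect_error(unused_capacity_single(sp(eta = 0.02)), "1 - b\\*eta")
})

test_that("unused capacity grows with eta and falls linearly with alpha", {
  etas <- seq(0, 0.009, by = 0.001)
  Fs <- vapply(etas, function(e) unused_capacity_single(sp(eta = e)),
               numeric(1))
  expect_true(all(diff(Fs) > 0))
  # divergence approaching the critical failure probability 1/b
  expect_gt(unused_capacity_single(sp(eta = 0.01 * (1 - 1e-6))), 1e3)
  alphas <- c(0, 1e-3, 1e-2, 0.1)
  Fa <- vapply(alphas, function(a) unused_capacity_single(sp(alpha = a)),
               numeric(1))
  expect_true(all(diff(Fa) < 0))
  # linear: second differences vanish on an equispaced alpha grid
  Fl <- vapply(seq(0, 0.3, by = 0.1),
               function(a) unused_capacity_single(sp(alpha = a)), numeric(1))
  expect_equal(diff(Fl, differences = 2), rep(0, 2), tolerance = 1e-12)
})

test_that("critical failure probability matches its closed form", {
  expect_equal(critical_failure_probability(sp(kappa = 0)), 0.01)
  expect_equal(critical_failure_probability(sp(alpha = 0)),
               0.01 * (1 - 0.01 * 99 / 99))
  expect_equal(critical_failure_probability(sp(alpha = 0)), 0.0099)
  # any spacer loss pushes the critical value below 1/b
  expect_lt(critical_failure_probability(sp()), 1 / 100)
})

test_that("spacer to wild-type ratio is growth-rate independent", {
  expect_equal(spacer_ratio_single(sp(eta = 0, alpha = 0)), 99)
  expect_equal(spacer_ratio_single(sp()), 98.99 / 0.5)
  for (r in c(0.5, 1, 2))
    expect_identical(spacer_ratio_single(sp(r = r)), spacer_ratio_single(sp()))
  expect_error(spacer_ratio_single(sp(eta = 0.02)), "1 - b\\*eta")
})

test_that("mean failure probability is the abundance-weighted mean", {
  expect_equal(mean_failure_probability(rep(3, 4), c(0.1, 0.2, 0.3, 0.4)),
               0.25)
  expect_equal(mean_failure_probability(c(0, 0, 7), c(0.1, 0.2, 0.3)), 0.3)
  expect_equal(mean_failure_probability(c(1, 3), c(0, 0.01)), 0.0075)
  expect_error(mean_failure_probability(c(0, 0), c(0.1, 0.2)), "undefined")
  ev <- runif(5)
  m <- mean_failure_probability(runif(5), ev)
  expect_gte(m, min(ev)); expect_lte(m, max(ev))
})

test_that("multi-spacer unused capacity agrees with the single-spacer form", {
  mp <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
                            alpha_vec = rep(0.0972 / 20, 20),
                            eta_vec = rep(0.005, 20))
  p1 <- sp(eta = 0.005, alpha = 0.0972)
  expect_equal(unused_capacity_multi(0.005, mp), unused_capacity_single(p1))
  expect_equal(unused_capacity_multi(0, mp),
               0.01 * (100 * (1 - 0.0972) - 1) / 99)
  mp0 <- multi_spacer_params(K = 1e5, kappa = 0, g = 1e-4, b = 100,
                             alpha_vec = rep(0.0972 / 20, 20),
                             eta_vec = rep(0.005, 20))
  expect_equal(unused_capacity_multi(0.005, mp0), 0)
  expect_error(unused_capacity_multi(0.02, mp), "eta_bar")
})

test_that("coexistence solve is self-consistent and kills the full RHS", {
  for (mode in c("effectiveness_varying", "correlated", "anticorrelated")) {
    p <- multi_spacer_scenario(mode)$params
    sol <- solve_coexistence_multi(p)
    expect_true(sol$valid)
    # the solved mean failure probability reproduces itself from the
    # abundances it implies
    expect_lt(abs(mean_failure_probability(sol$n_vec_star, p$eta_vec) -
                    sol$eta_bar), 1e-10)
    # total abundance ratio (third steady-state relation)
    expect_lt(abs(sum(sol$n_vec_star) / sol$n0_star -
                    (p$b * (1 - sum(p$alpha_vec)) - 1) /
                    (1 - p$b * sol$eta_bar)), 1e-10 * 1e2)
    expect_lt(sol$residual_norm, 1e-8 * p$K)
    expect_equal(sol$n_total, p$K * (1 - sol$F))
    # phage pressure relation g v = b f F
    expect_equal(p$g * sol$v_star, p$b * p$f * sol$F)
  }
})

test_that("identical failure probabilities give abundances proportional to alpha", {
  av <- c(0.01, 0.03, 0.002, 0.05)
  p <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
                           alpha_vec = av, eta_vec = rep(0.004, 4))
  sol <- solve_coexistence_multi(p)
  expect_true(sol$valid)
  expect_equal(sol$eta_bar, 0.004)
  expect_equal(sol$n_vec_star / sum(sol$n_vec_star), av / sum(av))
  # fully symmetric spacers: uniform distribution
  ps <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
                            alpha_vec = rep(0.02, 5),
                            eta_vec = rep(0.003, 5))
  sols <- solve_coexistence_multi(ps)
  expect_equal(unname(as.numeric(spacer_fractions(sols))), rep(0.2, 5))
})

test_that("coexistence requires spacer loss", {
  p <- multi_spacer_params(K = 1e5, kappa = 0, g = 1e-4, b = 100,
                           alpha_vec = rep(0.001, 3),
                           eta_vec = c(0.001, 0.002, 0.003))
  expect_error(solve_coexistence_multi(p), "spacer loss")
})

test_that("an unattainable coexistence point is flagged, not thrown", {
  # eta so large that 1 - b*eta_bar <= 0 for every candidate mean
  p <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
                           alpha_vec = c(0.01, 0.01),
                           eta_vec = c(0.05, 0.08))
  sol <- solve_coexistence_multi(p)
  expect_false(sol$valid)
  expect_true(is.na(sol$n_total))
})

test_that("numeric root finder reproduces the analytic coexistence state", {
  p <- sp()  # r = 1 coexistence parameters
  sol <- solve_coexistence_multi(embed_single_as_multi(p))
  analytic <- coexistence_state(sol)
  # start from a deliberately perturbed guess
  guess <- analytic * c(1.3, 0.8, 1.5, 0.6, 1.2)
  root <- steady_state_numeric(p, guess)
  expect_equal(unname(root), unname(analytic), tolerance = 1e-6)
  expect_lt(max(abs(single_rhs(root, p))), 1e-8 * p$K)
})

test_that("numeric root finder handles the capacity fixed point", {
  p <- sp(kappa = 0)
  root <- steady_state_numeric(p, single_state(n0 = p$K))
  expect_equal(unname(root), c(p$K, 0, 0, 0, 0))
})

test_that("with unequal growth rates the fixed point still obeys the ratio law", {
  p <- sp(r = 1.05)
  traj <- integrate_model(p, single_state(n0 = 1000, v = 1e4),
                          sim_config(t_max = 2000, n_outputs = 200))
  endpoint <- pmax(traj$states[nrow(traj$states), ], 0)
  root <- steady_state_numeric(p, endpoint)
  expect_lt(max(abs(single_rhs(root, p))) / (max(root) + 1), 1e-10)
  # the spacer/wild-type ratio does not depend on the growth rates
  expect_equal(root[["n1"]] / root[["n0"]], spacer_ratio_single(p),
               tolerance = 1e-6)
})

test_that("regime classification follows the analytic phase boundaries", {
  expect_identical(classify_regime(
    single_spacer_scenario(eta = 0.005)$params), "coexistence")
  expect_identical(classify_regime(sp(kappa = 0, eta = 0)),
                   "phage_extinction")
  expect_identical(classify_regime(sp(eta = 1)), "bacterial_extinction")
  expect_identical(classify_regime(sp(eta = 0.05)), "bacterial_extinction")
  # boundaries resolve conservatively to extinction
  etac <- critical_failure_probability(sp(eta = 0))
  expect_identical(classify_regime(sp(eta = etac)), "bacterial_extinction")
  expect_identical(classify_regime(sp(kappa = 0, eta = 1 / 100)),
                   "bacterial_extinction")
  # multi-spacer: validity of the coexistence solve decides
  expect_identical(classify_regime(multi_spacer_scenario("constant")$params),
                   "coexistence")
  pk0 <- multi_spacer_params(K = 1e5, kappa = 0, g = 1e-4, b = 100,
                             alpha_vec = c(0.01, 0.01),
                             eta_vec = c(0.005, 0.5))
  expect_identical(classify_regime(pk0), "phage_extinction")
})
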