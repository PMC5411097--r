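# Time integration, steady-state detection, outcome classification,
# transient statistics.

test_that("a capacity state with no phage yields a constant trajectory", {
  sc <- single_spacer_scenario(eta = 0, kappa = 0)
  traj <- integrate_model(sc$params, single_state(n0 = sc$params$K),
                          sim_config(t_max = 100, n_outputs = 50))
  expect_true(all(abs(traj$states[, "n0"] - sc$params$K) < 1e-6))
  expect_true(all(traj$states[, c("n1", "I0", "I1", "v")] == 0))
  ss <- detect_steady_state(traj)
  expect_equal(unname(ss), c(sc$params$K, 0, 0, 0, 0))
  expect_identical(classify_outcome(traj), "phage_extinction")
  ts <- transient_summary(traj)
  expect_identical(ts$v_peak, 0)
  expect_identical(ts$t_peak, 0)
  expect_identical(ts$oscillation_count, 0L)
})

test_that("the coexistence run shows bottleneck, recovery and oscillations", {
  sc <- single_spacer_scenario(eta = 0.005)
  traj <- run_scenario(sc)
  df <- as.data.frame(traj)
  n <- df$n_total
  # initial rise while infected cells have not yet lysed
  expect_gt(max(n[df$time < 2]), n[1])
  # bottleneck well below the initial population, then recovery to a
  # phage-limited plateau below capacity
  expect_lt(min(n), n[1])
  expect_gt(n[length(n)], 0.9 * sc$params$K)
  expect_lt(n[length(n)], sc$params$K)
  ts <- transient_summary(traj)
  expect_gt(ts$v_peak, df$v[1])
  expect_gt(ts$t_peak, 0)
  expect_lt(ts$n_bottleneck, n[1])
  expect_gte(ts$oscillation_count, 1L)  # spacer loss feeds damped cycles
  expect_identical(classify_outcome(traj), "coexistence")
})

test_that("long-time integration lands on the analytic steady state", {
  p <- single_spacer_params(f0 = 1, r = 1, K = 1e5, kappa = 1e-2, g = 1e-5,
                            eta = 0.005, alpha = 1e-4, mu = 1, b = 100)
  traj <- integrate_model(p, single_state(n0 = 1000, v = 1e4),
                          sim_config(t_max = 5000, n_outputs = 300))
  endpoint <- traj$states[nrow(traj$states), ]
  root <- steady_state_numeric(p, pmax(endpoint, 0))
  expect_equal(unname(endpoint), unname(root), tolerance = 1e-4)
  F <- unused_capacity_single(p)
  expect_equal(sum(endpoint[1:4]) / p$K, 1 - F, tolerance = 1e-4)
  expect_equal(endpoint[["n1"]] / endpoint[["n0"]], spacer_ratio_single(p),
               tolerance = 1e-4)
})

test_that("an unfinished transient is detected and refused classification", {
  sc <- single_spacer_scenario(eta = 0.005)
  early <- integrate_model(sc$params, sc$initial_state,
                           sim_config(t_max = 50, n_outputs = 60))
  expect_null(detect_steady_state(early))
  expect_error(classify_outcome(early), class = "crisprdyn_undetermined")
})

test_that("extinction regimes classify from trajectories", {
  sc0 <- single_spacer_scenario(eta = 0, kappa = 0, t_max = 500)
  t0 <- run_scenario(sc0)
  expect_identical(classify_outcome(t0), "phage_extinction")
  fin <- t0$states[nrow(t0$states), ]
  expect_lt(fin[["v"]], 1e-6 * sc0$params$K)
  expect_gt(sum(fin[1:4]), 0.999 * sc0$params$K)

  scb <- single_spacer_scenario(eta = 0.05, t_max = 500)
  tb <- run_scenario(scb)
  expect_identical(classify_outcome(tb), "bacterial_extinction")
  expect_lt(total_bacteria(tb$states[nrow(tb$states), ]),
            1e-6 * scb$params$K)
})

test_that("N = 1 multi-spacer trajectories match single-spacer ones", {
  p <- single_spacer_params(f0 = 1, r = 1, K = 1e5, kappa = 2e-3, g = 1e-5,
                            eta = 0.005, alpha = 1e-4, mu = 1, b = 100)
  cfg <- sim_config(t_max = 1000, n_outputs = 200)
  ts <- integrate_model(p, single_state(n0 = 1000, v = 1e4), cfg)
  tm <- integrate_model(embed_single_as_multi(p),
                        multi_state(n0 = 1000, n_vec = 0, v = 1e4), cfg)
  rel <- abs(tm$states - ts$states) / (abs(ts$states) + 1)
  expect_lt(max(rel), 10 * cfg$rel_tol)
})

test_that("time is measured in units of the growth rate", {
  # doubling every rate and halving the horizon reproduces the same endpoint
  p1 <- single_spacer_params(f0 = 1, r = 1, K = 1e5, kappa = 1e-2, g = 1e-5,
                             eta = 0.005, alpha = 1e-4, mu = 1, b = 100)
  p2 <- single_spacer_params(f0 = 2, r = 1, K = 1e5, kappa = 2e-2, g = 2e-5,
                             eta = 0.005, alpha = 1e-4, mu = 2, b = 100)
  s0 <- single_state(n0 = 1000, v = 1e4)
  e1 <- integrate_model(p1, s0, sim_config(t_max = 100, n_outputs = 100))
  e2 <- integrate_model(p2, s0, sim_config(t_max = 50, n_outputs = 100))
  f1 <- e1$states[nrow(e1$states), ]
  f2 <- e2$states[nrow(e2$states), ]
  expect_equal(unname(f2), unname(f1), tolerance = 1e-5)
})

test_that("tightening the solver tolerance leaves the endpoint stable", {
  sc <- single_spacer_scenario(eta = 0.005, t_max = 1000)
  loose <- integrate_model(sc$params, sc$initial_state,
                           sim_config(t_max = 1000, rel_tol = 1e-6,
                                      abs_tol = 1e-8))
  tight <- integrate_model(sc$params, sc$initial_state,
                           sim_config(t_max = 1000, rel_tol = 5e-7,
                                      abs_tol = 1e-8))
  fl <- loose$states[nrow(loose$states), ]
  ft <- tight$states[nrow(tight$states), ]
  expect_lt(max(abs(fl - ft) / (abs(ft) + 1)), 10 * 1e-6)
})

test_that("populations stay in the non-negative orthant within tolerance", {
  for (eta in c(0, 0.005, 0.05)) {
    sc <- single_spacer_scenario(eta = eta, t_max = 1000)
    traj <- run_scenario(sc)
    expect_gte(min(traj$states), -100 * sc$config$abs_tol)
  }
})

test_that("a higher failure probability sustains more phage at steady state", {
  vs <- vapply(c(0.001, 0.003, 0.005, 0.008), function(eta) {
    p <- single_spacer_params(f0 = 1, r = 1, K = 1e5, kappa = 1e-2,
                              g = 1e-5, eta = eta, alpha = 1e-4, mu = 1,
                              b = 100)
    traj <- integrate_model(p, single_state(n0 = 1000, v = 1e4),
                            sim_config(t_max = 5000, n_outputs = 200))
    traj$states[nrow(traj$states), "v"]
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("trajectory writers produce the documented layouts", {
  sc <- single_spacer_scenario(eta = 0.005, t_max = 100, n_outputs = 50)
  traj <- run_scenario(sc)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, csv)
  df <- utils::read.csv(csv)
  expect_identical(names(df),
                   c("time", "n0", "n_1", "I0", "I_1", "v", "n_total"))
  expect_equal(nrow(df), 50)
  expect_equal(df$n_total, df$n0 + df$n_1 + df$I0 + df$I_1)

  js <- jsonlite::fromJSON(write_summary_json(traj))
  expect_true(all(c("outcome", "v_peak", "t_peak", "n_bottleneck",
                    "oscillation_count") %in% names(js)))
  expect_identical(js$outcome, "undetermined")  # t_max = 100 is mid-transient
})
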