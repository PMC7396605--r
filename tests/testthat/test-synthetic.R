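test_that("closed-form distillation matches independent arithmetic", {
  # 0.5^(-0.0275) - 1, evaluated independently: 19.2444 permil
  expect_equal(rayleigh_delta(0.5, -27.5, 0), 19.244379, tolerance = 1e-6)
  expect_equal(rayleigh_delta(c(0.9, 0.1), 0, -30), c(-30, -30))
  expect_equal(rayleigh_delta(1, -27.5, -30), -30)
})

test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(-27.5, -5.3, seed = 123)
  s1 <- simulate_rayleigh_series(cfg)
  s2 <- simulate_rayleigh_series(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_rayleigh_series(simulation_config(-27.5, -5.3, seed = 124))
  expect_false(identical(s1$measurements$delta_c, s3$measurements$delta_c))
})

test_that("default design is nine vials in triplicate with 0.5 permil noise", {
  cfg <- simulation_config(-27.5, -5.3, seed = 1)
  expect_equal(cfg$f_grid, seq(0.9, 0.1, by = -0.1))
  expect_identical(cfg$n_replicates, 3L)
  expect_equal(cfg$noise_sd, 0.5)
  s <- simulate_rayleigh_series(cfg)
  expect_identical(nrow(s$measurements), 27L)
  expect_identical(length(unique(s$measurements$vial_id)), 9L)

  expect_error(simulation_config(-27.5, f_grid = c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(simulation_config(-27.5, noise_sd = -0.1), ">= 0")
  expect_error(simulation_config(-27.5, n_replicates = 0), ">= 1")
})

test_that("study fixtures carry the published generating truth", {
  s <- make_study_fixture("1,2-DCA", "1,2-DCA", seed = 4)
  expect_equal(fit_rayleigh(s, "C")$epsilon, -27.5, tolerance = 0.1 * 27.5)
  expect_equal(fit_rayleigh(s, "Cl")$epsilon, -5.3, tolerance = 0.2 * 5.3)

  s <- make_study_fixture("cDCE", "VC", seed = 4)
  expect_equal(fit_rayleigh(s, "C")$epsilon, -14.7, tolerance = 0.15 * 14.7)

  expect_error(make_study_fixture("1,2-DCA", "PCE"), "not determined")
  expect_error(make_study_fixture("1,2-DCA", "VC"), "not determined")
  expect_error(make_study_fixture("TCE", "PCE"), "unknown combination")
})

test_that("fitted-slope noise scales as sd/sqrt(n Var(ln f))", {
  n_rep <- 300
  ses <- sapply(c(0.25, 1.0), function(noise) {
    est <- vapply(seq_len(n_rep), function(i) {
      cfg <- simulation_config(-27.5, noise_sd = noise, seed = 40000 + i)
      fit_rayleigh(simulate_rayleigh_series(cfg), "C")$epsilon
    }, numeric(1))
    sd(est)
  })
  f <- rep(seq(0.9, 0.1, -0.1), each = 3)
  pred <- c(0.25, 1.0) / sqrt(length(f) * mean((log(f) - mean(log(f)))^2))
  for (i in 1:2) {
    expect_lt(ses[i] / pred[i], 1.2)
    expect_gt(ses[i] / pred[i], 1 / 1.2)
  }
})

test_that("isotopologue kinetics with unit KIEs show no fractionation", {
  sys <- isotopologue_system("C", 2, reactive_positions = 1:2, kie = 1)
  traj <- simulate_isotopologues(sys, f_stop = 0.1)
  expect_lt(max(abs(traj$delta_permil)), 1e-6)
})

test_that("fully-reactive isotopologue systems invert the AKIE algebra exactly", {
  # single atom, single reactive position: exactly log-linear trajectory
  for (kie in c(1.005, 1.013, 1.057)) {
    sys <- isotopologue_system("Cl", 1, kie = kie)
    traj <- simulate_isotopologues(sys, f_stop = 0.1)
    eps_fit <- fit_epsilon_from_trajectory(traj)
    expect_equal(eps_fit, epsilon_from_kie(kie, 1), tolerance = 0.1 /
                   abs(epsilon_from_kie(kie, 1)))
  }
  # published chlorine limit: KIE = 1.013 maps to about -12.8 permil
  sys <- isotopologue_system("Cl", 1, kie = 1.013)
  eps <- fit_epsilon_from_trajectory(simulate_isotopologues(sys, 0.1))
  expect_equal(eps, -12.83, tolerance = 0.01)
})

test_that("non-reacting positions dilute the bulk effect per x/n at low conversion", {
  # VC-like carbon: 2 C, 1 reactive; algebra holds in the low-conversion
  # window, and the integrated full-range curve bends away from it as the
  # reactive-heavy pool depletes faster than the non-reactive-heavy pool
  sys <- isotopologue_system("C", 2, reactive_positions = 1, kie = 1.057)
  traj <- simulate_isotopologues(sys, f_stop = 0.1, n_steps = 600)
  alg <- epsilon_from_kie(1.057, 2)  # -26.96 permil
  eps_low <- fit_epsilon_from_trajectory(traj, f_min = 0.9)
  expect_equal(eps_low, alg, tolerance = 0.3 / abs(alg))
  eps_full <- fit_epsilon_from_trajectory(traj)
  expect_gt(abs(eps_full), abs(alg))          # drift is outward
  expect_lt(abs(eps_full - alg), 1.0)         # and bounded (~0.5 permil)

  # at chlorine-scale KIE the drift is negligible even over the full range
  sys_cl <- isotopologue_system("Cl", 2, reactive_positions = 1,
                                kie = 1.013)
  eps_cl <- fit_epsilon_from_trajectory(
    simulate_isotopologues(sys_cl, 0.1, n_steps = 600))
  expect_equal(eps_cl, epsilon_from_kie(1.013, 2),
               tolerance = 0.1 / abs(epsilon_from_kie(1.013, 2)))
})

test_that("mass is conserved along deterministic and stochastic trajectories", {
  sys <- isotopologue_system("C", 2, reactive_positions = 1, kie = 1.057)
  traj <- simulate_isotopologues(sys, f_stop = 0.1)
  expect_lt(max(abs(traj$remaining + traj$reacted -
                      attr(traj, "initial_total"))), 1e-8)

  sys_n <- isotopologue_system("Cl", 1, kie = 1.02, n_total = 50000)
  st <- simulate_isotopologues(sys_n, f_stop = 0.2, method = "stochastic",
                               seed = 1, n_steps = 50)
  expect_true(all(st$remaining + st$reacted ==
                    attr(st, "initial_total")))
  st2 <- simulate_isotopologues(sys_n, f_stop = 0.2, method = "stochastic",
                                seed = 1, n_steps = 50)
  expect_identical(st, st2)
})

test_that("fitted epsilon converges to the trace limit, linearly in abundance", {
  eps_at <- function(p) {
    sys <- isotopologue_system("C", 2, reactive_positions = 1,
                               kie = 1.057, abundance = p)
    fit_epsilon_from_trajectory(simulate_isotopologues(sys, 0.1,
                                                       n_steps = 600),
                                f_min = 0.5)
  }
  # trace labels: abundance no longer matters
  expect_lt(abs(eps_at(1e-4) - eps_at(3e-4)), 0.01)
  # finite abundance departs from the trace limit at first order in p
  d_small <- abs(eps_at(4e-3) - eps_at(1e-5))
  d_large <- abs(eps_at(4e-2) - eps_at(1e-5))
  expect_gt(d_large / d_small, 7)
  expect_lt(d_large / d_small, 13)
})

test_that("multinomial chlorine isotopologues agree with the dilute limit", {
  dilute <- isotopologue_system("Cl", 2, reactive_positions = 1,
                                kie = 1.013, abundance = 0.001)
  multi <- isotopologue_system("Cl", 2, reactive_positions = 1,
                               kie = 1.013, abundance = 0.001,
                               multinomial = TRUE)
  e1 <- fit_epsilon_from_trajectory(simulate_isotopologues(dilute, 0.1))
  e2 <- fit_epsilon_from_trajectory(simulate_isotopologues(multi, 0.1))
  expect_equal(e1, e2, tolerance = 1e-3)

  # at natural 37Cl abundance only the multinomial mode is meaningful
  nat <- isotopologue_system("Cl", 4, reactive_positions = 1,
                             kie = 1.013, abundance = 0.24,
                             multinomial = TRUE)
  traj <- simulate_isotopologues(nat, 0.1)
  expect_true(all(is.finite(traj$delta_permil)))
})

test_that("invalid isotopologue configurations are rejected", {
  expect_error(isotopologue_system("C", 2, kie = 0), "> 0")
  expect_error(isotopologue_system("C", 2, kie = -1.05), "> 0")
  sys <- isotopologue_system("C", 2, kie = 1.05)
  expect_error(simulate_isotopologues(sys, f_stop = 0), "between 0 and 1")
  expect_error(simulate_isotopologues(sys, f_stop = 1.2),
               "between 0 and 1")
  expect_error(isotopologue_system("C", 2, abundance = 0.6),
               "singly-labeled")
})

test_that("concerted channel rule slows the molecule by the product of KIEs", {
  # singly-labeled: one heavy atom, rate k/KIE regardless of geometry
  sys <- isotopologue_system("C", 2, reactive_positions = 1:2,
                             kie = 1.05,
                             channel_rule = "single_concerted_channel")
  traj <- simulate_isotopologues(sys, f_stop = 0.1)
  eps <- fit_epsilon_from_trajectory(traj, f_min = 0.9)
  # every heavy molecule reacts at k/KIE: bulk effect 1000*(1/KIE - 1)
  expect_equal(eps, 1000 * (1 / 1.05 - 1), tolerance = 1)
})
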