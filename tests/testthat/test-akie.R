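test_that("registry lookup returns the published position parameters", {
  p <- registry_lookup("cDCE", "C")
  expect_identical(c(p$n, p$x, p$z), c(2L, 1L, 2L))
  p <- registry_lookup("VC", "Cl", "one_step")
  expect_identical(c(p$n, p$x, p$z), c(1L, 1L, 1L))
  p <- registry_lookup("PCE", "Cl")
  expect_identical(c(p$n, p$x, p$z), c(4L, 1L, 4L))
  p <- registry_lookup("1,2-DCA", "Cl", "concerted")
  expect_identical(c(p$n, p$x, p$z), c(2L, 2L, 2L))
  expect_identical(p$provenance, "reconstructed")
  expect_identical(registry_lookup("1,2-DCA", "C", "stepwise")$provenance,
                   "literature")

  expect_error(registry_lookup("TCE", "C"), "valid combinations")
  # 1,2-DCA needs an explicit mechanism
  expect_error(registry_lookup("1,2-DCA", "C"), "valid combinations")
  expect_error(position_params("X", "C", "one_step", n = 2, x = 3, z = 1),
               "1 <= x <= n")
})

test_that("AKIE worked examples reproduce published dihaloelimination values", {
  conc_c <- registry_lookup("1,2-DCA", "C", "concerted")
  expect_equal(compute_akie(0, conc_c)$akie_display, 1.000)
  expect_equal(compute_akie(-27.5, conc_c)$akie_display, 1.058)
  expect_equal(compute_akie(-18.5, conc_c)$akie_display, 1.038)
  expect_equal(
    compute_akie(-4.5, registry_lookup("1,2-DCA", "Cl", "stepwise"))$akie_display,
    1.018)
  expect_equal(
    compute_akie(-4.5, registry_lookup("1,2-DCA", "Cl", "concerted"))$akie_display,
    1.009)
})

test_that("registry reproduces the arithmetically consistent published AKIEs", {
  # (compound, cultivation, element, mechanism, published AKIE); rows whose
  # published value is not reproducible from the published epsilon at
  # 3-decimal rounding (all PCE rows, one VC carbon row, the stepwise
  # entries computed from unrounded epsilon) are excluded by design
  cases <- list(
    list("cDCE", "PCE",     "C",  "one_step",  1.102),
    list("cDCE", "1,2-DCA", "C",  "one_step",  1.093),
    list("VC",   "PCE",     "C",  "one_step",  1.069),
    list("VC",   "1,2-DCA", "C",  "one_step",  1.040),
    list("VC",   "VC",      "C",  "one_step",  1.051),
    list("1,2-DCA", "1,2-DCA", "C",  "concerted", 1.058),
    list("1,2-DCA", "cDCE",    "C",  "concerted", 1.038),
    list("1,2-DCA", "cDCE",    "Cl", "concerted", 1.009),
    list("1,2-DCA", "cDCE",    "Cl", "stepwise",  1.018),
    list("cDCE", "cDCE", "Cl", "one_step", 1.005),
    list("cDCE", "VC",   "Cl", "one_step", 1.004)
  )
  ref <- reference_epsilons()
  for (cs in cases) {
    row <- ref[ref$compound == cs[[1]] &
                 ref$cultivation_acceptor == cs[[2]], ]
    eps <- if (cs[[3]] == "C") row$epsilon_c else row$epsilon_cl
    akie <- compute_akie(eps, registry_lookup(cs[[1]], cs[[3]], cs[[4]]))
    expect_lt(abs(akie$akie - cs[[5]]), 0.002,
              label = sprintf("%s/%s %s %s: |%.4f - %.3f|", cs[[1]],
                              cs[[2]], cs[[3]], cs[[4]], akie$akie,
                              cs[[5]]))
  }
})

test_that("AKIE map is monotone, invertible, and propagates CIs in order", {
  params <- registry_lookup("cDCE", "C")
  eps_grid <- seq(-40, 20, by = 5)
  akies <- vapply(eps_grid, function(e) compute_akie(e, params)$akie,
                  numeric(1))
  expect_true(all(diff(akies) < 0))  # strictly decreasing in epsilon

  # normal/inverse effects bracket 1 symmetrically to first order
  a_plus <- compute_akie(2, params)$akie
  a_minus <- compute_akie(-2, params)$akie
  expect_lt(abs((a_minus - 1) + (a_plus - 1)), 2e-4)
  expect_gt(a_minus, 1)
  expect_lt(a_plus, 1)

  # algebraic round trip to machine precision
  for (p in list(params, registry_lookup("1,2-DCA", "Cl", "concerted"),
                 registry_lookup("VC", "Cl"))) {
    for (eps in c(-31.7, -5.3, -0.4, 3)) {
      akie <- compute_akie(eps, p)$akie
      expect_equal(invert_akie(akie, p), eps, tolerance = 1e-12)
    }
  }

  res <- compute_akie(-27.5, registry_lookup("1,2-DCA", "C", "concerted"),
                      epsilon_ci = c(-31.6, -23.4))
  expect_equal(res$ci95[2], 1 / (1 + 2 * (-31.6) / 1000), tolerance = 1e-12)
  expect_equal(res$ci95[1], 1 / (1 + 2 * (-23.4) / 1000), tolerance = 1e-12)
  expect_true(res$ci95[1] < res$akie && res$akie < res$ci95[2])

  expect_error(compute_akie(-300, registry_lookup("PCE", "C")),
               "out of domain")
})

test_that("factor override replaces the combinatorial factor", {
  p <- registry_lookup("PCE", "C")  # printed factor z*n/x = 8
  expect_equal(compute_akie(-9.8, p)$factor, 8)
  over <- compute_akie(-9.8, p, factor_override = 4)
  expect_equal(over$akie, 1 / (1 - 4 * 9.8 / 1000), tolerance = 1e-12)
})

test_that("Streitwieser screening flags exceedances with margins", {
  chk <- streitwieser_check(1.129, "C")
  expect_true(chk$exceeds)
  expect_equal(chk$margin, 0.072, tolerance = 1e-9)
  expect_false(streitwieser_check(1.009, "Cl")$exceeds)
  expect_false(streitwieser_check(1.000, "C")$exceeds)
  expect_equal(streitwieser_limit("C"), 1.057)
  expect_equal(streitwieser_limit("Cl"), 1.013)
})

test_that("stepwise dihaloelimination is rejected by joint Streitwieser exceedance", {
  rep <- evaluate_mechanism_scenarios(-27.5, -5.3)
  expect_false(rep$plausible[["stepwise"]])
  expect_true(rep$scenarios$stepwise$akie_c$exceeds_limit)
  expect_true(rep$scenarios$stepwise$akie_cl$exceeds_limit)
  expect_true(rep$plausible[["concerted"]])
  expect_identical(rep$surviving, "concerted")

  rep <- evaluate_mechanism_scenarios(-18.5, -4.5)
  expect_false(rep$plausible[["stepwise"]])
  expect_gt(rep$scenarios$stepwise$akie_c$akie, 1.057)
  expect_true(rep$plausible[["concerted"]])

  rep <- evaluate_mechanism_scenarios(0, 0)
  expect_true(all(rep$plausible))
  expect_setequal(rep$surviving, c("concerted", "stepwise"))
})

test_that("dual-element patterns are classified against the boundary", {
  low <- lambda_from_summary(3.5, 0.8)
  expect_identical(classify_dual_pattern(low)$label, "low_lambda_pattern")
  high <- lambda_from_summary(12.2, 2.5)
  expect_identical(classify_dual_pattern(high)$label, "high_lambda_pattern")
  amb <- lambda_from_summary(6.0, 2.0)
  expect_identical(classify_dual_pattern(amb)$label, "ambiguous")
  # boundary is configurable: with Lambda* = 2 the PCE-like slope sits
  # wholly above the boundary
  expect_identical(classify_dual_pattern(low, boundary = 2)$label,
                   "high_lambda_pattern")
})
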