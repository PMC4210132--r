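test_that("integration matches a brute-force fixed-step oracle", {
  m <- base_model()
  cond <- cond_of("B6", "control")
  tr <- integrate_model(m, cond, times = c(0, 100))
  adaptive <- tr[nrow(tr), -1]
  oracle <- euler_integrate(cond, t_end = 100, dt = 1e-3)
  for (sp in SPECIES7) {
    if (oracle[[sp]] > 1e-8)
      expect_equal(unname(adaptive[[sp]]), unname(oracle[[sp]]),
                   tolerance = 0.01)
    else
      expect_lt(abs(adaptive[[sp]]), 1e-6)
  }
})

test_that("a zero-input system stays identically zero", {
  m <- base_model()
  no_pc <- eico_condition("B6", "control",
                          stats::setNames(rep(1, 10), m$activities$id), 0)
  tr <- integrate_model(m, no_pc, t_end = 1e4, times = c(0, 10, 1e4))
  expect_identical(max(abs(tr[, -1])), 0)
  ss <- steady_state(m, no_pc)
  expect_true(ss$converged)
  expect_identical(unname(ss$concentrations), rep(0, 7))
})

test_that("steady states converge with residuals below tolerance for all six conditions", {
  m <- base_model()
  for (s in c("AJ", "B6", "PWD")) {
    for (tr in c("control", "ddc")) {
      ss <- cached_steady(s, tr)
      expect_true(ss$converged)
      expect_lte(ss$residual_norm, 1e-6)
      expect_true(all(ss$concentrations >= 0))
      # re-evaluating the RHS at the reported state reproduces the residual
      d <- eico_rhs(m, ss$concentrations, cond_of(s, tr))
      expect_lte(max(abs(d)), 1e-6)
    }
  }
})

test_that("the steady state does not depend on the start state", {
  m <- base_model()
  for (s in c("AJ", "B6", "PWD")) {
    for (tr in c("control", "ddc")) {
      a <- cached_steady(s, tr)$concentrations
      b <- steady_state(m, cond_of(s, tr),
                        init = rep(10, 7))$concentrations
      expect_true(all(abs(b - a) / pmax(a, 1e-12) < 1e-3))
    }
  }
})

test_that("the adaptive steady state agrees with the long-horizon Euler limit", {
  cond <- cond_of("B6", "control")
  adaptive <- cached_steady("B6", "control")$concentrations
  oracle <- euler_integrate(cond, t_end = 4e4, dt = 0.5)
  expect_true(all(abs(adaptive - oracle) / pmax(oracle, 1e-12) < 0.01))
})

test_that("upstream activity increases propagate downstream at steady state", {
  m <- base_model()
  base <- cached_steady("B6", "control")$concentrations
  r <- cond_of("B6", "control")$ratios
  r["PTGS1"] <- 2
  doubled <- steady_state(m, eico_condition("B6", "ddc", r, 249))
  expect_true(doubled$converged)
  expect_gt(doubled$concentrations[["PGD2"]], base[["PGD2"]])
})

test_that("fold-change tables classify against the symmetric band", {
  m <- base_model()
  ctrl <- cached_steady("B6", "control")

  # control vs itself: the all-ones table
  fc <- fold_changes(ctrl, ctrl)
  expect_equal(fc$ratio, rep(1, 7))
  expect_true(all(fc$classification == "unchanged"))

  # the band is a pure function of ratio and threshold
  ddc <- cached_steady("B6", "ddc")
  fc2 <- fold_changes(ctrl, ddc, threshold = 1.5)
  manual <- ifelse(fc2$ratio >= 1.5, "up",
            ifelse(fc2$ratio <= 1 / 1.5, "down", "unchanged"))
  expect_identical(fc2$classification, manual)
  fc3 <- fold_changes(ctrl, ddc, threshold = 3)
  expect_true(all(fc3$classification[fc3$ratio < 3 & fc3$ratio > 1/3] ==
                  "unchanged"))

  # refusal on non-converged inputs
  broken <- ctrl
  broken$converged <- FALSE
  expect_error(fold_changes(broken, ddc), "converged")
  expect_error(fold_changes(ctrl, ddc, threshold = 1), "threshold")

  # zero control concentration: undefined ratio, undefined class
  m0 <- base_model()
  no_pc <- eico_condition("B6", "control",
                          stats::setNames(rep(1, 10), m0$activities$id), 0)
  zss <- steady_state(m0, no_pc)
  fc4 <- fold_changes(zss, zss)
  expect_true(all(is.na(fc4$ratio)))
  expect_true(all(is.na(fc4$classification)))
})

test_that("conditions carry the tabulated initial values", {
  expect_equal(cond_of("B6", "control")$pc_um, 249)
  expect_equal(cond_of("PWD", "ddc")$ratios[["GPX"]], 19.42)
  expect_equal(cond_of("AJ", "ddc")$ratios[["ALOX5AP"]], 4.81)
  expect_equal(cond_of("AJ", "ddc")$pc_um, 206)
  ctrl <- cond_of("AJ", "control")
  expect_true(all(ctrl$ratios == 1))
  expect_error(eico_condition("AJ", "control",
                              stats::setNames(c(2, rep(1, 9)),
                                              names(ctrl$ratios)), 269),
               "control")
  expect_error(get_condition("XX", "control", base_conditions()))
})
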