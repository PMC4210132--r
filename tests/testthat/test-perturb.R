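test_that("an empty reversion reproduces the plain DDC steady state", {
  m <- base_model()
  plain <- cached_steady("AJ", "ddc")
  rev <- revert_enzymes(m, cond_of("AJ", "ddc"), cond_of("AJ", "control"),
                        character())
  expect_true(rev$converged)
  expect_equal(rev$concentrations, plain$concentrations, tolerance = 1e-8)
})

test_that("reversion is restricted to the six perturbed activities", {
  m <- base_model()
  expect_error(revert_enzymes(m, cond_of("AJ", "ddc"),
                              cond_of("AJ", "control"), "PTGDS"),
               "ALOX5AP")
  expect_error(revert_enzymes(m, cond_of("AJ", "ddc"),
                              cond_of("AJ", "control"), "XYZ"))
})

test_that("the six-enzyme reversion deviates from the reference only through PC", {
  m <- base_model()
  six <- revert_enzymes(m, cond_of("AJ", "ddc"), cond_of("AJ", "control"),
                        c("ALOX5AP", "GPX", "PKCD", "PTGS1", "PERK", "PSTAT3"))
  ref <- cached_steady("AJ", "control")$concentrations
  # the same model with all ratios at control but PC clamped at the DDC
  # value isolates the PC effect
  pc_only <- steady_state(m, eico_condition("AJ", "control",
                                            cond_of("AJ", "control")$ratios,
                                            cond_of("AJ", "ddc")$pc_um))
  expect_equal(six$concentrations, pc_only$concentrations, tolerance = 1e-6)
  dev_six <- max(abs(six$concentrations - ref) / pmax(ref, 1e-12))
  dev_pc <- max(abs(pc_only$concentrations - ref) / pmax(ref, 1e-12))
  expect_equal(dev_six, dev_pc, tolerance = 1e-4)
})

test_that("the reversion screen summarizes restoration per subset", {
  m <- base_model()
  scr <- reversion_screen(m, cond_of("AJ", "ddc"), cond_of("AJ", "control"),
                          subsets = list("GPX", c("ALOX5AP", "GPX"),
                                         c("ALOX5AP", "GPX", "PKCD", "PTGS1",
                                           "PERK", "PSTAT3")))
  ov <- restored_subsets(scr)
  expect_equal(nrow(ov), 3L)
  expect_true(all(ov$converged))
  # single and pair do not restore; the full six do
  expect_false(ov$overall_restored[ov$subset == "GPX"])
  expect_false(ov$overall_restored[ov$subset == "ALOX5AP+GPX"])
  expect_true(ov$overall_restored[ov$subset ==
                                  "ALOX5AP+GPX+PERK+PKCD+PSTAT3+PTGS1"])
  expect_error(reversion_screen(m, cond_of("AJ", "ddc"),
                                cond_of("AJ", "control"), subsets = list()),
               "non-empty")
})

test_that("drug-screen classifications are deterministic and the identity factor is neutral", {
  m <- base_model()
  ddc <- cond_of("AJ", "ddc")
  one <- drug_screen(m, ddc, enzymes = c("PTGS1", "GPX"), factors = 1)
  expect_true(all(one$classification == "unchanged"))
  expect_equal(one$ratio, rep(1, nrow(one)), tolerance = 1e-6)

  a <- drug_screen(m, ddc, enzymes = "PTGS1", factors = c(3, 9))
  b <- drug_screen(m, ddc, enzymes = "PTGS1", factors = c(3, 9))
  expect_identical(as.data.frame(a), as.data.frame(b))

  expect_error(drug_screen(m, ddc, factors = 0.5), "factors must be")
  expect_error(drug_screen(m, ddc, enzymes = "NOPE"), "unknown")
})

test_that("knockdowns act on the targeted branch", {
  m <- base_model()
  scr <- drug_screen(m, cond_of("AJ", "ddc"), enzymes = "ALOX5AP",
                     factors = 3)
  d <- as.data.frame(scr)
  expect_equal(d$classification[d$metabolite == "5-HPETE"], "down")
  expect_equal(d$classification[d$metabolite == "LTA4"], "down")
  # prostaglandin branch untouched by a 5-LOX knockdown
  expect_equal(d$classification[d$metabolite == "PGD2"], "unchanged")
})
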