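test_that("the constructed model matches the shipped constants table", {
  m <- base_model()
  expect_s3_class(m, "eico_model")
  expect_equal(nrow(m$metabolites), 8L)
  expect_equal(sum(m$metabolites$fixed), 1L)
  expect_true(m$metabolites$fixed[m$metabolites$id == "PC"])
  expect_length(m$reactions, 12L)
  expect_equal(nrow(m$activities), 10L)

  sinks <- names(Filter(function(r) is.na(r$product), m$reactions))
  expect_setequal(sinks, c("R3", "R5", "R8", "R11", "R12"))

  expect_equal(m$reactions$R1$params[["k_m"]], 2500)
  expect_equal(m$reactions$R11$params[["k_cat"]], 0.052)

  # unit-annotated round trip: every constant equals the shipped table,
  # constant for constant
  tab <- eico_constants()
  got <- get_constants(m)
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$reaction[i], tab$parameter[i], sep = ".")
    expect_identical(unname(got[key]), tab$value[i])
  }
  expect_setequal(tab$unit[tab$parameter == "k_cat"], "s^-1")

  # topology of the regulatory links
  expect_identical(m$reactions$R1$activators, c("PLA2", "PERK"))
  expect_identical(m$reactions$R1$inhibitor, "AA")
  expect_identical(m$reactions$R2$inhibitor, "5-HPETE")
  expect_identical(m$reactions$R4$inhibitor, "LTA4")
  expect_setequal(m$reactions$R6$activators, c("ALOX15", "PKCD", "PSTAT3"))
  expect_identical(m$reactions$R7$activators, "GPX")
  expect_identical(m$reactions$R9$activators, "PTGS1")
  expect_identical(m$reactions$R9$inhibitor, "PGH2")
  expect_identical(m$reactions$R10$activators, "PTGDS")

  # the alternative R7 catalyst is available as a switch
  m2 <- eico_model(r7_activator = "ALOX15")
  expect_identical(m2$reactions$R7$activators, "ALOX15")
})

test_that("evaluate_rate implements the rate laws and their guard rails", {
  m <- base_model()
  u1 <- stats::setNames(rep(1, 10), m$activities$id)

  # first-order decay: 0.0012 * 100
  expect_equal(evaluate_rate("R3", c("5-HPETE" = 100), u1, model = m), 0.12)

  # zero substrate means zero flux, for every reaction
  zero <- stats::setNames(rep(0, 8), m$metabolites$id)
  for (rid in names(m$reactions))
    expect_identical(evaluate_rate(rid, zero, u1, model = m), 0)

  # product inhibition of R1: doubling AA strictly lowers the flux
  conc <- c(PC = 249000, AA = 50)
  v_base <- evaluate_rate("R1", conc, u1, model = m)
  v_high <- evaluate_rate("R1", c(PC = 249000, AA = 100), u1, model = m)
  expect_gt(v_base, v_high)

  # errors: unresolved ids and negative concentrations
  expect_error(evaluate_rate("R1", c(PC = 1), u1, model = m), "unresolved")
  expect_error(evaluate_rate("R1", c(PC = 1, AA = -1), u1, model = m),
               "non-negative")
  expect_error(evaluate_rate("R2", c(AA = 1, "5-HPETE" = 0),
                             c(ALOX5 = 1), model = m), "unresolved")
})

test_that("activator scaling is exactly linear and inhibition strictly monotone", {
  m <- base_model()
  u1 <- stats::setNames(rep(1, 10), m$activities$id)
  conc <- c(PC = 249000, AA = 40, "5-HPETE" = 1, LTA4 = 5, "15-HPETE" = 0.5,
            "15-HETE" = 2, PGH2 = 1.5, PGD2 = 2)
  probes <- list(R2 = "ALOX5AP", R4 = "ALOX5", R6 = "PKCD", R7 = "GPX",
                 R9 = "PTGS1", R10 = "PTGDS", R1 = "PERK")
  for (rid in names(probes)) {
    for (c_scale in c(0.5, 2, 7.3)) {
      u2 <- u1
      u2[probes[[rid]]] <- c_scale
      expect_equal(evaluate_rate(rid, conc, u2, model = m),
                   c_scale * evaluate_rate(rid, conc, u1, model = m),
                   tolerance = 1e-12)
    }
  }
  # increasing the inhibitor concentration strictly decreases the flux
  inhibitors <- list(R1 = "AA", R2 = "5-HPETE", R4 = "LTA4",
                     R6 = "15-HPETE", R7 = "15-HETE", R9 = "PGH2")
  for (rid in names(inhibitors)) {
    hi <- conc
    hi[inhibitors[[rid]]] <- conc[inhibitors[[rid]]] * 3 + 1
    expect_lt(evaluate_rate(rid, hi, u1, model = m),
              evaluate_rate(rid, conc, u1, model = m))
  }
})

test_that("the RHS respects the clamped boundary species and conservation structure", {
  m <- base_model()
  zero7 <- rep(0, 7)

  # PC clamped at zero: no mass anywhere, all derivatives vanish
  no_pc <- eico_condition("B6", "control",
                          stats::setNames(rep(1, 10), m$activities$id), 0)
  expect_identical(unname(eico_rhs(m, zero7, no_pc)), zero7)

  # PC positive: AA is the sole product of the sole PC-consuming reaction
  ctrl <- cond_of("B6", "control")
  d <- eico_rhs(m, zero7, ctrl)
  expect_gt(d[["AA"]], 0)
  expect_identical(unname(d[names(d) != "AA"]), rep(0, 6))

  expect_error(eico_rhs(m, rep(0, 5), ctrl), "length")
  expect_error(eico_rhs(m, c(-1, rep(0, 6)), ctrl), "non-negative")

  # flux bookkeeping: derivative of 15-HETE is exactly v7 - v8
  y <- c(AA = 10, "5-HPETE" = 1, LTA4 = 1, "15-HPETE" = 1, "15-HETE" = 1,
         PGH2 = 1, PGD2 = 1)
  v <- eico_fluxes(m, y, ctrl)
  d2 <- eico_rhs(m, y, ctrl)
  expect_equal(d2[["15-HETE"]], unname(v["R7"] - v["R8"]))
  expect_equal(d2[["AA"]], unname(v["R1"] - v["R2"] - v["R6"] - v["R9"] - v["R12"]))
})

test_that("constants can be overridden and invalid overrides are rejected", {
  m <- base_model()
  m2 <- set_constants(m, c("R9.v_max" = 0.5, "R3.k_cat" = 0.002))
  expect_equal(unname(get_constants(m2)["R9.v_max"]), 0.5)
  expect_equal(unname(get_constants(m2)["R3.k_cat"]), 0.002)
  # original untouched
  expect_equal(unname(get_constants(m)["R9.v_max"]), 0.168)
  expect_error(set_constants(m, c("R99.v_max" = 1)), "unknown")
  expect_error(set_constants(m, c("R9.v_max" = -1)), "positive")
  expect_error(set_constants(m, stats::setNames(1, "")), "named")
})

test_that("non-negativity is preserved along trajectories from any non-negative start", {
  m <- base_model()
  set.seed(101)
  for (i in 1:5) {
    init <- stats::runif(7, 0, 50)
    tr <- integrate_model(m, cond_of("AJ", "ddc"), t_end = 2000,
                          times = c(0, 10, 100, 2000), init = init)
    expect_true(all(tr[, -1] >= -1e-8))
  }
})
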