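make_perfect_spec <- function(strain = "B6") {
  m <- base_model()
  sc <- cached_steady(strain, "control")$concentrations
  sd <- cached_steady(strain, "ddc")$concentrations
  objective_spec(m, cond_of(strain, "control"), cond_of(strain, "ddc"),
                 experimental_control = sc, experimental_ddc = sd)
}

test_that("the objective vanishes exactly at a self-consistent specification", {
  spec <- make_perfect_spec()
  expect_identical(eico_objective(numeric(0), spec), 0)
})

test_that("a single perturbed experimental value contributes its squared residual", {
  m <- base_model()
  sc <- cached_steady("B6", "control")$concentrations
  sd <- cached_steady("B6", "ddc")$concentrations
  for (delta in c(0.5, -0.2, 3)) {
    sc2 <- sc
    sc2[["15-HETE"]] <- sc2[["15-HETE"]] + delta
    spec <- objective_spec(m, cond_of("B6", "control"), cond_of("B6", "ddc"),
                           experimental_control = sc2, experimental_ddc = sd)
    expect_equal(eico_objective(numeric(0), spec), delta^2, tolerance = 1e-6)
  }
})

test_that("the objective prefers the generating parameters over a distorted model", {
  scen <- generate_scenario(5, perturbation_scale = 0, noise_cv = 0)
  meas <- simulate_measurements(scen)
  spec <- scenario_spec(scen, meas, strain = "B6", model = scen$model)
  f_truth <- eico_objective(numeric(0), spec)
  expect_equal(f_truth, 0, tolerance = 1e-8)
  doubled <- get_constants(scen$model)["R9.v_max"] * 2
  expect_gt(eico_objective(doubled, spec), f_truth)
})

test_that("objective validates parameter names and values", {
  spec <- make_perfect_spec()
  expect_error(eico_objective(c("R1.k_q" = 1), spec), "unknown")
  expect_error(eico_objective(c("R9.v_max" = -1), spec), "positive")
  expect_error(objective_spec(base_model(), cond_of("B6", "control"),
                              cond_of("B6", "ddc"),
                              experimental_control = c(AA = 1),
                              experimental_ddc = c(AA = 1)),
               "missing")
})

test_that("a one-generation GA that contains the truth returns it", {
  # the initial population is seeded with the current model constants, so a
  # spec built around the unperturbed model carries the optimum already
  spec <- make_perfect_spec()
  fit <- eico_fit(spec, population_size = 6, generations = 1, seed = 3)
  expect_equal(fit$best_objective, 0, tolerance = 1e-10)
  start <- spec$parameter_space$start
  expect_equal(unname(coef(fit)[spec$parameter_space$parameter]), start,
               tolerance = 1e-12)
})

test_that("the GA is deterministic for a fixed seed and elitist across generations", {
  spec <- make_perfect_spec()
  f1 <- eico_fit(spec, population_size = 8, generations = 4, seed = 11)
  f2 <- eico_fit(spec, population_size = 8, generations = 4, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$best_objective, f2$best_objective)
  expect_identical(f1$generation_trace, f2$generation_trace)
  expect_true(all(diff(f1$generation_trace) <= 0))
  # on a non-degenerate problem, different seeds explore differently
  scen <- generate_scenario(13, perturbation_scale = 0.3, noise_cv = 0)
  spec2 <- scenario_spec(scen, simulate_measurements(scen), strain = "B6")
  g1 <- eico_fit(spec2, population_size = 8, generations = 4, seed = 11)
  g2 <- eico_fit(spec2, population_size = 8, generations = 4, seed = 12)
  expect_false(identical(g1$generation_trace, g2$generation_trace))
})

test_that("fitted parameters respect their declared bounds", {
  scen <- generate_scenario(9, perturbation_scale = 0.3, noise_cv = 0)
  meas <- simulate_measurements(scen)
  spec <- scenario_spec(scen, meas, strain = "B6")
  fit <- eico_fit(spec, population_size = 10, generations = 5, seed = 2)
  ps <- spec$parameter_space
  p <- coef(fit)[ps$parameter]
  expect_true(all(p >= ps$lower - 1e-12 & p <= ps$upper + 1e-12))
  expect_equal(fit$n_evaluations, 10 + 5 * 9)
})

test_that("fit accessor methods are coherent", {
  spec <- make_perfect_spec()
  fit <- eico_fit(spec, population_size = 6, generations = 2, seed = 3)
  expect_s3_class(fit, "eico_fit")
  expect_named(coef(fit), spec$parameter_space$parameter)
  pred <- predict(fit, "both")
  expect_equal(rownames(pred), c("control", "ddc"))
  res <- residuals(fit)
  expect_equal(dim(res), c(2L, 5L))
  # perfect fit: residuals vanish
  expect_lt(max(abs(res)), 1e-5)
  s <- summary(fit)
  expect_s3_class(s, "summary.eico_fit")
  expect_output(print(s), "Parameters")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  sims <- simulate(fit, nsim = 2, seed = 4, noise_cv = 0.1)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "data.frame")
  # seeded: regeneration identical
  sims2 <- simulate(fit, nsim = 2, seed = 4, noise_cv = 0.1)
  expect_identical(sims, sims2)
})

test_that("default parameter space pins the literature-sourced R1 Michaelis constant", {
  ps <- default_parameter_space(base_model())
  expect_false("R1.k_m" %in% ps$parameter)
  expect_equal(nrow(ps), 23L)
  expect_true(all(ps$lower < ps$upper))
  expect_equal(ps$upper / ps$start, rep(100, 23L))
})
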