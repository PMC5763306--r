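test_that("perturbation preserves per-sample value multisets and is seeded", {
  set.seed(61)
  ex <- matrix(rnorm(30 * 4), 30, 4,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  expect_identical(perturb_expression(ex, 0, 1), ex)
  p1 <- perturb_expression(ex, 1, 7)
  p2 <- perturb_expression(ex, 1, 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, perturb_expression(ex, 1, 8)))
  for (s in 1:4) expect_setequal(unname(p1[, s]), unname(ex[, s]))
  # partial level only touches the selected fraction of rows
  p3 <- perturb_expression(ex, 0.25, 3)
  moved <- rowSums(p3 != ex) > 0
  expect_lte(sum(moved), floor(0.25 * 30))
  expect_error(perturb_expression(ex, 1.5, 1), "level")
})

test_that("exchange-flux error follows the normalized mean square form", {
  sol <- structure(list(fluxes = c(e1 = 8, e2 = 3), objective_value = 1,
                        status = "optimal"), class = "FluxSolution")
  expect_equal(exchange_flux_error(sol, c(e1 = 10)), 0.04)
  expect_equal(exchange_flux_error(sol, c(e1 = 8, e2 = 3)), 0)
  # scale invariance of the normalization
  sol2 <- sol; sol2$fluxes <- sol$fluxes * 2
  expect_equal(exchange_flux_error(sol2, c(e1 = 20)),
               exchange_flux_error(sol, c(e1 = 10)))
  both <- exchange_flux_error(sol, c(e1 = 10), log10 = TRUE)
  expect_equal(unname(both["log10_error"]), log10(0.04))
  expect_error(exchange_flux_error(sol, numeric()), "nonempty")
  expect_error(exchange_flux_error(sol, c(zz = 1)), "missing")
})

test_that("level-zero robustness replicates all equal the unperturbed error", {
  bm <- make_diauxic_benchmark(seed = 1)
  theta <- 2
  ref <- simulate_fluxes(bm$model, bm$net, bm$lin_model, bm$context, theta,
                         sample = "glucose")
  v_obs <- ref$fluxes[bm$model$exchange]
  tab <- robustness_run(bm$model, bm$net, bm$lin_model, bm$context, theta,
                        v_obs, levels = 0, replicates = 4, seed = 5,
                        sample = "glucose")
  expect_equal(tab$error, rep(exchange_flux_error(ref, v_obs), 4))
  expect_equal(tab$error, rep(0, 4))
})

test_that("replicate errors depend on their seed stream, not on ordering", {
  bm <- make_diauxic_benchmark(seed = 1)
  theta <- 2
  ref <- simulate_fluxes(bm$model, bm$net, bm$lin_model, bm$context, theta,
                         sample = "glucose")
  v_obs <- ref$fluxes[bm$model$exchange]
  a <- robustness_run(bm$model, bm$net, bm$lin_model, bm$context, theta,
                      v_obs, levels = 0.5, replicates = 6, seed = 9,
                      sample = "glucose")
  b <- robustness_run(bm$model, bm$net, bm$lin_model, bm$context, theta,
                      v_obs, levels = 0.5, replicates = 6, seed = 9,
                      sample = "glucose")
  expect_equal(a$error, b$error)
})

test_that("influence-based prediction is more noise-robust than raw GPR input", {
  bm <- make_diauxic_benchmark(seed = 1)
  cal <- calibrate_theta(bm$model, bm$net, bm$lin_model, bm$context,
                         v_obs = 2.5, sample = "glucose")
  theta <- cal$theta_opt
  ex <- bm$model$exchange
  # each route is scored against its own unperturbed reference, so the
  # statistic isolates sensitivity to the permutation noise
  v_infl <- simulate_fluxes(bm$model, bm$net, bm$lin_model, bm$context,
                            theta, sample = "glucose")$fluxes[ex]
  v_raw <- simulate_fluxes(bm$model, bm$net, bm$lin_model, bm$context,
                           theta, sample = "glucose",
                           use_raw_expression = TRUE)$fluxes[ex]
  raw <- robustness_run(bm$model, bm$net, bm$lin_model, bm$context, theta,
                        v_raw, levels = 0.5, replicates = 100, seed = 11,
                        sample = "glucose", input = "raw")
  infl <- robustness_run(bm$model, bm$net, bm$lin_model, bm$context, theta,
                         v_infl, levels = 0.5, replicates = 100, seed = 11,
                         sample = "glucose", input = "influence")
  # paired sign check: influence beats raw replicate by replicate
  w <- stats::wilcox.test(infl$error, raw$error, paired = TRUE,
                          alternative = "less")
  expect_lt(w$p.value, 0.01)
  # raw input carries a heavy error tail that the regulon averaging removes
  expect_lt(mean(infl$error), mean(raw$error))
  expect_lt(stats::sd(infl$error), stats::sd(raw$error))
})
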