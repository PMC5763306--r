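test_that("softplus bound matches closed forms and is overflow/underflow safe", {
  expect_equal(softplus_bound(0, 0), log(2), tolerance = 1e-12)
  expect_equal(softplus_bound(2, 3), log(1 + exp(5)), tolerance = 1e-12)
  expect_equal(softplus_bound(2, 3), 5.0067153, tolerance = 1e-7)
  # deep negative arguments stay positive without underflowing to garbage
  lo <- softplus_bound(-50, 0)
  expect_gte(lo, 0)
  expect_lte(lo, 1e-20)
  # far past the overflow switch the linear asymptote takes over exactly
  expect_equal(softplus_bound(970, 30), 1000)
  expect_equal(softplus_bound(c(0, 2), c(0)), log(1 + exp(c(0, 2))))
})

test_that("bounds are tightened by min/max and never relax irreversibility", {
  S <- matrix(c(1, -1, -1), 1, 3,
              dimnames = list("A", c("in", "irrev", "rev")))
  m <- metabolic_model(S, lb = c(0, 0, -1000), ub = c(10, 1000, 1000),
                       objective = "irrev")
  cs <- structure(data.frame(reaction = c("irrev", "rev"),
                             gpr_value = c(0, 0), bound = c(2.3, 2.3)),
                  class = c("SoftplusConstraintSet", "data.frame"))
  out <- apply_constraints(m, cs)
  expect_equal(unname(out$ub["irrev"]), 2.3)
  expect_equal(unname(out$lb["irrev"]), 0)       # irreversibility kept
  expect_equal(unname(out$lb["rev"]), -2.3)      # mirrored magnitude bound
  expect_equal(unname(out$ub["rev"]), 2.3)
  # a looser bound than the model's own leaves it untouched
  cs2 <- cs; cs2$bound <- c(5000, 5000)
  out2 <- apply_constraints(m, cs2)
  expect_equal(unname(out2$ub["irrev"]), 1000)
  # input model is unmodified
  expect_equal(unname(m$ub["irrev"]), 1000)
})

test_that("FBA solves the toys and matches the vertex-enumeration oracle", {
  chain <- make_toy_model("chain")
  expect_equal(solve_fba(chain)$objective_value, 10)

  branch <- make_toy_model("branch")
  sol <- solve_fba(branch)
  expect_equal(sol$objective_value, oracle_fba_vertex(branch),
               tolerance = 1e-9)

  diauxic <- make_toy_model("diauxic")
  expect_equal(solve_fba(diauxic)$objective_value,
               oracle_fba_vertex(diauxic), tolerance = 1e-9)

  # closed uptake -> zero objective
  closed <- chain
  closed$ub["uptake"] <- 0
  expect_equal(solve_fba(closed)$objective_value, 0)

  # minimization sense
  expect_equal(solve_fba(chain, sense = "min")$objective_value, 0)
})

test_that("infeasible models report status instead of raising", {
  S <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("u", "c1", "b")))
  m <- metabolic_model(S, lb = c(5, 0, 0), ub = c(10, 2, 1000),
                       objective = "b")
  sol <- solve_fba(m)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("optimal solutions satisfy steady state and bounds within tolerance", {
  set.seed(51)
  for (kind in c("chain", "branch", "diauxic")) {
    m <- make_toy_model(kind)
    sol <- solve_fba(m)
    expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= m$lb - 1e-6))
    expect_true(all(sol$fluxes <= m$ub + 1e-6))
  }
})

test_that("ethanol-closed diauxic model grows on glucose only", {
  m <- make_toy_model("diauxic")
  m$lb["EX_eth"] <- 0
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes["RESPE"]), 0, tolerance = 1e-9)
})

test_that("regulatory constraints leave plain FBA as the theta upper limit", {
  bm <- make_diauxic_benchmark(seed = 1)
  plain <- solve_fba(bm$model)$objective_value
  thetas <- seq(-10, 10, length.out = 8)
  growth <- vapply(thetas, function(th)
    simulate_fluxes(bm$model, bm$net, bm$lin_model, bm$context, th,
                    sample = "glucose")$objective_value, numeric(1))
  expect_true(all(diff(growth) >= -1e-9))
  expect_true(all(growth <= plain + 1e-9))
  # a context defining no regulator of any modeled gene leaves every GPR
  # evaluation undefined, which reduces to plain FBA exactly
  empty_pred <- simulate_fluxes(bm$model, bm$net, bm$lin_model,
                                matrix(0, 1, 1,
                                       dimnames = list("unrelated", "s")),
                                theta = 0, context_type = "influence")
  cs <- attr(empty_pred, "constraints")
  expect_identical(nrow(cs), 0L)
  expect_equal(empty_pred$objective_value, plain)
})

test_that("fold-change report filters at two-fold and marks from-zero fluxes", {
  fa <- structure(list(fluxes = c(r1 = 2, r2 = 1, r3 = 0, r4 = 1),
                       objective_value = 1, status = "optimal"),
                  class = "FluxSolution")
  fb <- structure(list(fluxes = c(r1 = 8, r2 = 1.5, r3 = 0.7, r4 = 0),
                       objective_value = 1, status = "optimal"),
                  class = "FluxSolution")
  rep <- flux_fold_change(fa, fb, min_fold = 2)
  expect_setequal(rep$reaction, c("r1", "r3", "r4"))
  expect_equal(rep$log2_fc[rep$reaction == "r1"], 2)
  expect_identical(rep$note[rep$reaction == "r3"], "from_zero")
  expect_identical(rep$note[rep$reaction == "r4"], "to_zero")
})
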