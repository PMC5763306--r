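test_that("planted networks have the requested structure and are seeded", {
  net <- make_planted_network(5, 12, 2, seed = 3)
  truth <- attr(net, "truth")
  expect_equal(nrow(truth), 24L)
  expect_setequal(unique(truth$sign), c(1, -1))
  # every target keeps at least one activator
  acts <- tapply(truth$sign, truth$target, function(s) any(s > 0))
  expect_true(all(acts))
  expect_identical(attr(make_planted_network(5, 12, 2, seed = 3), "truth"),
                   truth)
  expect_false(identical(
    attr(make_planted_network(5, 12, 2, seed = 4), "truth"), truth))
  expect_error(make_planted_network(1, 5), "n_regs")
})

test_that("expression generators are pure functions of parameters and seed", {
  net <- make_planted_network(4, 8, 2, seed = 5)
  a <- make_expression(net, 20, noise_sd = 0.2, seed = 9)
  b <- make_expression(net, 20, noise_sd = 0.2, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, make_expression(net, 20, noise_sd = 0.2,
                                            seed = 10)))
  expect_setequal(rownames(a),
                  c(net$regulators, unique(attr(net, "truth")$target)))
})

test_that("planted regulator influence tracks the regulator state", {
  net <- make_planted_network(6, 30, 2, seed = 12)
  ex <- make_expression(net, 100, noise_sd = 0.2, seed = 13)
  infl <- compute_influence(net, ex)
  defined <- rownames(infl)[stats::complete.cases(infl)]
  expect_gt(length(defined), 0L)
  for (j in defined) {
    # targets combine several regulators through a min, so the regulator's
    # own state explains its influence only partially; the informative
    # signal is a clear positive association
    expect_gt(stats::cor(infl[j, ], ex[j, ]), 0.5)
    qs <- stats::quantile(ex[j, ], c(0.25, 0.75))
    expect_lt(mean(infl[j, ex[j, ] <= qs[1]]), 0)
    expect_gt(mean(infl[j, ex[j, ] >= qs[2]]),
              mean(infl[j, ex[j, ] <= qs[1]]))
  }
})

test_that("the discrete regime feeds mining with recoverable logic", {
  net <- make_planted_network(4, 10, 2, seed = 21)
  ex <- make_expression(net, 80, noise_sd = 0.2, regime = "discrete_logic",
                        seed = 22)
  truth <- attr(net, "truth")
  disc <- discretize(ex, 1, scale = "sd")
  g <- truth$target[1]
  cands <- mine_coregulators(disc, g, net$regulators, max_set_size = 2,
                             min_support = 0.5)
  keys <- vapply(cands, candidate_key, character(1))
  tr <- truth[truth$target == g, ]
  want <- paste(paste(sort(tr$regulator[tr$sign > 0]), collapse = ","), "|",
                paste(sort(tr$regulator[tr$sign < 0]), collapse = ","))
  expect_true(want %in% keys)
})

test_that("baseline offsets shift genes additively and consistently", {
  net <- make_planted_network(3, 6, 2, seed = 31)
  base <- stats::setNames(rnorm(9, sd = 2),
                          c(paste0("R", 1:3), paste0("G", 1:6)))
  plain <- make_expression(net, 15, noise_sd = 0.1, seed = 32)
  shifted <- make_expression(net, 15, noise_sd = 0.1, seed = 32,
                             baselines = base)
  expect_equal(shifted, plain + base[rownames(plain)])
})

test_that("the diauxic benchmark assembles a coherent study", {
  bm <- make_diauxic_benchmark(seed = 2)
  expect_s3_class(bm$model, "MetabolicModel")
  expect_setequal(colnames(bm$context), c("glucose", "ethanol"))
  # every model gene the GPRs need is modeled by the predictor
  expect_true(all(model_genes(bm$model) %in% names(bm$lin_model$genes)))
  # influence is defined for both regulators in both contexts
  infl <- compute_influence(bm$net, bm$context)
  expect_false(anyNA(infl))
  # the glucose context pushes fermentation up and respiration down
  pred <- predict(bm$lin_model, infl)
  expect_gt(pred["FERM1", "glucose"], pred["FERM1", "ethanol"])
  expect_lt(pred["RESP1", "glucose"], pred["RESP1", "ethanol"])
})
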