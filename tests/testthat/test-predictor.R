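one_reg_net <- function() {
  regulatory_network(data.frame(regulator = "J", target = "g1", sign = 1))
}

test_that("noise-free single-regulator data is identified exactly", {
  set.seed(41)
  infl <- matrix(rnorm(10), 1, 10, dimnames = list("J", paste0("s", 1:10)))
  ex <- matrix(2 * infl, 1, 10, dimnames = list("g1", colnames(infl)))
  fm <- fit_influence_model(one_reg_net(), infl, ex)
  expect_equal(unname(fm$genes$g1$beta), 2, tolerance = 1e-10)
})

test_that("two-regulator fixture matches the normal-equations oracle", {
  set.seed(42)
  net <- regulatory_network(data.frame(regulator = c("J1", "J2"),
                                       target = "g1", sign = c(1, -1)))
  infl <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("J1", "J2"), paste0("s", 1:6)))
  y <- 1.3 * infl["J1", ] - 0.4 * infl["J2", ] + rnorm(6, sd = 0.1)
  ex <- matrix(y, 1, 6, dimnames = list("g1", colnames(infl)))
  fm <- fit_influence_model(net, infl, ex)
  expect_equal(unname(fm$genes$g1$beta), oracle_ols(t(infl), y),
               tolerance = 1e-10)
})

test_that("genes without regulators or samples are skipped and reported", {
  net <- one_reg_net()
  infl <- matrix(rnorm(5), 1, 5, dimnames = list("J", paste0("s", 1:5)))
  ex <- matrix(rnorm(10), 2, 5,
               dimnames = list(c("g1", "orphan"), colnames(infl)))
  fm <- fit_influence_model(net, infl, ex)
  expect_named(fm$genes, "g1")
  expect_true("orphan" %in% fm$skipped$gene)
  expect_match(fm$skipped$reason[fm$skipped$gene == "orphan"], "no regulators")

  # too few samples: 1 covariate needs >= 2 usable samples
  fm2 <- fit_influence_model(net, infl[, 1, drop = FALSE],
                             ex[, 1, drop = FALSE])
  expect_true("g1" %in% fm2$skipped$gene)
})

test_that("in-sample predictions reproduce fitted values and zero influences give zero", {
  set.seed(43)
  net <- regulatory_network(data.frame(
    regulator = rep(c("J1", "J2"), each = 2),
    target = rep(c("g1", "g2"), 2), sign = c(1, 1, -1, 1)))
  infl <- matrix(rnorm(20), 2, 10,
                 dimnames = list(c("J1", "J2"), paste0("s", 1:10)))
  ex <- matrix(rnorm(20), 2, 10, dimnames = list(c("g1", "g2"),
                                                 colnames(infl)))
  fm <- fit_influence_model(net, infl, ex)
  pred <- predict(fm, infl)
  for (g in c("g1", "g2")) {
    m <- fm$genes[[g]]
    expect_equal(pred[g, ], t(infl[m$regulators, , drop = FALSE]) %*% m$beta
                 |> as.vector() |> stats::setNames(colnames(infl)))
  }
  zero <- matrix(0, 2, 1, dimnames = list(c("J1", "J2"), "z"))
  expect_equal(unname(predict(fm, zero)[, "z"]), c(0, 0))
})

test_that("undefined context influence marks the prediction missing", {
  net <- one_reg_net()
  infl <- matrix(rnorm(5), 1, 5, dimnames = list("J", paste0("s", 1:5)))
  ex <- matrix(2 * infl, 1, 5, dimnames = list("g1", colnames(infl)))
  fm <- fit_influence_model(net, infl, ex)
  ctx <- matrix(c(1, NA), 1, 2, dimnames = list("J", c("c1", "c2")))
  pred <- predict(fm, ctx)
  expect_equal(unname(pred["g1", "c1"]), 2)
  expect_true(is.na(pred["g1", "c2"]))
})

test_that("held-out prediction is exact when expression is linear in influence", {
  set.seed(45)
  regs <- paste0("J", 1:3)
  genes <- paste0("g", 1:10)
  edges <- do.call(rbind, lapply(genes, function(g)
    data.frame(regulator = sample(regs, 2), target = g, sign = c(1, -1))))
  net <- regulatory_network(edges)
  infl <- matrix(rnorm(3 * 60), 3, 60,
                 dimnames = list(regs, paste0("s", 1:60)))
  B <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(genes, regs))
  # zero out coefficients for regulators not in Pa(g)
  for (g in genes) B[g, setdiff(regs, regulators_of(net, g))] <- 0
  ex <- B %*% infl
  train <- paste0("s", 1:40)
  held <- paste0("s", 41:60)
  fm <- fit_influence_model(net, infl[, train], ex[, train])
  pred <- predict(fm, infl[, held])
  expect_setequal(rownames(pred), genes)
  rmse <- sqrt(mean((pred[genes, ] - ex[genes, held])^2))
  expect_lt(rmse, 1e-8)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  net <- regulatory_network(data.frame(regulator = c("J1", "J2"),
                                       target = "g1", sign = 1))
  base <- rnorm(8)
  infl <- rbind(J1 = base, J2 = base)  # perfectly collinear
  colnames(infl) <- paste0("s", 1:8)
  ex <- matrix(3 * base, 1, 8, dimnames = list("g1", colnames(infl)))
  expect_warning(fm <- fit_influence_model(net, infl, ex), "minimum-norm")
  expect_equal(unname(fm$genes$g1$beta), c(1.5, 1.5), tolerance = 1e-8)
})

test_that("model JSON serialization round-trips", {
  set.seed(46)
  net <- make_planted_network(3, 5, 2, seed = 47)
  ex <- make_expression(net, 30, noise_sd = 0.1, seed = 48)
  infl <- compute_influence(net, ex)
  fm <- fit_influence_model(net, infl, ex)
  f <- withr::local_tempfile(fileext = ".json")
  write_influence_model(fm, f)
  back <- read_influence_model(f)
  expect_identical(names(back$genes), names(fm$genes))
  for (g in names(fm$genes)) {
    expect_equal(back$genes[[g]]$beta, fm$genes[[g]]$beta)
    expect_identical(back$genes[[g]]$regulators, fm$genes[[g]]$regulators)
  }
  expect_equal(predict(back, infl), predict(fm, infl))
})
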