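test_that("discretization centers per gene and applies the threshold", {
  ex <- rbind(g1 = c(1.2, -0.5, -0.7), g2 = c(4, 4, 4))
  colnames(ex) <- paste0("s", 1:3)
  # g1 mean 0 -> values unchanged by centering
  d <- discretize(ex, 1, scale = "absolute")
  expect_identical(d["g1", ], c(s1 = 1L, s2 = 0L, s3 = 0L))
  # constant gene centers to zero everywhere
  expect_identical(unname(d["g2", ]), c(0L, 0L, 0L))
  expect_error(discretize(ex, 0), "positive")
  expect_error(discretize(ex, -1), "positive")
})

test_that("mining recovers copies, sign flips and AND combinations", {
  set.seed(3)
  n <- 40
  r1 <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
  r2 <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
  disc <- rbind(R1 = r1, R2 = r2, tc = r1, tf = -r2, ta = pmin(r1, r2))
  colnames(disc) <- paste0("s", 1:n)

  keys <- function(cands) vapply(cands, candidate_key, character(1))

  cc <- mine_coregulators(disc, "tc", c("R1", "R2"), 2, min_support = 1)
  expect_true("R1 | " %in% keys(cc))
  cf <- mine_coregulators(disc, "tf", c("R1", "R2"), 2, min_support = 1)
  expect_true(" | R2" %in% keys(cf))
  ca <- mine_coregulators(disc, "ta", c("R1", "R2"), 2, min_support = 1)
  expect_true("R1,R2 | " %in% keys(ca))

  # exhaustive-enumeration agreement (both directions) at several supports
  for (tgt in c("tc", "tf", "ta")) {
    for (ms in c(0.5, 0.8, 1)) {
      got <- sort(keys(mine_coregulators(disc, tgt, c("R1", "R2"), 2, ms)))
      want <- sort(unique(oracle_mine_exhaustive(disc, tgt, c("R1", "R2"),
                                                 2, ms)))
      expect_identical(got, want)
    }
  }
})

test_that("raising min_support never adds candidates", {
  set.seed(9)
  disc <- matrix(sample(c(-1L, 0L, 1L), 5 * 30, replace = TRUE), 5, 30,
                 dimnames = list(c("R1", "R2", "R3", "t1", "t2"),
                                 paste0("s", 1:30)))
  regs <- c("R1", "R2", "R3")
  prev <- NULL
  for (ms in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- vapply(mine_coregulators(disc, "t1", regs, 2, ms),
                  candidate_key, character(1))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(mine_coregulators(disc, "R1", regs, 2, 0.5), "target")
  expect_error(mine_coregulators(disc, "t1", regs, 0, 0.5), "max_set_size")
})

test_that("candidate scoring matches the normal-equations R^2", {
  set.seed(21)
  ex <- matrix(rnorm(4 * 5), 4, 5,
               dimnames = list(c("R1", "R2", "t", "u"), paste0("s", 1:5)))
  # 5-sample fixture against the closed-form OLS oracle
  X <- cbind(1, act = pmin(ex["R1", ], ex["R2", ]))
  beta <- oracle_ols(X, ex["t", ])
  res <- ex["t", ] - as.vector(X %*% beta)
  r2_oracle <- 1 - sum(res^2) / sum((ex["t", ] - mean(ex["t", ]))^2)
  expect_equal(score_local_grn(ex, "t", c("R1", "R2")),
               min(max(r2_oracle, 0), 1), tolerance = 1e-10)

  # exact reconstruction scores 1
  ex["t", ] <- pmin(ex["R1", ], ex["R2", ])
  expect_equal(score_local_grn(ex, "t", c("R1", "R2")), 1)

  # independent noise stays low at n = 50 over several seeds
  for (s in 1:5) {
    set.seed(100 + s)
    exn <- matrix(rnorm(3 * 50), 3, 50,
                  dimnames = list(c("R1", "R2", "t"), paste0("s", 1:50)))
    expect_lt(score_local_grn(exn, "t", "R1", "R2"), 0.2)
  }

  expect_error(score_local_grn(ex[, 1:2], "t", c("R1", "R2")),
               "fewer samples")
})

test_that("network inference is deterministic and respects degenerate evidence", {
  net <- make_planted_network(4, 6, 2, seed = 5)
  ex <- make_expression(net, 60, noise_sd = 0.2, regime = "discrete_logic",
                        seed = 6)
  regs <- paste0("R", 1:4)
  a <- infer_network(ex, regs)
  b <- infer_network(ex, regs)
  expect_identical(a$edges, b$edges)

  # zero regulators -> empty network
  empty <- infer_network(ex, character())
  expect_identical(nrow(empty$edges), 0L)

  # evidence weight 1 with score 1 on a true edge forces that selection:
  # the target is a noisy copy of R1, so both {R1} and supersets are mined,
  # and only the {R1} candidate averages evidence 1
  set.seed(77)
  r <- matrix(rnorm(2 * 50), 2, 50,
              dimnames = list(c("R1", "R2"), paste0("s", 1:50)))
  ex2 <- rbind(r, t1 = r["R1", ] + rnorm(50, sd = 0.1))
  ev <- data.frame(regulator = "R1", target = "t1", score = 1)
  forced <- infer_network(ex2, c("R1", "R2"), targets = "t1",
                          evidence = ev, evidence_weight = 1)
  sel <- forced$edges[forced$edges$target == "t1", ]
  expect_identical(sel$regulator, "R1")
  expect_identical(sel$sign, 1)
})
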