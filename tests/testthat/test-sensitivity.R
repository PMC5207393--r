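test_that("Latin hypercube samples stratify each log-uniform margin", {
  des <- sensitivity_design(c("a", "b"), nominal = c(a = 1, b = 0.05),
                            n = 10, seed = 4)
  x <- lhs_sample(des)
  expect_identical(dim(x), c(10L, 2L))
  for (j in 1:2) {
    nom <- des$nominal[[j]]
    u <- (log(x[, j]) - log(nom / 10)) / log(100)
    expect_true(all(u >= 0 & u <= 1))
    # exactly one sample per decile stratum
    expect_identical(sort(findInterval(u, seq(0, 1, 0.1),
                                       rightmost.closed = TRUE)), 1:10)
  }
})

test_that("large log-uniform samples match the target distribution", {
  des <- sensitivity_design("a", nominal = c(a = 2), n = 1e4, seed = 9)
  x <- lhs_sample(des)[, 1]
  expect_gte(min(x), 0.2)
  expect_lte(max(x), 20)
  u <- (log(x) - log(0.2)) / log(100)
  expect_lt(suppressWarnings(stats::ks.test(u, "punif")$statistic), 0.02)
})

test_that("the LHS draw is reproducible bit-for-bit from its seed", {
  des <- sensitivity_design(c("a", "b"), nominal = c(a = 1, b = 2), n = 50,
                            seed = 123)
  expect_identical(lhs_sample(des), lhs_sample(des))
})

test_that("PRCC recovers perfect and monotone dependences", {
  set.seed(11)
  n <- 500
  x <- cbind(x1 = runif(n), x2 = runif(n, 0.5, 2), x3 = runif(n))
  res <- prcc(x, x[, "x1"])
  expect_gt(res$prcc[res$parameter == "x1"], 0.99)
  expect_lt(max(abs(res$prcc[res$parameter != "x1"])), 0.1)
  # monotone two-input surface with a dummy parameter
  y <- exp(x[, "x1"]) - 1 / x[, "x2"]
  res2 <- prcc(x, y)
  expect_gt(res2$prcc[res2$parameter == "x1"], 0)
  expect_gt(res2$prcc[res2$parameter == "x2"], 0)
  expect_lt(abs(res2$prcc[res2$parameter == "x3"]),
            min(res2$prcc[res2$parameter != "x3"]))
})

test_that("PRCC equals the explicit residualization oracle", {
  set.seed(21)
  x <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("p", 1:4)))
  y <- 2 * x[, 1] - x[, 3] + rnorm(50, 0, 0.1)
  got <- prcc(x, y)
  rx <- apply(x, 2, rank)
  ry <- rank(y)
  for (j in 1:4) {
    others <- rx[, -j]
    ex <- stats::residuals(stats::lm(rx[, j] ~ others))
    ey <- stats::residuals(stats::lm(ry ~ others))
    expect_equal(got$prcc[j], stats::cor(ex, ey), tolerance = 1e-10)
  }
})

test_that("PRCC is invariant under monotone transforms of the output", {
  set.seed(31)
  x <- matrix(runif(300), 100, 3, dimnames = list(NULL, paste0("p", 1:3)))
  y <- x[, 1]^2 + 0.2 * x[, 2]
  a <- prcc(x, y)
  b <- prcc(x, exp(3 * y))
  expect_equal(a$prcc, b$prcc, tolerance = 1e-12)
})

test_that("degenerate columns and degenerate outputs are flagged", {
  set.seed(41)
  x <- cbind(p1 = runif(30), p2 = rep(2, 30))
  res <- prcc(x, x[, 1])
  expect_true(res$degenerate[res$parameter == "p2"])
  expect_true(is.na(res$prcc[res$parameter == "p2"]))
  res2 <- prcc(cbind(p1 = runif(30), p2 = runif(30)), rep(1, 30))
  expect_true(all(res2$degenerate))
  expect_error(prcc(x[1:3, ], x[1:3, 1]), "n > p")
})

test_that("scenario designs carry the documented parameter subsets", {
  d <- sensitivity_scenario("psmad_tgfb", n = 50, seed = 2)
  expect_true(all(c("kf75", "kf79", "kf73", "vm34") %in% d$parameters))
  expect_identical(d$output$species, "pS2S4_n")
  d2 <- sensitivity_scenario("hif_dimer_hypoxia", n = 50, seed = 2)
  expect_true(all(c("kf4", "kf8", "kf19", "vm1") %in% d2$parameters))
  expect_identical(d2$output$species, "HIF1d_n")
})
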