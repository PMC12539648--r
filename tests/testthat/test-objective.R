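# Objective function, design, surrogate and the SMF optimizer.

test_that("normalized mean squared error and combined objective", {
  expect_equal(normalized_mse(c(1, 2), c(1, 2), 1), 0)
  expect_equal(normalized_mse(2, 1, 1), 1)
  expect_equal(normalized_mse(2, 1, 2), normalized_mse(2, 1, 1) / 4)
  expect_error(normalized_mse(numeric(0), numeric(0), 1))
  expect_error(normalized_mse(1, 1, 0))
  expect_equal(combined_objective(0, 0), 0)
  expect_equal(combined_objective(0.2, 0.4), 0.3)
  expect_equal(combined_objective(0.4, 0.2), combined_objective(0.2, 0.4))
  expect_error(combined_objective(-1, 0))
})

test_that("Latin hypercube design: stratification, bounds and determinism", {
  bounds <- rbind(c(-2, 10), c(4, 30))
  X <- lhs_sample(bounds, 4, seed = 11)
  expect_equal(dim(X), c(4, 2))
  for (j in 1:2) {
    expect_true(all(X[, j] >= bounds[1, j] & X[, j] <= bounds[2, j]))
    stratum <- floor(4 * (X[, j] - bounds[1, j]) /
                       (bounds[2, j] - bounds[1, j]))
    expect_setequal(stratum, 0:3) # one point per equal-probability stratum
  }
  expect_identical(X, lhs_sample(bounds, 4, seed = 11))
  expect_false(identical(X, lhs_sample(bounds, 4, seed = 12)))
  expect_error(lhs_sample(rbind(c(0, 0), c(1, 0)), 4, 1), "degenerate")
})

test_that("kriging surrogate interpolates and respects symmetry", {
  X <- matrix(c(0.1, 0.2, 0.55, 0.8, 0.35, 0.9,
                0.7, 0.15, 0.4, 0.6, 0.85, 0.3), ncol = 2)
  y <- sin(5 * X[, 1]) + X[, 2]^2
  sur <- kriging_surrogate(X, y)
  expect_equal(predict(sur, X), y, tolerance = 1e-6)
  # constant training values give a constant surface
  surc <- kriging_surrogate(X, rep(2.5, nrow(X)))
  probe <- matrix(runif(10), ncol = 2)
  expect_equal(predict(surc, probe), rep(2.5, 5), tolerance = 1e-6)
  # two symmetric 1-D points: the midpoint prediction is their mean
  sur1 <- kriging_surrogate(matrix(c(0.2, 0.8)), c(1, 3),
                            bounds = rbind(0, 1))
  expect_equal(predict(sur1, matrix(0.5)), 2, tolerance = 1e-8)
  expect_error(kriging_surrogate(matrix(c(0.2, 0.2)), c(1, 2)),
               "conflicting")
})

test_that("SMF optimizer solves box-constrained analytic problems", {
  bounds <- rbind(c(0, 0), c(1, 1))
  # convex quadratic with interior minimum
  f <- function(x) sum((x - c(0.37, 0.62))^2)
  res <- smf_optimize(f, bounds, seed = 3, budget = 160)
  expect_lt(max(abs(res$A_star - c(0.37, 0.62))), 1e-2)
  expect_equal(res$phi_star, min(res$evaluations$phi))
  # incumbent sequence is non-increasing
  inc <- cummin(res$evaluations$phi)
  expect_true(all(diff(inc) <= 0))
  # linear objective: minimizer on the box boundary
  g <- function(x) 2 * x[1] - 3 * x[2]
  res2 <- smf_optimize(g, bounds, seed = 5, budget = 120)
  expect_lt(abs(res2$A_star[1] - 0), 5e-3)
  expect_lt(abs(res2$A_star[2] - 1), 5e-3)
  # objective failures are tolerated
  h <- function(x) if (x[1] < 0.5) stop("fail") else sum(x^2)
  res3 <- smf_optimize(h, bounds, seed = 7, budget = 60)
  expect_true(is.finite(res3$phi_star))
  expect_gte(res3$A_star[1], 0.5 - 0.05)
})

test_that("SMF runs are deterministic for a fixed seed", {
  bounds <- rbind(c(-1, -1), c(1, 1))
  f <- function(x) (x[1] - 0.2)^2 + 2 * (x[2] + 0.4)^2 + 0.1 * sin(8 * x[1])
  r1 <- smf_optimize(f, bounds, seed = 42, budget = 80)
  r2 <- smf_optimize(f, bounds, seed = 42, budget = 80)
  expect_identical(r1$A_star, r2$A_star)
  expect_identical(r1$evaluations, r2$evaluations)
})
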