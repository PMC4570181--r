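test_that("shrinkage operator satisfies its closed-form identities", {
  expect_equal(shrink(5, 2), 3)
  expect_equal(shrink(-5, 2), -3)
  expect_equal(shrink(1, 2), 0)
  expect_equal(shrink(0, 2), 0)
  # elementwise on vectors, odd symmetry
  x <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(shrink(x, 1), c(-2, 0, 0, 0, 2))
  expect_equal(shrink(-x, 1), -shrink(x, 1))
  expect_error(shrink(1, -1))
})

test_that("objective value evaluates mu*||S||_1 + 0.5*||AS - Phi||^2", {
  phi <- c(1, 2, 3)
  expect_equal(objective_value(diag(3), phi, numeric(3), 1), 0.5 * 14)
  expect_equal(objective_value(diag(2), c(0, 0), c(1, -1), 2), 5)
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4); s <- rnorm(4); b <- rnorm(3)
  expect_equal(objective_value(A, b, s, 0),
               0.5 * sum((A %*% s - b)^2))
})

test_that("hand-iterated 1x1 worked example converges to the exact solution", {
  # A = [2], Phi = [2], mu = 1, delta = 0.25:
  # v1 = 4, S1 = 0.25 * shrink(4, 1) = 0.75
  # v2 = 4 + 2*(2 - 1.5) = 5, S2 = 0.25 * shrink(5, 1) = 1.0
  # v3 = 5, S3 = 1.0  -> relative change 0, converged
  fit <- lbsr_solve(matrix(2, 1, 1), 2,
                    solver_config(mu = 1, delta = 0.25))
  expect_equal(fit$iterations, 3L)
  expect_true(fit$converged)
  expect_equal(as.numeric(fit$S), 1.0)
  expect_equal(as.numeric(fit$v_final), 5)
  expect_equal(length(fit$residual_history), 3L)
  expect_equal(length(fit$rel_change_history), 3L)
})

test_that("zero measurements yield the zero reconstruction immediately", {
  A <- matrix(rnorm(20, 0, 1), 4, 5)
  fit <- lbsr_solve(A, numeric(4), solver_config(mu = 1, delta = 0.1))
  expect_equal(fit$S, numeric(5))
  fit2 <- l1sb_solve(A, numeric(4), solver_config(mu = 1, delta = 0.1))
  expect_equal(fit2$S, numeric(5))
})

test_that("each LBSR iterate is the prox of the l1 norm at delta*v", {
  # S^{k+1} = delta * shrink(v^{k+1}, mu) minimizes
  # mu*|s| + (1/(2 delta)) (s - delta v)^2 per coordinate; verify the
  # stored final iterate against per-coordinate numerical minimization
  set.seed(42)
  for (case in 1:50) {
    m <- sample(3:6, 1); n <- sample(3:8, 1)
    A <- matrix(rnorm(m * n), m, n)
    phi <- rnorm(m)
    mu <- runif(1, 0.05, 2)
    delta <- 1 / spectral_norm(A)^2 * runif(1, 0.3, 1)
    fit <- lbsr_solve(A, phi, solver_config(mu = mu, delta = delta,
                                            max_iter = sample(2:30, 1),
                                            epsilon = 1e-9))
    v <- fit$v_final
    for (j in seq_len(n)) {
      f <- function(s) mu * abs(s) + (s - delta * v[j])^2 / (2 * delta)
      opt <- stats::optimize(f, interval = delta * abs(v[j]) * c(-2, 2) +
                               c(-1, 1))
      expect_equal(fit$S[j], opt$minimum, tolerance = 1e-4)
    }
  }
})

test_that("LBSR recovers a sparse source from a random Gaussian system", {
  inst <- gaussian_instance(20, 50, 3, seed = 7)
  delta <- 1 / spectral_norm(inst$A)^2
  mu <- 10 * max(abs(inst$s_true)) / delta
  fit <- lbsr_solve(inst$A, inst$phi,
                    solver_config(mu = mu, delta = delta, epsilon = 1e-7,
                                  max_iter = 20000))
  expect_identical(which(fit$S != 0), which(inst$s_true != 0))
  expect_lt(sqrt(sum((fit$S - inst$s_true)^2)) / sqrt(sum(inst$s_true^2)),
            1e-2)
})

test_that("LBSR drives the residual to zero on consistent full-row-rank systems", {
  set.seed(11)
  for (case in 1:3) {
    A <- matrix(rnorm(6 * 15), 6, 15)
    s0 <- numeric(15); s0[sample(15, 2)] <- c(1, -2)
    phi <- as.numeric(A %*% s0)
    delta <- 1 / spectral_norm(A)^2
    fit <- lbsr_solve(A, phi, solver_config(mu = 1, delta = delta,
                                            epsilon = 1e-12,
                                            max_iter = 50000))
    expect_lt(utils::tail(fit$residual_history, 1),
              1e-6 * sqrt(sum(phi^2)))
  }
})

test_that("stopping rule fires at the first relative change <= epsilon", {
  set.seed(3)
  A <- matrix(rnorm(40), 5, 8)
  phi <- rnorm(5)
  delta <- 1 / spectral_norm(A)^2
  fit <- lbsr_solve(A, phi, solver_config(mu = 0.1, delta = delta,
                                          epsilon = 1e-3, max_iter = 5000))
  rel <- fit$rel_change_history
  k <- fit$iterations
  if (fit$converged) {
    expect_lte(rel[k], 1e-3)
    earlier <- rel[seq_len(k - 1)]
    expect_true(all(is.na(earlier) | earlier > 1e-3))
  }
})

test_that("divergent step size aborts with a diagnostic", {
  set.seed(5)
  A <- matrix(rnorm(40), 5, 8)
  phi <- rnorm(5)
  expect_error(
    lbsr_solve(A, phi, solver_config(mu = 1e-6, delta = 1e6,
                                     max_iter = 5000)),
    "delta|non-finite")
})

test_that("default parameters follow the documented formulas", {
  expect_equal(default_parameters(matrix(2, 1, 1), 1)$delta, 0.25)
  # orthonormal rows: sigma_max = 1 so delta = 1
  q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:4]
  expect_equal(default_parameters(t(q), rnorm(4))$delta, 1,
               tolerance = 1e-6)
  A <- matrix(c(1, 2, -3, 4), 2, 2)
  phi <- c(1, -1)
  expect_equal(default_parameters(A, phi, method = "l1sb")$mu,
               0.01 * max(abs(crossprod(A, phi))))
  # Bregman-scale rule: mu*delta tracks the least-squares solution scale,
  # so it is invariant to rescaling the data and equivariant in A
  cfg <- default_parameters(A, phi)
  s_ls <- solve(A, phi)
  expect_equal(cfg$mu * cfg$delta, 5 * max(abs(s_ls)), tolerance = 1e-6)
  cfg2 <- default_parameters(A, 10 * phi)
  expect_equal(cfg2$mu, 10 * cfg$mu, tolerance = 1e-6)
  expect_warning(cfg <- default_parameters(diag(2), c(0, 0)), "degenerate")
  expect_gt(cfg$mu, 0)
  expect_error(default_parameters(matrix(0, 2, 2), c(1, 1)), "zero")
})

test_that("l2-CG matches closed forms and a dense normal-equation solve", {
  phi <- c(3, -1, 2)
  expect_equal(l2cg_solve(diag(3), phi, lambda = 0)$S, phi)
  expect_equal(l2cg_solve(diag(3), phi, lambda = 1)$S, phi / 2)
  set.seed(9)
  for (case in 1:5) {
    A <- matrix(rnorm(100), 10, 10) + diag(10)
    phi <- rnorm(10)
    dense <- solve(crossprod(A) + 0.1 * diag(10), crossprod(A, phi))
    fit <- l2cg_solve(A, phi, lambda = 0.1, cg_tol = 1e-12)
    expect_lt(sqrt(sum((fit$S - dense)^2)) / sqrt(sum(dense^2)), 1e-8)
  }
})

test_that("Split Bregman matches the closed-form prox when A = I", {
  set.seed(13)
  phi <- rnorm(6, sd = 2)
  mu <- 0.7
  fit <- l1sb_solve(diag(6), phi,
                    solver_config(mu = mu, delta = 1, epsilon = 1e-10,
                                  max_iter = 2000))
  expect_equal(fit$S, shrink(phi, mu), tolerance = 1e-6)
})

test_that("Split Bregman beats the l2 solution on the l1 objective", {
  set.seed(17)
  A <- matrix(rnorm(8 * 12), 8, 12)
  s0 <- numeric(12); s0[c(2, 9)] <- c(1, 2)
  phi <- as.numeric(A %*% s0) + rnorm(8, sd = 0.01)
  mu <- 0.1
  delta <- 1 / spectral_norm(A)^2
  sb <- l1sb_solve(A, phi, solver_config(mu = mu, delta = delta,
                                         epsilon = 1e-8, max_iter = 3000))
  l2 <- l2cg_solve(A, phi, lambda = 1e-8)
  expect_lte(objective_value(A, phi, sb$S, mu),
             objective_value(A, phi, l2$S, mu) + 1e-8)
})

test_that("Split Bregman agrees with a brute-force grid minimizer on tiny problems", {
  set.seed(23)
  A <- matrix(rnorm(6), 3, 2)
  s0 <- c(1.2, 0)
  phi <- as.numeric(A %*% s0)
  mu <- 0.3
  fit <- l1sb_solve(A, phi, solver_config(mu = mu, delta = 1,
                                          epsilon = 1e-10, max_iter = 3000))
  # dense grid refinement around the origin-to-truth box
  obj <- function(s) objective_value(A, phi, s, mu)
  lo <- c(-2, -2); hi <- c(2, 2)
  best <- c(0, 0)
  for (pass in 1:4) {
    g1 <- seq(lo[1], hi[1], length.out = 21)
    g2 <- seq(lo[2], hi[2], length.out = 21)
    vals <- outer(g1, g2, Vectorize(function(a, b) obj(c(a, b))))
    ij <- arrayInd(which.min(vals), dim(vals))
    best <- c(g1[ij[1]], g2[ij[2]])
    h <- (hi - lo) / 10
    lo <- best - h; hi <- best + h
  }
  expect_lt(max(abs(fit$S - best)), 5e-3)
  expect_lte(obj(fit$S), obj(best) + 1e-6)
})

test_that("reconstruct() dispatches and returns a well-formed fit object", {
  inst <- gaussian_instance(10, 20, 2, seed = 31)
  for (method in c("lbsr", "l2cg", "l1sb")) {
    fit <- reconstruct(inst$A, inst$phi, method = method)
    expect_s3_class(fit, "otrecon")
    expect_identical(fit$method, method)
    expect_length(fit$S, 20)
    expect_true(is.finite(fit$runtime_s))
    s <- summary(fit)
    expect_s3_class(s, "summary.otrecon")
    expect_identical(s$n, 20L)
    r <- residuals(fit, inst$A, inst$phi)
    expect_length(r, 10)
  }
  expect_output(print(reconstruct(inst$A, inst$phi)), "otrecon fit")
})
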