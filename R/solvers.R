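#' Soft-thresholding (shrinkage) operator
#'
#' `shrink(x, gamma) = sign(x) * max(|x| - gamma, 0)`, applied elementwise;
#' the proximal operator of the l1 norm. `shrink(0, gamma) = 0`.
#'
#' @param x numeric vector.
#' @param gamma nonnegative threshold.
#' @return numeric vector of the same length.
#' @export
shrink <- function(x, gamma) {
  stopifnot(gamma >= 0)
  sign(x) * pmax(abs(x) - gamma, 0)
}

#' Value of the l1-regularized least-squares objective
#'
#' `J_mu(S) = mu * ||S||_1 + 1/2 * ||A S - Phi||_2^2`, the convex objective
#' whose minimizer balances data fidelity against sparsity of the
#' reconstructed source.
#'
#' @param A m x n matrix (or `sensitivity`).
#' @param phi length-m measurement vector (or `measurement_set`).
#' @param s length-n source vector.
#' @param mu nonnegative regularization weight.
#' @return scalar objective value.
#' @export
objective_value <- function(A, phi, s, mu) {
  A <- as_matrix_A(A); phi <- as_phi(phi)
  r <- as.numeric(A %*% s) - phi
  mu * sum(abs(s)) + 0.5 * sum(r^2)
}

as_matrix_A <- function(A) if (inherits(A, "sensitivity")) A$entries else A
as_phi <- function(phi) if (inherits(phi, "measurement_set")) phi$values else phi

#' Solver configuration
#'
#' @param mu positive l1 regularization weight.
#' @param delta positive step size of the linearized Bregman iteration (and
#'   the shrinkage scaling of the Split Bregman auxiliary update).
#' @param epsilon relative-change stopping tolerance in (0, 1): iteration
#'   stops at the first k with `||S^{k+1} - S^k|| / ||S^k|| <= epsilon`
#'   (the test is skipped while `||S^k|| = 0`).
#' @param max_iter iteration cap (>= 1).
#' @param nonneg project iterates onto the nonnegative orthant after
#'   shrinkage (off by default: source density is physically nonnegative,
#'   but the plain algorithm does not enforce it).
#' @return a `solver_config` list.
#' @export
solver_config <- function(mu, delta, epsilon = 1e-3, max_iter = 5000L,
                          nonneg = FALSE) {
  stopifnot(mu > 0, delta > 0, epsilon > 0, epsilon < 1, max_iter >= 1)
  structure(list(mu = mu, delta = delta, epsilon = epsilon,
                 max_iter = as.integer(max_iter), nonneg = isTRUE(nonneg)),
            class = "solver_config")
}

#' Default solver parameters derived from the problem data
#'
#' The step size is `delta = 1 / sigma_max(A)^2` (largest singular value
#' estimated by a fixed 100-step power iteration on `A^T A` from a
#' deterministic start vector), which guarantees non-expansive linearized
#' Bregman updates.
#'
#' The regularization weight depends on how the solver uses `mu`:
#' * `method = "lbsr"`: the linearized Bregman iteration converges (for
#'   consistent data) to the solution of
#'   `min mu ||S||_1 + 1/(2 delta) ||S||_2^2  s.t.  A S = Phi`, so `mu`
#'   must dominate the scale of `S / delta` for the l1 term to matter.
#'   The default is `mu = 5 * max|S~| / delta`, where `S~` is a cheap
#'   scale probe of the least-squares solution (20 unregularized conjugate
#'   gradient steps on the normal equations) — scale-invariant in both
#'   `A` and `Phi`.
#' * `method = "l1sb"` (penalized problem, Eq.-level `mu`): the default is
#'   `mu = 0.01 * max|A^T Phi|`, a small fraction of the largest
#'   back-projected datum; `mu` beyond `max|A^T Phi|` would annihilate the
#'   solution entirely.
#'
#' `epsilon = 1e-3`, `max_iter = 5000`. All fields can be overridden.
#'
#' @param A m x n matrix (or `sensitivity`).
#' @param phi length-m measurement vector (or `measurement_set`).
#' @param method `"lbsr"` (default) or `"l1sb"` — selects the `mu` rule.
#' @return a `solver_config`.
#' @export
default_parameters <- function(A, phi, method = c("lbsr", "l1sb")) {
  method <- match.arg(method)
  A <- as_matrix_A(A); phi <- as_phi(phi)
  if (all(A == 0)) stop("A is identically zero")
  smax <- spectral_norm(A)
  delta <- 1 / smax^2
  mu <- if (method == "lbsr") {
    5 * max(abs(cg_scale_probe(A, phi))) / delta
  } else {
    0.01 * max(abs(crossprod(A, phi)))
  }
  if (mu == 0) {
    warning("A^T Phi is zero (degenerate data); substituting a machine floor for mu")
    mu <- .Machine$double.xmin
  }
  solver_config(mu = mu, delta = delta)
}

# scale probe: a few plain CG steps on A^T A x = A^T phi, enough to learn
# the magnitude of the least-squares solution (not its support)
cg_scale_probe <- function(A, phi, n_iter = 20L) {
  b <- as.numeric(crossprod(A, phi))
  op <- function(x) as.numeric(crossprod(A, A %*% x))
  cg_iterate(op, b, tol = 1e-12, max_iter = n_iter)$x
}

# largest singular value by fixed-count power iteration (deterministic)
spectral_norm <- function(A, n_iter = 100L) {
  n <- ncol(A)
  v <- sin(seq_len(n))  # fixed, nonzero start
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(n_iter)) {
    w <- as.numeric(crossprod(A, A %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
  }
  sqrt(sqrt(sum(as.numeric(crossprod(A, A %*% v))^2)))
}

recon_result <- function(S, v, iterations, residual_history,
                         rel_change_history, converged, method, config,
                         col_meta = NULL, n_nodes = NULL) {
  S_full <- S
  if (!is.null(col_meta) && !is.null(n_nodes)) {
    S_full <- numeric(n_nodes)
    S_full[col_meta] <- S
  }
  structure(list(S = S_full, S_active = S, v_final = v,
                 iterations = iterations,
                 residual_history = residual_history,
                 rel_change_history = rel_change_history,
                 converged = converged, method = method, config = config,
                 col_meta = col_meta, n_nodes = n_nodes),
            class = "otrecon")
}

#' Linearized Bregman iteration with sparse (l1) regularization
#'
#' Solves the sparse reconstruction problem
#' `min_S mu ||S||_1 + 1/2 ||A S - Phi||_2^2` by the two-line linearized
#' Bregman iteration, which requires only matrix products and scalar
#' shrinkage:
#' \preformatted{
#'   v^0 = 0, S^0 = 0
#'   v^{k+1} = v^k + A^T (Phi - A S^k)
#'   S^{k+1} = delta * shrink(v^{k+1}, mu)
#' }
#' stopping at the first k with `||S^{k+1} - S^k|| / ||S^k|| <= epsilon`
#' (skipped while `||S^k|| = 0`), or at `max_iter`.
#'
#' @param A m x n matrix or `sensitivity` object.
#' @param phi length-m vector or `measurement_set`.
#' @param config a `solver_config`; default [default_parameters()].
#' @return an `otrecon` result (see [reconstruct()]).
#' @export
lbsr_solve <- function(A, phi, config = default_parameters(A, phi)) {
  sens <- if (inherits(A, "sensitivity")) A else NULL
  A <- as_matrix_A(A); phi <- as_phi(phi)
  stopifnot(nrow(A) == length(phi))
  n <- ncol(A)
  v <- numeric(n); S <- numeric(n)
  res_h <- rel_h <- numeric(config$max_iter)
  converged <- FALSE
  it <- 0L
  for (k in seq_len(config$max_iter)) {
    it <- k
    r <- phi - as.numeric(A %*% S)   # residual of S^{k-1}
    if (k > 1L) res_h[k - 1L] <- sqrt(sum(r^2))
    v <- v + as.numeric(crossprod(A, r))
    S_new <- config$delta * shrink(v, config$mu)
    if (config$nonneg) S_new <- pmax(S_new, 0)
    if (!all(is.finite(S_new)))
      stop("non-finite iterate at iteration ", k,
           "; the step size is too large (use delta <= 1/sigma_max(A)^2)")
    ns <- sqrt(sum(S^2))
    rel <- if (ns > 0) sqrt(sum((S_new - S)^2)) / ns else NA_real_
    rel_h[k] <- rel
    S <- S_new
    if (!is.na(rel) && rel <= config$epsilon) { converged <- TRUE; break }
  }
  res_h[it] <- sqrt(sum((phi - as.numeric(A %*% S))^2))
  res_h <- res_h[seq_len(it)]
  rel_h <- rel_h[seq_len(it)]
  recon_result(S, v, it, res_h, rel_h, converged, "lbsr", config,
               col_meta = sens$col_meta, n_nodes = sens$n_nodes)
}

# plain conjugate gradient for SPD operator given as a closure
cg_iterate <- function(apply_op, b, tol, max_iter, x0 = NULL) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - apply_op(x)
  p <- r
  rs <- sum(r^2)
  b2 <- sqrt(sum(b^2))
  converged <- sqrt(rs) <= tol * max(b2, .Machine$double.xmin)
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    Ap <- apply_op(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (sqrt(rs_new) <= tol * max(b2, .Machine$double.xmin)) {
      converged <- TRUE
    } else {
      p <- r + (rs_new / rs) * p
    }
    rs <- rs_new
  }
  list(x = x, iterations = it, converged = converged)
}

#' Tikhonov (l2) reconstruction by conjugate gradients
#'
#' Solves the regularized normal equations
#' `(A^T A + lambda I) S = A^T Phi` with the conjugate gradient method —
#' the classical l2-norm baseline, which localizes well but yields smooth,
#' non-sparse source estimates.
#'
#' @param A m x n matrix or `sensitivity`.
#' @param phi length-m vector or `measurement_set`.
#' @param lambda Tikhonov weight (>= 0; > 0 required if `A^T A` singular).
#' @param cg_tol relative residual tolerance of CG (default 1e-8).
#' @param max_iter CG iteration cap (default 1000).
#' @return an `otrecon` result.
#' @export
l2cg_solve <- function(A, phi, lambda = 0, cg_tol = 1e-8, max_iter = 20000L) {
  sens <- if (inherits(A, "sensitivity")) A else NULL
  A <- as_matrix_A(A); phi <- as_phi(phi)
  stopifnot(lambda >= 0, nrow(A) == length(phi))
  b <- as.numeric(crossprod(A, phi))
  op <- function(x) as.numeric(crossprod(A, A %*% x)) + lambda * x
  sol <- cg_iterate(op, b, cg_tol, max_iter)
  if (!sol$converged)
    warning("conjugate gradient did not reach tolerance within ", max_iter,
            " iterations")
  res <- sqrt(sum((phi - as.numeric(A %*% sol$x))^2))
  recon_result(sol$x, v = NULL, iterations = sol$iterations,
               residual_history = res, rel_change_history = numeric(0),
               converged = sol$converged, method = "l2cg",
               config = list(lambda = lambda, cg_tol = cg_tol,
                             max_iter = max_iter),
               col_meta = sens$col_meta, n_nodes = sens$n_nodes)
}

#' Split Bregman l1 reconstruction
#'
#' Minimizes `mu ||S||_1 + 1/2 ||A S - Phi||_2^2` by splitting: an
#' auxiliary variable d is constrained to equal S, and the iteration
#' alternates (i) a quadratic solve in S by conjugate gradients,
#' (ii) `d = shrink(S + b, mu * delta)`, (iii) the Bregman update
#' `b <- b + S - d`. The penalty weight is `1/delta`. Stopping rule as in
#' [lbsr_solve()].
#'
#' @param A m x n matrix or `sensitivity`.
#' @param phi length-m vector or `measurement_set`.
#' @param config a `solver_config`; `config$delta` sets the splitting
#'   penalty `1/delta` and shrinkage threshold `mu * delta`.
#' @param inner_tol CG tolerance of the quadratic subproblem.
#' @param inner_max_iter CG cap per outer iteration.
#' @return an `otrecon` result.
#' @export
l1sb_solve <- function(A, phi, config = default_parameters(A, phi),
                       inner_tol = 1e-8, inner_max_iter = 200L) {
  sens <- if (inherits(A, "sensitivity")) A else NULL
  A <- as_matrix_A(A); phi <- as_phi(phi)
  stopifnot(nrow(A) == length(phi))
  n <- ncol(A)
  lam <- 1 / config$delta
  S <- d <- bb <- numeric(n)
  Atphi <- as.numeric(crossprod(A, phi))
  op <- function(x) as.numeric(crossprod(A, A %*% x)) + lam * x
  res_h <- rel_h <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (k in seq_len(config$max_iter)) {
    it <- k
    rhs <- Atphi + lam * (d - bb)
    S_new <- cg_iterate(op, rhs, inner_tol, inner_max_iter, x0 = S)$x
    d <- shrink(S_new + bb, config$mu * config$delta)
    if (config$nonneg) d <- pmax(d, 0)
    bb <- bb + S_new - d
    if (!all(is.finite(S_new)))
      stop("non-finite iterate at iteration ", k)
    ns <- sqrt(sum(S^2))
    rel <- if (ns > 0) sqrt(sum((S_new - S)^2)) / ns else NA_real_
    res_h[k] <- sqrt(sum((phi - as.numeric(A %*% S_new))^2))
    rel_h[k] <- rel
    S <- S_new
    if (!is.na(rel) && rel <= config$epsilon) { converged <- TRUE; break }
  }
  recon_result(d, v = bb, iterations = it, residual_history = res_h,
               rel_change_history = rel_h, converged = converged,
               method = "l1sb", config = config,
               col_meta = sens$col_meta, n_nodes = sens$n_nodes)
}

#' Reconstruct an internal source distribution from boundary measurements
#'
#' The central fitting function: dispatches to one of the three inverse
#' solvers and returns a classed result with standard accessor methods.
#'
#' By default the system is column-equilibrated before solving
#' (`precondition = TRUE`): each column of `A` is scaled to unit Euclidean
#' norm and the solution is rescaled back afterwards. This is the standard
#' sensitivity normalization for diffuse tomography operators — without
#' it, the reconstruction systematically drifts toward high-sensitivity
#' nodes near the detectors (depth bias), because shallow nodes explain
#' boundary data with less source amplitude. Equilibration changes the
#' regularized solution (it reweights the penalty), not the data fit.
#'
#' @param A `sensitivity` object (or plain m x n matrix).
#' @param phi `measurement_set` (or plain length-m vector).
#' @param method `"lbsr"` (linearized Bregman, sparse; default), `"l2cg"`
#'   (Tikhonov by conjugate gradients) or `"l1sb"` (Split Bregman l1).
#' @param config a `solver_config` for the l1 methods; defaults to
#'   [default_parameters()] on the (possibly equilibrated) system.
#' @param lambda Tikhonov weight for `"l2cg"`; defaults to
#'   `1e-6 * max(diag(A^T A))` of the solved system.
#' @param precondition equilibrate columns to unit norm before solving.
#' @param ... further arguments passed to the underlying solver.
#' @return an object of class `otrecon` with components `S` (full-length
#'   nodal source estimate when column metadata is available), `S_active`,
#'   `iterations`, `residual_history`, `rel_change_history`, `converged`,
#'   `v_final`, `method`, `config`.
#' @seealso [lbsr_solve()], [l2cg_solve()], [l1sb_solve()]
#' @export
reconstruct <- function(A, phi, method = c("lbsr", "l2cg", "l1sb"),
                        config = NULL, lambda = NULL, precondition = TRUE,
                        ...) {
  method <- match.arg(method)
  t0 <- proc.time()[["elapsed"]]
  sens <- if (inherits(A, "sensitivity")) A else NULL
  Am <- as_matrix_A(A)
  col_scale <- rep(1, ncol(Am))
  if (precondition) {
    col_scale <- sqrt(colSums(Am^2))
    if (any(col_scale == 0))
      stop("cannot equilibrate: A has an all-zero column")
    Asolve <- sweep(Am, 2, col_scale, "/")
    if (!is.null(sens)) { sens$entries <- Asolve; Asolve <- sens }
  } else {
    Asolve <- A
  }
  fit <- switch(method,
    lbsr = lbsr_solve(Asolve, phi,
                      config = config %||% default_parameters(Asolve, phi)),
    l2cg = {
      if (is.null(lambda))
        lambda <- 1e-6 * max(colSums(as_matrix_A(Asolve)^2))
      l2cg_solve(Asolve, phi, lambda = lambda, ...)
    },
    l1sb = l1sb_solve(Asolve, phi,
                      config = config %||%
                        default_parameters(Asolve, phi, method = "l1sb"),
                      ...))
  if (precondition) {
    fit$S_active <- fit$S_active / col_scale
    if (!is.null(fit$col_meta)) {
      fit$S <- numeric(fit$n_nodes)
      fit$S[fit$col_meta] <- fit$S_active
    } else {
      fit$S <- fit$S_active
    }
    fit$col_scale <- col_scale
  }
  fit$runtime_s <- proc.time()[["elapsed"]] - t0
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.otrecon <- function(x, ...) {
  cat(sprintf("otrecon fit (%s): %d iterations, %s\n", x$method,
              x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  nz <- sum(x$S_active != 0)
  cat(sprintf("  nonzero coefficients: %d of %d; max |S| = %.4g\n",
              nz, length(x$S_active), max(abs(x$S_active))))
  if (length(x$residual_history))
    cat(sprintf("  final residual ||AS - Phi|| = %.4g\n",
                utils::tail(x$residual_history, 1)))
  invisible(x)
}

#' @export
summary.otrecon <- function(object, ...) {
  out <- list(
    method = object$method,
    iterations = object$iterations,
    converged = object$converged,
    nonzero = sum(object$S_active != 0),
    n = length(object$S_active),
    max_value = max(object$S_active),
    final_residual = if (length(object$residual_history))
      utils::tail(object$residual_history, 1) else NA_real_,
    final_rel_change = if (length(object$rel_change_history))
      utils::tail(object$rel_change_history, 1) else NA_real_,
    runtime_s = object$runtime_s %||% NA_real_
  )
  class(out) <- "summary.otrecon"
  out
}

#' @export
print.summary.otrecon <- function(x, ...) {
  cat(sprintf("method: %s\niterations: %d (converged: %s)\n", x$method,
              x$iterations, x$converged))
  cat(sprintf("support: %d / %d nonzero; max value %.4g\n", x$nonzero, x$n,
              x$max_value))
  cat(sprintf("final residual: %.4g; final relative change: %.4g\n",
              x$final_residual, x$final_rel_change))
  if (is.finite(x$runtime_s)) cat(sprintf("runtime: %.2f s\n", x$runtime_s))
  invisible(x)
}

#' @export
coef.otrecon <- function(object, full = TRUE, ...)
  if (full) object$S else object$S_active

#' Residuals of a reconstruction against its measurements
#' @param object an `otrecon` fit.
#' @param A,phi the system matrix and measurements used for the fit.
#' @param ... unused.
#' @return length-m residual vector `Phi - A S`.
#' @export
residuals.otrecon <- function(object, A, phi, ...) {
  Am <- as_matrix_A(A); phi <- as_phi(phi)
  as_phi(phi) - as.numeric(Am %*% object$S_active)
}

#' Plot solver convergence diagnostics
#' @param x an `otrecon` fit.
#' @param ... passed to [plot()].
#' @export
plot.otrecon <- function(x, ...) {
  if (!length(x$residual_history)) {
    warning("no iteration history to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$residual_history), x$residual_history,
                 type = "l", log = "y", xlab = "iteration",
                 ylab = "||A S - Phi||", main = paste("convergence:", x$method),
                 ...)
  invisible(x)
}
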