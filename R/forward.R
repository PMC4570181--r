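#' Internal reflection parameter for the Robin boundary condition
#'
#' The refractive-index-mismatch factor A_n entering the boundary condition
#' phi + 2 A_n D dphi/dnu = 0, computed from the relative refractive index
#' by the standard polynomial fit to the effective Fresnel reflectance
#' R_eff = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n,
#' A_n = (1 + R_eff) / (1 - R_eff).
#'
#' @param n_rel relative refractive index tissue/air (>= 1).
#' @return dimensionless A_n (1 for matched boundaries).
#' @export
boundary_mismatch_factor <- function(n_rel) {
  if (n_rel == 1) return(1)
  r_eff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + r_eff) / (1 - r_eff)
}

#' Assemble the FEM diffusion operator on a labeled mesh
#'
#' Discretizes the diffusion approximation
#' \deqn{-\nabla\cdot(D\nabla\phi) + \mu_a \phi = q,\quad
#'       \phi + 2 A_n D \,\partial\phi/\partial\nu = 0 \ \mathrm{on}\
#'       \partial\Omega,}
#' with linear (P1) tetrahedral elements: `K = K_diff + K_abs + K_bnd`
#' (stiffness + absorption mass + Robin boundary mass) and the consistent
#' mass matrix `M`, so a nodal source-density vector `q` yields the load
#' `M q`. `K` is symmetric positive definite. `D = 1/(3 (mu_a + mu_s'))`
#' per region.
#'
#' @param mesh a `tetmesh`.
#' @param optics_by_region list mapping region label (character) to
#'   `optical_properties` for the wavelength channel being assembled.
#' @return list with sparse matrices `K` and `M` (class `dgCMatrix`).
#' @export
assemble_diffusion_system <- function(mesh, optics_by_region) {
  labs <- sort(unique(mesh$region))
  miss <- setdiff(as.character(labs), names(optics_by_region))
  if (length(miss))
    stop("no optical properties for region label(s): ",
         paste(miss, collapse = ", "))
  mu_a <- D <- A_n <- numeric(max(labs))
  for (l in labs) {
    o <- optics_by_region[[as.character(l)]]
    mu_a[l] <- o$mu_a
    D[l] <- diffusion_coefficient(o)
    A_n[l] <- boundary_mismatch_factor(o$refractive_index)
  }
  n <- nrow(mesh$nodes)
  tets <- mesh$tets
  vol <- signed_tet_volumes(mesh$nodes, tets)
  Dt <- D[mesh$region]
  mat <- mu_a[mesh$region]

  # P1 barycentric gradients: with edge matrix T = [a b c] (columns),
  # rows of T^{-1} are grad(lambda_2..4); grad(lambda_1) = -sum.
  p1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  a <- mesh$nodes[tets[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[tets[, 3], , drop = FALSE] - p1
  cc <- mesh$nodes[tets[, 4], , drop = FALSE] - p1
  det6 <- 6 * vol
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cross3(b, cc) / det6
  g3 <- cross3(cc, a) / det6
  g4 <- cross3(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)

  nt <- nrow(tets)
  ii <- jj <- integer(16L * nt)
  kk <- mm <- numeric(16L * nt)
  pos <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- pos + seq_len(nt)
    ii[idx] <- tets[, i]
    jj[idx] <- tets[, j]
    kk[idx] <- Dt * vol * rowSums(G[[i]] * G[[j]]) +
      mat * vol * (if (i == j) 0.1 else 0.05)
    mm[idx] <- vol * (if (i == j) 0.1 else 0.05)
    pos <- pos + nt
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(n, n))

  # Robin boundary term: (1/(2 A_n)) * face mass matrix, coefficient taken
  # from the region of the owning tet
  bf <- mesh$boundary_faces
  if (nrow(bf)) {
    alpha <- 1 / (2 * A_n[mesh$region[mesh$boundary_face_tet]])
    e1 <- mesh$nodes[bf[, 2], , drop = FALSE] - mesh$nodes[bf[, 1], , drop = FALSE]
    e2 <- mesh$nodes[bf[, 3], , drop = FALSE] - mesh$nodes[bf[, 1], , drop = FALSE]
    cr <- cross3(e1, e2)
    area <- 0.5 * sqrt(rowSums(cr^2))
    nb <- nrow(bf)
    bi <- bj <- integer(9L * nb); bx <- numeric(9L * nb)
    pos <- 0L
    for (i in 1:3) for (j in 1:3) {
      idx <- pos + seq_len(nb)
      bi[idx] <- bf[, i]
      bj[idx] <- bf[, j]
      bx[idx] <- alpha * area * (if (i == j) 1 / 6 else 1 / 12)
      pos <- pos + nb
    }
    K <- K + Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(n, n))
  }
  list(K = methods::as(K, "CsparseMatrix"), M = methods::as(M, "CsparseMatrix"))
}

mesh_center <- function(mesh) colMeans(mesh$nodes)

lateral_boundary_nodes <- function(mesh, tol = 1e-6) {
  ctr <- mesh_center(mesh)
  bn <- sort(unique(as.vector(mesh$boundary_faces)))
  r <- sqrt((mesh$nodes[bn, 1] - ctr[1])^2 + (mesh$nodes[bn, 2] - ctr[2])^2)
  bn[r >= max(r) * (1 - tol)]
}

#' Place boundary excitation sources and their detector arcs
#'
#' Excitation point sources are equally spaced on the boundary circle in
#' the z = 0 plane. For the excitation at angle theta, its detector group
#' is the set of lateral boundary nodes whose angular coordinate lies
#' within `fov_degrees / 2` of theta + 180 degrees (detection from the
#' opposite side) and whose |z| does not exceed `z_band`.
#'
#' @param mesh a `tetmesh` (cylinder-like: lateral boundary at max radius).
#' @param n_excitations number of excitation positions (>= 1).
#' @param fov_degrees detector field of view in degrees, in (0, 360].
#' @param z_band half-height of the detector band in mm (default: full).
#' @return a `detector_set`: `detector_nodes` (union of all groups),
#'   `positions`, `excitation_nodes`, `excitation_angles` (radians), and
#'   `groups` (list of node-index vectors, one per excitation).
#' @export
place_detectors <- function(mesh, n_excitations, fov_degrees,
                            z_band = Inf) {
  stopifnot(n_excitations >= 1, fov_degrees > 0, fov_degrees <= 360)
  ctr <- mesh_center(mesh)
  lat <- lateral_boundary_nodes(mesh)
  xc <- mesh$nodes[lat, 1] - ctr[1]; yc <- mesh$nodes[lat, 2] - ctr[2]
  R <- max(sqrt(xc^2 + yc^2))
  th_exc <- 2 * pi * (seq_len(n_excitations) - 1) / n_excitations
  exc_nodes <- vapply(th_exc, function(th)
    nearest_node(mesh, ctr + c(R * cos(th), R * sin(th), 0)), integer(1))
  ang <- atan2(yc, xc)
  zok <- abs(mesh$nodes[lat, 3] - ctr[3]) <= z_band
  half <- fov_degrees / 2 * pi / 180
  groups <- lapply(th_exc, function(th) {
    d <- ang - (th + pi)
    d <- atan2(sin(d), cos(d))  # wrap to (-pi, pi]
    g <- lat[abs(d) <= half + 1e-12 & zok]
    if (!length(g))
      stop("no boundary detector node in a field of view; ",
           "increase fov_degrees or refine the mesh")
    g
  })
  det <- sort(unique(unlist(groups)))
  structure(list(detector_nodes = det,
                 positions = mesh$nodes[det, , drop = FALSE],
                 excitation_nodes = exc_nodes,
                 excitation_angles = th_exc,
                 groups = groups),
            class = "detector_set")
}

#' @export
print.detector_set <- function(x, ...) {
  cat(sprintf("detector_set: %d excitation(s), %d detector nodes (groups of %s)\n",
              length(x$excitation_nodes), length(x$detector_nodes),
              paste(vapply(x$groups, length, integer(1)), collapse = ", ")))
  invisible(x)
}

#' Build the sensitivity (system) matrix A of the linear model A S = Phi
#'
#' Row (e, d) maps a nodal source density to the fluence measured at
#' detector node d under excitation e.
#' * `channel = "emission-only"` (bioluminescence/Cerenkov-like):
#'   `A[(e,d), j] = (K_em^{-1} M)[d, j]`, identical across excitations.
#' * `channel = "excitation-weighted"` (fluorescence, Born approximation):
#'   the emission row is weighted by the excitation fluence,
#'   `A[(e,d), j] = phi_x^(e)(j) * (K_em^{-1} M)[d, j]`, where phi_x^(e)
#'   solves the excitation-channel diffusion system with a unit point
#'   source at the excitation node.
#'
#' Columns are computed by one adjoint solve per unique detector node
#' (K is symmetric, so adjoint and forward constructions agree).
#'
#' @param ph a `phantom` (must carry an `excitation` optics channel for
#'   `"excitation-weighted"`).
#' @param detectors a `detector_set`.
#' @param channel `"excitation-weighted"` or `"emission-only"`.
#' @param candidate_nodes integer node indices forming the reconstruction
#'   support (default: all interior nodes).
#' @param excitation_fluence optional n x E matrix overriding the computed
#'   excitation fluence (testing hook; e.g. all-ones recovers the
#'   emission-only matrix).
#' @return a `sensitivity` object: dense `entries` (m x n_candidates),
#'   `row_meta` (data.frame: excitation, detector_node), `col_meta`
#'   (candidate node indices), `n_nodes`, `channel`.
#' @export
build_sensitivity_matrix <- function(ph, detectors,
                                     channel = c("excitation-weighted",
                                                 "emission-only"),
                                     candidate_nodes = NULL,
                                     excitation_fluence = NULL) {
  channel <- match.arg(channel)
  mesh <- ph$mesh
  n <- nrow(mesh$nodes)
  if (is.null(candidate_nodes)) {
    bn <- unique(as.vector(mesh$boundary_faces))
    candidate_nodes <- setdiff(seq_len(n), bn)
  }
  sys_em <- assemble_diffusion_system(mesh, ph$optics_by_region$emission)
  ch <- Matrix::Cholesky(sys_em$K, LDL = FALSE)
  det_nodes <- detectors$detector_nodes
  E <- Matrix::sparseMatrix(i = det_nodes, j = seq_along(det_nodes), x = 1,
                            dims = c(n, length(det_nodes)))
  W <- as.matrix(Matrix::solve(ch, E, system = "A"))   # K^{-1} e_d
  G <- as.matrix(sys_em$M %*% W)                       # G[j, d] = (K^{-1} M)[d, j]

  nE <- length(detectors$excitation_nodes)
  if (channel == "excitation-weighted") {
    if (is.null(excitation_fluence)) {
      if (is.null(ph$optics_by_region$excitation))
        stop("phantom has no 'excitation' optics channel")
      sys_x <- assemble_diffusion_system(mesh, ph$optics_by_region$excitation)
      B <- Matrix::sparseMatrix(i = detectors$excitation_nodes,
                                j = seq_len(nE), x = 1, dims = c(n, nE))
      excitation_fluence <- as.matrix(Matrix::solve(sys_x$K, B))
    }
    stopifnot(nrow(excitation_fluence) == n, ncol(excitation_fluence) == nE)
  }

  det_pos <- match(unlist(detectors$groups), det_nodes)
  m <- length(det_pos)
  exc_id <- rep(seq_len(nE), vapply(detectors$groups, length, integer(1)))
  Gc <- G[candidate_nodes, , drop = FALSE]
  A <- t(Gc[, det_pos, drop = FALSE])
  if (channel == "excitation-weighted")
    A <- A * t(excitation_fluence[candidate_nodes, exc_id, drop = FALSE])
  # clip tiny negative discretization undershoot
  floor_tol <- 1e-8 * max(A)
  if (min(A) < -floor_tol)
    warning("sensitivity entries below -1e-8 * max; check mesh quality")
  structure(list(entries = A,
                 row_meta = data.frame(excitation = exc_id,
                                       detector_node = unlist(detectors$groups)),
                 col_meta = candidate_nodes,
                 n_nodes = n,
                 channel = channel),
            class = "sensitivity")
}

#' @export
print.sensitivity <- function(x, ...) {
  cat(sprintf("sensitivity matrix: %d rows (excitation x detector), %d candidate source nodes, channel %s\n",
              nrow(x$entries), ncol(x$entries), x$channel))
  invisible(x)
}

#' Restrict a sensitivity matrix to a permissible source region
#'
#' Keeps only the columns whose candidate node coordinates fall inside the
#' closed box `[x1,x2] x [y1,y2] x [z1,z2]`; column metadata is preserved
#' so reconstructions re-embed into the full nodal vector with zeros
#' outside the box. A priori restriction of the source support shrinks the
#' system matrix and reduces the ill-posedness of the inversion.
#'
#' @param sens a `sensitivity` object.
#' @param mesh the `tetmesh` the matrix was built on.
#' @param box 3 x 2 matrix (or list of three length-2 vectors), closed
#'   intervals in mm.
#' @return a `sensitivity` with restricted columns.
#' @export
restrict_psr <- function(sens, mesh, box) {
  if (is.list(box)) box <- do.call(rbind, box)
  box <- matrix(as.numeric(box), 3, 2)
  xyz <- mesh$nodes[sens$col_meta, , drop = FALSE]
  keep <- xyz[, 1] >= box[1, 1] & xyz[, 1] <= box[1, 2] &
          xyz[, 2] >= box[2, 1] & xyz[, 2] <= box[2, 2] &
          xyz[, 3] >= box[3, 1] & xyz[, 3] <= box[3, 2]
  if (!any(keep))
    stop("permissible source region contains no candidate node")
  sens$entries <- sens$entries[, keep, drop = FALSE]
  sens$col_meta <- sens$col_meta[keep]
  sens
}

#' Simulate boundary measurements Phi = A S_true + noise
#'
#' @param sens a `sensitivity` object (or plain matrix).
#' @param s_true full-length nodal source vector (restricted internally to
#'   the candidate columns) or a vector matching `ncol(A)`.
#' @param noise_sigma_rel relative Gaussian noise level: the noise standard
#'   deviation is `noise_sigma_rel * max(A S_true)`. 0 gives exact data.
#' @param seed RNG seed for the noise draw.
#' @return a `measurement_set`: `values` (length m), `noise_model`, `seed`.
#' @export
simulate_measurements <- function(sens, s_true, noise_sigma_rel = 0,
                                  seed = 0L) {
  stopifnot(noise_sigma_rel >= 0)
  A <- if (inherits(sens, "sensitivity")) sens$entries else sens
  if (inherits(sens, "sensitivity") && length(s_true) == sens$n_nodes)
    s_true <- s_true[sens$col_meta]
  stopifnot(length(s_true) == ncol(A))
  phi <- as.numeric(A %*% s_true)
  if (noise_sigma_rel > 0) {
    sd <- noise_sigma_rel * max(phi)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    phi <- phi + stats::rnorm(length(phi), 0, sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  structure(list(values = phi,
                 noise_model = sprintf("gaussian, sd = %g * max(A S)",
                                       noise_sigma_rel),
                 seed = seed),
            class = "measurement_set")
}
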