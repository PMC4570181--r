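#' Location error between reconstructed and true source centers
#'
#' Euclidean distance
#' `LE = sqrt((x - x0)^2 + (y - y0)^2 + (z - z0)^2)` in mm, where
#' `(x0, y0, z0)` is the actual source center and `(x, y, z)` the
#' reconstructed one.
#'
#' @param recon_center,true_center finite length-3 coordinates (mm).
#' @return nonnegative distance in mm.
#' @export
location_error <- function(recon_center, true_center) {
  stopifnot(length(recon_center) == 3, length(true_center) == 3,
            all(is.finite(recon_center)), all(is.finite(true_center)))
  sqrt(sum((as.numeric(recon_center) - as.numeric(true_center))^2))
}

# lumped nodal volumes: each tet spreads V/4 onto its vertices
nodal_volumes <- function(mesh) {
  v <- signed_tet_volumes(mesh$nodes, mesh$tets)
  w <- numeric(nrow(mesh$nodes))
  for (k in 1:4) {
    acc <- tapply(v / 4, mesh$tets[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + as.numeric(acc)
  }
  w
}

#' Extract reconstructed source centers from a nodal image
#'
#' Nodes with `S >= rel_threshold * max(S)` are grouped into connected
#' components over the mesh edge graph; components with fewer than
#' `min_cluster` nodes are dropped; each surviving component's center is
#' the S-weighted centroid of its nodes. Centers are returned sorted by
#' descending component energy (sum of S times lumped nodal volume).
#'
#' @param S length-n nodal vector (or an `otrecon` fit).
#' @param mesh the `tetmesh` the vector lives on.
#' @param rel_threshold relative threshold in (0, 1), default 0.5.
#' @param min_cluster minimum component size in nodes (default 1).
#' @return k x 3 matrix of centers (mm) with attribute `energy`.
#' @export
extract_source_centers <- function(S, mesh, rel_threshold = 0.5,
                                   min_cluster = 1L) {
  if (inherits(S, "otrecon")) S <- S$S
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  if (all(S == 0)) stop("empty reconstruction: S is identically zero")
  sel <- which(S >= rel_threshold * max(S))
  ed <- mesh_edges(mesh)
  keep <- ed[, 1] %in% sel & ed[, 2] %in% sel
  map <- integer(nrow(mesh$nodes)); map[sel] <- seq_along(sel)
  g <- igraph::graph_from_edgelist(
    cbind(map[ed[keep, 1]], map[ed[keep, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(sel) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  w <- nodal_volumes(mesh)
  centers <- NULL; energy <- numeric(0)
  for (ci in seq_len(max(comp))) {
    nodes <- sel[comp == ci]
    if (length(nodes) < min_cluster) next
    sw <- S[nodes]
    ctr <- colSums(mesh$nodes[nodes, , drop = FALSE] * sw) / sum(sw)
    centers <- rbind(centers, ctr)
    energy <- c(energy, sum(S[nodes] * w[nodes]))
  }
  if (is.null(centers)) stop("no cluster of at least ", min_cluster, " nodes")
  ord <- order(energy, decreasing = TRUE)
  out <- centers[ord, , drop = FALSE]
  dimnames(out) <- NULL
  attr(out, "energy") <- energy[ord]
  out
}

#' Contrast-to-noise ratio of a reconstruction
#'
#' `CNR = |mean_ROI - mean_BG| / sqrt(w_ROI var_ROI + w_BG var_BG)` with
#' volume-fraction weights `w`; means and variances are volume-weighted
#' over nodes (lumped nodal volumes by default). Larger CNR means the
#' reconstructed source stands out more clearly from the background.
#'
#' @param S length-n nodal vector (or `otrecon` fit).
#' @param roi_node_mask logical length-n mask (or integer node indices)
#'   defining the region of interest; must be nonempty and a strict subset.
#' @param volume_weights optional length-n positive node weights.
#' @param mesh optional `tetmesh`, used to compute lumped nodal volumes
#'   when `volume_weights` is missing (equal weights if neither is given).
#' @return dimensionless CNR; `Inf` (with a warning) if the pooled
#'   variance is zero but the contrast is not.
#' @export
cnr <- function(S, roi_node_mask, volume_weights = NULL, mesh = NULL) {
  if (inherits(S, "otrecon")) S <- S$S
  n <- length(S)
  if (is.numeric(roi_node_mask))
    roi_node_mask <- seq_len(n) %in% as.integer(roi_node_mask)
  stopifnot(length(roi_node_mask) == n)
  if (!any(roi_node_mask) || all(roi_node_mask))
    stop("ROI must be a nonempty strict subset of nodes")
  w <- volume_weights %||% (if (!is.null(mesh)) nodal_volumes(mesh)
                            else rep(1, n))
  stopifnot(length(w) == n, all(w > 0))
  wmean <- function(x, ww) sum(ww * x) / sum(ww)
  wvar <- function(x, ww) {
    m <- wmean(x, ww)
    sum(ww * (x - m)^2) / sum(ww)
  }
  roi <- roi_node_mask; bg <- !roi
  w_roi <- sum(w[roi]) / sum(w)
  w_bg <- sum(w[bg]) / sum(w)
  contrast <- abs(wmean(S[roi], w[roi]) - wmean(S[bg], w[bg]))
  pooled <- w_roi * wvar(S[roi], w[roi]) + w_bg * wvar(S[bg], w[bg])
  if (pooled == 0) {
    if (contrast == 0) return(0)
    warning("zero pooled variance; CNR is infinite")
    return(Inf)
  }
  contrast / sqrt(pooled)
}

#' Evaluate a reconstruction against a phantom's ground truth
#'
#' Extracts source centers from the reconstruction, matches each true
#' (snapped) source center to the nearest extracted center (greedy
#' nearest-pair without replacement, order-invariant), and reports per-pair
#' location error, the CNR of the true-source neighborhood (ROI = nodes
#' within `r_roi` of the true centers), the maximum reconstructed nodal
#' value, iteration count and runtime.
#'
#' @param ph a `phantom` with at least one true source.
#' @param recon an `otrecon` fit (or plain nodal vector).
#' @param r_roi ROI radius around true centers in mm (default 2).
#' @param rel_threshold,min_cluster passed to [extract_source_centers()].
#' @param runtime_s optional runtime override (s).
#' @return an `eval_report`: data.frame `per_source` (true/recon centers,
#'   `le_mm`), `cnr`, `max_energy`, `n_iterations`, `runtime_s`,
#'   `incomplete` flag.
#' @export
evaluate_run <- function(ph, recon, r_roi = 2, rel_threshold = 0.5,
                         min_cluster = 1L, runtime_s = NULL) {
  S <- if (inherits(recon, "otrecon")) recon$S else recon
  stopifnot(length(S) == nrow(ph$mesh$nodes))
  true_ctr <- ph$true_centers
  if (is.null(true_ctr) || nrow(true_ctr) == 0)
    stop("phantom has no true sources to evaluate against")
  centers <- extract_source_centers(S, ph$mesh, rel_threshold, min_cluster)
  k_true <- nrow(true_ctr); k_rec <- nrow(centers)
  # greedy nearest-pair matching without replacement
  d <- outer(seq_len(k_true), seq_len(k_rec),
             Vectorize(function(i, j) location_error(centers[j, ],
                                                     true_ctr[i, ])))
  d <- matrix(d, k_true, k_rec)
  match_idx <- rep(NA_integer_, k_true)
  dd <- d
  for (step in seq_len(min(k_true, k_rec))) {
    ij <- arrayInd(which.min(dd), dim(dd))
    match_idx[ij[1]] <- ij[2]
    dd[ij[1], ] <- Inf
    dd[, ij[2]] <- Inf
  }
  incomplete <- anyNA(match_idx)
  le <- numeric(k_true)
  rc <- matrix(NA_real_, k_true, 3)
  for (i in seq_len(k_true)) {
    j <- match_idx[i]
    if (is.na(j)) j <- which.min(d[i, ])  # unmatched: nearest center
    le[i] <- d[i, j]
    rc[i, ] <- centers[j, ]
  }
  nd <- ph$mesh$nodes
  roi <- rep(FALSE, nrow(nd))
  for (i in seq_len(k_true)) {
    d2 <- (nd[, 1] - true_ctr[i, 1])^2 + (nd[, 2] - true_ctr[i, 2])^2 +
          (nd[, 3] - true_ctr[i, 3])^2
    roi <- roi | d2 <= r_roi^2
  }
  rep_cnr <- cnr(S, roi, mesh = ph$mesh)
  per_source <- data.frame(
    true_x = true_ctr[, 1], true_y = true_ctr[, 2], true_z = true_ctr[, 3],
    recon_x = rc[, 1], recon_y = rc[, 2], recon_z = rc[, 3], le_mm = le)
  structure(list(per_source = per_source, cnr = rep_cnr,
                 max_energy = max(S),
                 n_iterations = if (inherits(recon, "otrecon"))
                   recon$iterations else NA_integer_,
                 runtime_s = runtime_s %||%
                   (if (inherits(recon, "otrecon"))
                      recon$runtime_s %||% NA_real_ else NA_real_),
                 incomplete = incomplete),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("reconstruction evaluation\n")
  ps <- x$per_source
  for (i in seq_len(nrow(ps)))
    cat(sprintf("  source %d: true (%.2f, %.2f, %.2f) -> recon (%.2f, %.2f, %.2f), LE = %.2f mm\n",
                i, ps$true_x[i], ps$true_y[i], ps$true_z[i],
                ps$recon_x[i], ps$recon_y[i], ps$recon_z[i], ps$le_mm[i]))
  cat(sprintf("  CNR = %.3g; max reconstructed value = %.4g; iterations = %s; runtime = %s s\n",
              x$cnr, x$max_energy,
              ifelse(is.na(x$n_iterations), "NA", x$n_iterations),
              ifelse(is.na(x$runtime_s), "NA", sprintf("%.2f", x$runtime_s))))
  if (x$incomplete) cat("  WARNING: fewer extracted centers than true sources\n")
  invisible(x)
}

#' Write an evaluation report as JSON and a flat CSV row
#' @param report an `eval_report`.
#' @param path_json,path_csv output paths (either may be NULL to skip).
#' @param method method label for the CSV row.
#' @param append append to an existing CSV (keeps its header).
#' @export
write_eval_report <- function(report, path_json = NULL, path_csv = NULL,
                              method = "unknown", append = FALSE) {
  if (!is.null(path_json))
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(path_csv)) {
    ps <- report$per_source
    row <- data.frame(
      method = method,
      recon_centers = paste(sprintf("(%.2f, %.2f, %.2f)", ps$recon_x,
                                    ps$recon_y, ps$recon_z), collapse = " "),
      le_mm = paste(sprintf("%.2f", ps$le_mm), collapse = " "),
      cnr = report$cnr,
      reconstruction_time_s = report$runtime_s,
      max_reconstructed_energy = report$max_energy)
    utils::write.table(row, path_csv, sep = ",", row.names = FALSE,
                       col.names = !append || !file.exists(path_csv),
                       append = append && file.exists(path_csv))
  }
  invisible(report)
}
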