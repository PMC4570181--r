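#' Write a mesh as a legacy VTK unstructured grid (ASCII)
#'
#' Region labels are stored as CELL_DATA field `region`; any nodal fields
#' supplied in `point_data` (e.g. a source vector as `source`) are written
#' as POINT_DATA scalar fields.
#'
#' @param mesh a `tetmesh`.
#' @param path output file path (`.vtk`).
#' @param point_data named list of length-n numeric nodal fields.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "tetmesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  wl(sprintf("CELLS %d %d", nt, 5L * nt))
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  wl(sprintf("CELL_TYPES %d", nt))
  writeLines(rep("10", nt), con)
  wl(sprintf("CELL_DATA %d", nt), "SCALARS region int 1",
     "LOOKUP_TABLE default")
  writeLines(as.character(mesh$region), con)
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == n)
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      writeLines(format(v, digits = 17, trim = TRUE, scientific = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_mesh_vtk()]
#'
#' Supports ASCII legacy files with tetrahedral cells (type 10), one integer
#' CELL_DATA field and scalar POINT_DATA fields.
#'
#' @param path path to a `.vtk` file.
#' @return list with `mesh` (a `tetmesh`) and `point_data` (named list).
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- scan(text = ln[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  nt <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cl <- scan(text = ln[(ic + 1):(ic + nt)], quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  if (any(cl[, 1] != 4)) stop("only tetrahedral cells are supported")
  tets <- cl[, 2:5] + 1L
  region <- rep(1L, nt)
  ir <- grep("^SCALARS region", ln)
  if (length(ir))
    region <- as.integer(scan(text = ln[(ir[1] + 2):(ir[1] + 1 + nt)],
                              quiet = TRUE))
  point_data <- list()
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) {
    isc <- grep("^SCALARS", ln)
    isc <- isc[isc > ipd[1]]
    for (i in isc) {
      nm <- strsplit(ln[i], "\\s+")[[1]][2]
      point_data[[nm]] <- scan(text = ln[(i + 2):(i + 1 + n)], quiet = TRUE)
    }
  }
  list(mesh = tet_mesh(nodes, tets, region), point_data = point_data)
}

#' Write a mesh as a TetGen-style .node/.ele plain-text pair
#'
#' `basepath.node` holds node coordinates, `basepath.ele` the tetrahedra
#' with the region label as a per-element attribute.
#'
#' @param mesh a `tetmesh`.
#' @param basepath path without extension.
#' @export
write_mesh_tetgen <- function(mesh, basepath) {
  n <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  nodef <- paste0(basepath, ".node")
  elef <- paste0(basepath, ".ele")
  writeLines(c(sprintf("%d 3 0 0", n),
               paste(seq_len(n),
                     format(mesh$nodes[, 1], digits = 17, trim = TRUE),
                     format(mesh$nodes[, 2], digits = 17, trim = TRUE),
                     format(mesh$nodes[, 3], digits = 17, trim = TRUE))),
             nodef)
  writeLines(c(sprintf("%d 4 1", nt),
               paste(seq_len(nt), mesh$tets[, 1], mesh$tets[, 2],
                     mesh$tets[, 3], mesh$tets[, 4], mesh$region)),
             elef)
  invisible(basepath)
}

#' Read a TetGen-style .node/.ele pair
#' @param basepath path without extension (expects `.node` and `.ele`).
#' @return a `tetmesh`.
#' @export
read_mesh_tetgen <- function(basepath) {
  nodef <- paste0(basepath, ".node")
  elef <- paste0(basepath, ".ele")
  hl <- scan(nodef, nlines = 1, quiet = TRUE)
  n <- as.integer(hl[1])
  nd <- matrix(scan(nodef, skip = 1, nlines = n, quiet = TRUE),
               nrow = n, byrow = TRUE)
  nodes <- nd[, 2:4, drop = FALSE]
  hl <- scan(elef, nlines = 1, quiet = TRUE)
  nt <- as.integer(hl[1]); nattr <- if (length(hl) >= 3) as.integer(hl[3]) else 0L
  el <- matrix(scan(elef, skip = 1, nlines = nt, quiet = TRUE),
               nrow = nt, byrow = TRUE)
  tets <- el[, 2:5, drop = FALSE]
  region <- if (nattr >= 1L) as.integer(el[, 6]) else rep(1L, nt)
  if (min(tets) == 0L) tets <- tets + 1L  # 0-based files
  tet_mesh(nodes, tets, region)
}
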