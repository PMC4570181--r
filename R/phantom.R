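#' Optical properties of a tissue region
#'
#' Absorption coefficient `mu_a` and reduced scattering coefficient
#' `mu_s_prime`, both in 1/mm, plus the refractive index used by the Robin
#' boundary condition of the diffusion model.
#'
#' @param mu_a absorption coefficient (1/mm), > 0.
#' @param mu_s_prime reduced scattering coefficient (1/mm), > 0.
#' @param refractive_index dimensionless, >= 1 (default 1.37, soft tissue).
#' @return an `optical_properties` object.
#' @export
optical_properties <- function(mu_a, mu_s_prime, refractive_index = 1.37) {
  stopifnot(is.numeric(mu_a), mu_a > 0,
            is.numeric(mu_s_prime), mu_s_prime > 0,
            is.numeric(refractive_index), refractive_index >= 1)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime,
                 refractive_index = refractive_index),
            class = "optical_properties")
}

#' Diffusion coefficient D = 1 / (3 (mu_a + mu_s'))
#' @param optics an `optical_properties` object.
#' @return diffusion coefficient in mm.
#' @export
diffusion_coefficient <- function(optics)
  1 / (3 * (optics$mu_a + optics$mu_s_prime))

load_preset_optics <- function(file) {
  tab <- utils::read.csv(system.file("extdata", file, package = "otrecon",
                                     mustWork = TRUE))
  out <- list()
  for (ch in unique(tab$channel)) {
    sub <- tab[tab$channel == ch, ]
    optics <- lapply(seq_len(nrow(sub)), function(i)
      optical_properties(sub$mu_a[i], sub$mu_s_prime[i],
                         sub$refractive_index[i]))
    names(optics) <- as.character(sub$region_label)
    attr(optics, "tissue") <- stats::setNames(sub$tissue,
                                              as.character(sub$region_label))
    out[[ch]] <- optics
  }
  out
}

#' Label cylinder-phantom regions from an analytic inclusion layout
#'
#' Every tetrahedron whose centroid falls inside an inclusion shape receives
#' that inclusion's label; later layout entries win where shapes overlap.
#' All other tets receive `background_label`. Shapes are analytic cylinders
#' (axis z) or ellipsoids.
#'
#' @param mesh a `tetmesh`.
#' @param layout list of inclusions, each a list with `label` (integer),
#'   `shape` (`"cylinder"` or `"ellipsoid"`), `center` (length-3, mm), and
#'   either `radius` + `half_height` (cylinder) or `semiaxes` (ellipsoid).
#' @param background_label label for tets in no inclusion (default 1).
#' @return the mesh with updated `region`; node/tet arrays unchanged.
#' @export
assign_cylinder_regions <- function(mesh, layout, background_label = 1L) {
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  region <- rep(as.integer(background_label), nrow(mesh$tets))
  for (inc in layout) {
    ctr <- inc$center
    inside <- switch(inc$shape,
      cylinder = {
        (cen[, 1] - ctr[1])^2 + (cen[, 2] - ctr[2])^2 <= inc$radius^2 &
          abs(cen[, 3] - ctr[3]) <= inc$half_height
      },
      ellipsoid = {
        ax <- inc$semiaxes
        ((cen[, 1] - ctr[1]) / ax[1])^2 + ((cen[, 2] - ctr[2]) / ax[2])^2 +
          ((cen[, 3] - ctr[3]) / ax[3])^2 <= 1
      },
      stop("unknown inclusion shape: ", inc$shape))
    if (!any(inside))
      warning("inclusion with label ", inc$label, " contains no tet centroid")
    region[inside] <- as.integer(inc$label)
  }
  mesh$region <- region
  mesh
}

#' Default 4-tissue inclusion layout for the heterogeneous cylinder
#'
#' A qualitative cross-section with muscle background (label 1), two lung
#' cylinders (2), a central bone column (3) and a heart ellipsoid (4). The
#' inclusion positions and sizes are a documented approximation (the
#' reconstruction targets are the source positions, which are exact); every
#' entry can be overridden by supplying a custom layout.
#'
#' @return a layout list accepted by [assign_cylinder_regions()].
#' @export
default_cylinder_layout <- function() {
  list(
    list(label = 2L, shape = "cylinder", center = c(-2, 4.5, 0),
         radius = 2.8, half_height = 6),
    list(label = 2L, shape = "cylinder", center = c(-2, -4.5, 0),
         radius = 2.8, half_height = 6),
    list(label = 3L, shape = "cylinder", center = c(-2, 0, 0),
         radius = 1.4, half_height = 10),
    list(label = 4L, shape = "ellipsoid", center = c(2.5, 0, 1),
         semiaxes = c(2.4, 2.4, 3))
  )
}

#' Nearest mesh node to a point
#' @param mesh a `tetmesh`.
#' @param p length-3 coordinate (mm).
#' @return node index (ties broken by lowest index).
#' @export
nearest_node <- function(mesh, p) {
  d2 <- (mesh$nodes[, 1] - p[1])^2 + (mesh$nodes[, 2] - p[2])^2 +
        (mesh$nodes[, 3] - p[3])^2
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

#' Place ground-truth sources on mesh nodes
#'
#' Each source is a sphere (`center`, `radius`, `density`): every node
#' within `radius` of the center is assigned exactly `density` (power per
#' unit volume, arbitrary units). `radius = 0` assigns the single nearest
#' node. Later sources overwrite earlier ones on shared nodes. The snapped
#' center of each source — the density-weighted centroid of the nodes it
#' was actually assigned to, which reduces to the single nearest node for
#' `radius = 0` — is recorded so that localization is judged against the
#' source as it exists on the mesh, not against the off-mesh request.
#'
#' @param mesh a `tetmesh`.
#' @param sources list of `list(center =, radius =, density =)`.
#' @return length-n numeric nodal vector with attributes
#'   `snapped_centers` (k x 3 matrix) and `snapped_nodes` (indices).
#' @export
place_sources <- function(mesh, sources) {
  n <- nrow(mesh$nodes)
  s <- numeric(n)
  snapped <- matrix(numeric(0), 0, 3)
  snodes <- integer(0)
  bb <- apply(mesh$nodes, 2, range)
  for (src in sources) {
    ctr <- src$center
    stopifnot(src$radius >= 0, src$density > 0)
    if (any(ctr < bb[1, ] - 1e-9) || any(ctr > bb[2, ] + 1e-9))
      stop("source center (", paste(ctr, collapse = ", "),
           ") lies outside the mesh bounding volume")
    j <- nearest_node(mesh, ctr)
    if (src$radius == 0) {
      sel <- j
    } else {
      d2 <- (mesh$nodes[, 1] - ctr[1])^2 + (mesh$nodes[, 2] - ctr[2])^2 +
            (mesh$nodes[, 3] - ctr[3])^2
      sel <- which(d2 <= src$radius^2)
      if (!length(sel)) {
        warning("no node within radius of source center; using nearest node")
        sel <- j
      }
    }
    s[sel] <- src$density
    snapped <- rbind(snapped, colMeans(mesh$nodes[sel, , drop = FALSE]))
    snodes <- c(snodes, j)
  }
  attr(s, "snapped_centers") <- snapped
  attr(s, "snapped_nodes") <- snodes
  s
}

#' Build a phantom from a named preset
#'
#' Presets:
#' * `"cylinder_4tissue"`: heterogeneous cylinder, 20 mm diameter and
#'   height, four tissues (muscle/lungs/bone/heart) with tabulated
#'   excitation- and emission-wavelength optics, and two spherical sources
#'   S1 at (6, 5, 0) and S2 at (6, -5, 0) mm (radius 1 mm, unit density).
#' * `"mouse_tissues"`: attaches tabulated murine tissue optics
#'   (single channel, labels 1..8) to a user-supplied labeled mesh.
#' * `"homogeneous"`: single-region cylinder with user-supplied optics.
#'
#' @param preset_name one of the presets above.
#' @param resolution target mesh edge length in mm (cylinder presets).
#' @param seed forwarded to the mesh generator (deterministic anyway).
#' @param mesh labeled `tetmesh`, required for `"mouse_tissues"`.
#' @param optics named `list(emission = , excitation = )` of per-label
#'   optics lists, required for `"homogeneous"` (emission only is enough).
#' @param sources list of sources as for [place_sources()]; defaults to the
#'   S1/S2 pair for `"cylinder_4tissue"`, empty otherwise.
#' @param layout inclusion layout for `"cylinder_4tissue"`; defaults to
#'   [default_cylinder_layout()].
#' @return a `phantom`: list with `mesh`, `optics_by_region` (per channel),
#'   `sources`, `true_source_vector`, `true_centers` (snapped, k x 3).
#' @export
make_phantom <- function(preset_name, resolution = 1.1, seed = 0L,
                         mesh = NULL, optics = NULL, sources = NULL,
                         layout = NULL) {
  presets <- c("cylinder_4tissue", "mouse_tissues", "homogeneous")
  if (!preset_name %in% presets)
    config_error("unknown preset '", preset_name, "'; available: ",
                 paste(presets, collapse = ", "))
  if (preset_name == "cylinder_4tissue") {
    mesh <- generate_cylinder_mesh(10, 20, resolution, seed)
    if (is.null(layout)) layout <- default_cylinder_layout()
    mesh <- assign_cylinder_regions(mesh, layout)
    optics <- load_preset_optics("optics_cylinder_4tissue.csv")
    if (is.null(sources))
      sources <- list(list(center = c(6, 5, 0), radius = 1, density = 1),
                      list(center = c(6, -5, 0), radius = 1, density = 1))
  } else if (preset_name == "mouse_tissues") {
    if (is.null(mesh))
      stop("preset 'mouse_tissues' requires a labeled mesh")
    optics <- load_preset_optics("optics_mouse_tissues.csv")
    if (is.null(sources)) sources <- list()
  } else {
    if (is.null(optics))
      stop("preset 'homogeneous' requires optics")
    if (is.null(mesh)) mesh <- generate_cylinder_mesh(10, 20, resolution, seed)
    mesh$region <- rep(1L, nrow(mesh$tets))
    if (!is.null(names(optics)) && all(names(optics) %in%
                                       c("emission", "excitation"))) {
      # already per-channel
    } else {
      optics <- list(emission = list(`1` = optics))
    }
    if (is.null(sources)) sources <- list()
  }
  phantom(mesh, optics, sources)
}

#' Construct a phantom from parts
#' @param mesh labeled `tetmesh`.
#' @param optics_by_region per-channel list: `optics_by_region$emission` is
#'   a list mapping region label (as character) to `optical_properties`;
#'   an `excitation` channel is optional.
#' @param sources list of sources (see [place_sources()]).
#' @return a `phantom` object.
#' @export
phantom <- function(mesh, optics_by_region, sources = list()) {
  stopifnot(inherits(mesh, "tetmesh"))
  labs <- unique(mesh$region)
  for (ch in names(optics_by_region)) {
    miss <- setdiff(as.character(labs), names(optics_by_region[[ch]]))
    if (length(miss))
      stop("regions without optics in channel '", ch, "': ",
           paste(miss, collapse = ", "))
  }
  sv <- place_sources(mesh, sources)
  structure(list(mesh = mesh, optics_by_region = optics_by_region,
                 sources = sources, true_source_vector = sv,
                 true_centers = attr(sv, "snapped_centers"),
                 true_nodes = attr(sv, "snapped_nodes")),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d nodes, %d tets, %d region(s), channels: %s\n",
              nrow(x$mesh$nodes), nrow(x$mesh$tets),
              length(unique(x$mesh$region)),
              paste(names(x$optics_by_region), collapse = ", ")))
  if (length(x$sources))
    for (i in seq_along(x$sources)) {
      s <- x$sources[[i]]
      cat(sprintf("  source %d: center (%g, %g, %g) mm, radius %g mm, density %g (snapped to (%g, %g, %g))\n",
                  i, s$center[1], s$center[2], s$center[3], s$radius,
                  s$density, x$true_centers[i, 1], x$true_centers[i, 2],
                  x$true_centers[i, 3]))
    }
  invisible(x)
}

#' Write a phantom to a directory (VTK mesh + JSON description)
#'
#' The mesh (with region labels and the true source vector as the `source`
#' nodal field) is written to `mesh.vtk`; optics and source specifications
#' to `phantom.json`. [read_phantom()] reproduces optics and source vectors
#' exactly.
#'
#' @param ph a `phantom`.
#' @param dir output directory (created if missing).
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh_vtk(ph$mesh, file.path(dir, "mesh.vtk"),
                 point_data = list(source = as.numeric(ph$true_source_vector)))
  desc <- list(
    optics_by_region = lapply(ph$optics_by_region, function(ch)
      lapply(ch, function(o) o[c("mu_a", "mu_s_prime", "refractive_index")])),
    sources = ph$sources
  )
  jsonlite::write_json(desc, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#' @param dir directory containing `mesh.vtk` and `phantom.json`.
#' @return a `phantom`.
#' @export
read_phantom <- function(dir) {
  mv <- read_mesh_vtk(file.path(dir, "mesh.vtk"))
  desc <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = FALSE)
  optics <- lapply(desc$optics_by_region, function(ch)
    lapply(ch, function(o)
      optical_properties(o$mu_a, o$mu_s_prime, o$refractive_index)))
  sources <- lapply(desc$sources, function(s)
    list(center = unlist(s$center), radius = s$radius, density = s$density))
  phantom(mv$mesh, optics, sources)
}
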