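test_that("P1 element matrices match the closed-form mass matrix", {
  m <- unit_tet()
  sys <- assemble_diffusion_system(m, homogeneous_optics(1, 1e-9, 1))
  V <- 1 / 6
  Mref <- matrix(V / 20, 4, 4); diag(Mref) <- V / 10
  expect_equal(as.matrix(sys$M), Mref, ignore_attr = TRUE,
               tolerance = 1e-12)
  # with mu_s' -> 0 and n = 1 (matched boundary), K = D*stiffness +
  # mu_a*M + boundary mass/2; check the absorption part by subtracting
  # the analytic stiffness for D = 1/(3(mu_a + mu_s'))
  g <- rbind(c(-1, -1, -1), diag(3))    # barycentric gradients
  Kdiff <- (1 / 3) * V * g %*% t(g) / 1  # D = 1/3 at mu_a=1, mu_s'=0
  D <- 1 / (3 * (1 + 1e-9))
  Kdiff <- D * V * g %*% t(g)
  bnd <- as.matrix(sys$K) - Kdiff - Mref
  # remaining term is the Robin face mass with alpha = 1/2 on all 4 faces
  expect_true(all(bnd >= -1e-12))
  expect_equal(sum(bnd), 0.5 * (3 * 0.5 + sqrt(3) / 2),
               tolerance = 1e-12)  # alpha * total boundary area
})

test_that("assembled operators are symmetric positive definite", {
  m <- small_cylinder()
  m$region <- rep(1:2, length.out = nrow(m$tets))
  optics <- list(`1` = optical_properties(0.01, 1),
                 `2` = optical_properties(0.02, 1.5))
  sys <- assemble_diffusion_system(m, optics)
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(assemble_diffusion_system(m, optics[1]), "2")
})

test_that("FEM fluence matches the infinite-medium Green's function mid-range", {
  # homogeneous cylinder, point source at the center; in the diffusion
  # model phi(r) = exp(-mu_eff r) / (4 pi D r) away from boundaries
  mu_a <- 0.02; mu_s <- 1.0
  m <- generate_cylinder_mesh(10, 20, 0.8, 0)
  sys <- assemble_diffusion_system(m, homogeneous_optics(mu_a, mu_s))
  j <- nearest_node(m, c(0, 0, 0))
  b <- numeric(nrow(m$nodes)); b[j] <- 1
  phi <- as.numeric(Matrix::solve(sys$K, b))
  D <- 1 / (3 * (mu_a + mu_s))
  mu_eff <- sqrt(mu_a / D)
  r <- sqrt(rowSums((t(t(m$nodes) - m$nodes[j, ]))^2))
  for (r0 in c(2, 3, 4, 5, 6)) {
    sel <- which(abs(r - r0) < 0.3)
    got <- mean(phi[sel])
    want <- mean(exp(-mu_eff * r[sel]) / (4 * pi * D * r[sel]))
    expect_lt(abs(got - want) / want, 0.15)
  }
})

test_that("raising absorption lowers every sensitivity entry", {
  m <- small_cylinder()
  det <- place_detectors(m, 2, 180)
  make <- function(mu_a) {
    ph <- phantom(m, list(emission = homogeneous_optics(mu_a, 1)))
    build_sensitivity_matrix(ph, det, channel = "emission-only")$entries
  }
  A1 <- make(0.01); A2 <- make(0.05)
  expect_true(all(A2 < A1))
})

test_that("detector arcs sit opposite their excitation within the field of view", {
  m <- small_cylinder()
  det <- place_detectors(m, 2, 160)
  ang <- function(nodes) atan2(m$nodes[nodes, 2], m$nodes[nodes, 1]) * 180 / pi
  a1 <- ang(det$groups[[1]]) %% 360       # excitation at 0 deg
  expect_true(all(a1 >= 100 - 1e-6 & a1 <= 260 + 1e-6))
  # opposite arcs of 160 deg do not overlap
  expect_length(intersect(det$groups[[1]], det$groups[[2]]), 0)
  # full field of view sees every lateral boundary node
  det360 <- place_detectors(m, 1, 360)
  r <- sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2)
  bn <- sort(unique(as.vector(m$boundary_faces)))
  lat <- bn[r[bn] >= max(r[bn]) * (1 - 1e-6)]
  expect_setequal(det360$groups[[1]], lat)
})

test_that("sensitivity matrix obeys reciprocity and the Born identity", {
  m <- small_cylinder()
  ph <- phantom(m, list(emission = homogeneous_optics(0.01, 1),
                        excitation = homogeneous_optics(0.013, 1.2)))
  det <- place_detectors(m, 2, 360)
  sens <- build_sensitivity_matrix(ph, det, channel = "emission-only")
  # emission-only: the row blocks of the two excitations are identical
  g1 <- which(sens$row_meta$excitation == 1)
  g2 <- which(sens$row_meta$excitation == 2)
  i2 <- match(sens$row_meta$detector_node[g1],
              sens$row_meta$detector_node[g2])
  common <- which(!is.na(i2))
  expect_gt(length(common), 0)
  expect_equal(sens$entries[g1[common], ],
               sens$entries[g2[i2[common]], ], tolerance = 1e-12)
  # reciprocity: entry by direct forward solve equals the adjoint value
  sys <- assemble_diffusion_system(m, ph$optics_by_region$emission)
  d <- sens$row_meta$detector_node[5]
  jcol <- 7L; j <- sens$col_meta[jcol]
  q <- numeric(nrow(m$nodes)); q[j] <- 1
  fwd <- as.numeric(Matrix::solve(sys$K, sys$M %*% q))[d]
  expect_lt(abs(fwd - sens$entries[5, jcol]) / abs(fwd), 1e-10)
  # Born form with unit excitation fluence reduces to emission-only
  ones <- matrix(1, nrow(m$nodes), 2)
  sens_b <- build_sensitivity_matrix(ph, det, channel = "excitation-weighted",
                                     excitation_fluence = ones)
  expect_equal(sens_b$entries, sens$entries, tolerance = 1e-12)
  # physical nonnegativity up to discretization floor, no all-zero rows
  expect_gte(min(sens$entries), -1e-8 * max(sens$entries))
  expect_true(all(apply(abs(sens$entries), 1, max) > 0))
})

test_that("measurement simulation is exact at zero noise and seeded otherwise", {
  m <- small_cylinder()
  ph <- phantom(m, list(emission = homogeneous_optics(0.01, 1)),
                sources = list(list(center = c(1, 0, 0), radius = 1,
                                    density = 1)))
  det <- place_detectors(m, 2, 180)
  sens <- build_sensitivity_matrix(ph, det, channel = "emission-only")
  meas <- simulate_measurements(sens, ph$true_source_vector)
  expect_equal(meas$values,
               as.numeric(sens$entries %*%
                            ph$true_source_vector[sens$col_meta]))
  expect_equal(simulate_measurements(sens, numeric(nrow(m$nodes)))$values,
               numeric(nrow(sens$entries)))
  expect_equal(simulate_measurements(diag(3), c(1, 2, 3))$values, c(1, 2, 3))
  n1 <- simulate_measurements(sens, ph$true_source_vector, 0.05, seed = 4)
  n2 <- simulate_measurements(sens, ph$true_source_vector, 0.05, seed = 4)
  n3 <- simulate_measurements(sens, ph$true_source_vector, 0.05, seed = 5)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
})

test_that("permissible source region restriction keeps column metadata", {
  m <- small_cylinder()
  ph <- phantom(m, list(emission = homogeneous_optics(0.01, 1)),
                sources = list(list(center = c(1, 0, 0), radius = 1,
                                    density = 1)))
  det <- place_detectors(m, 2, 180)
  sens <- build_sensitivity_matrix(ph, det, channel = "emission-only")
  whole <- restrict_psr(sens, m, rbind(c(-10, 10), c(-10, 10), c(-10, 10)))
  expect_identical(whole$entries, sens$entries)
  # a box holding exactly one candidate node
  j <- sens$col_meta[3]
  p <- m$nodes[j, ]
  one <- restrict_psr(sens, m, rbind(p[1] + c(-.01, .01), p[2] + c(-.01, .01),
                                     p[3] + c(-.01, .01)))
  expect_identical(one$col_meta, j)
  expect_equal(ncol(one$entries), 1L)
  expect_error(restrict_psr(sens, m, rbind(c(90, 99), c(0, 1), c(0, 1))),
               "no candidate node")
  # reconstruction from a restricted matrix re-embeds with zeros outside
  box <- rbind(c(0, 5), c(-5, 5), c(-3, 3))
  psr <- restrict_psr(sens, m, box)
  meas <- simulate_measurements(psr, ph$true_source_vector)
  fit <- reconstruct(psr, meas, "lbsr")
  out <- setdiff(seq_len(nrow(m$nodes)), psr$col_meta)
  expect_true(all(fit$S[out] == 0))
})

test_that("the torso-coordinate permissible source region restricts a shifted phantom", {
  # the published PSR box lives in micro-CT torso coordinates; emulate it
  # on synthetic data by translating a cylinder into that frame
  m <- small_cylinder()
  m$nodes <- sweep(m$nodes, 2, c(22, 32, 7), "+")
  m <- tet_mesh(m$nodes, m$tets, m$region)
  ph <- phantom(m, list(emission = homogeneous_optics(0.01, 1)),
                sources = list(list(center = c(20, 30, 5), radius = 0,
                                    density = 1)))
  det <- place_detectors(m, 2, 200)
  sens <- build_sensitivity_matrix(ph, det, channel = "emission-only")
  box <- rbind(c(10, 25), c(15, 35), c(2, 10))
  psr <- restrict_psr(sens, m, box)
  expect_lt(ncol(psr$entries), ncol(sens$entries))
  xyz <- m$nodes[psr$col_meta, , drop = FALSE]
  expect_true(all(xyz[, 1] >= 10 & xyz[, 1] <= 25 &
                  xyz[, 2] >= 15 & xyz[, 2] <= 35 &
                  xyz[, 3] >= 2 & xyz[, 3] <= 10))
  # the true source lies inside the box, so restriction preserves recovery
  meas <- simulate_measurements(psr, ph$true_source_vector)
  fit <- reconstruct(psr, meas, "lbsr")
  rep <- evaluate_run(ph, fit)
  expect_lt(max(rep$per_source$le_mm), 1.0)
})

test_that("sensitivity matrices persist through the binary + sidecar format", {
  m <- small_cylinder()
  ph <- phantom(m, list(emission = homogeneous_optics(0.01, 1)))
  det <- place_detectors(m, 2, 180)
  sens <- build_sensitivity_matrix(ph, det, channel = "emission-only")
  base <- tempfile()
  write_sensitivity(sens, base)
  rt <- read_sensitivity(base)
  expect_equal(rt$entries, sens$entries)
  expect_identical(rt$col_meta, sens$col_meta)
  expect_equal(rt$row_meta, sens$row_meta)
  expect_identical(rt$channel, sens$channel)
})
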