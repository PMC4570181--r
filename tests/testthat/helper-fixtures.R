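# shared fixtures built in code at test time

small_cylinder <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cylinder_mesh(5, 6, 1.6, 0)
    cache
  }
})

homogeneous_optics <- function(mu_a = 0.01, mu_s = 1.0, n = 1.37)
  list(`1` = optical_properties(mu_a, mu_s, n))

# single reference tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1)
unit_tet <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tet_mesh(nodes, matrix(1:4, 1, 4))
}

gaussian_instance <- function(m, n, k, seed, density = 1) {
  set.seed(seed)
  A <- matrix(rnorm(m * n), m, n)
  s <- numeric(n)
  s[sample.int(n, k)] <- density * runif(k, 0.5, 1.5)
  list(A = A, s_true = s, phi = as.numeric(A %*% s))
}
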