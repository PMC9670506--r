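# Shared fixtures, built in code.

chart_nb <- build_icosahedron()                       # neighbor-anchored frames
chart_tp <- build_icosahedron(frames = "transport")   # spec transport frames
grid_ref <- build_kernel_grid(0.6, 5L, 2L, TRUE)      # the reference 11-point grid

# a smooth deterministic test function on the sphere (no interpolation error)
smooth_fn <- function(p) {
  sin(3 * p[1]) + 0.5 * p[2]^2 - cos(2 * p[3]) + 0.3 * p[1] * p[2]
}

# sampled-values array (12, 1, K) for one channel by direct evaluation
sampled_values_for <- function(chart, grid, fn = smooth_fn) {
  K <- nrow(grid$offsets)
  sv <- array(0, dim = c(12, 1, K))
  for (v in 1:12) {
    pts <- sample_points_for_vertex(chart, v, grid)
    sv[v, 1, ] <- apply(pts, 1, fn)
  }
  sv
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

random_lift_kernel <- function(cin = 1, cout = 1, K = 11) {
  lift_kernel(array(stats::rnorm(cin * cout * K), dim = c(cin, cout, K)),
              stats::rnorm(cout))
}

random_group_kernel <- function(cin = 1, cout = 1, nr = 5) {
  group_kernel(array(stats::rnorm(cin * cout * nr), dim = c(cin, cout, nr)),
               stats::rnorm(cout))
}

# the composed network on raw sampled values (no Watson), for invariance tests
compose_net <- function(sv, kl, kg, grid) {
  project_max(relu(group_correlate(relu(lift_forward(sv, kl, grid)), kg)))
}
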