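test_that("a delta kernel at the center reads off the vertex value at every rotation", {
  sv <- sampled_values_for(chart_nb, grid_ref)
  w <- array(0, dim = c(1, 1, 11))
  w[1, 1, 1] <- 1                             # offset 1 is the center
  F <- lift_forward(sv, lift_kernel(w, 0), grid_ref)
  for (k in 1:5)
    expect_equal(F[, k, 1], sv[, 1, 1], tolerance = 1e-14)
})

test_that("a constant input lifts to c * sum(w) + bias everywhere", {
  sv <- array(2.5, dim = c(12, 1, 11))
  set.seed(20)
  kl <- random_lift_kernel()
  F <- lift_forward(sv, kl, grid_ref)
  expect_equal(as.numeric(F), rep(2.5 * sum(kl$weights) + kl$bias, 60),
               tolerance = 1e-12)
})

test_that("lift_forward and group_correlate are linear in their inputs", {
  set.seed(21)
  kl <- random_lift_kernel(cin = 2, cout = 3)
  kl$bias[] <- 0
  sv1 <- array(stats::rnorm(12 * 2 * 11), dim = c(12, 2, 11))
  sv2 <- array(stats::rnorm(12 * 2 * 11), dim = c(12, 2, 11))
  expect_equal(lift_forward(sv1 + 2 * sv2, kl, grid_ref),
               lift_forward(sv1, kl, grid_ref) +
                 2 * lift_forward(sv2, kl, grid_ref),
               tolerance = 1e-10)
  kg <- random_group_kernel(cin = 3, cout = 2)
  kg$bias[] <- 0
  F1 <- array(stats::rnorm(12 * 5 * 3), dim = c(12, 5, 3))
  F2 <- array(stats::rnorm(12 * 5 * 3), dim = c(12, 5, 3))
  expect_equal(group_correlate(F1 + 3 * F2, kg),
               group_correlate(F1, kg) + 3 * group_correlate(F2, kg),
               tolerance = 1e-10)
})

test_that("re-anchoring one vertex's frame by 2*pi/5 shifts its rotation axis one slot", {
  v <- 4L
  chart2 <- rotate_vertex_frame(chart_nb, v, 2 * pi / 5)
  set.seed(22)
  kl <- random_lift_kernel()
  F0 <- lift_forward(sampled_values_for(chart_nb, grid_ref), kl, grid_ref)
  F1 <- lift_forward(sampled_values_for(chart2, grid_ref), kl, grid_ref)
  # other vertices untouched
  expect_equal(F1[-v, , ], F0[-v, , ], tolerance = 1e-9)
  # rotated frame: new ray i points where old ray i+1 pointed, so the lift
  # at rotation k now equals the old lift at rotation k-1 (cyclic)
  expect_equal(F1[v, , 1], F0[v, c(5, 1, 2, 3, 4), 1], tolerance = 1e-9)
})

test_that("group correlation matches the brute-force double sum on 100 random instances", {
  set.seed(23)
  worst <- 0
  for (rep in 1:100) {
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    F <- array(stats::rnorm(12 * 5 * cin), dim = c(12, 5, cin))
    kg <- random_group_kernel(cin = cin, cout = cout)
    out <- group_correlate(F, kg)
    # O(25) oracle per vertex/channel
    oracle <- array(0, dim = c(12, 5, cout))
    for (vtx in 1:12) for (s in 0:4) for (co in seq_len(cout)) {
      acc <- kg$bias[co]
      for (r in 0:4) for (ci in seq_len(cin))
        acc <- acc + F[vtx, r + 1, ci] * kg$weights[ci, co, ((r - s) %% 5) + 1]
      oracle[vtx, s + 1, co] <- acc
    }
    worst <- max(worst, max(abs(out - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("a delta group kernel at rotation zero returns the channel-summed input", {
  set.seed(24)
  F <- array(stats::rnorm(12 * 5 * 3), dim = c(12, 5, 3))
  w <- array(0, dim = c(3, 1, 5))
  w[, 1, 1] <- 1
  out <- group_correlate(F, group_kernel(w, 0.25))
  expect_equal(out[, , 1], apply(F, c(1, 2), sum) + 0.25, tolerance = 1e-12)
})

test_that("group correlation is equivariant to cyclic shifts of the rotation axis", {
  set.seed(25)
  F <- array(stats::rnorm(12 * 5 * 2), dim = c(12, 5, 2))
  kg <- random_group_kernel(cin = 2, cout = 2)
  sh <- function(A, m) A[, ((seq_len(5) - 1 + m) %% 5) + 1, , drop = FALSE]
  for (m in 1:4)
    expect_equal(group_correlate(sh(F, m), kg), sh(group_correlate(F, kg), m),
                 tolerance = 1e-12)
})

test_that("projection is the rotation max and shift-invariant; relu behaves", {
  set.seed(26)
  F <- array(stats::rnorm(12 * 5 * 4), dim = c(12, 5, 4))
  M <- project_max(F)
  expect_equal(dim(M), c(12, 4))
  expect_equal(M, apply(F, c(1, 3), max))
  Fc <- array(1.5, dim = c(12, 5, 2))
  expect_equal(project_max(Fc), matrix(1.5, 12, 2))
  sh <- F[, c(3, 4, 5, 1, 2), , drop = FALSE]
  expect_equal(project_max(sh), M)
  x <- c(-2, 0, 3.5)
  expect_equal(relu(x), c(0, 0, 3.5))
  expect_equal(relu(relu(F)), relu(F))
})

test_that("lift then group correlation without ReLU factors into a single lifting", {
  set.seed(27)
  cin <- 2; cl <- 3; co <- 2
  kl <- random_lift_kernel(cin = cin, cout = cl)
  kg <- random_group_kernel(cin = cl, cout = co)
  sv <- array(stats::rnorm(12 * cin * 11), dim = c(12, cin, 11))
  composed <- group_correlate(lift_forward(sv, kl, grid_ref), kg)
  # equivalent single lifting kernel:
  # W'[ci,co,j] = sum_m sum_cl wl[ci,cl,sigma_{-m}(j)] * wg[cl,co,m+1]
  P <- bgcnn:::grid_rotation_permutations(grid_ref)
  W2 <- array(0, dim = c(cin, co, 11))
  for (m in 0:4) {
    pm_inv <- P[((5 - m) %% 5) + 1, ]
    for (ci in seq_len(cin)) for (c2 in seq_len(co)) for (j in 1:11) {
      W2[ci, c2, j] <- W2[ci, c2, j] +
        sum(kl$weights[ci, , pm_inv[j]] * kg$weights[, c2, m + 1])
    }
  }
  b2 <- sapply(seq_len(co), function(c2)
    sum(kl$bias * rowSums(kg$weights[, c2, , drop = FALSE][, 1, ])) + kg$bias[c2])
  direct <- lift_forward(sv, lift_kernel(W2, b2), grid_ref)
  expect_equal(composed, direct, tolerance = 1e-10)
})

test_that("the composed network is exactly invariant under 2*pi/5 re-anchorings", {
  set.seed(28)
  kl <- random_lift_kernel()
  kg <- random_group_kernel(cin = 1, cout = 5)
  ref <- compose_net(sampled_values_for(chart_nb, grid_ref), kl, kg, grid_ref)
  # random per-vertex multiples of 2*pi/5
  chart2 <- chart_nb
  for (v in 1:12)
    chart2 <- rotate_vertex_frame(chart2, v, sample(0:4, 1) * 2 * pi / 5)
  out <- compose_net(sampled_values_for(chart2, grid_ref), kl, kg, grid_ref)
  expect_equal(out, ref, tolerance = 1e-6)
})

test_that("the composed network is invariant under base-vertex change after grid realignment", {
  set.seed(29)
  kl <- random_lift_kernel()
  kg <- random_group_kernel(cin = 1, cout = 5)
  ref_chart <- chart_tp
  ref <- compose_net(sampled_values_for(ref_chart, grid_ref), kl, kg, grid_ref)
  for (b in c(4L, 9L)) {
    other <- build_icosahedron(base_index = b, frames = "transport")
    snapped <- realign_frames(other, ref_chart)
    out <- compose_net(sampled_values_for(snapped, grid_ref), kl, kg, grid_ref)
    expect_equal(out, ref, tolerance = 1e-6)
  }
})

test_that("arbitrary-angle re-anchoring is only approximately neutral", {
  set.seed(30)
  kl <- random_lift_kernel()
  kg <- random_group_kernel(cin = 1, cout = 5)
  ref <- compose_net(sampled_values_for(chart_nb, grid_ref), kl, kg, grid_ref)
  chart2 <- chart_nb
  for (v in 1:12)
    chart2 <- rotate_vertex_frame(chart2, v, stats::runif(1, 0, 2 * pi))
  out <- compose_net(sampled_values_for(chart2, grid_ref), kl, kg, grid_ref)
  expect_gt(max(abs(out - ref)), 1e-8)               # not exact
  # the residual is the error of discretising SO(2) by 5 rotations; with an
  # unsmoothed test function and random kernels it stays well under the
  # feature scale
  expect_lt(max(abs(out - ref)) / max(abs(ref)), 0.5)
})

test_that("lift_forward rejects grids without full cyclic symmetry", {
  g <- grid_ref
  g$ray_of[2] <- 3L                               # corrupt the layout
  sv <- array(0, dim = c(12, 1, 11))
  expect_error(lift_forward(sv, random_lift_kernel(), g), "symmetry")
})
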