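test_that("icosahedral chart has the regular-icosahedron combinatorics", {
  for (chart in list(chart_nb, chart_tp)) {
    expect_equal(nrow(chart$vertices), 12)
    expect_true(all(lengths(chart$adjacency) == 5))
    n_edges <- sum(lengths(chart$adjacency)) / 2
    expect_equal(n_edges, 30)
    # adjacent vertices subtend arccos(1/sqrt(5))
    for (i in 1:12) {
      d <- chart$vertices[chart$adjacency[[i]], ] %*% chart$vertices[i, ]
      expect_true(all(abs(d - 1 / sqrt(5)) < 1e-10))
    }
    expect_equal(acos(1 / sqrt(5)), 1.10715, tolerance = 1e-5)
    # vertex 1 at the north pole by convention, unit norms
    expect_equal(chart$vertices[1, ], c(0, 0, 1), tolerance = 1e-12)
    expect_true(all(abs(sqrt(rowSums(chart$vertices^2)) - 1) < 1e-12))
  }
})

test_that("every vertex's antipode is also a vertex (6 pairs)", {
  V <- chart_nb$vertices
  partner <- sapply(1:12, function(i) {
    which(apply(V, 1, function(w) max(abs(w + V[i, ]))) < 1e-9)
  })
  expect_true(all(lengths(partner) == 1))
  expect_setequal(unlist(partner), 1:12)
})

test_that("chart construction is deterministic (bitwise identical)", {
  expect_identical(build_icosahedron(), build_icosahedron())
  expect_identical(build_icosahedron(frames = "transport"),
                   build_icosahedron(frames = "transport"))
})

test_that("frames are right-handed orthonormal triples at every vertex", {
  for (chart in list(chart_nb, chart_tp)) {
    for (i in 1:12) {
      e1 <- chart$e1[i, ]; e2 <- chart$e2[i, ]; v <- chart$vertices[i, ]
      expect_lt(max(abs(c(sum(e1 * e2), sum(e1 * v), sum(e2 * v)))), 1e-10)
      expect_lt(abs(sum(e1^2) - 1), 1e-10)
      expect_lt(abs(sum(e2^2) - 1), 1e-10)
      expect_lt(abs(det(rbind(e1, e2, v)) - 1), 1e-10)
    }
  }
})

test_that("exp_map fixes the zero vector and hits known closed forms", {
  x <- c(0, 0, 1)
  expect_identical(exp_map(x, c(0, 0, 0)), x)
  # quarter great circle from the north pole along e1 = (1,0,0)
  expect_equal(exp_map(x, c(pi / 2, 0, 0)), c(1, 0, 0), tolerance = 1e-12)
  # half great circle reaches the antipode
  expect_equal(exp_map(x, c(pi, 0, 0)), -x, tolerance = 1e-12)
})

test_that("log_map is the inverse of exp_map and rejects the antipode", {
  x <- c(0, 0, 1)
  expect_equal(log_map(x, x), c(0, 0, 0))
  expect_error(log_map(x, -x), "antipode")
  # |log| equals the geodesic distance
  y <- c(1, 0, 0)
  expect_equal(sqrt(sum(log_map(x, y)^2)), pi / 2, tolerance = 1e-12)
})

test_that("exp/log roundtrip holds over 1000 random tangent vectors", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    x <- as.numeric(random_unit_vectors(1))
    u <- stats::rnorm(3)
    u <- u - sum(u * x) * x                  # project to tangent plane
    u <- u / sqrt(sum(u^2)) * stats::runif(1, 0, 3)
    if (sqrt(sum(u^2)) >= pi) u <- u * (pi - 1e-3) / sqrt(sum(u^2))
    y <- exp_map(x, u)
    v <- log_map(x, y)
    worst <- max(worst, max(abs(v - u)), max(abs(exp_map(x, v) - y)))
  }
  expect_lt(worst, 1e-9)
})

test_that("parallel transport is the identity at the base and isometric", {
  f0 <- transport_frame(chart_tp, chart_tp$base_index)
  expect_equal(f0$e1, chart_tp$base_frame$e1, tolerance = 1e-12)
  expect_equal(f0$e2, chart_tp$base_frame$e2, tolerance = 1e-12)
  for (i in 1:12) {
    f <- transport_frame(chart_tp, i)
    G <- rbind(f$e1, f$e2)
    expect_lt(max(abs(G %*% t(G) - diag(2))), 1e-10)   # inner products kept
    expect_lt(max(abs(G %*% chart_tp$vertices[i, ])), 1e-10)
  }
})

test_that("transport along a meridian by pi/2 turns e1 downward", {
  # travelling from the north pole towards (1,0,0) with e1 the direction of
  # travel: after a quarter circle the travel direction points to -z.
  x0 <- c(0, 0, 1)
  target <- c(1, 0, 0)
  R <- rotation_about_axis(c(0, -1, 0), -pi / 2)  # x0 x target = (0,-1,0)
  e1_transported <- as.numeric(R %*% c(1, 0, 0))
  expect_equal(e1_transported, c(0, 0, -1), tolerance = 1e-12)
  # the same via the chart machinery: a Rodrigues oracle cross-check
  leg <- bgcnn:::.transport_leg(x0, target, c(1, 0, 0), c(0, 1, 0))
  expect_equal(leg$e1, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(leg$e2, c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(sum(leg$e1 * target)), 1e-12)
})

test_that("the kernel grid has the printed layout: 11 offsets, radius 0.6", {
  expect_equal(nrow(grid_ref$offsets), 11)
  expect_equal(sum(is.na(grid_ref$ray_of)), 1)          # one center
  radii <- sqrt(rowSums(grid_ref$offsets^2))
  expect_equal(max(radii), 0.6, tolerance = 1e-12)
  expect_setequal(round(radii[!is.na(grid_ref$ray_of)], 10), c(0.3, 0.6))
  # general count: n_rays * n_samples + center
  g2 <- build_kernel_grid(1, 7L, 3L, FALSE)
  expect_equal(nrow(g2$offsets), 21)
  expect_error(build_kernel_grid(0), "positive")
})

test_that("the offset set is invariant under rotation by 2*pi/5", {
  th <- 2 * pi / 5
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotated <- grid_ref$offsets %*% t(Rot)
  for (j in seq_len(nrow(rotated))) {
    d <- sqrt(rowSums((grid_ref$offsets -
                         matrix(rotated[j, ], 11, 2, byrow = TRUE))^2))
    expect_lt(min(d), 1e-12)
  }
  expect_lt(max(abs(rotated[1, ])), 1e-15)              # center fixed
})

test_that("vertex sample points stay in the kernel ball and balls overlap", {
  for (v in c(1, 5, 12)) {
    pts <- sample_points_for_vertex(chart_nb, v, grid_ref)
    expect_equal(nrow(pts), 11)
    expect_equal(pts[1, ], chart_nb$vertices[v, ], tolerance = 1e-12)
    gd <- acos(pmin(1, pts %*% chart_nb$vertices[v, ]))
    expect_lt(max(gd), 0.6 + 1e-9)
  }
  # two radius-0.6 balls at adjacent vertices overlap: 1.2 > edge length
  expect_gt(2 * 0.6, acos(1 / sqrt(5)))
})

test_that("neighbor-anchored rays point at the five neighbors", {
  for (i in 1:12) {
    v <- chart_nb$vertices[i, ]
    nb_dirs <- t(sapply(chart_nb$adjacency[[i]], function(j) {
      u <- log_map(v, chart_nb$vertices[j, ]); u / sqrt(sum(u^2))
    }))
    # each ray direction (angle 2*pi*k/5 in the frame) hits some neighbor
    for (k in 0:4) {
      ray <- cos(2 * pi * k / 5) * chart_nb$e1[i, ] +
        sin(2 * pi * k / 5) * chart_nb$e2[i, ]
      expect_lt(min(sqrt(rowSums((nb_dirs -
                                    matrix(ray, 5, 3, byrow = TRUE))^2))),
                1e-9)
    }
  }
})

test_that("realign_frames snaps transported frames onto the 5-fold grid", {
  other <- build_icosahedron(base_index = 7L, frames = "transport")
  snapped <- realign_frames(other, chart_nb)
  step <- 2 * pi / 5
  for (i in 1:12) {
    c_ <- sum(snapped$e1[i, ] * chart_nb$e1[i, ])
    s_ <- sum(snapped$e1[i, ] * chart_nb$e2[i, ])
    ang <- atan2(s_, c_) %% step
    expect_lt(min(ang, step - ang), 1e-9)
  }
})
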