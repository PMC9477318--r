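test_that("linear taper gives the expected tip radius and radius profile", {
  w <- build_gamma_like_whisker(arc_length_mm = 20,
                                material = material_params(
                                  base_radius_um = 100, taper_ratio = 15))
  expect_equal(w$radii[1], 100)
  expect_equal(w$radii[length(w$radii)], 6.666667, tolerance = 1e-6)
  expect_equal(w$radii[1] / w$radii[length(w$radii)], 15, tolerance = 1e-6)
  # radius at arc length s is exactly linear
  s <- c(0, 5, 10, 20)
  expect_equal(radius_at(w, s), 100 - (100 - 100 / 15) * s / 20)
  # radii strictly decreasing, arc lengths strictly increasing
  expect_true(all(diff(w$radii) < 0))
  expect_true(all(diff(w$arc_lengths) > 0))
})

test_that("gamma-like generator: planar limit, proximal planarity, distal rise", {
  wp <- build_gamma_like_whisker(outplane_coeff = 0)
  expect_true(all(wp$nodes[, 3] == 0))
  w <- build_gamma_like_whisker()
  L <- w$total_arc_length
  prox <- abs(w$nodes[w$arc_lengths <= 0.7 * L, 3])
  dist <- abs(w$nodes[w$arc_lengths > 0.7 * L, 3])
  expect_lt(max(prox), 0.05 * L)
  expect_gt(max(dist), max(prox))
  # conventions: base at origin, tip toward +y
  expect_equal(w$nodes[1, ], c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(w$nodes[nrow(w$nodes), 2], 0)
  # arc length preserved by construction/resampling within 0.1%
  expect_equal(w$total_arc_length, 20, tolerance = 1e-3)
})

test_that("generator rejects invalid parameters", {
  expect_error(build_gamma_like_whisker(arc_length_mm = -1), "positive")
  expect_error(build_gamma_like_whisker(n_nodes = 10), "n_nodes")
  expect_error(material_params(taper_ratio = 0.5), "taper_ratio")
  expect_error(material_params(poisson_ratio = 0.7), "poisson_ratio")
})

test_that("spherical/cartesian conversions match hand values and round trip", {
  expect_equal(as.numeric(spherical_to_cartesian(contact_point(10, 0, 0))),
               c(10, 0, 0))
  expect_equal(as.numeric(spherical_to_cartesian(contact_point(10, 90, 0))),
               c(0, 10, 0), tolerance = 1e-12)
  set.seed(7)
  n <- 1000
  cp <- contact_point(runif(n, 0.1, 30), runif(n, -179, 179),
                      runif(n, -89, 89))
  back <- cartesian_to_spherical(spherical_to_cartesian(cp))
  expect_equal(back$r_mm, cp$r_mm, tolerance = 1e-9)
  expect_equal(back$theta_deg, cp$theta_deg, tolerance = 1e-9)
  expect_equal(back$phi_deg, cp$phi_deg, tolerance = 1e-9)
  expect_error(cartesian_to_spherical(c(0, 0, 0)), "zero-length")
})

test_that("frame alignment is idempotent and rigid-motion invariant", {
  w <- build_gamma_like_whisker(n_nodes = 60)
  again <- to_whisker_frame(w$nodes)
  expect_equal(again, w$nodes, tolerance = 1e-9, ignore_attr = TRUE)
  # random rigid motion, then re-alignment, recovers the node set
  set.seed(11)
  for (rep in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -pi, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    moved <- sweep(w$nodes %*% t(R), 2, rnorm(3, sd = 5), "+")
    rec <- to_whisker_frame(moved)
    expect_equal(rec, w$nodes, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("a planar parabola opening toward -y is flipped into convention", {
  x <- seq(0, 15, length.out = 40)
  nodes <- cbind(x, -0.02 * x^2, 0)
  al <- to_whisker_frame(nodes)
  expect_gt(al[nrow(al), 2], 0)
})

test_that("degenerate inputs are rejected", {
  pts <- matrix(rep(c(1, 2, 3), each = 12), ncol = 3)
  expect_error(to_whisker_frame(pts), "degenerate|duplicate")
  expect_error(whisker_shape(matrix(rnorm(9), 3)), "n >= 10")
})

test_that("whisker point files round trip and arc length matches quadrature", {
  w <- build_gamma_like_whisker(n_nodes = 80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_whisker_points(w, path)
  w2 <- load_whisker_points(path, material = w$material, n_nodes = 80)
  expect_equal(w2$nodes, w$nodes, tolerance = 1e-6, ignore_attr = TRUE)

  # straight-line file: arc length equals the chord
  p2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(s_mm = seq(0, 12, length.out = 100),
                   x_mm = seq(0, 12, length.out = 100), y_mm = 0, z_mm = 0)
  write.csv(df, p2, row.names = FALSE)
  ws <- load_whisker_points(p2)
  expect_equal(ws$total_arc_length, 12, tolerance = 1e-6)

  # quadratic planar curve at 50 points: arc length vs numeric quadrature
  x <- seq(0, 10, length.out = 50)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x_mm = x, y_mm = 0.05 * x^2, z_mm = 0), p3,
            row.names = FALSE)
  wq <- load_whisker_points(p3)
  quad <- integrate(function(t) sqrt(1 + (0.1 * t)^2), 0, 10,
                    rel.tol = 1e-10)$value
  expect_equal(wq$total_arc_length, quad, tolerance = 1e-3)

  expect_error(load_whisker_points(withr::local_tempfile()), "cannot read")
  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x_mm = 1:5, y_mm = 0, z_mm = 0), p4,
            row.names = FALSE)
  expect_error(load_whisker_points(p4), "at least 10")
})
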