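test_that("base loads carry the applied force and its moment", {
  b <- base_reactions(c(0, -1, 0), c(10, 0, 0))
  expect_equal(unlist(b),
               c(Fx = 0, Fy = -1, Fz = 0, Mx = 0, My = 0, Mz = -10))
  expect_equal(unlist(base_reactions(c(0, 0, 0), c(5, 2, 1))),
               setNames(rep(0, 6), c("Fx", "Fy", "Fz", "Mx", "My", "Mz")))
  # |M| = |p||F| sin(angle) over random pairs
  set.seed(13)
  for (rep in 1:50) {
    f <- rnorm(3); p <- rnorm(3)
    b <- base_reactions(f, p)
    Mn <- sqrt(b$Mx^2 + b$My^2 + b$Mz^2)
    cosang <- sum(f * p) / sqrt(sum(f^2) * sum(p^2))
    expected <- sqrt(sum(p^2)) * sqrt(sum(f^2)) * sqrt(1 - cosang^2)
    expect_equal(Mn, expected, tolerance = 1e-12)
  }
})

test_that("small tip load on a uniform cylinder matches Euler-Bernoulli", {
  cyl <- straight_whisker(taper_ratio = 1)
  # F L^3 / (3 E I): 20 uN on a 20 mm, 100 um radius, 3 GPa rod
  EI <- 3e9 * pi * 0.1^4 / 4
  delta <- 20 * 20^3 / (3 * EI)
  r <- deflect_under_force(cyl, 100, c(0, 20, 0))
  expect_true(r$converged)
  expect_equal(r$nodes[100, 2], delta, tolerance = 0.01)
})

test_that("a target on the undeflected whisker needs no force", {
  w <- gamma_whisker()
  target <- cartesian_to_spherical(w$nodes[50, , drop = FALSE])
  d <- deflect_to_point(w, target)
  expect_true(d$converged)
  expect_equal(sqrt(sum(d$applied_force^2)), 0, tolerance = 1e-6)
  expect_equal(unlist(d$base_loads), setNames(rep(0, 6),
               c("Fx", "Fy", "Fz", "Mx", "My", "Mz")), tolerance = 1e-6)
})

test_that("planar large-deflection loads match an independent 2D integration", {
  w <- straight_whisker()
  target2d <- c(10 * cos(5 * pi / 180), 10 * sin(5 * pi / 180))
  oracle <- planar_elastica_oracle(target = target2d)
  expect_lt(oracle$residual, 5e-3)
  d <- deflect_to_point(w, contact_point(10, 5, 0))
  expect_true(d$converged)
  expect_equal(d$base_loads$Fx, oracle$force[1], tolerance = 0.01)
  expect_equal(d$base_loads$Fy, oracle$force[2], tolerance = 0.01)
  expect_equal(d$base_loads$Mz, oracle$moment_z, tolerance = 0.01)
})

test_that("converged deflections satisfy equilibrium and frictionless contact", {
  w <- gamma_whisker()
  targets <- list(c(10, 5, 0), c(12, 0, 10), c(8, -15, -10), c(16, 12, 5))
  for (tg in targets) {
    d <- deflect_to_point(w, contact_point(tg[1], tg[2], tg[3]))
    expect_true(d$converged)
    # static equilibrium closure to 1e-6 relative: the transmitted load is
    # the applied force and its moment about the base
    f <- d$applied_force; p <- d$contact_location
    expect_equal(c(d$base_loads$Fx, d$base_loads$Fy, d$base_loads$Fz), f,
                 tolerance = 1e-6)
    m <- c(p[2] * f[3] - p[3] * f[2], p[3] * f[1] - p[1] * f[3],
           p[1] * f[2] - p[2] * f[1])
    expect_equal(c(d$base_loads$Mx, d$base_loads$My, d$base_loads$Mz), m,
                 tolerance = 1e-6)
    # frictionless: force orthogonal to the contact tangent
    expect_lt(abs(sum(f * d$contact_tangent)) / max(sqrt(sum(f^2)), 1e-12),
              1e-6)
    # the deflected whisker passes through the target
    tgt <- as.numeric(spherical_to_cartesian(
      contact_point(tg[1], tg[2], tg[3])))
    expect_lt(sqrt(sum((d$contact_location - tgt)^2)), 0.011)
  }
})

test_that("base loads scale linearly with Young's modulus", {
  w1 <- build_gamma_like_whisker(material = material_params(
    youngs_modulus_GPa = 3))
  w2 <- build_gamma_like_whisker(material = material_params(
    youngs_modulus_GPa = 6))
  for (tg in list(c(10, 5, 0), c(12, -8, 6))) {
    d1 <- deflect_to_point(w1, contact_point(tg[1], tg[2], tg[3]))
    d2 <- deflect_to_point(w2, contact_point(tg[1], tg[2], tg[3]))
    expect_true(d1$converged && d2$converged)
    expect_equal(unlist(d2$base_loads), 2 * unlist(d1$base_loads),
                 tolerance = 1e-5)
    # same converged geometry
    expect_equal(d2$contact_arc_length, d1$contact_arc_length,
                 tolerance = 1e-3)
  }
})

test_that("planar whisker with in-plane targets keeps Fz, Mx, My at zero", {
  w <- planar_whisker()
  for (tg in list(c(10, 5, 0), c(14, -6, 0), c(8, 18, 0))) {
    d <- deflect_to_point(w, contact_point(tg[1], tg[2], tg[3]))
    expect_true(d$converged)
    ref <- max(abs(unlist(d$base_loads)))
    expect_lt(abs(d$base_loads$Fz) / ref, 1e-8)
    expect_lt(abs(d$base_loads$Mx) / ref, 1e-8)
    expect_lt(abs(d$base_loads$My) / ref, 1e-8)
  }
})

test_that("bending moment approaches force times arc length for tiny deflections", {
  w <- straight_whisker()
  s_c <- 10
  d <- deflect_to_point(w, contact_point(s_c, 1, 0))  # ~1 degree deflection
  expect_true(d$converged)
  sig <- decompose_loads(as.data.frame(unclass(d$base_loads)))
  fmag <- sqrt(sum(d$applied_force^2))
  expect_equal(sig$MB, fmag * d$contact_arc_length, tolerance = 0.01)
})

test_that("targets beyond the whisker length are discarded as unreachable", {
  w <- gamma_whisker()
  d <- deflect_to_point(w, contact_point(30, 0, 0))
  expect_false(d$converged)
  expect_equal(d$reason, "unreachable")
})

test_that("a grid restricted to the undeflected whisker converges with zero loads", {
  w <- gamma_whisker()
  idx <- c(40, 60, 80)
  sph <- cartesian_to_spherical(w$nodes[idx, ])
  grid <- data.frame(r_mm = sph$r_mm, theta_deg = sph$theta_deg,
                     phi_deg = sph$phi_deg)
  res <- reachable_space(w, grid)
  expect_true(all(res$converged))
  expect_true(all(abs(as.matrix(res[, c("Fx","Fy","Fz","Mx","My","Mz")]))
                  < 1e-6))
})
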