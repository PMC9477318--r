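test_that("grid construction matches the printed counts", {
  full <- build_grid(c(6, 20), 1, c(-65, 65), 1, c(-60, 60), 1)
  expect_equal(nrow(full), 15 * 131 * 121)   # 237,765 candidate points
  reduced <- build_grid()                     # 2 mm / 3 deg / 3 deg
  expect_equal(nrow(reduced), 8 * 44 * 41)
  single <- build_grid(c(10, 10), 1, c(0, 0), 1, c(0, 0), 1)
  expect_equal(nrow(single), 1)
  expect_error(build_grid(r_step = 0), "steps")
  expect_error(build_grid(r_range = c(10, 5)), "ordered")
})

test_that("small-deflection exclusion follows the s_closest * tan(2 deg) rule", {
  w <- straight_whisker()
  # on the whisker: distance zero -> excluded
  expect_true(flag_small_deflection(matrix(c(10, 0, 0), 1), w))
  # s_closest = 10 mm: threshold 10 tan(2 deg) = 0.349 mm
  expect_true(flag_small_deflection(matrix(c(10, 0.30, 0), 1), w))
  expect_false(flag_small_deflection(matrix(c(10, 1.0, 0), 1), w))
  # shrinking the cone from 2 to 1 degree never excludes a retained point
  set.seed(21)
  pts <- cbind(runif(200, 5, 19), runif(200, -3, 3), runif(200, -3, 3))
  e2 <- flag_small_deflection(pts, w, cone_deg = 2)
  e1 <- flag_small_deflection(pts, w, cone_deg = 1)
  expect_true(all(!e2 | !e1 | e2))      # e1 TRUE implies e2 TRUE
  expect_true(all(which(e1) %in% which(e2)))
})

test_that("triplet specification enforces three distinct known signals", {
  expect_s3_class(triplet_spec("Fx", "MB", "MD"), "triplet_spec")
  expect_error(triplet_spec("Fx", "Fx", "MD"), "distinct")
  expect_error(triplet_spec("Fx", "MB"), "distinct|3")
  expect_error(triplet_spec("Fx", "MB", "XX"), "distinct|names")
})

test_that("inversion returns an exact record verbatim and interpolates nearby", {
  tab <- synthetic_table(function(r, th, ph) {
    data.frame(Fx = -r + th / 50 + ph / 100, FT = r, FD = 0 * r,
               Mx = ph / 10, MB = (21 - r) * 2 - th / 25,
               MD = (th + 90) * pi / 180 + ph * pi / 360)
  })
  spec <- triplet_spec("Fx", "MB", "MD")
  rec <- retained_records(tab)
  i <- 777
  q <- rec[i, c("Fx", "MB", "MD_rad")]
  est <- invert_triplet(q, tab, spec)
  expect_equal(est$r_mm, rec$r_mm[i])
  expect_equal(est$theta_deg, rec$theta_deg[i])
  expect_equal(est$phi_deg, rec$phi_deg[i])
  expect_false(est$extrapolated)
  # a query far outside the signal cloud is flagged
  qfar <- data.frame(Fx = 1000, MB = -500, MD_rad = 1)
  expect_true(invert_triplet(qfar, tab, spec)$extrapolated)
})

test_that("region classification distinguishes CF, CB and large deflections", {
  rec <- data.frame(theta_deg = c(-10, 10, 5), tangent_x = c(0.9, 0.8, -0.2),
                    converged = TRUE)
  expect_equal(classify_region(rec),
               c("concave-forward", "concave-backward", "large-deflection"))
  expect_error(classify_region(data.frame(theta_deg = 1)), "metadata")
})

test_that("pushing past the transverse-force tube flips FD by ~180 degrees", {
  # force-driven continuation: a frictionless load of growing magnitude at a
  # proximal node carries the contact tangent past the y-z plane (the FT ~ 0
  # tube); across the crossing the transverse-force direction jumps by pi
  w <- planar_whisker()
  node <- which.min(abs(w$arc_lengths - 17.5))
  sigs <- list(); tx <- c()
  dirv <- c(0, 1, 0)
  for (fm in seq(20, 170, 10)) {
    f <- fm * dirv
    for (it in 1:8) {   # re-aim the force orthogonal to the local tangent
      r <- deflect_under_force(w, node, f)
      if (!isTRUE(r$converged)) break
      tt <- r$link_tangents[min(node, nrow(r$link_tangents)), ]
      f <- f - sum(f * tt) * tt
      f <- f / sqrt(sum(f^2)) * fm
    }
    if (!isTRUE(r$converged)) break
    tx <- c(tx, tt[1])
    b <- base_reactions(f, r$nodes[node, ])
    sigs[[length(sigs) + 1]] <- decompose_loads(as.data.frame(unclass(b)))
    if (tt[1] < -0.02) break
  }
  sig <- do.call(rbind, sigs)
  expect_gt(sum(tx <= 0), 0)          # reached the large-deflection side
  expect_gt(sum(tx > 0), 0)
  # the transverse force magnitude collapses on approach to the tube
  expect_lt(sig$FT[sum(tx > 0)], max(sig$FT) / 2)
  fd_small <- sig$FD_rad[tx > 0][1]
  fd_large <- sig$FD_rad[tx <= 0][sum(tx <= 0)]
  dd <- abs(((fd_large - fd_small + pi) %% (2 * pi)) - pi)
  expect_equal(dd, pi, tolerance = 0.25)
})

test_that("mapping tables survive the CSV round trip losslessly", {
  tab <- synthetic_table(function(r, th, ph)
    data.frame(Fx = -r, FT = r, FD = 0 * r, Mx = ph, MB = 21 - r,
               MD = (th + 90) * pi / 180),
    r = seq(8, 16, 2), th = seq(-30, 30, 10), ph = seq(-20, 20, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping_table(tab, path)
  back <- read_mapping_table(path)
  for (col in names(tab$records)) {
    expect_equal(back$records[[col]], tab$records[[col]], tolerance = 1e-12,
                 label = col)
  }
  expect_equal(back$whisker_fingerprint, tab$whisker_fingerprint)
  expect_equal(back$cone_deg, tab$cone_deg)
})
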