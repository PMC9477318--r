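test_that("probe steps are 0.05% of each signal's range", {
  st <- step_from_range(list(MD_rad = c(0, 1), MB = c(-2, 2), Fx = c(0, 10)))
  expect_equal(st[["MD"]], 5e-4)
  expect_equal(st[["MB"]], 2e-3)
  expect_equal(st[["Fx"]], 5e-3)
  expect_error(step_from_range(list(MD_rad = c(1, 1), MB = c(0, 1),
                                    Fx = c(0, 1))), "degenerate")
  # ranges chosen to invert the rule onto prescribed steps
  st2 <- step_from_range(list(MD_rad = c(0, 6.0e-3 / 5e-4),
                              MB = c(0, 3.1e-3 / 5e-4),
                              Fx = c(0, 2.2e-4 / 5e-4)))
  expect_equal(st2[["MD"]], 6.0e-3)
  expect_equal(st2[["MB"]], 3.1e-3)
  expect_equal(st2[["Fx"]], 2.2e-4)
})

# a synthetic mapping linear in the signals: r = a MB + b, theta = c MD,
# phi = d Fx, which the central differences must recover exactly
linear_jacobian_table <- function(a = -0.5, c = 30, d = 2) {
  synthetic_table(function(r, th, ph)
    data.frame(Fx = ph / d, FT = r, FD = 0 * r, Mx = ph,
               MB = (r - 23) / a, MD = pmax(th / c + pi, 0.01)))
}

test_that("a linear synthetic field yields its exact Jacobian", {
  a <- -0.5; cc <- 30; d <- 2
  tab <- linear_jacobian_table(a, cc, d)
  rec <- retained_records(tab)
  set.seed(2)
  probes <- rec[sample(nrow(rec), 150), c("MD_rad", "MB", "Fx")]
  env <- signal_envelope(rec)
  jf <- jacobian_at(probes, tab, step_from_range(env))
  keep <- stats::complete.cases(jf$J)
  expect_gt(mean(keep), 0.8)
  J <- jf$J[keep, ]
  expect_equal(median(J[, "dr_dMB"]), a, tolerance = 0.02)
  expect_equal(median(J[, "dth_dMD"]), cc, tolerance = 0.02)
  expect_equal(median(J[, "dph_dFx"]), d, tolerance = 0.02)
  for (el in c("dr_dMD", "dr_dFx", "dth_dMB", "dth_dFx", "dph_dMD",
               "dph_dMB")) {
    expect_lt(abs(median(J[, el])), 0.05 * max(abs(c(a, cc, d))))
  }
})

test_that("central differences agree with a finer-grid derivative oracle", {
  # smooth nonlinear synthetic mapping: r depends quadratically on MB
  tab <- synthetic_table(function(r, th, ph)
    data.frame(Fx = ph / 2, FT = r, FD = 0 * r, Mx = ph,
               MB = sqrt(23 - r) * 4, MD = th / 30 + pi),
    r = seq(6, 20, 0.5), th = seq(-60, 60, 4), ph = seq(-40, 40, 5))
  rec <- retained_records(tab)
  set.seed(4)
  probes <- rec[sample(nrow(rec), 80), c("MD_rad", "MB", "Fx")]
  env <- signal_envelope(rec)
  jf <- jacobian_at(probes, tab, step_from_range(env))
  # analytic: MB = 4 sqrt(23 - r) => dr/dMB = -MB / 8
  keep <- is.finite(jf$J[, "dr_dMB"])
  ana <- -probes$MB[keep] / 8
  rel <- abs(jf$J[keep, "dr_dMB"] - ana) / abs(ana)
  expect_lt(median(rel), 0.05)
})

test_that("trimming and binning keep the books straight", {
  tab <- linear_jacobian_table()
  rec <- retained_records(tab)
  set.seed(6)
  probes <- rec[sample(nrow(rec), 400), c("MD_rad", "MB", "Fx")]
  jf <- jacobian_at(probes, tab, step_from_range(signal_envelope(rec)))
  bs <- trim_and_bin(jf)
  for (el in names(bs$elements)) {
    e <- bs$elements[[el]]
    # trimmed + binned = valid, and counts in bins sum to binned samples
    expect_equal(e$n_trimmed + e$n_binned, e$n_valid)
    expect_equal(sum(e$bins$count), e$n_binned)
    # trimming removes at most ~1% (the central 99% interval)
    expect_lte(e$n_trimmed, ceiling(0.011 * e$n_valid) + 1)
    # max-count bin has weight 1; floor at 0.05
    expect_equal(max(e$bins$weight), 1)
    expect_true(all(e$bins$weight >= 0.05))
    under <- e$bins$count < 0.05 * max(e$bins$count)
    if (any(under)) expect_true(all(e$bins$weight[under] == 0.05))
  }
  expect_error(trim_and_bin(jf, min_valid = 1e6), "too few")
})

test_that("uniform values lose about 1% to the central 99% interval", {
  tab <- linear_jacobian_table()
  rec <- retained_records(tab)
  set.seed(8)
  probes <- rec[sample(nrow(rec), 500), c("MD_rad", "MB", "Fx")]
  jf <- jacobian_at(probes, tab, step_from_range(signal_envelope(rec)))
  # overwrite one element with uniform noise to test the trim definition
  jf$J[, "dr_dMD"] <- runif(nrow(jf$J))
  bs <- trim_and_bin(jf)
  e <- bs$elements[["dr_dMD"]]
  expect_equal(e$n_trimmed / e$n_valid, 0.01, tolerance = 0.01)
})
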