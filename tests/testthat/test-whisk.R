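test_that("trials are reproducible from their seed", {
  w <- gamma_whisker()
  t1 <- synth_whisk_trial(w, seed = 5)
  t2 <- synth_whisk_trial(w, seed = 5)
  expect_identical(t1$frames, t2$frames)
  t3 <- synth_whisk_trial(w, seed = 6)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("a peg beyond the whisker's reach yields no contact frames", {
  w <- gamma_whisker()
  tr <- synth_whisk_trial(w, peg = peg_model(30, 30), seed = 1)
  expect_equal(sum(tr$frames$in_contact), 0)
})

test_that("the default trial gives a back-surface then a front-surface episode", {
  tr <- gamma_trial()
  fr <- tr$frames
  ep <- whiskmap:::.contact_episodes(fr$in_contact)
  expect_length(ep, 2)
  expect_gt(min(lengths(ep)), 5)
  # ground truth contact points sit on the peg cylinder surface
  ic <- fr$in_contact
  d <- sqrt((fr$cx[ic] - tr$peg$x_mm)^2 + (fr$cy[ic] - tr$peg$y_mm)^2)
  expect_equal(d, rep(tr$peg$diameter_mm / 2, sum(ic)), tolerance = 1e-9)
  # first episode presses the caudal (lower-azimuth) side, second the rostral
  az <- atan2(fr$cy - tr$peg$y_mm, fr$cx - tr$peg$x_mm)
  az_peg <- atan2(tr$peg$y_mm, tr$peg$x_mm)   # direction base -> peg axis
  side <- sin(az - az_peg)                    # <0 caudal of the axis ray
  expect_lt(mean(side[ep[[1]]]), 0)
  expect_gt(mean(side[ep[[2]]]), 0)
})

test_that("the 85 Hz zero-phase filter passes DC, kills 200 Hz, keeps 60 Hz", {
  w <- gamma_whisker()
  tr <- synth_whisk_trial(w, duration_s = 0.5, basepoint_sigma_mm = 0,
                          orient_sigma_deg = 0, seed = 1)
  # constant channel: unchanged
  tr0 <- tr; tr0$frames$bz <- 0.5
  f0 <- lowpass_basepose(tr0, w)
  core <- 100:400
  expect_equal(f0$frames$bz[core], rep(0.5, length(core)), tolerance = 1e-6)
  # sinusoidal probes measured away from the filter edges
  probe <- function(freq) {
    trf <- tr
    t_s <- tr$frames$t_ms / 1000
    trf$frames$bz <- sin(2 * pi * freq * t_s)
    out <- lowpass_basepose(trf, w)$frames$bz
    core <- 100:400
    max(abs(out[core])) / 1
  }
  expect_lt(20 * log10(probe(200)), -20)   # > 20 dB down at 200 Hz
  expect_gt(20 * log10(probe(60)), -1)     # < 1 dB ripple at 60 Hz
  expect_error(lowpass_basepose(tr, w, cutoff_hz = 600), "Nyquist")
})

test_that("signal series: zeros off contact, solver consistency on contact", {
  tr <- gamma_trial()
  sig <- gamma_trial_signals()
  w <- gamma_whisker()
  off <- !tr$frames$in_contact
  expect_true(all(abs(as.matrix(sig[off, c("Fx","Fy","Fz","Mx","My","Mz")]))
                  == 0))
  expect_gt(mean(sig$solved[tr$frames$in_contact]), 0.9)
  # a frozen single frame equals a direct deflect_to_point call
  i <- which(tr$frames$in_contact & sig$solved)[10]
  d <- deflect_to_point(w, contact_point(tr$frames$r_wobj_mm[i],
                                         tr$frames$theta_wobj_deg[i],
                                         tr$frames$phi_wobj_deg[i]))
  expect_true(d$converged)
  expect_equal(as.numeric(sig[i, c("Fx", "Fy", "Fz")]),
               c(d$base_loads$Fx, d$base_loads$Fy, d$base_loads$Fz),
               tolerance = 0.05)
})

test_that("the bending direction flips by ~180 degrees between episodes", {
  tr <- gamma_trial()
  sig <- gamma_trial_signals()
  ep <- whiskmap:::.contact_episodes(tr$frames$in_contact)
  md1 <- sig$MD_rad[ep[[1]]]; md1 <- md1[is.finite(md1)]
  md2 <- sig$MD_rad[ep[[2]]]; md2 <- md2[is.finite(md2)]
  m1 <- atan2(mean(sin(md1)), mean(cos(md1)))
  m2 <- atan2(mean(sin(md2)), mean(cos(md2)))
  dd <- abs(((m2 - m1 + pi) %% (2 * pi)) - pi)
  expect_equal(dd, pi, tolerance = 0.5)
})

test_that("whisker-frame to lab-frame transforms round trip exactly", {
  set.seed(31)
  for (rep in 1:10) {
    R <- whiskmap:::.pose_rotation(runif(1, 0, 120), runif(1, -30, 30),
                                   runif(1, -20, 20))
    b <- rnorm(3)
    p <- rnorm(3, sd = 10)
    lab <- as.numeric(R %*% p) + b
    back <- as.numeric(t(R) %*% (lab - b))
    expect_equal(back, p, tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})
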