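# Synthetic whisking-against-a-peg trials: pose kinematics at 1 kHz,
# geometric whisker-peg contact, forward mechanics, and lab-frame peg
# reconstruction from inverted signals.

#' Vertical peg model
#'
#' @param x_mm,y_mm lab-frame position of the vertical peg axis.
#' @param diameter_mm peg diameter. Default 2.7.
#' @param z_range_mm vertical extent. Default c(-10, 10).
#' @return object of class `peg_model`.
#' @export
peg_model <- function(x_mm, y_mm, diameter_mm = 2.7,
                      z_range_mm = c(-10, 10)) {
  .assert(diameter_mm > 0, "diameter must be positive")
  structure(list(x_mm = x_mm, y_mm = y_mm, diameter_mm = diameter_mm,
                 z_range_mm = z_range_mm),
            class = "peg_model")
}

# rotation whisker frame -> lab frame from protraction (about z), elevation
# (about the protracted y-axis), torsion (roll about the whisker x-axis)
.pose_rotation <- function(protraction_deg, elevation_deg, torsion_deg = 0) {
  a <- .deg2rad(protraction_deg); b <- .deg2rad(elevation_deg)
  g <- .deg2rad(torsion_deg)
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(g), -sin(g)), c(0, sin(g), cos(g)))
  Rz %*% Ry %*% Rx
}

# contact geometry for one frame: pose the rigid whisker, find the deepest
# penetrating node, project it radially to the peg surface
.frame_contact <- function(whisker, peg, basepoint, R) {
  lab <- sweep(whisker$nodes %*% t(R), 2, basepoint, "+")
  dx <- lab[, 1] - peg$x_mm
  dy <- lab[, 2] - peg$y_mm
  d <- sqrt(dx^2 + dy^2)
  rad <- peg$diameter_mm / 2
  inside <- d < rad & lab[, 3] >= peg$z_range_mm[1] &
    lab[, 3] <= peg$z_range_mm[2]
  if (!any(inside)) {
    return(list(depth = 0, contact_lab = NULL, s_mm = NA_real_))
  }
  i <- which(inside)[which.min(d[inside])]
  contact_lab <- c(peg$x_mm + rad * dx[i] / d[i],
                   peg$y_mm + rad * dy[i] / d[i],
                   lab[i, 3])
  list(depth = rad - d[i], contact_lab = contact_lab,
       s_mm = whisker$arc_lengths[i])
}

#' Synthesise a whisking trial against a vertical peg
#'
#' Generates a 1 kHz pose time series (sinusoidal protraction with a smaller
#' in-phase elevation sweep, fixed basepoint, seeded Gaussian jitter on
#' basepoint and orientation), sweeps the posed rigid whisker through the
#' peg, and derives per-frame contact. One full whisk cycle gives a forward
#' sweep pressing the caudal (back) surface of the peg and a backward sweep
#' pressing the rostral (front) surface; frames between the two (deep
#' penetration, i.e. after the real whisker would have slipped past) are not
#' in contact.
#'
#' @param whisker a `whisker_shape`.
#' @param peg a [peg_model()]. Default places the peg 11 mm from the
#'   basepoint near the top of the protraction sweep, so the whisker presses
#'   it slowly and contact episodes last tens of milliseconds.
#' @param duration_s trial length, seconds. Default 0.5 (one cycle).
#' @param freq_hz whisk frequency. Default 2 (slow exploratory whisking).
#' @param protraction_mean_deg,protraction_amp_deg centre and amplitude of
#'   the protraction sweep.
#' @param elevation_amp_deg elevation sweep amplitude.
#' @param elevation_freq_mult elevation oscillates at this multiple of the
#'   protraction frequency (default 3), so each contact episode sweeps
#'   through a range of heights and the contacts paint vertical bands on
#'   the peg rather than a single spot.
#' @param depth_max_mm contact is held while the rigid-whisker penetration
#'   depth is below this; beyond it the whisker is taken to slip past.
#'   Default 1.0.
#' @param basepoint_sigma_mm basepoint jitter s.d. (per axis). Default 0.06
#'   (about one video pixel).
#' @param orient_sigma_deg orientation jitter s.d. Default 0.5.
#' @param seed RNG seed for the jitter.
#' @return object of class `whisk_trajectory`: data frame `frames` (t_ms,
#'   basepoint, angles, in_contact, contact_lab, contact_whisker spherical
#'   coordinates, depth) plus the generating parameters.
#' @export
synth_whisk_trial <- function(whisker,
                              peg = peg_model(-0.959, 10.958),
                              duration_s = 0.5, freq_hz = 2,
                              protraction_mean_deg = 72,
                              protraction_amp_deg = 30,
                              elevation_amp_deg = 8,
                              elevation_freq_mult = 3,
                              depth_max_mm = 1.0,
                              basepoint_sigma_mm = 0.06,
                              orient_sigma_deg = 0.5,
                              seed = 1) {
  t_ms <- seq(0, duration_s * 1000 - 1)
  nt <- length(t_ms)
  ph <- 2 * pi * freq_hz * t_ms / 1000 - pi / 2
  set.seed(seed)
  fr <- data.frame(
    t_ms = t_ms,
    bx = rnorm(nt, 0, basepoint_sigma_mm),
    by = rnorm(nt, 0, basepoint_sigma_mm),
    bz = rnorm(nt, 0, basepoint_sigma_mm),
    protraction_deg = protraction_mean_deg +
      protraction_amp_deg * sin(ph) + rnorm(nt, 0, orient_sigma_deg),
    elevation_deg = elevation_amp_deg * sin(elevation_freq_mult * ph) +
      rnorm(nt, 0, orient_sigma_deg),
    torsion_deg = rnorm(nt, 0, orient_sigma_deg))
  traj <- structure(list(frames = fr, whisker_fingerprint =
                           .whisker_fingerprint(whisker),
                         peg = peg, depth_max_mm = depth_max_mm,
                         freq_hz = freq_hz, seed = seed),
                    class = "whisk_trajectory")
  .recompute_contact(traj, whisker)
}

# derive contact columns from the pose channels
.recompute_contact <- function(traj, whisker) {
  fr <- traj$frames
  nt <- nrow(fr)
  depth <- numeric(nt)
  s_mm <- rep(NA_real_, nt)
  clab <- matrix(NA_real_, nt, 3)
  for (i in seq_len(nt)) {
    R <- .pose_rotation(fr$protraction_deg[i], fr$elevation_deg[i],
                        fr$torsion_deg[i])
    g <- .frame_contact(whisker, traj$peg, c(fr$bx[i], fr$by[i], fr$bz[i]), R)
    depth[i] <- g$depth
    if (!is.null(g$contact_lab)) {
      clab[i, ] <- g$contact_lab
      s_mm[i] <- g$s_mm
    }
  }
  pressing <- c(FALSE, diff(depth) > 0) & depth > 0
  in_contact <- pressing & depth <= traj$depth_max_mm &
    is.finite(s_mm) & s_mm >= 0.3 * whisker$total_arc_length
  fr$in_contact <- in_contact
  fr$depth_mm <- depth
  fr$s_guess_mm <- s_mm
  fr$cx <- ifelse(in_contact, clab[, 1], NA_real_)
  fr$cy <- ifelse(in_contact, clab[, 2], NA_real_)
  fr$cz <- ifelse(in_contact, clab[, 3], NA_real_)
  # contact point in whisker-centred coordinates
  fr$r_wobj_mm <- NA_real_; fr$theta_wobj_deg <- NA_real_
  fr$phi_wobj_deg <- NA_real_
  for (i in which(in_contact)) {
    R <- .pose_rotation(fr$protraction_deg[i], fr$elevation_deg[i],
                        fr$torsion_deg[i])
    pw <- as.numeric(t(R) %*% (clab[i, ] - c(fr$bx[i], fr$by[i], fr$bz[i])))
    sph <- cartesian_to_spherical(pw)
    fr$r_wobj_mm[i] <- sph$r_mm
    fr$theta_wobj_deg[i] <- sph$theta_deg
    fr$phi_wobj_deg[i] <- sph$phi_deg
  }
  traj$frames <- fr
  traj
}

#' @export
print.whisk_trajectory <- function(x, ...) {
  ep <- .contact_episodes(x$frames$in_contact)
  cat("whisk_trajectory:", nrow(x$frames), "frames at 1 kHz;",
      sum(x$frames$in_contact), "contact frames in", length(ep),
      "episode(s)\n")
  invisible(x)
}

# list of index vectors, one per contiguous contact episode
.contact_episodes <- function(in_contact) {
  r <- rle(in_contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lapply(which(r$values), function(k) starts[k]:ends[k])
}

#' Low-pass filter the pose channels of a trajectory
#'
#' Applies a zero-phase 4th-order Butterworth low-pass (default cutoff
#' 85 Hz, mirroring video-tracking smoothing) to the basepoint and
#' orientation channels only, then recomputes the contact geometry from the
#' smoothed pose.
#'
#' @param traj a `whisk_trajectory`.
#' @param whisker the `whisker_shape` the trajectory was built with.
#' @param cutoff_hz cutoff frequency. Default 85.
#' @return the filtered `whisk_trajectory`.
#' @export
lowpass_basepose <- function(traj, whisker, cutoff_hz = 85) {
  fs <- 1000
  .assert(cutoff_hz > 0 && cutoff_hz < fs / 2,
          "cutoff must lie below the 500 Hz Nyquist frequency")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  fr <- traj$frames
  for (col in c("bx", "by", "bz", "protraction_deg", "elevation_deg",
                "torsion_deg")) {
    fr[[col]] <- as.numeric(signal::filtfilt(bf, fr[[col]]))
  }
  traj$frames <- fr
  .recompute_contact(traj, whisker)
}

#' Compute base signals along a whisking trial
#'
#' Runs the contact solver for every contact frame (warm starting from the
#' previous frame) and decomposes the base loads into the signal set.
#' Non-contact frames carry zero loads; non-converged frames are flagged.
#'
#' @param traj a `whisk_trajectory`.
#' @param whisker the `whisker_shape`.
#' @param opts [solver_options()].
#' @return data frame: `t_ms`, `in_contact`, `solved`, the six loads, and
#'   the signal set columns.
#' @export
trial_to_signals <- function(traj, whisker, opts = solver_options()) {
  fr <- traj$frames
  nt <- nrow(fr)
  loads <- matrix(0, nt, 6,
                  dimnames = list(NULL, c("Fx","Fy","Fz","Mx","My","Mz")))
  solved <- !fr$in_contact  # vacuously true off contact
  f_warm <- NULL; s_warm <- -1
  prev_contact <- FALSE
  for (i in seq_len(nt)) {
    if (!fr$in_contact[i]) { prev_contact <- FALSE; next }
    if (!prev_contact) { f_warm <- NULL; s_warm <- -1 }
    cp <- contact_point(fr$r_wobj_mm[i], fr$theta_wobj_deg[i],
                        fr$phi_wobj_deg[i])
    d <- deflect_to_point(whisker, cp, opts, f_init = f_warm, s_init = s_warm)
    if (d$converged) {
      loads[i, ] <- .loads_vec(d$base_loads)
      solved[i] <- TRUE
      f_warm <- d$applied_force; s_warm <- d$contact_arc_length
      prev_contact <- TRUE
    } else {
      f_warm <- NULL; s_warm <- -1
      prev_contact <- FALSE
    }
  }
  sig <- decompose_loads(as.data.frame(loads))
  cbind(data.frame(t_ms = fr$t_ms, in_contact = fr$in_contact,
                   solved = solved), as.data.frame(loads), sig[, c("FT",
                   "FD_rad", "MB", "MD_rad")])
}

#' Reconstruct the peg from inverted signals
#'
#' For every solved contact frame outside the small-deflection exclusion
#' cone, inverts the signal triplet through the mapping table, transforms
#' the whisker-frame estimate into the lab frame with that frame's pose,
#' and compares against the ground-truth contact points, splitting errors
#' into radial (along the base-to-contact ray) and angular (perpendicular)
#' components.
#'
#' @param signals from [trial_to_signals()].
#' @param traj the `whisk_trajectory`.
#' @param whisker the `whisker_shape`.
#' @param table a `mapping_table` built with the same whisker.
#' @param spec the [triplet_spec()] to invert (default Fx, MB, MD).
#' @param cone_deg small-deflection exclusion cone (degrees). Default 2.
#' @return object of class `reconstruction_result`: data frame `points`
#'   (per retained frame: estimated and true lab-frame contact points,
#'   radial/angular error in mm, episode id) and summary medians.
#' @export
reconstruct_peg <- function(signals, traj, whisker, table,
                            spec = triplet_spec("Fx", "MB", "MD"),
                            cone_deg = 2) {
  .assert(identical(table$whisker_fingerprint,
                    .whisker_fingerprint(whisker)),
          "mapping table was built for a different whisker")
  fr <- traj$frames
  use <- fr$in_contact & signals$solved
  .assert(any(use), "no solved contact frames")
  # exclude small-angle deflections
  tgt_w <- spherical_to_cartesian(contact_point(
    fr$r_wobj_mm[use], fr$theta_wobj_deg[use], fr$phi_wobj_deg[use]))
  excl <- rep(TRUE, nrow(fr))
  excl[use] <- flag_small_deflection(tgt_w, whisker, cone_deg)
  use <- use & !excl
  .assert(any(use), "all contact frames excluded; nothing to reconstruct")
  inv <- invert_triplet(signals[use, , drop = FALSE], table, spec)
  est_w <- spherical_to_cartesian(contact_point(inv$r_mm, inv$theta_deg,
                                                inv$phi_deg))
  idx <- which(use)
  est_lab <- matrix(NA_real_, length(idx), 3)
  for (j in seq_along(idx)) {
    i <- idx[j]
    R <- .pose_rotation(fr$protraction_deg[i], fr$elevation_deg[i],
                        fr$torsion_deg[i])
    est_lab[j, ] <- as.numeric(R %*% est_w[j, ]) +
      c(fr$bx[i], fr$by[i], fr$bz[i])
  }
  truth <- cbind(fr$cx[idx], fr$cy[idx], fr$cz[idx])
  base <- cbind(fr$bx[idx], fr$by[idx], fr$bz[idx])
  errv <- est_lab - truth
  u <- truth - base
  u <- u / sqrt(rowSums(u^2))
  radial <- rowSums(errv * u)
  angular <- sqrt(pmax(rowSums(errv^2) - radial^2, 0))
  # episode ids
  ep <- .contact_episodes(fr$in_contact)
  epi <- rep(NA_integer_, nrow(fr))
  for (k in seq_along(ep)) epi[ep[[k]]] <- k
  pts <- data.frame(t_ms = fr$t_ms[idx], episode = epi[idx],
                    est_x = est_lab[, 1], est_y = est_lab[, 2],
                    est_z = est_lab[, 3],
                    true_x = truth[, 1], true_y = truth[, 2],
                    true_z = truth[, 3],
                    radial_err_mm = radial, angular_err_mm = angular,
                    extrapolated = inv$extrapolated)
  structure(list(points = pts,
                 median_radial_err_mm = median(abs(radial)),
                 median_angular_err_mm = median(abs(angular)),
                 n_frames = length(idx), n_excluded = sum(excl & fr$in_contact),
                 triplet = spec),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat("peg reconstruction from (", paste(x$triplet, collapse = ", "), "):",
      x$n_frames, "frames (", x$n_excluded, "excluded )\n")
  cat(sprintf("  median |radial error| %.3f mm, median |angular error| %.3f mm\n",
              x$median_radial_err_mm, x$median_angular_err_mm))
  invisible(x)
}
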