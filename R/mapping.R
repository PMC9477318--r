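# Forward mapping tables: contact-point grid -> base signals, the
# small-deflection exclusion cone, region labels, and table inversion.

#' Build a spherical contact-point grid
#'
#' Cartesian product of inclusive 1-D grids in radial distance, azimuth, and
#' elevation. The full-resolution grid spans r 6..20 mm in 1 mm steps,
#' azimuth -65..65 deg and elevation -60..60 deg in 1 deg steps (237,765
#' points); the desk-scale default halves/thirds the steps.
#'
#' @param r_range length-2 numeric, mm. Default c(6, 20).
#' @param r_step mm. Default 2.
#' @param theta_range length-2 numeric, degrees. Default c(-65, 65).
#' @param theta_step degrees. Default 3.
#' @param phi_range length-2 numeric, degrees. Default c(-60, 60).
#' @param phi_step degrees. Default 3.
#' @return data frame with columns `r_mm`, `theta_deg`, `phi_deg`.
#' @export
build_grid <- function(r_range = c(6, 20), r_step = 2,
                       theta_range = c(-65, 65), theta_step = 3,
                       phi_range = c(-60, 60), phi_step = 3) {
  .assert(r_step > 0 && theta_step > 0 && phi_step > 0, "steps must be > 0")
  .assert(r_range[1] <= r_range[2] && theta_range[1] <= theta_range[2] &&
          phi_range[1] <= phi_range[2], "ranges must be ordered")
  g <- expand.grid(r_mm = seq(r_range[1], r_range[2], by = r_step),
                   theta_deg = seq(theta_range[1], theta_range[2],
                                   by = theta_step),
                   phi_deg = seq(phi_range[1], phi_range[2], by = phi_step),
                   KEEP.OUT.ATTRS = FALSE)
  .assert(nrow(g) > 0, "empty grid")
  g
}

#' Flag contact points inside the small-deflection exclusion cone
#'
#' A point is excluded when its distance to the nearest point of the
#' undeflected whisker is less than s_closest * tan(2 deg), where s_closest
#' is the arc length of that nearest whisker point. Contacts this close to
#' the whisker produce deflections too small for the lookup table to resolve
#' radial distance.
#'
#' @param targets matrix (n x 3) of Cartesian positions (mm), or a
#'   [contact_point()] with vectorised fields.
#' @param whisker a `whisker_shape` (frame-aligned).
#' @param cone_deg half-angle of the exclusion cone in degrees. Default 2.
#' @return logical vector: TRUE = excluded.
#' @export
flag_small_deflection <- function(targets, whisker, cone_deg = 2) {
  if (inherits(targets, "contact_point"))
    targets <- spherical_to_cartesian(targets)
  targets <- rbind(targets)
  nn <- cpp_knn(whisker$nodes, targets, 1L)
  s_closest <- whisker$arc_lengths[as.integer(nn$index[, 1])]
  as.vector(nn$dist[, 1] < s_closest * tan(.deg2rad(cone_deg)))
}

#' Build a forward mapping table over the reachable space
#'
#' Runs the reachable-space sweep, decomposes the base loads into the signal
#' set, applies the small-deflection exclusion, and labels regions
#' (concave-forward / concave-backward / large-deflection).
#'
#' @param whisker a `whisker_shape`.
#' @param grid from [build_grid()].
#' @param opts [solver_options()].
#' @param cone_deg small-deflection exclusion cone half-angle (degrees).
#' @param progress as in [reachable_space()].
#' @return An object of class `mapping_table`: a list with `records` (data
#'   frame), `grid_spec`, `whisker_fingerprint`, `cone_deg`, and counts.
#' @export
build_mapping <- function(whisker, grid, opts = solver_options(),
                          cone_deg = 2, progress = 0) {
  sweep <- reachable_space(whisker, grid, opts, progress)
  sig <- decompose_loads(.zero_na(sweep[, c("Fx", "Fy", "Fz",
                                            "Mx", "My", "Mz")]))
  rec <- cbind(sweep, sig[, c("FT", "FD_rad", "MB", "MD_rad")])
  tgt <- spherical_to_cartesian(contact_point(rec$r_mm, rec$theta_deg,
                                              rec$phi_deg))
  rec$excluded_small_deflection <- flag_small_deflection(tgt, whisker,
                                                         cone_deg)
  rec$large_deflection <- rec$converged & !is.na(rec$tangent_x) &
    rec$tangent_x <= 0
  rec$region <- ifelse(rec$large_deflection, "large-deflection",
                       ifelse(rec$theta_deg < 0, "concave-forward",
                              "concave-backward"))
  rec$region[!rec$converged] <- NA_character_
  structure(list(records = rec,
                 grid_spec = list(r = sort(unique(grid$r_mm)),
                                  theta = sort(unique(grid$theta_deg)),
                                  phi = sort(unique(grid$phi_deg))),
                 whisker_fingerprint = .whisker_fingerprint(whisker),
                 cone_deg = cone_deg,
                 n_converged = sum(rec$converged),
                 n_discarded = sum(!rec$converged),
                 n_excluded = sum(rec$converged &
                                  rec$excluded_small_deflection)),
            class = "mapping_table")
}

#' Behavioural-region grid for the peg demonstration
#'
#' A finer spherical grid covering the region the synthetic whisking trial
#' actually touches (about 8-14 mm radial distance, modest azimuths and
#' elevations). Lookup inversion near the whisker needs roughly 1 mm / 1.5
#' degree resolution to resolve radial distance; sweeping this focused
#' region costs about as much as the global reduced grid.
#'
#' @return data frame of grid points, as [build_grid()].
#' @export
peg_demo_grid <- function() {
  build_grid(c(8, 14), 1, c(-10, 26), 1.5, c(-12, 12), 1.5)
}

.zero_na <- function(df) {
  df[] <- lapply(df, function(x) ifelse(is.na(x), 0, x))
  df
}

#' @export
print.mapping_table <- function(x, ...) {
  cat("mapping_table:", nrow(x$records), "grid points;",
      x$n_converged, "converged,", x$n_discarded, "discarded (slip),",
      x$n_excluded, "inside the small-deflection cone\n")
  cat("  whisker", x$whisker_fingerprint, "; exclusion cone",
      x$cone_deg, "deg\n")
  invisible(x)
}

#' Retained records of a mapping table
#'
#' Converged records outside the small-deflection exclusion cone.
#'
#' @param table a `mapping_table`.
#' @return data frame of retained records.
#' @export
retained_records <- function(table) {
  r <- table$records
  r[r$converged & !r$excluded_small_deflection, , drop = FALSE]
}

#' Classify a record's deflection region
#'
#' Concave-forward (azimuth on the side the intrinsic curvature faces away
#' from, theta < 0), concave-backward (theta >= 0), or large-deflection:
#' the whisker segment at the contact has been pushed past the orientation
#' parallel to the y-z plane (tangent x-component <= 0), beyond the tube
#' where the transverse force vanishes and its direction flips by 180 deg.
#'
#' @param record one row of a mapping table's `records` (or any data frame
#'   with `theta_deg`, `tangent_x`, `converged`).
#' @return character vector of labels.
#' @export
classify_region <- function(record) {
  .assert(all(c("theta_deg", "tangent_x", "converged") %in% names(record)),
          "record lacks deflection metadata")
  .assert(all(record$converged), "cannot classify non-converged records")
  ifelse(record$tangent_x <= 0, "large-deflection",
         ifelse(record$theta_deg < 0, "concave-forward", "concave-backward"))
}

# --- triplets -------------------------------------------------------------

.SIGNAL_NAMES <- c("Fx", "FT", "FD", "Mx", "MB", "MD")
.DIRECTION_SIGNALS <- c("FD", "MD")

#' Specify a signal triplet
#'
#' @param ... three distinct signal names from Fx, FT, FD, Mx, MB, MD.
#' @return character vector of class `triplet_spec`.
#' @export
triplet_spec <- function(...) {
  s <- c(...)
  .assert(length(s) == 3 && !anyDuplicated(s) && all(s %in% .SIGNAL_NAMES),
          "a triplet is 3 distinct names from Fx, FT, FD, Mx, MB, MD")
  structure(s, class = "triplet_spec")
}

# column names in the records for a signal name
.signal_column <- function(s) {
  ifelse(s %in% .DIRECTION_SIGNALS, paste0(s, "_rad"), s)
}

# Embed triplet values for distance computations: magnitudes z-scored with
# the table's statistics, directions mapped to (cos, sin) on the unit circle.
.embed_signals <- function(values, spec, center, scale) {
  out <- NULL
  for (s in spec) {
    v <- values[[.signal_column(s)]]
    if (s %in% .DIRECTION_SIGNALS) {
      out <- cbind(out, cos(v), sin(v))
    } else {
      out <- cbind(out, (v - center[[s]]) / scale[[s]])
    }
  }
  out
}

.embed_stats <- function(records, spec) {
  center <- list(); scale <- list()
  for (s in setdiff(spec, .DIRECTION_SIGNALS)) {
    v <- records[[.signal_column(s)]]
    center[[s]] <- mean(v)
    scale[[s]] <- max(sd(v), 1e-12)
  }
  list(center = center, scale = scale)
}

#' Invert a signal triplet to a contact-point estimate
#'
#' Looks the query up in the mapping table: an exact triplet match returns
#' that record's coordinates; otherwise the k nearest table samples in
#' standardised triplet space (directions embedded on the unit circle) are
#' combined by inverse-distance weighting.
#'
#' @param query named list / one-row data frame with the triplet's values
#'   (`Fx`, `MB`, `MD_rad`, ... using the table's column names), or a data
#'   frame of many queries.
#' @param table a `mapping_table`.
#' @param spec a [triplet_spec()].
#' @param k neighbours used for the weighted estimate. Default 8.
#' @return data frame with `r_mm`, `theta_deg`, `phi_deg` estimates plus
#'   diagnostics: `nn_dist` (standardised distance to the nearest sample)
#'   and `extrapolated` (query far outside the sampled signal cloud).
#' @export
invert_triplet <- function(query, table, spec, k = 8) {
  rec <- retained_records(table)
  .assert(nrow(rec) > 0, "mapping table has no retained records")
  query <- as.data.frame(query)
  cols <- .signal_column(spec)
  .assert(all(cols %in% names(query)), paste("query must provide",
          paste(cols, collapse = ", ")))
  st <- .embed_stats(rec, spec)
  emb_tab <- .embed_signals(rec, spec, st$center, st$scale)
  emb_q <- .embed_signals(query, spec, st$center, st$scale)
  keep <- complete.cases(emb_q)
  kk <- min(k, nrow(rec))
  nn <- cpp_knn(emb_tab, emb_q[keep, , drop = FALSE], kk)
  # typical spacing: median distance to the nearest other sample
  self <- cpp_knn(emb_tab, emb_tab, 2L)
  spacing <- median(self$dist[, 2])
  est <- matrix(NA_real_, nrow(query), 3)
  nn_dist <- rep(NA_real_, nrow(query))
  ki <- 0
  for (i in which(keep)) {
    ki <- ki + 1
    idx <- as.integer(nn$index[ki, ])
    d <- nn$dist[ki, ]
    if (d[1] < 1e-12) {       # exact table record: return it verbatim
      est[i, ] <- as.numeric(rec[idx[1], c("r_mm", "theta_deg", "phi_deg")])
    } else {
      wgt <- 1 / (d + 1e-12)^2
      wgt <- wgt / sum(wgt)
      est[i, ] <- c(sum(wgt * rec$r_mm[idx]),
                    sum(wgt * rec$theta_deg[idx]),
                    sum(wgt * rec$phi_deg[idx]))
    }
    nn_dist[i] <- d[1]
  }
  data.frame(r_mm = est[, 1], theta_deg = est[, 2], phi_deg = est[, 3],
             nn_dist = nn_dist,
             extrapolated = !is.na(nn_dist) & nn_dist > 3 * spacing)
}
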