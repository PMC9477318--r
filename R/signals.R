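# Decomposition of the six base reactions into the signal set
# (Fx, FT, FD, Mx, MB, MD): axial force, transverse force magnitude and
# direction, twisting moment, bending moment magnitude and direction.

#' Decompose base loads into the whisker signal set
#'
#' The transverse force and bending moment are rewritten as magnitude and
#' direction: FT = sqrt(Fy^2 + Fz^2), MB = sqrt(My^2 + Mz^2), with the
#' directions FD, MD the quadrant-aware angles of (Fy, Fz) and (My, Mz)
#' mapped to [0, 2*pi). Axial force Fx and twisting moment Mx pass through.
#'
#' @param loads a `base_loads` object, or a data frame with columns
#'   `Fx, Fy, Fz, Mx, My, Mz` (vectorised).
#' @param zero_tol magnitudes below this (uN or uN mm) have an undefined
#'   direction, flagged NA rather than numeric noise. Default 1e-9.
#' @return A data frame with columns `Fx` (uN), `FT` (uN), `FD_rad`
#'   ([0, 2pi) or NA), `Mx` (uN mm), `MB` (uN mm), `MD_rad`.
#' @export
decompose_loads <- function(loads, zero_tol = 1e-9) {
  if (inherits(loads, "base_loads")) loads <- as.data.frame(unclass(loads))
  .assert(all(c("Fx", "Fy", "Fz", "Mx", "My", "Mz") %in% names(loads)),
          "loads must carry Fx, Fy, Fz, Mx, My, Mz")
  .assert(all(is.finite(as.matrix(loads[, c("Fx","Fy","Fz","Mx","My","Mz")]))),
          "loads must be finite")
  FT <- sqrt(loads$Fy^2 + loads$Fz^2)
  MB <- sqrt(loads$My^2 + loads$Mz^2)
  FD <- ifelse(FT < zero_tol, NA_real_, atan2(loads$Fz, loads$Fy) %% (2 * pi))
  MD <- ifelse(MB < zero_tol, NA_real_, atan2(loads$Mz, loads$My) %% (2 * pi))
  data.frame(Fx = loads$Fx, FT = FT, FD_rad = FD,
             Mx = loads$Mx, MB = MB, MD_rad = MD)
}

#' Recompose transverse components from magnitude and direction
#'
#' Inverse of the (FT, FD) <-> (Fy, Fz) pair of [decompose_loads()].
#'
#' @param magnitude FT (or MB).
#' @param direction_rad FD (or MD) in radians.
#' @return A two-column matrix of the (y, z) components.
#' @export
recompose_transverse <- function(magnitude, direction_rad) {
  cbind(y = magnitude * cos(direction_rad),
        z = magnitude * sin(direction_rad))
}

#' Circular offset between bending-moment and transverse-force directions
#'
#' Returns MD - FD mapped to (-180, 180] degrees. Because each reaction
#' moment lies in a plane perpendicular to its reaction force, the offset is
#' exactly +/-90 degrees whenever Fx = 0, and close to 90 degrees elsewhere.
#'
#' @param signals a data frame from [decompose_loads()] (columns `FD_rad`,
#'   `MD_rad`).
#' @return offset(s) in degrees; error if any direction is undefined.
#' @export
direction_offset <- function(signals) {
  .assert(all(is.finite(signals$FD_rad)) && all(is.finite(signals$MD_rad)),
          "direction undefined (magnitude below zero threshold)")
  d <- (signals$MD_rad - signals$FD_rad) %% (2 * pi)
  d <- ifelse(d > pi, d - 2 * pi, d)
  .rad2deg(d)
}

#' Unwrap a direction time series
#'
#' Removes 2*pi jumps from a sampled direction signal so trajectories can be
#' plotted on a continuous axis. NA gaps are preserved.
#'
#' @param x direction series in radians.
#' @return unwrapped series.
#' @export
unwrap_direction <- function(x) {
  ok <- which(is.finite(x))
  if (length(ok) < 2) return(x)
  v <- x[ok]
  d <- diff(v)
  d <- d - 2 * pi * round(d / (2 * pi))
  x[ok] <- v[1] + c(0, cumsum(d))
  x
}

# circular mean of angles in degrees
.circ_mean_deg <- function(deg) {
  a <- .deg2rad(deg)
  .rad2deg(atan2(mean(sin(a)), mean(cos(a)))) %% 360
}
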