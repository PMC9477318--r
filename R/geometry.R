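# Whisker geometry: construction, loading, frame alignment, and the
# whisker-centred spherical contact coordinates (r_wobj, theta_wobj, phi_wobj).

#' Material and taper parameters of a whisker
#'
#' @param youngs_modulus_GPa Young's modulus in GPa. Default 3, a typical
#'   value for rat whisker keratin.
#' @param poisson_ratio Poisson's ratio (dimensionless, in (0, 0.5)).
#'   Default 0.38.
#' @param base_radius_um Cross-section radius at the base, micrometres.
#'   Default 100.
#' @param taper_ratio Base radius divided by tip radius. 1 means a cylinder;
#'   rat whiskers are near 15. Must be >= 1.
#' @return An object of class `material_params`.
#' @export
material_params <- function(youngs_modulus_GPa = 3, poisson_ratio = 0.38,
                            base_radius_um = 100, taper_ratio = 15) {
  .assert(youngs_modulus_GPa > 0, "youngs_modulus_GPa must be positive")
  .assert(poisson_ratio > 0 && poisson_ratio < 0.5,
          "poisson_ratio must lie in (0, 0.5)")
  .assert(base_radius_um > 0, "base_radius_um must be positive")
  .assert(taper_ratio >= 1, "taper_ratio must be >= 1 (cylinder = 1)")
  structure(list(youngs_modulus_GPa = youngs_modulus_GPa,
                 poisson_ratio = poisson_ratio,
                 base_radius_um = base_radius_um,
                 taper_ratio = taper_ratio),
            class = "material_params")
}

#' Construct a whisker shape from centreline nodes
#'
#' Low-level constructor: attaches linear taper and material parameters to an
#' ordered polyline (base to tip) and aligns it to the whisker-centred frame.
#'
#' @param nodes numeric matrix (n x 3) of centreline positions in mm, base
#'   first.
#' @param material a [material_params()] object.
#' @param align if TRUE (default) the nodes are passed through
#'   [to_whisker_frame()].
#' @return An object of class `whisker_shape` with elements `nodes`,
#'   `arc_lengths` (mm, cumulative), `radii` (um, linear taper),
#'   `material`, and `total_arc_length` (mm).
#' @export
whisker_shape <- function(nodes, material = material_params(), align = TRUE) {
  nodes <- as.matrix(nodes)
  .assert(ncol(nodes) == 3 && nrow(nodes) >= 10,
          "nodes must be an n x 3 matrix with n >= 10")
  .assert(all(is.finite(nodes)), "nodes must be finite")
  if (align) nodes <- .align_nodes(nodes)
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                       nodes[-nrow(nodes), , drop = FALSE])^2))
  .assert(all(seg > 0), "duplicate consecutive nodes")
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  tip_radius <- material$base_radius_um / material$taper_ratio
  radii <- material$base_radius_um -
    (material$base_radius_um - tip_radius) * s / L
  structure(list(nodes = nodes, arc_lengths = s, radii = radii,
                 material = material, total_arc_length = L),
            class = "whisker_shape")
}

#' @export
print.whisker_shape <- function(x, ...) {
  cat("whisker_shape:", nrow(x$nodes), "nodes,",
      sprintf("arc length %.3f mm,", x$total_arc_length),
      sprintf("base radius %.1f um, taper ratio %.2f\n",
              x$material$base_radius_um, x$material$taper_ratio))
  invisible(x)
}

# Resample a polyline to n nodes at uniform arc-length spacing using cubic
# splines per coordinate on a fine arc-length grid.
.resample_polyline <- function(nodes, n, fine_factor = 25) {
  m <- nrow(nodes)
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-m, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  sf <- seq(0, s[m], length.out = max(m * fine_factor, 500))
  fine <- vapply(1:3, function(k) {
    if (m >= 4) splinefun(s, nodes[, k], method = "natural")(sf)
    else approx(s, nodes[, k], xout = sf)$y
  }, numeric(length(sf)))
  segf <- sqrt(rowSums((fine[-1, , drop = FALSE] -
                        fine[-nrow(fine), , drop = FALSE])^2))
  sa <- c(0, cumsum(segf))
  su <- seq(0, sa[length(sa)], length.out = n)
  vapply(1:3, function(k) approx(sa, fine[, k], xout = su)$y, numeric(n))
}

#' Build a synthetic gamma-like whisker
#'
#' Generates a whisker emulating the gamma vibrissa used in the behavioural
#' setting: mostly planar with quadratic in-plane curvature, plus a distal
#' segment that leaves the plane, with a linear taper along arc length. The
#' proximal 70% of arc length is planar by construction.
#'
#' @param arc_length_mm total arc length (mm). Default 20.
#' @param inplane_coeff quadratic in-plane coefficient (1/mm): the planar
#'   backbone is y = inplane_coeff * x^2. Default 0.015.
#' @param outplane_coeff peak out-of-plane offset at the tip (mm) of the
#'   distal segment. Default 1.5; 0 gives a perfectly planar whisker.
#' @param outplane_onset fraction of arc length at which the out-of-plane
#'   curvature begins. Default 0.7.
#' @param n_nodes number of centreline nodes (>= 20). Default 100.
#' @param material a [material_params()] object.
#' @return A `whisker_shape`.
#' @examples
#' w <- build_gamma_like_whisker()
#' w$radii[1] / w$radii[length(w$radii)]  # = taper ratio
#' @export
build_gamma_like_whisker <- function(arc_length_mm = 20,
                                     inplane_coeff = 0.015,
                                     outplane_coeff = 1.5,
                                     outplane_onset = 0.7,
                                     n_nodes = 100,
                                     material = material_params()) {
  .assert(arc_length_mm > 0, "arc_length_mm must be positive")
  .assert(n_nodes >= 20, "n_nodes must be >= 20")
  .assert(outplane_onset > 0 && outplane_onset < 1,
          "outplane_onset must be in (0, 1)")
  # planar backbone y = a x^2, sampled densely in x, then arc-parameterised
  xs <- seq(0, 2 * arc_length_mm, length.out = 4000)
  ys <- inplane_coeff * xs^2
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg))
  keep <- s <= arc_length_mm * 1.001
  xs <- xs[keep]; ys <- ys[keep]; s <- s[keep]
  .assert(max(s) >= arc_length_mm * 0.999,
          "inplane_coeff too large for requested arc length")
  u <- s / arc_length_mm
  zs <- ifelse(u > outplane_onset,
               outplane_coeff * ((u - outplane_onset) / (1 - outplane_onset))^2,
               0)
  raw <- cbind(xs, ys, zs)
  nodes <- .resample_polyline(raw, n_nodes)
  # rescale so total arc length is exact (out-of-plane bend lengthens the curve)
  segn <- sqrt(rowSums((nodes[-1, ] - nodes[-n_nodes, ])^2))
  nodes <- nodes * (arc_length_mm / sum(segn))
  whisker_shape(nodes, material)
}

#' Align an ordered point set to the whisker-centred frame
#'
#' The whisker-centred frame places the base at the origin, the x-axis along
#' the proximal whisker (chord from the base to 10% of arc length), rotates
#' the best-fit plane of the proximal 70% of the whisker onto the x-y plane,
#' and orients the intrinsic curvature so the tip points toward +y.
#'
#' @param points numeric matrix (n x 3), ordered base to tip, n >= 10.
#' @return The aligned n x 3 matrix of points (mm).
#' @export
to_whisker_frame <- function(points) {
  points <- as.matrix(points)
  .assert(nrow(points) >= 10 && ncol(points) == 3,
          "points must be an n x 3 matrix with n >= 10")
  .align_nodes(points)
}

.align_nodes <- function(p) {
  n <- nrow(p)
  p <- sweep(p, 2, p[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  .assert(all(seg > 0), "degenerate geometry: coincident consecutive points")
  s <- c(0, cumsum(seg))
  L <- s[n]
  # proximal direction: chord to the node nearest 10% arc length
  i10 <- which.min(abs(s - 0.1 * L))
  if (i10 < 2) i10 <- 2
  chord <- p[i10, ]
  .assert(sqrt(sum(chord^2)) > 1e-12, "degenerate proximal direction")
  R1 <- .rotation_between(chord / sqrt(sum(chord^2)), c(1, 0, 0))
  p <- p %*% t(R1)
  # rotate about x so the proximal 70% best-fit plane is the x-y plane
  prox <- p[s <= 0.7 * L, , drop = FALSE]
  Syy <- sum(prox[, 2]^2); Szz <- sum(prox[, 3]^2)
  Syz <- sum(prox[, 2] * prox[, 3])
  if (Syy + Szz > 1e-12) {
    # rotate about x so the minor axis of the proximal (y, z) scatter becomes z
    ev <- eigen(matrix(c(Syy, Syz, Syz, Szz), 2), symmetric = TRUE)
    v <- ev$vectors[, 2]  # minor eigenvector (v_y, v_z)
    if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v  # fix sign ambiguity
    alpha <- atan2(v[1], v[2])
    ca <- cos(alpha); sa <- sin(alpha)
    Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
    p <- p %*% t(Rx)
  }
  # intrinsic curvature points the tip toward +y
  if (p[n, 2] < 0) p <- p %*% diag(c(1, -1, -1))
  p
}

# minimal rotation matrix taking unit vector u to unit vector v
.rotation_between <- function(u, v) {
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2)); cth <- sum(u * v)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- perp - sum(perp * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(.rodrigues(ax, pi))
  }
  .rodrigues(ax / s, atan2(s, cth))
}

.rodrigues <- function(axis, angle) {
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Contact point in whisker-centred spherical coordinates
#'
#' @param r_mm radial distance from the whisker base (mm), > 0.
#' @param theta_deg azimuth of the contact point from the x-axis, degrees.
#' @param phi_deg elevation from the x-y plane, degrees, in (-90, 90).
#' @return An object of class `contact_point`.
#' @export
contact_point <- function(r_mm, theta_deg, phi_deg) {
  .assert(all(r_mm > 0), "r_mm must be positive")
  .assert(all(is.finite(c(r_mm, theta_deg, phi_deg))),
          "contact coordinates must be finite")
  .assert(all(phi_deg > -90 & phi_deg < 90), "phi_deg must lie in (-90, 90)")
  structure(list(r_mm = r_mm, theta_deg = theta_deg, phi_deg = phi_deg),
            class = "contact_point")
}

#' Convert whisker-centred spherical coordinates to Cartesian
#'
#' @param cp a [contact_point()] (vectorised fields allowed).
#' @return numeric matrix (n x 3) of positions in mm.
#' @export
spherical_to_cartesian <- function(cp) {
  th <- .deg2rad(cp$theta_deg); ph <- .deg2rad(cp$phi_deg)
  cbind(x = cp$r_mm * cos(ph) * cos(th),
        y = cp$r_mm * cos(ph) * sin(th),
        z = cp$r_mm * sin(ph))
}

#' Convert Cartesian positions to whisker-centred spherical coordinates
#'
#' @param p numeric vector of length 3 or matrix (n x 3), mm.
#' @return A [contact_point()] with vectorised fields.
#' @export
cartesian_to_spherical <- function(p) {
  p <- rbind(p)
  r <- sqrt(rowSums(p^2))
  .assert(all(r > 0), "zero-length vector has no spherical representation")
  contact_point(r, .rad2deg(atan2(p[, 2], p[, 1])), .rad2deg(asin(p[, 3] / r)))
}

#' Load whisker centreline points from file
#'
#' Reads an ordered polyline (base to tip) from CSV (columns
#' `s_mm,x_mm,y_mm,z_mm`; `s_mm` may be omitted) or JSON
#' (fields `units` and `points`), resamples to uniform arc-length spacing,
#' aligns to the whisker-centred frame, and attaches taper and material.
#'
#' @param path file path (.csv or .json).
#' @param material a [material_params()] object.
#' @param n_nodes node count after resampling. Default 100.
#' @return A `whisker_shape`.
#' @export
load_whisker_points <- function(path, material = material_params(),
                                n_nodes = 100) {
  .assert(file.exists(path), paste("cannot read file:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    pts <- as.matrix(obj$points)
  } else {
    df <- read.csv(path, comment.char = "#")
    .assert(all(c("x_mm", "y_mm", "z_mm") %in% names(df)),
            "CSV must have columns x_mm, y_mm, z_mm")
    pts <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  }
  .assert(nrow(pts) >= 10, "need at least 10 points")
  .assert(all(is.finite(pts)), "points must be finite")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  .assert(all(seg > 0), "duplicate consecutive points in file")
  whisker_shape(.resample_polyline(pts, n_nodes), material)
}

#' Write whisker centreline points to CSV
#'
#' @param whisker a `whisker_shape`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_whisker_points <- function(whisker, path) {
  df <- data.frame(s_mm = whisker$arc_lengths,
                   x_mm = whisker$nodes[, 1],
                   y_mm = whisker$nodes[, 2],
                   z_mm = whisker$nodes[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# whisker centreline; units mm", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Bending and torsional rigidities at joint nodes 1..n-1 (base node through
# the penultimate node), in uN mm^2.  In the mm / uN unit system 1 Pa equals
# 1 uN/mm^2 numerically, so E[uN/mm^2] = E[GPa] * 1e9.  I = pi r^4 / 4 and
# J = 2 I for a circular section; G = E / (2 (1 + nu)).
.joint_rigidities <- function(whisker) {
  E <- whisker$material$youngs_modulus_GPa * 1e9   # uN / mm^2
  G <- E / (2 * (1 + whisker$material$poisson_ratio))
  r_mm <- whisker$radii / 1000
  n <- length(r_mm)
  I <- pi * r_mm^4 / 4
  list(EI = E * I[1:(n - 1)], GJ = G * 2 * I[1:(n - 1)])
}

#' Cross-section radius at an arc length
#'
#' Linear taper: radius(s) = base - (base - tip) * s / L.
#'
#' @param whisker a `whisker_shape`.
#' @param s_mm arc length(s) in mm.
#' @return radius in micrometres.
#' @export
radius_at <- function(whisker, s_mm) {
  b <- whisker$material$base_radius_um
  t <- b / whisker$material$taper_ratio
  b - (b - t) * s_mm / whisker$total_arc_length
}

# fingerprint of shape + material, used to tie tables to whiskers
.whisker_fingerprint <- function(whisker) {
  v <- c(round(as.numeric(whisker$nodes), 9),
         whisker$material$youngs_modulus_GPa,
         whisker$material$poisson_ratio,
         whisker$material$base_radius_um,
         whisker$material$taper_ratio)
  # order-dependent polynomial hash; stable across sessions
  h <- 0
  for (x in v) h <- (h * 31 + sum(as.integer(charToRaw(format(x, digits = 12))))) %% 2147483647
  sprintf("w%010d", h)
}
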