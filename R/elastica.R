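# Quasistatic, frictionless deflection of the whisker to a prescribed contact
# point, and the six reaction loads at the whisker base.

#' Solver options for the elastica contact solver
#'
#' @param tol_pos_mm positional tolerance at the contact (mm): the contact
#'   material point must reach the target within this distance. Default
#'   0.01 (10 um).
#' @param max_outer maximum Newton iterations on the contact force.
#' @param max_inner maximum fixed-point iterations for the deflected shape.
#' @param tol_inner convergence tolerance of the shape relaxation (radians /
#'   mm).
#' @return A list of solver options.
#' @export
solver_options <- function(tol_pos_mm = 0.01, max_outer = 80,
                           max_inner = 300, tol_inner = 1e-10) {
  .assert(tol_pos_mm > 0 && tol_inner > 0, "solver tolerances must be positive")
  list(tol_pos_mm = tol_pos_mm, max_outer = max_outer,
       max_inner = max_inner, tol_inner = tol_inner)
}

#' Base loads transmitted by a point contact
#'
#' Static equilibrium closure at the clamped base: the whisker transmits the
#' applied contact force into the follicle together with its moment about
#' the base, F = f_applied and M = p_contact x f_applied (the follicle's
#' support reaction is the negative of both). With this sign convention the
#' axial component Fx is the tension at the base: positive when the contact
#' pulls the whisker out of the follicle, negative when it pushes the
#' whisker in, which is the usual situation during bending. Only contacts
#' that straighten the intrinsic curvature produce positive Fx.
#'
#' @param applied_force numeric length-3, uN, in the whisker-centred frame.
#' @param contact_location numeric length-3, mm.
#' @return An object of class `base_loads` with fields `Fx, Fy, Fz` (uN) and
#'   `Mx, My, Mz` (uN mm).
#' @export
base_reactions <- function(applied_force, contact_location) {
  .assert(all(is.finite(applied_force)) && all(is.finite(contact_location)),
          "applied_force and contact_location must be finite")
  f <- as.numeric(applied_force); p <- as.numeric(contact_location)
  m <- c(p[2] * f[3] - p[3] * f[2],
         p[3] * f[1] - p[1] * f[3],
         p[1] * f[2] - p[2] * f[1])
  structure(list(Fx = f[1], Fy = f[2], Fz = f[3],
                 Mx = m[1], My = m[2], Mz = m[3]),
            class = "base_loads")
}

.loads_vec <- function(b) c(b$Fx, b$Fy, b$Fz, b$Mx, b$My, b$Mz)

#' Deflect the whisker under a prescribed point force
#'
#' Forward problem: apply a fixed force at a node and relax the elastic chain
#' to equilibrium. Mostly useful for validation against closed-form beam
#' results.
#'
#' @param whisker a `whisker_shape`.
#' @param node_index node at which the force is applied (1-based).
#' @param force numeric length-3, uN.
#' @param opts [solver_options()].
#' @return A list with `converged`, `nodes` (deflected), and
#'   `link_tangents`.
#' @export
deflect_under_force <- function(whisker, node_index, force,
                                opts = solver_options()) {
  rig <- .joint_rigidities(whisker)
  cpp_deflect_force(whisker$nodes, rig$EI, rig$GJ, node_index,
                    as.numeric(force), opts$max_inner, opts$tol_inner)
}

#' Deflect the whisker to a prescribed contact point
#'
#' Solves for the frictionless point load (orthogonal to the local deflected
#' tangent) and the contact arc length that bring a material point of the
#' whisker onto the target, using damped Newton iteration with continuation
#' from the undeflected shape. Non-convergence is reported as slip,
#' mirroring how a whisker slides off a contact it cannot hold.
#'
#' @param whisker a `whisker_shape`.
#' @param target a [contact_point()] (single point), or numeric length-3
#'   Cartesian position in mm.
#' @param opts [solver_options()].
#' @param f_init optional warm-start force (uN); when given (with `s_init`),
#'   continuation is skipped and the Newton solve starts from this state.
#' @param s_init optional warm-start contact arc length (mm).
#' @param fallback when a warm-started solve fails, retry by continuation
#'   from the undeflected shape (default TRUE).
#' @return An object of class `deflection_result`: `converged`, `reason`,
#'   `applied_force` (uN), `contact_location` (mm), `contact_arc_length`
#'   (mm), `contact_tangent`, `deflected_nodes`, `base_loads`, `iterations`.
#' @export
deflect_to_point <- function(whisker, target, opts = solver_options(),
                             f_init = NULL, s_init = -1, fallback = TRUE) {
  tgt <- if (inherits(target, "contact_point"))
    as.numeric(spherical_to_cartesian(target)) else as.numeric(target)
  .assert(length(tgt) == 3 && all(is.finite(tgt)), "invalid target")
  if (sqrt(sum(tgt^2)) > whisker$total_arc_length) {
    return(.deflection_failure("unreachable"))
  }
  rig <- .joint_rigidities(whisker)
  res <- if (is.null(f_init)) {
    cpp_deflect_to_point(whisker$nodes, rig$EI, rig$GJ, tgt,
                         opts$tol_pos_mm, opts$max_outer, opts$max_inner,
                         opts$tol_inner)
  } else {
    r <- cpp_solve_contact(whisker$nodes, rig$EI, rig$GJ, tgt,
                           as.numeric(f_init), s_init, opts$tol_pos_mm,
                           opts$max_outer, opts$max_inner, opts$tol_inner)
    if (!r$converged && fallback)  # warm start failed; retry by continuation
      r <- cpp_deflect_to_point(whisker$nodes, rig$EI, rig$GJ, tgt,
                                opts$tol_pos_mm, opts$max_outer,
                                opts$max_inner, opts$tol_inner)
    r
  }
  if (!isTRUE(res$converged)) return(.deflection_failure(res$reason))
  structure(list(converged = TRUE, reason = "converged",
                 applied_force = res$force,
                 contact_location = res$contact,
                 contact_arc_length = res$s_c,
                 contact_index = res$contact_index,
                 contact_tangent = res$tangent,
                 deflected_nodes = res$nodes,
                 base_loads = base_reactions(res$force, res$contact),
                 iterations = res$iterations),
            class = "deflection_result")
}

.deflection_failure <- function(reason) {
  structure(list(converged = FALSE, reason = reason,
                 applied_force = c(0, 0, 0), contact_location = NULL,
                 contact_arc_length = NA_real_, contact_index = NA_integer_,
                 contact_tangent = NULL, deflected_nodes = NULL,
                 base_loads = NULL, iterations = NA_integer_),
            class = "deflection_result")
}

#' @export
print.deflection_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("deflection: converged at s = %.2f mm, |F| = %.4g uN\n",
                x$contact_arc_length, sqrt(sum(x$applied_force^2))))
  } else {
    cat("deflection: not converged (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Sweep the whisker over a grid of contact points
#'
#' Deflects the whisker to every grid point, recording the six base loads for
#' converged points and a discard reason otherwise. Points are visited in an
#' order that walks outward in azimuth at fixed (r, phi) so each solve warm
#' starts from its neighbour.
#'
#' @param whisker a `whisker_shape`.
#' @param grid data frame with columns `r_mm`, `theta_deg`, `phi_deg`
#'   (from [build_grid()]).
#' @param opts [solver_options()].
#' @param progress print progress every so many points (0 = silent).
#' @return A data frame with one row per grid point: the grid coordinates,
#'   achieved contact coordinates (`r_fit_mm`, `theta_fit_deg`,
#'   `phi_fit_deg`), contact arc length `s_mm`, tangent x-component
#'   `tangent_x`, the loads `Fx..Mz`, `converged`, and `reason`.
#' @export
reachable_space <- function(whisker, grid, opts = solver_options(),
                            progress = 0) {
  .assert(nrow(grid) > 0, "empty grid")
  n <- nrow(grid)
  out <- data.frame(r_mm = grid$r_mm, theta_deg = grid$theta_deg,
                    phi_deg = grid$phi_deg,
                    r_fit_mm = NA_real_, theta_fit_deg = NA_real_,
                    phi_fit_deg = NA_real_, s_mm = NA_real_,
                    tangent_x = NA_real_,
                    Fx = NA_real_, Fy = NA_real_, Fz = NA_real_,
                    Mx = NA_real_, My = NA_real_, Mz = NA_real_,
                    converged = FALSE, reason = "", stringsAsFactors = FALSE)
  solve_one <- function(i, warm) {
    cp <- contact_point(grid$r_mm[i], grid$theta_deg[i], grid$phi_deg[i])
    # inside a branch walk the warm chain is already a continuation, so a
    # failed warm solve is slip; no per-point continuation retry
    d <- deflect_to_point(whisker, cp, opts,
                          f_init = warm$f, s_init = warm$s,
                          fallback = is.null(warm$f))
    if (d$converged) {
      sph <- cartesian_to_spherical(d$contact_location)
      out$r_fit_mm[i] <<- sph$r_mm
      out$theta_fit_deg[i] <<- sph$theta_deg
      out$phi_fit_deg[i] <<- sph$phi_deg
      out$s_mm[i] <<- d$contact_arc_length
      out$tangent_x[i] <<- d$contact_tangent[1]
      out[i, c("Fx", "Fy", "Fz", "Mx", "My", "Mz")] <<-
        as.list(.loads_vec(d$base_loads))
      out$converged[i] <<- TRUE
      out$reason[i] <<- "converged"
      list(f = d$applied_force, s = d$contact_arc_length)
    } else {
      out$reason[i] <<- d$reason
      NULL
    }
  }
  done <- 0
  tick <- function(k = 1) {
    done <<- done + k
    if (progress > 0 && done %/% progress >
        (done - k) %/% progress)
      message(sprintf("  sweep %d / %d (%d converged)", done, n,
                      sum(out$converged)))
  }
  # Walk each radius from the whisker outward: elevations ordered by |phi|,
  # azimuth branches from theta = 0 outward, warm starting each branch from
  # the previous elevation's branch seed.  Once the whisker slips along a
  # branch, the rest of the branch is slip too (monotone envelope); once a
  # whole elevation finds no contact, higher elevations of the same sign are
  # out of reach as well.
  for (r in sort(unique(grid$r_mm))) {
    phis <- sort(unique(grid$phi_deg[grid$r_mm == r]))
    phis <- phis[order(abs(phis), phis)]
    seed <- list()     # branch seeds keyed by sign of phi
    dead_side <- c("-1" = FALSE, "0" = FALSE, "1" = FALSE)
    for (ph in phis) {
      sgn <- as.character(sign(ph))
      idx <- which(grid$r_mm == r & grid$phi_deg == ph)
      if (dead_side[[sgn]]) {
        out$reason[idx] <- "slip"
        tick(length(idx))
        next
      }
      th <- grid$theta_deg[idx]
      branch_warm <- seed[[sgn]] %||% seed[["0"]] %||% list(f = NULL, s = -1)
      branch_seed <- NULL
      any_hit <- FALSE
      for (dir in list(idx[th >= 0][order(th[th >= 0])],
                       idx[th < 0][order(-th[th < 0])])) {
        warm <- branch_warm
        alive <- TRUE
        misses <- 0
        for (i in dir) {
          if (!alive) {
            out$reason[i] <- "slip"
            tick()
            next
          }
          res <- solve_one(i, warm)
          tick()
          if (!is.null(res)) {
            warm <- res
            any_hit <- TRUE
            misses <- 0
            if (is.null(branch_seed)) branch_seed <- res
          } else {
            warm <- list(f = NULL, s = -1)
            misses <- misses + 1
            # tolerate a few cold misses near the whisker, then declare slip
            if (misses >= 3 || any_hit) alive <- FALSE
          }
        }
      }
      if (!is.null(branch_seed)) seed[[sgn]] <- branch_seed
      if (sgn == "0" && !is.null(branch_seed)) {
        seed[["-1"]] <- branch_seed; seed[["1"]] <- branch_seed
      }
      if (!any_hit && sgn != "0") dead_side[[sgn]] <- TRUE
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
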