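# Shared fixtures (built lazily, cached for the whole test run) and
# independent oracles used across the suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

gamma_whisker <- function() fixture("gamma", function() build_gamma_like_whisker())

straight_whisker <- function(taper_ratio = 15, n = 100, L = 20) {
  whisker_shape(cbind(seq(0, L, length.out = n), 0, 0),
                material_params(taper_ratio = taper_ratio))
}

planar_whisker <- function() {
  fixture("planar", function()
    build_gamma_like_whisker(outplane_coeff = 0))
}

# the reduced-grid mapping table on the gamma-like whisker: the workhorse
# fixture for mapping, uniqueness, sensitivity, and acceptance tests
gamma_table <- function() {
  fixture("gamma_table", function()
    build_mapping(gamma_whisker(), build_grid()))
}

# smaller tables for the clear-case uniqueness contrasts
cylinder_table <- function() {
  fixture("cylinder_table", function() {
    w <- fixture("cylinder", function()
      build_gamma_like_whisker(material = material_params(taper_ratio = 1)))
    build_mapping(w, build_grid(r_step = 2, theta_step = 6, phi_step = 8))
  })
}

planar_table <- function() {
  # planar whisker deflected to in-plane contacts only (phi = 0 plane);
  # theta sampled finely so the table still holds >= 1000 records
  fixture("planar_table", function()
    build_mapping(planar_whisker(),
                  build_grid(r_step = 0.5, theta_step = 2,
                             phi_range = c(0, 0), phi_step = 1)))
}

# synthetic whisk trial + signals against the default peg
gamma_trial <- function() {
  fixture("gamma_trial", function() {
    w <- gamma_whisker()
    lowpass_basepose(synth_whisk_trial(w, seed = 42), w)
  })
}

gamma_trial_signals <- function() {
  fixture("gamma_signals", function()
    trial_to_signals(gamma_trial(), gamma_whisker()))
}

# --- independent planar large-deflection elastica oracle ------------------
#
# Continuous planar rod integrated with a fine Euler scheme:
# theta'(s) = kappa0(s) + M(s)/EI(s), M(s) = cross((p_c - p(s)), f),
# point load f at arc s_c, f orthogonal to the rod tangent at s_c.
# Unknowns (|f|, s_c) solved by Nelder-Mead so p(s_c) hits the target.
planar_elastica_oracle <- function(L = 20, base_radius_um = 100,
                                   taper_ratio = 15, E_GPa = 3,
                                   kappa0 = function(s) 0,
                                   target, n_s = 1200) {
  E <- E_GPa * 1e9
  rt <- base_radius_um / taper_ratio
  EI <- function(s) {
    r <- (base_radius_um - (base_radius_um - rt) * s / L) / 1000
    E * pi * r^4 / 4
  }
  ds <- L / n_s
  sgrid <- seq(0, L, length.out = n_s + 1)
  shape_for <- function(fmag, sc) {
    ic <- max(2, min(n_s, round(sc / ds)))
    pc <- target  # moment arm fixed to the (sought) contact position
    th <- numeric(n_s + 1)
    px <- numeric(n_s + 1); py <- numeric(n_s + 1)
    f <- c(0, 0)
    for (pass in 1:25) {
      # force orthogonal to current tangent at contact
      tc <- c(cos(th[ic]), sin(th[ic]))
      f <- fmag * c(-tc[2], tc[1])
      for (i in 1:n_s) {
        # midpoint (RK2) step of the curvature/position system
        M1 <- if (i <= ic) (pc[1] - px[i]) * f[2] - (pc[2] - py[i]) * f[1]
              else 0
        k1 <- kappa0(sgrid[i]) + M1 / EI(sgrid[i])
        xm <- px[i] + cos(th[i]) * ds / 2
        ym <- py[i] + sin(th[i]) * ds / 2
        thm <- th[i] + k1 * ds / 2
        M2 <- if (i <= ic) (pc[1] - xm) * f[2] - (pc[2] - ym) * f[1] else 0
        k2 <- kappa0(sgrid[i] + ds / 2) + M2 / EI(sgrid[i] + ds / 2)
        th[i + 1] <- th[i] + k2 * ds
        px[i + 1] <- px[i] + cos(thm) * ds
        py[i + 1] <- py[i] + sin(thm) * ds
      }
      pc_new <- c(px[ic], py[ic])
      if (sqrt(sum((pc_new - pc)^2)) < 1e-10) { pc <- pc_new; break }
      pc <- pc + 0.7 * (pc_new - pc)
    }
    list(pc = pc, f = f, th = th)
  }
  obj <- function(par) {
    sh <- shape_for(par[1], max(min(par[2], L), 0.5))
    sum((sh$pc - target)^2)
  }
  r0 <- sqrt(sum(target^2))
  fit <- optim(c(100, r0), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-14))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-14))
  sh <- shape_for(fit$par[1], max(min(fit$par[2], L), 0.5))
  list(residual = sqrt(fit$value),
       force = sh$f, contact = sh$pc,
       moment_z = sh$pc[1] * sh$f[2] - sh$pc[2] * sh$f[1])
}

# analytic mapping table (no solver): signals are a prescribed function of
# the contact coordinates, which lets uniqueness/inversion machinery be
# validated independently of the mechanics
synthetic_table <- function(f_signals,
                            r = seq(6, 20, 1), th = seq(-60, 60, 4),
                            ph = seq(-45, 45, 5)) {
  g <- expand.grid(r_mm = r, theta_deg = th, phi_deg = ph)
  sig <- f_signals(g$r_mm, g$theta_deg, g$phi_deg)
  rec <- data.frame(g,
                    r_fit_mm = g$r_mm, theta_fit_deg = g$theta_deg,
                    phi_fit_deg = g$phi_deg, s_mm = g$r_mm,
                    tangent_x = 1,
                    Fx = sig$Fx, Fy = 0, Fz = 0, Mx = sig$Mx,
                    My = 0, Mz = 0,
                    converged = TRUE, reason = "converged",
                    FT = sig$FT, FD_rad = sig$FD, MB = sig$MB,
                    MD_rad = sig$MD,
                    excluded_small_deflection = FALSE,
                    large_deflection = FALSE,
                    region = ifelse(g$theta_deg < 0, "concave-forward",
                                    "concave-backward"))
  structure(list(records = rec,
                 grid_spec = list(r = r, theta = th, phi = ph),
                 whisker_fingerprint = "synthetic", cone_deg = 2,
                 n_converged = nrow(rec), n_discarded = 0, n_excluded = 0),
            class = "mapping_table")
}
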