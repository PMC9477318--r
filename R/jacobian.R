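# Numerical sensitivity of the contact-point mapping: the 3x3 Jacobian of
# (r, theta, phi) with respect to (MD, MB, Fx), evaluated by central
# differences through a scattered-data interpolant, then trimmed and binned.

# Moving-least-squares local-linear interpolation of contact coordinates
# over (MD, MB, Fx) space.  MD is embedded as (cos, sin); MB and Fx are
# scaled by their range.  For each query the k nearest samples receive
# Gaussian distance weights and a weighted linear model per output.
.mls_interp <- function(queries, samples, values, k = 24) {
  rng <- list(MB = range(samples$MB), Fx = range(samples$Fx))
  sc <- function(df) cbind(cos(df$MD_rad), sin(df$MD_rad),
                           (df$MB - rng$MB[1]) / max(diff(rng$MB), 1e-12),
                           (df$Fx - rng$Fx[1]) / max(diff(rng$Fx), 1e-12))
  S <- sc(samples)
  Q <- sc(queries)
  kk <- min(k, nrow(S))
  nn <- cpp_knn(S, Q, kk)
  out <- matrix(NA_real_, nrow(Q), ncol(values))
  for (i in seq_len(nrow(Q))) {
    idx <- as.integer(nn$index[i, ])
    d <- nn$dist[i, ]
    h <- max(d[kk] / 2, 1e-9)
    wgt <- exp(-(d / h)^2)
    A <- cbind(1, S[idx, , drop = FALSE])
    ok <- tryCatch({
      WA <- A * wgt
      M <- crossprod(WA, A)
      rhs <- crossprod(WA, values[idx, , drop = FALSE])
      beta <- solve(M + diag(1e-8, ncol(A)), rhs)
      out[i, ] <- c(1, Q[i, ]) %*% beta
      TRUE
    }, error = function(e) FALSE)
    if (!ok) out[i, ] <- colSums(values[idx, , drop = FALSE] * wgt) / sum(wgt)
  }
  out
}

#' Central-difference step sizes from signal ranges
#'
#' Each mechanical variable's probe step is 0.05% of its own range.
#'
#' @param envelope data frame / list with elements `MD_rad`, `MB`, `Fx`,
#'   each a length-2 min/max.
#' @return named numeric vector of steps (MD in radians, MB in uN mm, Fx in
#'   uN).
#' @export
step_from_range <- function(envelope) {
  st <- vapply(c("MD_rad", "MB", "Fx"), function(nm) {
    r <- envelope[[nm]]
    .assert(length(r) == 2 && r[2] > r[1],
            paste("degenerate range for", nm))
    5e-4 * (r[2] - r[1])
  }, numeric(1))
  names(st) <- c("MD", "MB", "Fx")
  st
}

#' Evaluate the contact-point Jacobian at probe points
#'
#' For each probe location in (MD, MB, Fx) space, each of the nine elements
#' d(r, theta, phi)/d(MD, MB, Fx) is a central difference of the
#' interpolated contact coordinate, holding the other two variables fixed
#' (18 interpolations per probe). Probes whose +/- step leaves the data
#' cloud produce flagged (NA) elements via interpolation failure.
#'
#' @param probes data frame with columns `MD_rad`, `MB`, `Fx` (the probe
#'   locations; typically retained table records inside the envelope).
#' @param table a `mapping_table`.
#' @param steps from [step_from_range()].
#' @param k interpolation neighbourhood size.
#' @return A list of class `jacobian_field`: `probes`, `J` (n x 9 matrix,
#'   columns dr/dMD, dr/dMB, dr/dFx, dth/dMD, ..., dph/dFx), `steps`,
#'   and `interp_method`.
#' @export
jacobian_at <- function(probes, table, steps, k = 24) {
  .assert(all(steps > 0), "steps must be positive")
  rec <- retained_records(table)
  rec <- rec[is.finite(rec$MD_rad), , drop = FALSE]
  samples <- rec[, c("MD_rad", "MB", "Fx")]
  values <- as.matrix(rec[, c("r_mm", "theta_deg", "phi_deg")])
  n <- nrow(probes)
  # 6 probe variants: +/- step in each of MD, MB, Fx
  qs <- vector("list", 6)
  vars <- c("MD_rad", "MB", "Fx")
  stepv <- c(steps[["MD"]], steps[["MB"]], steps[["Fx"]])
  m <- 0
  for (v in 1:3) for (sgn in c(1, -1)) {
    m <- m + 1
    q <- probes[, c("MD_rad", "MB", "Fx")]
    q[[vars[v]]] <- q[[vars[v]]] + sgn * stepv[v]
    qs[[m]] <- q
  }
  allq <- do.call(rbind, qs)
  vals <- .mls_interp(allq, samples, values, k)   # 18 interpolations / probe
  J <- matrix(NA_real_, n, 9)
  colnames(J) <- c("dr_dMD", "dr_dMB", "dr_dFx",
                   "dth_dMD", "dth_dMB", "dth_dFx",
                   "dph_dMD", "dph_dMB", "dph_dFx")
  for (v in 1:3) {
    plus <- vals[((2 * v - 2) * n + 1):((2 * v - 1) * n), , drop = FALSE]
    minus <- vals[((2 * v - 1) * n + 1):((2 * v) * n), , drop = FALSE]
    d <- (plus - minus) / (2 * stepv[v])
    J[, v] <- d[, 1]      # dr/dvar
    J[, 3 + v] <- d[, 2]  # dtheta/dvar
    J[, 6 + v] <- d[, 3]  # dphi/dvar
  }
  structure(list(probes = probes, J = J, steps = steps, k = k,
                 interp_method = "moving-least-squares local linear"),
            class = "jacobian_field")
}

#' Signal envelope of a trial or table
#'
#' Min/max of MD, MB, Fx over rows with defined directions.
#'
#' @param signals data frame with `MD_rad`, `MB`, `Fx`.
#' @return list of length-2 ranges.
#' @export
signal_envelope <- function(signals) {
  s <- signals[is.finite(signals$MD_rad) & signals$MB > 0, , drop = FALSE]
  list(MD_rad = range(s$MD_rad), MB = range(s$MB), Fx = range(s$Fx))
}

#' Trim and bin a Jacobian field for display
#'
#' Per element: values outside the central 99% interval are removed; the
#' remainder is binned 50 x 50 over (mechanical variable value x element
#' value). Each bin carries its mean element value, count, and a display
#' weight proportional to count, floored at 0.05 for bins with fewer than 5%
#' of the maximum bin count.
#'
#' @param field a `jacobian_field` from [jacobian_at()].
#' @param n_bins bins per direction. Default 50.
#' @param min_valid minimum valid samples per element. Default 100.
#' @return A list of class `binned_sensitivity`: per element a data frame of
#'   non-empty bins (`x_mid`, `y_mid`, `mean`, `count`, `weight`) plus
#'   bookkeeping counts (`n_valid`, `n_trimmed`, `n_binned`).
#' @export
trim_and_bin <- function(field, n_bins = 50, min_valid = 100) {
  vars <- c("MD", "MB", "Fx")
  var_col <- c(MD = "MD_rad", MB = "MB", Fx = "Fx")
  out <- list()
  for (el in colnames(field$J)) {
    v <- field$J[, el]
    xvar <- vars[match(sub(".*_d", "", el), vars)]
    x <- field$probes[[var_col[[xvar]]]]
    valid <- is.finite(v)
    .assert(sum(valid) >= min_valid,
            sprintf("too few valid samples for %s (%d)", el, sum(valid)))
    qs <- quantile(v[valid], c(0.005, 0.995), names = FALSE)
    keep <- valid & v >= qs[1] & v <= qs[2]
    xb <- cut(x[keep], breaks = n_bins, labels = FALSE)
    yb <- cut(v[keep], breaks = n_bins, labels = FALSE)
    key <- interaction(xb, yb, drop = TRUE)
    agg <- data.frame(
      x_mid = tapply(x[keep], key, mean),
      y_mid = tapply(v[keep], key, mean),
      mean = tapply(v[keep], key, mean),
      count = as.integer(tapply(v[keep], key, length)))
    wmax <- max(agg$count)
    agg$weight <- agg$count / wmax
    agg$weight[agg$count < 0.05 * wmax] <- 0.05
    out[[el]] <- list(bins = agg, n_valid = sum(valid),
                      n_trimmed = sum(valid) - sum(keep),
                      n_binned = sum(keep))
  }
  structure(list(elements = out, n_bins = n_bins,
                 steps = field$steps, interp_method = field$interp_method),
            class = "binned_sensitivity")
}

#' @export
print.binned_sensitivity <- function(x, ...) {
  cat("binned_sensitivity:", length(x$elements), "Jacobian elements,",
      x$n_bins, "x", x$n_bins, "bins;", x$interp_method, "\n")
  for (el in names(x$elements)) {
    e <- x$elements[[el]]
    cat(sprintf("  %-8s valid %5d, trimmed %4d\n", el, e$n_valid,
                e$n_trimmed))
  }
  invisible(x)
}

#' Interquartile spread of Jacobian elements by signal magnitude
#'
#' Compares the spread (IQR) of each Jacobian element between probes in the
#' bottom and top quartiles of |MB| (or |Fx|): sensitivity spread contracts
#' as the loading grows.
#'
#' @param field a `jacobian_field`.
#' @param by "MB" or "Fx".
#' @return data frame with columns `element`, `iqr_low`, `iqr_high`.
#' @export
spread_by_magnitude <- function(field, by = c("MB", "Fx")) {
  by <- match.arg(by)
  mag <- abs(field$probes[[by]])
  qs <- quantile(mag, c(0.25, 0.75))
  lo <- mag <= qs[1]
  hi <- mag >= qs[2]
  res <- lapply(colnames(field$J), function(el) {
    v <- field$J[, el]
    data.frame(element = el,
               iqr_low = stats::IQR(v[lo], na.rm = TRUE),
               iqr_high = stats::IQR(v[hi], na.rm = TRUE))
  })
  do.call(rbind, res)
}
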