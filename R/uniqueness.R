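# Uniqueness testing: which triplets of base signals map uniquely
# (invertibly) to the 3D contact point, overall and within region conditions.

#' Enumerate all signal triplets
#'
#' All 20 unordered 3-subsets of \{Fx, FT, FD, Mx, MB, MD\}, in a fixed
#' deterministic order.
#'
#' @return list of [triplet_spec()] objects.
#' @export
enumerate_triplets <- function() {
  cmb <- combn(.SIGNAL_NAMES, 3)
  lapply(seq_len(ncol(cmb)), function(i) triplet_spec(cmb[, i]))
}

#' Uniqueness thresholds
#'
#' A mapping counts as uniquely invertible when a neural-network regression
#' from the triplet to (r, theta, phi) reaches held-out median absolute
#' errors below these bounds, and the geometric overlap scan finds no pair of
#' records that are close in signal space but distant in contact space.
#'
#' @param r_mm held-out median |error| bound for radial distance. Default 1.
#' @param theta_deg bound for azimuth. Default 2.
#' @param phi_deg bound for elevation. Default 2.
#' @param eps_cp_mm overlap scan: a record is an overlap witness when its
#'   nearest signal-space neighbour lies farther than this (mm) away in
#'   contact space. Default 4 (20% of the 20 mm whisker).
#' @param eps_sig_factor overlap scan: the intruding neighbour must also be
#'   genuinely close in signal space - nearer than this multiple of the
#'   census median nearest-neighbour spacing - so that isolated records at
#'   the edge of the reachable cloud (whose nearest neighbour is far in
#'   every sense) are not mistaken for folds. Default 0.5.
#' @return list of thresholds.
#' @export
uniqueness_thresholds <- function(r_mm = 1, theta_deg = 2, phi_deg = 2,
                                  eps_cp_mm = 4, eps_sig_factor = 0.5) {
  list(r_mm = r_mm, theta_deg = theta_deg, phi_deg = phi_deg,
       eps_cp_mm = eps_cp_mm, eps_sig_factor = eps_sig_factor)
}

#' Filter a mapping table by region condition
#'
#' Conditions follow the region vocabulary: `All` (identity), `ELD`
#' (exclude large deflections), `CF` / `CB` (only concave-forward /
#' concave-backward contacts), and combinations `ELD-CF`, `ELD-CB`.
#'
#' @param table a `mapping_table`.
#' @param condition one of "All", "ELD", "CF", "CB", "ELD-CF", "ELD-CB".
#' @return the filtered `mapping_table`.
#' @export
region_filter <- function(table, condition = "All") {
  .assert(condition %in% c("All", "ELD", "CF", "CB", "ELD-CF", "ELD-CB"),
          paste("unknown region condition:", condition))
  r <- table$records
  keep <- rep(TRUE, nrow(r))
  if (grepl("ELD", condition)) keep <- keep & !(r$converged & r$large_deflection)
  if (grepl("CF", condition))
    keep <- keep & (!r$converged | r$region %in% "concave-forward")
  if (grepl("CB", condition))
    keep <- keep & (!r$converged | r$region %in% "concave-backward")
  out <- table
  out$records <- r[keep, , drop = FALSE]
  out$n_converged <- sum(out$records$converged)
  out$n_discarded <- sum(!out$records$converged)
  out$n_excluded <- sum(out$records$converged &
                        out$records$excluded_small_deflection)
  out
}

# fit one seeded nnet replicate and return held-out median absolute errors
.fit_uniqueness_net <- function(X, Y, seed, size = 32, maxit = 400,
                                train_frac = 0.8, max_train = 4000) {
  set.seed(seed)
  n <- nrow(X)
  idx <- sample(n)
  ntr <- floor(train_frac * n)
  tr <- idx[seq_len(min(ntr, max_train))]
  te <- idx[(ntr + 1):n]
  ys <- apply(Y, 2, sd)
  ym <- colMeans(Y)
  Ys <- sweep(sweep(Y, 2, ym), 2, pmax(ys, 1e-12), "/")
  fit <- tryCatch(
    nnet::nnet(x = X[tr, , drop = FALSE], y = Ys[tr, , drop = FALSE],
               size = size, linout = TRUE, maxit = maxit, decay = 1e-5,
               MaxNWts = 20000, trace = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  pred <- predict(fit, X[te, , drop = FALSE])
  pred <- sweep(sweep(pred, 2, pmax(ys, 1e-12), "*"), 2, ym, "+")
  abs_err <- abs(pred - Y[te, , drop = FALSE])
  apply(abs_err, 2, median)
}

#' Test a signal triplet for unique invertibility
#'
#' Two evidence streams: (1) seeded replicate neural-network fits from the
#' triplet to (r, theta, phi) must reach held-out median errors below the
#' thresholds (majority vote over seeds); (2) an exhaustive geometric scan
#' must find no record whose nearest neighbour in standardised signal space
#' intrudes from a distant part of contact space (farther than `eps_cp_mm`
#' away while closer in signal space than half the typical
#' nearest-neighbour spacing). The
#' mapping is `unique` only if both streams agree; a failed fit is reported
#' as `inconclusive`, never as unique.
#'
#' @param table a `mapping_table`.
#' @param spec a [triplet_spec()].
#' @param condition region condition (see [region_filter()]). Default "All".
#' @param thresholds [uniqueness_thresholds()].
#' @param seeds integer seeds for replicate network fits. Default 1:3.
#' @param min_records minimum retained records required. Default 1000.
#' @return An object of class `uniqueness_report`.
#' @export
test_uniqueness <- function(table, spec, condition = "All",
                            thresholds = uniqueness_thresholds(),
                            seeds = 1:3, min_records = 1000) {
  tab <- region_filter(table, condition)
  rec <- retained_records(tab)
  .assert(nrow(rec) >= min_records,
          sprintf("too few retained records (%d < %d)", nrow(rec),
                  min_records))
  st <- .embed_stats(rec, spec)
  X <- .embed_signals(rec, spec, st$center, st$scale)
  ok <- complete.cases(X)
  rec <- rec[ok, , drop = FALSE]
  X <- X[ok, , drop = FALSE]
  Y <- as.matrix(rec[, c("r_mm", "theta_deg", "phi_deg")])
  # evidence 1: replicate network fits
  errs <- lapply(seeds, function(s) .fit_uniqueness_net(X, Y, s))
  fitted <- !vapply(errs, is.null, logical(1))
  votes <- vapply(errs[fitted], function(e) {
    e[1] < thresholds$r_mm && e[2] < thresholds$theta_deg &&
      e[3] < thresholds$phi_deg
  }, logical(1))
  err_med <- if (any(fitted)) apply(do.call(rbind, errs[fitted]), 2, median)
             else c(NA_real_, NA_real_, NA_real_)
  # evidence 2: exhaustive geometric overlap scan. For an invertible,
  # well-sampled mapping every record's nearest neighbour in signal space is
  # also a neighbour in contact space; where the mapping's sheets intersect
  # (a fold), records from a distant part of contact space intrude closer
  # than the record's own grid neighbours. The overlap count is the number
  # of records whose nearest signal-space neighbour lies farther than
  # eps_cp away in contact space.
  cp <- spherical_to_cartesian(contact_point(rec$r_mm, rec$theta_deg,
                                             rec$phi_deg))
  nnsig <- cpp_knn(X, X, 2L)
  j1 <- as.integer(nnsig$index[, 2])
  d_sig <- nnsig$dist[, 2]
  cp_dist <- sqrt(rowSums((cp - cp[j1, , drop = FALSE])^2))
  # typical spacing from the strictly positive neighbour distances, so that
  # exact signal duplicates (a fully degenerate mapping) still register
  pos <- d_sig[d_sig > 1e-12]
  scale_sig <- if (length(pos)) median(pos) else 0
  hits <- which(cp_dist > thresholds$eps_cp_mm &
                d_sig <= thresholds$eps_sig_factor * scale_sig)
  ov <- list(count = length(hits),
             i = hits, j = j1[hits])
  net_solved <- sum(votes) > length(votes) / 2
  verdict <- if (!any(fitted) || length(votes) == 0) "inconclusive"
             else if (net_solved && ov$count == 0) "unique"
             else "not-unique"
  structure(list(triplet = spec, condition = condition, verdict = verdict,
                 n_records = nrow(rec),
                 err_r_mm = err_med[1], err_theta_deg = err_med[2],
                 err_phi_deg = err_med[3],
                 net_votes = votes, net_solved = net_solved,
                 overlap_count = ov$count,
                 overlap_pairs = if (length(ov$i)) head(cbind(ov$i, ov$j), 20)
                                 else NULL,
                 thresholds = thresholds, seeds = seeds,
                 architecture = "nnet single hidden layer, 32 units"),
            class = "uniqueness_report")
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf("triplet (%s) [%s]: %s\n", paste(x$triplet, collapse = ", "),
              x$condition, x$verdict))
  cat(sprintf("  held-out median errors: r %.3f mm, theta %.3f deg, phi %.3f deg\n",
              x$err_r_mm, x$err_theta_deg, x$err_phi_deg))
  cat(sprintf("  net votes: %d/%d; overlap pairs: %g (n = %d records)\n",
              sum(x$net_votes), length(x$net_votes), x$overlap_count,
              x$n_records))
  invisible(x)
}

#' Run the uniqueness census over all 20 triplets
#'
#' @param table a `mapping_table`.
#' @param condition region condition. Default "All".
#' @param thresholds [uniqueness_thresholds()].
#' @param seeds replicate fit seeds.
#' @param min_records minimum retained records per test.
#' @param progress print one line per triplet.
#' @return list with `reports` (20 `uniqueness_report`s) and `unique`
#'   (character vector, e.g. "Fx+MB+MD", of triplets judged unique).
#' @export
uniqueness_census <- function(table, condition = "All",
                              thresholds = uniqueness_thresholds(),
                              seeds = 1:3, min_records = 1000,
                              progress = FALSE) {
  specs <- enumerate_triplets()
  reports <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    reports[[i]] <- test_uniqueness(table, specs[[i]], condition,
                                    thresholds, seeds, min_records)
    if (progress) print(reports[[i]])
  }
  uniq <- vapply(reports[vapply(reports, function(r)
    r$verdict == "unique", logical(1))],
    function(r) paste(r$triplet, collapse = "+"), character(1))
  list(reports = reports, unique = uniq, condition = condition)
}
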