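#' Assign focus positions to equal-size intervals
#'
#' The chromosome is normalised to unit length and divided into
#' `n_intervals` equal intervals; each focus maps to the half-open bin
#' `[k/n, (k+1)/n)` containing its normalised coordinate, with the top
#' edge closed so a focus at exactly the chromosome end falls in the last
#' interval.
#'
#' @param positions numeric focus positions (um from the marked end).
#' @param axis_length chromosome axis length (um), > 0.
#' @param n_intervals number of intervals (>= 2; the reference protocol
#'   uses 30, roughly 0.1 um per interval on budding-yeast chromosome XV).
#' @return Integer vector of 1-based interval indices, same length as
#'   `positions`.
#' @export
assign_foci_to_intervals <- function(positions, axis_length, n_intervals = 30) {
  stopifnot(length(axis_length) == 1, axis_length > 0, n_intervals >= 2)
  n_intervals <- as.integer(n_intervals)
  if (length(positions) == 0) return(integer(0))
  bad <- which(positions < 0 | positions > axis_length)
  if (length(bad))
    stop(sprintf("focus position %g outside [0, %g] (entry %d)",
                 positions[bad[1]], axis_length, bad[1]))
  idx <- floor(positions / axis_length * n_intervals) + 1L
  idx[idx > n_intervals] <- n_intervals  # position == axis_length
  as.integer(idx)
}

# Presence matrix: chromosomes x intervals, TRUE where the chromosome has
# >= 1 focus in the interval. All CoC quantities derive from it.
presence_matrix <- function(chroms, n_intervals = 30) {
  stopifnot(inherits(chroms, "focus_data"), nrow(chroms) >= 1)
  n_intervals <- as.integer(n_intervals)
  M <- matrix(FALSE, nrow = nrow(chroms), ncol = n_intervals)
  for (i in seq_len(nrow(chroms))) {
    idx <- assign_foci_to_intervals(chroms$foci[[i]],
                                    chroms$axis_length_um[i], n_intervals)
    M[i, unique(idx)] <- TRUE
  }
  M
}

#' Per-interval crossover frequencies
#'
#' Frequency of chromosomes bearing at least one focus in each interval
#' (presence, not focus count: two foci in one interval count once).
#'
#' @param chroms a `focus_data` object.
#' @param n_intervals number of equal-size intervals.
#' @return List with `freq` (length-`n_intervals` numeric),
#'   `n_chromosomes`, and `n_intervals`.
#' @export
interval_profile <- function(chroms, n_intervals = 30) {
  M <- presence_matrix(chroms, n_intervals)
  list(freq = colMeans(M), n_chromosomes = nrow(M),
       n_intervals = as.integer(n_intervals))
}

#' Observed and predicted double-crossover frequencies for interval pairs
#'
#' For every unordered interval pair (i < j): the observed double-CO
#' frequency is the fraction of chromosomes with foci in both intervals;
#' the predicted frequency under independence is the product of the two
#' single-interval frequencies; their ratio is the coefficient of
#' coincidence, CoC = Obs DCO / Pred DCO. Pairs whose predicted frequency
#' is zero have undefined CoC (`NA`, `defined = FALSE`) and are excluded
#' from curve averaging. The inter-interval distance is between interval
#' midpoints, in normalised axis units.
#'
#' @inheritParams interval_profile
#' @return Data frame with one row per pair: `interval_i`, `interval_j`,
#'   `obs_dco`, `pred_dco`, `coc`, `defined`, `distance`.
#' @export
coc_pairs <- function(chroms, n_intervals = 30) {
  M <- presence_matrix(chroms, n_intervals)
  n <- nrow(M)
  freq <- colMeans(M)
  both <- crossprod(M) / n            # obs DCO for every pair
  ut <- which(upper.tri(both), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  i <- ut[, 1]; j <- ut[, 2]
  obs <- both[ut]
  pred <- freq[i] * freq[j]
  coc <- ifelse(pred > 0, obs / pred, NA_real_)
  data.frame(
    interval_i = as.integer(i), interval_j = as.integer(j),
    obs_dco = obs, pred_dco = pred, coc = coc, defined = pred > 0,
    distance = (j - i) / ncol(M)
  )
}

#' Coefficient-of-coincidence curve
#'
#' Averages defined CoC values over interval pairs sharing the same
#' inter-interval distance (distances are exact multiples of
#' 1/n_intervals, so grouping is exact). With an `experiment` column on
#' the input, one curve is computed per experiment and averaged, with the
#' standard error across experiments; otherwise a single pooled curve is
#' returned. Under no interference the curve fluctuates around 1; under
#' interference it is near 0 at short distances and rises toward 1.
#'
#' @param chroms a `focus_data` object (optionally with an `experiment`
#'   column).
#' @param n_intervals number of equal-size intervals.
#' @param by_experiment average replicate curves when an `experiment`
#'   column is present (default `TRUE`).
#' @return A `coc_curve` object: data frame `distance`, `mean_coc`, `se`,
#'   `n_pairs` (and `n_experiments` when replicates were averaged), plus
#'   attributes recording interval count and excluded (undefined) pairs.
#' @export
coc_curve <- function(chroms, n_intervals = 30, by_experiment = TRUE) {
  stopifnot(inherits(chroms, "focus_data"))
  groups <- if (by_experiment && "experiment" %in% names(chroms))
    split(seq_len(nrow(chroms)), chroms$experiment) else
    list(seq_len(nrow(chroms)))
  per <- lapply(groups, function(rows) {
    pr <- coc_pairs(chroms[rows, , drop = FALSE], n_intervals)
    pr <- pr[pr$defined, , drop = FALSE]
    if (!nrow(pr)) return(NULL)
    agg <- stats::aggregate(coc ~ distance, pr, mean)
    cnt <- stats::aggregate(coc ~ distance, pr, length)
    data.frame(distance = agg$distance, coc = agg$coc, n_pairs = cnt$coc)
  })
  per <- Filter(Negate(is.null), per)
  if (!length(per)) stop("coc_curve: no defined interval pairs")
  n_undef <- {
    pr_all <- coc_pairs(chroms, n_intervals)
    sum(!pr_all$defined)
  }
  if (length(per) == 1) {
    cur <- per[[1]]
    out <- data.frame(distance = cur$distance, mean_coc = cur$coc,
                      se = NA_real_, n_pairs = cur$n_pairs)
  } else {
    dist <- sort(unique(unlist(lapply(per, `[[`, "distance"))))
    vals <- sapply(per, function(cur)
      cur$coc[match(dist, cur$distance)])       # matrix dist x experiment
    npair <- sapply(per, function(cur)
      cur$n_pairs[match(dist, cur$distance)])
    out <- data.frame(
      distance = dist,
      mean_coc = rowMeans(vals, na.rm = TRUE),
      se = apply(vals, 1, function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
      }),
      n_pairs = rowSums(npair, na.rm = TRUE)
    )
    out$n_experiments <- rowSums(!is.na(vals))
  }
  attr(out, "n_intervals") <- as.integer(n_intervals)
  attr(out, "n_undefined_pairs") <- n_undef
  class(out) <- c("coc_curve", "data.frame")
  out
}

#' @export
print.coc_curve <- function(x, ...) {
  cat(sprintf("CoC curve: %d distances, %d intervals, %d undefined pair(s) excluded\n",
              nrow(x), attr(x, "n_intervals"), attr(x, "n_undefined_pairs")))
  cat(sprintf("  CoC at smallest distance (%.3f): %.3f\n",
              x$distance[1], x$mean_coc[1]))
  cat(sprintf("  grand mean CoC: %.3f\n",
              stats::weighted.mean(x$mean_coc, x$n_pairs)))
  invisible(x)
}

#' Plot a CoC curve
#'
#' @param x a `coc_curve` object.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.coc_curve <- function(x, ...) {
  graphics::plot(x$distance, x$mean_coc, type = "b", pch = 16,
                 xlab = "inter-interval distance (fraction of axis)",
                 ylab = "coefficient of coincidence", ...)
  if (any(!is.na(x$se)))
    graphics::arrows(x$distance, x$mean_coc - x$se,
                     x$distance, x$mean_coc + x$se,
                     angle = 90, code = 3, length = 0.02)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a CoC curve as TSV
#'
#' Columns `distance mean_coc se n_pairs`.
#'
#' @param curve a `coc_curve` object.
#' @param path output path.
#' @export
write_coc_curve <- function(curve, path) {
  utils::write.table(
    as.data.frame(curve)[, c("distance", "mean_coc", "se", "n_pairs")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
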