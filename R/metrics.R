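#' Per-nucleus focus and axis-length summaries
#'
#' Sums focus counts and axis lengths over the chromosomes of each
#' nucleus; the focus density is foci per micrometre of axis. Nuclei
#' containing at least one chromosome with no focus are flagged — on a
#' per-homolog-pair basis these are failures of the obligatory crossover.
#'
#' @param chroms a `focus_data` object.
#' @return Data frame with one row per nucleus: `strain`, `nucleus_id`,
#'   `n_chromosomes`, `total_axis_um`, `total_foci`, `foci_per_um`,
#'   `has_focusless_chromosome`.
#' @export
summarize_nuclei <- function(chroms) {
  stopifnot(inherits(chroms, "focus_data"), nrow(chroms) >= 1)
  key <- paste(chroms$strain, chroms$nucleus_id, chroms$chromosome_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (nucleus_id, chromosome_id) record: ",
         gsub("\r", "/", d, fixed = TRUE))
  }
  nk <- paste(chroms$strain, chroms$nucleus_id, sep = "\r")
  idx <- split(seq_len(nrow(chroms)), factor(nk, levels = unique(nk)))
  rows <- lapply(idx, function(i) {
    counts <- lengths(chroms$foci[i])
    axis <- sum(chroms$axis_length_um[i])
    data.frame(
      strain = chroms$strain[i[1]],
      nucleus_id = chroms$nucleus_id[i[1]],
      n_chromosomes = length(i),
      total_axis_um = axis,
      total_foci = sum(counts),
      foci_per_um = sum(counts) / axis,
      has_focusless_chromosome = any(counts == 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zero-focus (obligatory-crossover failure) frequencies
#'
#' @param chroms a `focus_data` object.
#' @return List with `per_chromosome` (fraction of chromosomes carrying
#'   no focus) and `per_nucleus` (fraction of nuclei with at least one
#'   such chromosome).
#' @export
zero_focus_frequencies <- function(chroms) {
  nuc <- summarize_nuclei(chroms)
  list(per_chromosome = mean(lengths(chroms$foci) == 0),
       per_nucleus = mean(nuc$has_focusless_chromosome))
}

#' Multiplicative independence expectation for a double mutant
#'
#' If two factors reduce a quantity to fractions `frac_a` and `frac_b` of
#' the wild-type level independently, the double mutant is expected at
#' their product. E.g. axis lengths at 0.82 and 0.58 of wild type predict
#' 0.4756 (about 48\%) in the double mutant.
#'
#' @param frac_a,frac_b single-mutant levels as fractions of wild type,
#'   in `[0, 1]`.
#' @return `frac_a * frac_b`.
#' @export
expected_under_independence <- function(frac_a, frac_b) {
  if (any(!is.finite(c(frac_a, frac_b))) ||
      any(c(frac_a, frac_b) < 0) || any(c(frac_a, frac_b) > 1))
    stop("fractions must lie in [0, 1]")
  frac_a * frac_b
}

#' Conditional fraction of two percentages
#'
#' E.g. 26\% of cells sporulate while 75\% complete both meiotic
#' divisions: among division-competent cells, 26/75 = 34.7\% sporulate.
#'
#' @param numerator_pct,denominator_pct percentages; denominator > 0.
#' @return The ratio as a percentage.
#' @export
conditional_fraction <- function(numerator_pct, denominator_pct) {
  if (!is.finite(denominator_pct) || denominator_pct <= 0)
    stop("denominator percentage must be > 0")
  100 * numerator_pct / denominator_pct
}

#' Overlap percentage from counts
#'
#' @param n_overlapping,n_total counts with
#'   `0 <= n_overlapping <= n_total`, `n_total > 0`.
#' @param digits decimals for display rounding (default 2, matching
#'   focus-overlap reporting conventions); the unrounded value is
#'   returned as attribute `exact`.
#' @return Percentage rounded to `digits`.
#' @export
overlap_fraction <- function(n_overlapping, n_total, digits = 2) {
  if (n_total <= 0 || n_overlapping < 0 || n_overlapping > n_total)
    stop("need 0 <= n_overlapping <= n_total with n_total > 0")
  exact <- 100 * n_overlapping / n_total
  structure(round(exact, digits), exact = exact)
}

#' Score tetrad fluorescence patterns for chromosome missegregation
#'
#' A tetrad with exactly two yellow and two red spores reflects faithful
#' segregation of the marked chromosome; any other pattern containing at
#' least one fluorescent spore scores as missegregated. Tetrads with no
#' fluorescent spore are excluded from the denominator.
#'
#' @param tetrads data frame with columns `tetrad_id`, `c1`..`c4`, values
#'   `Y`, `R` or `N` (case-insensitive).
#' @return List with `frequency`, `n_missegregated`, `n_scored`,
#'   `n_excluded`.
#' @export
missegregation_frequency <- function(tetrads) {
  stopifnot(is.data.frame(tetrads), nrow(tetrads) >= 1)
  cols <- c("c1", "c2", "c3", "c4")
  miss <- setdiff(cols, names(tetrads))
  if (length(miss))
    stop("tetrad table: missing column(s): ", paste(miss, collapse = ", "))
  m <- toupper(as.matrix(tetrads[, cols]))
  bad <- !(m %in% c("Y", "R", "N"))
  if (any(bad))
    stop("tetrad table: invalid colour value '",
         m[which(bad)[1]], "' (expected Y, R or N)")
  ny <- rowSums(m == "Y"); nr <- rowSums(m == "R")
  dark <- ny + nr == 0
  normal <- ny == 2 & nr == 2
  scored <- !dark
  if (!any(scored))
    stop("no scoreable tetrads: every tetrad lacks fluorescent spores")
  n_mis <- sum(scored & !normal)
  list(frequency = n_mis / sum(scored), n_missegregated = n_mis,
       n_scored = sum(scored), n_excluded = sum(dark))
}

signif_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "n.s."
}

strain_comparison <- function(test, estimate_a, estimate_b, n_a, n_b,
                              statistic, df = NA_real_, p_value,
                              sd_a = NA_real_, sd_b = NA_real_,
                              note = NULL) {
  out <- list(test = test, estimate_a = estimate_a, estimate_b = estimate_b,
              sd_a = sd_a, sd_b = sd_b, n_a = n_a, n_b = n_b,
              ratio_b_over_a = if (is.finite(estimate_a) && estimate_a != 0)
                estimate_b / estimate_a else NA_real_,
              statistic = statistic, df = df, p_value = p_value,
              stars = signif_stars(p_value), note = note)
  class(out) <- "strain_comparison"
  out
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("%s\n", x$test))
  cat(sprintf("  A: %.4g (n = %d)   B: %.4g (n = %d)   B/A = %.3f\n",
              x$estimate_a, x$n_a, x$estimate_b, x$n_b, x$ratio_b_over_a))
  stat_lab <- if (is.finite(x$df))
    sprintf("statistic = %.3f, df = %.1f", x$statistic, x$df) else
    sprintf("statistic = %.3f", x$statistic)
  cat(sprintf("  %s, p = %.4g (%s)\n", stat_lab, x$p_value, x$stars))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Two-proportion z-test
#'
#' Pooled-variance z statistic for the difference of two proportions with
#' a two-sided normal p-value — the standard test for comparing event
#' frequencies (e.g. missegregation rates) between strains.
#'
#' @param x1,n1 successes and trials for sample A.
#' @param x2,n2 successes and trials for sample B.
#' @return A `strain_comparison` object.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    return(strain_comparison("two-proportion z-test (pooled)",
                             p1, p2, n1, n2, NA_real_, p_value = NA_real_,
                             note = "degenerate pooled proportion; statistic undefined"))
  }
  z <- (p2 - p1) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  p <- 2 * stats::pnorm(-abs(z))
  strain_comparison("two-proportion z-test (pooled)", p1, p2, n1, n2, z,
                    p_value = p)
}

#' t-test of strain means
#'
#' Welch's unequal-variance t-test by default (set `pooled = TRUE` for
#' the classical equal-variance form), two-sided — for comparing mean
#' event counts (focus numbers, axis lengths) between strains.
#'
#' @param samples_a,samples_b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (classical Student) form.
#' @return A `strain_comparison` object.
#' @export
welch_t <- function(samples_a, samples_b, pooled = FALSE) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each sample needs at least two observations")
  if (stats::sd(samples_a) == 0 && stats::sd(samples_b) == 0) {
    eq <- isTRUE(all.equal(mean(samples_a), mean(samples_b)))
    return(strain_comparison(
      "t-test of means", mean(samples_a), mean(samples_b),
      length(samples_a), length(samples_b),
      statistic = if (eq) 0 else Inf,
      p_value = if (eq) 1 else 0,
      sd_a = 0, sd_b = 0,
      note = "zero variance in both samples"))
  }
  tt <- stats::t.test(samples_a, samples_b, var.equal = pooled)
  strain_comparison(
    if (pooled) "Student t-test of means (pooled variance)"
    else "Welch t-test of means",
    mean(samples_a), mean(samples_b),
    length(samples_a), length(samples_b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    sd_a = stats::sd(samples_a), sd_b = stats::sd(samples_b))
}

#' Per-strain summary table
#'
#' One row per strain: nucleus counts, focus-count and axis-length means
#' and SDs, pooled focus density and zero-focus frequencies. This is the
#' standard per-genotype readout of crossover-patterning phenotypes.
#'
#' @param chroms a `focus_data` object.
#' @return Data frame with columns `strain n_nuclei mean_foci sd_foci
#'   mean_axis_um sd_axis foci_per_um zero_focus_chrom_freq
#'   zero_focus_nucleus_freq`.
#' @export
strain_summary <- function(chroms) {
  stopifnot(inherits(chroms, "focus_data"))
  rows <- lapply(split(seq_len(nrow(chroms)), chroms$strain), function(i) {
    sub <- chroms[i, , drop = FALSE]
    class(sub) <- c("focus_data", "data.frame")
    nuc <- summarize_nuclei(sub)
    zf <- zero_focus_frequencies(sub)
    data.frame(
      strain = sub$strain[1],
      n_nuclei = nrow(nuc),
      mean_foci = mean(nuc$total_foci),
      sd_foci = stats::sd(nuc$total_foci),
      mean_axis_um = mean(nuc$total_axis_um),
      sd_axis = stats::sd(nuc$total_axis_um),
      foci_per_um = sum(nuc$total_foci) / sum(nuc$total_axis_um),
      zero_focus_chrom_freq = zf$per_chromosome,
      zero_focus_nucleus_freq = zf$per_nucleus,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a tetrad colour table
#'
#' TSV with header `tetrad_id c1 c2 c3 c4` and values `Y`/`R`/`N`.
#'
#' @param path file path.
#' @return Data frame of tetrad patterns.
#' @export
read_tetrad_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("tetrad_id", "c1", "c2", "c3", "c4")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("tetrad table ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_tetrad_table
#' @param tetrads data frame of tetrad patterns.
#' @export
write_tetrad_table <- function(tetrads, path) {
  utils::write.table(tetrads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
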