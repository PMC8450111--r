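# Small in-code fixtures shared across test files.

# One chromosome with given length and foci, minimal labels.
chrom1 <- function(axis, foci, nucleus = "n1", chrom = "c1", strain = "s") {
  focus_chromosome(strain, nucleus, chrom, axis, foci)
}

# Bind per-chromosome records into one focus_data object.
bind_chroms <- function(...) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, function(p) {
    p$foci <- NULL
    as.data.frame(p)
  }))
  focus_data(df, unlist(lapply(parts, `[[`, "foci"), recursive = FALSE))
}

# The four-chromosome enumeration example: foci in intervals {2,6}, {2},
# {6}, {} of a 30-interval chromosome of length 3 (1-based indices).
four_chrom_example <- function() {
  bind_chroms(
    chrom1(3, c(0.15, 0.55), nucleus = "n1"),   # intervals 2 and 6
    chrom1(3, 0.15, nucleus = "n2"),            # interval 2
    chrom1(3, 0.55, nucleus = "n3"),            # interval 6
    chrom1(3, numeric(0), nucleus = "n4")       # none
  )
}

# Independent brute-force CoC enumeration: loops over chromosomes and
# interval pairs directly, no shared code with coc_pairs().
brute_force_coc <- function(chroms, n_intervals) {
  n <- nrow(chroms)
  in_interval <- function(i, k) {
    p <- chroms$foci[[i]]
    L <- chroms$axis_length_um[i]
    if (!length(p)) return(FALSE)
    idx <- floor(p / L * n_intervals) + 1
    idx[idx > n_intervals] <- n_intervals
    k %in% idx
  }
  rows <- list()
  for (a in seq_len(n_intervals - 1)) for (b in (a + 1):n_intervals) {
    obs <- 0; fa <- 0; fb <- 0
    for (i in seq_len(n)) {
      ina <- in_interval(i, a); inb <- in_interval(i, b)
      fa <- fa + ina; fb <- fb + inb
      obs <- obs + (ina && inb)
    }
    pred <- (fa / n) * (fb / n)
    rows[[length(rows) + 1]] <- data.frame(
      interval_i = a, interval_j = b, obs_dco = obs / n, pred_dco = pred,
      coc = if (pred > 0) (obs / n) / pred else NA_real_,
      defined = pred > 0, distance = (b - a) / n_intervals)
  }
  do.call(rbind, rows)
}

# Random small dataset for oracle-equivalence sweeps.
random_small_dataset <- function(n_chrom, max_foci = 4) {
  parts <- lapply(seq_len(n_chrom), function(i) {
    L <- stats::runif(1, 1, 4)
    k <- sample(0:max_foci, 1)
    chrom1(L, sort(stats::runif(k, 0, L)), nucleus = paste0("n", i))
  })
  do.call(bind_chroms, parts)
}
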