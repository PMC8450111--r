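test_that("nucleus summaries sum counts and lengths exactly", {
  d <- bind_chroms(chrom1(2, c(0.5, 1.0, 1.5), nucleus = "n1", chrom = "c1"),
                   chrom1(1, numeric(0), nucleus = "n1", chrom = "c2"),
                   chrom1(3, 0.2, nucleus = "n2", chrom = "c1"))
  s <- summarize_nuclei(d)
  expect_equal(nrow(s), 2)
  n1 <- s[s$nucleus_id == "n1", ]
  expect_equal(n1$total_foci, 3)
  expect_equal(n1$total_axis_um, 3)
  expect_equal(n1$foci_per_um, 1.0)
  expect_true(n1$has_focusless_chromosome)
  expect_false(s$has_focusless_chromosome[s$nucleus_id == "n2"])
  # totals conserve the input focus count
  expect_equal(sum(s$total_foci), sum(lengths(d$foci)))
})

test_that("duplicate chromosome records are a data error", {
  d <- bind_chroms(chrom1(2, 0.5, nucleus = "n1", chrom = "c1"),
                   chrom1(2, 1.5, nucleus = "n1", chrom = "c1"))
  expect_error(summarize_nuclei(d), "duplicate")
})

test_that("densities are invariant under proportional rescaling", {
  d <- bind_chroms(chrom1(2, c(0.5, 1.5), nucleus = "n1"),
                   chrom1(4, 1, nucleus = "n2"))
  scaled <- focus_data(
    transform(as.data.frame(d)[names(d) != "foci"],
              axis_length_um = axis_length_um * 2),
    lapply(d$foci, `*`, 2))
  expect_equal(summarize_nuclei(scaled)$total_foci,
               summarize_nuclei(d)$total_foci)
  expect_equal(summarize_nuclei(scaled)$foci_per_um,
               summarize_nuclei(d)$foci_per_um / 2)
})

test_that("zero-focus frequencies count chromosomes and nuclei", {
  d <- bind_chroms(chrom1(2, 0.5, nucleus = "n1", chrom = "c1"),
                   chrom1(2, numeric(0), nucleus = "n1", chrom = "c2"))
  zf <- zero_focus_frequencies(d)
  expect_equal(zf$per_chromosome, 0.5)
  expect_equal(zf$per_nucleus, 1.0)
  full <- bind_chroms(chrom1(2, 0.5, nucleus = "n1"),
                      chrom1(2, 0.7, nucleus = "n2"))
  expect_equal(unlist(zero_focus_frequencies(full)),
               c(per_chromosome = 0, per_nucleus = 0))
})

test_that("Poisson simulation reproduces the analytic zero class", {
  n <- 10000
  sim <- simulate_focus_dataset(
    simulation_config(shape = 1, mean_spacing = 1, axis_length_mean = 3,
                      axis_length_cv = 0, n_nuclei = n, seed = 31))
  zf <- zero_focus_frequencies(sim)
  p0 <- exp(-3)
  expect_lt(abs(zf$per_chromosome - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("independence expectation is the product of fractions", {
  expect_equal(expected_under_independence(0.82, 0.58), 0.4756)
  expect_equal(round(100 * expected_under_independence(0.82, 0.58)), 48)
  expect_equal(expected_under_independence(0.90, 0.57), 0.513)
  expect_equal(round(100 * expected_under_independence(0.90, 0.57)), 51)
  expect_equal(expected_under_independence(1, 0.3), 0.3)
  # commutative and bounded by each argument
  set.seed(3)
  a <- runif(20); b <- runif(20)
  expect_equal(expected_under_independence(a, b),
               expected_under_independence(b, a))
  expect_true(all(expected_under_independence(a, b) <= pmin(a, b)))
  expect_error(expected_under_independence(1.2, 0.5), "\\[0, 1\\]")
})

test_that("conditional fraction reproduces the sporulation arithmetic", {
  expect_equal(conditional_fraction(26, 75), 2600 / 75)
  expect_equal(round(conditional_fraction(26, 75)), 35)
  expect_equal(conditional_fraction(40, 40), 100)
  expect_equal(conditional_fraction(0, 60), 0)
  expect_error(conditional_fraction(10, 0), "> 0")
})

test_that("overlap fraction reports exact percentages", {
  expect_equal(as.numeric(overlap_fraction(112, 3281)), 3.41)
  expect_equal(as.numeric(overlap_fraction(4948, 5100)), 97.02)
  expect_equal(as.numeric(overlap_fraction(0, 50)), 0)
  expect_equal(attr(overlap_fraction(1, 3), "exact"), 100 / 3)
  expect_error(overlap_fraction(5, 4), "n_total")
  expect_error(overlap_fraction(-1, 4), "n_total")
})

test_that("missegregation scoring classifies and excludes correctly", {
  tet <- function(pats) {
    out <- data.frame(tetrad_id = as.character(seq_along(pats)),
                      do.call(rbind, pats), stringsAsFactors = FALSE)
    setNames(out, c("tetrad_id", "c1", "c2", "c3", "c4"))
  }
  normal <- c("Y", "Y", "R", "R")
  mis <- c("Y", "R", "R", "R")
  dark <- c("N", "N", "N", "N")
  d <- tet(c(rep(list(normal), 99), list(mis)))
  res <- missegregation_frequency(d)
  expect_equal(res$frequency, 0.01)
  expect_equal(res$n_scored, 100)
  expect_equal(res$n_excluded, 0)
  # dark tetrads are excluded from the denominator entirely
  with_dark <- tet(c(rep(list(normal), 99), list(mis), rep(list(dark), 40)))
  res2 <- missegregation_frequency(with_dark)
  expect_equal(res2$frequency, 0.01)
  expect_equal(res2$n_excluded, 40)
  # partially fluorescent aberrant patterns score as missegregated
  res3 <- missegregation_frequency(tet(list(normal, c("Y", "N", "N", "N"))))
  expect_equal(res3$frequency, 0.5)
  expect_error(missegregation_frequency(tet(list(dark, dark))), "scoreable")
  expect_error(missegregation_frequency(tet(list(c("Y", "Y", "R", "B")))),
               "invalid colour")
})

test_that("missegregation classifier recovers a simulated rate", {
  tet <- simulate_tetrads(10000, missegregation_rate = 0.05,
                          blank_rate = 0.1, seed = 12)
  res <- missegregation_frequency(tet)
  se <- sqrt(0.05 * 0.95 / res$n_scored)
  expect_lt(abs(res$frequency - 0.05), 3 * se)
  expect_equal(res$n_scored + res$n_excluded, 10000)
})

test_that("two-proportion z matches the chi-square cross-check", {
  eq <- two_proportion_z(10, 100, 20, 200)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  cmp <- two_proportion_z(15, 815, 39, 777)
  ref <- prop.test(c(15, 39), c(815, 777), correct = FALSE)
  expect_equal(cmp$statistic^2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
  # tiny samples: finite output, no crash
  tiny <- two_proportion_z(0, 1, 1, 1)
  expect_true(is.finite(tiny$p_value))
  expect_gt(tiny$p_value, 0.05)
  # degenerate pooled proportion is flagged, not computed
  deg <- two_proportion_z(0, 10, 0, 12)
  expect_true(is.na(deg$statistic))
  expect_match(deg$note, "degenerate")
})

test_that("t-test of means handles the standard and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  ident <- welch_t(x, x)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  # manual Welch formula oracle
  a <- c(3.1, 2.8, 3.6, 3.0); b <- c(4.0, 4.4, 3.9, 4.6, 4.2)
  got <- welch_t(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 5)
  t_manual <- (mean(b) - mean(a)) / se
  expect_equal(abs(got$statistic), abs(t_manual), tolerance = 1e-12)
  # strongly shifted samples are overwhelmingly significant
  set.seed(2)
  g1 <- rnorm(200); g2 <- rnorm(200, mean = 1)
  expect_lt(welch_t(g1, g2)$p_value, 1e-10)
  # pooled option reproduces classical Student
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(welch_t(a, b, pooled = TRUE)$p_value, ref$p.value)
  expect_error(welch_t(1, x), "at least two")
  flat <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  expect_match(flat$note, "zero variance")
})

test_that("significance stars follow the standard thresholds", {
  expect_equal(meicoc:::signif_stars(0.2), "n.s.")
  expect_equal(meicoc:::signif_stars(0.05), "n.s.")
  expect_equal(meicoc:::signif_stars(0.049), "*")
  expect_equal(meicoc:::signif_stars(0.009), "**")
  expect_equal(meicoc:::signif_stars(0.0009), "***")
})

test_that("strain summary aggregates per strain", {
  d <- bind_chroms(chrom1(2, c(0.5, 1), nucleus = "n1", strain = "wt"),
                   chrom1(2, 0.5, nucleus = "n2", strain = "wt"),
                   chrom1(3, numeric(0), nucleus = "n1", strain = "mut"))
  s <- strain_summary(d)
  expect_equal(sort(s$strain), c("mut", "wt"))
  wt <- s[s$strain == "wt", ]
  expect_equal(wt$n_nuclei, 2)
  expect_equal(wt$mean_foci, 1.5)
  expect_equal(wt$foci_per_um, 3 / 4)
  mut <- s[s$strain == "mut", ]
  expect_equal(mut$zero_focus_chrom_freq, 1)
  expect_equal(mut$zero_focus_nucleus_freq, 1)
})
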