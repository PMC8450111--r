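test_that("interval assignment uses half-open bins with closed top edge", {
  # boundary: position 0 -> first interval; position L -> last interval
  expect_equal(assign_foci_to_intervals(0, 3, 30), 1L)
  expect_equal(assign_foci_to_intervals(3, 3, 30), 30L)
  # mid-axis: normalised 0.5 of a 30-interval axis starts interval 16
  expect_equal(assign_foci_to_intervals(1, 2, 30), 16L)
  expect_equal(assign_foci_to_intervals(numeric(0), 3, 30), integer(0))
  expect_error(assign_foci_to_intervals(3.5, 3, 30), "outside")
  expect_error(assign_foci_to_intervals(-0.1, 3, 30), "outside")
})

test_that("interval assignment conserves the focus count", {
  set.seed(21)
  for (rep in 1:10) {
    d <- random_small_dataset(sample(1:10, 1))
    total <- sum(lengths(d$foci))
    assigned <- sum(vapply(seq_len(nrow(d)), function(i)
      length(assign_foci_to_intervals(d$foci[[i]], d$axis_length_um[i], 6)),
      integer(1)))
    expect_identical(assigned, total)
  }
})

test_that("interval profile counts presence, not focus multiplicity", {
  prof <- interval_profile(four_chrom_example(), 30)
  expect_equal(prof$freq[2], 0.5)
  expect_equal(prof$freq[6], 0.5)
  expect_equal(sum(prof$freq), 1.0)  # only intervals 2 and 6 occupied
  # two foci in the same interval count once
  two_in_one <- chrom1(3, c(0.31, 0.35))
  expect_equal(interval_profile(two_in_one, 30)$freq[4], 1.0)
  # all-empty chromosomes give all-zero frequencies
  empty <- chrom1(3, numeric(0))
  expect_true(all(interval_profile(empty, 30)$freq == 0))
})

test_that("coc_pairs reproduces the hand enumeration and guards division", {
  pairs <- coc_pairs(four_chrom_example(), 30)
  expect_equal(nrow(pairs), 30 * 29 / 2)
  p26 <- pairs[pairs$interval_i == 2 & pairs$interval_j == 6, ]
  expect_equal(p26$obs_dco, 0.25)
  expect_equal(p26$pred_dco, 0.25)
  expect_equal(p26$coc, 1.0)
  expect_equal(p26$distance, 4 / 30)
  # a pair with an unoccupied interval is flagged undefined
  p12 <- pairs[pairs$interval_i == 1 & pairs$interval_j == 2, ]
  expect_false(p12$defined)
  expect_true(is.na(p12$coc))
  # nonzero marginals but no joint occupancy: CoC = 0
  d <- bind_chroms(chrom1(1, 0.05, nucleus = "n1"),
                   chrom1(1, 0.95, nucleus = "n2"))
  pr <- coc_pairs(d, 2)
  expect_equal(pr$coc, 0)
  expect_true(pr$defined)
})

test_that("coc_pairs matches brute-force enumeration on small datasets", {
  set.seed(33)
  for (rep in 1:25) {
    d <- random_small_dataset(sample(2:10, 1))
    n_int <- sample(2:6, 1)
    got <- coc_pairs(d, n_int)
    want <- brute_force_coc(d, n_int)
    expect_equal(got$obs_dco, want$obs_dco)
    expect_equal(got$pred_dco, want$pred_dco)
    expect_equal(got$coc, want$coc)
    expect_equal(got$defined, want$defined)
    expect_equal(got$distance, want$distance)
  }
})

test_that("CoC is invariant under rescaling of all lengths", {
  set.seed(44)
  d <- random_small_dataset(8)
  scaled <- focus_data(
    transform(as.data.frame(d)[names(d) != "foci"],
              axis_length_um = axis_length_um * 7.3),
    lapply(d$foci, `*`, 7.3))
  expect_equal(coc_pairs(d, 6), coc_pairs(scaled, 6))
})

test_that("coc_curve averages by exact distance and handles single pairs", {
  d <- bind_chroms(chrom1(1, c(0.1, 0.9), nucleus = "n1"),
                   chrom1(1, 0.1, nucleus = "n2"))
  cur <- coc_curve(d, 2)   # one pair at distance 1/2
  expect_s3_class(cur, "coc_curve")
  expect_equal(nrow(cur), 1)
  expect_equal(cur$distance, 0.5)
  expect_equal(cur$n_pairs, 1L)
  pr <- coc_pairs(d, 2)
  expect_equal(cur$mean_coc, pr$coc[pr$defined])
  # all pairs undefined -> error
  expect_error(coc_curve(chrom1(3, numeric(0)), 4), "no defined")
})

test_that("replicate curves are averaged with a standard error", {
  set.seed(55)
  parts <- lapply(1:3, function(e) {
    sim <- simulate_focus_dataset(
      simulation_config(shape = 1, mean_spacing = 0.5, n_nuclei = 300,
                        axis_length_cv = 0, seed = 100 + e))
    sim$experiment <- paste0("exp", e)
    sim$nucleus_id <- paste0(e, "_", sim$nucleus_id)
    sim
  })
  all3 <- focus_data(do.call(rbind, lapply(parts, function(p) {
    p2 <- as.data.frame(p); p2$foci <- NULL; p2
  })), unlist(lapply(parts, `[[`, "foci"), recursive = FALSE))
  cur <- coc_curve(all3, 10, by_experiment = TRUE)
  expect_true(all(is.finite(cur$se)))
  expect_true(all(cur$n_experiments == 3))
  # pooled curve (ignoring experiments) has no SE
  pooled <- coc_curve(all3, 10, by_experiment = FALSE)
  expect_true(all(is.na(pooled$se)))
  # replicate mean at each distance equals the mean of per-replicate curves
  one <- coc_curve(parts[[1]], 10)
  expect_equal(nrow(one), nrow(cur))
})

test_that("no-interference simulations give CoC near one", {
  sim <- simulate_focus_dataset(
    simulation_config(shape = 1, mean_spacing = 0.5, axis_length_mean = 3,
                      axis_length_cv = 0.15, n_nuclei = 2000, seed = 17))
  cur <- coc_curve(sim, 30)
  grand <- weighted.mean(cur$mean_coc, cur$n_pairs)
  expect_lt(abs(grand - 1), 0.05)
})

test_that("strong interference suppresses CoC at short distances", {
  sim <- simulate_focus_dataset(
    simulation_config(shape = 10, mean_spacing = 0.9, axis_length_mean = 3,
                      axis_length_cv = 0.15, n_nuclei = 2000, seed = 18))
  cur <- coc_curve(sim, 30)
  expect_lt(cur$mean_coc[1], 0.1)
  far <- cur$mean_coc[cur$distance > 0.5 & cur$distance < 0.9]
  expect_gt(mean(far), 0.7)
})

test_that("short-distance CoC decreases with increasing interference", {
  short_coc <- vapply(c(1, 2, 5, 10), function(nu) {
    sim <- simulate_focus_dataset(
      simulation_config(shape = nu, mean_spacing = 0.9,
                        axis_length_mean = 3, axis_length_cv = 0,
                        n_nuclei = 2000, seed = 200 + nu))
    cur <- coc_curve(sim, 30)
    mean(cur$mean_coc[cur$distance <= 3 / 30])
  }, numeric(1))
  expect_true(all(diff(short_coc) < 0))
})
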