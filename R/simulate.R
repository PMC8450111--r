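#' Simulation configuration for focus datasets
#'
#' Parameters of the stationary gamma-renewal model used to generate
#' per-chromosome focus positions. The shape parameter `shape` (nu) is
#' the interference-strength scalar: nu = 1 gives a homogeneous Poisson
#' process (no interference); larger nu gives more evenly spaced foci
#' (stronger interference). `mean_spacing` (mu) is the mean inter-focus
#' distance in micrometres, so the expected focus count per chromosome is
#' axis length / mu regardless of nu (stationary renewal theorem).
#' Per-nucleus axis lengths are lognormal with the stated mean and
#' coefficient of variation.
#'
#' @param shape gamma shape nu > 0.
#' @param mean_spacing mean inter-focus distance mu > 0 (um).
#' @param axis_length_mean mean axis length (um).
#' @param axis_length_cv coefficient of variation of axis length (>= 0;
#'   0 gives a fixed length).
#' @param n_nuclei number of nuclei.
#' @param chromosomes_per_nucleus chromosomes scored per nucleus.
#' @param seed integer root seed; each nucleus draws from its own child
#'   stream derived from it, so a dataset is reproducible nucleus by
#'   nucleus.
#' @param strain strain label stamped on every record.
#' @param obligate_co if `TRUE`, chromosomes are redrawn until they carry
#'   at least one focus (default off: the zero-focus class is itself a
#'   quantity of interest).
#' @return A `simulation_config` object (validated list).
#' @export
simulation_config <- function(shape = 2, mean_spacing = 1.0,
                              axis_length_mean = 3.0, axis_length_cv = 0.15,
                              n_nuclei = 200, chromosomes_per_nucleus = 1,
                              seed = 1L, strain = "sim",
                              obligate_co = FALSE) {
  cfg <- list(shape = as.numeric(shape),
              mean_spacing = as.numeric(mean_spacing),
              axis_length_mean = as.numeric(axis_length_mean),
              axis_length_cv = as.numeric(axis_length_cv),
              n_nuclei = as.integer(n_nuclei),
              chromosomes_per_nucleus = as.integer(chromosomes_per_nucleus),
              seed = as.integer(seed), strain = as.character(strain),
              obligate_co = isTRUE(obligate_co))
  with(cfg, {
    if (!is.finite(shape) || shape <= 0) stop("config: shape must be > 0")
    if (!is.finite(mean_spacing) || mean_spacing <= 0)
      stop("config: mean_spacing must be > 0")
    if (!is.finite(axis_length_mean) || axis_length_mean <= 0)
      stop("config: axis_length_mean must be > 0")
    if (!is.finite(axis_length_cv) || axis_length_cv < 0)
      stop("config: axis_length_cv must be >= 0")
    if (n_nuclei < 1) stop("config: n_nuclei must be >= 1")
    if (chromosomes_per_nucleus < 1)
      stop("config: chromosomes_per_nucleus must be >= 1")
  })
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Gamma-renewal simulation config\n")
  cat(sprintf("  shape (nu) = %g, mean spacing (mu) = %g um\n",
              x$shape, x$mean_spacing))
  cat(sprintf("  axis length: lognormal mean %g um, CV %g\n",
              x$axis_length_mean, x$axis_length_cv))
  cat(sprintf("  %d nuclei x %d chromosome(s), seed %d, strain '%s'\n",
              x$n_nuclei, x$chromosomes_per_nucleus, x$seed, x$strain))
  invisible(x)
}

# Child-stream seed for nucleus i: deterministic function of the root seed,
# kept inside 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + 9973 * as.double(i)) %% 2147483647)
}

# Draw one chromosome's focus positions on [0, L] from the stationary
# gamma-renewal process: the first event comes from the equilibrium
# forward-recurrence distribution (sampled as U * length-biased gap, and
# the length-biased version of Gamma(nu, theta) is Gamma(nu + 1, theta)),
# subsequent gaps are i.i.d. Gamma(nu, theta) with theta = mu / nu.
renewal_positions <- function(L, shape, mean_spacing) {
  theta <- mean_spacing / shape
  pos <- stats::runif(1) * stats::rgamma(1, shape = shape + 1, scale = theta)
  if (pos > L) return(numeric(0))
  out <- pos
  batch <- max(8L, ceiling(L / mean_spacing + 6 * sqrt(L / mean_spacing / shape)))
  repeat {
    gaps <- stats::rgamma(batch, shape = shape, scale = theta)
    cand <- pos + cumsum(gaps)
    keep <- cand <= L
    out <- c(out, cand[keep])
    if (!all(keep)) return(out)
    pos <- cand[length(cand)]
  }
}

#' Simulate a focus dataset under a stationary gamma-renewal process
#'
#' For each nucleus, draws an axis length from a lognormal with the
#' configured mean and CV, then places foci along each chromosome by a
#' stationary gamma renewal with shape nu and mean spacing mu. Events past
#' the axis end are discarded; zero-focus chromosomes are retained.
#' Identical config (including seed) gives bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return A `focus_data` object with `config$n_nuclei *
#'   config$chromosomes_per_nucleus` rows.
#' @examples
#' cfg <- simulation_config(shape = 1, mean_spacing = 1, axis_length_mean = 3,
#'                          axis_length_cv = 0, n_nuclei = 50, seed = 7)
#' sim <- simulate_focus_dataset(cfg)
#' mean(lengths(sim$foci))  # close to 3 = L / mu
#' @export
simulate_focus_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cv <- config$axis_length_cv
  # lognormal parameterised by arithmetic mean and CV
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$axis_length_mean) - sdlog^2 / 2
  n_chrom <- config$n_nuclei * config$chromosomes_per_nucleus
  foci <- vector("list", n_chrom)
  axis <- numeric(n_chrom)
  row <- 0L
  for (i in seq_len(config$n_nuclei)) {
    set.seed(child_seed(config$seed, i))
    for (j in seq_len(config$chromosomes_per_nucleus)) {
      L <- if (cv > 0) stats::rlnorm(1, meanlog, sdlog) else config$axis_length_mean
      p <- renewal_positions(L, config$shape, config$mean_spacing)
      if (config$obligate_co) {
        tries <- 0L
        while (!length(p) && tries < 1000L) {
          p <- renewal_positions(L, config$shape, config$mean_spacing)
          tries <- tries + 1L
        }
      }
      row <- row + 1L
      axis[row] <- L
      foci[[row]] <- p
    }
  }
  nuc <- rep(seq_len(config$n_nuclei), each = config$chromosomes_per_nucleus)
  chrom <- rep(seq_len(config$chromosomes_per_nucleus), config$n_nuclei)
  focus_data(data.frame(
    strain = config$strain,
    nucleus_id = sprintf("n%04d", nuc),
    chromosome_id = sprintf("c%02d", chrom),
    axis_length_um = axis,
    stringsAsFactors = FALSE
  ), foci)
}

#' Simulate tetrad fluorescence patterns
#'
#' Emulates the spore-autonomous fluorescence assay: a tetrad with faithful
#' segregation of the marked chromosome shows two yellow and two red
#' spores; a missegregation event produces an aberrant colour multiset.
#' Independently, a tetrad may fail to express either fluorophore (all
#' spores dark), which the scoring step excludes.
#'
#' @param n number of tetrads.
#' @param missegregation_rate probability of an aberrant (non 2Y/2R)
#'   fluorescent pattern.
#' @param blank_rate probability that a tetrad is all-dark, applied
#'   independently.
#' @param seed integer seed.
#' @return Data frame `tetrad_id, c1, c2, c3, c4` with values `Y`/`R`/`N`.
#' @export
simulate_tetrads <- function(n, missegregation_rate = 0, blank_rate = 0,
                             seed = 1L) {
  stopifnot(n >= 0, missegregation_rate >= 0, missegregation_rate <= 1,
            blank_rate >= 0, blank_rate <= 1)
  n <- as.integer(n)
  cols <- c("c1", "c2", "c3", "c4")
  if (n == 0) {
    out <- data.frame(tetrad_id = character(0), c1 = character(0),
                      c2 = character(0), c3 = character(0), c4 = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  set.seed(as.integer(seed))
  # aberrant patterns: any fluorescent multiset other than 2Y/2R
  aberrant <- list(c("Y", "Y", "Y", "R"), c("Y", "R", "R", "R"),
                   c("Y", "Y", "Y", "Y"), c("R", "R", "R", "R"),
                   c("Y", "Y", "R", "N"), c("Y", "R", "R", "N"),
                   c("Y", "R", "N", "N"))
  mat <- matrix("N", nrow = n, ncol = 4)
  mis <- stats::runif(n) < missegregation_rate
  blank <- stats::runif(n) < blank_rate
  for (i in seq_len(n)) {
    if (blank[i]) next
    pat <- if (mis[i]) aberrant[[sample.int(length(aberrant), 1)]]
           else c("Y", "Y", "R", "R")
    mat[i, ] <- sample(pat)   # spore order is arbitrary
  }
  out <- data.frame(tetrad_id = sprintf("t%05d", seq_len(n)),
                    mat, stringsAsFactors = FALSE)
  names(out) <- c("tetrad_id", cols)
  out
}

#' Simulate a nucleus image with Gaussian spots
#'
#' Uniform background plus circular Gaussian-profile spots plus i.i.d.
#' Gaussian pixel noise, clipped at zero. The elliptical nucleus mask and
#' the exact integrated spot signal are returned so quantification can be
#' checked against ground truth.
#'
#' @param width,height raster size in pixels.
#' @param background uniform background level (counts/pixel).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param spots data frame (or NULL) with columns `x`, `y` (pixel centres,
#'   1-based), `amplitude`, `width` (Gaussian sigma in pixels).
#' @param seed integer seed.
#' @return List with `image` (height x width numeric matrix), `mask`
#'   (logical matrix, elliptical nucleus region), and `true_signal`
#'   (sum over pixels of the noise-free spot component).
#' @export
simulate_nucleus_image <- function(width, height, background = 100,
                                   noise_sd = 0, spots = NULL, seed = 1L) {
  stopifnot(width >= 1, height >= 1, background >= 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), width), nrow = height)
  signal <- matrix(0, nrow = height, ncol = width)
  if (!is.null(spots) && nrow(spots)) {
    if (any(spots$x < 1 | spots$x > width | spots$y < 1 | spots$y > height))
      stop("spot centre outside the raster")
    for (k in seq_len(nrow(spots))) {
      signal <- signal + spots$amplitude[k] *
        exp(-((xs - spots$x[k])^2 + (ys - spots$y[k])^2) /
              (2 * spots$width[k]^2))
    }
  }
  img <- background + signal
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(height * width, 0, noise_sd),
                        nrow = height)
  img <- pmax(img, 0)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  mask <- ((xs - cx) / (width / 2))^2 + ((ys - cy) / (height / 2))^2 <= 1
  list(image = img, mask = mask, true_signal = sum(signal))
}
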