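#' Sample an intensity line profile from an image
#'
#' Intensities along the segment from `(x1, y1)` to `(x2, y2)` (pixel
#' coordinates, 1-based), one sample per unit of arc length, by
#' nearest-pixel lookup (bilinear interpolation optional). In the
#' background-estimation procedure the segment is drawn perpendicular to
#' a chromosome fragment, long enough to reach flat background on both
#' sides.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param x1,y1,x2,y2 segment endpoints in pixel coordinates.
#' @param interpolate use bilinear interpolation instead of
#'   nearest-pixel lookup.
#' @return List with `positions` (offsets along the line, pixels) and
#'   `intensities`.
#' @export
sample_line_profile <- function(image, x1, y1, x2, y2, interpolate = FALSE) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len <= 0) stop("line endpoints coincide")
  n <- max(2L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- x1 + t * (x2 - x1); ys <- y1 + t * (y2 - y1)
  if (any(xs < 1 | xs > ncol(image) | ys < 1 | ys > nrow(image)))
    stop("line extends outside the image")
  if (interpolate) {
    x0 <- pmin(floor(xs), ncol(image) - 1L); y0 <- pmin(floor(ys), nrow(image) - 1L)
    fx <- xs - x0; fy <- ys - y0
    v <- (1 - fx) * (1 - fy) * image[cbind(y0, x0)] +
      fx * (1 - fy) * image[cbind(y0, x0 + 1)] +
      (1 - fx) * fy * image[cbind(y0 + 1, x0)] +
      fx * fy * image[cbind(y0 + 1, x0 + 1)]
  } else {
    v <- image[cbind(round(ys), round(xs))]
  }
  list(positions = t * len, intensities = as.numeric(v))
}

#' Background level from a perpendicular line profile
#'
#' A line drawn across a chromosome fragment shows a roughly bell-shaped
#' intensity bump over a flat floor. The background pixel intensity is
#' the level at which the profile flattens into horizontal tails. This is
#' operationalised as: lightly smooth the profile (moving average, window
#' 3), find the maximal outer runs on each side where the absolute
#' discrete slope stays below `slope_frac` of the profile's dynamic range
#' (peak minus minimum), require at least `min_tail` consecutive samples
#' per tail, and return the mean raw intensity over both tails.
#'
#' @param profile list with `positions` and `intensities` (>= 7 samples),
#'   as from [sample_line_profile()].
#' @param slope_frac flatness criterion as a fraction of dynamic range
#'   (default 0.02).
#' @param min_tail minimum consecutive flat samples per tail.
#' @return Background level (scalar).
#' @export
profile_background <- function(profile, slope_frac = 0.02, min_tail = 3L) {
  y <- profile$intensities
  if (length(y) < 7) stop("profile too short: need >= 7 samples")
  if (any(y < 0)) stop("negative intensity in profile")
  sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  sm[1] <- y[1]; sm[length(y)] <- y[length(y)]
  sm <- as.numeric(sm)
  rng <- max(sm) - min(sm)
  if (rng <= 1e-9 * max(abs(sm), 1)) return(mean(y))  # flat profile
  slope <- abs(diff(sm))
  flat <- slope < slope_frac * rng   # flat[i]: segment between i and i+1
  # maximal flat run anchored at each end
  left_run <- 0L
  while (left_run < length(flat) && flat[left_run + 1L]) left_run <- left_run + 1L
  right_run <- 0L
  while (right_run < length(flat) && flat[length(flat) - right_run]) right_run <- right_run + 1L
  if (left_run < min_tail || right_run < min_tail)
    stop("no flat tail found on ",
         if (left_run < min_tail && right_run < min_tail) "either side"
         else if (left_run < min_tail) "the start side" else "the end side",
         " of the profile; draw a longer perpendicular line")
  idx <- c(seq_len(left_run + 1L),
           seq(length(y) - right_run, length(y)))
  mean(y[unique(idx)])
}

#' Per-nucleus background from three line profiles
#'
#' The background fluorescence per pixel for a nucleus is the mean of the
#' background levels estimated from three perpendicular line profiles
#' across randomly chosen chromosome fragments.
#'
#' @param profiles list of exactly three profiles
#'   (see [sample_line_profile()]).
#' @param ... passed to [profile_background()].
#' @return Mean background level.
#' @export
nucleus_background <- function(profiles, ...) {
  if (length(profiles) != 3)
    stop("exactly three line profiles are required, got ", length(profiles))
  vals <- vapply(seq_along(profiles), function(i) {
    tryCatch(profile_background(profiles[[i]], ...),
             error = function(e) stop("profile ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  mean(vals)
}

#' Background-corrected integrated fluorescence intensity
#'
#' Within the nucleus mask, counts the pixels whose intensity is strictly
#' above the per-pixel background; the raw total is the sum of those
#' pixels' intensities and the corrected total subtracts background times
#' the pixel count:
#' corrected = raw_total - background_per_pixel * n_pixels_above.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape (the circled nucleus).
#' @param background_per_pixel background level (>= 0), e.g. from
#'   [nucleus_background()].
#' @return An `intensity_result` list: `background_per_pixel`,
#'   `n_pixels_above`, `raw_total`, `corrected_total`.
#' @export
integrated_intensity <- function(image, mask, background_per_pixel) {
  stopifnot(is.matrix(image), identical(dim(image), dim(mask)),
            background_per_pixel >= 0)
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty nucleus mask")
  v <- image[mask]
  above <- v > background_per_pixel
  raw <- sum(v[above])
  out <- list(background_per_pixel = background_per_pixel,
              n_pixels_above = sum(above),
              raw_total = raw,
              corrected_total = raw - background_per_pixel * sum(above))
  class(out) <- "intensity_result"
  out
}

#' @export
print.intensity_result <- function(x, ...) {
  cat(sprintf(
    "Integrated intensity: raw %.4g over %d pixels above background %.4g; corrected %.4g\n",
    x$raw_total, x$n_pixels_above, x$background_per_pixel,
    x$corrected_total))
  invisible(x)
}

#' Quantify a nucleus image end to end
#'
#' Samples the three user-supplied perpendicular lines, estimates the
#' per-nucleus background as their mean flattening level, and integrates
#' the background-corrected intensity over the mask.
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape.
#' @param lines data frame with columns `x1 y1 x2 y2`, exactly 3 rows.
#' @param slope_frac flatness criterion for [profile_background()].
#' @return An `intensity_result`.
#' @export
quantify_nucleus <- function(image, mask, lines, slope_frac = 0.02) {
  stopifnot(is.data.frame(lines), nrow(lines) == 3,
            all(c("x1", "y1", "x2", "y2") %in% names(lines)))
  profiles <- lapply(seq_len(3), function(i)
    sample_line_profile(image, lines$x1[i], lines$y1[i],
                        lines$x2[i], lines$y2[i]))
  bg <- nucleus_background(profiles, slope_frac = slope_frac)
  integrated_intensity(image, mask, bg)
}

#' Read / write single-channel 16-bit TIFF images
#'
#' Images are stored as 16-bit grayscale TIFFs holding integer counts in
#' `[0, 65535]`; masks as 8-bit TIFFs with 0/255. In memory both are
#' plain matrices (counts, and logical).
#'
#' @param path file path.
#' @return `read_image_tiff`: numeric matrix of counts;
#'   `read_mask_tiff`: logical matrix.
#' @export
read_image_tiff <- function(path) {
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' @rdname read_image_tiff
#' @export
read_mask_tiff <- function(path) {
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0
}

#' @rdname read_image_tiff
#' @param image numeric matrix of counts (clipped to `[0, 65535]`).
#' @export
write_image_tiff <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_image_tiff
#' @param mask logical matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}
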