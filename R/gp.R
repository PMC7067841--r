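# C-Laurdan generalized polarization (GP): ratiometric readout of membrane
# packing. GP = (I_blue - I_red) / (I_blue + I_red) over two emission bands,
# computed either from a full emission spectrum or per pixel from a
# two-channel spectral image after binning / background subtraction /
# dual-channel thresholding.

#' Construct an emission spectrum
#'
#' @param wavelengths Wavelengths in nm, strictly ascending.
#' @param intensities Non-negative intensities, same length.
#' @return An `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavelengths, intensities) {
  wavelengths <- as.numeric(wavelengths); intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities lengths differ")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be ascending")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(list(wavelengths = wavelengths, intensities = intensities),
            class = "emission_spectrum")
}

#' GP band definitions
#'
#' Cuvette spectroscopy integrates 420-460 nm (blue) vs 470-510 nm (red);
#' confocal spectral imaging collects 433-463 nm vs 473-503 nm detector bands.
#' The two modes use different bands and their GP values are not mixed.
#'
#' @param mode `"spectroscopy"` or `"imaging"`.
#' @return List with `blue` and `red` wavelength ranges (nm, inclusive).
#' @export
gp_bands <- function(mode = c("spectroscopy", "imaging")) {
  mode <- match.arg(mode)
  switch(mode,
         spectroscopy = list(blue = c(420, 460), red = c(470, 510)),
         imaging      = list(blue = c(433, 463), red = c(473, 503)))
}

#' GP from an emission spectrum
#'
#' `GP = (S_blue - S_red) / (S_blue + S_red)` with band sums taken over
#' samples falling inclusively inside each band.
#'
#' @param spectrum An [emission_spectrum()].
#' @param bands Band definition, default [gp_bands()] for spectroscopy.
#' @return GP value in \[-1, 1\].
#' @export
#' @examples
#' s <- simulate_emission_spectrum(gp_target = 0.3, seed = 1, noise_sd = 0)
#' gp_from_spectrum(s)
gp_from_spectrum <- function(spectrum, bands = gp_bands("spectroscopy")) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelengths
  if (min(wl) > bands$blue[1] || max(wl) < bands$red[2])
    stop(sprintf("spectrum must cover %g-%g nm", bands$blue[1], bands$red[2]))
  in_blue <- wl >= bands$blue[1] & wl <= bands$blue[2]
  in_red <- wl >= bands$red[1] & wl <= bands$red[2]
  if (!any(in_blue) || !any(in_red))
    stop("no samples inside a GP band")
  sb <- sum(spectrum$intensities[in_blue])
  sr <- sum(spectrum$intensities[in_red])
  if (sb + sr <= 0) stop("zero total band intensity")
  (sb - sr) / (sb + sr)
}

#' Construct a two-channel spectral image pair
#'
#' @param blue,red Same-shape non-negative intensity matrices (blue = shorter
#'   wavelength band).
#' @return A `spectral_image_pair` object.
#' @export
spectral_image_pair <- function(blue, red) {
  blue <- as.matrix(blue); red <- as.matrix(red)
  if (!identical(dim(blue), dim(red))) stop("channel shapes differ")
  if (any(blue < 0) || any(red < 0)) stop("intensities must be non-negative")
  structure(list(blue = blue, red = red), class = "spectral_image_pair")
}

#' 2x2 sum-binning of an intensity image
#'
#' Photon-count-preserving binning: each output pixel is the sum of a 2x2
#' block; a trailing odd row/column is dropped.
#'
#' @param img Numeric matrix.
#' @return Binned matrix of dimension `floor(dim/2)`.
#' @export
bin2 <- function(img) {
  img <- as.matrix(img)
  nr <- nrow(img) %/% 2L; nc <- ncol(img) %/% 2L
  if (nr < 1L || nc < 1L) stop("image too small to bin")
  img <- img[seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
  img[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
    img[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
    img[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE] +
    img[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE]
}

#' Bin a boolean mask to match a 2x2-binned image
#'
#' @param mask Logical matrix.
#' @param min_count How many of the 4 block pixels must be inside for the
#'   binned pixel to count as inside: 1 dilates, 2 (default) keeps the
#'   majority boundary, 4 erodes (useful for contamination-free ROIs).
#' @return Logical matrix of dimension `floor(dim/2)`.
#' @export
bin_mask <- function(mask, min_count = 2) {
  stopifnot(min_count %in% 1:4)
  bin2(mask * 1) >= min_count
}

#' Preprocess a spectral image pair for GP mapping
#'
#' The map pipeline: 2x2 sum-binning, per-channel background subtraction
#' (clipped at zero), and dual-channel thresholding that keeps only pixels
#' whose background-subtracted intensity exceeds 3 background standard
#' deviations in both channels.
#'
#' Background statistics come from a user-supplied ROI (logical mask at the
#' unbinned resolution); without one, pixels at or below the 10th intensity
#' percentile in both channels are used as an automatic background estimate.
#'
#' @param pair A [spectral_image_pair()] (unbinned).
#' @param background_roi Optional logical matrix marking background pixels.
#' @return List: `blue`, `red` (binned, subtracted), `valid` (logical mask),
#'   `background` (per-channel mean/sd at the binned scale).
#' @export
preprocess_pair <- function(pair, background_roi = NULL) {
  stopifnot(inherits(pair, "spectral_image_pair"))
  if (nrow(pair$blue) < 4L || ncol(pair$blue) < 4L)
    stop("image must be at least 4x4")
  b <- bin2(pair$blue); r <- bin2(pair$red)
  if (!is.null(background_roi)) {
    background_roi <- as.matrix(background_roi)
    if (!identical(dim(background_roi), dim(pair$blue)))
      stop("background ROI shape must match the unbinned image")
    roi <- bin_mask(background_roi)
    if (!any(roi)) stop("background ROI is empty after binning")
  } else {
    roi <- (b <= stats::quantile(b, 0.10)) & (r <= stats::quantile(r, 0.10))
    if (!any(roi)) roi <- b <= stats::quantile(b, 0.10)
  }
  bg <- list(blue = list(mean = mean(b[roi]), sd = stats::sd(as.numeric(b[roi]))),
             red = list(mean = mean(r[roi]), sd = stats::sd(as.numeric(r[roi]))))
  if (is.na(bg$blue$sd)) bg$blue$sd <- 0
  if (is.na(bg$red$sd)) bg$red$sd <- 0
  bs <- pmax(b - bg$blue$mean, 0)
  rs <- pmax(r - bg$red$mean, 0)
  valid <- (bs > 3 * bg$blue$sd) & (rs > 3 * bg$red$sd)
  structure(list(blue = bs, red = rs, valid = valid, background = bg),
            class = "preprocessed_pair")
}

#' Per-pixel GP map
#'
#' `GP = (I_blue - I_red) / (I_blue + I_red)` at every valid pixel. Valid
#' pixels with a zero denominator are marked invalid and counted.
#'
#' @param pre A [preprocess_pair()] result, or a `spectral_image_pair` of
#'   already-processed channels (then all pixels are taken valid).
#' @return A `gp_map` object: `gp` (matrix, `NA` outside the mask),
#'   `valid` (logical), `n_zero_denominator`, `background`.
#' @export
gp_map <- function(pre) {
  if (inherits(pre, "spectral_image_pair"))
    pre <- list(blue = pre$blue, red = pre$red,
                valid = matrix(TRUE, nrow(pre$blue), ncol(pre$blue)),
                background = NULL)
  den <- pre$blue + pre$red
  zero_den <- pre$valid & den <= 0
  valid <- pre$valid & den > 0
  g <- matrix(NA_real_, nrow(den), ncol(den))
  g[valid] <- (pre$blue[valid] - pre$red[valid]) / den[valid]
  structure(list(gp = g, valid = valid,
                 n_zero_denominator = sum(zero_den),
                 background = pre$background),
            class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  cat(sprintf("<GP map %dx%d: %d valid pixels, mean GP %.3f>\n",
              nrow(x$gp), ncol(x$gp), sum(x$valid),
              mean(x$gp[x$valid])))
  invisible(x)
}

# Local maxima with a one-sided drop (prominence) of at least
# prom_frac * range of the valid part of the line. The drop is measured as
# the deeper of the two descents before a higher value, an NA run or the
# line end is reached: a plasma-membrane peak sitting at the edge of the
# valid region still registers through its descent into the cell interior.
.find_peaks <- function(v, prom_frac = 0.25) {
  n <- length(v)
  ok <- is.finite(v)
  if (sum(ok) < 3L) return(integer(0))
  rng <- diff(range(v[ok]))
  if (rng <= 0) return(integer(0))
  min_prom <- prom_frac * rng
  peaks <- integer(0)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    left <- if (i > 1L && ok[i - 1L]) v[i - 1L] else -Inf
    right <- if (i < n && ok[i + 1L]) v[i + 1L] else -Inf
    if (v[i] <= left || v[i] < right) next
    lmin <- v[i]; j <- i - 1L
    while (j >= 1L && ok[j] && v[j] <= v[i]) { lmin <- min(lmin, v[j]); j <- j - 1L }
    rmin <- v[i]; j <- i + 1L
    while (j <= n && ok[j] && v[j] <= v[i]) { rmin <- min(rmin, v[j]); j <- j + 1L }
    if (v[i] - min(lmin, rmin) >= min_prom) peaks <- c(peaks, i)
  }
  peaks
}

# fallback for a perfectly uniform GP map, where a line scan has no peaks
# to anchor on but the internal GP is unambiguous
quantify_regions_uniform <- function(map, n_bins) {
  px <- map$gp[map$valid]
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  h <- graphics::hist(pmin(pmax(px, -1), 1), breaks = breaks, plot = FALSE)
  structure(list(internal_mean_gp = mean(px), pm_mean_gp = NA_real_,
                 histogram = list(mids = h$mids, counts = h$counts,
                                  density = h$density),
                 method = "line_scan", n_pixels = length(px),
                 n_lines_skipped = 0L),
            class = "region_quantification")
}

#' Quantify GP in internal membranes and at the plasma membrane
#'
#' Three quantification methods for the internal-membrane GP, mirroring
#' standard practice with GP maps:
#' \describe{
#'   \item{`mask_histogram`}{mean and histogram of GP inside a supplied
#'     internal-membrane mask;}
#'   \item{`line_scan`}{horizontal scans across the cell: the two outermost
#'     prominent GP peaks per line are taken as plasma membrane (PM), the
#'     mean of values strictly between them as internal membranes;}
#'   \item{`perinuclear_roi`}{mean GP inside a supplied perinuclear ROI.}
#' }
#'
#' @param map A [gp_map()].
#' @param method One of `"mask_histogram"`, `"line_scan"`, `"perinuclear_roi"`.
#' @param roi Logical matrix (binned resolution) for the mask/ROI methods.
#' @param lines Row indices to scan for `line_scan`; by default rows whose
#'   valid-pixel count is at least 60% of the best row's, which restricts
#'   scans to lines crossing the cell body rather than grazing the PM.
#' @param n_bins Histogram bin count over \[-1, 1\].
#' @param prominence Peak prominence as a fraction of the line's GP range.
#' @param pm_margin Pixels adjacent to each PM peak excluded from the
#'   internal-membrane average (keeps ring shoulders out; default 3, about
#'   one binned ring width).
#' @return A `region_quantification`: `internal_mean_gp`, `pm_mean_gp`
#'   (`NA` except for `line_scan`), `histogram` (`mids`, `counts`, `density`),
#'   `method`, `n_pixels`, `n_lines_skipped`.
#' @export
quantify_regions <- function(map,
                             method = c("mask_histogram", "line_scan",
                                        "perinuclear_roi"),
                             roi = NULL, lines = NULL, n_bins = 100,
                             prominence = 0.25, pm_margin = 3L) {
  stopifnot(inherits(map, "gp_map"))
  method <- match.arg(method)
  if (sum(map$valid) < 1L) stop("GP map has no valid pixels")
  pm_mean <- NA_real_
  n_skipped <- 0L

  if (method %in% c("mask_histogram", "perinuclear_roi")) {
    if (is.null(roi)) stop(sprintf("method '%s' requires an ROI mask", method))
    roi <- as.matrix(roi)
    if (!identical(dim(roi), dim(map$gp)))
      stop("ROI shape must match the GP map")
    px <- map$gp[roi & map$valid]
    if (length(px) == 0L) stop("no valid pixels inside the ROI")
    internal <- mean(px)
  } else {
    if (is.null(lines)) {
      nvalid <- rowSums(map$valid)
      lines <- which(nvalid >= 5L & nvalid >= 0.6 * max(nvalid))
    }
    if (length(lines) == 0L) stop("no scannable lines")
    pm_line <- internal_line <- rep(NA_real_, length(lines))
    internal_px <- numeric(0)
    for (li in seq_along(lines)) {
      v <- map$gp[lines[li], ]
      pk <- .find_peaks(v, prom_frac = prominence)
      if (length(pk) < 2L) { n_skipped <- n_skipped + 1L; next }
      lo <- min(pk); hi <- max(pk)
      # peak GP from a 3-px window: counters the upward bias of a noisy max
      win <- function(i) {
        w <- v[max(1L, i - 1L):min(length(v), i + 1L)]
        mean(w[is.finite(w)])
      }
      pm_line[li] <- mean(c(win(lo), win(hi)))
      ilo <- lo + pm_margin + 1L; ihi <- hi - pm_margin - 1L
      if (ihi < ilo) { n_skipped <- n_skipped + 1L; next }
      between <- v[ilo:ihi]
      between <- between[is.finite(between)]
      if (length(between)) {
        internal_line[li] <- mean(between)
        internal_px <- c(internal_px, between)
      }
    }
    if (n_skipped > 0L)
      warning(sprintf("%d line scan(s) skipped (no PM peak pair or no interior)",
                      n_skipped))
    if (all(is.na(internal_line))) {
      # degenerate uniform map: no peaks anywhere, but a well-defined GP
      vals <- map$gp[map$valid]
      if (diff(range(vals)) <= 1e-12)
        return(quantify_regions_uniform(map, n_bins))
      stop("no line scan yielded internal pixels")
    }
    pm_mean <- mean(pm_line, na.rm = TRUE)
    internal <- mean(internal_line, na.rm = TRUE)
    px <- internal_px
  }

  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  h <- graphics::hist(pmin(pmax(px, -1), 1), breaks = breaks, plot = FALSE)
  structure(list(internal_mean_gp = internal, pm_mean_gp = pm_mean,
                 histogram = list(mids = h$mids, counts = h$counts,
                                  density = h$density),
                 method = method, n_pixels = length(px),
                 n_lines_skipped = n_skipped),
            class = "region_quantification")
}

#' @export
print.region_quantification <- function(x, ...) {
  cat(sprintf("<%s: internal GP %.3f%s, %d pixels>\n", x$method,
              x$internal_mean_gp,
              if (is.na(x$pm_mean_gp)) ""
              else sprintf(", PM GP %.3f", x$pm_mean_gp),
              x$n_pixels))
  invisible(x)
}

#' Treated-minus-untreated GP difference
#'
#' `delta GP = mean(treated GP) - mean(untreated GP)`, the within-experiment
#' normalization used to compare treatments.
#'
#' @param treated,untreated Lists of `region_quantification` objects of the
#'   same method, or numeric vectors of GP values.
#' @param region For quantifications, which value to compare:
#'   `"internal"` or `"pm"`.
#' @return The GP difference.
#' @export
delta_gp <- function(treated, untreated, region = c("internal", "pm")) {
  region <- match.arg(region)
  pull <- function(lst) {
    if (is.numeric(lst)) return(list(values = lst, method = "numeric"))
    if (inherits(lst, "region_quantification")) lst <- list(lst)
    stopifnot(all(vapply(lst, inherits, logical(1), "region_quantification")))
    meth <- unique(vapply(lst, `[[`, character(1), "method"))
    field <- if (region == "internal") "internal_mean_gp" else "pm_mean_gp"
    list(values = vapply(lst, `[[`, numeric(1), field), method = meth)
  }
  a <- pull(treated); b <- pull(untreated)
  if (length(a$values) == 0L || length(b$values) == 0L)
    stop("both groups must be non-empty")
  if (a$method[1] != "numeric" && b$method[1] != "numeric" &&
      (length(a$method) > 1L || length(b$method) > 1L ||
       a$method[1] != b$method[1]))
    stop("mixed region quantification methods")
  if (any(is.na(c(a$values, b$values))))
    stop("NA GP values (pm GP requested from a non-line-scan method?)")
  mean(a$values) - mean(b$values)
}

#' Read a two-channel spectral image pair from TIFF
#'
#' @param blue_path,red_path Paths to single-page grayscale TIFFs, or
#'   `blue_path` alone pointing to a two-page TIFF (page 1 blue, page 2 red).
#' @param scale Multiply intensities by this factor (TIFF readers often
#'   rescale to \[0, 1\]).
#' @return A [spectral_image_pair()].
#' @export
read_spectral_pair <- function(blue_path, red_path = NULL, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF requires the 'tiff' package")
  if (is.null(red_path)) {
    pages <- tiff::readTIFF(blue_path, all = TRUE, as.is = TRUE)
    if (length(pages) < 2L) stop("two-page TIFF expected")
    spectral_image_pair(pages[[1]] * scale, pages[[2]] * scale)
  } else {
    spectral_image_pair(tiff::readTIFF(blue_path, as.is = TRUE) * scale,
                        tiff::readTIFF(red_path, as.is = TRUE) * scale)
  }
}
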