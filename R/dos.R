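#' Angular density of states (DoS)
#'
#' Normalized equal-width histogram of a three-atom angle over [0, pi].
#' Binning is linear, not circular: these angles live on the closed interval
#' [0, pi], there is no wrap-around.  Values exactly at pi fall in the last
#' bin.
#'
#' @param series An [angle_series()] or a numeric vector of radians.
#' @param n_bins Number of equal-width bins over [0, pi]; the default 90
#'   gives 2-degree resolution, ample for the ~0.9 rad mode separations
#'   typical of switch angles.
#' @return Object of class `angle_dos`: `breaks` (n_bins + 1 edges), `mass`
#'   (per-bin fractions summing to 1), `n_frames`.
#' @export
build_dos <- function(series, n_bins = 90L) {
  vals <- if (inherits(series, "angle_series")) series$values
          else as.numeric(series)
  if (length(vals) == 0L) stop("cannot build a DoS from an empty series")
  if (n_bins < 2L) stop("n_bins must be at least 2")
  breaks <- seq(0, pi, length.out = n_bins + 1L)
  bin <- pmin(n_bins, 1L + floor(vals / pi * n_bins))  # pi -> last bin
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(breaks = breaks, mass = counts / length(vals),
                 n_frames = length(vals)),
            class = "angle_dos")
}

#' @export
print.angle_dos <- function(x, ...) {
  m <- find_modes(x)
  cat("<angle_dos> ", length(x$mass), " bins over [0, pi], ",
      x$n_frames, " frames, ", nrow(m$modes), " mode(s) at ",
      paste(sprintf("%.2f", m$modes$location), collapse = ", "),
      " rad\n", sep = "")
  invisible(x)
}

#' @export
plot.angle_dos <- function(x, main = "angular density of states", ...) {
  mid <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$mass, names.arg = NULL, space = 0, border = NA,
                    xlab = "angle (rad)", ylab = "fraction of frames",
                    main = main, ...)
  graphics::axis(1, at = seq(0, length(x$mass), length.out = 5L),
                 labels = sprintf("%.2f", seq(0, pi, length.out = 5L)))
  invisible(x)
}

#' Smooth a DoS with a centered moving average
#'
#' Stabilizes peak detection on finitely sampled histograms.  Ends are
#' handled by reflection so total mass is preserved.
#'
#' @param dos An `angle_dos`.
#' @param window Odd number of bins; `window = 1` is the identity.
#' @return A smoothed `angle_dos` with the same bins and `n_frames`.
#' @export
smooth_dos <- function(dos, window = 5L) {
  if (window %% 2L != 1L || window < 1L)
    stop("smoothing window must be odd and >= 1")
  if (window == 1L) return(dos)
  m <- dos$mass
  h <- (window - 1L) %/% 2L
  padded <- c(rev(m[seq_len(h)]), m, rev(m[length(m) - seq_len(h) + 1L]))
  sm <- stats::filter(padded, rep(1 / window, window), sides = 2L)
  out <- as.numeric(sm[(h + 1L):(h + length(m))])
  dos$mass <- out / sum(out)  # reflection can shift edge mass; renormalize
  dos
}

#' Locate modes (angular states) in a DoS
#'
#' Local maxima of the per-bin mass above a prominence threshold, with
#' nearby peaks merged; modes are returned sorted by height descending
#' (ties broken by lower bin index).  When two or more modes exist, the
#' valley is the minimum mass between the top two modes.
#'
#' @param dos An `angle_dos` (smooth it first for noisy data).
#' @param min_prominence Minimum peak height as a fraction of the tallest
#'   bin's height.
#' @param min_separation_bins Peaks closer than this many bins are merged
#'   into the taller one.
#' @return List with `modes` (data.frame: bin, location, height, mass, fwhm)
#'   and `valley_height` (NA when fewer than 2 modes).
#' @export
find_modes <- function(dos, min_prominence = 0.05, min_separation_bins = 5L) {
  m <- dos$mass
  nb <- length(m)
  mid <- (dos$breaks[-1L] + dos$breaks[-(nb + 1L)]) / 2
  left <- c(-Inf, m[-nb])
  right <- c(m[-1L], -Inf)
  peaks <- which(m > left & m >= right & m >= min_prominence * max(m))
  # merge peaks closer than min_separation_bins, keeping the taller
  if (length(peaks) > 1L) {
    keep <- order(-m[peaks], peaks)  # tallest first, lower bin on ties
    chosen <- integer()
    for (p in peaks[keep]) {
      if (all(abs(p - chosen) >= min_separation_bins)) chosen <- c(chosen, p)
    }
    peaks <- chosen
  }
  peaks <- peaks[order(-m[peaks], peaks)]
  # basin boundaries: partition bins at minima between successive peaks
  sorted_p <- sort(peaks)
  cuts <- integer(0)
  if (length(sorted_p) > 1L) {
    for (i in seq_len(length(sorted_p) - 1L)) {
      rng <- (sorted_p[i] + 1L):(sorted_p[i + 1L] - 1L)
      if (length(rng) == 0L) rng <- sorted_p[i]
      cuts <- c(cuts, rng[which.min(m[rng])])
    }
  }
  lo <- c(1L, cuts + 1L)
  hi <- c(cuts, nb)
  basin_of <- function(p) which(lo <= p & p <= hi)[1L]
  bw <- pi / nb
  rows <- lapply(peaks, function(p) {
    b <- basin_of(p)
    seg <- lo[b]:hi[b]
    half <- m[p] / 2
    data.frame(bin = p, location = mid[p], height = m[p],
               mass = sum(m[seg]), fwhm = bw * sum(m[seg] >= half))
  })
  modes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin = integer(), location = numeric(), height = numeric(),
               mass = numeric(), fwhm = numeric())
  valley <- NA_real_
  if (nrow(modes) >= 2L) {
    b1 <- modes$bin[1L]; b2 <- modes$bin[2L]
    rng <- (min(b1, b2) + 1L):(max(b1, b2) - 1L)
    valley <- if (length(rng)) min(m[rng]) else min(m[c(b1, b2)])
  }
  list(modes = modes, valley_height = valley)
}

#' Names of the 14 engineered DoS features
#' @return Character vector of length 14.
#' @export
dos_feature_names <- function() {
  c("n_modes", "major_mode_loc", "minor_mode_loc", "mode_separation",
    "major_height", "minor_height", "height_ratio", "valley_ratio",
    "minor_mass_fraction", "major_fwhm", "minor_fwhm",
    "sample_variance", "sample_skewness", "bimodality_coefficient")
}

#' Extract the 14-feature vector of a DoS
#'
#' Features summarize the mode structure (count, locations, separation,
#' heights, height ratio, valley-to-minor-peak ratio, minor-mode mass
#' fraction, two FWHMs) and the shape moments (variance, skewness, and the
#' bimodality coefficient (skewness^2 + 1) / kurtosis) of the smoothed DoS.
#' A single-mode DoS takes sentinel values: zero separation, zero minor
#' height/mass/FWHM, valley_ratio 0.
#'
#' @param dos An `angle_dos`.
#' @param smooth_window Passed to [smooth_dos()] before feature extraction.
#' @param min_prominence,min_separation_bins Passed to [find_modes()].
#' @return Named numeric vector of length 14 (see [dos_feature_names()]).
#' @export
dos_features <- function(dos, smooth_window = 5L, min_prominence = 0.05,
                         min_separation_bins = 5L) {
  sm <- smooth_dos(dos, smooth_window)
  fm <- find_modes(sm, min_prominence, min_separation_bins)
  modes <- fm$modes
  nb <- length(sm$mass)
  mid <- (sm$breaks[-1L] + sm$breaks[-(nb + 1L)]) / 2
  w <- sm$mass / sum(sm$mass)
  mu <- sum(w * mid)
  v <- sum(w * (mid - mu)^2)
  skew <- if (v > 0) sum(w * (mid - mu)^3) / v^1.5 else 0
  kurt <- if (v > 0) sum(w * (mid - mu)^4) / v^2 else 3
  bc <- (skew^2 + 1) / kurt

  nm <- nrow(modes)
  if (nm >= 2L) {
    major <- modes[1L, ]; minor <- modes[2L, ]
    total_mass <- sum(modes$mass)
    feats <- c(
      n_modes = nm,
      major_mode_loc = major$location,
      minor_mode_loc = minor$location,
      mode_separation = abs(major$location - minor$location),
      major_height = major$height,
      minor_height = minor$height,
      height_ratio = minor$height / major$height,
      valley_ratio = min(1, fm$valley_height / minor$height),
      minor_mass_fraction = min(0.5, minor$mass / (major$mass + minor$mass)),
      major_fwhm = major$fwhm,
      minor_fwhm = minor$fwhm,
      sample_variance = v, sample_skewness = skew,
      bimodality_coefficient = bc)
  } else {
    major <- modes[1L, ]
    feats <- c(
      n_modes = nm, major_mode_loc = major$location, minor_mode_loc = 0,
      mode_separation = 0, major_height = major$height, minor_height = 0,
      height_ratio = 0, valley_ratio = 0, minor_mass_fraction = 0,
      major_fwhm = major$fwhm, minor_fwhm = 0,
      sample_variance = v, sample_skewness = skew,
      bimodality_coefficient = bc)
  }
  stats::setNames(as.numeric(feats), dos_feature_names())
}

#' Heuristic switch label for a DoS
#'
#' A bootstrap labeling aid (switch calls in production come from the
#' trained classifier): label 1 iff the smoothed DoS has exactly two modes,
#' the valley between them is deep relative to the minor peak, and the minor
#' mode carries non-trivial mass — i.e. a bimodal DoS with no intermediate
#' state.
#'
#' @param dos An `angle_dos`.
#' @param max_valley_ratio Valley height over minor-peak height must be
#'   below this for label 1.
#' @param min_minor_mass Minor mode's mass fraction must exceed this.
#' @inheritParams dos_features
#' @return Integer 0 or 1 with attribute `source = "heuristic"`.
#' @export
heuristic_label <- function(dos, max_valley_ratio = 0.4,
                            min_minor_mass = 0.05, smooth_window = 5L,
                            min_prominence = 0.05, min_separation_bins = 5L) {
  f <- dos_features(dos, smooth_window, min_prominence, min_separation_bins)
  lab <- as.integer(f[["n_modes"]] == 2 &&
                    f[["valley_ratio"]] <= max_valley_ratio &&
                    f[["minor_mass_fraction"]] >= min_minor_mass)
  attr(lab, "source") <- "heuristic"
  lab
}
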