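#' Generate a synthetic angle series with ground truth
#'
#' Emulates the angular dynamics the pipeline is built to detect: unimodal
#' fluctuation about one center; a stable switch ("ss") that jumps between
#' two centers at scheduled frames; an unstable switch ("us") that follows a
#' symmetric two-state Markov chain; and a bimodal density with an occupied
#' intermediate state ("intermediate"), which is not a switch.  Per-frame
#' noise is a truncated Gaussian (rejection-sampled into [0, pi]) around the
#' active mode center.
#'
#' Defaults mirror realistic switch angles: mode centers 1.6 and 2.5 rad
#' (0.9 rad separation) and spread 0.08 rad.
#'
#' @param mode One of `"unimodal"`, `"ss"`, `"us"`, `"intermediate"`.
#' @param n_frames Frames to generate.
#' @param centers Mode centers in (0, pi).  Length 1 for unimodal, 2 for
#'   ss/us; for intermediate a third, middle center is added automatically
#'   when only 2 are given.
#' @param sds Per-mode spreads (radians); recycled to the number of centers.
#' @param weights Mixture weights for `"intermediate"` (i.i.d. state draws);
#'   default `c(0.4, 0.2, 0.4)` with the intermediate state in the middle.
#' @param transitions For `"ss"`: strictly increasing frame indices (1-based
#'   index of the first frame in the new state) at which the state flips;
#'   default a single jump at `n_frames %/% 2 + 1`.
#' @param switch_prob For `"us"`: per-frame probability of switching state.
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @param segments Optional 0-based segment matrix to stamp onto the series.
#' @return List of class `synthetic_angle_series`: `series` (an
#'   [angle_series()]), `states` (ground-truth per-frame state, 0-based),
#'   `switch_label` (1 for ss/us, else 0), `grade` (`"SS"`, `"US"` or `NA`),
#'   `n_true_transitions`, and the generating parameters in `spec`.
#' @export
gen_angle_series <- function(mode = c("unimodal", "ss", "us", "intermediate"),
                             n_frames = 1000L,
                             centers = c(1.6, 2.5), sds = 0.08,
                             weights = c(0.4, 0.2, 0.4),
                             transitions = NULL, switch_prob = 0.1,
                             seed = 1L, segments = NULL) {
  mode <- match.arg(mode)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be positive")
  if (mode == "unimodal") centers <- centers[1L]
  if (mode == "intermediate" && length(centers) == 2L)
    centers <- c(centers[1L], mean(centers), centers[2L])
  if (any(centers <= 0) || any(centers >= pi))
    stop("mode centers must lie strictly inside (0, pi)")
  if (anyDuplicated(centers)) stop("mode centers must be distinct")
  sds <- rep_len(as.numeric(sds), length(centers))
  if (any(sds <= 0)) stop("mode spreads must be positive")

  set.seed(seed)
  states <- switch(mode,
    unimodal = integer(n_frames),
    ss = {
      if (is.null(transitions)) transitions <- n_frames %/% 2L + 1L
      transitions <- as.integer(transitions)
      if (any(transitions < 2L) || any(transitions > n_frames) ||
          is.unsorted(transitions, strictly = TRUE))
        stop("transition frames must be strictly increasing in [2, n_frames]")
      s <- integer(n_frames)
      cur <- 0L
      bounds <- c(transitions, n_frames + 1L)
      start <- 1L
      for (b in bounds) {
        if (b > start) s[start:(b - 1L)] <- cur
        cur <- 1L - cur
        start <- b
      }
      s
    },
    us = {
      if (switch_prob <= 0 || switch_prob >= 1)
        stop("switch_prob must be in (0, 1)")
      flips <- stats::rbinom(n_frames - 1L, 1L, switch_prob)
      as.integer(cumsum(c(0L, flips)) %% 2L)
    },
    intermediate = {
      weights <- weights / sum(weights)
      if (length(weights) != length(centers))
        stop("need one weight per center")
      sample.int(length(centers), n_frames, replace = TRUE,
                 prob = weights) - 1L
    })

  vals <- rnorm_truncated(n_frames, centers[states + 1L], sds[states + 1L])
  ser <- angle_series(vals, segments = segments)
  n_tr <- count_transitions(states, ser$segments)
  structure(list(
    series = ser, states = states,
    switch_label = as.integer(mode %in% c("ss", "us")),
    grade = switch(mode, ss = "SS", us = "US", NA_character_),
    n_true_transitions = n_tr,
    spec = list(mode = mode, n_frames = n_frames, centers = centers,
                sds = sds, weights = if (mode == "intermediate") weights,
                transitions = if (mode == "ss") transitions,
                switch_prob = if (mode == "us") switch_prob, seed = seed)),
    class = "synthetic_angle_series")
}

# Gaussian truncated to [0, pi] by rejection; exact, and effectively a
# plain Gaussian for centers several sigma inside the interval.
rnorm_truncated <- function(n, mean, sd, lower = 0, upper = pi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' @export
print.synthetic_angle_series <- function(x, ...) {
  cat("<synthetic_angle_series> mode ", x$spec$mode, ", ",
      x$spec$n_frames, " frames, ", x$n_true_transitions,
      " true transition(s)\n", sep = "")
  invisible(x)
}

#' Generate a balanced labeled DoS feature corpus
#'
#' Stands in for a visually labeled training set: equal numbers of unimodal,
#' clean bimodal (half single-jump, half oscillating) and
#' bimodal-with-intermediate angle series, with randomized centers, spreads
#' and separations inside clear-margin ranges.  Only clean bimodal series
#' are labeled 1 (switch).
#'
#' @param n_per_class Series per class.
#' @param n_frames Frames per series.
#' @param seed Corpus seed; per-series seeds are derived from it.
#' @param n_bins,smooth_window DoS construction parameters.
#' @param min_separation_sd Lower bound on (mode separation) / spread for
#'   the bimodal classes; the default 6 keeps modes well resolved.
#' @return List of class `labeled_corpus`: `features` (data.frame of the 14
#'   features plus `id`), `labels` (0/1, source `synthetic_truth`), `class`
#'   (generating class per row).
#' @export
gen_labeled_corpus <- function(n_per_class = 200L, n_frames = 2000L,
                               seed = 1L, n_bins = 90L, smooth_window = 5L,
                               min_separation_sd = 6) {
  if (n_per_class < 1L) stop("n_per_class must be at least 1")
  classes <- rep(c("unimodal", "bimodal", "intermediate"),
                 each = n_per_class)
  set.seed(seed)
  n <- length(classes)
  sds <- stats::runif(n, 0.05, 0.12)
  sep <- pmax(min_separation_sd * sds, stats::runif(n, 0.6, 1.1))
  lo <- stats::runif(n, 0.6, pi - 0.6 - sep)
  sub_seed <- sample.int(.Machine$integer.max %/% 2L, n)
  us_flag <- rep_len(c(FALSE, TRUE), n)  # alternate ss / us within bimodal
  rows <- vector("list", n)
  labels <- integer(n)
  for (i in seq_len(n)) {
    g <- switch(classes[i],
      unimodal = gen_angle_series("unimodal", n_frames,
                                  centers = lo[i] + sep[i] / 2, sds = sds[i],
                                  seed = sub_seed[i]),
      bimodal = gen_angle_series(if (us_flag[i]) "us" else "ss", n_frames,
                                 centers = c(lo[i], lo[i] + sep[i]),
                                 sds = sds[i], seed = sub_seed[i]),
      intermediate = gen_angle_series("intermediate", n_frames,
                                      centers = c(lo[i], lo[i] + sep[i]),
                                      sds = sds[i], seed = sub_seed[i]))
    labels[i] <- g$switch_label
    rows[[i]] <- dos_features(build_dos(g$series, n_bins),
                              smooth_window = smooth_window)
  }
  feats <- as.data.frame(do.call(rbind, rows))
  feats <- cbind(id = sprintf("synthetic_%04d", seq_len(n)), feats,
                 stringsAsFactors = FALSE)
  structure(list(features = feats, labels = labels, class = classes,
                 seed = seed),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat("<labeled_corpus> ", nrow(x$features), " angles (",
      sum(x$labels == 1L), " switch / ", sum(x$labels == 0L),
      " nonswitch), classes: ",
      paste(names(table(x$class)), table(x$class), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Build a toy 3-D trajectory realizing prescribed angle schedules
#'
#' Constructs a small all-ALA peptide-like system in which, for each residue
#' given a dynamics spec, the O-CA-N angle follows the generated schedule
#' exactly: CA (the vertex) and N are fixed and O moves on a unit-length arm
#' in the residue's xy-plane at the scheduled angle.  All other atoms are
#' static, so their angles are unimodal (constant).  This inverts the angle
#' computation and exercises the geometry -> DoS -> stability chain end to
#' end.
#'
#' @param n_residues Total residues (5-atom ALA selections).
#' @param dynamics Named list mapping residue index (as character) to a
#'   [gen_angle_series()] result whose series drives that residue's O-CA-N
#'   angle.
#' @param arm_length Length of the moving O arm and the fixed N arm.
#' @return List of class `toy_system`: `trajectory` (a [trajectory_set()]),
#'   `dynamics` (the input specs), `moving_triplet` (atom names).
#' @export
gen_toy_trajectory <- function(n_residues = 3L, dynamics = list(),
                               arm_length = 1.5) {
  if (n_residues < 1L) stop("need at least one residue")
  if (length(dynamics)) {
    ridx <- as.integer(names(dynamics))
    if (any(is.na(ridx)) || any(ridx < 1L) || any(ridx > n_residues))
      stop("dynamics names must be residue indices in 1..n_residues")
    n_fr <- unique(vapply(dynamics,
                          function(d) length(d$series$values), 1L))
    if (length(n_fr) != 1L)
      stop("all dynamic residues must share one frame count")
  } else {
    n_fr <- 1L
  }
  atoms <- selected_atoms("ALA")  # N CA CB C O
  n_atoms <- length(atoms) * n_residues
  atom <- data.frame(
    eleno = seq_len(n_atoms),
    elety = rep(atoms, n_residues),
    resid = "ALA",
    resno = rep(seq_len(n_residues), each = length(atoms)),
    stringsAsFactors = FALSE)
  # static template, one residue every 5 Angstrom along z
  base <- matrix(0, n_atoms, 3L)
  for (r in seq_len(n_residues)) {
    o <- (r - 1L) * length(atoms)
    z <- (r - 1L) * 5
    base[o + 1L, ] <- c(arm_length, 0, z)        # N: fixed arm along +x
    base[o + 2L, ] <- c(0, 0, z)                 # CA: vertex
    base[o + 3L, ] <- c(-1, -1, z + 0.5)         # CB
    base[o + 4L, ] <- c(0.8, -1.2, z)            # C
    base[o + 5L, ] <- c(arm_length * cos(1.6),   # O: moving arm
                        arm_length * sin(1.6), z)
  }
  xyz <- matrix(rep(t(base), n_fr), nrow = n_fr, byrow = TRUE)
  segments <- NULL
  for (key in names(dynamics)) {
    r <- as.integer(key)
    th <- dynamics[[key]]$series$values
    o3 <- 3L * ((r - 1L) * length(atoms) + 5L - 1L)  # O atom columns
    z <- (r - 1L) * 5
    xyz[, o3 + 1L] <- arm_length * cos(th)
    xyz[, o3 + 2L] <- arm_length * sin(th)
    xyz[, o3 + 3L] <- z
    segments <- dynamics[[key]]$series$segments
  }
  structure(list(trajectory = trajectory_set(atom, xyz, segments),
                 dynamics = dynamics,
                 moving_triplet = c(atom_a = "N", vertex = "CA",
                                    atom_b = "O")),
            class = "toy_system")
}
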