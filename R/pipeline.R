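#' A default SS/US model calibrated on clearly separated synthetic ratios
#'
#' Fits the 1-D logistic stability classifier on synthetic instability
#' ratios drawn from the two clear regimes — stable switches below 1%,
#' unstable switches above 6% — so that the decision boundary falls in the
#' intermediate band.
#'
#' @param n_per_class Ratios per class.
#' @param seed Seed for the draws.
#' @return A [stability_fit()] model.
#' @export
default_stability_model <- function(n_per_class = 40L, seed = 1L) {
  set.seed(seed)
  ss <- stats::runif(n_per_class, 0.02, 0.9)
  us <- stats::runif(n_per_class, 6.1, 40)
  stability_fit(c(ss, us), rep(c("SS", "US"), each = n_per_class),
                seed = seed)
}

#' Run the full switch-residue scan on a trajectory set
#'
#' Executes the whole chain: selected-atom triplet enumeration per residue,
#' per-frame angle measurement, DoS construction and 14-feature extraction,
#' switch classification, two-cluster state assignment and instability
#' ratio for each switch angle, SS/US grading, and the ANSR/ATSC residue
#' report.  Optionally conditions a per-frame global property (e.g. RMSD)
#' on the angular states of each switch residue.
#'
#' @param ts A [trajectory_set()] (or a `toy_system`, whose trajectory is
#'   used).
#' @param model A fitted [switch_fit()] classifier for the 14 DoS features.
#' @param stability A [stability_fit()] model; default
#'   [default_stability_model()].
#' @param table Selection table ([selection_table()]).
#' @param n_bins,smooth_window DoS parameters.
#' @param property Optional numeric per-frame global property, or a CSV
#'   path readable by [read_property_series()].
#' @param residue_grade `"any"` (residue is SS if any of its switch angles
#'   is SS) or `"majority"` (majority vote over its switch angles).
#' @param out_dir If non-NULL, reports are written there (see
#'   [write_scan_reports()]).
#' @param seed Seed recorded in provenance (the scan itself is
#'   deterministic given the fitted models).
#' @return Object of class `switch_scan`: `report` (a [residue_report()]),
#'   `angles` (per-angle table: features, call, transitions, ratio, grade),
#'   `property_summaries` (per switch residue, when a property is given),
#'   `config`.
#' @export
switch_scan <- function(ts, model, stability = default_stability_model(),
                        table = selection_table(), n_bins = 90L,
                        smooth_window = 5L, property = NULL,
                        residue_grade = c("any", "majority"),
                        out_dir = NULL, seed = 1L) {
  if (inherits(ts, "toy_system")) ts <- ts$trajectory
  if (!inherits(ts, "trajectory_set")) stop("ts must be a trajectory_set")
  if (n_frames(ts) == 0L) stop("geometry stage: trajectory has no frames")
  residue_grade <- match.arg(residue_grade)
  if (is.character(property)) property <- read_property_series(property)
  if (!is.null(property) && length(property) != n_frames(ts))
    stop("property series has ", length(property), " frames but the ",
         "trajectory has ", n_frames(ts))

  res_tab <- unique(ts$atom[, c("resno", "resid")])
  res_tab <- res_tab[res_tab$resid %in% names(table), , drop = FALSE]
  if (nrow(res_tab) == 0L)
    stop("geometry stage: no residue in the topology has a selection entry")

  angle_rows <- list()
  residues <- list()
  prop_sum <- list()
  for (i in seq_len(nrow(res_tab))) {
    rno <- res_tab$resno[i]
    rname <- res_tab$resid[i]
    trips <- enumerate_triplets(selected_atoms(rname, table))
    feats <- matrix(NA_real_, nrow(trips), 14L,
                    dimnames = list(NULL, dos_feature_names()))
    traces <- vector("list", nrow(trips))
    for (j in seq_len(nrow(trips))) {
      ser <- measure_angle_series(ts, rno, trips$atom_a[j], trips$vertex[j],
                                  trips$atom_b[j])
      feats[j, ] <- dos_features(build_dos(ser, n_bins),
                                 smooth_window = smooth_window)
      traces[[j]] <- ser
    }
    calls <- predict(model, as.data.frame(feats))
    roll <- residue_rollup(trips, calls)
    grades <- rep(NA_character_, nrow(trips))
    ratios <- rep(NA_real_, nrow(trips))
    transitions <- rep(NA_integer_, nrow(trips))
    for (j in which(calls == 1L)) {
      trace <- assign_states(traces[[j]])
      rec <- instability_ratio(trace)
      transitions[j] <- rec$transitions
      ratios[j] <- rec$ratio_percent
      grades[j] <- predict(stability, rec)
      if (!is.null(property)) {
        key <- as.character(rno)
        if (is.null(prop_sum[[key]]))
          prop_sum[[key]] <- state_property_summary(trace, property)
      }
    }
    res_grade <- NA_character_
    sw <- grades[calls == 1L]
    if (length(sw)) {
      res_grade <- if (residue_grade == "any") {
        if (any(sw == "SS")) "SS" else "US"
      } else {
        if (sum(sw == "SS") * 2L > length(sw)) "SS" else "US"
      }
    }
    residues[[i]] <- list(residue_index = rno, residue_name = rname,
                          rollup = roll, grade = res_grade)
    angle_rows[[i]] <- data.frame(
      residue_index = rno, residue_name = rname,
      triplet = triplet_id(trips$atom_a, trips$vertex, trips$atom_b),
      as.data.frame(feats), switch_call = calls,
      transitions = transitions, ratio_percent = ratios, grade = grades,
      stringsAsFactors = FALSE)
  }
  angles <- do.call(rbind, angle_rows)
  rownames(angles) <- NULL
  out <- structure(list(
    report = residue_report(residues),
    angles = angles,
    property_summaries = if (length(prop_sum)) prop_sum,
    config = list(n_bins = n_bins, smooth_window = smooth_window,
                  residue_grade = residue_grade, seed = seed,
                  classifier = model$kind,
                  stability_boundary = stability$boundary,
                  n_frames = n_frames(ts),
                  n_segments = nrow(ts$segments))),
    class = "switch_scan")
  if (!is.null(out_dir)) write_scan_reports(out, out_dir)
  out
}

#' @export
print.switch_scan <- function(x, ...) {
  cat("switch scan over ", x$config$n_frames, " frames (",
      x$config$n_segments, " trajectory segment(s)), classifier: ",
      x$config$classifier, "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @export
summary.switch_scan <- function(object, ...) {
  print(object)
  sw <- object$angles[object$angles$switch_call == 1L, , drop = FALSE]
  if (nrow(sw)) {
    cat("\nswitch angles:\n")
    print.data.frame(sw[, c("residue_index", "triplet", "transitions",
                            "ratio_percent", "grade")], row.names = FALSE)
  }
  if (!is.null(object$property_summaries)) {
    cat("\nstate-conditioned property summaries:\n")
    for (key in names(object$property_summaries)) {
      cat("residue ", key, ": ", sep = "")
      print(object$property_summaries[[key]])
    }
  }
  invisible(object)
}

#' Write scan reports and a provenance record
#'
#' Emits `report.csv` / `report.json` (the residue report), `angles.csv`
#' (per-angle features, calls, instability ratios, grades) and
#' `provenance.json` (configuration, its MD5 hash, seeds and package
#' version).  Output is deterministic: rerunning an identical scan writes
#' byte-identical files.
#'
#' @param scan A [switch_scan()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_scan_reports <- function(scan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_report <- file.path(out_dir, "report.csv")
  p_json <- file.path(out_dir, "report.json")
  p_angles <- file.path(out_dir, "angles.csv")
  p_prov <- file.path(out_dir, "provenance.json")
  utils::write.csv(as.data.frame(scan$report), p_report, row.names = FALSE)
  jsonlite::write_json(as.data.frame(scan$report), p_json, digits = NA,
                       auto_unbox = TRUE)
  utils::write.csv(scan$angles, p_angles, row.names = FALSE)
  cfg_file <- tempfile()
  jsonlite::write_json(scan$config, cfg_file, digits = NA,
                       auto_unbox = TRUE)
  prov <- list(config = scan$config,
               config_md5 = unname(tools::md5sum(cfg_file)),
               package_version =
                 as.character(utils::packageVersion("switchscan")))
  unlink(cfg_file)
  jsonlite::write_json(prov, p_prov, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(p_report, p_json, p_angles, p_prov))
}
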