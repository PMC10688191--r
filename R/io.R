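#' Write / read per-angle time-series tables
#'
#' The on-disk table has one row per (angle, frame) with columns
#' `residue_index`, `residue_name`, `atom_a`, `vertex`, `atom_b`, `frame`
#' (0-based), `trajectory_id` (0-based segment number) and `angle_rad`.
#' Round-trips are lossless to full double precision.
#'
#' @param series_list A single [angle_series()] or a list of them (each with
#'   a `triplet` identifier).
#' @param path CSV path.
#' @return `write_angle_table` invisibly returns `path`; `read_angle_table`
#'   a list of `angle_series`.
#' @export
write_angle_table <- function(series_list, path) {
  if (inherits(series_list, "angle_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    tp <- s$triplet
    if (is.null(tp)) stop("series without triplet identifier cannot be ",
                          "written to an angle table")
    n <- length(s$values)
    seg_id <- integer(n)
    for (i in seq_len(nrow(s$segments)))
      seg_id[(s$segments[i, 1L] + 1L):s$segments[i, 2L]] <- i - 1L
    data.frame(residue_index = tp$residue_index,
               residue_name = tp$residue_name,
               atom_a = tp$atom_a, vertex = tp$vertex, atom_b = tp$atom_b,
               frame = seq_len(n) - 1L, trajectory_id = seg_id,
               angle_rad = sprintf("%.17g", s$values),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_angle_table
#' @export
read_angle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_index", "residue_name", "atom_a", "vertex", "atom_b",
            "frame", "trajectory_id", "angle_rad")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("angle table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$angle_rad) | df$angle_rad < 0 |
               df$angle_rad > pi + 1e-12)
  if (length(bad))
    stop("angle table ", path, " has out-of-range angle_rad at line ",
         bad[1L] + 1L, " (value ", df$angle_rad[bad[1L]],
         "; angles must lie in [0, pi])")
  key <- paste(df$residue_index, df$atom_a, df$vertex, df$atom_b, sep = "|")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    ends <- cumsum(as.integer(table(factor(d$trajectory_id,
                                           levels = unique(d$trajectory_id)))))
    angle_series(d$angle_rad,
                 segments = cbind(c(0L, ends[-length(ends)]), ends),
                 triplet = list(residue_index = d$residue_index[1L],
                                residue_name = d$residue_name[1L],
                                atom_a = d$atom_a[1L], vertex = d$vertex[1L],
                                atom_b = d$atom_b[1L]))
  })
}

#' Write / read DoS feature matrices with optional labels
#'
#' One row per angle: identifier columns (`id` and any others present),
#' then the 14 feature columns of [dos_feature_names()], plus `label` when
#' labels are supplied.
#'
#' @param features data.frame containing the 14 feature columns.
#' @param path CSV path.
#' @param labels Optional 0/1 vector written as a `label` column.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` a list with `features` and `labels` (NULL if the
#'   file has no label column).
#' @export
write_feature_table <- function(features, path, labels = NULL) {
  df <- as.data.frame(features)
  if (!is.null(labels)) df$label <- as.integer(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(dos_feature_names(), names(df))
  if (length(missing))
    stop("feature table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  labels <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  list(features = df[setdiff(names(df), "label")], labels = labels)
}

#' Read a per-frame global-property series
#'
#' CSV with columns `frame` (0-based), `value`, and optionally
#' `trajectory_id`.  Rows are returned in frame order.
#'
#' @param path CSV path.
#' @return Numeric vector of property values, one per frame.
#' @export
read_property_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "value") %in% names(df)))
    stop("property series ", path, " needs columns frame, value")
  as.numeric(df$value[order(df$frame)])
}
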