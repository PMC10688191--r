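#' Angle at a vertex from three points
#'
#' The angle between the arms (a - vertex) and (b - vertex), computed as the
#' arccos of their normalized dot product (clamped to [-1, 1] against
#' round-off).  Invariant under global rotation, translation and uniform
#' scaling, and symmetric in the two arms.
#'
#' @param p_a,p_vertex,p_b Numeric length-3 coordinates, or matrices with one
#'   row per frame and 3 columns (vectorized over frames).
#' @return Angle(s) in radians, in [0, pi].
#' @examples
#' three_atom_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # pi/2
#' @export
three_atom_angle <- function(p_a, p_vertex, p_b) {
  if (is.null(dim(p_a))) p_a <- matrix(p_a, nrow = 1L)
  if (is.null(dim(p_vertex))) p_vertex <- matrix(p_vertex, nrow = 1L)
  if (is.null(dim(p_b))) p_b <- matrix(p_b, nrow = 1L)
  u <- p_a - p_vertex
  v <- p_b - p_vertex
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  bad <- which(nu == 0 | nv == 0)
  if (length(bad))
    stop("zero-length arm at frame(s) ", paste(bad, collapse = ", "),
         ": arm atom coincides with the vertex")
  ct <- rowSums(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, ct)))
}

#' Construct an angle time series
#'
#' @param values Numeric vector of angles in radians, all in [0, pi].
#' @param segments 0-based half-open `[start, end)` trajectory boundaries
#'   (two-column matrix); defaults to one segment.
#' @param triplet Optional list or one-row data.frame identifying the source
#'   (residue_index, residue_name, atom_a, vertex, atom_b).
#' @return Object of class `angle_series`.
#' @export
angle_series <- function(values, segments = NULL, triplet = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("angle series must be non-empty")
  if (any(!is.finite(values)) || any(values < 0) || any(values > pi + 1e-12))
    stop("angle values must be finite and in [0, pi]")
  n <- length(values)
  if (is.null(segments)) segments <- cbind(start = 0L, end = n)
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (segments[1L, 1L] != 0L || segments[nrow(segments), 2L] != n ||
      any(segments[, 2L] <= segments[, 1L]) ||
      (nrow(segments) > 1L &&
       any(segments[-1L, 1L] != segments[-nrow(segments), 2L])))
    stop("segments must partition [0, ", n, ")")
  structure(list(values = values, segments = segments, triplet = triplet),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  tp <- x$triplet
  lab <- if (is.null(tp)) "" else
    paste0(" ", tp$residue_name, tp$residue_index, " ",
           triplet_id(tp$atom_a, tp$vertex, tp$atom_b))
  cat("<angle_series>", lab, " ", length(x$values), " frames, ",
      nrow(x$segments), " segment(s), range [",
      sprintf("%.3f", min(x$values)), ", ",
      sprintf("%.3f", max(x$values)), "] rad\n", sep = "")
  invisible(x)
}

#' Measure one residue angle over every frame of a trajectory set
#'
#' @param ts A [trajectory_set()].
#' @param residue_index Residue number in the topology.
#' @param atom_a,vertex,atom_b Atom names of the canonical triplet.
#' @return An [angle_series()] inheriting the trajectory segments.
#' @export
measure_angle_series <- function(ts, residue_index, atom_a, vertex, atom_b) {
  ia <- atom_xyz_index(ts, residue_index, atom_a)
  iv <- atom_xyz_index(ts, residue_index, vertex)
  ib <- atom_xyz_index(ts, residue_index, atom_b)
  res_name <- ts$atom$resid[ts$atom$resno == residue_index][1L]
  vals <- three_atom_angle(ts$xyz[, ia, drop = FALSE],
                           ts$xyz[, iv, drop = FALSE],
                           ts$xyz[, ib, drop = FALSE])
  angle_series(vals, segments = ts$segments,
               triplet = list(residue_index = residue_index,
                              residue_name = res_name, atom_a = atom_a,
                              vertex = vertex, atom_b = atom_b))
}

#' Per-frame RMSD to a reference frame after optimal superposition
#'
#' Each frame is least-squares superposed (rotation + translation) onto the
#' reference frame over the chosen atom subset, then the root-mean-square
#' deviation over that subset is reported, in the trajectory's length unit.
#'
#' @param ts A [trajectory_set()].
#' @param reference_frame 1-based index of the reference frame.
#' @param atom_rows Integer rows of `ts$atom` to superpose over; default all.
#' @return Numeric vector, one RMSD per frame.
#' @export
rmsd_series <- function(ts, reference_frame = 1L, atom_rows = NULL) {
  if (reference_frame < 1L || reference_frame > n_frames(ts))
    stop("reference frame ", reference_frame, " out of range")
  if (is.null(atom_rows)) atom_rows <- seq_len(nrow(ts$atom))
  if (length(atom_rows) == 0L) stop("atom subset is empty")
  if (any(atom_rows < 1L) || any(atom_rows > nrow(ts$atom)))
    stop("atom subset indexes atoms absent from the topology")
  inds <- as.vector(t(outer(3L * (atom_rows - 1L), 1:3, `+`)))
  ref <- ts$xyz[reference_frame, inds]
  fitted <- bio3d::fit.xyz(fixed = ts$xyz[reference_frame, ],
                           mobile = ts$xyz,
                           fixed.inds = inds, mobile.inds = inds)
  d <- sweep(fitted[, inds, drop = FALSE], 2L, ref)
  unname(sqrt(rowSums(d * d) / length(atom_rows)))
}

#' Per-frame distance between one named atom of two residues
#'
#' @param ts A [trajectory_set()].
#' @param residue_i,residue_j Residue numbers.
#' @param atom_name Atom name present in both residues (e.g. "CA").
#' @return Numeric vector of Euclidean distances, one per frame.
#' @export
pair_distance_series <- function(ts, residue_i, residue_j, atom_name = "CA") {
  ii <- atom_xyz_index(ts, residue_i, atom_name)
  jj <- atom_xyz_index(ts, residue_j, atom_name)
  d <- ts$xyz[, ii, drop = FALSE] - ts$xyz[, jj, drop = FALSE]
  sqrt(rowSums(d * d))
}
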