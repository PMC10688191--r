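#' In-memory trajectory set
#'
#' Bundles a topology (atom table) with pooled coordinates from one or more
#' trajectories.  Frames are pooled by concatenation in input order;
#' `segments` records each source trajectory as a 0-based half-open frame
#' range `[start, end)`, so downstream transition counting never crosses a
#' trajectory boundary.
#'
#' @param atom data.frame with at least columns `eleno`, `elety`, `resno`,
#'   `resid` (as in a `bio3d` pdb object's `$atom`).
#' @param xyz numeric matrix, one row per frame, 3 columns per atom
#'   (x1, y1, z1, x2, ...).
#' @param segments two-column integer matrix of 0-based half-open
#'   `[start, end)` ranges, one row per source trajectory; defaults to a
#'   single segment covering all frames.
#' @return Object of class `trajectory_set`.
#' @export
trajectory_set <- function(atom, xyz, segments = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atom))
    stop("xyz has ", ncol(xyz), " columns but topology has ", nrow(atom),
         " atoms (need 3 columns per atom)")
  n <- nrow(xyz)
  if (is.null(segments)) segments <- cbind(start = 0L, end = n)
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0L || segments[1L, 1L] != 0L ||
      segments[nrow(segments), 2L] != n ||
      any(segments[, 2L] <= segments[, 1L]) ||
      (nrow(segments) > 1L &&
       any(segments[-1L, 1L] != segments[-nrow(segments), 2L])))
    stop("segments must partition [0, ", n, ") without gaps or overlap")
  structure(list(atom = atom, xyz = xyz, segments = segments),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", nrow(x$atom), " atoms, ", nrow(x$xyz),
      " frames in ", nrow(x$segments), " trajectory segment(s)\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param ts A [trajectory_set()].
#' @export
n_frames <- function(ts) nrow(ts$xyz)

#' Read a topology and coordinate trajectories from files
#'
#' The topology is a PDB file.  Each trajectory file may be a DCD file or a
#' multi-model PDB; multiple files are pooled by concatenation in the order
#' given and their boundaries recorded as segments.  XTC is not supported.
#'
#' @param pdb_file Path to the topology PDB.
#' @param traj_files Character vector of trajectory paths (`.dcd` or `.pdb`).
#'   If empty, the topology's own coordinates form a single-frame trajectory.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(pdb_file, traj_files = character()) {
  pdb <- bio3d::read.pdb(pdb_file)
  if (length(traj_files) == 0L) {
    return(trajectory_set(pdb$atom, matrix(pdb$xyz, nrow = 1L)))
  }
  frames <- list()
  seg_len <- integer(length(traj_files))
  for (i in seq_along(traj_files)) {
    f <- traj_files[[i]]
    ext <- tolower(tools::file_ext(f))
    xyz <- switch(ext,
      dcd = bio3d::read.dcd(f, verbose = FALSE),
      pdb = {
        p <- bio3d::read.pdb(f, multi = TRUE)
        p$xyz
      },
      xtc = stop("XTC trajectories are not supported; convert '", f,
                 "' to DCD or multi-model PDB first"),
      stop("unrecognized trajectory format '", ext, "' for file ", f)
    )
    xyz <- matrix(as.numeric(xyz), ncol = ncol(xyz))
    if (ncol(xyz) != 3L * nrow(pdb$atom))
      stop("trajectory ", f, " has ", ncol(xyz) / 3, " atoms but topology ",
           pdb_file, " has ", nrow(pdb$atom))
    frames[[i]] <- xyz
    seg_len[i] <- nrow(xyz)
  }
  ends <- cumsum(seg_len)
  trajectory_set(pdb$atom, do.call(rbind, frames),
                 cbind(start = c(0L, ends[-length(ends)]), end = ends))
}

#' Write a trajectory set as topology PDB plus multi-model PDB trajectory
#'
#' @param ts A [trajectory_set()].
#' @param pdb_file Output path for the single-frame topology.
#' @param traj_file Output path for the multi-model coordinate trajectory;
#'   `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_trajectory_pdb <- function(ts, pdb_file, traj_file = NULL) {
  a <- ts$atom
  bio3d::write.pdb(file = pdb_file, xyz = ts$xyz[1L, ], eleno = a$eleno,
                   elety = a$elety, resid = a$resid, resno = a$resno)
  if (!is.null(traj_file)) {
    bio3d::write.pdb(file = traj_file, xyz = ts$xyz, eleno = a$eleno,
                     elety = a$elety, resid = a$resid, resno = a$resno)
  }
  invisible(c(pdb_file, traj_file))
}

# Column indices (into xyz) of one named atom of one residue.
atom_xyz_index <- function(ts, residue_index, atom_name) {
  row <- which(ts$atom$resno == residue_index & ts$atom$elety == atom_name)
  if (length(row) == 0L)
    stop("atom ", atom_name, " not found in residue ", residue_index,
         " of the topology")
  if (length(row) > 1L)
    stop("atom name ", atom_name, " is ambiguous in residue ", residue_index)
  3L * (row - 1L) + 1:3
}
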