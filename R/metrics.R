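#' Angle switch ratio (ANSR) of a residue
#'
#' Number of switch angles over the total enumerable angles of the residue.
#' A residue with two switch angles out of the 10 formed by a 5-atom
#' selection has ANSR 2/10.
#'
#' @param labels 0/1 switch call per triplet of the residue, or a
#'   [residue_rollup()] result.
#' @return List of class `ansr`: `numerator`, `denominator`, `ratio`.
#' @export
ansr <- function(labels) {
  if (is.list(labels) && !is.null(labels$n_switch)) {
    num <- labels$n_switch; den <- labels$n_total
  } else {
    labels <- as.integer(labels)
    num <- sum(labels == 1L); den <- length(labels)
  }
  structure(list(numerator = num, denominator = den, ratio = num / den),
            class = "ansr")
}

#' @export
print.ansr <- function(x, ...) {
  cat(sprintf("ANSR = %d/%d = %.3f\n", x$numerator, x$denominator, x$ratio))
  invisible(x)
}

#' Atom switch contribution (ATSC) of a residue
#'
#' For each atom, the number of switch triplets that contain it (vertex and
#' arm positions count alike).  Counts always sum to 3 times the number of
#' switch triplets.
#'
#' @param switch_triplets data.frame with columns `atom_a`, `vertex`,
#'   `atom_b`: the triplets of one residue called switch.
#' @return Named integer vector of per-atom counts, sorted by count
#'   descending then atom name; empty when there are no switch triplets.
#' @export
atsc <- function(switch_triplets) {
  if (nrow(switch_triplets) == 0L)
    return(stats::setNames(integer(0), character(0)))
  atoms <- c(switch_triplets$atom_a, switch_triplets$vertex,
             switch_triplets$atom_b)
  counts <- table(atoms)
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(-out, names(out))]
}

#' State-conditioned summary of a global property
#'
#' Splits a per-frame scalar property (RMSD, activation level, helix
#' distance, ...) by the angular state of a residue and reports per-state
#' means, their difference, and the point-biserial correlation between state
#' and property (the Pearson correlation of the binary state with the
#' property).
#'
#' @param trace A [assign_states()] state trace, or 0/1 vector.
#' @param property Numeric vector, one value per frame, aligned with the
#'   trace.
#' @return List of class `state_property_summary`: `mean_state0`,
#'   `mean_state1`, `n_state0`, `n_state1`, `mean_difference`,
#'   `correlation`.
#' @export
state_property_summary <- function(trace, property) {
  states <- if (inherits(trace, "state_trace")) trace$states
            else as.integer(trace)
  property <- as.numeric(property)
  if (length(states) != length(property))
    stop("property series has ", length(property),
         " frames but the state trace has ", length(states))
  s1 <- states == 1L
  m0 <- mean(property[!s1]); m1 <- mean(property[s1])
  corr <- if (stats::sd(states) == 0 || stats::sd(property) == 0) 0
          else stats::cor(states, property)
  structure(list(mean_state0 = m0, mean_state1 = m1,
                 n_state0 = sum(!s1), n_state1 = sum(s1),
                 mean_difference = m1 - m0, correlation = corr),
            class = "state_property_summary")
}

#' @export
print.state_property_summary <- function(x, ...) {
  cat(sprintf(
    "state 0: mean %.4g (n=%d) | state 1: mean %.4g (n=%d)\ndifference %.4g, point-biserial correlation %.3f\n",
    x$mean_state0, x$n_state0, x$mean_state1, x$n_state1,
    x$mean_difference, x$correlation))
  invisible(x)
}

#' Assemble and rank the per-residue switch report
#'
#' @param residues List of per-residue entries, each a list with
#'   `residue_index`, `residue_name`, `rollup` (from [residue_rollup()]),
#'   and optionally `grade` (`"SS"`, `"US"`, or `NA` for nonswitch).
#' @return data.frame of class `residue_report`, sorted SS first, then US,
#'   then nonswitch; within a grade by ANSR descending, ties by residue
#'   index.  Columns: residue_index, residue_name, is_switch, grade,
#'   ansr_numerator, ansr_denominator, ansr, atsc, switch_triplets.
#' @export
residue_report <- function(residues) {
  idx <- vapply(residues, function(r) as.integer(r$residue_index), 1L)
  if (anyDuplicated(idx))
    stop("duplicate residue index in report: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  rows <- lapply(residues, function(r) {
    a <- ansr(r$rollup)
    grade <- if (!r$rollup$is_switch) "nonswitch"
             else if (is.null(r$grade) || is.na(r$grade)) "switch" else r$grade
    counts <- atsc(r$rollup$switch_triplets)
    data.frame(
      residue_index = as.integer(r$residue_index),
      residue_name = r$residue_name,
      is_switch = r$rollup$is_switch,
      grade = grade,
      ansr_numerator = a$numerator,
      ansr_denominator = a$denominator,
      ansr = a$ratio,
      atsc = paste(sprintf("%s:%d", names(counts), counts), collapse = ", "),
      switch_triplets = paste(
        triplet_id(r$rollup$switch_triplets$atom_a,
                   r$rollup$switch_triplets$vertex,
                   r$rollup$switch_triplets$atom_b), collapse = ", "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rank <- match(out$grade, c("SS", "US", "switch", "nonswitch"))
  out <- out[order(rank, -out$ansr, out$residue_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("residue_report", "data.frame")
  out
}

#' @export
print.residue_report <- function(x, ...) {
  cat("residue switch report (", sum(x$is_switch), " switch / ",
      nrow(x), " residues)\n", sep = "")
  show <- x
  show$ansr <- sprintf("%d/%d", x$ansr_numerator, x$ansr_denominator)
  print.data.frame(show[, c("residue_index", "residue_name", "grade",
                            "ansr", "atsc")], row.names = FALSE)
  invisible(x)
}
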