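# Reference-anchored conservation. The alignment reference row is mapped
# to 1-based protein coordinates (gap columns in the reference have no
# coordinate and are dropped), and each reference position p gets the
# score s = n/t where n counts the NON-reference sequences carrying the
# reference's residue at that column and t is the total number of
# non-reference sequences. The reference never counts itself: with it
# included s could never reach 0, contradicting the intended endpoint
# ("no other sequences matching"). t is constant across positions, so a
# gap in another sequence counts as a mismatch rather than shrinking t;
# unaligned regions are thereby penalized on the conservation track.

aln_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "alignment_set"))
  do.call(rbind, strsplit(alignment$seqs, ""))
}

#' Map reference residues to alignment columns
#'
#' For each non-gap character of the reference row, records the alignment
#' column it occupies. The result is strictly increasing; columns where
#' the reference carries a gap are absent.
#'
#' @param alignment An `alignment_set` (see [read_alignment()]).
#' @return Integer vector of 1-based alignment column indices; element `p`
#'   is the column of reference residue `p`.
#' @examples
#' aln <- alignment_set(c(ref = "AC-GT", other = "ACAGT"), "ref")
#' build_column_map(aln)
#' @export
build_column_map <- function(alignment) {
  ref <- strsplit(alignment$seqs[[alignment$reference_id]], "")[[1L]]
  cols <- which(ref != GAP_CHAR)
  if (length(cols) == 0L)
    stop(sprintf("reference row '%s' is entirely gaps", alignment$reference_id),
         call. = FALSE)
  cols
}

#' Per-position conservation scores
#'
#' Computes, for every residue of the reference sequence, the score
#' s = n/t: n is the number of non-reference sequences whose character at
#' that reference position's alignment column equals the reference
#' residue, and t the total number of non-reference sequences. Scores lie
#' in `[0, 1]`; 0 means no other sequence matches the reference at that
#' position, 1 means all do. A gap in a non-reference sequence never
#' matches an amino acid.
#'
#' @param alignment An `alignment_set` with at least two sequences.
#' @param context Optional [protein_context()]; if supplied, its length
#'   must equal the reference's residue count or an error is raised.
#' @return An object of class `conservation_profile`: a data frame with
#'   columns `position`, `ref_letter`, `n`, `t`, `score`, one row per
#'   reference residue.
#' @examples
#' aln <- alignment_set(c(human = "CDE", mouse = "CDA", rat = "CQE"), "human")
#' conservation_scores(aln)
#' @export
conservation_scores <- function(alignment, context = NULL) {
  m <- aln_matrix(alignment)
  if (nrow(m) < 2L)
    stop("conservation requires at least one non-reference sequence",
         call. = FALSE)
  cols <- build_column_map(alignment)
  iref <- which(rownames(m) == alignment$reference_id)
  others <- m[-iref, cols, drop = FALSE]
  ref_letters <- m[iref, cols]
  n <- colSums(others == matrix(ref_letters, nrow = nrow(others),
                                ncol = length(cols), byrow = TRUE))
  t_total <- nrow(others)
  if (!is.null(context)) {
    stopifnot(inherits(context, "protein_context"))
    if (context$length != length(cols))
      stop(sprintf("protein length mismatch: context says %d, reference row has %d residues",
                   context$length, length(cols)), call. = FALSE)
  }
  out <- data.frame(position = seq_along(cols), ref_letter = unname(ref_letters),
                    n = unname(n), t = t_total, score = unname(n) / t_total,
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", class(out))
  out
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d positions, mean s = %.3f (t = %d)\n",
              nrow(x), mean(x$score), x$t[1L]))
  NextMethod()
}

#' Export a conservation profile as TSV
#'
#' Writes one row per reference position with columns `position`,
#' `ref_letter`, `n`, `t`, `score`, plus a header line.
#'
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conservation_tsv <- function(profile, path) {
  lines <- c("position\tref_letter\tn\tt\tscore",
             sprintf("%d\t%s\t%d\t%d\t%s", profile$position,
                     profile$ref_letter, profile$n, profile$t,
                     format(profile$score, digits = 15, trim = TRUE,
                            scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}
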