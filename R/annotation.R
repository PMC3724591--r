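# Variant annotation: for each mutation, which named domains contain its
# position ([start, end], inclusive both ends, matching the 1-based
# inclusive file coordinates), whether the position is a PTM site, and
# the conservation score there when a profile is available.

#' Annotate mutations with domain and PTM membership
#'
#' Reproduces the annotation table of the tool's interactive version:
#' each amino-acid change is marked present/absent in every domain whose
#' inclusive interval contains its position, and at post-translational
#' modification sites. Output order equals input order; overlapping
#' domains are all reported, in architecture-file order.
#'
#' @param mutations Mutation data frame (see [read_mutation_file()]).
#' @param domains Architecture data frame, or `NULL`.
#' @param ptms Integer vector of PTM positions, or `NULL`.
#' @param profile Optional `conservation_profile`; when it covers a
#'   mutation's position the score is attached, otherwise `NA`.
#' @return A data frame with the mutation columns plus `domains_hit`
#'   (list column of character vectors), `is_ptm_site` (logical) and
#'   `conservation` (numeric, `NA` when unavailable).
#' @examples
#' doms <- data.frame(name = c("Signal Peptide", "Transmembrane"),
#'                    start = c(1L, 636L), end = c(24L, 653L))
#' mut <- data.frame(protein = "RET", gene = "RET", position = 650L,
#'                   ref = "C", alt = "R")
#' annotate_mutations(mut, doms, ptms = NULL)
#' @export
annotate_mutations <- function(mutations, domains = NULL, ptms = NULL,
                               profile = NULL) {
  n <- nrow(mutations)
  hits <- vector("list", n)
  ptm <- logical(n)
  cons <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- mutations$position[i]
    if (!is.null(domains) && nrow(domains) > 0L)
      hits[[i]] <- domains$name[domains$start <= p & p <= domains$end]
    else hits[[i]] <- character(0)
    ptm[i] <- !is.null(ptms) && p %in% ptms
    if (!is.null(profile)) {
      j <- match(p, profile$position)
      if (!is.na(j)) cons[i] <- profile$score[j]
    }
  }
  out <- mutations
  out$domains_hit <- hits
  out$is_ptm_site <- ptm
  out$conservation <- cons
  out
}

#' Write the annotation table
#'
#' Tab-separated with header `protein`, `gene`, `position`, `ref`, `alt`,
#' `domains` (semicolon-joined, or "none"), `ptm_site` (yes/no),
#' `conservation` (blank when no profile covered the position).
#'
#' @param annotated Output of [annotate_mutations()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotated, path) {
  dom <- vapply(annotated$domains_hit, function(d)
    if (length(d) == 0L) "none" else paste(d, collapse = ";"), character(1))
  cons <- ifelse(is.na(annotated$conservation), "",
                 format(annotated$conservation, digits = 15, trim = TRUE,
                        scientific = FALSE))
  lines <- c("protein\tgene\tposition\tref\talt\tdomains\tptm_site\tconservation",
             sprintf("%s\t%s\t%d\t%s\t%s\t%s\t%s\t%s",
                     annotated$protein, annotated$gene, annotated$position,
                     annotated$ref, annotated$alt, dom,
                     ifelse(annotated$is_ptm_site, "yes", "no"), cons))
  writeLines(lines, path)
  invisible(path)
}
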