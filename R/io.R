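# Tabular input/output: mutation, architecture and PTM files, aligned FASTA.
# All three tabular formats are tab-separated, '#' starts a comment line,
# blank lines are skipped, and a single header row is auto-detected (a
# non-integer in the numeric column of the first data line, with at least
# two data lines following) and dropped.

AA_REF_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
AA_ALT_ALPHABET <- c(AA_REF_ALPHABET, "*")
GAP_CHAR <- "-"

#' Protein context
#'
#' Scalar metadata for the protein under study: its length in amino acids
#' and the query name printed as the plot title.
#'
#' @param length Protein length in amino acids (integer, >= 1).
#' @param query_name Name displayed as the figure title.
#' @return An object of class `protein_context`.
#' @examples
#' protein_context(1114, "RET")
#' @export
protein_context <- function(length, query_name) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("protein length must be a positive integer", call. = FALSE)
  if (!is.character(query_name) || length(query_name) != 1L || !nzchar(query_name))
    stop("query_name must be a non-empty string", call. = FALSE)
  structure(list(length = length, query_name = query_name),
            class = "protein_context")
}

#' @export
print.protein_context <- function(x, ...) {
  cat(sprintf("<protein_context> %s, %d aa\n", x$query_name, x$length))
  invisible(x)
}

# Read a tab file into a list of character vectors (fields per line),
# keeping original line numbers for error messages.
read_tab_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
  list(fields = lapply(raw[keep], function(l) strsplit(l, "\t", fixed = TRUE)[[1]]),
       lineno = keep)
}

is_integerish <- function(x) grepl("^[+-]?[0-9]+$", x)

# Header auto-detection: first data line has a non-integer in column `col`
# and at least two data lines follow.
detect_header <- function(fields, col) {
  if (length(fields) < 3L) return(FALSE)
  f1 <- fields[[1L]]
  length(f1) >= col && !is_integerish(trimws(f1[col]))
}

#' Read a mutation file
#'
#' Each data line carries at least five tab-separated fields in the order
#' protein name, gene name, 1-based amino-acid position, reference amino
#' acid, alternate amino acid. Amino-acid letters are normalized to upper
#' case. Entries whose reference and alternate residue are identical are
#' dropped with a warning (they describe no change); duplicated positions
#' are kept.
#'
#' @param path Path to a tab-separated mutation file.
#' @return A data frame with columns `protein`, `gene`, `position`
#'   (integer), `ref`, `alt`, one row per mutation, in file order.
#' @examples
#' f <- tempfile()
#' writeLines("RET\tRET\t634\tC\tR", f)
#' read_mutation_file(f)
#' @export
read_mutation_file <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$fields) == 0L)
    stop(sprintf("mutation file is empty: %s", path), call. = FALSE)
  if (detect_header(tl$fields, 3L)) {
    tl$fields <- tl$fields[-1L]
    tl$lineno <- tl$lineno[-1L]
  }
  n <- length(tl$fields)
  protein <- gene <- ref <- alt <- character(n)
  position <- integer(n)
  drop <- logical(n)
  for (i in seq_len(n)) {
    f <- tl$fields[[i]]
    ln <- tl$lineno[i]
    if (length(f) < 5L)
      stop(sprintf("line %d: expected >= 5 tab-separated fields, found %d",
                   ln, length(f)), call. = FALSE)
    pos <- trimws(f[3L])
    if (!is_integerish(pos))
      stop(sprintf("line %d: position '%s' is not an integer", ln, pos),
           call. = FALSE)
    p <- as.integer(pos)
    if (is.na(p) || p < 1L)
      stop(sprintf("line %d: position %s out of range (must be >= 1)", ln, pos),
           call. = FALSE)
    r <- toupper(trimws(f[4L])); a <- toupper(trimws(f[5L]))
    if (nchar(r) != 1L || !(r %in% AA_REF_ALPHABET))
      stop(sprintf("line %d: invalid reference amino acid '%s'", ln, f[4L]),
           call. = FALSE)
    if (nchar(a) != 1L || !(a %in% AA_ALT_ALPHABET))
      stop(sprintf("line %d: invalid alternate amino acid '%s'", ln, f[5L]),
           call. = FALSE)
    if (r == a) {
      warning(sprintf("line %d: reference and alternate amino acid identical (%s%d%s); entry dropped",
                      ln, r, p, a), call. = FALSE)
      drop[i] <- TRUE
    }
    protein[i] <- trimws(f[1L]); gene[i] <- trimws(f[2L])
    position[i] <- p; ref[i] <- r; alt[i] <- a
  }
  out <- data.frame(protein = protein, gene = gene, position = position,
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  out[!drop, , drop = FALSE]
}

#' Write a mutation file
#'
#' Inverse of [read_mutation_file()]: emits one tab-separated line per
#' mutation, no header, so that write-then-read reproduces the input
#' field-for-field.
#'
#' @param mutations Data frame as returned by [read_mutation_file()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mutation_file <- function(mutations, path) {
  lines <- sprintf("%s\t%s\t%d\t%s\t%s", mutations$protein, mutations$gene,
                   mutations$position, mutations$ref, mutations$alt)
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein architecture file
#'
#' Each line names one domain: architecture name, start site, end site
#' (tab-separated, 1-based inclusive coordinates).
#'
#' @param path Path to a tab-separated architecture file.
#' @return A data frame with columns `name`, `start`, `end`, in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("Signal Peptide\t1\t24", "Transmembrane\t636\t653"), f)
#' read_architecture_file(f)
#' @export
read_architecture_file <- function(path) {
  tl <- read_tab_lines(path)
  if (detect_header(tl$fields, 2L)) {
    tl$fields <- tl$fields[-1L]
    tl$lineno <- tl$lineno[-1L]
  }
  n <- length(tl$fields)
  name <- character(n); start <- end <- integer(n)
  for (i in seq_len(n)) {
    f <- tl$fields[[i]]; ln <- tl$lineno[i]
    if (length(f) < 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields (name, start, end)", ln),
           call. = FALSE)
    if (!nzchar(trimws(f[1L])))
      stop(sprintf("line %d: empty domain name", ln), call. = FALSE)
    for (j in 2:3) if (!is_integerish(trimws(f[j])))
      stop(sprintf("line %d: domain bound '%s' is not an integer", ln, f[j]),
           call. = FALSE)
    s <- as.integer(trimws(f[2L])); e <- as.integer(trimws(f[3L]))
    if (s < 1L)
      stop(sprintf("line %d: domain '%s' start %d < 1", ln, f[1L], s), call. = FALSE)
    if (s > e)
      stop(sprintf("domain '%s': start exceeds end (%d > %d)", trimws(f[1L]), s, e),
           call. = FALSE)
    name[i] <- trimws(f[1L]); start[i] <- s; end[i] <- e
  }
  data.frame(name = name, start = start, end = end, stringsAsFactors = FALSE)
}

#' Write a protein architecture file
#' @param domains Data frame with columns `name`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_architecture_file <- function(domains, path) {
  writeLines(sprintf("%s\t%d\t%d", domains$name, domains$start, domains$end), path)
  invisible(path)
}

#' Read a post-translational modification file
#'
#' One site position per line (first tab-separated field). Duplicates are
#' preserved in file order.
#'
#' @param path Path to the PTM file.
#' @return Integer vector of 1-based site positions (may be empty).
#' @export
read_ptm_file <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$fields) == 0L) return(integer(0))
  if (detect_header(tl$fields, 1L)) {
    tl$fields <- tl$fields[-1L]
    tl$lineno <- tl$lineno[-1L]
  }
  out <- integer(length(tl$fields))
  for (i in seq_along(tl$fields)) {
    v <- trimws(tl$fields[[i]][1L]); ln <- tl$lineno[i]
    if (!is_integerish(v))
      stop(sprintf("line %d: PTM position '%s' is not an integer", ln, v),
           call. = FALSE)
    p <- as.integer(v)
    if (p < 1L)
      stop(sprintf("line %d: PTM position %d out of range (must be >= 1)", ln, p),
           call. = FALSE)
    out[i] <- p
  }
  out
}

#' Write a post-translational modification file
#' @param ptms Integer vector of site positions.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ptm_file <- function(ptms, path) {
  writeLines(sprintf("%d", as.integer(ptms)), path)
  invisible(path)
}

#' Read an aligned multi-FASTA
#'
#' Reads a multiple sequence alignment (e.g. MUSCLE output in FASTA
#' format) and designates one record as the reference against which
#' conservation is computed. Sequences are uppercased; '.' gap characters
#' are normalized to '-'. Identifiers are the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_id Identifier of the reference record.
#' @return An object of class `alignment_set`: a list with `seqs` (named
#'   character vector of equal-length aligned sequences) and
#'   `reference_id`.
#' @export
read_alignment <- function(path, reference_id) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           seqonly = FALSE)
  if (length(fa) == 0L) stop(sprintf("no sequences in %s", path), call. = FALSE)
  ids <- vapply(fa, function(s) attr(s, "name"), character(1))
  seqs <- toupper(vapply(fa, function(s) as.character(s)[1L], character(1)))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- ids
  alignment_set(seqs, reference_id)
}

#' Construct an alignment set
#'
#' @param seqs Named character vector of aligned sequences (equal length,
#'   '-' for gaps).
#' @param reference_id Name of the reference sequence.
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(seqs, reference_id) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
    bad <- names(seqs)[lens != modal]
    stop(sprintf("ragged alignment: sequence length differs for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  hits <- which(names(seqs) == reference_id)
  if (length(hits) == 0L)
    stop(sprintf("reference id '%s' not found; available: %s",
                 reference_id, paste(names(seqs), collapse = ", ")),
         call. = FALSE)
  if (length(hits) > 1L)
    stop(sprintf("reference id '%s' matches %d records", reference_id,
                 length(hits)), call. = FALSE)
  structure(list(seqs = seqs, reference_id = reference_id),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d sequences x %d columns, reference '%s'\n",
              length(x$seqs), nchar(x$seqs[[1L]]), x$reference_id))
  invisible(x)
}

#' Write an aligned multi-FASTA
#' @param alignment An `alignment_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path) {
  seqinr::write.fasta(as.list(alignment$seqs), names(alignment$seqs),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Validate inputs against a protein context
#'
#' Checks every mutation position, PTM position and domain interval
#' against the protein length. Validation never raises: it returns a
#' report that callers can inspect and act on.
#'
#' @param mutations Mutation data frame (may be `NULL`).
#' @param domains Architecture data frame (may be `NULL`).
#' @param ptms Integer vector of PTM positions (may be `NULL`).
#' @param context A [protein_context()].
#' @return A data frame with columns `input`, `label`, `message`, one row
#'   per violation; zero rows iff all records are in range.
#' @examples
#' ctx <- protein_context(1114, "RET")
#' m <- data.frame(protein = "RET", gene = "RET", position = 2000,
#'                 ref = "C", alt = "R")
#' validate_inputs(m, NULL, NULL, ctx)
#' @export
validate_inputs <- function(mutations = NULL, domains = NULL, ptms = NULL,
                            context) {
  stopifnot(inherits(context, "protein_context"))
  L <- context$length
  rows <- list()
  add <- function(input, label, msg)
    rows[[length(rows) + 1L]] <<- data.frame(input = input, label = label,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    bad <- which(mutations$position > L | mutations$position < 1L)
    for (i in bad)
      add("mutation",
          sprintf("%s%d%s", mutations$ref[i], mutations$position[i],
                  mutations$alt[i]),
          sprintf("position %d outside 1..%d", mutations$position[i], L))
  }
  if (!is.null(domains) && nrow(domains) > 0L) {
    bad <- which(domains$end > L | domains$start < 1L)
    for (i in bad)
      add("domain", domains$name[i],
          sprintf("interval [%d, %d] exceeds protein length %d",
                  domains$start[i], domains$end[i], L))
  }
  if (!is.null(ptms) && length(ptms) > 0L) {
    bad <- which(ptms > L | ptms < 1L)
    for (i in bad)
      add("ptm", sprintf("site %d", ptms[i]),
          sprintf("position %d outside 1..%d", ptms[i], L))
  }
  if (length(rows) == 0L)
    return(data.frame(input = character(0), label = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
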