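# Synthetic inputs. Every generator runs on its own seeded random stream
# (the caller's .Random.seed is saved and restored), so fixtures are
# reproducible and never perturb global state. The RET-like fixture
# mirrors the published case study: four domains (Signal Peptide 1-24,
# Cadherin 191-270, Transmembrane 636-653, Tyrosine Kinase 724-1005), a
# broad mutation set spread over the protein, and a clustered set of
# cysteine substitutions just N-terminal of the transmembrane start, the
# MEN2A pattern.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configure a synthetic fixture
#'
#' @param protein_length Protein length in amino acids.
#' @param n_mutations Number of mutations to simulate.
#' @param cluster Optional `list(center =, half_width =, fraction =)`:
#'   a fraction of mutations is drawn uniformly from
#'   `[center - half_width, center + half_width]`, the rest uniformly
#'   over the whole protein.
#' @param n_alignment_sequences Number of sequences in a simulated
#'   alignment, including the reference (>= 2).
#' @param identity_profile Per-position probability `q_p` that a
#'   non-reference sequence matches the reference; length must equal
#'   `protein_length`. Default 0.9 everywhere.
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(protein_length, n_mutations = 0L, cluster = NULL,
                           n_alignment_sequences = 2L,
                           identity_profile = rep(0.9, protein_length),
                           seed = 1L) {
  protein_length <- as.integer(protein_length)
  stopifnot(protein_length >= 1L, n_mutations >= 0L)
  if (!is.null(cluster)) {
    stopifnot(all(c("center", "half_width", "fraction") %in% names(cluster)))
    lo <- cluster$center - cluster$half_width
    hi <- cluster$center + cluster$half_width
    if (lo < 1L || hi > protein_length)
      stop(sprintf("cluster window [%d, %d] outside protein 1..%d",
                   lo, hi, protein_length), call. = FALSE)
    if (cluster$fraction < 0 || cluster$fraction > 1)
      stop("cluster fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(identity_profile) != protein_length)
    stop("identity_profile length must equal protein_length", call. = FALSE)
  if (any(identity_profile < 0 | identity_profile > 1))
    stop("identity_profile values must lie in [0, 1]", call. = FALSE)
  structure(list(protein_length = protein_length,
                 n_mutations = as.integer(n_mutations), cluster = cluster,
                 n_alignment_sequences = as.integer(n_alignment_sequences),
                 identity_profile = identity_profile, seed = as.integer(seed)),
            class = "fixture_config")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Simulate a mutation set
#'
#' Draws `n_mutations` positions — optionally with a clustered fraction —
#' and reference/alternate residues uniformly from the 20 amino acids
#' with ref != alt. Deterministic for a fixed seed.
#'
#' @param config A [fixture_config()].
#' @param protein,gene Names written into every record.
#' @return A mutation data frame (see [read_mutation_file()]).
#' @export
simulate_mutations <- function(config, protein = "SYNTH", gene = "SYNTH") {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_mutations
  if (n == 0L)
    return(data.frame(protein = character(0), gene = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  with_local_seed(config$seed, {
    if (!is.null(config$cluster)) {
      k <- round(config$cluster$fraction * n)
      lo <- config$cluster$center - config$cluster$half_width
      hi <- config$cluster$center + config$cluster$half_width
      pos <- c(sample(lo:hi, k, replace = TRUE),
               sample.int(config$protein_length, n - k, replace = TRUE))
    } else {
      pos <- sample.int(config$protein_length, n, replace = TRUE)
    }
    ref <- sample(AA20, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L), character(1))
    data.frame(protein = protein, gene = gene, position = as.integer(pos),
               ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  })
}

#' Simulate an alignment with controlled per-position identity
#'
#' The reference sequence is drawn uniformly over the 20 amino acids;
#' each non-reference sequence independently matches the reference at
#' position `p` with probability `identity_profile[p]` and otherwise
#' carries a uniformly chosen different residue. With `gap_rate > 0`,
#' non-reference characters are further replaced by gaps at that rate
#' (gaps count as mismatches in conservation scoring). No gaps are
#' placed in the reference, so alignment columns equal protein positions.
#'
#' @param config A [fixture_config()].
#' @param gap_rate Per-character probability of a gap in non-reference
#'   sequences (default 0).
#' @return An `alignment_set` whose reference is named `"reference"`.
#' @export
simulate_alignment <- function(config, gap_rate = 0) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_alignment_sequences < 2L)
    stop("n_alignment_sequences must be >= 2", call. = FALSE)
  L <- config$protein_length
  q <- config$identity_profile
  with_local_seed(config$seed, {
    ref <- sample(AA20, L, replace = TRUE)
    nseq <- config$n_alignment_sequences - 1L
    seqs <- character(nseq)
    for (i in seq_len(nseq)) {
      match_p <- stats::runif(L) < q
      chars <- ref
      for (j in which(!match_p))
        chars[j] <- sample(setdiff(AA20, ref[j]), 1L)
      if (gap_rate > 0) {
        gap <- stats::runif(L) < gap_rate
        chars[gap] <- GAP_CHAR
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    all <- c(paste(ref, collapse = ""), seqs)
    names(all) <- c("reference", sprintf("seq%d", seq_len(nseq)))
    alignment_set(all, "reference")
  })
}

# The MEN2A-style clustered cysteine substitutions: extracellular
# cysteines just N-terminal of the transmembrane start at 636.
RET_CLUSTER_POSITIONS <- c(609L, 611L, 618L, 620L, 630L, 634L)

#' A RET-like demonstration fixture
#'
#' Deterministic synthetic inputs shaped like the published RET case
#' study: the four annotated domains, a broad mutation set distributed
#' over the whole protein ("all disease mutations"), a clustered set of
#' cysteine substitutions immediately N-terminal of the transmembrane
#' domain (the MEN2A pattern), and a handful of intracellular PTM sites.
#' The protein length defaults to 1114 residues and is a parameter, not a
#' constant.
#'
#' @param length Protein length (>= 1005, so the Tyrosine Kinase domain
#'   fits).
#' @param n_background Number of broadly distributed mutations.
#' @param seed Seed for the background mutation draw.
#' @return A list with elements `mutations` (broad set),
#'   `mutations_secondary` (clustered MEN2A-like set), `domains`, `ptms`
#'   and `context`.
#' @examples
#' fx <- make_ret_like_fixture()
#' fx$domains
#' @export
make_ret_like_fixture <- function(length = 1114L, n_background = 40L,
                                  seed = 2013L) {
  length <- as.integer(length)
  if (length < 1005L)
    stop("length must be >= 1005 so all four domains fit", call. = FALSE)
  domains <- data.frame(
    name = c("Signal Peptide", "Cadherin", "Transmembrane", "Tyrosine Kinase"),
    start = c(1L, 191L, 636L, 724L),
    end = c(24L, 270L, 653L, 1005L),
    stringsAsFactors = FALSE)
  cfg <- fixture_config(protein_length = length, n_mutations = n_background,
                        seed = seed)
  mutations <- simulate_mutations(cfg, protein = "RET-like", gene = "RET-like")
  cluster <- data.frame(protein = "RET-like", gene = "RET-like",
                        position = RET_CLUSTER_POSITIONS,
                        ref = "C",
                        alt = c("R", "Y", "S", "R", "F", "W"),
                        stringsAsFactors = FALSE)
  ptms <- c(687L, 696L, 905L, 981L, 1015L)
  ptms <- ptms[ptms <= length]
  list(mutations = mutations, mutations_secondary = cluster,
       domains = domains, ptms = ptms,
       context = protein_context(length, "RET-like"))
}
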