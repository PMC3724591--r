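# Shared test helpers: tiny file writers and independent brute-force
# oracles kept deliberately separate from the package's own code paths.

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# An aligned FASTA file from a named character vector of sequences.
write_fasta_tmp <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), f)
  f
}

mutation_df <- function(position, ref = "C", alt = "R", protein = "P",
                        gene = "G") {
  data.frame(protein = protein, gene = gene, position = as.integer(position),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# Brute-force conservation oracle: per reference residue, walk every
# other sequence character by character.
oracle_conservation <- function(seqs, reference_id) {
  chars <- strsplit(seqs, "")
  ref <- chars[[reference_id]]
  others <- chars[names(seqs) != reference_id]
  pos <- 0L
  out <- NULL
  for (col in seq_along(ref)) {
    if (ref[col] == "-") next
    pos <- pos + 1L
    n <- 0L
    for (s in others) if (s[col] == ref[col]) n <- n + 1L
    out <- rbind(out, data.frame(position = pos, ref_letter = ref[col],
                                 n = n, t = length(others),
                                 score = n / length(others)))
  }
  out
}

# Brute-force domain containment oracle.
oracle_domains_hit <- function(position, domains) {
  hits <- character(0)
  for (i in seq_len(nrow(domains)))
    if (domains$start[i] <= position && position <= domains$end[i])
      hits <- c(hits, domains$name[i])
  hits
}

count_svg_nodes <- function(path, xpath) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  length(xml2::xml_find_all(doc, xpath))
}
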