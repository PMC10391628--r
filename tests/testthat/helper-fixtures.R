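# Shared fixture builders and partition-comparison helpers.

# Minimal rearrangement records with sensible defaults; any field can be
# overridden with a vector recycled to n.
make_records <- function(n, sample_id = "s1",
                         v_call = "IGHV1*01", d_call = "IGHD1*01",
                         j_call = "IGHJ1*01",
                         junction = "TGTGCGAGATGG",
                         junction_aa = "CARW",
                         c_call = "IGHM",
                         sequence_alignment = NULL,
                         germline_alignment = NULL,
                         productive = TRUE, consensus_count = 1L) {
  germ <- paste0("ATGGCTGCAAAA", "TGTGCGAGATGG", "CTGGTG")
  df <- data.frame(
    sequence_id = sprintf("%s_seq%03d", rep_len(sample_id, n), seq_len(n)),
    sample_id = rep_len(sample_id, n),
    v_call = rep_len(v_call, n),
    d_call = rep_len(d_call, n),
    j_call = rep_len(j_call, n),
    junction = rep_len(junction, n),
    junction_aa = rep_len(junction_aa, n),
    c_call = rep_len(c_call, n),
    sequence_alignment = rep_len(sequence_alignment %||% germ, n),
    germline_alignment = rep_len(germline_alignment %||% germ, n),
    productive = rep_len(productive, n),
    consensus_count = rep_len(as.integer(consensus_count), n),
    stringsAsFactors = FALSE
  )
  df$isotype <- bcraging::collapse_isotype(df$c_call)
  df
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random in-frame junction of len_aa amino acids
random_junction_nt <- function(len_aa) {
  codons <- names(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])
  paste(c("TGT", sample(codons, len_aa - 2, replace = TRUE), "TGG"),
        collapse = "")
}

# records with random V/J/junction structure for clone-assignment oracles
random_clone_records <- function(n, n_v = 4, n_j = 3, len_aa_pool = 5:7,
                                 sample_id = "s1") {
  jx <- vapply(seq_len(n), function(i) {
    len <- if (length(len_aa_pool) == 1) len_aa_pool else sample(len_aa_pool, 1)
    random_junction_nt(len)
  }, character(1))
  translate_nt <- function(nt) {
    paste(Biostrings::GENETIC_CODE[substring(nt, seq(1, nchar(nt) - 2, 3),
                                             seq(3, nchar(nt), 3))],
          collapse = "")
  }
  make_records(
    n, sample_id = sample_id,
    v_call = sample(paste0("IGHV", seq_len(n_v)), n, replace = TRUE),
    j_call = sample(paste0("IGHJ", seq_len(n_j)), n, replace = TRUE),
    junction = jx,
    junction_aa = vapply(jx, translate_nt, character(1))
  )
}

# TRUE iff two cluster labellings describe the same partition (Rand == 1)
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# small clone_partition built from a vector of clone sizes
partition_from_sizes <- function(sizes, sample_id = "s1") {
  clone_id <- rep(sprintf("c%03d", seq_along(sizes)), sizes)
  recs <- make_records(sum(sizes), sample_id = sample_id)
  recs$junction_aa <- paste0("CAR", clone_id)  # distinct triples per clone
  bcraging::assign_clones_identity(recs)
}
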