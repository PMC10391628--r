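# Affinity-maturation profiling: somatic hypermutation (synonymous vs
# non-synonymous against the inferred germline), class-switch staging of
# clones, isotype composition, and CDR3-length Gaussian statistics.

BASE_RAW <- charToRaw("ACGT")

#' Count synonymous and non-synonymous mutations in one alignment
#'
#' Compares an observed sequence to its inferred germline over equal-length
#' alignment strings. Positions inside the junction span are excluded (the
#' junction defines clonal identity and is analysed separately); positions
#' where either string carries a gap (`.` or `-`) or `N`, or whose germline
#' codon is incomplete or ambiguous, are excluded from the informative set.
#' Each mismatch is classified by translating the germline codon with and
#' without the substitution, the other codon positions taken from the
#' germline (the single-substitution approximation); substitutions creating
#' a stop codon count as non-synonymous.
#'
#' @param sequence_alignment Observed aligned nucleotide string.
#' @param germline_alignment Germline aligned string (same length).
#' @param junction_span Optional `c(start, end)` of the junction in
#'   1-based alignment coordinates; `NULL` when no junction lies in the
#'   alignment.
#' @param frame_offset Reading-frame offset of the alignment, 0/1/2.
#' @return List: `n_syn`, `n_nonsyn`, `n_informative`, `freq_syn`,
#'   `freq_nonsyn` (mutations per informative position).
#' @export
count_shm <- function(sequence_alignment, germline_alignment,
                      junction_span = NULL, frame_offset = 0L) {
  if (nchar(sequence_alignment) != nchar(germline_alignment)) {
    stop("sequence_alignment and germline_alignment differ in length")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  L <- nchar(sequence_alignment)
  s <- charToRaw(toupper(sequence_alignment))
  g <- charToRaw(toupper(germline_alignment))
  in_junction <- rep(FALSE, L)
  if (!is.null(junction_span)) {
    if (junction_span[1] < 1 || junction_span[2] > L ||
        junction_span[1] > junction_span[2]) {
      stop("junction_span outside the alignment")
    }
    in_junction[junction_span[1]:junction_span[2]] <- TRUE
  }
  valid <- (s %in% BASE_RAW) & (g %in% BASE_RAW)
  # positions whose germline codon is not fully resolved cannot be classified
  codon_start <- frame_offset + 1L + 3L * ((seq_len(L) - frame_offset - 1L) %/% 3L)
  codon_start[seq_len(L) <= frame_offset] <- NA_integer_
  g_ok <- g %in% BASE_RAW
  codon_ok <- !is.na(codon_start) & (codon_start + 2L) <= L
  cs <- codon_start[codon_ok]
  codon_ok[codon_ok] <- g_ok[cs] & g_ok[cs + 1L] & g_ok[cs + 2L]
  informative <- valid & codon_ok & !in_junction
  n_informative <- sum(informative)

  mismatch <- which(informative & (s != g))
  n_syn <- 0L
  n_nonsyn <- 0L
  gc_tab <- Biostrings::GENETIC_CODE
  for (p in mismatch) {
    cs <- codon_start[p]
    germ_codon <- rawToChar(g[cs:(cs + 2L)])
    mut <- g[cs:(cs + 2L)]
    mut[p - cs + 1L] <- s[p]
    mut_codon <- rawToChar(mut)
    if (identical(gc_tab[[germ_codon]], gc_tab[[mut_codon]])) {
      n_syn <- n_syn + 1L
    } else {
      n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(n_syn = n_syn, n_nonsyn = n_nonsyn, n_informative = n_informative,
       freq_syn = if (n_informative > 0) n_syn / n_informative else NA_real_,
       freq_nonsyn = if (n_informative > 0) n_nonsyn / n_informative
                     else NA_real_)
}

#' Per-sequence mutation profiles for a record set
#'
#' Applies [count_shm()] to every record. The junction span is taken from
#' `junction_start`/`junction_end` columns when present, otherwise located
#' as the first occurrence of the junction string in the germline alignment.
#'
#' @param records Rearrangement `data.frame`.
#' @param frame_offset Reading-frame offset (default 0).
#' @return `data.frame`: `sequence_id`, `sample_id`, `n_syn`, `n_nonsyn`,
#'   `n_informative`, `freq_syn`, `freq_nonsyn`.
#' @export
shm_profiles <- function(records, frame_offset = 0L) {
  n <- nrow(records)
  have_span <- all(c("junction_start", "junction_end") %in% names(records))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    span <- if (have_span && !is.na(records$junction_start[i])) {
      c(records$junction_start[i], records$junction_end[i])
    } else if (!is.na(records$junction[i]) && nzchar(records$junction[i])) {
      hit <- regexpr(records$junction[i], records$germline_alignment[i],
                     fixed = TRUE)
      if (hit > 0) c(hit, hit + attr(hit, "match.length") - 1L) else NULL
    } else {
      NULL
    }
    prof <- count_shm(records$sequence_alignment[i],
                      records$germline_alignment[i],
                      junction_span = span, frame_offset = frame_offset)
    out[[i]] <- prof
  }
  data.frame(
    sequence_id = records$sequence_id,
    sample_id = records$sample_id,
    n_syn = vapply(out, `[[`, integer(1), "n_syn"),
    n_nonsyn = vapply(out, `[[`, integer(1), "n_nonsyn"),
    n_informative = vapply(out, `[[`, integer(1), "n_informative"),
    freq_syn = vapply(out, `[[`, numeric(1), "freq_syn"),
    freq_nonsyn = vapply(out, `[[`, numeric(1), "freq_nonsyn"),
    stringsAsFactors = FALSE
  )
}

CSR_STAGES <- c("IgM+IgD+SHM-", "IgM+IgD+SHM+", "IgM-IgD-")

#' Class-switch stage of one clone
#'
#' A clone with at least one IgM or IgD member is unswitched (`IgM+IgD+`),
#' split into naive (`SHM-`) vs antigen-stimulated (`SHM+`) by whether any
#' member carries at least `shm_min_mutations` mutations; a clone with no
#' naive isotypes is post-antigenic (`IgM-IgD-`).
#'
#' @param isotypes Character vector of member isotype classes.
#' @param total_mutations Integer vector of member mutation counts
#'   (syn + nonsyn), aligned with `isotypes`.
#' @param shm_min_mutations Minimum mutations for SHM-positive (default 1).
#' @return One of `"IgM+IgD+SHM-"`, `"IgM+IgD+SHM+"`, `"IgM-IgD-"`.
#' @export
stage_clone <- function(isotypes, total_mutations, shm_min_mutations = 1L) {
  keep <- !is.na(isotypes)
  if (any(!keep)) {
    warning(sprintf("ignoring %d member(s) with missing isotype", sum(!keep)))
  }
  isotypes <- isotypes[keep]
  total_mutations <- total_mutations[keep]
  if (length(isotypes) == 0) stop("clone has no members with an isotype")
  if (any(isotypes %in% c("IgM", "IgD"))) {
    if (any(total_mutations >= shm_min_mutations, na.rm = TRUE)) {
      "IgM+IgD+SHM+"
    } else {
      "IgM+IgD+SHM-"
    }
  } else {
    "IgM-IgD-"
  }
}

#' Class-switch stages for every clone of a partition
#'
#' @param partition A `clone_partition`.
#' @param profiles Per-sequence mutation profiles from [shm_profiles()].
#' @param shm_min_mutations Minimum mutations for SHM-positive (default 1).
#' @return `data.frame`: `clone_id`, `sample_id`, `stage`.
#' @export
stage_clones <- function(partition, profiles, shm_min_mutations = 1L) {
  mem <- partition$membership
  mut <- profiles$n_syn + profiles$n_nonsyn
  mut <- mut[match(mem$sequence_id, profiles$sequence_id)]
  stages <- vapply(split(seq_len(nrow(mem)), mem$clone_id), function(idx) {
    stage_clone(mem$isotype[idx], mut[idx], shm_min_mutations)
  }, character(1))
  data.frame(clone_id = names(stages), sample_id = partition$sample_id,
             stage = unname(stages), stringsAsFactors = FALSE)
}

#' Fractions of clones per class-switch stage
#'
#' @param stages Output of [stage_clones()].
#' @return Named numeric vector over the three stages (sums to 1).
#' @export
stage_fractions <- function(stages) {
  tab <- table(factor(stages$stage, levels = CSR_STAGES))
  setNames(as.numeric(tab) / nrow(stages), CSR_STAGES)
}

#' Isotype composition of a sample
#'
#' Fraction of classified records (or, with `weight = TRUE`, of total UMI
#' consensus counts) per isotype class.
#'
#' @param records Rearrangement `data.frame` of one sample.
#' @param weight Weight records by `consensus_count` (default `FALSE`).
#' @return Named numeric vector over `{IgM, IgD, IgG, IgE, IgA}`, summing
#'   to 1.
#' @export
isotype_fractions <- function(records, weight = FALSE) {
  keep <- !is.na(records$isotype)
  if (!any(keep)) stop("no records with a classified isotype")
  iso <- factor(records$isotype[keep], levels = ISOTYPE_CLASSES)
  w <- if (weight) records$consensus_count[keep] else rep(1, sum(keep))
  tot <- tapply(w, iso, sum, default = 0)
  setNames(as.numeric(tot) / sum(w), ISOTYPE_CLASSES)
}

#' Gaussian statistics of CDR3 (junction) amino-acid lengths
#'
#' Maximum-likelihood Gaussian location with the conventional
#' n-1-denominator standard deviation (the denominator convention is
#' recorded in the result).
#'
#' @param lengths Numeric vector of junction amino-acid lengths (>= 2).
#' @return List: `mean`, `sd`, `n`, `sd_denominator`.
#' @export
cdr3_stats <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) < 2) stop("need >= 2 lengths for a Gaussian fit")
  list(mean = mean(lengths), sd = sd(lengths), n = length(lengths),
       sd_denominator = "n-1")
}

#' Between-replicate variability of per-sample CDR3 means
#'
#' The standard deviation of per-mouse mean lengths within each group.
#'
#' @param sample_means Numeric vector of per-sample mean lengths.
#' @param groups Grouping vector (e.g. diet x age), same length.
#' @return `data.frame`: `group`, `between_sd`, `n`.
#' @export
cdr3_group_variability <- function(sample_means, groups) {
  out <- lapply(split(sample_means, groups), function(v) {
    data.frame(between_sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  })
  res <- do.call(rbind, out)
  data.frame(group = names(out), between_sd = res$between_sd, n = res$n,
             stringsAsFactors = FALSE, row.names = NULL)
}
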