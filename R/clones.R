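# Clone inference: partition a sample's rearrangements into clonal lineages.
#
# Two modes are supported. The default "identity" rule groups sequences
# sharing the same V gene, the same J gene, and an identical CDR3
# (junction) amino-acid sequence. The "threshold" rule performs
# single-linkage clustering of junction nucleotide sequences within
# V/J/junction-length groups at a sample-specific normalized Hamming
# distance threshold detected from the distance-to-nearest distribution.

# internal: gene-level call — first listed assignment, allele suffix stripped
gene_call <- function(call) {
  first <- sub(",.*$", "", as.character(call))
  sub("\\*.*$", "", first)
}

new_clone_partition <- function(sample_id, clones, membership, mode,
                                threshold = NA_real_) {
  structure(list(sample_id = sample_id, clones = clones,
                 membership = membership, mode = mode, threshold = threshold),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat(sprintf("clone_partition: sample %s, %d clones over %d records (%s mode%s)\n",
              x$sample_id, nrow(x$clones), nrow(x$membership), x$mode,
              if (x$mode == "threshold")
                sprintf(", threshold %.4f", x$threshold) else ""))
  invisible(x)
}

# internal: shared scaffolding — drop records with empty junction_aa
prepare_clone_records <- function(records) {
  bad <- is.na(records$junction_aa) | !nzchar(records$junction_aa)
  if (any(bad)) {
    warning(sprintf("excluded %d record(s) with empty junction_aa: %s",
                    sum(bad),
                    paste(records$sequence_id[bad], collapse = ", ")))
    records <- records[!bad, , drop = FALSE]
  }
  records
}

build_partition <- function(records, clone_id, mode, threshold = NA_real_) {
  membership <- data.frame(
    sequence_id = records$sequence_id,
    clone_id = clone_id,
    isotype = if ("isotype" %in% names(records)) records$isotype
              else NA_character_,
    consensus_count = if ("consensus_count" %in% names(records))
      records$consensus_count else 1L,
    stringsAsFactors = FALSE
  )
  first <- !duplicated(clone_id)
  clones <- data.frame(
    clone_id = clone_id[first],
    sample_id = records$sample_id[first],
    v_call = gene_call(records$v_call[first]),
    j_call = gene_call(records$j_call[first]),
    junction_aa = records$junction_aa[first],
    stringsAsFactors = FALSE
  )
  sizes <- table(clone_id)
  wsizes <- tapply(membership$consensus_count, clone_id, sum)
  clones$size <- as.integer(sizes[clones$clone_id])
  clones$weighted_size <- as.integer(wsizes[clones$clone_id])
  clones <- clones[order(-clones$size, clones$clone_id), , drop = FALSE]
  rownames(clones) <- NULL
  new_clone_partition(records$sample_id[1], clones, membership, mode,
                      threshold)
}

#' Assign clones by V/J gene and CDR3 amino-acid identity
#'
#' Two records share a clone iff their (V gene, J gene, junction amino-acid
#' sequence) triples are equal. Gene calls are taken at gene level (allele
#' suffixes stripped; of multiple comma-separated assignments the first is
#' used). Records with an empty `junction_aa` are excluded with a warning.
#' Clone ids are the triple itself, hence stable across runs.
#'
#' @param records Rearrangement `data.frame` of one sample.
#' @return A `clone_partition` (fields `clones`, `membership`, `mode`).
#' @export
assign_clones_identity <- function(records) {
  records <- prepare_clone_records(records)
  if (nrow(records) == 0) stop("no records with a junction_aa to partition")
  key <- paste(gene_call(records$v_call), gene_call(records$j_call),
               records$junction_aa, sep = "_")
  build_partition(records, key, mode = "identity")
}

# internal: group keys for nucleotide-distance operations
vjl_group <- function(records) {
  paste(gene_call(records$v_call), gene_call(records$j_call),
        nchar(records$junction), sep = "_")
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Distance to nearest junction neighbour
#'
#' For each record, the minimal normalized Hamming distance between its
#' junction and any other junction in the same (V gene, J gene, junction
#' length) group. Records alone in their group have no defined distance and
#' are excluded.
#'
#' @param records Rearrangement `data.frame` of one sample.
#' @return `data.frame` with `sequence_id` and `dist_nearest`.
#' @export
distance_to_nearest <- function(records) {
  records <- prepare_clone_records(records)
  grp <- vjl_group(records)
  out <- lapply(split(seq_len(nrow(records)), grp), function(idx) {
    if (length(idx) < 2) return(NULL)
    jx <- records$junction[idx]
    L <- nchar(jx[1])
    m <- matrix(unlist(lapply(jx, charToRaw)), nrow = L)
    d <- vapply(seq_along(idx), function(i) {
      mism <- colSums(m != m[, i])
      min(mism[-i]) / L
    }, numeric(1))
    data.frame(sequence_id = records$sequence_id[idx], dist_nearest = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    warning("fewer than 2 comparable records in every group; no distances")
    return(data.frame(sequence_id = character(0), dist_nearest = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect a sample-specific clustering threshold
#'
#' Fits a Gaussian kernel density to the distance-to-nearest distribution
#' and returns the location of the density minimum between the two largest
#' modes. A unimodal (or degenerate) distribution returns the configured
#' fallback with attribute `unimodal = TRUE` and a warning.
#'
#' @param distances Numeric vector of nearest-neighbour distances.
#' @param fallback Threshold returned when no valley exists (default 0.1).
#' @return Threshold in `[0, 1]`, with attribute `unimodal`.
#' @export
find_threshold <- function(distances, fallback = 0.1) {
  d <- distances[is.finite(distances)]
  if (length(d) < 50) {
    stop("need >= 50 finite distances to detect a threshold; ",
         "use identity mode instead")
  }
  if (sd(d) == 0) {
    warning("degenerate distance distribution; using fallback threshold")
    return(structure(fallback, unimodal = TRUE))
  }
  den <- density(d, kernel = "gaussian", n = 512, from = 0,
                 to = max(d) + sd(d))
  y <- den$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2) {
    warning("unimodal distance distribution; using fallback threshold")
    return(structure(fallback, unimodal = TRUE))
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  structure(min(max(den$x[valley], 0), 1), unimodal = FALSE)
}

#' Assign clones by single-linkage clustering at a distance threshold
#'
#' Within each (V gene, J gene, junction length) group, junction nucleotide
#' sequences are clustered by single linkage; two records are clonally
#' related when connected by a chain of pairs at normalized Hamming
#' distance <= `threshold`.
#'
#' @param records Rearrangement `data.frame` of one sample.
#' @param threshold Normalized Hamming distance threshold in `(0, 1]`
#'   (0 is accepted as the degenerate identical-junction limit).
#' @return A `clone_partition` with `mode = "threshold"`.
#' @export
assign_clones_threshold <- function(records, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  records <- prepare_clone_records(records)
  if (nrow(records) == 0) stop("no records with a junction_aa to partition")
  grp <- vjl_group(records)
  clone_id <- character(nrow(records))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    jx <- records$junction[idx]
    if (length(idx) == 1) {
      comp <- 1L
    } else {
      ujx <- unique(jx)
      if (length(ujx) == 1) {
        comp <- rep(1L, length(idx))
      } else {
        L <- nchar(ujx[1])
        m <- matrix(unlist(lapply(ujx, charToRaw)), nrow = L)
        dm <- matrix(0, length(ujx), length(ujx))
        for (i in seq_along(ujx)) {
          dm[, i] <- colSums(m != m[, i]) / L
        }
        hc <- hclust(as.dist(dm), method = "single")
        ucomp <- cutree(hc, h = threshold + 1e-12)
        comp <- ucomp[match(jx, ujx)]
      }
    }
    # stable component labels: smallest junction string in the component
    rep_jx <- tapply(jx, comp, min)
    clone_id[idx] <- paste(g, rep_jx[as.character(comp)], sep = "_")
  }
  build_partition(records, clone_id, mode = "threshold",
                  threshold = threshold)
}

#' Clone abundance vector of a partition
#'
#' @param partition A `clone_partition`.
#' @param by Count member records (`"records"`, default) or sum their UMI
#'   consensus counts (`"consensus_count"`).
#' @param isotype Optional isotype class; abundances are then computed over
#'   the records of that class only (clones absent from the slice drop out).
#' @return Named numeric vector of clone sizes.
#' @export
clone_abundances <- function(partition, by = c("records", "consensus_count"),
                             isotype = NULL) {
  by <- match.arg(by)
  mem <- partition$membership
  if (!is.null(isotype)) {
    mem <- mem[!is.na(mem$isotype) & mem$isotype == isotype, , drop = FALSE]
  }
  if (nrow(mem) == 0) return(setNames(numeric(0), character(0)))
  w <- if (by == "records") rep(1, nrow(mem)) else mem$consensus_count
  ab <- tapply(w, mem$clone_id, sum)
  setNames(as.numeric(ab), names(ab))
}

#' Clone summary table of a partition
#'
#' @param partition A `clone_partition`.
#' @return `data.frame`: clone_id, sample_id, size, weighted_size, v_call,
#'   j_call, junction_aa, mode.
#' @export
clone_table <- function(partition) {
  out <- partition$clones
  out$mode <- partition$mode
  out[, c("clone_id", "sample_id", "size", "weighted_size", "v_call",
          "j_call", "junction_aa", "mode")]
}
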