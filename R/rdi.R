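# Repertoire Dissimilarity Index (RDI).
#
# Five-step procedure: (1) subsample each repertoire to a uniform depth,
# (2) count the abundance of each feature (V, D and J gene segments),
# (3) normalize the counts, (4) compare repertoires pairwise, (5) take the
# Euclidean distance — repeated (default 100 times) and averaged.
#
# Default normalization is within-segment proportions (the V, D and J
# blocks each sum to 1; the D block is computed over records with a D call
# and renormalized, so unidentifiable D segments do not contribute a
# spurious feature). A log2(x + pseudocount) block-centred variant is
# available via `normalization = "log"`.

# internal: the fixed shared feature space over one or more record sets
build_feature_space <- function(record_list, features = c("v", "d", "j"),
                                reference = NULL) {
  get_genes <- function(col) {
    found <- sort(unique(unlist(lapply(record_list, function(r) {
      g <- gene_call(r[[col]])
      g[!is.na(g) & nzchar(g)]
    }))))
    found
  }
  space <- list()
  if ("v" %in% features) space$v <- get_genes("v_call")
  if ("d" %in% features) space$d <- get_genes("d_call")
  if ("j" %in% features) space$j <- get_genes("j_call")
  if (!is.null(reference)) {
    lens <- reference$lengths
    if (!is.null(space$v)) space$v <- sort(union(space$v, lens$name[lens$segment == "V"]))
    if (!is.null(space$d)) space$d <- sort(union(space$d, lens$name[lens$segment == "D"]))
    if (!is.null(space$j)) space$j <- sort(union(space$j, lens$name[lens$segment == "J"]))
  }
  space
}

count_block <- function(calls, genes) {
  g <- gene_call(calls)
  g <- g[!is.na(g) & nzchar(g)]
  tab <- table(factor(g, levels = genes))
  as.numeric(tab)
}

normalize_block <- function(counts, normalization, pseudocount = 0.5) {
  if (normalization == "proportion") {
    s <- sum(counts)
    if (s == 0) return(counts)
    counts / s
  } else {
    x <- log2(counts + pseudocount)
    x - mean(x)
  }
}

#' Gene-segment usage counts of one subsample
#'
#' Subsamples `depth` records without replacement and counts gene-segment
#' occurrences over a fixed feature space (absent features count 0; records
#' without a D call contribute no D feature).
#'
#' @param records Rearrangement `data.frame` of one sample.
#' @param depth Subsample depth (`<=` record count).
#' @param seed Integer seed.
#' @param features Segment subsets to use (default `c("v", "d", "j")`).
#' @param feature_space Optional precomputed space from the compared set;
#'   defaults to the genes present in `records`.
#' @return List with per-segment count vectors (`v`, `d`, `j`) and the
#'   subsample `depth`.
#' @export
usage_counts <- function(records, depth, seed = 1L,
                         features = c("v", "d", "j"), feature_space = NULL) {
  n <- nrow(records)
  if (depth > n) {
    stop(sprintf("depth %d exceeds record count %d", depth, n))
  }
  space <- feature_space %||% build_feature_space(list(records), features)
  set.seed(seed)
  idx <- if (depth == n) seq_len(n) else sample.int(n, depth)
  sub <- records[idx, , drop = FALSE]
  counts <- list()
  if (!is.null(space$v)) counts$v <- setNames(count_block(sub$v_call, space$v), space$v)
  if (!is.null(space$d)) counts$d <- setNames(count_block(sub$d_call, space$d), space$d)
  if (!is.null(space$j)) counts$j <- setNames(count_block(sub$j_call, space$j), space$j)
  c(counts, list(depth = depth))
}

# internal: one normalized usage vector from a subsample index set
usage_vector_at <- function(records, idx, space, normalization) {
  sub <- records[idx, , drop = FALSE]
  blocks <- list()
  if (!is.null(space$v)) {
    blocks$v <- normalize_block(count_block(sub$v_call, space$v), normalization)
  }
  if (!is.null(space$d)) {
    blocks$d <- normalize_block(count_block(sub$d_call, space$d), normalization)
  }
  if (!is.null(space$j)) {
    blocks$j <- normalize_block(count_block(sub$j_call, space$j), normalization)
  }
  unlist(blocks, use.names = FALSE)
}

#' Averaged RDI between two repertoires
#'
#' Per repeat, each sample is independently subsampled to `depth`, usage
#' counts are normalized, and the Euclidean distance between the two usage
#' vectors is taken; the mean over `n_repeats` is returned. Subsample
#' streams are keyed by sample-id order, so the value is symmetric in its
#' arguments under a shared seed.
#'
#' @param records_a,records_b Rearrangement `data.frame`s of two samples.
#' @param depth Subsample depth (both samples must have `>= depth` records).
#' @param n_repeats Number of subsample repeats (default 100).
#' @param seed Integer seed.
#' @param normalization `"proportion"` (default) or `"log"`.
#' @param features Segment subsets (default V + D + J).
#' @param feature_space Optional shared feature space.
#' @return Mean RDI (numeric scalar).
#' @export
rdi_pair <- function(records_a, records_b, depth, n_repeats = 100L,
                     seed = 1L, normalization = c("proportion", "log"),
                     features = c("v", "d", "j"), feature_space = NULL) {
  normalization <- match.arg(normalization)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  for (r in list(records_a, records_b)) {
    if (nrow(r) < depth) {
      stop(sprintf("sample %s has %d records, below depth %d",
                   r$sample_id[1], nrow(r), depth))
    }
  }
  space <- feature_space %||%
    build_feature_space(list(records_a, records_b), features)
  ids <- c(records_a$sample_id[1], records_b$sample_id[1])
  slot <- rank(ids, ties.method = "first")  # order-independent stream keys
  dists <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + 2L * r + slot[1])
    ia <- sample.int(nrow(records_a), depth)
    set.seed(seed + 2L * r + slot[2])
    ib <- sample.int(nrow(records_b), depth)
    ua <- usage_vector_at(records_a, ia, space, normalization)
    ub <- usage_vector_at(records_b, ib, space, normalization)
    dists[r] <- sqrt(sum((ua - ub)^2))
  }
  mean(dists)
}

#' Pairwise RDI matrix over a set of samples
#'
#' Per repeat, every sample is subsampled once to the common depth and all
#' pairwise Euclidean distances between normalized usage vectors are
#' computed; entries are averaged over repeats (the scheme of the original
#' RDI implementation). Samples below depth are excluded with a warning.
#'
#' @param record_list Named list of per-sample rearrangement `data.frame`s
#'   (e.g. from [split_samples()]).
#' @param depth Subsample depth; defaults to the minimum sample size.
#' @param n_repeats Number of repeats (default 100).
#' @param seed Integer seed.
#' @param normalization `"proportion"` (default) or `"log"`.
#' @param features Segment subsets (default V + D + J).
#' @param reference Optional germline reference fixing the feature space.
#' @return Object of class `rdi_matrix`: `matrix` (symmetric, zero
#'   diagonal), `depth`, `n_repeats`, `normalization`, `features`.
#' @export
rdi_matrix <- function(record_list, depth = NULL, n_repeats = 100L, seed = 1L,
                       normalization = c("proportion", "log"),
                       features = c("v", "d", "j"), reference = NULL) {
  normalization <- match.arg(normalization)
  if (length(record_list) < 2) stop("need >= 2 samples for an RDI matrix")
  sizes <- vapply(record_list, nrow, integer(1))
  depth <- as.integer(depth %||% min(sizes))
  below <- sizes < depth
  if (any(below)) {
    warning("excluded sample(s) below depth ", depth, ": ",
            paste(names(record_list)[below], collapse = ", "))
    record_list <- record_list[!below]
    if (length(record_list) < 2) stop("fewer than 2 samples at depth")
  }
  ids <- names(record_list)
  space <- build_feature_space(record_list, features, reference)
  S <- length(record_list)
  acc <- matrix(0, S, S, dimnames = list(ids, ids))
  flen <- length(space$v) + length(space$d) + length(space$j)
  for (r in seq_len(n_repeats)) {
    U <- vapply(seq_len(S), function(i) {
      set.seed(seed + 1000L * r + i)
      idx <- sample.int(nrow(record_list[[i]]), depth)
      usage_vector_at(record_list[[i]], idx, space, normalization)
    }, numeric(flen))
    acc <- acc + as.matrix(stats::dist(t(U)))
  }
  structure(list(matrix = acc / n_repeats, depth = depth,
                 n_repeats = as.integer(n_repeats),
                 normalization = normalization, features = features),
            class = "rdi_matrix")
}

#' @export
print.rdi_matrix <- function(x, ...) {
  cat(sprintf("rdi_matrix: %d samples, depth %d, %d repeats, %s normalization\n",
              nrow(x$matrix), x$depth, x$n_repeats, x$normalization))
  invisible(x)
}

#' Long-format pair table of an RDI matrix
#'
#' @param rdi An `rdi_matrix`.
#' @return `data.frame`: sample_a, sample_b, rdi, depth, n_repeats,
#'   normalization.
#' @export
rdi_long <- function(rdi) {
  m <- rdi$matrix
  ids <- rownames(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
             rdi = m[pairs], depth = rdi$depth, n_repeats = rdi$n_repeats,
             normalization = rdi$normalization, stringsAsFactors = FALSE)
}

#' Per-sample mean RDI to same-group samples
#'
#' The per-mouse dissimilarity covariate used in the morbidity correlation:
#' for each sample, the mean RDI to all other samples of its (diet x age)
#' group.
#'
#' @param rdi An `rdi_matrix`.
#' @param design Cohort design `data.frame` with `sample_id`, `diet`,
#'   `age_months`.
#' @return `data.frame`: `sample_id`, `rdi_group_mean`.
#' @export
rdi_sample_means <- function(rdi, design) {
  m <- rdi$matrix
  ids <- rownames(m)
  meta <- design[match(ids, design$sample_id), , drop = FALSE]
  grp <- paste(meta$diet, meta$age_months)
  out <- vapply(seq_along(ids), function(i) {
    peers <- which(grp == grp[i] & seq_along(ids) != i)
    if (length(peers) == 0) return(NA_real_)
    mean(m[i, peers])
  }, numeric(1))
  data.frame(sample_id = ids, rdi_group_mean = out, stringsAsFactors = FALSE)
}

#' Group-mean RDI summary (within diet x age cells)
#'
#' @param rdi An `rdi_matrix`.
#' @param design Cohort design `data.frame`.
#' @return `data.frame`: diet, age_months, mean_rdi, n_pairs.
#' @export
rdi_group_summary <- function(rdi, design) {
  m <- rdi$matrix
  ids <- rownames(m)
  meta <- design[match(ids, design$sample_id), , drop = FALSE]
  grp <- paste(meta$diet, meta$age_months, sep = "|")
  cells <- unique(grp)
  out <- lapply(cells, function(g) {
    idx <- which(grp == g)
    if (length(idx) < 2) return(NULL)
    vals <- m[idx, idx][upper.tri(m[idx, idx])]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    data.frame(diet = parts[1], age_months = as.integer(parts[2]),
               mean_rdi = mean(vals), n_pairs = length(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
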