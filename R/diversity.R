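# Hill diversity spectra with uniform-depth subsampling and bootstrap, and
# the P20 clonal-expansion statistic.
#
# The Hill number of order q of a clone abundance vector p is
#   qD = (sum_i p_i^q)^(1/(1-q)),
# with the q -> 1 limit exp(-sum_i p_i log p_i) (exponential Shannon
# entropy); q = 0 is clone richness and q = 2 the inverse Simpson
# concentration. "Shannon diversity" and "Simpson diversity" are reported
# on the Hill scale (1D, 2D) throughout; raw indices are available via
# `as_index`.

#' Hill number of order q
#'
#' @param abundances Non-negative abundance (or frequency) vector with at
#'   least one positive entry; normalized internally.
#' @param q Diversity order, `q >= 0`. Orders within `1e-9` of 1 are
#'   evaluated as the entropy-exponential limit.
#' @param as_index Return the raw index instead of the Hill number:
#'   Shannon entropy for `q = 1`, the Simpson concentration
#'   `1 - sum(p^2)` for `q = 2` (default `FALSE`).
#' @return Diversity of order `q` (`>= 1` on the Hill scale).
#' @examples
#' hill_number(c(0.5, 0.25, 0.25), 1)  # 2.8284
#' @export
hill_number <- function(abundances, q, as_index = FALSE) {
  if (any(abundances < 0) || !any(abundances > 0)) {
    stop("abundances must be non-negative with at least one positive entry")
  }
  if (q < 0) stop("q must be >= 0")
  p <- abundances[abundances > 0]
  p <- p / sum(p)
  if (abs(q - 1) < 1e-9) {
    h <- -sum(p * log(p))
    return(if (as_index) h else exp(h))
  }
  if (q == 2 && as_index) return(1 - sum(p^2))
  if (q == 0) return(if (as_index) length(p) else length(p))
  sum(p^q)^(1 / (1 - q))
}

#' Hill diversity spectrum over a grid of orders
#'
#' @param abundances Abundance vector (see [hill_number()]).
#' @param q_grid Numeric vector of orders (default `seq(0, 4, by = 0.1)`).
#' @return `data.frame` with columns `q` and `qD`.
#' @export
hill_spectrum <- function(abundances, q_grid = seq(0, 4, by = 0.1)) {
  data.frame(q = q_grid,
             qD = vapply(q_grid, function(q) hill_number(abundances, q),
                         numeric(1)))
}

#' Rarefied Hill spectrum with bootstrap over subsamples
#'
#' Draws `n_boot` subsamples of `depth` records without replacement from the
#' partition's membership, recomputes clone abundances per subsample, and
#' reports the mean Hill number and a percentile band per order. Uniform
#' depth across compared samples (conventionally the minimum sample size of
#' the compared set) makes spectra comparable across ages and diets.
#'
#' @param partition A `clone_partition`.
#' @param q_grid Orders to evaluate (default `c(0, 1, 2)`).
#' @param depth Subsample depth; defaults to the full sample size.
#' @param n_boot Number of subsample replicates (default 200).
#' @param seed Integer seed.
#' @param by Abundance weighting, as in [clone_abundances()].
#' @param conf Width of the percentile band (default 0.95).
#' @return `data.frame`: `sample_id`, `q`, `mean_qD`, `ci_lo`, `ci_hi`,
#'   `depth`, `n_boot`.
#' @export
diversity_with_resampling <- function(partition, q_grid = c(0, 1, 2),
                                      depth = NULL, n_boot = 200L,
                                      seed = 1L,
                                      by = c("records", "consensus_count"),
                                      conf = 0.95) {
  by <- match.arg(by)
  mem <- partition$membership
  n <- nrow(mem)
  depth <- as.integer(depth %||% n)
  if (depth > n) {
    stop(sprintf("depth %d exceeds size %d of sample %s", depth, n,
                 partition$sample_id))
  }
  if (n_boot < 1) stop("n_boot must be >= 1")
  codes <- match(mem$clone_id, unique(mem$clone_id))
  n_codes <- max(codes)
  w <- if (by == "records") NULL else mem$consensus_count
  set.seed(seed)
  qd <- matrix(NA_real_, nrow = n_boot, ncol = length(q_grid))
  for (b in seq_len(n_boot)) {
    idx <- if (depth == n) seq_len(n) else sample.int(n, depth)
    ab <- if (is.null(w)) tabulate(codes[idx], nbins = n_codes)
          else as.numeric(tapply(w[idx], factor(codes[idx], levels = seq_len(n_codes)), sum))
    ab[is.na(ab)] <- 0
    qd[b, ] <- vapply(q_grid, function(q) hill_number(ab, q), numeric(1))
  }
  a <- (1 - conf) / 2
  data.frame(
    sample_id = partition$sample_id,
    q = q_grid,
    mean_qD = colMeans(qd),
    ci_lo = apply(qd, 2, quantile, probs = a),
    ci_hi = apply(qd, 2, quantile, probs = 1 - a),
    depth = depth,
    n_boot = as.integer(n_boot)
  )
}

#' P20 clonal-expansion statistic
#'
#' The summed relative frequency of the 20 largest clones (all clones when
#' fewer than 20 exist), with ties at the rank-20 boundary broken
#' deterministically by clone id.
#'
#' @param partition A `clone_partition`.
#' @param by Abundance weighting, as in [clone_abundances()].
#' @param isotype Optional isotype slice.
#' @param top Number of top ranks summed (default 20).
#' @return List with `sample_id`, `p20`, and the sorted `rank_abundance`
#'   vector of relative clone frequencies.
#' @export
p20 <- function(partition, by = c("records", "consensus_count"),
                isotype = NULL, top = 20L) {
  by <- match.arg(by)
  ab <- clone_abundances(partition, by = by, isotype = isotype)
  if (length(ab) == 0) stop("empty partition: no clones to rank")
  ord <- order(-ab, names(ab))
  freq <- ab[ord] / sum(ab)
  list(sample_id = partition$sample_id,
       p20 = sum(freq[seq_len(min(top, length(freq)))]),
       rank_abundance = unname(freq))
}
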