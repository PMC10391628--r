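test_that("identity rule requires matching V, J and CDR3 amino acids", {
  recs <- make_records(2, v_call = "IGHV1*01", j_call = "IGHJ2*01",
                       junction_aa = "CARDYW")
  p <- assign_clones_identity(recs)
  expect_equal(nrow(p$clones), 1)
  expect_equal(p$clones$size, 2)

  # same V and CDR3 but different J genes: two clones
  recs2 <- make_records(2, v_call = "IGHV1*01",
                        j_call = c("IGHJ1*01", "IGHJ2*01"),
                        junction_aa = "CARDYW")
  expect_equal(nrow(assign_clones_identity(recs2)$clones), 2)

  # allele suffixes and secondary calls are ignored at gene level
  recs3 <- make_records(2, v_call = c("IGHV1*01", "IGHV1*02,IGHV3*01"),
                        j_call = "IGHJ1*01", junction_aa = "CARDYW")
  expect_equal(nrow(assign_clones_identity(recs3)$clones), 1)

  # empty junction_aa records are excluded with a warning
  recs4 <- make_records(3)
  recs4$junction_aa[2] <- ""
  expect_warning(p4 <- assign_clones_identity(recs4), "junction_aa")
  expect_equal(sum(p4$clones$size), 2)
})

test_that("identity partition equals the brute-force triple-equality oracle", {
  set.seed(21)
  recs <- random_clone_records(200)
  p <- assign_clones_identity(recs)
  # O(n^2) oracle: union-find over pairwise triple equality
  n <- nrow(recs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  strip <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (strip(recs$v_call[i]) == strip(recs$v_call[j]) &&
        strip(recs$j_call[i]) == strip(recs$j_call[j]) &&
        recs$junction_aa[i] == recs$junction_aa[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  oracle <- vapply(seq_len(n), find, integer(1))
  got <- p$membership$clone_id[match(recs$sequence_id,
                                     p$membership$sequence_id)]
  expect_true(same_partition(got, oracle))
  expect_equal(sum(p$clones$size), n)
})

test_that("distance to nearest matches hand values and the all-pairs oracle", {
  recs <- make_records(2, junction = c("AAAAAA", "AAAAAT"),
                       junction_aa = c("KX", "KY"))
  d <- distance_to_nearest(recs)
  expect_equal(d$dist_nearest, c(1 / 6, 1 / 6))

  recs2 <- make_records(2, junction = "AAAAAA", junction_aa = "KK")
  expect_equal(distance_to_nearest(recs2)$dist_nearest, c(0, 0))

  set.seed(31)
  recs3 <- random_clone_records(100, n_v = 2, n_j = 2, len_aa_pool = 5)
  got <- distance_to_nearest(recs3)
  strip <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))
  grp <- paste(strip(recs3$v_call), strip(recs3$j_call),
               nchar(recs3$junction))
  for (i in seq_len(nrow(recs3))) {
    peers <- which(grp == grp[i] & seq_len(nrow(recs3)) != i)
    expected <- if (length(peers) == 0) NA_real_ else {
      min(vapply(peers, function(j) {
        a <- strsplit(recs3$junction[i], "")[[1]]
        b <- strsplit(recs3$junction[j], "")[[1]]
        sum(a != b) / length(a)
      }, numeric(1)))
    }
    hit <- got$dist_nearest[got$sequence_id == recs3$sequence_id[i]]
    if (is.na(expected)) {
      expect_length(hit, 0)
    } else {
      expect_equal(hit, expected)
    }
  }
})

test_that("threshold detection finds the valley of a bimodal mixture", {
  set.seed(41)
  d <- c(abs(rnorm(1000, 0.02, 0.01)), rnorm(1000, 0.30, 0.05))
  thr <- find_threshold(d)
  expect_gt(thr, 0.05)
  expect_lt(thr, 0.25)
  expect_false(attr(thr, "unimodal"))
  # grid-search density-minimum oracle on the same sample
  den <- density(d, kernel = "gaussian", n = 512, from = 0,
                 to = max(d) + sd(d))
  grid <- den$x[den$x > 0.05 & den$x < 0.25]
  ygrid <- den$y[den$x > 0.05 & den$x < 0.25]
  expect_equal(as.numeric(thr), grid[which.min(ygrid)], tolerance = 0.02)

  expect_warning(thr0 <- find_threshold(rep(0, 100)), "fallback")
  expect_equal(as.numeric(thr0), 0.1)
  expect_true(attr(thr0, "unimodal"))

  expect_error(find_threshold(runif(10)), ">= 50")
})

test_that("single-linkage threshold clustering is transitive", {
  # junctions at pairwise distances A-B 0.05, B-C 0.05, A-C 0.10 (20 nt)
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c("T", rep("A", 19)), collapse = "")
  cc <- paste(c("T", "T", rep("A", 18)), collapse = "")
  recs <- make_records(3, junction = c(a, b, cc), junction_aa = "CARXX")
  p <- assign_clones_threshold(recs, 0.06)
  expect_equal(nrow(p$clones), 1)
  expect_equal(p$clones$size, 3)
  # threshold 0: identical junctions only
  p0 <- assign_clones_threshold(recs, 0)
  expect_equal(nrow(p0$clones), 3)
})

test_that("threshold partition equals the graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(51)
  recs <- random_clone_records(150, n_v = 2, n_j = 2, len_aa_pool = 4:5)
  thr <- 0.3
  p <- assign_clones_threshold(recs, thr)
  strip <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))
  grp <- paste(strip(recs$v_call), strip(recs$j_call), nchar(recs$junction))
  n <- nrow(recs)
  edges <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (grp[i] == grp[j]) {
      aa <- strsplit(recs$junction[i], "")[[1]]
      bb <- strsplit(recs$junction[j], "")[[1]]
      if (sum(aa != bb) / length(aa) <= thr) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  # different V/J/length groups must stay apart even at distance 0
  oracle <- paste(grp, igraph::components(g)$membership)
  got <- p$membership$clone_id[match(recs$sequence_id,
                                     p$membership$sequence_id)]
  expect_true(same_partition(got, oracle))
})

test_that("both modes recover the planted partition on mutation-free junctions", {
  spec <- cohort_spec(seqs_per_sample = 200, n_clones_base = 60, seed = 8)
  ref <- make_germline_reference(6, 3, 3, seed = 8)
  out <- generate_sample(spec, list(sample_id = "gt", mouse_id = "m",
                                    tissue = "spleen", diet = "AL",
                                    age_months = 20), ref, seed = 88)
  truth <- out$ground_truth$clone_of
  for (p in list(assign_clones_identity(out$records),
                 assign_clones_threshold(out$records, 0.1))) {
    got <- p$membership$clone_id[match(names(truth),
                                       p$membership$sequence_id)]
    expect_true(same_partition(got, truth))
  }
})

test_that("clone sizes are invariant under record order permutation", {
  set.seed(61)
  recs <- random_clone_records(120)
  p1 <- assign_clones_identity(recs)
  p2 <- assign_clones_identity(recs[sample(nrow(recs)), ])
  expect_equal(p1$clones[order(p1$clones$clone_id), c("clone_id", "size")],
               p2$clones[order(p2$clones$clone_id), c("clone_id", "size")],
               ignore_attr = TRUE)
})

test_that("identity partitions refine threshold partitions", {
  spec <- cohort_spec(seqs_per_sample = 150, n_clones_base = 50, seed = 12)
  ref <- make_germline_reference(5, 3, 3, seed = 12)
  out <- generate_sample(spec, list(sample_id = "ref", mouse_id = "m",
                                    tissue = "spleen", diet = "DR",
                                    age_months = 16), ref, seed = 5)
  pi <- assign_clones_identity(out$records)
  pt <- assign_clones_threshold(out$records, 0.2)
  id_of <- setNames(pi$membership$clone_id, pi$membership$sequence_id)
  th_of <- setNames(pt$membership$clone_id, pt$membership$sequence_id)
  # every identity clone maps into exactly one threshold clone
  for (cl in unique(id_of)) {
    members <- names(id_of)[id_of == cl]
    expect_length(unique(th_of[members]), 1)
  }
})
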