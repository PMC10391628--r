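test_that("germline reference has the right composition and is deterministic", {
  ref <- make_germline_reference(20, 10, 4, seed = 1)
  expect_length(ref$genes, 34)
  expect_equal(sum(ref$lengths$segment == "V"), 20)
  expect_true(all(ref$lengths$length[ref$lengths$segment == "V"] %in% 252:300))
  expect_true(all(ref$lengths$length[ref$lengths$segment == "J"] %in% 42:60))
  expect_true(all(ref$lengths$length[ref$lengths$segment == "D"] %in% 10:30))
  expect_false(anyDuplicated(names(ref$genes)) > 0)

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_germline(make_germline_reference(20, 10, 4, seed = 1)$genes, f1)
  write_germline(make_germline_reference(20, 10, 4, seed = 1)$genes, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(make_germline_reference(1, 0, 4, seed = 1), ">= 2")
})

test_that("zero requested sequences yield an empty sample", {
  spec <- cohort_spec(seqs_per_sample = 0, seed = 1)
  ref <- make_germline_reference(5, 3, 3, seed = 1)
  out <- generate_sample(spec, list(sample_id = "s0", mouse_id = "m0",
                                    tissue = "spleen", diet = "AL",
                                    age_months = 16), ref, seed = 1)
  expect_equal(nrow(out$records), 0)
  expect_length(out$ground_truth$clone_of, 0)
})

test_that("identical spec and seed reproduce a sample byte-for-byte", {
  spec <- cohort_spec(seqs_per_sample = 100, n_clones_base = 40, seed = 5)
  ref <- make_germline_reference(6, 3, 3, seed = 5)
  meta <- list(sample_id = "det", mouse_id = "m", tissue = "spleen",
               diet = "DR", age_months = 20)
  a <- generate_sample(spec, meta, ref, seed = 77)
  b <- generate_sample(spec, meta, ref, seed = 77)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_rearrangements(a$records, f1)
  write_rearrangements(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("near-uniform clone sizes reproduce the multinomial P20 oracle", {
  # independent oracle: multinomial sampling from a uniform 500-clone law
  n_clones <- 500; n_seq <- 2000; n_seeds <- 50
  set.seed(99)
  oracle <- replicate(n_seeds, {
    cnt <- as.vector(rmultinom(1, n_seq, rep(1 / n_clones, n_clones)))
    sum(sort(cnt, decreasing = TRUE)[1:20]) / n_seq
  })
  spec <- cohort_spec(seqs_per_sample = n_seq, n_clones_base = n_clones,
                      alpha0 = 1e7, expansion_slope = c(AL = 0, DR = 0),
                      prop_nonproductive = 0, seed = 1)
  ref <- make_germline_reference(6, 3, 3, seed = 1)
  meta <- list(sample_id = "u", mouse_id = "m", tissue = "spleen",
               diet = "AL", age_months = 24)
  got <- vapply(seq_len(n_seeds), function(s) {
    gt <- generate_sample(spec, meta, ref, seed = 1000 + s)$ground_truth
    sum(sort(gt$clone_sizes, decreasing = TRUE)[1:20]) / n_seq
  }, numeric(1))
  se <- sqrt(var(oracle) / n_seeds + var(got) / n_seeds)
  expect_lt(abs(mean(got) - mean(oracle)), 3 * se)
})

test_that("empirical isotype fractions match the requested spleen mix", {
  mix <- c(IgM = 0.61, IgG = 0.23, IgA = 0.13, IgD = 0.02, IgE = 0.01)
  spec <- cohort_spec(seqs_per_sample = 10000, n_clones_base = 500,
                      isotype_mix = list(spleen = mix),
                      prop_nonproductive = 0, seed = 2)
  ref <- make_germline_reference(6, 3, 3, seed = 2)
  out <- generate_sample(spec, list(sample_id = "iso", mouse_id = "m",
                                    tissue = "spleen", diet = "AL",
                                    age_months = 5), ref, seed = 42)
  frac <- isotype_fractions(out$records)
  for (cls in names(mix)) {
    se <- sqrt(mix[[cls]] * (1 - mix[[cls]]) / 10000)
    expect_lt(abs(frac[[cls]] - mix[[cls]]), 3 * se + 1e-12, label = cls)
  }
})

test_that("stronger expansion slopes skew clone sizes and lower diversity", {
  ref <- make_germline_reference(6, 3, 3, seed = 3)
  meta <- list(sample_id = "x", mouse_id = "m", tissue = "spleen",
               diet = "AL", age_months = 24)
  stat_for <- function(slope, seeds) {
    spec <- cohort_spec(seqs_per_sample = 1000, n_clones_base = 300,
                        expansion_slope = c(AL = slope, DR = slope),
                        prop_nonproductive = 0, seed = 1)
    vapply(seeds, function(s) {
      gt <- generate_sample(spec, meta, ref, seed = s)$ground_truth
      sizes <- gt$clone_sizes[gt$clone_sizes > 0]
      top <- sort(sizes, decreasing = TRUE)[seq_len(min(20, length(sizes)))]
      c(p20 = sum(top) / sum(sizes), h1 = hill_number(sizes, 1))
    }, numeric(2))
  }
  lo <- stat_for(0.05, 1:10)
  hi <- stat_for(0.25, 1:10)
  expect_gt(mean(hi["p20", ]), mean(lo["p20", ]))
  expect_lt(mean(hi["h1", ]), mean(lo["h1", ]))
})

test_that("ground-truth partitions cover every sequence exactly once", {
  spec <- cohort_spec(ages = c(16, 24), diets = c("AL", "DR"),
                      tissues = c("spleen", "ileum"), n_mice_per_group = 2,
                      seqs_per_sample = 120, n_clones_base = 50, seed = 13)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$design), 2 * 2 * 2 * 2)
  for (sid in coh$design$sample_id) {
    gt <- coh$ground_truth[[sid]]
    recs <- coh$records[coh$records$sample_id == sid, ]
    expect_setequal(names(gt$clone_of), recs$sequence_id)
    expect_equal(sum(gt$clone_sizes), nrow(recs))
  }
})

test_that("uncoupled morbidity is null and strong coupling is monotone", {
  set.seed(7)
  expansion <- setNames(runif(200), paste0("m", 1:200))
  # coupling 0: Spearman within the permutation null band
  path0 <- generate_morbidity(expansion, coupling = 0, noise_sd = 1, seed = 3)
  idx0 <- macromorbidity(path0)
  rho0 <- cor(expansion[idx0$mouse_id], idx0$macromorbidity,
              method = "spearman")
  expect_lt(abs(rho0), 2.58 / sqrt(length(expansion) - 1))
  # strong coupling, zero noise: index monotone non-decreasing in expansion
  path1 <- generate_morbidity(expansion, coupling = 5, noise_sd = 0, seed = 3)
  idx1 <- macromorbidity(path1)
  ord <- order(expansion[idx1$mouse_id])
  expect_true(all(diff(idx1$macromorbidity[ord]) >= 0))
  # small tie-free case: Spearman exactly 1
  small <- setNames(c(0.1, 0.35, 0.6, 0.8), paste0("s", 1:4))
  ps <- generate_morbidity(small, coupling = 5, noise_sd = 0, seed = 1)
  is <- macromorbidity(ps)
  if (length(unique(is$macromorbidity)) == 4) {
    expect_equal(cor(small[is$mouse_id], is$macromorbidity,
                     method = "spearman"), 1)
  }
  # negative coupling flips the correlation sign
  pneg <- generate_morbidity(expansion, coupling = -5, noise_sd = 0, seed = 3)
  ineg <- macromorbidity(pneg)
  expect_lt(cor(expansion[ineg$mouse_id], ineg$macromorbidity,
                method = "spearman"), -0.9)
})
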