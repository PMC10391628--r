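test_that("mutation counting matches hand-worked codon cases", {
  germ <- "GGGAAA"
  expect_equal(count_shm(germ, germ)[c("n_syn", "n_nonsyn", "freq_syn")],
               list(n_syn = 0L, n_nonsyn = 0L, freq_syn = 0))
  # GGG -> GGA: Gly -> Gly (synonymous); AAA -> GAA: Lys -> Glu
  got <- count_shm("GGAGAA", germ)
  expect_equal(got$n_syn, 1L)
  expect_equal(got$n_nonsyn, 1L)
  expect_equal(got$n_informative, 6L)
  # 2 mutations over 300 informative positions
  germ300 <- paste(rep("GGGAAA", 50), collapse = "")
  obs300 <- paste0("GGAGAA", paste(rep("GGGAAA", 49), collapse = ""))
  got300 <- count_shm(obs300, germ300)
  expect_equal(got300$freq_syn + got300$freq_nonsyn, 2 / 300,
               tolerance = 1e-9)
  expect_error(count_shm("AAA", "AAAA"), "length")
  expect_error(count_shm(germ, germ, junction_span = c(5, 9)), "junction_span")
})

test_that("S/NS classification matches the exhaustive codon-table oracle", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])
  n_checked <- 0
  for (codon in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(codon, pos, pos))) {
        mutated <- codon
        substr(mutated, pos, pos) <- alt
        got <- count_shm(mutated, codon)
        aa_g <- seqinr::translate(strsplit(codon, "")[[1]])
        aa_m <- seqinr::translate(strsplit(mutated, "")[[1]])
        if (aa_g == aa_m) {
          expect_equal(got$n_syn, 1L, label = paste(codon, "->", mutated))
          expect_equal(got$n_nonsyn, 0L)
        } else {
          expect_equal(got$n_nonsyn, 1L, label = paste(codon, "->", mutated))
          expect_equal(got$n_syn, 0L)
        }
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 549)
})

test_that("junction, gaps and ambiguous bases are excluded from counting", {
  germ <- "GGGAAACCCTTT"
  obs <- "GGAAAACCCTTA"  # mutations at pos 3 and 12
  # junction span covers codon 4: its mutation is not counted
  got <- count_shm(obs, germ, junction_span = c(10, 12))
  expect_equal(got$n_syn + got$n_nonsyn, 1L)
  expect_equal(got$n_informative, 9L)
  # gap and N positions drop out of the informative set
  # the gap and N positions themselves drop out of the informative set
  got2 <- count_shm("GG-AAANCCTTT", germ)
  expect_equal(got2$n_informative, 10L)
  expect_equal(got2$n_syn + got2$n_nonsyn, 0L)
  # an unresolvable germline codon excludes all three of its positions
  got3 <- count_shm("GGGAAACCCTTT", "GGGAA-CCCTTT")
  expect_equal(got3$n_informative, 9L)
})

test_that("planted mutations are recovered exactly on synthetic data", {
  spec <- cohort_spec(seqs_per_sample = 150, n_clones_base = 60, seed = 17)
  ref <- make_germline_reference(5, 3, 3, seed = 17)
  out <- generate_sample(spec, list(sample_id = "shm", mouse_id = "m",
                                    tissue = "spleen", diet = "AL",
                                    age_months = 20), ref, seed = 6)
  prof <- shm_profiles(out$records)
  truth <- out$ground_truth$shm[match(prof$sequence_id,
                                      out$ground_truth$shm$sequence_id), ]
  expect_equal(prof$n_syn, truth$n_syn)
  expect_equal(prof$n_nonsyn, truth$n_nonsyn)
  # per-sequence total frequency reflects the planted isotype rates
  expect_gt(mean(prof$n_syn + prof$n_nonsyn), 0)
})

test_that("clone staging follows the naive/stimulated/switched rule", {
  expect_equal(stage_clone(c("IgG", "IgG"), c(5L, 2L)), "IgM-IgD-")
  expect_equal(stage_clone("IgM", 0L), "IgM+IgD+SHM-")
  expect_equal(stage_clone(c("IgM", "IgG"), c(3L, 0L)), "IgM+IgD+SHM+")
  expect_equal(stage_clone("IgD", 1L), "IgM+IgD+SHM+")
  expect_warning(got <- stage_clone(c("IgM", NA), c(0L, 9L)), "missing")
  expect_equal(got, "IgM+IgD+SHM-")
  expect_error(suppressWarnings(stage_clone(NA_character_, 1L)), "isotype")
  # brute-force cross-check over enumerated member attribute combinations
  isos <- c("IgM", "IgD", "IgG", "IgA")
  for (i1 in isos) for (i2 in isos) for (m in c(0L, 2L)) {
    got <- stage_clone(c(i1, i2), c(m, 0L))
    naive_iso <- any(c(i1, i2) %in% c("IgM", "IgD"))
    expected <- if (!naive_iso) "IgM-IgD-"
                else if (m >= 1) "IgM+IgD+SHM+" else "IgM+IgD+SHM-"
    expect_equal(got, expected, label = paste(i1, i2, m))
  }
})

test_that("stage fractions over a sample sum to one", {
  spec <- cohort_spec(seqs_per_sample = 200, n_clones_base = 80, seed = 19)
  ref <- make_germline_reference(5, 3, 3, seed = 19)
  out <- generate_sample(spec, list(sample_id = "st", mouse_id = "m",
                                    tissue = "ileum", diet = "DR",
                                    age_months = 24),
                         ref, seed = 2)
  part <- assign_clones_identity(out$records)
  prof <- shm_profiles(out$records)
  sf <- stage_fractions(stage_clones(part, prof))
  expect_equal(sum(sf), 1, tolerance = 1e-9)
  expect_true(all(sf >= 0))
})

test_that("isotype fractions match arithmetic and weighting expectations", {
  recs <- make_records(5, c_call = "IGHA")
  f <- isotype_fractions(recs)
  expect_equal(f[["IgA"]], 1)
  expect_equal(sum(f), 1)

  counts <- c(IgM = 61, IgG = 23, IgA = 13, IgD = 2, IgE = 1)
  recs2 <- make_records(100, c_call = rep(paste0("IGH", c("M", "G", "A", "D", "E")),
                                          counts))
  f2 <- isotype_fractions(recs2)
  expect_equal(f2[c("IgM", "IgG", "IgA", "IgD", "IgE")],
               c(IgM = 0.61, IgG = 0.23, IgA = 0.13, IgD = 0.02, IgE = 0.01))
  # order invariance
  expect_equal(isotype_fractions(recs2[sample(100), ]), f2)

  recs3 <- make_records(2, c_call = c("IGHM", "IGHG1"),
                        consensus_count = c(99L, 1L))
  expect_equal(isotype_fractions(recs3, weight = TRUE)[["IgM"]], 0.99)
  recs3$isotype <- NA_character_
  expect_error(isotype_fractions(recs3), "isotype")
})

test_that("CDR3 Gaussian statistics use the n-1 convention", {
  expect_equal(cdr3_stats(rep(15, 4))[c("mean", "sd")],
               list(mean = 15, sd = 0))
  got <- cdr3_stats(c(12, 14, 16))
  expect_equal(got$mean, 14)
  expect_equal(got$sd, 2)
  expect_equal(got$sd_denominator, "n-1")
  expect_error(cdr3_stats(numeric(0)), ">= 2")
  expect_error(cdr3_stats(10), ">= 2")

  gv <- cdr3_group_variability(c(14, 15, 16, 20, 22),
                               c("a", "a", "a", "b", "b"))
  expect_equal(gv$between_sd[gv$group == "a"], 1)
  expect_equal(gv$between_sd[gv$group == "b"], sd(c(20, 22)))
})
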