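# Synthetic AIRR cohort generator with planted ground truth.
#
# Emulates the statistical structure the downstream analysis assumes:
# clone-size skew growing with age (faster under ad libitum feeding than
# dietary restriction), per-mouse idiosyncratic V/D/J usage whose divergence
# grows with age, tissue-specific isotype composition, somatic hypermutation
# planted outside the junction at isotype-dependent rates, and morbidity
# scores coupled to the planted clonal expansion.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc != "*"])
})

random_codons <- function(n) {
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

#' Specify a synthetic cohort
#'
#' Defaults encode the cross-sectional dietary-restriction design: five
#' female mice per diet group at 5/16/20/24 months, diets `AL`, `DR`
#' (restriction from 3 months) and `AL_DR16M` (switch at 16 months, sampled
#' only at ages >= 16). Clone sizes are symmetric-Dirichlet with
#' per-component concentration `alpha0 * exp(-cumulative expansion
#' exposure)`, where exposure accrues at `expansion_slope[diet]` per month of
#' life under that diet from 3 months of age; `AL_DR16M` accrues at the `AL`
#' rate until 16 months, then the `DR` rate. Per-mouse V/D/J usage vectors
#' are drawn from a Dirichlet centred on the population usage vector with
#' precision decaying analogously at `usage_idiosyncrasy[diet]` per month.
#' Effect sizes are illustrative, anchored to the qualitative pattern of an
#' aging murine repertoire (top-20 clonal abundance near 0.8 under `AL` and
#' 0.6 under `DR` at 24 months).
#'
#' @param n_mice_per_group Mice per diet x age cell (default 5).
#' @param ages Sampling ages in months (default `c(5, 16, 20, 24)`).
#' @param diets Diet labels (subset of `AL`, `DR`, `AL_DR16M`).
#' @param tissues Tissues sampled per mouse (default `"spleen"`).
#' @param seqs_per_sample UMI-consensus sequences per sample (default 5000).
#' @param n_clones_base Latent clones per sample (default 1500).
#' @param alpha0 Baseline Dirichlet concentration per clone at 3 months.
#' @param expansion_slope Named per-diet exposure rate per month for
#'   clone-size skew.
#' @param kappa0 Baseline usage-vector precision at 3 months.
#' @param usage_idiosyncrasy Named per-diet exposure rate per month for
#'   usage divergence.
#' @param shm_rate Expected mutations per sequence by isotype class.
#' @param isotype_mix Per-tissue isotype probability vectors (must sum to 1).
#' @param junction_shm_rate Expected junction mutations per sequence
#'   (default 0; keeping the junction clean makes the identity clone rule
#'   exact on synthetic data).
#' @param prop_nonproductive Fraction of non-productive rearrangements.
#' @param morbidity_coupling Coefficient linking standardized planted
#'   expansion to the latent morbidity score.
#' @param morbidity_noise_sd Gaussian noise on the latent morbidity score.
#' @param n_v,n_d,n_j Germline reference sizes.
#' @param seed Master seed for the cohort.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_mice_per_group = 5L,
                        ages = c(5L, 16L, 20L, 24L),
                        diets = c("AL", "DR", "AL_DR16M"),
                        tissues = "spleen",
                        seqs_per_sample = 5000L,
                        n_clones_base = 1500L,
                        alpha0 = 2,
                        expansion_slope = c(AL = 0.25, DR = 0.21),
                        kappa0 = 200,
                        usage_idiosyncrasy = c(AL = 0.15, DR = 0.08),
                        shm_rate = c(IgM = 2, IgD = 1, IgG = 8, IgE = 6, IgA = 10),
                        isotype_mix = list(
                          spleen = c(IgM = 0.61, IgG = 0.23, IgA = 0.13,
                                     IgD = 0.02, IgE = 0.01),
                          ileum = c(IgM = 0.08, IgG = 0.02, IgA = 0.89,
                                    IgD = 0.005, IgE = 0.005)),
                        junction_shm_rate = 0,
                        prop_nonproductive = 0.02,
                        morbidity_coupling = 1,
                        morbidity_noise_sd = 0.5,
                        n_v = 20L, n_d = 10L, n_j = 4L,
                        seed = 1L) {
  stopifnot(n_mice_per_group >= 1, seqs_per_sample >= 0, n_clones_base >= 1,
            alpha0 > 0, kappa0 > 0, junction_shm_rate >= 0,
            prop_nonproductive >= 0, prop_nonproductive < 1,
            all(shm_rate >= 0))
  if (!all(diets %in% DIET_LEVELS)) stop("unknown diet label")
  if (!all(tissues %in% TISSUE_LEVELS)) stop("unknown tissue label")
  for (tt in tissues) {
    mix <- isotype_mix[[tt]]
    if (is.null(mix) || abs(sum(mix) - 1) > 1e-9) {
      stop("isotype_mix for tissue '", tt, "' must sum to 1")
    }
    if (!all(names(mix) %in% ISOTYPE_CLASSES)) stop("unknown isotype class")
  }
  structure(list(
    n_mice_per_group = as.integer(n_mice_per_group), ages = as.integer(ages),
    diets = diets, tissues = tissues,
    seqs_per_sample = as.integer(seqs_per_sample),
    n_clones_base = as.integer(n_clones_base), alpha0 = alpha0,
    expansion_slope = expansion_slope, kappa0 = kappa0,
    usage_idiosyncrasy = usage_idiosyncrasy, shm_rate = shm_rate,
    isotype_mix = isotype_mix, junction_shm_rate = junction_shm_rate,
    prop_nonproductive = prop_nonproductive,
    morbidity_coupling = morbidity_coupling,
    morbidity_noise_sd = morbidity_noise_sd,
    n_v = as.integer(n_v), n_d = as.integer(n_d), n_j = as.integer(n_j),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# internal: cumulative per-month exposure under a diet schedule, from age 3
diet_exposure <- function(rates, diet, age_months) {
  r_al <- rates[["AL"]]
  r_dr <- rates[["DR"]]
  switch(diet,
         AL = r_al * (age_months - 3),
         DR = r_dr * (age_months - 3),
         AL_DR16M = r_al * (min(age_months, 16) - 3) +
           r_dr * max(0, age_months - 16),
         stop("unknown diet: ", diet))
}

alpha_for <- function(spec, diet, age_months) {
  spec$alpha0 * exp(-diet_exposure(spec$expansion_slope, diet, age_months))
}

kappa_for <- function(spec, diet, age_months) {
  spec$kappa0 * exp(-diet_exposure(spec$usage_idiosyncrasy, diet, age_months))
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  s <- sum(x)
  if (s <= 0 || !is.finite(s)) {
    # extreme concentration underflow: fall back to a single random atom
    x <- numeric(length(alpha))
    x[sample.int(length(alpha), 1)] <- 1
    return(x)
  }
  x / s
}

#' Generate a germline V/D/J reference
#'
#' V genes are 252-300 nt in frame (built from sense codons so the germline
#' translates cleanly), J genes 42-60 nt in frame, D genes 10-30 nt.
#' Deterministic given the seed.
#'
#' @param n_v,n_d,n_j Number of genes per segment (`n_v`, `n_j` >= 2, since
#'   the clone definition needs at least two distinguishable genes).
#' @param seed Integer seed.
#' @return List with `genes` (named character vector) and `lengths`
#'   (`data.frame` of name, segment, length).
#' @export
make_germline_reference <- function(n_v = 20L, n_d = 10L, n_j = 4L, seed = 1L) {
  if (n_v < 2 || n_j < 2) {
    stop("n_v and n_j must each be >= 2 (clone definition needs >= 2 ",
         "distinguishable genes)")
  }
  set.seed(seed)
  v <- vapply(seq_len(n_v), function(i) random_codons(sample(84:100, 1)),
              character(1))
  names(v) <- paste0("IGHV", seq_len(n_v))
  d <- if (n_d > 0) {
    vapply(seq_len(n_d), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), replace = TRUE),
            collapse = "")
    }, character(1))
  } else character(0)
  if (n_d > 0) names(d) <- paste0("IGHD", seq_len(n_d))
  j <- vapply(seq_len(n_j), function(i) random_codons(sample(14:20, 1)),
              character(1))
  names(j) <- paste0("IGHJ", seq_len(n_j))
  genes <- c(v, d, j)
  lengths <- data.frame(
    name = names(genes),
    segment = rep(c("V", "D", "J"), c(n_v, n_d, n_j)),
    length = nchar(genes),
    stringsAsFactors = FALSE
  )
  list(genes = genes, lengths = lengths)
}

# internal: population-level usage vector over one segment's genes
# (deterministic geometric skew, shared by all mice)
population_usage <- function(gene_names, decay = 0.85) {
  p <- decay^(seq_along(gene_names) - 1)
  setNames(p / sum(p), gene_names)
}

# internal: random in-frame junction of len_aa amino acids (Cys...Trp)
random_junction <- function(len_aa) {
  paste0("TGT", random_codons(len_aa - 2L), "TGG")
}

C_CALL_POOL <- list(
  IgM = "IGHM", IgD = "IGHD", IgG = c("IGHG1", "IGHG2B", "IGHG3"),
  IgE = "IGHE", IgA = "IGHA"
)

#' Generate one synthetic sample with ground truth
#'
#' Draws latent clone weights from a symmetric Dirichlet whose concentration
#' encodes age- and diet-dependent clonal expansion, assigns each clone V/J
#' (and usually D) genes from the mouse's idiosyncratic usage vector, builds
#' in-frame sequences (germline V + clonal junction + germline J), and plants
#' somatic hypermutation as independent substitutions outside the junction at
#' isotype-dependent rates, recording each planted change as synonymous or
#' non-synonymous against the germline codon.
#'
#' @param spec A [cohort_spec()].
#' @param meta One-row `data.frame` (or list) with `sample_id`, `mouse_id`,
#'   `tissue`, `diet`, `age_months`.
#' @param germline Reference from [make_germline_reference()].
#' @param seed Integer seed for this sample.
#' @return List with `records` (rearrangement `data.frame`) and
#'   `ground_truth` (clone partition, clone weights/sizes, usage vectors,
#'   planted mutation counts, expansion score).
#' @export
generate_sample <- function(spec, meta, germline, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (meta$diet == "AL_DR16M" && meta$age_months < 16) {
    stop("AL_DR16M is only valid at ages >= 16 months")
  }
  set.seed(seed)
  n_seq <- spec$seqs_per_sample
  empty <- data.frame(
    sequence_id = character(0), sample_id = character(0),
    v_call = character(0), d_call = character(0), j_call = character(0),
    junction = character(0), junction_aa = character(0),
    c_call = character(0), isotype = character(0),
    sequence_alignment = character(0), germline_alignment = character(0),
    productive = logical(0), consensus_count = integer(0),
    junction_start = integer(0), junction_end = integer(0),
    stringsAsFactors = FALSE
  )
  if (n_seq == 0) {
    return(list(records = empty,
                ground_truth = list(clone_of = integer(0),
                                    clone_weights = numeric(0),
                                    clone_sizes = integer(0),
                                    usage = NULL,
                                    shm = data.frame(),
                                    expansion_score = NA_real_)))
  }

  n_clones <- spec$n_clones_base
  alpha <- alpha_for(spec, meta$diet, meta$age_months)
  clone_weights <- rdirichlet1(rep(alpha, n_clones))
  clone_of <- sample.int(n_clones, n_seq, replace = TRUE, prob = clone_weights)

  lens <- germline$lengths
  v_names <- lens$name[lens$segment == "V"]
  d_names <- lens$name[lens$segment == "D"]
  j_names <- lens$name[lens$segment == "J"]
  kappa <- kappa_for(spec, meta$diet, meta$age_months)
  usage <- list(
    v = setNames(rdirichlet1(kappa * population_usage(v_names)), v_names),
    d = if (length(d_names) > 0)
      setNames(rdirichlet1(kappa * population_usage(d_names)), d_names)
    else NULL,
    j = setNames(rdirichlet1(kappa * population_usage(j_names)), j_names)
  )

  # clone-level attributes (only clones that were actually sampled)
  used <- sort(unique(clone_of))
  clone_v <- setNames(sample(v_names, length(used), replace = TRUE,
                             prob = usage$v), used)
  clone_j <- setNames(sample(j_names, length(used), replace = TRUE,
                             prob = usage$j), used)
  clone_d <- setNames(rep(NA_character_, length(used)), used)
  if (length(d_names) > 0) {
    has_d <- runif(length(used)) < 0.9
    clone_d[has_d] <- sample(d_names, sum(has_d), replace = TRUE,
                             prob = usage$d)
  }
  clone_junction <- setNames(vapply(used, function(i) {
    random_junction(sample(8:24, 1))
  }, character(1)), used)

  mix <- spec$isotype_mix[[meta$tissue]]
  isotype <- sample(names(mix), n_seq, replace = TRUE, prob = mix)

  translate1 <- function(nt) {
    paste(Biostrings::GENETIC_CODE[substring(
      nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))], collapse = "")
  }
  clone_key <- as.character(clone_of)
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")

  # per-clone germline context
  clone_germ <- lapply(used, function(i) {
    key <- as.character(i)
    v_seq <- germline$genes[[clone_v[key]]]
    j_seq <- germline$genes[[clone_j[key]]]
    germ <- paste0(v_seq, clone_junction[key], j_seq)
    list(germ = germ,
         jx_start = nchar(v_seq) + 1L,
         jx_end = nchar(v_seq) + nchar(clone_junction[key]),
         junction_aa = translate1(clone_junction[key]))
  })
  names(clone_germ) <- as.character(used)

  seq_aln <- character(n_seq)
  n_syn <- integer(n_seq)
  n_nonsyn <- integer(n_seq)
  germ_aln <- character(n_seq)
  jx_start <- integer(n_seq)
  jx_end <- integer(n_seq)
  junction <- character(n_seq)
  junction_aa <- character(n_seq)

  for (s in seq_len(n_seq)) {
    cg <- clone_germ[[clone_key[s]]]
    str <- cg$germ
    L <- nchar(str)
    rate <- spec$shm_rate[[isotype[s]]]
    n_mut <- if (rate > 0) rpois(1, rate) else 0L
    jxs <- cg$jx_start; jxe <- cg$jx_end
    jx_nt <- clone_junction[[clone_key[s]]]
    if (n_mut > 0) {
      candidates <- c(seq_len(jxs - 1L), seq.int(jxe + 1L, L))
      pos <- sample(candidates, min(n_mut, length(candidates)))
      for (p in pos) {
        old <- substr(str, p, p)
        new <- sample(setdiff(bases, old), 1)
        cstart <- ((p - 1L) %/% 3L) * 3L + 1L
        germ_codon <- substr(cg$germ, cstart, cstart + 2L)
        mut_codon <- germ_codon
        substr(mut_codon, p - cstart + 1L, p - cstart + 1L) <- new
        if (identical(gc_tab[[germ_codon]], gc_tab[[mut_codon]])) {
          n_syn[s] <- n_syn[s] + 1L
        } else {
          n_nonsyn[s] <- n_nonsyn[s] + 1L
        }
        substr(str, p, p) <- new
      }
    }
    if (spec$junction_shm_rate > 0) {
      n_jmut <- rpois(1, spec$junction_shm_rate)
      if (n_jmut > 0) {
        pos <- sample(jxs:jxe, min(n_jmut, jxe - jxs + 1L))
        for (p in pos) {
          substr(str, p, p) <- sample(setdiff(bases, substr(str, p, p)), 1)
        }
        jx_nt <- substr(str, jxs, jxe)
      }
    }
    seq_aln[s] <- str
    germ_aln[s] <- cg$germ
    jx_start[s] <- jxs
    jx_end[s] <- jxe
    junction[s] <- jx_nt
    junction_aa[s] <- cg$junction_aa
  }

  c_call <- vapply(isotype, function(it) {
    pool <- C_CALL_POOL[[it]]
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1))

  records <- data.frame(
    sequence_id = sprintf("%s_seq%05d", meta$sample_id, seq_len(n_seq)),
    sample_id = meta$sample_id,
    v_call = unname(clone_v[clone_key]),
    d_call = unname(clone_d[clone_key]),
    j_call = unname(clone_j[clone_key]),
    junction = junction,
    junction_aa = junction_aa,
    c_call = unname(c_call),
    isotype = isotype,
    sequence_alignment = seq_aln,
    germline_alignment = germ_aln,
    productive = runif(n_seq) >= spec$prop_nonproductive,
    consensus_count = 1L + rpois(n_seq, 2),
    junction_start = jx_start,
    junction_end = jx_end,
    stringsAsFactors = FALSE
  )

  sizes <- tabulate(clone_of, nbins = n_clones)
  expansion_score <- sum(sort(sizes, decreasing = TRUE)[1:min(20, n_clones)]) /
    n_seq
  list(
    records = records,
    ground_truth = list(
      clone_of = setNames(clone_of, records$sequence_id),
      clone_weights = clone_weights,
      clone_sizes = sizes,
      usage = usage,
      shm = data.frame(sequence_id = records$sequence_id,
                       n_syn = n_syn, n_nonsyn = n_nonsyn,
                       stringsAsFactors = FALSE),
      expansion_score = expansion_score
    )
  )
}

#' Generate pathology records coupled to planted clonal expansion
#'
#' Latent morbidity = `coupling` x standardized planted expansion + Gaussian
#' noise; the latent score is mapped monotonically to a tumor-affected organ
#' count in `{0, 1, 2, 3}` and a non-neoplastic finding count in `{0..7}`
#' (labels drawn from the closed finding vocabulary).
#'
#' @param expansion Named numeric vector of planted per-mouse expansion.
#' @param coupling Coupling coefficient (sign flips the correlation sign).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Pathology `data.frame` (`mouse_id`, `n_tumor_organs`, `findings`).
#' @export
generate_morbidity <- function(expansion, coupling, noise_sd, seed) {
  set.seed(seed)
  n <- length(expansion)
  z <- if (n > 1 && sd(expansion) > 0) {
    (expansion - mean(expansion)) / sd(expansion)
  } else {
    rep(0, n)
  }
  latent <- coupling * z + rnorm(n, 0, noise_sd)
  r <- rank(latent, ties.method = "first")
  q <- (r - 0.5) / n
  organs <- ifelse(q < 0.60, 0L, ifelse(q < 0.85, 1L, ifelse(q < 0.95, 2L, 3L)))
  burden <- pmin(7L, as.integer(floor(8 * (r - 1) / n)))
  vocab <- morbidity_findings()
  findings <- lapply(burden, function(b) {
    if (b == 0) character(0) else sort(sample(vocab, b))
  })
  data.frame(mouse_id = names(expansion), n_tumor_organs = organs,
             findings = I(findings), stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Builds the germline reference, the cross-sectional design (fresh mice per
#' diet x age cell; `AL_DR16M` only at ages >= 16), one sample per mouse x
#' tissue, and pathology records coupled to the planted spleen expansion
#' (first tissue if no spleen is simulated). Deterministic given
#' `spec$seed`; each sample uses an independent derived seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (all samples, one `data.frame`), `design`,
#'   `ground_truth` (named per sample), `pathology`, `germline`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  germline <- make_germline_reference(spec$n_v, spec$n_d, spec$n_j,
                                      seed = spec$seed)
  cells <- expand.grid(diet = spec$diets, age_months = spec$ages,
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$diet == "AL_DR16M" & cells$age_months < 16), ,
                 drop = FALSE]
  design <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    mouse <- sprintf("%s_%02dm_m%d", cells$diet[i], cells$age_months[i],
                     seq_len(spec$n_mice_per_group))
    expand.grid(mouse_id = mouse, tissue = spec$tissues,
                stringsAsFactors = FALSE)[
      , c("mouse_id", "tissue"), drop = FALSE] |>
      transform(diet = cells$diet[i], age_months = cells$age_months[i])
  }))
  design$sample_id <- paste(design$mouse_id, design$tissue, sep = "_")
  design <- design[, c("sample_id", "mouse_id", "tissue", "diet",
                       "age_months")]
  rownames(design) <- NULL

  records <- vector("list", nrow(design))
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    out <- generate_sample(spec, as.list(design[i, ]), germline,
                           seed = spec$seed + 7919L * i)
    records[[i]] <- out$records
    truth[[i]] <- out$ground_truth
  }
  names(truth) <- design$sample_id
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  ref_tissue <- if ("spleen" %in% spec$tissues) "spleen" else spec$tissues[1]
  idx <- design$tissue == ref_tissue
  expansion <- setNames(
    vapply(truth[design$sample_id[idx]], function(g) g$expansion_score,
           numeric(1)),
    design$mouse_id[idx]
  )
  pathology <- generate_morbidity(expansion, spec$morbidity_coupling,
                                  spec$morbidity_noise_sd,
                                  seed = spec$seed + 104729L)
  list(records = records, design = design, ground_truth = truth,
       pathology = pathology, germline = germline, spec = spec)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rearrangements(cohort$records, file.path(dir, "rearrangements.tsv"))
  write_germline(cohort$germline$genes, file.path(dir, "germline.fasta"))
  write_pathology(cohort$pathology, file.path(dir, "pathology.csv"))
  utils::write.table(cohort$design, file.path(dir, "design.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
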