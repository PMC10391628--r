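# End-to-end pipeline: simulate (or read) -> clones -> diversity/P20 -> RDI
# -> maturation -> morbidity -> statistics, with a run manifest.
#
# All parameters flow through a single run config. The master seed is
# expanded into per-stage substreams so changing one stage's replication
# settings does not perturb another stage's draws.

STAGE_SEED_OFFSETS <- c(simulate = 0L, diversity = 11L, rdi = 23L)

#' Build a pipeline run configuration
#'
#' Either `spec` (a [cohort_spec()]; the cohort is simulated) or
#' `input_dir` (a directory holding `rearrangements.tsv`, `germline.fasta`,
#' `pathology.csv`, `design.csv`) must be provided. The default simulated
#' cohort is 3 diets x 3 ages (16/20/24 months) x 5 mice, spleen, 5000
#' sequences per sample.
#'
#' @param spec Optional [cohort_spec()].
#' @param input_dir Optional input directory.
#' @param clone_mode `"identity"` (default) or `"threshold"`.
#' @param threshold_fallback Fallback clustering threshold (default 0.1).
#' @param q_grid Diversity orders (default `c(0, 1, 2)`).
#' @param n_boot Diversity bootstrap replicates (default 100).
#' @param rdi_depth RDI subsample depth; `NULL` (default) uses the minimum
#'   sample size per tissue. An explicit depth larger than some sample
#'   aborts the run naming that sample.
#' @param rdi_n_repeats RDI subsample repeats (default 100).
#' @param rdi_normalization `"proportion"` (default) or `"log"`.
#' @param rdi_features RDI segment subsets (default V + D + J).
#' @param frame_offset Reading-frame offset for mutation counting.
#' @param shm_min_mutations SHM-positive staging threshold (default 1).
#' @param weight_by `"records"` (default) or `"consensus_count"`.
#' @param stats_family Bonferroni family scope for the timepoint tests
#'   (`"tissue"`: all metric x age x diet-pair tests within a tissue).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = NULL, input_dir = NULL,
                       clone_mode = c("identity", "threshold"),
                       threshold_fallback = 0.1,
                       q_grid = c(0, 1, 2), n_boot = 100L,
                       rdi_depth = NULL,
                       rdi_n_repeats = 100L,
                       rdi_normalization = "proportion",
                       rdi_features = c("v", "d", "j"),
                       frame_offset = 0L, shm_min_mutations = 1L,
                       weight_by = c("records", "consensus_count"),
                       stats_family = "tissue",
                       seed = 1L) {
  clone_mode <- match.arg(clone_mode)
  weight_by <- match.arg(weight_by)
  if (is.null(spec) && is.null(input_dir)) {
    spec <- cohort_spec(ages = c(16L, 20L, 24L), tissues = "spleen",
                       seed = seed)
  }
  structure(list(
    spec = spec, input_dir = input_dir, clone_mode = clone_mode,
    threshold_fallback = threshold_fallback, q_grid = q_grid,
    n_boot = as.integer(n_boot),
    rdi_depth = if (!is.null(rdi_depth)) as.integer(rdi_depth) else NULL,
    rdi_n_repeats = as.integer(rdi_n_repeats),
    rdi_normalization = rdi_normalization, rdi_features = rdi_features,
    frame_offset = as.integer(frame_offset),
    shm_min_mutations = as.integer(shm_min_mutations),
    weight_by = weight_by, stats_family = stats_family,
    seed = as.integer(seed)
  ), class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# internal: per-sample maturation summary row
maturation_row <- function(sample_id, records, partition, profiles,
                           shm_min_mutations) {
  stg <- stage_clones(partition, profiles, shm_min_mutations)
  sf <- stage_fractions(stg)
  iso <- isotype_fractions(records)
  cs <- cdr3_stats(nchar(records$junction_aa))
  mut <- profiles$n_syn + profiles$n_nonsyn
  clone_freq <- tapply(profiles$freq_syn + profiles$freq_nonsyn,
                       partition$membership$clone_id[
                         match(profiles$sequence_id,
                               partition$membership$sequence_id)],
                       mean)
  data.frame(
    sample_id = sample_id,
    freq_syn = mean(profiles$freq_syn, na.rm = TRUE),
    freq_nonsyn = mean(profiles$freq_nonsyn, na.rm = TRUE),
    freq_total_clone = mean(clone_freq, na.rm = TRUE),
    mean_mutations = mean(mut),
    cdr3_mean = cs$mean, cdr3_sd = cs$sd,
    frac_IgM = iso[["IgM"]], frac_IgD = iso[["IgD"]],
    frac_IgG = iso[["IgG"]], frac_IgE = iso[["IgE"]],
    frac_IgA = iso[["IgA"]],
    stage_naive = sf[["IgM+IgD+SHM-"]],
    stage_stimulated = sf[["IgM+IgD+SHM+"]],
    stage_switched = sf[["IgM-IgD-"]],
    stringsAsFactors = FALSE
  )
}

PIPELINE_METRICS <- c("hill_1", "hill_2", "p20", "rdi_group_mean",
                      "freq_syn", "freq_nonsyn", "cdr3_mean", "cdr3_sd",
                      "frac_IgM", "frac_IgD", "frac_IgG", "frac_IgE",
                      "frac_IgA", "stage_naive", "stage_stimulated",
                      "stage_switched")

#' Run the full repertoire pipeline
#'
#' Executes every stage on a simulated or provided cohort and writes all
#' report tables plus a manifest to `out_dir`. Deterministic given the
#' config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`metric_table`,
#'   `stats`, `manifest`, paths).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  counts <- list()

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$input_dir)) {
    cohort <- with_stage("read_inputs", {
      list(records = read_rearrangements(
             file.path(config$input_dir, "rearrangements.tsv")),
           design = read_cohort_design(
             file.path(config$input_dir, "design.csv")),
           pathology = read_pathology(
             file.path(config$input_dir, "pathology.csv")),
           germline = local({
             fp <- file.path(config$input_dir, "germline.fasta")
             if (file.exists(fp)) {
               genes <- read_germline(fp)
               list(genes = genes,
                    lengths = data.frame(
                      name = names(genes),
                      segment = ifelse(grepl("V", names(genes)), "V",
                                ifelse(grepl("D", names(genes)), "D", "J")),
                      length = nchar(genes), stringsAsFactors = FALSE))
             } else NULL
           }))
    })
    say("read %d records from %s", nrow(cohort$records), config$input_dir)
  } else {
    spec <- config$spec
    spec$seed <- config$seed + STAGE_SEED_OFFSETS[["simulate"]]
    cohort <- with_stage("simulate", generate_cohort(spec))
    input_dir <- file.path(out_dir, "inputs")
    write_cohort(cohort, input_dir)
    say("simulated %d samples (%d records)", nrow(cohort$design),
        nrow(cohort$records))
  }
  records <- cohort$records
  design <- cohort$design
  n_before <- nrow(records)
  records <- records[records$productive, , drop = FALSE]
  counts$productive_dropped <- n_before - nrow(records)
  say("dropped %d non-productive records", counts$productive_dropped)
  samples <- split_samples(records)
  samples <- samples[design$sample_id[design$sample_id %in% names(samples)]]

  # --- clones -----------------------------------------------------------
  partitions <- with_stage("clones", {
    lapply(samples, function(recs) {
      if (config$clone_mode == "identity") {
        assign_clones_identity(recs)
      } else {
        d <- distance_to_nearest(recs)
        thr <- tryCatch(find_threshold(d$dist_nearest,
                                       fallback = config$threshold_fallback),
                        error = function(e) config$threshold_fallback)
        assign_clones_threshold(recs, as.numeric(thr))
      }
    })
  })
  clones_tab <- do.call(rbind, lapply(partitions, clone_table))
  rownames(clones_tab) <- NULL
  write_report(clones_tab, file.path(out_dir, "clones.tsv"))
  counts$clones <- nrow(clones_tab)

  # --- diversity and P20 ------------------------------------------------
  div_seed <- config$seed + STAGE_SEED_OFFSETS[["diversity"]]
  tissue_of <- setNames(design$tissue, design$sample_id)
  div_tab <- with_stage("diversity", {
    out <- lapply(names(partitions), function(sid) {
      tis <- tissue_of[[sid]]
      peers <- names(samples)[tissue_of[names(samples)] == tis]
      depth <- min(vapply(samples[peers], nrow, integer(1)))
      cbind(diversity_with_resampling(
        partitions[[sid]], q_grid = config$q_grid, depth = depth,
        n_boot = config$n_boot, seed = div_seed, by = config$weight_by),
        tissue = tis)
    })
    do.call(rbind, out)
  })
  write_report(div_tab, file.path(out_dir, "diversity.tsv"))

  p20_tab <- with_stage("p20", {
    do.call(rbind, lapply(names(partitions), function(sid) {
      res <- p20(partitions[[sid]], by = config$weight_by)
      data.frame(sample_id = sid, p20 = res$p20,
                 n_clones = length(res$rank_abundance),
                 stringsAsFactors = FALSE)
    }))
  })
  write_report(p20_tab, file.path(out_dir, "p20.tsv"))

  # --- RDI --------------------------------------------------------------
  rdi_seed <- config$seed + STAGE_SEED_OFFSETS[["rdi"]]
  rdi_results <- with_stage("rdi", {
    lapply(unique(design$tissue), function(tis) {
      ids <- design$sample_id[design$tissue == tis]
      ids <- ids[ids %in% names(samples)]
      if (length(ids) < 2) return(NULL)
      if (!is.null(config$rdi_depth)) {
        sizes <- vapply(samples[ids], nrow, integer(1))
        below <- sizes < config$rdi_depth
        if (any(below)) {
          stop(sprintf("RDI depth %d exceeds the size of sample(s): %s",
                       config$rdi_depth,
                       paste(ids[below], collapse = ", ")))
        }
      }
      rdi_matrix(samples[ids], depth = config$rdi_depth,
                 n_repeats = config$rdi_n_repeats,
                 seed = rdi_seed, normalization = config$rdi_normalization,
                 features = config$rdi_features,
                 reference = cohort$germline)
    })
  })
  names(rdi_results) <- unique(design$tissue)
  rdi_results <- Filter(Negate(is.null), rdi_results)
  rdi_long_tab <- do.call(rbind, lapply(names(rdi_results), function(tis) {
    cbind(rdi_long(rdi_results[[tis]]), tissue = tis)
  }))
  write_report(rdi_long_tab, file.path(out_dir, "rdi_long.tsv"))
  rdi_mat_tab <- do.call(rbind, lapply(names(rdi_results), function(tis) {
    m <- rdi_results[[tis]]$matrix
    cbind(data.frame(sample_id = rownames(m), tissue = tis,
                     stringsAsFactors = FALSE), as.data.frame(m))
  }))
  write_report(rdi_mat_tab, file.path(out_dir, "rdi_matrix.tsv"))
  rdi_means <- do.call(rbind, lapply(rdi_results, rdi_sample_means, design))

  # --- maturation -------------------------------------------------------
  mat_tab <- with_stage("maturation", {
    do.call(rbind, lapply(names(samples), function(sid) {
      profiles <- shm_profiles(samples[[sid]],
                               frame_offset = config$frame_offset)
      maturation_row(sid, samples[[sid]], partitions[[sid]], profiles,
                     config$shm_min_mutations)
    }))
  })
  write_report(mat_tab, file.path(out_dir, "maturation.tsv"))

  # --- morbidity --------------------------------------------------------
  morb <- with_stage("morbidity", macromorbidity(cohort$pathology))
  write_report(morb, file.path(out_dir, "morbidity.tsv"))

  # --- metric table -----------------------------------------------------
  metric_table <- with_stage("metric_table", {
    hill_wide <- do.call(rbind, lapply(split(div_tab, div_tab$sample_id),
      function(d) {
        row <- data.frame(sample_id = d$sample_id[1])
        for (q in config$q_grid) {
          row[[sprintf("hill_%g", q)]] <- d$mean_qD[d$q == q]
        }
        row
      }))
    mt <- merge(design, hill_wide, by = "sample_id")
    mt <- merge(mt, p20_tab[, c("sample_id", "p20")], by = "sample_id")
    mt <- merge(mt, rdi_means, by = "sample_id", all.x = TRUE)
    mt <- merge(mt, mat_tab, by = "sample_id")
    before <- nrow(mt)
    mt <- merge(mt, morb, by = "mouse_id")
    if (nrow(mt) != before) {
      warning(sprintf("morbidity join changed row count %d -> %d",
                      before, nrow(mt)))
    }
    mt[order(mt$sample_id), , drop = FALSE]
  })
  write_report(metric_table, file.path(out_dir, "metric_table.tsv"))
  counts$metric_rows <- nrow(metric_table)

  # --- statistics -------------------------------------------------------
  metrics <- intersect(PIPELINE_METRICS, names(metric_table))
  stats <- with_stage("statistics",
                      cohort_statistics(metric_table, metrics,
                                        config$stats_family))
  write_report(stats$regression, file.path(out_dir, "stats_regression.tsv"))
  write_report(stats$anova, file.path(out_dir, "stats_anova.tsv"))
  write_report(stats$timepoint, file.path(out_dir, "stats_timepoint.tsv"))
  write_report(stats$correlation,
               file.path(out_dir, "stats_correlation.tsv"))

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_ser <- config
  cfg_ser$spec <- if (!is.null(config$spec)) unclass(config$spec) else NULL
  yaml::write_yaml(unclass(cfg_ser), cfg_path)
  manifest <- list(
    package = "bcraging",
    version = as.character(utils::packageVersion("bcraging")),
    seed = config$seed,
    stage_seeds = as.list(config$seed + STAGE_SEED_OFFSETS),
    parameter_hash = unname(tools::md5sum(cfg_path)),
    n_samples = length(samples),
    n_records = nrow(records),
    counts = counts,
    tables = c("clones.tsv", "diversity.tsv", "p20.tsv", "rdi_long.tsv",
               "rdi_matrix.tsv", "maturation.tsv", "morbidity.tsv",
               "metric_table.tsv", "stats_regression.tsv",
               "stats_anova.tsv", "stats_timepoint.tsv",
               "stats_correlation.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(metric_table = metric_table, stats = stats,
                 manifest = manifest, out_dir = out_dir,
                 partitions = partitions, rdi = rdi_results))
}

#' Cohort statistical layer over a metric table
#'
#' Per-diet age regressions, two-way ANOVA per diet pair, Mann-Whitney
#' tests per time point with Bonferroni correction, and Spearman
#' metric-morbidity correlations (per tissue).
#'
#' @param metric_table One row per sample with metadata, metrics and
#'   morbidity columns.
#' @param metrics Metric column names to analyse.
#' @param stats_family Bonferroni family scope for the timepoint tests.
#' @return List of `data.frame`s: `regression`, `anova`, `timepoint`,
#'   `correlation`.
#' @export
cohort_statistics <- function(metric_table, metrics,
                              stats_family = "tissue") {
  regression <- list(); anova <- list(); timepoint <- list()
  correlation <- list()
  for (tis in unique(metric_table$tissue)) {
    mt <- metric_table[metric_table$tissue == tis, , drop = FALSE]
    diets <- unique(mt$diet)
    for (metric in metrics) {
      vals <- mt[[metric]]
      for (diet in diets) {
        idx <- mt$diet == diet
        if (sum(idx) >= 3 && length(unique(mt$age_months[idx])) >= 2) {
          fit <- age_regression(vals[idx], mt$age_months[idx])
          regression[[length(regression) + 1L]] <- data.frame(
            tissue = tis, metric = metric, diet = diet,
            slope = fit$slope, intercept = fit$intercept, p = fit$p,
            r_squared = fit$r_squared, n = fit$n, stringsAsFactors = FALSE)
        }
      }
      if (length(diets) >= 2) {
        pairs <- utils::combn(sort(diets), 2, simplify = FALSE)
        for (pr in pairs) {
          idx <- mt$diet %in% pr
          ok <- tryCatch({
            av <- two_way_anova(vals[idx], mt$age_months[idx], mt$diet[idx])
            anova[[length(anova) + 1L]] <- data.frame(
              tissue = tis, metric = metric,
              diet_a = pr[1], diet_b = pr[2],
              p_age = av$p_age, p_diet = av$p_diet,
              p_interaction = av$p_interaction, stringsAsFactors = FALSE)
            TRUE
          }, error = function(e) FALSE)
          for (age in sort(unique(mt$age_months[idx]))) {
            a <- vals[mt$diet == pr[1] & mt$age_months == age]
            b <- vals[mt$diet == pr[2] & mt$age_months == age]
            if (sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2) {
              tt <- timepoint_test(a, b)
              timepoint[[length(timepoint) + 1L]] <- data.frame(
                tissue = tis, metric = metric, age_months = age,
                diet_a = pr[1], diet_b = pr[2], U = tt$U, p = tt$p,
                n_a = tt$n_x, n_b = tt$n_y, exact = tt$exact,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    ct <- tryCatch(
      cbind(morbidity_correlation(mt, metrics), tissue = tis),
      error = function(e) NULL)
    if (!is.null(ct)) correlation[[length(correlation) + 1L]] <- ct
  }
  timepoint <- do.call(rbind, timepoint) %||%
    data.frame(tissue = character(0))
  if (nrow(timepoint) > 0) {
    timepoint$p_bonferroni <- NA_real_
    for (tis in unique(timepoint$tissue)) {
      idx <- timepoint$tissue == tis
      timepoint$p_bonferroni[idx] <- bonferroni(timepoint$p[idx])
    }
    timepoint$family <- stats_family
  }
  list(
    regression = do.call(rbind, regression) %||% data.frame(),
    anova = do.call(rbind, anova) %||% data.frame(),
    timepoint = timepoint,
    correlation = do.call(rbind, correlation) %||% data.frame()
  )
}
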