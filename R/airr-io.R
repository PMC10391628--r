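# AIRR rearrangement table, germline FASTA, and pathology/cohort table I/O.
# Canonical dialect: AIRR Rearrangement TSV column names; other dialects are
# handled through `col_map`.

AIRR_REQUIRED <- c(
  "sequence_id", "sample_id", "v_call", "j_call", "junction", "junction_aa",
  "c_call", "sequence_alignment", "germline_alignment", "productive",
  "consensus_count"
)

AIRR_SUPPORTED <- c(
  "sequence_id", "sample_id", "v_call", "d_call", "j_call", "junction",
  "junction_aa", "c_call", "isotype", "sequence_alignment",
  "germline_alignment", "productive", "consensus_count",
  "junction_start", "junction_end"
)

ISOTYPE_CLASSES <- c("IgM", "IgD", "IgG", "IgE", "IgA")

#' Collapse constant-region calls to the five isotype classes
#'
#' Sub-isotypes (e.g. `IGHG1`, `IGHG2b`) collapse to their class (`IgG`);
#' already-collapsed labels pass through. Unrecognisable calls become `NA`.
#'
#' @param c_call Character vector of constant-region gene calls.
#' @return Character vector over `{IgM, IgD, IgG, IgE, IgA}` (or `NA`).
#' @examples
#' collapse_isotype(c("IGHG2b", "IGHM", "IgA"))
#' @export
collapse_isotype <- function(c_call) {
  cc <- toupper(trimws(as.character(c_call)))
  cc <- sub("^IGH", "IG", cc)          # IGHM -> IGM
  out <- rep(NA_character_, length(cc))
  out[grepl("^IGM", cc)] <- "IgM"
  out[grepl("^IGD", cc)] <- "IgD"
  out[grepl("^IGG", cc)] <- "IgG"
  out[grepl("^IGE", cc)] <- "IgE"
  out[grepl("^IGA", cc)] <- "IgA"
  out
}

parse_airr_logical <- function(x) {
  toupper(trimws(as.character(x))) %in% c("T", "TRUE", "1", "YES")
}

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement table in the AIRR dialect (one row per
#' UMI-consensus sequence). Rows violating structural invariants (alignment
#' strings of unequal length, consensus counts below 1, productive junctions
#' whose length is not a multiple of three) are dropped with a warning naming
#' their line numbers. Unknown columns are preserved as opaque annotations.
#'
#' @param path Path to the TSV file.
#' @param filter_productive Drop rows with `productive == FALSE` (default
#'   `TRUE`, the preprocessing used throughout the analysis).
#' @param collapse_duplicates Collapse rows identical in
#'   (sample, V, J, junction, isotype), summing `consensus_count`
#'   (default `FALSE`).
#' @param col_map Optional named character vector mapping canonical AIRR
#'   names to the file's column names, e.g. `c(c_call = "isotype_call")`.
#' @return A `data.frame` of rearrangement records carrying a collapsed
#'   `isotype` column; group per sample with [split_samples()].
#' @export
read_rearrangements <- function(path, filter_productive = TRUE,
                                collapse_duplicates = FALSE, col_map = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if (!"d_call" %in% names(df)) df$d_call <- NA_character_
  df$productive <- parse_airr_logical(df$productive)
  df$consensus_count <- suppressWarnings(as.integer(df$consensus_count))
  for (col in c("junction_start", "junction_end")) {
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  df$isotype <- collapse_isotype(df$c_call)

  line_no <- seq_len(nrow(df)) + 1L   # header is line 1
  aln_ok <- !is.na(df$sequence_alignment) & !is.na(df$germline_alignment) &
    nchar(df$sequence_alignment) == nchar(df$germline_alignment)
  cnt_ok <- !is.na(df$consensus_count) & df$consensus_count >= 1L
  jlen <- ifelse(is.na(df$junction), 0L, nchar(df$junction))
  frame_ok <- !df$productive | (jlen %% 3L == 0L)
  ok <- aln_ok & cnt_ok & frame_ok
  if (any(!ok)) {
    warning(sprintf("dropped %d malformed row(s) at line(s): %s",
                    sum(!ok), paste(line_no[!ok], collapse = ", ")))
    df <- df[ok, , drop = FALSE]
  }

  samples_before <- unique(df$sample_id)
  if (filter_productive) {
    df <- df[df$productive, , drop = FALSE]
    lost <- setdiff(samples_before, unique(df$sample_id))
    if (length(lost) > 0) {
      warning("sample(s) with zero productive records: ",
              paste(lost, collapse = ", "))
    }
  }
  if (collapse_duplicates && nrow(df) > 0) {
    key <- paste(df$sample_id, df$v_call, df$j_call, df$junction,
                 df$isotype, sep = "\r")
    counts <- tapply(df$consensus_count, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$consensus_count <- as.integer(counts[paste(
      df$sample_id, df$v_call, df$j_call, df$junction, df$isotype,
      sep = "\r")])
  }
  rownames(df) <- NULL
  df
}

#' Split a rearrangement table into per-sample record sets
#'
#' @param records Rearrangement `data.frame` with a `sample_id` column.
#' @return Named list of `data.frame`s, one per sample.
#' @export
split_samples <- function(records) {
  split(records, records$sample_id)
}

#' Write an AIRR rearrangement table
#'
#' @param records Rearrangement `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  out <- records
  out$productive <- ifelse(out$productive, "T", "F")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a germline V/D/J reference FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase gene sequences.
#' @export
read_germline <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a germline reference FASTA
#'
#' @param genes Named character vector of gene sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline <- function(genes, path) {
  ss <- Biostrings::DNAStringSet(genes)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' The closed vocabulary of macroscopic non-neoplastic findings
#'
#' Canonical labels for the necropsy findings scored by the macromorbidity
#' index: bad habitus/kyphosis, enlarged spleen, discoloration of white
#' adipose tissue, knotty/granular pancreas, uterine cysts, enlarged kidneys,
#' enlarged adrenal glands.
#'
#' @return Character vector of the seven canonical finding labels.
#' @export
morbidity_findings <- function() {
  c("bad habitus/kyphosis", "enlarged spleen", "WAT discoloration",
    "knotty/granular pancreas", "uterine cysts", "enlarged kidneys",
    "enlarged adrenal glands")
}

# internal: synonyms -> canonical labels; unknown labels raise an error
canonical_finding <- function(labels, vocabulary = morbidity_findings()) {
  syn <- c(
    "bad habitus" = "bad habitus/kyphosis",
    "kyphosis" = "bad habitus/kyphosis",
    "bad habitus/kyphosis" = "bad habitus/kyphosis",
    "enlarged spleen" = "enlarged spleen",
    "wat discoloration" = "WAT discoloration",
    "discoloration of wat" = "WAT discoloration",
    "knotty pancreas" = "knotty/granular pancreas",
    "granular pancreas" = "knotty/granular pancreas",
    "knotty/granular pancreas" = "knotty/granular pancreas",
    "uterine cysts" = "uterine cysts",
    "enlarged kidneys" = "enlarged kidneys",
    "enlarged adrenal glands" = "enlarged adrenal glands"
  )
  key <- tolower(trimws(labels))
  out <- unname(syn[key])
  bad <- is.na(out) | !(out %in% vocabulary)
  if (any(bad)) {
    stop("unknown finding label(s): ", paste(unique(labels[bad]), collapse = ", "))
  }
  out
}

#' Read a per-animal pathology table
#'
#' Accepts a CSV with columns `mouse_id`, `n_tumor_organs` and either a
#' semicolon-delimited `findings` column or one 0/1 column per finding label.
#' Finding labels are matched against the closed vocabulary
#' ([morbidity_findings()]); unknown labels and duplicated findings or mice
#' are errors.
#'
#' @param path CSV path.
#' @param vocabulary Finding vocabulary (escape hatch for other studies).
#' @return `data.frame` with `mouse_id`, `n_tumor_organs` and a `findings`
#'   list-column of canonical labels.
#' @export
read_pathology <- function(path, vocabulary = morbidity_findings()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("mouse_id", "n_tumor_organs")) {
    if (!col %in% names(df)) stop("missing mandatory column: ", col)
  }
  if (anyDuplicated(df$mouse_id)) {
    stop("duplicate mouse_id: ",
         paste(unique(df$mouse_id[duplicated(df$mouse_id)]), collapse = ", "))
  }
  df$n_tumor_organs <- as.integer(df$n_tumor_organs)
  if (any(is.na(df$n_tumor_organs)) || any(df$n_tumor_organs < 0)) {
    stop("n_tumor_organs must be a non-negative integer")
  }
  if ("findings" %in% names(df)) {
    findings <- lapply(df$findings, function(x) {
      if (is.na(x) || !nzchar(trimws(x))) return(character(0))
      canonical_finding(strsplit(x, ";")[[1]], vocabulary)
    })
  } else {
    finding_cols <- setdiff(names(df), c("mouse_id", "n_tumor_organs"))
    canon <- canonical_finding(finding_cols, vocabulary)
    findings <- lapply(seq_len(nrow(df)), function(i) {
      canon[as.integer(df[i, finding_cols]) == 1L]
    })
  }
  dup <- vapply(findings, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    stop("duplicated finding(s) for mouse: ",
         paste(df$mouse_id[dup], collapse = ", "))
  }
  data.frame(mouse_id = df$mouse_id, n_tumor_organs = df$n_tumor_organs,
             findings = I(findings), stringsAsFactors = FALSE)
}

#' Write a pathology table
#'
#' @param pathology `data.frame` as returned by [read_pathology()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pathology <- function(pathology, path) {
  out <- data.frame(
    mouse_id = pathology$mouse_id,
    n_tumor_organs = pathology$n_tumor_organs,
    findings = vapply(pathology$findings, paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

DIET_LEVELS <- c("AL", "DR", "AL_DR16M")
TISSUE_LEVELS <- c("spleen", "ileum")
AGE_LEVELS <- c(5L, 16L, 20L, 24L)

#' Read a cohort design table
#'
#' CSV with columns `sample_id`, `mouse_id`, `tissue`, `diet`, `age_months`.
#' Diets are `AL` (ad libitum), `DR` (restriction from 3 months) and
#' `AL_DR16M` (switch to restriction at 16 months, hence only valid at ages
#' >= 16).
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
read_cohort_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "mouse_id", "tissue", "diet", "age_months")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  df$age_months <- as.integer(df$age_months)
  if (!all(df$tissue %in% TISSUE_LEVELS)) stop("unknown tissue label")
  if (!all(df$diet %in% DIET_LEVELS)) stop("unknown diet label")
  bad <- df$diet == "AL_DR16M" & df$age_months < 16L
  if (any(bad)) {
    stop("AL_DR16M is only valid at ages >= 16 months (switch at 16): ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  df
}

#' Write a metric/report table as TSV
#'
#' @param df `data.frame`; one row per sample, one metric per column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
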