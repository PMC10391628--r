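# Macromorbidity index: neoplasia grade plus non-neoplastic finding burden.

#' Neoplasia grade from the tumor-affected organ count
#'
#' 0 = no tumors; 1 = one organ affected; 2 = two or more organs affected
#' (metastatic cancer).
#'
#' @param n_tumor_organs Non-negative integer vector.
#' @return Integer grade in `{0, 1, 2}`.
#' @export
neoplasia_grade <- function(n_tumor_organs) {
  n <- as.integer(n_tumor_organs)
  if (any(is.na(n)) || any(n < 0)) {
    stop("n_tumor_organs must be a non-negative integer")
  }
  pmin(n, 2L)
}

#' Macromorbidity index per mouse
#'
#' The sum of the neoplasia grade and the non-neoplastic pathology burden
#' (one degree per macroscopic finding at dissection; findings counted at
#' label level, so bilateral organs count once).
#'
#' @param pathology Pathology `data.frame` as from [read_pathology()].
#' @return `data.frame`: `mouse_id`, `neoplasia_grade`,
#'   `non_neoplastic_burden`, `macromorbidity`.
#' @export
macromorbidity <- function(pathology) {
  grade <- neoplasia_grade(pathology$n_tumor_organs)
  burden <- vapply(pathology$findings, length, integer(1))
  data.frame(mouse_id = pathology$mouse_id,
             neoplasia_grade = grade,
             non_neoplastic_burden = burden,
             macromorbidity = grade + burden,
             stringsAsFactors = FALSE)
}
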