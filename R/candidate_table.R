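#' Candidate tables
#'
#' A `candidate_table` is a data.frame of per-compound screen results with a
#' consecutive 1-based `ranking` column, ordered by mean target-gene
#' expression ascending (most negative, i.e. strongest suppression, first).
#' Required columns: `ranking`, `pert_id`, `pert_iname`, `n_profiles`,
#' `mean_expression`, `p_value`. An informational Benjamini-Hochberg
#' `q_value` column may be present; it never participates in selection
#' under the published preset.
#'
#' @param x data.frame to validate and classify.
#' @return `x` with class `candidate_table`, columns ordered canonically.
#' @export
as_candidate_table <- function(x) {
  if (inherits(x, "candidate_table")) return(x)
  if (!is.data.frame(x)) abort_args("a candidate table must be a data.frame")
  need <- c("ranking", "pert_id", "pert_iname", "n_profiles",
            "mean_expression", "p_value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort_args("candidate table is missing columns: %s",
               paste(miss, collapse = ", "))
  x <- x[, c(need, setdiff(names(x), need)), drop = FALSE]
  x$ranking <- as.integer(x$ranking)
  x$n_profiles <- as.integer(x$n_profiles)
  if (nrow(x) > 0 && !identical(x$ranking, seq_len(nrow(x))))
    abort_integrity("rankings must be consecutive from 1")
  rownames(x) <- NULL
  class(x) <- c("candidate_table", "data.frame")
  x
}

empty_candidate_table <- function() {
  as_candidate_table(data.frame(
    ranking = integer(0), pert_id = character(0), pert_iname = character(0),
    n_profiles = integer(0), mean_expression = numeric(0),
    p_value = numeric(0), stringsAsFactors = FALSE))
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("candidate_table: %d compound(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
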