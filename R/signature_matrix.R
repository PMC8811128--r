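#' Construct a level-5 signature matrix
#'
#' A `sig_matrix` holds replicate-collapsed (level-5) differential-expression
#' values on the z-score-like scale used by the L1000 platform: one value per
#' (gene, signature) pair, genes on rows and signatures on columns. Values are
#' dimensionless z-units relative to the plate control.
#'
#' @param values numeric matrix, genes x signatures. Dimnames, if present,
#'   are ignored in favour of `gene_ids` / `sig_ids`.
#' @param gene_ids character vector of unique gene identifiers (row order).
#' @param sig_ids character vector of unique signature identifiers
#'   (column order).
#'
#' @return An object of class `sig_matrix`: a numeric matrix whose rownames
#'   are gene ids and colnames are signature ids. Missing values are `NA`;
#'   all other entries must be finite.
#' @examples
#' m <- sig_matrix(matrix(rnorm(6), 2, 3),
#'                 gene_ids = c("101", "102"),
#'                 sig_ids = c("s1", "s2", "s3"))
#' dim(m)
#' @export
sig_matrix <- function(values, gene_ids, sig_ids) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_args("'values' must be a numeric matrix")
  gene_ids <- as.character(gene_ids)
  sig_ids <- as.character(sig_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sig_ids))
    abort_args("matrix is %d x %d but %d gene ids and %d signature ids given",
               nrow(values), ncol(values), length(gene_ids), length(sig_ids))
  if (anyDuplicated(gene_ids))
    abort_integrity("duplicate gene ids: %s",
                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sig_ids))
    abort_integrity("duplicate signature ids: %s",
                    paste(unique(sig_ids[duplicated(sig_ids)]), collapse = ", "))
  if (any(is.infinite(values)))
    abort_args("matrix values must be finite or NA")
  dimnames(values) <- list(gene_ids, sig_ids)
  class(values) <- c("sig_matrix", class(values))
  values
}

is_sig_matrix <- function(x) inherits(x, "sig_matrix")

#' @export
print.sig_matrix <- function(x, ...) {
  cat(sprintf("sig_matrix: %d genes x %d signatures (level-5 z-units)\n",
              nrow(x), ncol(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show_r <- seq_len(min(5L, nrow(x)))
    show_c <- seq_len(min(5L, ncol(x)))
    print(unclass(x)[show_r, show_c, drop = FALSE])
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

#' Extract one gene's values across all signatures
#'
#' @param matrix a `sig_matrix`.
#' @param gene_id gene identifier present on the row axis.
#' @return Named numeric vector (names are signature ids).
#' @export
gene_values <- function(matrix, gene_id) {
  if (!is_sig_matrix(matrix)) abort_args("'matrix' must be a sig_matrix")
  gene_id <- as.character(gene_id)
  if (!gene_id %in% rownames(matrix))
    abort_lookup("gene id not present in matrix: %s", gene_id)
  unclass(matrix)[gene_id, ]
}
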