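# File I/O for the standard L1000 artefacts: gene_info / sig_info metadata
# TSVs, the GCT (text, version 1.3) and GCTX (HDF5) matrix containers, and
# the ranked candidate table.

# GCTX layout: the matrix dataset lives at 0/DATA/0/matrix with row
# (gene) ids at 0/META/ROW/id and column (signature) ids at 0/META/COL/id.
# In the HDF5 file the matrix is stored signatures x genes (the layout
# written by the reference tooling); rhdf5 reverses HDF5 dimension order on
# read, so an R-side genes x signatures matrix round-trips unchanged.
GCTX_MATRIX <- "0/DATA/0/matrix"
GCTX_RID <- "0/META/ROW/id"
GCTX_CID <- "0/META/COL/id"
GCTX_VERSION <- "GCTX1.0"

pick_column <- function(header, candidates) {
  hit <- intersect(candidates, header)
  if (length(hit) == 0) NA_character_ else hit[[1L]]
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) abort_args("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "", na.strings = NULL)
}

#' Read an L1000 gene-info metadata table
#'
#' Parses a tab-separated gene annotation table in the dialect deposited
#' alongside L1000 level-5 data: a header row with a gene id column
#' (`pr_gene_id`), a symbol column (`pr_gene_symbol`) and the landmark /
#' well-inferred flag columns (`pr_is_lm`, `pr_is_bing`). The L1000
#' missing-value sentinel `-666` is mapped to `NA`.
#'
#' Each gene is assigned one of three inference tiers: `landmark` (measured
#' directly on the bead assay), `well_inferred` (imputed with validated
#' correlation to measurement) or `less_well_inferred`.
#'
#' @param path path to the tab-delimited gene-info file.
#' @return A data.frame with columns `gene_id` (character, unique), `symbol`
#'   (character, may be `NA`) and `tier` (factor with levels `landmark`,
#'   `well_inferred`, `less_well_inferred`).
#' @export
read_gene_metadata <- function(path) {
  tab <- read_tsv_raw(path)
  id_col <- pick_column(names(tab), c("pr_gene_id", "gene_id", "id"))
  sym_col <- pick_column(names(tab), c("pr_gene_symbol", "gene_symbol", "symbol"))
  lm_col <- pick_column(names(tab), c("pr_is_lm", "is_lm", "is_landmark", "landmark"))
  bing_col <- pick_column(names(tab), c("pr_is_bing", "is_bing", "is_well_inferred",
                                        "well_inferred"))
  cols <- c(gene_id = id_col, symbol = sym_col, landmark_flag = lm_col,
            inferred_flag = bing_col)
  if (anyNA(cols))
    abort_format("gene metadata is missing a required column: %s",
                 paste(names(cols)[is.na(cols)], collapse = ", "))
  gene_id <- trimws(tab[[id_col]])
  if (anyDuplicated(gene_id))
    abort_integrity("duplicate gene_id in %s: %s", path,
                    paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  is_lm <- sentinel_to_na(tab[[lm_col]]) %in% c("1", "TRUE", "true")
  is_bing <- sentinel_to_na(tab[[bing_col]]) %in% c("1", "TRUE", "true")
  tier <- ifelse(is_lm, "landmark",
                 ifelse(is_bing, "well_inferred", "less_well_inferred"))
  out <- data.frame(
    gene_id = gene_id,
    symbol = sentinel_to_na(tab[[sym_col]]),
    tier = factor(tier, levels = c("landmark", "well_inferred",
                                   "less_well_inferred")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read an L1000 sig-info signature metadata table
#'
#' Parses the tab-separated per-signature annotation table (one row per
#' level-5 signature). Standard columns are normalised to `sig_id`,
#' `pert_id`, `pert_iname`, `pert_type`, `cell_id`, `dose` and `time`; any
#' further columns in the file are preserved verbatim after these. The
#' sentinel `-666` becomes `NA` in every field.
#'
#' @param path path to the tab-delimited sig-info file. A `sig_id` column is
#'   required and must be unique.
#' @return A data.frame with the normalised columns above (character) plus
#'   any extra columns from the file.
#' @export
read_signature_metadata <- function(path) {
  tab <- read_tsv_raw(path)
  if (!"sig_id" %in% names(tab))
    abort_format("signature metadata is missing a required column: sig_id")
  sig_id <- trimws(tab[["sig_id"]])
  if (anyDuplicated(sig_id))
    abort_integrity("duplicate sig_id in %s: %s", path,
                    paste(unique(sig_id[duplicated(sig_id)]), collapse = ", "))
  std <- c(pert_id = "pert_id", pert_iname = "pert_iname",
           pert_type = "pert_type", cell_id = "cell_id")
  out <- data.frame(sig_id = sig_id, stringsAsFactors = FALSE)
  for (nm in names(std)) {
    out[[nm]] <- if (std[[nm]] %in% names(tab))
      sentinel_to_na(tab[[std[[nm]]]]) else NA_character_
  }
  dose_col <- pick_column(names(tab), c("pert_idose", "pert_dose", "dose"))
  time_col <- pick_column(names(tab), c("pert_itime", "pert_time", "time"))
  out[["dose"]] <- if (!is.na(dose_col)) sentinel_to_na(tab[[dose_col]]) else NA_character_
  out[["time"]] <- if (!is.na(time_col)) sentinel_to_na(tab[[time_col]]) else NA_character_
  consumed <- c("sig_id", unname(std), dose_col, time_col)
  extra <- setdiff(names(tab), consumed[!is.na(consumed)])
  for (nm in extra) out[[nm]] <- sentinel_to_na(tab[[nm]])
  rownames(out) <- NULL
  out
}

detect_matrix_format <- function(path) {
  if (!file.exists(path)) abort_args("file not found: %s", path)
  if (isTRUE(rhdf5::H5Fis_hdf5(path))) return("gctx")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1L && startsWith(first, "#")) return("gct")
  abort_format("cannot identify %s as GCTX (HDF5) or GCT text", path)
}

#' Read a level-5 signature matrix from GCTX or GCT
#'
#' Reads a genes x signatures differential-expression matrix from either the
#' binary GCTX container (HDF5) or the GCT text format, version 1.3. The
#' format is detected from the file itself. Row and column identifier order
#' is preserved exactly as stored; nothing is sorted.
#'
#' When `gene_subset` is given only those gene rows are materialised: for
#' GCTX the rows are read through an HDF5 hyperslab selection, and for GCT
#' the file is scanned line by line, so a single-gene query against a matrix
#' with hundreds of thousands of signatures never loads the full gene
#' dimension into memory.
#'
#' @param path path to a `.gctx` or `.gct` file.
#' @param gene_subset optional character vector of gene ids to extract, in
#'   the order requested. Every id must exist in the file.
#' @return A [sig_matrix].
#' @export
read_signature_matrix <- function(path, gene_subset = NULL) {
  switch(detect_matrix_format(path),
         gctx = read_gctx(path, gene_subset),
         gct = read_gct(path, gene_subset))
}

check_subset <- function(gene_subset, gene_ids, path) {
  gene_subset <- as.character(gene_subset)
  missing <- setdiff(gene_subset, gene_ids)
  if (length(missing) > 0)
    abort_lookup("gene ids not present in %s: %s", path,
                 paste(missing, collapse = ", "))
  gene_subset
}

read_gctx <- function(path, gene_subset = NULL) {
  rid <- trimws(as.character(rhdf5::h5read(path, GCTX_RID)))
  cid <- trimws(as.character(rhdf5::h5read(path, GCTX_CID)))
  if (is.null(gene_subset)) {
    vals <- rhdf5::h5read(path, GCTX_MATRIX)
  } else {
    gene_subset <- check_subset(gene_subset, rid, path)
    idx <- match(gene_subset, rid)
    ord <- sort(unique(idx))
    vals <- rhdf5::h5read(path, GCTX_MATRIX, index = list(ord, NULL))
    vals <- vals[match(idx, ord), , drop = FALSE]
    rid <- rid[idx]
  }
  vals <- as.matrix(vals)
  storage.mode(vals) <- "double"
  if (nrow(vals) != length(rid) || ncol(vals) != length(cid))
    abort_format("GCTX %s: matrix is %d x %d but %d row / %d column ids",
                 path, nrow(vals), ncol(vals), length(rid), length(cid))
  sig_matrix(vals, rid, cid)
}

read_gct <- function(path, gene_subset = NULL) {
  con <- file(path, open = "rt")
  on.exit(close(con), add = TRUE)
  version <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(version), "#1.3"))
    abort_format("GCT %s: unsupported version line %s (only #1.3 is read)",
                 path, dQuote(trimws(version)))
  dim_line <- readLines(con, n = 1L, warn = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(trimws(dim_line), "\t")[[1L]]))
  if (length(dims) != 4L || anyNA(dims) || any(dims < 0))
    abort_format("GCT %s: malformed dimension header %s (need 4 integers)",
                 path, dQuote(dim_line))
  n_genes <- dims[[1L]]; n_sigs <- dims[[2L]]
  n_rmeta <- dims[[3L]]; n_cmeta <- dims[[4L]]
  header <- strsplit(readLines(con, n = 1L, warn = FALSE), "\t")[[1L]]
  if (length(header) != 1L + n_rmeta + n_sigs)
    abort_format("GCT %s: header has %d fields, expected %d",
                 path, length(header), 1L + n_rmeta + n_sigs)
  cid <- trimws(header[(2L + n_rmeta):length(header)])
  if (n_cmeta > 0) readLines(con, n = n_cmeta, warn = FALSE)  # col metadata rows
  want <- if (is.null(gene_subset)) NULL else as.character(gene_subset)
  rid <- character(0)
  rows <- list()
  for (i in seq_len(n_genes)) {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      abort_format("GCT %s: expected %d data rows, file ended at row %d",
                   path, n_genes, i - 1L)
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    id <- trimws(fields[[1L]])
    rid <- c(rid, id)
    if (!is.null(want) && !(id %in% want)) next
    vals <- suppressWarnings(as.numeric(fields[(2L + n_rmeta):length(fields)]))
    if (length(vals) != n_sigs)
      abort_format("GCT %s: row %s has %d values, expected %d",
                   path, id, length(vals), n_sigs)
    rows[[id]] <- vals
  }
  if (is.null(want)) {
    keep <- rid
  } else {
    keep <- check_subset(want, rid, path)
  }
  mat <- do.call(rbind, rows[keep])
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = 0, ncol = n_sigs)
  sig_matrix(mat, keep, cid)
}

#' Write a signature matrix as GCTX or GCT
#'
#' Writes a [sig_matrix] to disk in the standard GCTX (HDF5) layout or as
#' GCT text, version 1.3. A GCTX round-trip reproduces values bit-exactly;
#' GCT text is written with four decimal places, so a round-trip agrees to
#' 1e-4. Matrices with an empty gene or signature axis are rejected.
#'
#' @param matrix a [sig_matrix].
#' @param path output path.
#' @param format `"gctx"` or `"gct"`.
#' @return Invisibly, `path`.
#' @export
write_signature_matrix <- function(matrix, path, format = c("gctx", "gct")) {
  format <- match.arg(format)
  if (!is_sig_matrix(matrix)) abort_args("'matrix' must be a sig_matrix")
  if (nrow(matrix) == 0L || ncol(matrix) == 0L)
    abort_format("refusing to write a degenerate %d x %d matrix",
                 nrow(matrix), ncol(matrix))
  if (format == "gctx") write_gctx(matrix, path) else write_gct(matrix, path)
  invisible(path)
}

write_gctx <- function(matrix, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "0")
  rhdf5::h5createGroup(path, "0/DATA")
  rhdf5::h5createGroup(path, "0/DATA/0")
  rhdf5::h5createGroup(path, "0/META")
  rhdf5::h5createGroup(path, "0/META/ROW")
  rhdf5::h5createGroup(path, "0/META/COL")
  # h5write stores an R genes x signatures matrix with HDF5 dims
  # (signatures, genes) — the reference GCTX orientation.
  rhdf5::h5write(unclass(matrix), path, GCTX_MATRIX)
  rhdf5::h5write(rownames(matrix), path, GCTX_RID)
  rhdf5::h5write(colnames(matrix), path, GCTX_CID)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(GCTX_VERSION, fid, "version")
  rhdf5::H5Fclose(fid)
}

write_gct <- function(matrix, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("#1.3", con)
  writeLines(sprintf("%d\t%d\t0\t0", nrow(matrix), ncol(matrix)), con)
  writeLines(paste(c("id", colnames(matrix)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    vals <- ifelse(is.na(matrix[i, ]), "NA", sprintf("%.4f", matrix[i, ]))
    paste(c(rownames(matrix)[i], vals), collapse = "\t")
  }, character(1))
  writeLines(body, con)
}

#' Write a ranked candidate table
#'
#' Serialises a [candidate_table] as a tab-separated file with the columns
#' `ranking`, `pert_id`, `pert_iname`, `mean_expression`, `p_value` and
#' `n_profiles`. Means are printed with three decimals and p-values in
#' scientific notation with three significant digits (the conventional
#' presentation for this kind of screen, e.g. `-0.605` and `4.16E-14`).
#'
#' @param table a [candidate_table].
#' @param path output path.
#' @return Invisibly, `path`.
#' @seealso [read_candidate_table()]
#' @export
write_candidate_table <- function(table, path) {
  table <- as_candidate_table(table)
  fmt_p <- ifelse(is.na(table$p_value), "NA", sprintf("%.2E", table$p_value))
  out <- data.frame(
    ranking = table$ranking,
    pert_id = table$pert_id,
    pert_iname = table$pert_iname,
    mean_expression = sprintf("%.3f", table$mean_expression),
    p_value = fmt_p,
    n_profiles = table$n_profiles,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#'
#' Also accepts a hand-typed copy of a published candidate table in the same
#' dialect (tab-separated, with at least `pert_id`, `pert_iname`,
#' `mean_expression` and `p_value` columns; `ranking` and `n_profiles` are
#' optional and recomputed downstream). Unicode minus signs are normalised.
#'
#' @param path path to the TSV.
#' @return A [candidate_table] (re-ranked if no ranking column was present).
#' @export
read_candidate_table <- function(path) {
  tab <- read_tsv_raw(path)
  need <- c("pert_id", "pert_iname", "mean_expression", "p_value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    abort_format("candidate table %s is missing columns: %s",
                 path, paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(gsub("−", "-", trimws(x))))
  int <- function(x) suppressWarnings(as.integer(trimws(x)))
  n <- nrow(tab)
  out <- data.frame(
    ranking = if ("ranking" %in% names(tab)) int(tab$ranking) else
      rep(NA_integer_, n),
    pert_id = trimws(tab$pert_id),
    pert_iname = trimws(tab$pert_iname),
    n_profiles = if ("n_profiles" %in% names(tab))
      int(tab$n_profiles) else rep(NA_integer_, n),
    mean_expression = num(tab$mean_expression),
    p_value = num(tab$p_value),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$mean_expression))
    abort_format("candidate table %s: non-numeric mean_expression values", path)
  if (anyNA(out$ranking)) out$ranking <- seq_len(nrow(out))
  as_candidate_table(out)
}
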