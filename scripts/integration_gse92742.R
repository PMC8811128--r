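#!/usr/bin/env Rscript

# Full-cohort reproduction of the CROT screen against the public GSE92742
# level-5 release. Requires the multi-gigabyte download (not shipped):
#   GSE92742_Broad_LINCS_Level5_COMPZ.MODZ_n473647x12328.gctx
#   GSE92742_Broad_LINCS_sig_info.txt
#   GSE92742_Broad_LINCS_gene_info.txt
# from the Gene Expression Omnibus, accession GSE92742.
#
# Usage:
#   Rscript scripts/integration_gse92742.R --dir <download dir> --out <tsv>
#
# With the published preset this reproduces: 473,647 level-5 profiles;
# 12,328 genes of which 978 landmark; 205,033 trt_cp signatures over 20,412
# small molecules; a 16-row candidate table with niclosamide at ranking 5
# (mean CROT expression -0.605) and cucurbitacin-i at ranking 1 (-0.953).
# Runtime is about one to two hours on a single CPU; the matrix is accessed
# one gene row at a time, so memory stays modest.

suppressPackageStartupMessages({
  library(cmapscreen)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", help = "directory with the GSE92742 files"),
  make_option("--out", type = "character", default = "gse92742_crot_candidates_reproduced.tsv")
)))
if (is.null(opts$dir)) stop("--dir is required (see the header of this script)")

path_of <- function(pattern) {
  hits <- list.files(opts$dir, pattern = pattern, full.names = TRUE)
  if (length(hits) != 1L)
    stop(sprintf("expected exactly one file matching %s in %s", pattern, opts$dir))
  hits
}

matrix_path <- path_of("Level5_COMPZ.*\\.gctx$")
sig_path <- path_of("sig_info\\.txt$")
gene_path <- path_of("gene_info\\.txt$")

message("reading metadata ...")
sig_meta <- read_signature_metadata(sig_path)
gene_meta <- read_gene_metadata(gene_path)
message(sprintf("%d signatures, %d genes (%d landmark)", nrow(sig_meta),
                nrow(gene_meta), sum(gene_meta$tier == "landmark")))

trt_cp <- filter_signatures(sig_meta, "trt_cp")
message(sprintf("trt_cp signatures: %d over %d small molecules",
                nrow(trt_cp), length(unique(trt_cp$pert_id))))

message("running the screen (single-gene slice of the level-5 matrix) ...")
table <- run_screen(matrix_path, sig_meta, gene_meta, screen_config())
message(sprintf("candidates selected: %d", nrow(table)))
print(table)

write_candidate_table(table, opts$out)
curated <- apply_exclusions(table, read_exclusion_list(system.file(
  "extdata", "gse92742_crot_exclusions.txt", package = "cmapscreen")))
message(sprintf("after curated exclusions: %d candidates", nrow(curated)))
write_candidate_table(curated, sub("\\.tsv$", "_curated.tsv", opts$out))
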