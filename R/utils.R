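# Internal helpers shared across the pipeline.

GENE_CLASSES <- c("pifsd_induced", "pifsd_repressed", "sd_only", "pif_only",
                  "ambiguous", "null")

# Extract the numeric genes x samples matrix from an expression tibble
# (first column gene_id, remaining columns one per sample).
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- expr$gene_id
  m
}

validate_expression <- function(expr, samples) {
  if (anyDuplicated(expr$gene_id)) {
    abort(paste0("duplicated gene ids: ",
                 paste(unique(expr$gene_id[duplicated(expr$gene_id)]), collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicated sample ids in sample sheet")
  sample_cols <- setdiff(names(expr), "gene_id")
  missing_meta <- setdiff(sample_cols, samples$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("samples in matrix absent from sample sheet: ",
                 paste(missing_meta, collapse = ", ")))
  }
  missing_col <- setdiff(samples$sample_id, sample_cols)
  if (length(missing_col) > 0) {
    abort(paste0("samples in sheet absent from matrix: ",
                 paste(missing_col, collapse = ", ")))
  }
  m <- expr_matrix(expr)
  if (any(!is.finite(m))) abort("expression matrix contains non-finite values")
  invisible(TRUE)
}

# Sample ids belonging to one genotype x condition cell.
group_sample_ids <- function(samples, group) {
  stopifnot(length(group) == 2)
  samples$sample_id[samples$genotype == group[1] & samples$condition == group[2]]
}

# Per-gene mean of log2 values over the samples of one group; named vector.
group_mean <- function(expr, samples, group) {
  ids <- group_sample_ids(samples, group)
  if (length(ids) == 0) {
    abort(paste0("no samples for group ", group[1], "-", group[2]))
  }
  m <- expr_matrix(expr)[, ids, drop = FALSE]
  rowMeans(m)
}

group_label <- function(group) paste(group[1], group[2], sep = "-")

# Round-half-to-even to one decimal, the convention used for reported percentages.
pct1 <- function(x) round(x, 1)
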