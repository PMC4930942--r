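# Percent contribution of PIFq to the wild-type night response.

#' Percent contribution of PIFq to the wild-type night response
#'
#' `100 * (fc_wt - fc_pifq) / fc_wt`, where both fold changes are log2
#' differences relative to the WT-LL reference: the fraction of the WT
#' night response (SD vs LL) removed by loss of the PIF quartet. 100 when
#' the mutant shows no response, 0 when it matches the wild type; values
#' above 100 (mutant response of opposite sign) are not clipped.
#'
#' @param fc_wt_log2 WT-SD minus WT-LL group-mean log2 fold change.
#' @param fc_pifq_log2 pifq-SD minus WT-LL group-mean log2 fold change.
#' @return Percent contribution (vectorized).
#' @export
contribution_pct <- function(fc_wt_log2, fc_pifq_log2) {
  100 * (fc_wt_log2 - fc_pifq_log2) / fc_wt_log2
}

#' Per-gene PIFq contribution records
#'
#' For each requested gene, computes the log2 fold changes of WT-SD and
#' pifq-SD relative to the WT-LL group mean and the derived percent
#' contribution. Genes whose WT night response is below `floor_log2fc` in
#' magnitude are flagged undefined (the ratio is unstable there) rather than
#' erroring; they are excluded from set summaries. PIF/SD gene lists always
#' pass the default floor, which equals the SS1.5F fold-change gate.
#'
#' @param expr,samples Expression tibble and sample sheet.
#' @param genes Character vector of gene ids (subset of the matrix universe).
#' @param floor_log2fc Minimum `|fc_wt_log2|` for a defined contribution
#'   (default `log2(1.5)`).
#' @return Tibble: gene_id, fc_wt_log2, fc_pifq_log2, contribution_pct,
#'   defined.
#' @export
per_gene_contribution <- function(expr, samples, genes,
                                  floor_log2fc = log2(1.5)) {
  validate_expression(expr, samples)
  missing <- setdiff(genes, expr$gene_id)
  if (length(missing) > 0) {
    abort(paste0("genes not in matrix: ", paste(head(missing, 5), collapse = ", ")))
  }
  mu_wtll <- group_mean(expr, samples, c("WT", "LL"))
  mu_wtsd <- group_mean(expr, samples, c("WT", "SD"))
  mu_pifqsd <- group_mean(expr, samples, c("pifq", "SD"))
  fc_wt <- (mu_wtsd - mu_wtll)[genes]
  fc_pifq <- (mu_pifqsd - mu_wtll)[genes]
  defined <- abs(fc_wt) >= floor_log2fc
  tibble(
    gene_id = genes,
    fc_wt_log2 = unname(fc_wt),
    fc_pifq_log2 = unname(fc_pifq),
    contribution_pct = unname(ifelse(defined, contribution_pct(fc_wt, fc_pifq),
                                     NA_real_)),
    defined = unname(defined)
  )
}

#' Mean log2 fold change of a gene set relative to WT-LL
#'
#' Mean over the genes of (group-mean log2 minus WT-LL-mean log2), with its
#' standard error over genes. The WT-LL group itself returns 0 by
#' construction.
#'
#' @param expr,samples Expression tibble and sample sheet.
#' @param genes Non-empty character vector of gene ids.
#' @param group Length-2 character vector `c(genotype, condition)`.
#' @return One-row tibble: group, mean_fc, se.
#' @export
set_mean_fc <- function(expr, samples, genes, group) {
  if (length(genes) == 0) abort("empty gene set")
  validate_expression(expr, samples)
  mu_ref <- group_mean(expr, samples, c("WT", "LL"))
  mu_grp <- group_mean(expr, samples, group)
  fc <- (mu_grp - mu_ref)[genes]
  tibble(group = group_label(group),
         mean_fc = mean(fc),
         se = if (length(fc) > 1) sd(fc) / sqrt(length(fc)) else 0)
}

#' Set-level PIFq contribution from set-mean fold changes
#'
#' The contribution formula applied to the set means (the ratio of means,
#' not the mean of ratios), matching how a set-level contribution is read
#' off a bar graph of mean fold changes.
#'
#' @inheritParams set_mean_fc
#' @return Percent contribution (scalar).
#' @export
set_contribution <- function(expr, samples, genes) {
  fc_wt <- set_mean_fc(expr, samples, genes, c("WT", "SD"))$mean_fc
  fc_pifq <- set_mean_fc(expr, samples, genes, c("pifq", "SD"))$mean_fc
  contribution_pct(fc_wt, fc_pifq)
}

#' Wilcoxon rank-sum comparison of two groups over a gene set
#'
#' Compares the distributions of per-gene group-mean log2 expression between
#' two genotype x condition groups across the genes of a set. Exact null
#' enumeration when the combined size is <= 20 and there are no ties;
#' otherwise the normal approximation with continuity correction (mid-ranks
#' for ties).
#'
#' @param expr,samples Expression tibble and sample sheet.
#' @param genes Gene set (>= 2 genes).
#' @param group_a,group_b Length-2 character vectors `c(genotype, condition)`.
#' @return Two-sided p-value.
#' @export
group_distribution_test <- function(expr, samples, genes, group_a, group_b) {
  if (length(genes) < 2) abort("need >= 2 genes")
  validate_expression(expr, samples)
  a <- group_mean(expr, samples, group_a)[genes]
  b <- group_mean(expr, samples, group_b)[genes]
  wilcoxon_p(a, b)
}

# Two-sided rank-sum p-value with the exact/approximate switch at combined
# n = 20; all-tied inputs return 1.
wilcoxon_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1) return(1)
  exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Rank genes by percent contribution
#'
#' Orders the defined contribution records descending and reports the
#' fraction of genes with contribution strictly above 50% and at or above
#' 100%.
#'
#' @param records Tibble from [per_gene_contribution()].
#' @return Object of class `contribution_ranking`: a list with `ranked`
#'   (tibble with a `rank` column), `frac_gt_50`, `frac_ge_100`,
#'   `n_defined`. Has [tidy()] and [glance()] methods.
#' @export
contribution_ranking <- function(records) {
  rec <- records[records$defined & !is.na(records$contribution_pct), ]
  if (nrow(rec) < 1) abort("no defined contribution records")
  rec <- arrange(rec, desc(.data$contribution_pct))
  rec$rank <- seq_len(nrow(rec))
  out <- list(
    ranked = rec,
    frac_gt_50 = mean(rec$contribution_pct > 50),
    frac_ge_100 = mean(rec$contribution_pct >= 100),
    n_defined = nrow(rec)
  )
  class(out) <- "contribution_ranking"
  out
}

#' @export
print.contribution_ranking <- function(x, ...) {
  cat("Contribution ranking:", x$n_defined, "genes;",
      sprintf("%.1f%% > 50%%, %.1f%% >= 100%%\n",
              100 * x$frac_gt_50, 100 * x$frac_ge_100))
  print(head(x$ranked, 5))
  invisible(x)
}

#' @rdname contribution_ranking
#' @param x A `contribution_ranking` object.
#' @param ... Unused.
#' @method tidy contribution_ranking
#' @export
tidy.contribution_ranking <- function(x, ...) x$ranked

#' @rdname contribution_ranking
#' @method glance contribution_ranking
#' @export
glance.contribution_ranking <- function(x, ...) {
  tibble(n_defined = x$n_defined, frac_gt_50 = x$frac_gt_50,
         frac_ge_100 = x$frac_ge_100)
}
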