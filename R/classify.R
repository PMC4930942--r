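# Sign-concordant intersection classification of the two contrasts.

#' Classify genes by the sign-concordant intersection of two contrasts
#'
#' Intersects the SS1.5F gene lists of the night contrast (WT-SD vs WT-LL,
#' `sd`) and the genotype contrast (pifq-SD vs WT-SD, `pif`) and labels each
#' gene of the shared universe:
#'
#' * `pifsd_induced`: SS1.5F in both, `sd_log2fc > 0` and `pif_log2fc < 0`
#'   (up in the wild type at night, down on removing PIFq);
#' * `pifsd_repressed`: SS1.5F in both, `sd_log2fc < 0` and `pif_log2fc > 0`;
#' * `ambiguous`: SS1.5F in both with the same sign in both contrasts;
#' * `sd_only` / `pif_only`: SS1.5F in exactly one contrast;
#' * `none`: in neither.
#'
#' A gene with `log2fc` exactly 0 cannot be SS1.5F in that contrast, so the
#' sign rules never see a zero.
#'
#' @param sd,pif Contrast tibbles from [run_contrast()] over the same gene
#'   universe.
#' @return Tibble: gene_id, label, sd_log2fc, pif_log2fc.
#' @export
classify_genes <- function(sd, pif) {
  if (!setequal(sd$gene_id, pif$gene_id)) {
    nd <- length(union(setdiff(sd$gene_id, pif$gene_id),
                       setdiff(pif$gene_id, sd$gene_id)))
    abort(paste0("contrasts cover different gene universes (symmetric difference: ",
                 nd, " genes)"))
  }
  pif <- pif[match(sd$gene_id, pif$gene_id), ]
  in_sd <- sd$ss15f
  in_pif <- pif$ss15f
  s_sd <- sign(sd$log2fc)
  s_pif <- sign(pif$log2fc)
  label <- dplyr::case_when(
    in_sd & in_pif & s_sd > 0 & s_pif < 0 ~ "pifsd_induced",
    in_sd & in_pif & s_sd < 0 & s_pif > 0 ~ "pifsd_repressed",
    in_sd & in_pif ~ "ambiguous",
    in_sd ~ "sd_only",
    in_pif ~ "pif_only",
    TRUE ~ "none"
  )
  tibble(gene_id = sd$gene_id, label = label,
         sd_log2fc = sd$log2fc, pif_log2fc = pif$log2fc)
}

#' Venn counts and percentages of a classification
#'
#' Counts the two SS1.5F lists, their intersection and its induced /
#' repressed / ambiguous split, and the headline percentages (one decimal,
#' round-half-even): common genes as a share of the genotype-contrast list,
#' and the induced / repressed shares of the common set. With an empty
#' intersection the percentages are `NA` rather than division failures.
#'
#' @param classification Tibble from [classify_genes()].
#' @return One-row tibble: n_sd_regulated, n_pif_regulated, n_common,
#'   n_induced, n_repressed, n_ambiguous, pct_common_of_pif,
#'   pct_induced_of_common, pct_repressed_of_common.
#' @export
venn_summary <- function(classification) {
  lab <- classification$label
  n_induced <- sum(lab == "pifsd_induced")
  n_repressed <- sum(lab == "pifsd_repressed")
  n_ambiguous <- sum(lab == "ambiguous")
  n_common <- n_induced + n_repressed + n_ambiguous
  n_sd <- n_common + sum(lab == "sd_only")
  n_pif <- n_common + sum(lab == "pif_only")
  tibble(
    n_sd_regulated = n_sd,
    n_pif_regulated = n_pif,
    n_common = n_common,
    n_induced = n_induced,
    n_repressed = n_repressed,
    n_ambiguous = n_ambiguous,
    pct_common_of_pif = if (n_pif > 0) pct1(100 * n_common / n_pif) else NA_real_,
    pct_induced_of_common = if (n_common > 0) pct1(100 * n_induced / n_common) else NA_real_,
    pct_repressed_of_common = if (n_common > 0) pct1(100 * n_repressed / n_common) else NA_real_
  )
}

#' Venn summary from printed counts
#'
#' Convenience constructor for computing the headline percentages directly
#' from count data (e.g. a published Venn diagram) without per-gene records.
#'
#' @param n_sd_regulated,n_pif_regulated,n_common,n_induced,n_repressed
#'   Nonnegative integers; `n_ambiguous` defaults to
#'   `n_common - n_induced - n_repressed`.
#' @param n_ambiguous Optional explicit ambiguous count.
#' @return One-row tibble as [venn_summary()].
#' @export
venn_summary_counts <- function(n_sd_regulated, n_pif_regulated, n_common,
                                n_induced, n_repressed,
                                n_ambiguous = n_common - n_induced - n_repressed) {
  if (n_common != n_induced + n_repressed + n_ambiguous) {
    abort("n_common must equal n_induced + n_repressed + n_ambiguous")
  }
  tibble(
    n_sd_regulated = as.integer(n_sd_regulated),
    n_pif_regulated = as.integer(n_pif_regulated),
    n_common = as.integer(n_common),
    n_induced = as.integer(n_induced),
    n_repressed = as.integer(n_repressed),
    n_ambiguous = as.integer(n_ambiguous),
    pct_common_of_pif = if (n_pif_regulated > 0) pct1(100 * n_common / n_pif_regulated) else NA_real_,
    pct_induced_of_common = if (n_common > 0) pct1(100 * n_induced / n_common) else NA_real_,
    pct_repressed_of_common = if (n_common > 0) pct1(100 * n_repressed / n_common) else NA_real_
  )
}

#' One-sided binomial test of reciprocal-sign concordance
#'
#' Among the common (SS1.5F-in-both) genes, counts those in the
#' reciprocal-sign quadrants (induced + repressed) as successes out of the
#' common total and returns the exact upper tail `P(X >= x | n, p = 0.5)` —
#' the association the fold-change scatterplot illustrates.
#'
#' @param classification Tibble from [classify_genes()].
#' @return One-sided binomial p-value.
#' @export
quadrant_binomial_test <- function(classification) {
  lab <- classification$label
  x <- sum(lab %in% c("pifsd_induced", "pifsd_repressed"))
  n <- x + sum(lab == "ambiguous")
  if (n < 1) abort("no common genes")
  pbinom(x - 1, n, 0.5, lower.tail = FALSE)
}

#' Overlap partition of two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return One-row tibble: n_a_only, n_b_only, n_both.
#' @export
set_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  tibble(n_a_only = length(setdiff(a, b)),
         n_b_only = length(setdiff(b, a)),
         n_both = length(intersect(a, b)))
}
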