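# Per-gene two-group contrasts with fold-change + FDR (SS1.5F) gating.

#' Per-gene Welch two-sample test on log2 values
#'
#' Vectorized textbook Welch t: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Genes where both groups have zero variance are flagged `degenerate` and
#' get p = 1 for equal means, p = 0 for unequal means (noiseless
#' separation). Suitable as `test_fun` for [run_contrast()].
#'
#' @param test_m,ref_m Numeric matrices (genes x replicates) of log2 values.
#' @return Tibble: log2fc, p_value, degenerate.
#' @export
welch_test <- function(test_m, ref_m) {
  n1 <- ncol(test_m); n2 <- ncol(ref_m)
  m1 <- rowMeans(test_m); m2 <- rowMeans(ref_m)
  v1 <- rowSums((test_m - m1)^2) / (n1 - 1)
  v2 <- rowSums((ref_m - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  log2fc <- m1 - m2
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, NA_real_, log2fc / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate & log2fc == 0] <- 1
  p[degenerate & log2fc != 0] <- 0
  tibble(log2fc = unname(log2fc), p_value = unname(p),
         degenerate = unname(degenerate))
}

# Per-gene moderated two-group test (limma): ordinary least-squares group
# fit with empirical-Bayes variance moderation across genes — the standard
# small-replicate microarray test and the closest open substitute for an
# error-weighted per-gene ANOVA. Genes with zero variance in both groups
# follow the same degenerate convention as welch_test.
moderated_test <- function(test_m, ref_m) {
  n1 <- ncol(test_m); n2 <- ncol(ref_m)
  m1 <- rowMeans(test_m); m2 <- rowMeans(ref_m)
  v1 <- rowSums((test_m - m1)^2) / (n1 - 1)
  v2 <- rowSums((ref_m - m2)^2) / (n2 - 1)
  log2fc <- m1 - m2
  degenerate <- v1 + v2 == 0
  p <- rep(NA_real_, length(log2fc))
  if (!all(degenerate)) {
    y <- cbind(ref_m, test_m)
    design <- cbind(Intercept = 1, group = rep(c(0, 1), c(n2, n1)))
    fit <- limma::eBayes(limma::lmFit(y, design))
    p <- fit$p.value[, "group"]
  }
  p[degenerate & log2fc == 0] <- 1
  p[degenerate & log2fc != 0] <- 0
  tibble(log2fc = unname(log2fc), p_value = unname(p),
         degenerate = unname(degenerate))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH adjustment: on p-values sorted ascending,
#' `q(i) = min_{j >= i} m * p(j) / j`, mapped back to input order and clipped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Run one two-group contrast with the SS1.5F gate
#'
#' Tests each gene between a test and a reference genotype x condition group
#' (default: a moderated two-group test, `moderated_test`, which shrinks
#' per-gene variances across genes via limma's empirical Bayes — the
#' standard choice at 2-3 microarray replicates), BH-corrects
#' across all genes of the contrast, and flags SS1.5F genes — those passing
#' both the FDR gate (`q_value <= alpha`) and the fold-change gate
#' (`|log2fc| >= log2(fc_threshold)`, closed boundary). `log2fc` is the
#' difference of group means of log2 values (test minus reference);
#' `fold_change_linear` is `2^|log2fc|` signed by direction.
#'
#' Genes with zero variance in both groups get p = 1 when the means are
#' equal and p = 0 when they differ (flagged in `degenerate`), so noiseless
#' data propagate no NaNs.
#'
#' @param expr Expression tibble (gene_id + sample columns, log2 scale).
#' @param samples Sample sheet tibble (sample_id, genotype, condition,
#'   replicate).
#' @param test_group,reference_group Length-2 character vectors
#'   `c(genotype, condition)`, e.g. `c("WT", "SD")`.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param test_fun Per-gene test: a function(test_matrix, ref_matrix)
#'   returning a tibble with `log2fc`, `p_value` (and optionally
#'   `degenerate`). Defaults to the moderated test; [welch_test()] (plain
#'   per-gene Welch t, no moderation) can be injected instead.
#' @return Tibble: gene_id, log2fc, fold_change_linear, p_value, q_value,
#'   ss15f, degenerate; attributes `test_group`, `reference_group`, `alpha`,
#'   `fc_threshold`.
#' @export
run_contrast <- function(expr, samples, test_group, reference_group,
                         alpha = 0.05, fc_threshold = 1.5,
                         test_fun = moderated_test) {
  validate_expression(expr, samples)
  if (identical(test_group, reference_group)) abort("test and reference groups must differ")
  m <- expr_matrix(expr)
  ids_t <- group_sample_ids(samples, test_group)
  ids_r <- group_sample_ids(samples, reference_group)
  for (gi in list(list(test_group, ids_t), list(reference_group, ids_r))) {
    if (length(gi[[2]]) < 2) {
      abort(paste0("group ", group_label(gi[[1]]), " has fewer than 2 replicates"))
    }
  }
  res <- test_fun(m[, ids_t, drop = FALSE], m[, ids_r, drop = FALSE])
  if (!all(c("log2fc", "p_value") %in% names(res))) {
    abort("test_fun must return columns log2fc and p_value")
  }
  if (is.null(res$degenerate)) res$degenerate <- FALSE
  q <- benjamini_hochberg(res$p_value)
  out <- tibble(
    gene_id = expr$gene_id,
    log2fc = res$log2fc,
    fold_change_linear = sign(res$log2fc) * 2^abs(res$log2fc) +
      (res$log2fc == 0) * 1,
    p_value = res$p_value,
    q_value = q,
    ss15f = q <= alpha & abs(res$log2fc) >= log2(fc_threshold),
    degenerate = res$degenerate
  )
  attr(out, "test_group") <- test_group
  attr(out, "reference_group") <- reference_group
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  out
}

#' Genes passing the SS1.5F gate of a contrast
#'
#' Re-applies the gate at the given thresholds (defaults to those stored on
#' the contrast result) and returns the passing gene ids.
#'
#' @param result Tibble from [run_contrast()].
#' @param alpha,fc_threshold Gate thresholds; default to the values the
#'   contrast was run with.
#' @return Character vector of gene ids.
#' @export
ss15f_gate <- function(result, alpha = attr(result, "alpha") %||% 0.05,
                       fc_threshold = attr(result, "fc_threshold") %||% 1.5) {
  result$gene_id[result$q_value <= alpha &
                   abs(result$log2fc) >= log2(fc_threshold)]
}
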