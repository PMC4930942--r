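# End-to-end workflow: contrasts -> classification -> contribution ->
# motif enrichment -> phase analysis, with a serializable report bundle.

#' Run the full dawn-transcriptome workflow
#'
#' Executes, in order: the night contrast (WT-SD vs WT-LL) and the genotype
#' contrast (pifq-SD vs WT-SD) with the SS1.5F gate; sign-concordant
#' classification with Venn counts and the quadrant binomial test; per-set
#' contribution statistics with Wilcoxon group comparisons; promoter motif
#' enrichment per class (if promoters are given); and phase calls, rhythmic
#' fractions and phase-bin enrichment (if time courses are given).
#'
#' @param expr,samples Expression tibble and sample sheet.
#' @param promoters Optional promoter tibble (gene_id, sequence).
#' @param profiles Optional diurnal profile tibble (gene_id + ZT columns).
#' @param alpha FDR threshold for the SS1.5F gate.
#' @param fc_threshold Linear fold-change threshold for the SS1.5F gate.
#' @param motifs Motif panel tibble (name, iupac).
#' @param rhythm_cutoff Rhythmicity cutoff on the template correlation.
#' @param period Diurnal period in hours.
#' @param background Gene universe for enrichment; defaults to all genes in
#'   the expression matrix (standing in for "all genes on the array").
#' @param seed Seed echoed in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return Object of class `dawn_report`: a list with elements `config`,
#'   `contrast_sd`, `contrast_pif`, `classification`, `venn`, `binomial_p`,
#'   `contribution`, `motif_enrichment`, `phase`. Has [tidy()] and
#'   [glance()] methods.
#' @export
run_full_pipeline <- function(expr, samples, promoters = NULL, profiles = NULL,
                              alpha = 0.05, fc_threshold = 1.5,
                              motifs = default_motifs(),
                              rhythm_cutoff = 0.7, period = 24,
                              background = NULL, seed = NULL) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  validate_expression(expr, samples)
  background <- background %||% expr$gene_id

  sd <- stage("contrast_sd",
              run_contrast(expr, samples, c("WT", "SD"), c("WT", "LL"),
                           alpha = alpha, fc_threshold = fc_threshold))
  pif <- stage("contrast_pif",
               run_contrast(expr, samples, c("pifq", "SD"), c("WT", "SD"),
                            alpha = alpha, fc_threshold = fc_threshold))
  cls <- stage("classify", classify_genes(sd, pif))
  venn <- stage("venn", venn_summary(cls))
  binom_p <- if (venn$n_common > 0) {
    stage("binomial", quadrant_binomial_test(cls))
  } else {
    NA_real_
  }

  sets <- list(
    induced = cls$gene_id[cls$label == "pifsd_induced"],
    repressed = cls$gene_id[cls$label == "pifsd_repressed"]
  )

  contribution <- purrr::imap(sets, function(genes, nm) {
    if (length(genes) < 2) return(NULL)
    stage(paste0("contribution_", nm), {
      recs <- per_gene_contribution(expr, samples, genes)
      rk <- contribution_ranking(recs)
      groups <- list(c("WT", "SD"), c("pifq", "SD"), c("WT", "LL"), c("pifq", "LL"))
      means <- purrr::map_dfr(groups, function(g) set_mean_fc(expr, samples, genes, g))
      tests <- tibble(
        comparison = c("WT-SD vs pifq-SD", "pifq-SD vs WT-LL", "pifq-SD vs pifq-LL"),
        p_value = c(
          group_distribution_test(expr, samples, genes, c("WT", "SD"), c("pifq", "SD")),
          group_distribution_test(expr, samples, genes, c("pifq", "SD"), c("WT", "LL")),
          group_distribution_test(expr, samples, genes, c("pifq", "SD"), c("pifq", "LL"))
        )
      )
      list(records = recs, ranking = glance(rk), set_means = means,
           set_contribution_pct = set_contribution(expr, samples, genes),
           wilcoxon = tests)
    })
  })

  motif_enrichment <- NULL
  if (!is.null(promoters)) {
    motif_enrichment <- purrr::imap(sets, function(genes, nm) {
      if (length(genes) == 0) return(NULL)
      stage(paste0("motif_", nm),
            enrich_gene_set(promoters, motifs, genes, background, alpha = alpha))
    })
  }

  phase <- NULL
  if (!is.null(profiles)) {
    phase <- stage("phase", {
      calls <- assign_phase(profiles, period = period, cutoff = rhythm_cutoff)
      avail <- purrr::map(sets, intersect, calls$gene_id)
      rhythmic_pct <- purrr::imap_dfr(avail, function(genes, nm) {
        tibble(set = nm,
               pct_rhythmic = if (length(genes) > 0) rhythmic_fraction(calls, genes) else NA_real_)
      })
      enr <- purrr::imap(avail, function(genes, nm) {
        rhythmic_in_set <- any(calls$rhythmic[calls$gene_id %in% genes])
        if (!rhythmic_in_set) return(NULL)
        phase_bin_enrichment(calls, genes, calls$gene_id, period = period)
      })
      list(calls = calls, rhythmic_pct = rhythmic_pct, bin_enrichment = enr)
    })
  }

  out <- list(
    config = list(alpha = alpha, fc_threshold = fc_threshold,
                  rhythm_cutoff = rhythm_cutoff, period = period,
                  motifs = as.list(setNames(motifs$iupac, motifs$name)),
                  n_genes = nrow(expr), n_samples = nrow(samples),
                  seed = seed),
    contrast_sd = sd, contrast_pif = pif,
    classification = cls, venn = venn, binomial_p = binom_p,
    contribution = contribution,
    motif_enrichment = motif_enrichment,
    phase = phase
  )
  class(out) <- "dawn_report"
  out
}

#' @export
print.dawn_report <- function(x, ...) {
  v <- x$venn
  cat("Dawn-transcriptome report\n")
  cat(sprintf("  SD-regulated: %d; PIF-regulated: %d; common: %d\n",
              v$n_sd_regulated, v$n_pif_regulated, v$n_common))
  cat(sprintf("  induced: %d (%s%%), repressed: %d (%s%%), ambiguous: %d\n",
              v$n_induced, format(v$pct_induced_of_common),
              v$n_repressed, format(v$pct_repressed_of_common), v$n_ambiguous))
  cat(sprintf("  quadrant binomial p: %s\n", format(x$binomial_p)))
  invisible(x)
}

#' @rdname run_full_pipeline
#' @param x A `dawn_report`.
#' @param ... Unused.
#' @method tidy dawn_report
#' @export
tidy.dawn_report <- function(x, ...) x$classification

#' @rdname run_full_pipeline
#' @method glance dawn_report
#' @export
glance.dawn_report <- function(x, ...) {
  dplyr::bind_cols(
    x$venn,
    tibble(
      binomial_p = x$binomial_p,
      contribution_induced_pct = x$contribution$induced$set_contribution_pct %||% NA_real_,
      contribution_repressed_pct = x$contribution$repressed$set_contribution_pct %||% NA_real_
    )
  )
}

#' Write a report bundle to disk
#'
#' Emits per-contrast TSVs, the classification TSV, contribution and
#' enrichment TSVs, phase-call TSVs, and a `report.json` with the scalar
#' summaries, config echo and seed. Output is deterministic: rerunning on
#' the same inputs reproduces the files byte for byte.
#'
#' @param report A `dawn_report` from [run_full_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "dawn_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$contrast_sd, "contrast_sd.tsv")
  wr(report$contrast_pif, "contrast_pif.tsv")
  wr(report$classification, "classification.tsv")
  for (nm in names(report$contribution)) {
    if (!is.null(report$contribution[[nm]])) {
      wr(report$contribution[[nm]]$records, paste0("contribution_", nm, ".tsv"))
    }
  }
  for (nm in names(report$motif_enrichment %||% list())) {
    if (!is.null(report$motif_enrichment[[nm]])) {
      wr(report$motif_enrichment[[nm]], paste0("motif_enrichment_", nm, ".tsv"))
    }
  }
  if (!is.null(report$phase)) {
    wr(report$phase$calls, "phase_calls.tsv")
    for (nm in names(report$phase$bin_enrichment)) {
      if (!is.null(report$phase$bin_enrichment[[nm]])) {
        wr(report$phase$bin_enrichment[[nm]], paste0("phase_enrichment_", nm, ".tsv"))
      }
    }
  }
  summary <- list(
    config = report$config,
    venn = as.list(report$venn),
    binomial_p = report$binomial_p,
    contribution = purrr::map(report$contribution, function(cc) {
      if (is.null(cc)) return(NULL)
      list(set_contribution_pct = cc$set_contribution_pct,
           ranking = as.list(cc$ranking),
           set_means = cc$set_means,
           wilcoxon = cc$wilcoxon)
    }),
    rhythmic_pct = if (!is.null(report$phase)) report$phase$rhythmic_pct else NULL
  )
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE,
                       dataframe = "rows")
  paths <- c(paths, p)
  invisible(paths)
}
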