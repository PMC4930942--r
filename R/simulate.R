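#' Default planted class fractions for simulated expression data
#'
#' A mostly-null gene universe with small regulated classes, mirroring the
#' situation on a whole-genome array where a few percent of genes respond to
#' the photoperiod contrast at dawn.
#'
#' @return Named numeric vector over the six gene classes, summing to 1.
#' @export
default_class_fractions <- function() {
  c(pifsd_induced = 0.06, pifsd_repressed = 0.06, sd_only = 0.10,
    pif_only = 0.05, ambiguous = 0.03, null = 0.70)
}

# Deterministic integer allocation of n genes to classes (largest remainder).
allocate_classes <- function(n_genes, fractions) {
  fractions <- fractions[GENE_CLASSES]
  raw <- fractions * n_genes
  base <- floor(raw)
  short <- n_genes - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  setNames(as.integer(base), GENE_CLASSES)
}

#' Simulate a dawn-harvest expression experiment with planted truth
#'
#' Generates a normalized log2 expression matrix for the 2x2 design
#' (genotype WT/pifq crossed with condition SD/LL, `n_replicates` biological
#' replicates each) with genes planted in six classes:
#'
#' * `pifsd_induced`: up in WT-SD only (`+effect_size_log2`); its full
#'   induction requires PIFq, so the planted contribution is 100%.
#' * `pifsd_repressed`: down in WT-SD by `effect_size_log2`; in pifq-SD the
#'   repression is only partially relieved, leaving
#'   `-effect_size_log2 * (1 - repressed_contribution)` (planted contribution
#'   `100 * repressed_contribution` percent).
#' * `sd_only`: same shift in WT-SD and pifq-SD (night-responsive,
#'   PIF-independent).
#' * `pif_only`: shift in pifq-SD only.
#' * `ambiguous`: same-sign shift in both contrasts (WT-SD vs WT-LL and
#'   pifq-SD vs WT-SD).
#' * `null`: baseline everywhere.
#'
#' Independent Gaussian noise of SD `noise_sd_log2` is added per
#' gene x replicate on the log2 scale. Two RNG streams are derived from
#' `seed` by fixed offsets so the planted truth (class membership, shift
#' signs) can be held fixed while the noise realization varies: the truth
#' stream uses `seed` itself and the noise stream `seed + 100003` unless
#' `noise_seed` is given.
#'
#' @param n_genes Number of genes.
#' @param class_fractions Named fractions over the six classes; must sum to 1.
#' @param effect_size_log2 Planted |log2 fold change| for regulated classes.
#' @param repressed_contribution Planted fraction (0, 1.5] of the WT-SD
#'   repression attributable to PIFq.
#' @param noise_sd_log2 Replicate noise SD on the log2 scale.
#' @param n_replicates Biological replicates per genotype x condition cell.
#' @param baseline_log2 Mean log2 intensity of the unregulated state.
#' @param seed Integer seed; drives both derived streams.
#' @param noise_seed Optional override for the noise stream seed.
#'
#' @return A list with `expr` (tibble: gene_id + one column per sample),
#'   `samples` (tibble: sample_id, genotype, condition, replicate) and
#'   `truth` (tibble: gene_id, class_label, planted_fc_wt_log2,
#'   planted_fc_pifq_log2 — the pifq-SD vs WT-SD contrast).
#' @export
simulate_expression <- function(n_genes = 2000,
                                class_fractions = default_class_fractions(),
                                effect_size_log2 = 1.5,
                                repressed_contribution = 0.69,
                                noise_sd_log2 = 0.3,
                                n_replicates = 3,
                                baseline_log2 = 8,
                                seed = 1,
                                noise_seed = NULL) {
  if (n_genes < 1) abort("n_genes must be positive")
  if (n_replicates < 1) abort("n_replicates must be positive")
  if (noise_sd_log2 < 0) abort("noise_sd_log2 must be nonnegative")
  if (effect_size_log2 <= 0) abort("effect_size_log2 must be positive")
  if (repressed_contribution <= 0 || repressed_contribution > 1.5) {
    abort("repressed_contribution must be in (0, 1.5]")
  }
  if (!setequal(names(class_fractions), GENE_CLASSES)) {
    abort(paste0("class_fractions must name exactly: ",
                 paste(GENE_CLASSES, collapse = ", ")))
  }
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9) {
    abort("class_fractions must be nonnegative and sum to 1")
  }

  counts <- allocate_classes(n_genes, class_fractions)
  labels <- rep(names(counts), counts)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  e <- effect_size_log2
  # Truth stream: shift signs for the classes where direction is free.
  signs <- withr::with_seed(seed, {
    list(sd_only = sample(c(-1, 1), counts[["sd_only"]], replace = TRUE),
         pif_only = sample(c(-1, 1), counts[["pif_only"]], replace = TRUE),
         ambiguous = sample(c(-1, 1), counts[["ambiguous"]], replace = TRUE))
  })

  # Planted group means relative to baseline, per gene and group.
  shift <- matrix(0, nrow = n_genes, ncol = 4,
                  dimnames = list(gene_ids, c("WT_SD", "WT_LL", "pifq_SD", "pifq_LL")))
  idx <- function(lab) which(labels == lab)
  shift[idx("pifsd_induced"), "WT_SD"] <- e
  shift[idx("pifsd_repressed"), "WT_SD"] <- -e
  shift[idx("pifsd_repressed"), "pifq_SD"] <- -e * (1 - repressed_contribution)
  shift[idx("sd_only"), "WT_SD"] <- signs$sd_only * e
  shift[idx("sd_only"), "pifq_SD"] <- signs$sd_only * e
  shift[idx("pif_only"), "pifq_SD"] <- signs$pif_only * e
  shift[idx("ambiguous"), "WT_SD"] <- signs$ambiguous * e
  shift[idx("ambiguous"), "pifq_SD"] <- 2 * signs$ambiguous * e

  groups <- expand.grid(replicate = seq_len(n_replicates),
                        condition = c("SD", "LL"),
                        genotype = c("WT", "pifq"),
                        stringsAsFactors = FALSE)
  samples <- tibble(
    sample_id = paste(groups$genotype, groups$condition, groups$replicate, sep = "_"),
    genotype = groups$genotype,
    condition = groups$condition,
    replicate = as.integer(groups$replicate)
  )

  group_of <- paste(groups$genotype, groups$condition, sep = "_")
  means <- baseline_log2 + shift[, group_of, drop = FALSE]
  colnames(means) <- samples$sample_id

  noise_seed <- noise_seed %||% (seed + 100003L)
  noise <- withr::with_seed(noise_seed, {
    matrix(rnorm(n_genes * nrow(samples), sd = noise_sd_log2),
           nrow = n_genes)
  })
  values <- means + noise

  expr <- as_tibble(values)
  expr <- dplyr::bind_cols(tibble(gene_id = gene_ids), expr)

  truth <- tibble(
    gene_id = gene_ids,
    class_label = labels,
    planted_fc_wt_log2 = shift[, "WT_SD"] - shift[, "WT_LL"],
    planted_fc_pifq_log2 = shift[, "pifq_SD"] - shift[, "WT_SD"]
  )

  list(expr = expr, samples = samples, truth = truth)
}

#' Default motif panel
#'
#' The four promoter elements examined by the pipeline: the G-box (CACGTG)
#' and PBE/HUD (CACATG) bound by PIF bHLH factors, the extended G-box/PBE
#' element CACRTGGG, and the ABA-responsive ABRE element ACGTGGC.
#'
#' @return Tibble with columns `name` and `iupac`.
#' @export
default_motifs <- function() {
  tibble(name = c("GBOX", "PBE", "EXT", "ABRE"),
         iupac = c("CACGTG", "CACATG", "CACRTGGG", "ACGTGGC"))
}

# One concrete expansion of an IUPAC word, drawn uniformly (current RNG stream).
sample_iupac_word <- function(iupac) {
  paste(vapply(strsplit(iupac, "")[[1]],
               function(ch) sample(iupac_expand_letter(ch), 1), ""),
        collapse = "")
}

#' Simulate promoter sequences with class-dependent planted motifs
#'
#' One uppercase A/C/G/T sequence of length `length` per gene (i.i.d. uniform
#' background). For each motif, genes whose class is in `target_classes`
#' receive, with probability `prob_in_target`, one concrete expansion of the
#' IUPAC word implanted at a random position; other genes receive one with
#' probability `prob_in_background`. Implants are recorded per gene.
#'
#' @param truth Truth tibble from [simulate_expression()] (columns gene_id,
#'   class_label).
#' @param motif_config Tibble with columns `name`, `iupac`, `prob_in_target`,
#'   `prob_in_background` and a list-column `target_classes` (character
#'   vectors of class labels). See [default_motif_config()].
#' @param length Promoter window length in bases (default 3000, the 3 kb
#'   upstream window the enrichment analysis assumes).
#' @param seed Integer seed.
#'
#' @return Tibble with columns `gene_id`, `sequence`, `planted_motifs`
#'   (comma-separated motif names, "" if none).
#' @export
simulate_promoters <- function(truth, motif_config = default_motif_config(),
                               length = 3000, seed = 1) {
  stopifnot(all(c("gene_id", "class_label") %in% names(truth)))
  req <- c("name", "iupac", "prob_in_target", "prob_in_background", "target_classes")
  if (!all(req %in% names(motif_config))) {
    abort(paste0("motif_config must have columns: ", paste(req, collapse = ", ")))
  }
  probs <- c(motif_config$prob_in_target, motif_config$prob_in_background)
  if (any(probs < 0 | probs > 1)) abort("motif probabilities must be in [0, 1]")
  if (any(nchar(motif_config$iupac) > length)) {
    abort("motif longer than promoter length")
  }
  n <- nrow(truth)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, "")
    planted <- rep("", n)
    for (j in seq_len(nrow(motif_config))) {
      motif <- motif_config$name[j]
      iupac <- toupper(motif_config$iupac[j])
      w <- nchar(iupac)
      targets <- truth$class_label %in% motif_config$target_classes[[j]]
      p <- ifelse(targets, motif_config$prob_in_target[j],
                  motif_config$prob_in_background[j])
      implant <- runif(n) < p
      for (i in which(implant)) {
        word <- sample_iupac_word(iupac)
        pos <- sample.int(length - w + 1, 1)
        seqs[i] <- paste0(substr(seqs[i], 1, pos - 1), word,
                          substr(seqs[i], pos + w, length))
        planted[i] <- if (planted[i] == "") motif else paste(planted[i], motif, sep = ",")
      }
    }
    tibble(gene_id = truth$gene_id, sequence = seqs, planted_motifs = planted)
  })
}

#' Default motif-planting configuration
#'
#' PIF-bound elements (G-box, PBE, extended element) are planted
#' preferentially in the induced class and the ABRE in the repressed class,
#' against a uniform-background implant rate.
#'
#' @param prob_in_target Implant probability for target-class genes.
#' @param prob_in_background Implant probability elsewhere.
#' @return Tibble accepted by [simulate_promoters()].
#' @export
default_motif_config <- function(prob_in_target = 0.6, prob_in_background = 0.1) {
  m <- default_motifs()
  m$prob_in_target <- prob_in_target
  m$prob_in_background <- prob_in_background
  m$target_classes <- list(
    "pifsd_induced", "pifsd_induced", "pifsd_induced", "pifsd_repressed"
  )
  m
}

#' Simulate diurnal time courses with planted peak phases
#'
#' Rhythmic genes follow `baseline + amplitude * cos(2*pi*(t - phase)/period)`
#' plus Gaussian noise; arrhythmic genes are flat plus noise. Planted phases
#' are drawn uniformly on `[0, period)`.
#'
#' @param gene_ids Character vector of gene ids.
#' @param timepoints Sampling times in hours (>= 8 points spanning >= one
#'   period; default every 2 h over 48 h).
#' @param period Period in hours.
#' @param amplitude Cosine amplitude (log2 units).
#' @param noise_sd Noise SD per gene x timepoint.
#' @param frac_arrhythmic Fraction of genes planted flat.
#' @param baseline Flat baseline level.
#' @param seed Integer seed.
#'
#' @return List with `profiles` (tibble: gene_id + `ZT<t>` columns) and
#'   `truth` (tibble: gene_id, rhythmic, planted_phase_h — NA for arrhythmic
#'   genes).
#' @export
simulate_diurnal <- function(gene_ids, timepoints = seq(0, 46, by = 2),
                             period = 24, amplitude = 1, noise_sd = 0.2,
                             frac_arrhythmic = 0, baseline = 8, seed = 1) {
  if (length(timepoints) == 0) abort("timepoints must be non-empty")
  if (length(timepoints) < 8 || diff(range(timepoints)) < period) {
    abort("need >= 8 timepoints spanning >= one full period")
  }
  n <- length(gene_ids)
  withr::with_seed(seed, {
    n_flat <- round(frac_arrhythmic * n)
    flat <- rep(FALSE, n)
    if (n_flat > 0) flat[sample.int(n, n_flat)] <- TRUE
    phase <- ifelse(flat, NA_real_, runif(n, 0, period))
    signal <- matrix(baseline, nrow = n, ncol = length(timepoints))
    rhythmic_idx <- which(!flat)
    for (i in rhythmic_idx) {
      signal[i, ] <- baseline + amplitude * cos(2 * pi * (timepoints - phase[i]) / period)
    }
    values <- signal + matrix(rnorm(n * length(timepoints), sd = noise_sd), nrow = n)
    colnames(values) <- paste0("ZT", timepoints)
    profiles <- dplyr::bind_cols(tibble(gene_id = gene_ids), as_tibble(values))
    truth <- tibble(gene_id = gene_ids, rhythmic = !flat, planted_phase_h = phase)
    list(profiles = profiles, truth = truth)
  })
}
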