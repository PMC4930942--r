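test_that("zero-noise group means equal the planted shifts exactly", {
  fr <- c(pifsd_induced = 1, pifsd_repressed = 0, sd_only = 0, pif_only = 0,
          ambiguous = 0, null = 0)
  sim <- simulate_expression(n_genes = 1, class_fractions = fr,
                             effect_size_log2 = 1.5, noise_sd_log2 = 0,
                             baseline_log2 = 8, seed = 7)
  mu <- function(g) mean(unlist(sim$expr[1, sim$samples$sample_id[
    sim$samples$genotype == g[1] & sim$samples$condition == g[2]]]))
  expect_identical(mu(c("WT", "SD")) - mu(c("WT", "LL")), 1.5)
  expect_identical(mu(c("pifq", "SD")) - mu(c("WT", "SD")), -1.5)
  expect_identical(mu(c("pifq", "LL")), 8)
})

test_that("an all-null universe sits at baseline in every group", {
  fr <- c(pifsd_induced = 0, pifsd_repressed = 0, sd_only = 0, pif_only = 0,
          ambiguous = 0, null = 1)
  sim <- simulate_expression(n_genes = 20, class_fractions = fr,
                             noise_sd_log2 = 0, baseline_log2 = 8, seed = 1)
  m <- as.matrix(sim$expr[-1])
  expect_true(all(m == 8))
  expect_true(all(sim$truth$class_label == "null"))
})

test_that("planted truth satisfies the sign invariants and covers each gene once", {
  sim <- simulate_expression(n_genes = 500, seed = 3)
  expect_identical(sort(sim$truth$gene_id), sort(sim$expr$gene_id))
  expect_false(anyDuplicated(sim$truth$gene_id) > 0)
  ind <- sim$truth[sim$truth$class_label == "pifsd_induced", ]
  rep_ <- sim$truth[sim$truth$class_label == "pifsd_repressed", ]
  expect_true(all(ind$planted_fc_wt_log2 > 0 & ind$planted_fc_pifq_log2 < 0))
  expect_true(all(rep_$planted_fc_wt_log2 < 0 & rep_$planted_fc_pifq_log2 > 0))
})

test_that("emitted sample means track the planted group means (averaging oracle)", {
  sim <- simulate_expression(n_genes = 2000, effect_size_log2 = 1.5,
                             noise_sd_log2 = 0.3, repressed_contribution = 0.69,
                             seed = 1)
  tol <- 3 * 0.3 / sqrt(3)
  m <- as.matrix(sim$expr[-1])
  ok <- logical(0) # one entry per gene x group mean estimate
  planted_group_shift <- function(truth, group) {
    # reconstruct the planted mean of each group from the truth fold changes
    if (identical(group, c("WT", "SD"))) truth$planted_fc_wt_log2
    else if (identical(group, c("pifq", "SD"))) truth$planted_fc_wt_log2 + truth$planted_fc_pifq_log2
    else rep(0, nrow(truth))
  }
  for (group in list(c("WT", "SD"), c("WT", "LL"), c("pifq", "SD"), c("pifq", "LL"))) {
    ids <- sim$samples$sample_id[sim$samples$genotype == group[1] &
                                   sim$samples$condition == group[2]]
    observed <- rowMeans(m[, ids])
    planted <- 8 + planted_group_shift(sim$truth, group)
    ok <- c(ok, abs(observed - planted) <= tol)
  }
  expect_gte(mean(ok), 0.99)
})

test_that("generation is seed-deterministic and truth is noise-seed invariant", {
  a <- simulate_expression(n_genes = 100, seed = 5)
  b <- simulate_expression(n_genes = 100, seed = 5)
  expect_identical(a, b)
  c1 <- simulate_expression(n_genes = 100, seed = 5, noise_seed = 99)
  expect_identical(a$truth, c1$truth)
  expect_false(identical(a$expr, c1$expr))
})

test_that("configuration errors are rejected", {
  expect_error(simulate_expression(n_genes = 0), "positive")
  fr <- default_class_fractions(); fr[1] <- fr[1] + 0.1
  expect_error(simulate_expression(class_fractions = fr), "sum to 1")
  expect_error(simulate_expression(n_replicates = 0), "positive")
})

test_that("forced implant plants the motif in every target-class promoter", {
  sim <- simulate_expression(n_genes = 60, seed = 2, noise_sd_log2 = 0)
  cfg <- default_motif_config(prob_in_target = 1, prob_in_background = 0)
  cfg <- cfg[cfg$name == "GBOX", ]
  prom <- simulate_promoters(sim$truth, cfg, length = 100, seed = 2)
  induced <- sim$truth$gene_id[sim$truth$class_label == "pifsd_induced"]
  expect_gt(length(induced), 0)
  hits <- genes_with_motif(prom, "CACGTG")
  expect_true(all(induced %in% hits))
  expect_true(all(grepl("GBOX", prom$planted_motifs[prom$gene_id %in% induced])))
})

test_that("background motif frequency matches the closed-form chance rate", {
  truth <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000),
                          class_label = "null")
  cfg <- default_motif_config(prob_in_target = 0, prob_in_background = 0)
  prom <- simulate_promoters(truth, cfg, length = 100, seed = 11)
  # Non-palindromic PBE: plus and minus strands contribute ~independently.
  p2 <- 1 - (1 - 4^-6)^(2 * 95)
  n_pbe <- length(genes_with_motif(prom, "CACATG"))
  expect_lt(abs(n_pbe - 1000 * p2), 3 * sqrt(1000 * p2 * (1 - p2)))
  # Palindromic G-box: the minus strand duplicates the plus sites, so the
  # chance rate uses one strand's windows only.
  p1 <- 1 - (1 - 4^-6)^95
  n_gbox <- length(genes_with_motif(prom, "CACGTG"))
  expect_lt(abs(n_gbox - 1000 * p1), 3 * sqrt(1000 * p1 * (1 - p1)))
})

test_that("degenerate promoter length yields exactly the motif", {
  truth <- tibble::tibble(gene_id = "g1", class_label = "pifsd_induced")
  cfg <- default_motif_config(prob_in_target = 1, prob_in_background = 1)
  cfg <- cfg[cfg$name == "GBOX", ]
  prom <- simulate_promoters(truth, cfg, length = 6, seed = 1)
  expect_identical(prom$sequence, "CACGTG")
  expect_error(simulate_promoters(truth, cfg, length = 5, seed = 1), "longer")
})

test_that("noiseless diurnal profiles peak at the planted phase", {
  dd <- simulate_diurnal("g1", timepoints = seq(0, 47.5, 0.5), amplitude = 1,
                         noise_sd = 0, frac_arrhythmic = 0, seed = 4)
  # overwrite the random phase with a fixed one via the cosine argmax check
  tp <- seq(0, 47.5, 0.5)
  phase <- dd$truth$planted_phase_h
  y <- as.numeric(dd$profiles[1, -1])
  expect_equal(tp[which.max(y)] %% 24, round(phase / 0.5) * 0.5 %% 24,
               tolerance = 0.51)
  flat <- simulate_diurnal("g1", amplitude = 0, noise_sd = 0.2,
                           frac_arrhythmic = 0, seed = 4)
  expect_lt(sd(as.numeric(flat$profiles[1, -1])), 0.5)
  expect_error(simulate_diurnal("g1", timepoints = c(0, 2, 4)), ">= 8")
})
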