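# Diurnal phase assignment and rhythmicity by cosine-template correlation.

# Parse timepoints from ZT<t> column names if not supplied.
profile_timepoints <- function(profiles, timepoints = NULL) {
  cols <- setdiff(names(profiles), "gene_id")
  if (is.null(timepoints)) {
    tp <- suppressWarnings(as.numeric(sub("^ZT", "", cols)))
    if (any(is.na(tp))) abort("cannot parse timepoints from column names; pass `timepoints`")
    timepoints <- tp
  }
  if (length(timepoints) != length(cols)) {
    abort("timepoints length must match the number of profile columns")
  }
  timepoints
}

#' Assign peak phase and rhythmicity to each time course
#'
#' Correlates each gene's z-scored profile with single-harmonic cosine
#' templates `cos(2*pi*(t - phi)/period)` over a grid of candidate phases
#' `phi` (step `grid_step` hours, default 0.5). The reported phase is the
#' arg-max phase (ties broken toward smaller `phi`), the rhythm score is the
#' maximum Pearson correlation, and a gene is called rhythmic when the score
#' reaches `cutoff` (default 0.7). Constant profiles get score 0 and are not
#' rhythmic.
#'
#' @param profiles Tibble: gene_id + one numeric column per timepoint
#'   (`ZT<t>` names, or pass `timepoints`).
#' @param timepoints Sampling times in hours; parsed from the column names
#'   when `NULL`.
#' @param period Period in hours (default 24).
#' @param cutoff Rhythmicity cutoff on the correlation score (default 0.7).
#' @param grid_step Phase grid step in hours (default 0.5).
#' @return Tibble: gene_id, phase_h (in `[0, period)`), rhythm_score,
#'   rhythmic.
#' @export
assign_phase <- function(profiles, timepoints = NULL, period = 24,
                         cutoff = 0.7, grid_step = 0.5) {
  timepoints <- profile_timepoints(profiles, timepoints)
  if (length(timepoints) < 8 || diff(range(timepoints)) < period) {
    abort("need >= 8 timepoints spanning >= one full period")
  }
  y <- expr_matrix(profiles)
  if (any(!is.finite(y))) abort("profiles contain non-finite values")
  tcount <- length(timepoints)
  phis <- seq(0, period - grid_step, by = grid_step)
  templates <- outer(phis, timepoints,
                     function(phi, t) cos(2 * pi * (t - phi) / period))
  tz <- templates - rowMeans(templates)
  tnorm <- sqrt(rowSums(tz^2))
  yz <- y - rowMeans(y)
  ynorm <- sqrt(rowSums(yz^2))
  constant <- ynorm == 0
  ynorm[constant] <- 1 # avoid 0/0; scores overwritten below
  corr <- (yz %*% t(tz)) / (ynorm %o% tnorm)
  best <- max.col(corr, ties.method = "first")
  score <- corr[cbind(seq_len(nrow(corr)), best)]
  score[constant] <- 0
  tibble(
    gene_id = profiles$gene_id,
    phase_h = unname(ifelse(constant, NA_real_, phis[best] %% period)),
    rhythm_score = unname(score),
    rhythmic = unname(score >= cutoff & !constant)
  )
}

#' Percentage of rhythmic genes in a set
#'
#' @param calls Tibble from [assign_phase()].
#' @param gene_set Non-empty character vector of gene ids, a subset of the
#'   calls.
#' @return Percentage (0-100).
#' @export
rhythmic_fraction <- function(calls, gene_set) {
  if (length(gene_set) == 0) abort("empty gene set")
  missing <- setdiff(gene_set, calls$gene_id)
  if (length(missing) > 0) abort("gene_set contains genes without phase calls")
  sub <- calls[calls$gene_id %in% gene_set, ]
  100 * sum(sub$rhythmic) / nrow(sub)
}

#' Phase-bin enrichment of a gene set (count / expected)
#'
#' Bins the phases of the rhythmic genes of a set into `n_bins` bins of
#' width `period / n_bins` (left-closed, right-open, starting at ZT0) and
#' compares the observed count per bin with the count expected from the
#' background phase distribution: `expected = set_total * background bin
#' fraction`. `fold = observed / expected`, `NA` where the expected count is
#' zero.
#'
#' @param calls Tibble from [assign_phase()].
#' @param gene_set,background Character vectors of gene ids; both must
#'   contain rhythmic genes.
#' @param n_bins Number of phase bins (default 24).
#' @param period Period in hours (default 24).
#' @return Tibble: bin_start, bin_end, observed, expected, fold.
#' @export
phase_bin_enrichment <- function(calls, gene_set, background, n_bins = 24,
                                 period = 24) {
  width <- period / n_bins
  rhythm <- calls[calls$rhythmic, ]
  set_ph <- rhythm$phase_h[rhythm$gene_id %in% gene_set]
  bg_ph <- rhythm$phase_h[rhythm$gene_id %in% background]
  if (length(set_ph) == 0 || length(bg_ph) == 0) {
    abort("no rhythmic genes in set or background")
  }
  bin <- function(ph) pmin(floor((ph %% period) / width), n_bins - 1)
  obs <- tabulate(bin(set_ph) + 1, nbins = n_bins)
  bg <- tabulate(bin(bg_ph) + 1, nbins = n_bins)
  expected <- length(set_ph) * bg / length(bg_ph)
  tibble(
    bin_start = (seq_len(n_bins) - 1) * width,
    bin_end = seq_len(n_bins) * width,
    observed = obs,
    expected = expected,
    fold = ifelse(expected > 0, obs / expected, NA_real_)
  )
}

#' Median and quartile profile of a gene set
#'
#' Per-timepoint median and 25th/75th percentiles of the set's time courses
#' (type-7 quantiles).
#'
#' @param profiles Tibble: gene_id + timepoint columns.
#' @param gene_set Non-empty character vector of gene ids.
#' @param timepoints Sampling times; parsed from column names when `NULL`.
#' @return Tibble: time_h, median, q25, q75.
#' @export
set_median_profile <- function(profiles, gene_set, timepoints = NULL) {
  if (length(gene_set) == 0) abort("empty gene set")
  timepoints <- profile_timepoints(profiles, timepoints)
  y <- expr_matrix(profiles[profiles$gene_id %in% gene_set, ])
  if (nrow(y) == 0) abort("no profiles for gene_set")
  tibble(
    time_h = timepoints,
    median = unname(apply(y, 2, median)),
    q25 = unname(apply(y, 2, quantile, probs = 0.25)),
    q75 = unname(apply(y, 2, quantile, probs = 0.75))
  )
}
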