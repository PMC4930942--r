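mk_profiles <- function(mat, tp) {
  colnames(mat) <- paste0("ZT", tp)
  dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", seq_len(nrow(mat)))),
                   tibble::as_tibble(mat))
}

test_that("a pure cosine is called at its own phase with score 1", {
  tp <- seq(0, 46, 2)
  prof <- mk_profiles(matrix(8 + cos(2 * pi * (tp - 20) / 24), 1), tp)
  call <- assign_phase(prof)
  expect_identical(call$phase_h, 20)
  expect_equal(call$rhythm_score, 1, tolerance = 1e-9)
  expect_true(call$rhythmic)
})

test_that("flat profiles score 0 and are not rhythmic", {
  tp <- seq(0, 46, 2)
  prof <- mk_profiles(matrix(8, 2, length(tp)), tp)
  calls <- assign_phase(prof)
  expect_identical(calls$rhythm_score, c(0, 0))
  expect_false(any(calls$rhythmic))
  expect_true(all(is.na(calls$phase_h)))
})

test_that("rhythm score is invariant to affine transforms of the profile", {
  tp <- seq(0, 46, 2)
  y <- 8 + cos(2 * pi * (tp - 7) / 24) + withr::with_seed(2, rnorm(length(tp), sd = 0.3))
  a <- assign_phase(mk_profiles(matrix(y, 1), tp))
  b <- assign_phase(mk_profiles(matrix(5 * y - 30, 1), tp))
  expect_equal(a$rhythm_score, b$rhythm_score, tolerance = 1e-12)
  expect_identical(a$phase_h, b$phase_h)
})

test_that("phase calls are equivariant under circular time shifts on the grid", {
  tp <- seq(0, 46, 2)
  phases <- seq(0, 23.5, 0.5)
  delta <- 3
  y0 <- t(vapply(phases, function(ph) cos(2 * pi * (tp - ph) / 24),
                 numeric(length(tp))))
  y1 <- t(vapply(phases + delta, function(ph) cos(2 * pi * (tp - ph) / 24),
                 numeric(length(tp))))
  c0 <- assign_phase(mk_profiles(y0, tp))
  c1 <- assign_phase(mk_profiles(y1, tp))
  expect_equal(c1$phase_h, (c0$phase_h + delta) %% 24, tolerance = 1e-9)
})

test_that("planted phases are recovered within 1 h for noisy cosines", {
  dd <- simulate_diurnal(sprintf("g%03d", 1:500), amplitude = 1,
                         noise_sd = 0.2, frac_arrhythmic = 0, seed = 6)
  calls <- assign_phase(dd$profiles)
  err <- phase_error(calls$phase_h, dd$truth$planted_phase_h)
  expect_gte(mean(err <= 1), 0.95)
  expect_gte(mean(calls$rhythmic), 0.99)
})

test_that("rhythmic_fraction recovers a planted rhythmic share", {
  expect_error(rhythmic_fraction(tibble::tibble(gene_id = "g", rhythmic = TRUE),
                                 character(0)), "empty")
  fracs <- vapply(1:5, function(s) {
    dd <- simulate_diurnal(sprintf("g%03d", 1:200), noise_sd = 0.2,
                           frac_arrhythmic = 0.4, seed = s)
    calls <- assign_phase(dd$profiles)
    rhythmic_fraction(calls, dd$truth$gene_id)
  }, 1)
  expect_true(all(abs(fracs - 60) <= 7))
})

test_that("phase-bin enrichment: point mass, self-comparison and conservation", {
  calls <- tibble::tibble(
    gene_id = paste0("g", 1:48),
    phase_h = c(rep(20.2, 24), seq(0, 23, length.out = 24)),
    rhythm_score = 1, rhythmic = TRUE)
  set <- paste0("g", 1:24)
  enr <- phase_bin_enrichment(calls, set, calls$gene_id)
  expect_identical(sum(enr$observed), 24L)
  expect_equal(sum(enr$expected), 24, tolerance = 1e-12)
  self <- phase_bin_enrichment(calls, calls$gene_id, calls$gene_id)
  expect_true(all(self$fold[self$observed > 0] == 1))
  # uniform background, all set phases in [20, 21)
  uniform_bg <- tibble::tibble(
    gene_id = paste0("b", 1:240),
    phase_h = rep(seq(0, 23, 1) + 0.5, each = 10),
    rhythm_score = 1, rhythmic = TRUE)
  point <- tibble::tibble(gene_id = paste0("s", 1:24), phase_h = 20.4,
                          rhythm_score = 1, rhythmic = TRUE)
  enr2 <- phase_bin_enrichment(dplyr::bind_rows(uniform_bg, point),
                               point$gene_id, uniform_bg$gene_id)
  expect_equal(enr2$fold[enr2$bin_start == 20], 24, tolerance = 1e-12)
  expect_true(all(enr2$observed[enr2$bin_start != 20] == 0))
})

test_that("a planted dawn-phased set is maximally enriched near its phase", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n_set <- 80; n_bg <- 400
      set_phases <- (rnorm(n_set, mean = 20, sd = 1)) %% 24
      bg_phases <- runif(n_bg, 0, 24)
      calls <- tibble::tibble(
        gene_id = c(paste0("s", 1:n_set), paste0("b", 1:n_bg)),
        phase_h = c(set_phases, bg_phases), rhythm_score = 1, rhythmic = TRUE)
      enr <- phase_bin_enrichment(calls, paste0("s", 1:n_set), calls$gene_id)
      best <- enr$bin_start[which.max(enr$fold)]
      best %in% c(19, 20)
    })
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("set median profiles collapse correctly in degenerate cases", {
  tp <- seq(0, 46, 2)
  y <- 8 + cos(2 * pi * (tp - 20) / 24)
  one <- set_median_profile(mk_profiles(matrix(y, 1), tp), "g1")
  expect_equal(one$median, y, tolerance = 1e-12)
  expect_equal(one$q25, y, tolerance = 1e-12)
  mirrored <- rbind(8 + cos(2 * pi * (tp - 5) / 24),
                    8 + cos(2 * pi * (tp - 17) / 24))
  two <- set_median_profile(mk_profiles(mirrored, tp), c("g1", "g2"))
  expect_equal(two$median, rep(8, length(tp)), tolerance = 1e-12)
})

test_that("the median curve of a phase-coherent set peaks at the planted phase", {
  dd <- simulate_diurnal(sprintf("g%03d", 1:100), noise_sd = 0.2,
                         frac_arrhythmic = 0, seed = 9)
  # force a common phase by regenerating profiles at phase 20
  tp <- seq(0, 46, 2)
  y <- t(vapply(1:100, function(i) {
    8 + cos(2 * pi * (tp - 20) / 24) + withr::with_seed(i, rnorm(length(tp), sd = 0.2))
  }, numeric(length(tp))))
  med <- set_median_profile(mk_profiles(y, tp), paste0("g", 1:100))
  peak <- med$time_h[which.max(med$median)] %% 24
  expect_lte(phase_error(peak, 20), 1)
})
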