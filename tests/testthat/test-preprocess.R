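make_set <- function(X, ppm = seq_len(ncol(X))) {
  spectrum_set(ppm, unname(as.matrix(X)))
}

test_that("extract_region keeps exactly the requested columns", {
  s <- make_set(matrix(1:30, 3, 10), ppm = 1:10)
  # identity when the window spans the axis and nothing is excluded
  expect_equal(extract_region(s, 1, 10)$intensities, s$intensities)
  # exclusion covering points 4-6 leaves 7 columns (direct enumeration)
  out <- extract_region(s, 1, 10, interval_list(3.5, 6.5))
  expect_equal(length(out$ppm), 7)
  expect_equal(out$ppm, c(1, 2, 3, 7, 8, 9, 10))
  expect_equal(out$intensities, s$intensities[, c(1:3, 7:10)])
})

test_that("extract_region rejects empty results and bad bounds", {
  s <- make_set(matrix(1:30, 3, 10), ppm = 1:10)
  expect_error(extract_region(s, 1, 10, interval_list(0, 11)),
               "no axis points")
  expect_error(extract_region(s, 11, 12), "no axis points")
})

test_that("provenance is append-only and names each transform", {
  s <- make_set(matrix(runif(30), 3, 10), ppm = 1:10)
  out <- extract_region(s, 2, 9)
  out <- unit_area_normalize(out)
  out <- mean_center(out)
  steps <- vapply(out$provenance, `[[`, "", "step")
  expect_equal(steps, c("extract_region", "unit_area_normalize",
                        "mean_center"))
})

test_that("select_reference maximizes mean correlation", {
  base <- sin(seq(0, 6, length.out = 50))
  withr::with_seed(1, {
    X <- rbind(t(replicate(9, base + rnorm(50, sd = 0.01))),
               rnorm(50))  # one outlier
  })
  s <- make_set(X, ppm = seq(0, 6, length.out = 50))
  ref <- select_reference(s)
  expect_lt(ref, 10)  # never the outlier
  # matches a direct computation of the mean-correlation vector
  C <- cor(t(X)); diag(C) <- NA
  expect_equal(ref, which.max(rowMeans(C, na.rm = TRUE)))
})

test_that("select_reference tie-breaks to the first sample", {
  X <- matrix(rep(sin(1:20), 3), 3, 20, byrow = TRUE)
  s <- make_set(X, ppm = 1:20)
  expect_equal(select_reference(s), 1L)
  expect_equal(select_reference(make_set(X[1:2, ], ppm = 1:20)), 1L)
})

test_that("zero-variance spectra get correlation 0 with a warning", {
  X <- rbind(sin(1:20), sin(1:20), rep(1, 20))
  s <- make_set(X, ppm = 1:20)
  expect_warning(ref <- select_reference(s), "zero-variance")
  expect_true(ref %in% 1:2)
})

test_that("interval alignment recovers a planted shift", {
  ppm <- seq(0, 2, by = 0.01)
  peak <- 0.05^2 / ((ppm - 1)^2 + 0.05^2)
  shifted <- c(rep(0, 3), peak[seq_len(length(peak) - 3)])  # moved +3 pts
  s <- make_set(rbind(peak, shifted), ppm = ppm)
  res <- interval_align(s, interval_list(0.5, 1.5), max_shift = 5,
                        reference = 1)
  expect_equal(unname(res$shifts[2, 1]), -3L)
  # aligned maximum coincides with the reference maximum
  idx <- which(ppm >= 0.5 & ppm <= 1.5)
  expect_equal(which.max(res$spectra$intensities[2, idx]),
               which.max(peak[idx]))
  # brute-force check: -3 is the cross-correlation argmax
  seg <- shifted[idx]; ref_seg <- peak[idx]
  scores <- sapply(-5:5, function(k)
    sum(nmrscreen:::shift_pad(seg, k) * ref_seg))
  expect_equal((-5:5)[which.max(scores)], -3)
})

test_that("alignment with max_shift 0 is the identity", {
  withr::with_seed(2, X <- matrix(runif(60), 3, 20))
  s <- make_set(X, ppm = seq(0, 1.9, by = 0.1))
  res <- interval_align(s, interval_list(0, 2), max_shift = 0)
  expect_equal(res$spectra$intensities, s$intensities)
  expect_true(all(res$shifts == 0))
})

test_that("alignment clamps at the shift bound", {
  ppm <- seq(0, 2, by = 0.01)
  peak <- 0.05^2 / ((ppm - 1)^2 + 0.05^2)
  shifted <- c(rep(0, 7), peak[seq_len(length(peak) - 7)])  # +7 points
  s <- make_set(rbind(peak, shifted), ppm = ppm)
  res <- interval_align(s, interval_list(0.5, 1.5), max_shift = 5,
                        reference = 1)
  expect_equal(unname(abs(res$shifts[2, 1])), 5L)
})

test_that("alignment preserves interior values (edge padding only)", {
  withr::with_seed(3, X <- matrix(runif(200), 2, 100))
  s <- make_set(X, ppm = seq(0.01, 1, by = 0.01))
  res <- interval_align(s, interval_list(0.2, 0.8), max_shift = 4,
                        reference = 1)
  idx <- which(s$ppm >= 0.2 & s$ppm <= 0.8)
  k <- res$shifts[2, 1]
  seg_in <- X[2, idx]; seg_out <- res$spectra$intensities[2, idx]
  if (k != 0) {
    # all but |k| edge-padded points are the original values, shifted
    kept <- if (k > 0) seg_out[-seq_len(k)] else
      seg_out[seq_len(length(idx) - abs(k))]
    orig <- if (k > 0) seg_in[seq_len(length(idx) - k)] else
      seg_in[-seq_len(abs(k))]
    expect_equal(kept, orig)
  }
  expect_error(interval_align(s, interval_list(0.2, 0.8), max_shift = 40),
               "narrower")
})

test_that("peak alignment recovers a global displacement", {
  ppm <- seq(0.5, 4, by = 0.01)
  spec <- 0.03^2 / ((ppm - 1.48)^2 + 0.03^2)
  displaced <- nmrscreen:::shift_pad(spec, -4)  # peak moved 4 pts left
  s <- make_set(rbind(spec, displaced), ppm = ppm)
  res <- align_to_peak(s, 1.48, 0.2)
  expect_equal(unname(res$shifts), c(0L, 4L))
  expect_equal(which.max(res$spectra$intensities[2, ]),
               which.max(spec))
})

test_that("flat search window leaves the spectrum unshifted, with warning", {
  s <- make_set(rbind(rep(1, 100)), ppm = seq(1, 1.99, by = 0.01))
  expect_warning(res <- align_to_peak(s, 1.48, 0.1), "flat")
  expect_equal(res$spectra$intensities, s$intensities)
})

test_that("PQN recovers exact dilution quotients", {
  base <- 1 + 0.05^2 / ((seq(0, 2, 0.01) - 1)^2 + 0.05^2)
  X <- rbind(base, base, base, 2 * base)
  s <- make_set(X, ppm = seq(0, 2, 0.01))
  res <- pqn_normalize(s, pre_normalize = FALSE)
  expect_equal(unname(res$factors), c(1, 1, 1, 2))
  expect_equal(res$spectra$intensities[4, ], res$spectra$intensities[1, ])
  # identical spectra: all factors 1, output = input
  s2 <- make_set(rbind(base, base), ppm = seq(0, 2, 0.01))
  res2 <- pqn_normalize(s2)
  expect_equal(unname(res2$factors), c(1, 1))
  expect_equal(res2$spectra$intensities, s2$intensities)
})

test_that("PQN dilution factors are invariant to a global rescale", {
  # factors are median-anchored relative dilutions: multiplying every
  # spectrum by c leaves them unchanged and scales the output by c
  withr::with_seed(4, X <- matrix(rlnorm(300), 6, 50))
  s <- make_set(X, ppm = seq(0.1, 5, length.out = 50))
  a <- pqn_normalize(s)
  b <- pqn_normalize(make_set(3 * X, ppm = s$ppm))
  expect_equal(b$factors, a$factors)
  expect_equal(b$spectra$intensities, 3 * a$spectra$intensities)
})

test_that("PQN recovers simulated log-normal dilution (generator truth)", {
  lib <- toy_library(cv = 0)
  gc <- generate_cohort(100, 0, 0, seed = 5)
  sim <- synthesize_spectra(gc$cohort, lib, noise_sd = 0.05,
                            dilution_sigma = 0.3, jitter_sd = 0.002,
                            ppm_grid = toy_grid(0.005), seed = 6)
  pq <- pqn_normalize(sim$spectra)
  expect_gt(cor(pq$factors, sim$truth$dilution, method = "spearman"),
            0.99)
})

test_that("PQN stays accurate under biological variation", {
  lib <- toy_library(cv = 0.2)
  gc <- generate_cohort(100, 0, 0, seed = 7)
  sim <- synthesize_spectra(gc$cohort, lib, noise_sd = 0.05,
                            dilution_sigma = 0.3, jitter_sd = 0.002,
                            ppm_grid = toy_grid(0.005), seed = 8)
  pq <- pqn_normalize(sim$spectra)
  expect_gt(cor(pq$factors, sim$truth$dilution, method = "spearman"), 0.9)
})

test_that("unit-area normalization yields unit integrals, idempotently", {
  withr::with_seed(5, X <- matrix(rlnorm(500), 5, 100))
  s <- make_set(X, ppm = seq(0, 9.9, by = 0.1))
  out <- unit_area_normalize(s)
  expect_equal(unname(nmrscreen:::trapz_rows(out$ppm, out$intensities)),
               rep(1, 5), tolerance = 1e-9)
  out2 <- unit_area_normalize(out)
  expect_equal(out2$intensities, out$intensities, tolerance = 1e-12)
  # constant spectrum height h on width w scales by 1/(h w)
  s3 <- make_set(rbind(rep(2, 11)), ppm = 0:10)
  expect_equal(max(abs(unit_area_normalize(s3)$intensities - 1 / 10)), 0,
               tolerance = 1e-12)
  expect_error(unit_area_normalize(make_set(rbind(rep(0, 11)), ppm = 0:10)),
               "non-positive")
})

test_that("centering and pareto scaling satisfy their identities", {
  withr::with_seed(6, X <- matrix(rnorm(200, sd = rep(c(4, 1), each = 100)),
                                  20, 10))
  s <- make_set(X, ppm = 1:10)
  cen <- mean_center(s)
  expect_lt(max(abs(colSums(cen$intensities))), 1e-9 * nrow(X))
  # centering twice = centering once
  expect_equal(mean_center(cen)$intensities, cen$intensities)
  par <- pareto_scale(cen)
  # column sds after = sqrt of sds before (direct recomputation)
  expect_equal(apply(par$intensities, 2, sd),
               sqrt(apply(cen$intensities, 2, sd)), tolerance = 1e-12)
  # a column with sd 4 is divided by 2
  j <- which.max(apply(cen$intensities, 2, sd))
  expect_equal(par$intensities[, j], cen$intensities[, j] /
                 sqrt(sd(cen$intensities[, j])))
})

test_that("pareto scaling leaves zero-variance columns alone", {
  X <- cbind(rnorm(10), rep(1, 10))
  s <- make_set(X, ppm = 1:2)
  expect_warning(out <- pareto_scale(s), "zero-variance")
  expect_equal(unname(out$intensities[, 2]), X[, 2])
})

test_that("region integrals match closed forms", {
  # flat spectrum: h * w
  s <- make_set(rbind(rep(3, 101)), ppm = seq(0, 10, 0.1))
  expect_equal(unname(integrate_region(s, 2, 6)), 3 * 4, tolerance = 1e-9)
  # Lorentzian amplitude A half-width g over +-20g:
  # closed form 2 A g arctan(20)
  g <- 0.05; A <- 7
  ppm <- seq(1 - 20 * g, 1 + 20 * g, length.out = 4001)
  s2 <- make_set(rbind(A * g^2 / ((ppm - 1)^2 + g^2)), ppm = ppm)
  expect_equal(unname(integrate_region(s2, min(ppm), max(ppm))),
               2 * A * g * atan(20), tolerance = 1e-5)
  # all-zero spectrum integrates to 0
  s3 <- make_set(rbind(rep(0, 101)), ppm = seq(0, 10, 0.1))
  expect_equal(unname(integrate_region(s3, 0, 10)), 0)
  expect_error(integrate_region(s, 20, 30), "axis points")
})

test_that("pipeline drivers record the expected stage order", {
  gc <- generate_cohort(12, 0, 0, seed = 9)
  sim <- synthesize_spectra(gc$cohort, toy_library(0.1), noise_sd = 0.02,
                            dilution_sigma = 0.2, jitter_sd = 0.002,
                            ppm_grid = toy_grid(0.01), seed = 10)
  ur <- preprocess_urine(sim$spectra, n_intervals = 50, max_shift = 2)
  steps <- vapply(ur$spectra$provenance, `[[`, "", "step")
  expect_equal(steps, c("synthesize", "extract_region", "interval_align",
                        "pqn_normalize", "mean_center", "pareto_scale"))

  sim2 <- synthesize_spectra(gc$cohort, serum_metabolite_library(),
                             noise_sd = 0.02, ppm_grid =
                               default_ppm_grid("serum", 0.01), seed = 11)
  se <- preprocess_serum(sim2$spectra)
  steps2 <- vapply(se$spectra$provenance, `[[`, "", "step")
  expect_equal(steps2, c("synthesize", "extract_region", "align_to_peak",
                         "unit_area_normalize", "mean_center"))
})
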