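#' Extract a spectral region and remove exclusion windows
#'
#' Restricts the axis to `[lo, hi]` and drops points inside any exclusion
#' window (typically residual water and urea). Column order is preserved.
#'
#' @param s A [spectrum_set()].
#' @param lo,hi Region bounds in ppm, `lo < hi`.
#' @param exclusions Optional [interval_list()] of windows to remove.
#' @return A `SpectrumSet` on the retained axis.
#' @export
extract_region <- function(s, lo, hi, exclusions = NULL) {
  stopifnot(inherits(s, "SpectrumSet"), lo < hi)
  keep <- s$ppm >= lo & s$ppm <= hi
  if (!is.null(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      keep <- keep & !(s$ppm >= exclusions$start[i] &
                       s$ppm <= exclusions$end[i])
    }
  }
  if (!any(keep)) stop("extract_region: no axis points retained")
  out <- spectrum_set(s$ppm[keep], s$intensities[, keep, drop = FALSE],
                      s$sample_id, s$provenance)
  add_provenance(out, "extract_region",
                 list(lo = lo, hi = hi,
                      exclusions = if (is.null(exclusions)) NULL else
                        as.data.frame(exclusions)))
}

#' Default water and urea exclusion windows for urine
#'
#' Conventional residual-signal regions: water 4.50-5.00 ppm, urea
#' 5.45-6.05 ppm.
#'
#' @return An [interval_list()].
#' @export
default_exclusions <- function() {
  interval_list(c(4.50, 5.45), c(5.00, 6.05))
}

#' Choose the alignment reference spectrum
#'
#' Returns the index of the spectrum with the highest mean Pearson
#' correlation to all other spectra; ties broken by lowest index. The
#' correlation with a zero-variance spectrum is defined as 0 (with a
#' warning).
#'
#' @param s A [spectrum_set()] with at least 2 samples.
#' @return Integer sample index (1-based).
#' @export
select_reference <- function(s) {
  X <- s$intensities
  n <- nrow(X)
  if (n < 2) stop("select_reference needs >= 2 samples")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance spectra: correlations with them set to 0 (",
            paste(s$sample_id[sds == 0], collapse = ", "), ")")
  }
  C <- suppressWarnings(stats::cor(t(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- NA
  mean_cor <- rowMeans(C, na.rm = TRUE)
  mean_cor[is.nan(mean_cor)] <- 0
  # which.max already breaks ties by lowest index
  unname(which.max(mean_cor))
}

# Shift a vector by k points (positive = to the right), edge-value padding.
shift_pad <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (abs(k) >= n) return(rep(if (k > 0) x[1] else x[n], n))
  if (k > 0) c(rep(x[1], k), x[seq_len(n - k)])
  else c(x[seq(1 - k, n)], rep(x[n], -k))
}

# Best integer shift of seg against ref by maximal cross-correlation
# (inner product of edge-padded shifted segment with the reference);
# ties prefer the smallest |shift|, then the negative one.
best_shift <- function(seg, ref, max_shift) {
  cand <- seq(-max_shift, max_shift)
  cand <- cand[order(abs(cand), cand)]  # 0, -1, 1, -2, 2, ...
  score <- vapply(cand, function(k) sum(shift_pad(seg, k) * ref), 0)
  cand[which.max(score)]
}

#' Interval-wise cross-correlation alignment
#'
#' Within each interval, every sample's segment is shifted by the integer
#' offset (at most `max_shift` points in either direction) that maximizes
#' its cross-correlation with the reference spectrum's segment; positions
#' vacated by the shift are filled with the segment's edge value. This is
#' the interval-correlation-shifting scheme used for urine spectra.
#'
#' @param s A [spectrum_set()].
#' @param intervals An [interval_list()] of alignment segments (ppm).
#' @param max_shift Maximum |shift| in grid points (>= 0).
#' @param reference Reference sample index; defaults to
#'   [select_reference()].
#' @return List with `spectra` (aligned `SpectrumSet`) and `shifts`
#'   (`n_samples x n_intervals` matrix of applied offsets).
#' @export
interval_align <- function(s, intervals, max_shift,
                           reference = select_reference(s)) {
  stopifnot(inherits(s, "SpectrumSet"), max_shift >= 0)
  X <- s$intensities
  n <- nrow(X)
  n_int <- nrow(intervals)
  shifts <- matrix(0L, n, n_int,
                   dimnames = list(s$sample_id, NULL))
  if (max_shift > 0) {
    for (j in seq_len(n_int)) {
      idx <- ppm_index(s$ppm, intervals$start[j], intervals$end[j])
      if (!length(idx)) next
      if (length(idx) < 2 * max_shift + 1) {
        stop("interval ", j, " narrower than 2*max_shift+1 points")
      }
      ref_seg <- X[reference, idx]
      for (i in seq_len(n)) {
        if (i == reference) next
        k <- best_shift(s$intensities[i, idx], ref_seg, max_shift)
        if (k != 0) {
          X[i, idx] <- shift_pad(s$intensities[i, idx], k)
          shifts[i, j] <- k
        }
      }
    }
  }
  out <- set_intensities(s, X)
  out <- add_provenance(out, "interval_align",
                        list(n_intervals = n_int, max_shift = max_shift,
                             reference = s$sample_id[reference]))
  list(spectra = out, shifts = shifts)
}

#' Align whole spectra on a landmark peak
#'
#' Shifts each spectrum globally (integer grid points, edge padding) so
#' that its maximum inside `[target - window, target + window]` lands on the
#' grid point nearest `target_ppm`. Used for serum spectra, which are
#' aligned on the left alanine doublet peak at 1.48 ppm.
#'
#' @param s A [spectrum_set()].
#' @param target_ppm Landmark position (default 1.48).
#' @param window Search half-width in ppm (default 0.05).
#' @return List with `spectra` and per-sample `shifts` (points applied).
#' @export
align_to_peak <- function(s, target_ppm = 1.48, window = 0.05) {
  idx <- ppm_index(s$ppm, target_ppm - window, target_ppm + window)
  if (!length(idx)) stop("search window outside the axis")
  target_idx <- idx[which.min(abs(s$ppm[idx] - target_ppm))]
  X <- s$intensities
  shifts <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    seg <- X[i, idx]
    if (diff(range(seg)) == 0) {
      warning("flat search window for sample ", s$sample_id[i],
              "; no shift applied")
      next
    }
    peak_idx <- idx[which.max(seg)]
    k <- target_idx - peak_idx
    if (k != 0) X[i, ] <- shift_pad(X[i, ], k)
    shifts[i] <- k
  }
  out <- set_intensities(s, X)
  out <- add_provenance(out, "align_to_peak",
                        list(target_ppm = target_ppm, window = window))
  list(spectra = out, shifts = stats::setNames(shifts, s$sample_id))
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: spectra are first (optionally) scaled to a
#' common total integral, the point-wise median spectrum is taken as
#' reference, and each spectrum is divided by the median of its point-wise
#' quotients to the reference over points where the reference exceeds
#' `noise_floor`. The returned factor is the total divisor applied to the
#' input spectrum, i.e. the dilution estimate.
#'
#' @param s A [spectrum_set()]; intensities should be essentially
#'   non-negative (small negative noise excursions are tolerated, since
#'   quotients are computed only over points where the reference exceeds
#'   the noise floor).
#' @param noise_floor Reference intensity below which points are ignored
#'   (default 0, i.e. use all strictly positive reference points).
#' @param pre_normalize Scale spectra to the median total integral before
#'   computing quotients (default `TRUE`).
#' @return List with `spectra` (normalized) and `factors` (per-sample
#'   dilution estimates).
#' @export
pqn_normalize <- function(s, noise_floor = 0, pre_normalize = TRUE) {
  X <- s$intensities
  area_factor <- rep(1, nrow(X))
  if (pre_normalize) {
    areas <- trapz_rows(s$ppm, X)
    if (any(areas <= 0)) stop("non-positive total area in samples: ",
                              paste(s$sample_id[areas <= 0], collapse = ", "))
    area_factor <- areas / stats::median(areas)
    X <- X / area_factor
  }
  ref <- apply(X, 2, stats::median)
  use <- ref > noise_floor
  if (!any(use)) stop("all reference points at or below the noise floor")
  q <- apply(X[, use, drop = FALSE], 1, function(x) {
    stats::median(x / ref[use])
  })
  X <- X / q
  factors <- area_factor * q
  out <- set_intensities(s, X)
  out <- add_provenance(out, "pqn_normalize",
                        list(noise_floor = noise_floor,
                             pre_normalize = pre_normalize))
  list(spectra = out, factors = stats::setNames(factors, s$sample_id))
}

#' Normalize each spectrum to unit area
#'
#' Divides every spectrum by its trapezoidal integral over the ppm axis.
#'
#' @param s A [spectrum_set()].
#' @return A `SpectrumSet` whose row integrals are 1.
#' @export
unit_area_normalize <- function(s) {
  areas <- trapz_rows(s$ppm, s$intensities)
  if (any(areas <= 0)) {
    stop("non-positive total area in samples: ",
         paste(s$sample_id[areas <= 0], collapse = ", "))
  }
  out <- set_intensities(s, s$intensities / areas)
  add_provenance(out, "unit_area_normalize", list())
}

#' Mean center columns
#'
#' Subtracts each column's (variable's) mean across samples.
#'
#' @param s A [spectrum_set()].
#' @return Centered `SpectrumSet`.
#' @export
mean_center <- function(s) {
  out <- set_intensities(s, scale(s$intensities, center = TRUE,
                                  scale = FALSE)[, , drop = FALSE])
  add_provenance(out, "mean_center", list())
}

#' Pareto scale columns
#'
#' Divides each (already centered) column by the square root of its
#' standard deviation, de-emphasizing intense signals less aggressively
#' than unit-variance scaling. Zero-variance columns are left unscaled
#' with a warning.
#'
#' @param s A [spectrum_set()] (center first with [mean_center()]).
#' @return Scaled `SpectrumSet`.
#' @export
pareto_scale <- function(s) {
  sds <- apply(s$intensities, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) left unscaled")
  }
  div <- ifelse(zero, 1, sqrt(sds))
  out <- set_intensities(s, sweep(s$intensities, 2, div, "/"))
  add_provenance(out, "pareto_scale", list(n_zero_variance = sum(zero)))
}

#' Integrate spectra over a ppm region
#'
#' Trapezoidal area under each spectrum between `lo` and `hi`; this is the
#' curve-area quantification used for metabolite levels.
#'
#' @param s A [spectrum_set()].
#' @param lo,hi Region bounds in ppm.
#' @return Named numeric vector of areas, one per sample.
#' @export
integrate_region <- function(s, lo, hi) {
  stopifnot(lo < hi)
  idx <- ppm_index(s$ppm, lo, hi)
  if (length(idx) < 2) {
    stop("region [", lo, ", ", hi, "] has fewer than 2 retained axis points",
         " (was it removed by extraction?)")
  }
  stats::setNames(trapz_rows(s$ppm[idx], s$intensities[, idx, drop = FALSE]),
                  s$sample_id)
}

#' Urine preprocessing pipeline
#'
#' extract (0.5-9.0 ppm minus water/urea windows) -> interval alignment ->
#' probabilistic quotient normalization -> mean centering -> pareto
#' scaling. Every stage is recorded in the provenance log.
#'
#' @param s Raw urine [spectrum_set()].
#' @param lo,hi Analysis window (defaults 0.5 and 9.0 ppm).
#' @param exclusions Water/urea windows; see [default_exclusions()].
#' @param n_intervals Number of alignment intervals (default 245).
#' @param max_shift Maximum alignment shift in points (default 3).
#' @param scale Apply centering and pareto scaling (default `TRUE`); turn
#'   off to obtain dilution-corrected spectra for curve-area
#'   quantification.
#' @return List with `spectra`, alignment `shifts`, and PQN `factors`.
#' @export
preprocess_urine <- function(s, lo = 0.5, hi = 9.0,
                             exclusions = default_exclusions(),
                             n_intervals = 245, max_shift = 3,
                             scale = TRUE) {
  s <- extract_region(s, lo, hi, exclusions)
  al <- interval_align(s, make_intervals(s$ppm, n_intervals), max_shift)
  pq <- pqn_normalize(al$spectra)
  out <- pq$spectra
  if (scale) out <- pareto_scale(mean_center(out))
  list(spectra = out, shifts = al$shifts, factors = pq$factors)
}

#' Serum preprocessing pipeline
#'
#' extract (0.1-4.2 ppm) -> global alignment on the alanine doublet at
#' 1.48 ppm -> unit-area normalization -> mean centering.
#'
#' @param s Raw serum [spectrum_set()].
#' @param lo,hi Analysis window (defaults 0.1 and 4.2 ppm).
#' @param target_ppm,window Landmark peak and search half-width for
#'   [align_to_peak()].
#' @param scale Apply mean centering (default `TRUE`).
#' @return List with `spectra` and per-sample alignment `shifts`.
#' @export
preprocess_serum <- function(s, lo = 0.1, hi = 4.2, target_ppm = 1.48,
                             window = 0.05, scale = TRUE) {
  s <- extract_region(s, lo, hi)
  al <- align_to_peak(s, target_ppm, window)
  out <- unit_area_normalize(al$spectra)
  if (scale) out <- mean_center(out)
  list(spectra = out, shifts = al$shifts)
}
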