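#' Construct a SpectrumSet
#'
#' A `SpectrumSet` holds a shared chemical-shift (ppm) axis, an intensity
#' matrix with one row per sample, the sample identifiers, and an append-only
#' provenance log recording every transform applied with its parameters.
#' It is the object every preprocessing stage consumes and returns.
#'
#' @param ppm Numeric vector, strictly increasing chemical-shift axis (ppm).
#' @param intensities Numeric matrix, `n_samples x length(ppm)`; no missing
#'   values allowed.
#' @param sample_id Character vector of unique sample identifiers; defaults to
#'   the row names of `intensities` or `S1, S2, ...`.
#' @param provenance List of prior transform records (used internally when a
#'   transform returns a modified set).
#'
#' @return An object of class `SpectrumSet`: a list with elements `ppm`,
#'   `intensities`, `sample_id`, `provenance`.
#' @export
#' @examples
#' s <- spectrum_set(ppm = seq(0, 1, length.out = 5),
#'                   intensities = matrix(rnorm(10), nrow = 2))
#' s
spectrum_set <- function(ppm, intensities, sample_id = NULL,
                         provenance = list()) {
  ppm <- as.numeric(ppm)
  if (!is.matrix(intensities)) intensities <- rbind(intensities)
  storage.mode(intensities) <- "double"
  if (length(ppm) != ncol(intensities)) {
    stop("length(ppm) [", length(ppm), "] must equal ncol(intensities) [",
         ncol(intensities), "]")
  }
  if (length(ppm) >= 2 && any(diff(ppm) <= 0)) {
    stop("ppm axis must be strictly increasing")
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities contain missing or non-finite values")
  }
  if (is.null(sample_id)) {
    sample_id <- rownames(intensities)
    if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(intensities)))
  }
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(intensities)) {
    stop("sample_id length must equal the number of spectra")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  rownames(intensities) <- sample_id
  structure(list(ppm = ppm, intensities = intensities,
                 sample_id = sample_id, provenance = provenance),
            class = "SpectrumSet")
}

#' @export
print.SpectrumSet <- function(x, ...) {
  cat(sprintf("SpectrumSet: %d spectra x %d points, delta %.3f-%.3f ppm\n",
              nrow(x$intensities), length(x$ppm),
              min(x$ppm), max(x$ppm)))
  if (length(x$provenance)) {
    cat("provenance:",
        paste(vapply(x$provenance, `[[`, "", "step"), collapse = " -> "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.SpectrumSet <- function(x) dim(x$intensities)

# Append a named transform record; provenance is append-only.
add_provenance <- function(s, step, params = list()) {
  s$provenance <- c(s$provenance,
                    list(list(step = step, params = params)))
  s
}

# Replace the data of a SpectrumSet while keeping identifiers/provenance.
set_intensities <- function(s, intensities, ppm = s$ppm) {
  spectrum_set(ppm, intensities, s$sample_id, s$provenance)
}

#' Ordered non-overlapping ppm intervals
#'
#' Validates and normalizes a two-column set of `(start_ppm, end_ppm)` pairs,
#' sorted and non-overlapping, used for exclusion windows and alignment
#' segments.
#'
#' @param start,end Numeric vectors of equal length with `start < end`
#'   element-wise.
#' @return A `data.frame` with columns `start` and `end`, class
#'   `interval_list`.
#' @export
interval_list <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start and end differ in length")
  if (any(start >= end)) stop("every interval needs start < end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)])) {
    stop("intervals overlap")
  }
  structure(data.frame(start = start, end = end), class =
              c("interval_list", "data.frame"))
}

#' Parse "a-b,c-d" interval shorthand
#'
#' @param x Character scalar like `"4.50-5.00,5.45-6.05"`.
#' @return An [interval_list()].
#' @export
parse_intervals <- function(x) {
  parts <- strsplit(strsplit(x, ",")[[1]], "-")
  bounds <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  interval_list(bounds[1, ], bounds[2, ])
}

#' Tile a ppm axis into equal-width alignment intervals
#'
#' Splits the retained axis (which may contain gaps after exclusion-window
#' removal) into `n` contiguous runs of near-equal column count, emulating a
#' manually segmented axis at scale.
#'
#' @param ppm The (possibly gapped) ppm axis of a `SpectrumSet`.
#' @param n Number of intervals (default 245).
#' @return An [interval_list()] whose bounds are actual axis values.
#' @export
make_intervals <- function(ppm, n = 245) {
  p <- length(ppm)
  if (n < 1 || n > p) stop("need 1 <= n <= length(ppm)")
  idx <- split(seq_len(p), cut(seq_len(p), n, labels = FALSE))
  start <- vapply(idx, function(i) ppm[min(i)], 0)
  end <- vapply(idx, function(i) ppm[max(i)], 0)
  # widen bounds marginally so membership by ppm value keeps the end points
  eps <- min(diff(ppm)) / 2
  interval_list(start - eps, end + eps)
}

# Column indices of the axis falling inside [lo, hi].
ppm_index <- function(ppm, lo, hi) which(ppm >= lo & ppm <= hi)

# Trapezoidal integral of rows of Y over axis x (handles gapped axes by
# integrating piecewise over the given points).
trapz_rows <- function(x, Y) {
  if (!is.matrix(Y)) Y <- rbind(Y)
  n <- length(x)
  if (n < 2) stop("need at least 2 points to integrate")
  w <- diff(x)
  as.numeric((Y[, -n, drop = FALSE] + Y[, -1, drop = FALSE]) %*% w) / 2
}
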