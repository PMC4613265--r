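#' Metabolite peak specification
#'
#' Describes one metabolite as a set of Lorentzian lines: centers (ppm),
#' relative peak heights and half-widths at half-maximum, plus a base
#' concentration (arbitrary units) and a between-sample coefficient of
#' variation.
#'
#' @param name Metabolite name.
#' @param peaks Matrix or data.frame with columns `center`, `height`,
#'   `half_width` (ppm, dimensionless >= 0, ppm > 0).
#' @param base_concentration Mean concentration in arbitrary units (> 0).
#' @param between_sample_cv Fractional between-sample variation (>= 0);
#'   concentrations are drawn log-normally with this sdlog.
#' @return A `metabolite_spec` object.
#' @export
metabolite_spec <- function(name, peaks, base_concentration,
                            between_sample_cv = 0.15) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "height", "half_width") %in% names(peaks)))
  if (any(peaks$height < 0)) stop(name, ": negative relative height")
  if (!all(peaks$half_width > 0)) stop(name, ": half_width must be > 0")
  tot <- sum(peaks$height)
  if (!is.finite(tot) || tot <= 0) {
    stop(name, ": relative heights must sum to a finite positive value")
  }
  if (base_concentration <= 0) stop(name, ": base_concentration must be > 0")
  if (between_sample_cv < 0) stop(name, ": between_sample_cv must be >= 0")
  structure(list(name = name, peaks = peaks,
                 base_concentration = base_concentration,
                 between_sample_cv = between_sample_cv),
            class = "metabolite_spec")
}

pk <- function(center, height, half_width = 0.006) {
  data.frame(center = center, height = height, half_width = half_width)
}

#' Reference urine metabolite library
#'
#' About fifteen urinary metabolites with textbook chemical shifts and
#' simple multiplet approximations, spanning the 0.5-9.0 ppm analysis
#' window: creatinine, hippurate, citrate, glycine, lactate, alanine,
#' dimethylamine, proline betaine, betaine, 4-deoxythreonic and
#' 4-deoxyerythronic acid, alpha-hydroxyisobutyrate, histidine,
#' phenylacetylglutamine, ascorbate. Peak positions and widths are
#' reference-value constants, editable by replacing entries.
#'
#' @return A named list of [metabolite_spec()] objects.
#' @export
urine_metabolite_library <- function() {
  specs <- list(
    metabolite_spec("creatinine", rbind(
      pk(3.05, 1.0), pk(4.06, 0.55)), 60, 0.15),
    metabolite_spec("hippurate", rbind(
      pk(7.55, 0.45), pk(7.64, 0.30), pk(7.84, 0.60), pk(3.97, 0.40)),
      40, 0.25),
    metabolite_spec("citrate", rbind(
      pk(2.55, 0.5), pk(2.67, 0.5)), 30, 0.2),
    metabolite_spec("glycine", pk(3.56, 1.0), 20, 0.2),
    metabolite_spec("lactate", rbind(
      pk(1.32, 0.55), pk(1.34, 0.55), pk(4.11, 0.25)), 15, 0.25),
    metabolite_spec("alanine", rbind(
      pk(1.47, 0.5), pk(1.49, 0.5)), 8, 0.2),
    metabolite_spec("dimethylamine", pk(2.72, 1.0), 10, 0.2),
    metabolite_spec("proline_betaine", rbind(
      pk(3.11, 0.6), pk(3.30, 0.3)), 12, 0.3),
    metabolite_spec("betaine", rbind(
      pk(3.26, 0.9), pk(3.90, 0.2)), 10, 0.2),
    metabolite_spec("deoxythreonic_acid", rbind(
      pk(1.13, 0.6), pk(1.15, 0.6)), 8, 0.2),
    metabolite_spec("deoxyerythronic_acid", rbind(
      pk(1.19, 0.5), pk(1.21, 0.5)), 6, 0.2),
    metabolite_spec("hydroxyisobutyrate", pk(1.36, 1.0), 6, 0.2),
    metabolite_spec("histidine", rbind(
      pk(7.07, 0.5), pk(7.78, 0.5)), 5, 0.2),
    metabolite_spec("phenylacetylglutamine", rbind(
      pk(7.36, 0.5), pk(7.42, 0.4), pk(2.26, 0.3)), 8, 0.2),
    metabolite_spec("ascorbate", pk(4.52, 0.6), 4, 0.25)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Reference serum metabolite library
#'
#' Two broad lipid envelopes (methyl ~0.9 ppm, methylene ~1.3 ppm, line
#' widths roughly ten times those of small molecules) plus sharp signals
#' from glucose, lactate, alanine, valine, pyruvate and the choline head
#' group of phosphatidylcholine, all inside the 0.1-4.2 ppm window.
#'
#' @return A named list of [metabolite_spec()] objects.
#' @export
serum_metabolite_library <- function() {
  specs <- list(
    metabolite_spec("lipid_ch3", pk(0.90, 1.0, 0.05), 50, 0.25),
    metabolite_spec("lipid_ch2", pk(1.30, 1.0, 0.06), 80, 0.3),
    metabolite_spec("glucose", rbind(
      pk(3.25, 0.5), pk(3.41, 0.6), pk(3.49, 0.5), pk(3.72, 0.7),
      pk(3.84, 0.4)), 40, 0.12),
    metabolite_spec("lactate", rbind(
      pk(1.32, 0.55), pk(1.34, 0.55), pk(4.11, 0.25)), 20, 0.2),
    metabolite_spec("alanine", rbind(
      pk(1.46, 0.5), pk(1.48, 0.5)), 12, 0.15),
    metabolite_spec("valine", rbind(
      pk(0.99, 0.5), pk(1.04, 0.5)), 8, 0.15),
    metabolite_spec("pyruvate", pk(2.37, 1.0), 6, 0.2),
    metabolite_spec("phosphatidylcholine", pk(3.22, 1.0), 25, 0.2)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Class effect map
#'
#' Fold-changes applied to the mean concentration of named metabolites in
#' samples with a given outcome.
#'
#' @param outcome `"PE"` or `"GH"`.
#' @param multipliers Named numeric vector of fold-changes (> 0), names are
#'   metabolite names present in the library in use.
#' @return An `effect_map` object.
#' @export
effect_map <- function(outcome, multipliers) {
  outcome <- match.arg(outcome, c("PE", "GH"))
  multipliers <- unlist(multipliers)
  if (is.null(names(multipliers)) || any(!nzchar(names(multipliers)))) {
    stop("multipliers must be a named vector")
  }
  if (any(multipliers <= 0)) stop("all multipliers must be > 0")
  structure(list(outcome = outcome, multipliers = multipliers),
            class = "effect_map")
}

#' Default effect maps
#'
#' Urine: cases show decreased hippurate, lactate and proline betaine and
#' increased creatinine, glycine, dimethylamine, 4-deoxythreonic acid,
#' alpha-hydroxyisobutyrate and histidine; gestational hypertension
#' additionally lowers citrate. Serum: raised lipid envelopes, lowered
#' phosphatidylcholine, lactate and glucose. Magnitudes are simulation
#' parameters chosen to give the pipeline realistic, detectable but
#' imperfect class separation.
#'
#' @param fluid `"urine"` or `"serum"`.
#' @return List of two [effect_map()]s (PE and GH).
#' @export
default_effect_maps <- function(fluid = c("urine", "serum")) {
  fluid <- match.arg(fluid)
  if (fluid == "urine") {
    base <- c(hippurate = 0.70, creatinine = 1.25, glycine = 1.20,
              dimethylamine = 1.20, proline_betaine = 0.75,
              lactate = 0.80, deoxythreonic_acid = 1.20,
              hydroxyisobutyrate = 1.15, histidine = 1.15)
    list(effect_map("PE", base),
         effect_map("GH", c(base, citrate = 0.80)))
  } else {
    base <- c(lipid_ch2 = 1.30, lipid_ch3 = 1.25,
              phosphatidylcholine = 0.80, lactate = 0.85, glucose = 0.90)
    list(effect_map("PE", base), effect_map("GH", base))
  }
}

#' Default covariate distribution parameters
#'
#' Location parameters are the published cohort medians per outcome group
#' (MAP 87.0/92.1/82.7 mmHg, BMI 24.8/27.1/23.5 kg/m2, age 26/28/28 years,
#' UtAPI 1.75/1.49/1.46); scales are derived from the reported IQRs
#' (sd = IQR/1.349 for normal laws; sdlog = IQR/(1.349 * median) for the
#' log-normal BMI and UtAPI).
#'
#' @return Nested list `params[[group]][[covariate]]` for groups
#'   `pe`, `gh`, `control`.
#' @export
default_covariate_params <- function() {
  iqr2sd <- function(iqr) iqr / 1.349
  grp <- function(map_med, map_iqr, age_med, age_iqr,
                  bmi_med, bmi_iqr, utapi_med, utapi_iqr) {
    list(map = list(law = "normal", mean = map_med, sd = iqr2sd(map_iqr)),
         age = list(law = "normal", mean = age_med, sd = iqr2sd(age_iqr)),
         bmi = list(law = "lognormal", meanlog = log(bmi_med),
                    sdlog = bmi_iqr / (1.349 * bmi_med)),
         utapi = list(law = "lognormal", meanlog = log(utapi_med),
                      sdlog = utapi_iqr / (1.349 * utapi_med)))
  }
  list(pe = grp(87.0, 11.1, 26, 7, 24.8, 5.6, 1.75, 0.70),
       gh = grp(92.1, 8.1, 28, 6, 27.1, 7.6, 1.49, 0.39),
       control = grp(82.7, 8.8, 28, 5, 23.5, 4.9, 1.46, 0.52))
}

draw_covariate <- function(n, p) {
  switch(p$law,
         normal = stats::rnorm(n, p$mean, p$sd),
         lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
         stop("unknown covariate law: ", p$law))
}

#' Generate a synthetic screening cohort
#'
#' Draws outcome labels with exact prevalence counts (`round(n * prevalence)`)
#' and maternal covariates (MAP, age, BMI, UtAPI) from per-group
#' distributions. A sample is never both preeclamptic and gestational
#' hypertensive.
#'
#' @param n Number of women (>= 10).
#' @param prevalence_pe,prevalence_gh Fractions in `[0, 1)` with
#'   `prevalence_pe + prevalence_gh < 1`.
#' @param covariate_params See [default_covariate_params()].
#' @param seed Integer seed; runs with equal seeds are identical.
#' @return List with `cohort` (data.frame: `sample_id`, `pe`, `gh`, `map`,
#'   `age`, `bmi`, `utapi`) and `truth` (the generator's hidden parameters).
#' @export
#' @examples
#' gc <- generate_cohort(100, 0.05, 0.05, seed = 1)
#' table(pe = gc$cohort$pe, gh = gc$cohort$gh)
generate_cohort <- function(n, prevalence_pe, prevalence_gh,
                            covariate_params = default_covariate_params(),
                            seed = NULL) {
  if (n < 10) stop("n must be >= 10")
  if (prevalence_pe < 0 || prevalence_gh < 0 ||
      prevalence_pe + prevalence_gh >= 1) {
    stop("prevalences must be >= 0 and sum to < 1")
  }
  n_pe <- round(n * prevalence_pe)
  n_gh <- round(n * prevalence_gh)
  run <- function() {
    group <- sample(rep(c("pe", "gh", "control"),
                        c(n_pe, n_gh, n - n_pe - n_gh)))
    cov <- lapply(c(map = "map", age = "age", bmi = "bmi", utapi = "utapi"),
                  function(v) {
                    x <- numeric(n)
                    for (g in c("pe", "gh", "control")) {
                      i <- which(group == g)
                      x[i] <- draw_covariate(length(i),
                                             covariate_params[[g]][[v]])
                    }
                    x
                  })
    cohort <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                         pe = as.integer(group == "pe"),
                         gh = as.integer(group == "gh"),
                         map = cov$map, age = cov$age, bmi = cov$bmi,
                         utapi = cov$utapi,
                         stringsAsFactors = FALSE)
    truth <- list(group = group, covariate_params = covariate_params,
                  n_pe = n_pe, n_gh = n_gh, seed = seed)
    list(cohort = cohort, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Height-one Lorentzian line: gamma^2 / ((x - c)^2 + gamma^2).
lorentzian <- function(x, center, half_width) {
  half_width^2 / ((x - center)^2 + half_width^2)
}

# Exact integral of height-one Lorentzian over [a, b].
lorentzian_integral <- function(a, b, center, half_width) {
  half_width * (atan((b - center) / half_width) -
                atan((a - center) / half_width))
}

#' Synthesize NMR spectra for a cohort
#'
#' Each spectrum is
#' `dilution * sum_m conc_m * sum_k height_k * L(center_k + jitter, gamma_k)`
#' plus an optional low-order polynomial baseline and i.i.d. Gaussian noise,
#' where `L` is a height-one Lorentzian. Case samples have metabolite mean
#' concentrations multiplied by the effect map matching their outcome.
#' Dilution factors are log-normal(0, `dilution_sigma`); per-sample,
#' per-metabolite chemical-shift jitter is normal(0, `jitter_sd`).
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param library Named list of [metabolite_spec()]s.
#' @param effects List of [effect_map()]s (one per outcome), or `NULL`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param dilution_sigma sdlog of the log-normal dilution factor.
#' @param jitter_sd Chemical-shift jitter sd in ppm.
#' @param ppm_grid Strictly increasing, uniformly spaced axis.
#' @param baseline_coef Polynomial baseline coefficients (ascending powers of
#'   ppm), default none.
#' @param seed Integer seed.
#' @return List with `spectra` (a [spectrum_set()]) and `truth` (dilution
#'   factors, jitter, per-sample concentrations, effect maps).
#' @export
synthesize_spectra <- function(cohort, library, effects = NULL,
                               noise_sd = 0, dilution_sigma = 0,
                               jitter_sd = 0, ppm_grid,
                               baseline_coef = NULL, seed = NULL) {
  stopifnot(is.data.frame(cohort), length(library) >= 1)
  ppm_grid <- as.numeric(ppm_grid)
  d <- diff(ppm_grid)
  if (any(d <= 0)) stop("ppm grid must be strictly increasing")
  if (diff(range(d)) > 1e-8 * mean(d)) stop("ppm grid must be uniform")
  for (m in library) {
    if (any(m$peaks$center < min(ppm_grid) | m$peaks$center > max(ppm_grid))) {
      stop("metabolite '", m$name, "' has peaks outside the ppm grid")
    }
  }
  if (!is.null(effects)) {
    known <- names(library)
    for (e in effects) {
      bad <- setdiff(names(e$multipliers), known)
      if (length(bad)) {
        stop("effect map names metabolites absent from the library: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  n <- nrow(cohort)
  p <- length(ppm_grid)
  mult_for <- function(i) {
    m <- rep(1, length(library)); names(m) <- names(library)
    if (is.null(effects)) return(m)
    out <- if (cohort$pe[i] == 1) "PE" else if (cohort$gh[i] == 1) "GH" else NA
    if (!is.na(out)) {
      for (e in effects) {
        if (e$outcome == out) m[names(e$multipliers)] <- e$multipliers
      }
    }
    m
  }
  run <- function() {
    dilution <- stats::rlnorm(n, 0, dilution_sigma)
    conc <- matrix(0, n, length(library),
                   dimnames = list(cohort$sample_id, names(library)))
    jitter <- matrix(0, n, length(library),
                     dimnames = list(cohort$sample_id, names(library)))
    X <- matrix(0, n, p)
    for (i in seq_len(n)) {
      mult <- mult_for(i)
      y <- numeric(p)
      for (j in seq_along(library)) {
        m <- library[[j]]
        cv <- m$between_sample_cv
        c_ij <- m$base_concentration * mult[j] *
          if (cv > 0) stats::rlnorm(1, -cv^2 / 2, cv) else 1
        j_ij <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
        conc[i, j] <- c_ij
        jitter[i, j] <- j_ij
        for (k in seq_len(nrow(m$peaks))) {
          y <- y + c_ij * m$peaks$height[k] *
            lorentzian(ppm_grid, m$peaks$center[k] + j_ij,
                       m$peaks$half_width[k])
        }
      }
      X[i, ] <- dilution[i] * y
    }
    if (!is.null(baseline_coef)) {
      b <- as.numeric(outer(ppm_grid, seq_along(baseline_coef) - 1, `^`) %*%
                        baseline_coef)
      X <- X + matrix(b, n, p, byrow = TRUE)
    }
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
    truth <- list(dilution = stats::setNames(dilution, cohort$sample_id),
                  concentrations = conc, jitter = jitter,
                  effects = effects, noise_sd = noise_sd,
                  dilution_sigma = dilution_sigma, jitter_sd = jitter_sd,
                  seed = seed)
    list(spectra = spectrum_set(ppm_grid, X, cohort$sample_id,
                                provenance = list(list(step = "synthesize",
                                                       params = list(seed = seed)))),
         truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default ppm grids for the two fluids
#'
#' Urine spectra span 0.5-9.0 ppm, serum 0.1-4.2 ppm.
#'
#' @param fluid `"urine"` or `"serum"`.
#' @param step Grid spacing in ppm (default 0.002).
#' @return Numeric axis.
#' @export
default_ppm_grid <- function(fluid = c("urine", "serum"), step = 0.002) {
  fluid <- match.arg(fluid)
  r <- if (fluid == "urine") c(0.5, 9.0) else c(0.1, 4.2)
  seq(r[1], r[2], by = step)
}
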