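# Small fixtures shared across tests; everything is generated in code.

# A two-metabolite toy library on a short axis: one "hippurate-like" peak
# pair and one "creatinine-like" singlet, with no between-sample variation
# unless asked for.
toy_library <- function(cv = 0) {
  list(
    hipp = metabolite_spec("hipp",
                           data.frame(center = c(7.55, 7.84),
                                      height = c(0.5, 0.6),
                                      half_width = 0.02),
                           base_concentration = 40,
                           between_sample_cv = cv),
    crn = metabolite_spec("crn",
                          data.frame(center = 3.05, height = 1,
                                     half_width = 0.02),
                          base_concentration = 60,
                          between_sample_cv = cv)
  )
}

toy_grid <- function(step = 0.01) seq(0.5, 9.0, by = step)

# Cluster data that is trivially separable: two shifted Gaussian blobs.
separable_data <- function(n_per_class = 20, p = 10, delta = 10,
                           seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
               matrix(rnorm(n_per_class * p, mean = delta), n_per_class))
    list(X = X, y = rep(0:1, each = n_per_class))
  })
}

# Null data: labels independent of X.
null_data <- function(n = 60, p = 15, prev = 0.3, seed = 7) {
  withr::with_seed(seed, {
    list(X = matrix(rnorm(n * p), n),
         y = sample(rep(c(1, 0), c(round(prev * n), n - round(prev * n)))))
  })
}
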