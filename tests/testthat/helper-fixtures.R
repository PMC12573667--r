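# Small fixtures shared across tests; everything is generated in code.

# Uniform-dose map of a given extent (mm) and spacing (mm/px).
uniform_dose_map <- function(dose, region = c(10, 10), spacing = 0.5,
                             pattern = "open") {
  nx <- round(region[1] / spacing)
  ny <- round(region[2] / spacing)
  dose_map(matrix(dose, ny, nx), spacing, pattern = pattern,
           nominal_dose = dose, flask_id = "fixture")
}

# Two-level plateau map: left half `peak`, right half `valley` Gy.
two_level_map <- function(peak = 4.1, valley = 0.9, n = 40, spacing = 1) {
  v <- matrix(valley, n, n)
  v[, seq_len(n / 2)] <- peak
  dose_map(v, spacing, pattern = "striped", nominal_dose = 5,
           flask_id = "fixture")
}

# Peak mask as a bare logical matrix (attributes stripped).
mask_values <- function(mask) {
  matrix(as.logical(mask), nrow(mask))
}

# Brute-force nearest-peak-pixel distance (cm), the oracle for the
# Euclidean distance transform.
brute_force_distance <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
  }
  out * spacing / 10
}

# Quadrat table drawn from the (M)LQ model at given covariates.
synthetic_quadrat_table <- function(n = 500, params = list(nc0 = 2.5,
                                                           alpha = 0.25,
                                                           beta = 0.035,
                                                           delta = -0.04),
                                    seed = 1) {
  set.seed(seed)
  D <- sample(c(0, 0.9, 2, 3.5, 4.1, 5, 10), n, replace = TRUE)
  d <- round(runif(n, 0, 1), 3) * (D < 2)
  tab <- data.frame(flask_id = "syn", pattern = "striped", nominal_dose = 5,
                    ix = seq_len(n), iy = 1L, NC = 0L, D = D, d = d,
                    included = TRUE)
  simulate_quadrat_counts(tab, params, seed = seed + 1)
}

# A small multi-flask study (striped only) for cross-validation tests.
small_study_config <- function(params = list(nc0 = 2.5, alpha = 0.25,
                                             beta = 0.035, delta = -0.04)) {
  experiment_config(patterns = "striped", nominal_doses = c(2, 5),
                    replicates = 4, controls = 4, region = c(32, 16),
                    spacing = 0.5, params = params)
}
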