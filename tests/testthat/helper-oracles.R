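# Independent 3x3 update-matrix oracle, written directly from the
# per-state balance equations (not via the package's update_matrix).
oracle_matrix <- function(m, phi = c(0, 0, 0)) {
  A <- matrix(0, 3, 3)
  A[1, 1] <- 1 - m[1] - phi[1]   # G0/G1 cells that stay
  A[2, 2] <- 1 - m[2] - phi[2]
  A[3, 3] <- 1 - m[3] - phi[3]
  A[2, 1] <- m[1]                # G0/G1 -> lateG1/S
  A[3, 2] <- m[2]                # lateG1/S -> G2/M
  A[1, 3] <- 2 * m[3]            # each dividing G2/M cell -> two G0/G1
  A
}

# Naive repeated multiplication (no squaring tricks).
oracle_power_apply <- function(A, x, n) {
  for (k in seq_len(n)) x <- A %*% x
  drop(x)
}

u87_constraints <- function() {
  growth_constraints(31.13, c(0.602, 0.235, 0.163), "U87")
}
u251_constraints <- function() {
  growth_constraints(24.93, c(0.581, 0.225, 0.194), "U251")
}

# Calibrations are deterministic given the seed; cache per session.
cached_calibration <- local({
  cache <- list()
  function(cell_line) {
    if (is.null(cache[[cell_line]])) {
      cons <- if (cell_line == "U87") u87_constraints() else u251_constraints()
      cache[[cell_line]] <<- fit_transition_params(cons, seed = 1)
    }
    cache[[cell_line]]
  }
})

# Minimal stand-in fit objects for AIC bookkeeping tests.
fake_fit <- function(log_likelihood, n_free, doses = c(0, 1, 2, 3),
                     counts = c(1, 0.8, 0.6, 0.4)) {
  structure(list(log_likelihood = log_likelihood,
                 n_free_params = as.integer(n_free),
                 data = list(doses = doses, mean_counts = counts)),
            class = "drug_fit_result")
}

fourpl_curve <- function(D, e_min, e_max, ec50, n) {
  h <- (D / ec50)^n
  e_min + e_max * h / (1 + h)
}
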