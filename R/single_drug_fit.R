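#' Single-drug dose-response data
#'
#' Container for one drug / cell line dose-response experiment at the 72-h
#' endpoint: mean relative live-cell count per dose with its dispersion,
#' optionally backed by replicate-level values.
#'
#' @param drug,cell_line labels.
#' @param doses numeric vector of doses in uM, including the 0 control.
#' @param mean_counts mean relative cell count per dose (> 0).
#' @param sd,se optional per-dose standard deviation / standard error.
#' @param replicates optional long `data.frame` with columns `dose_uM`,
#'   `replicate_id`, `relative_count`.
#' @return An object of class `dose_response_data`.
#' @export
dose_response_data <- function(drug, cell_line, doses, mean_counts,
                               sd = NULL, se = NULL, replicates = NULL) {
  doses <- as.numeric(doses)
  mean_counts <- as.numeric(mean_counts)
  if (!is.null(sd)) sd <- as.numeric(sd)
  if (!is.null(se)) se <- as.numeric(se)
  stopifnot(length(doses) == length(mean_counts), all(doses >= 0))
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses", call. = FALSE)
  if (!any(doses == 0))
    stop("control (dose 0) must be present", call. = FALSE)
  if (any(mean_counts <= 0))
    stop("relative counts must be positive", call. = FALSE)
  o <- order(doses)
  structure(list(drug = drug, cell_line = cell_line,
                 doses = doses[o], mean_counts = mean_counts[o],
                 sd = if (!is.null(sd)) sd[o], se = if (!is.null(se)) se[o],
                 replicates = replicates),
            class = "dose_response_data")
}

# Predicted relative counts at the data's doses for candidate drug params.
predict_counts_for_fit <- function(base, target_state, doses, ec50, hill_n,
                                   emax_phi, ec50_phi, horizon = 72L) {
  m <- c(base$m1, base$m2, base$m3)
  x0 <- 100 * growth_eigensystem(base)$proportions
  A0 <- update_matrix(base)
  x <- x0
  for (k in seq_len(horizon)) x <- drop(A0 %*% x)
  control_total <- sum(x)
  vapply(doses, function(D) {
    mi <- transition_inhibition(m[target_state], D, ec50, hill_n)
    phii <- death_rate(D, emax_phi, ec50_phi)
    mm <- m; phi <- c(0, 0, 0)
    mm[target_state] <- mi; phi[target_state] <- phii
    A <- matrix(c(1 - mm[1] - phi[1], 0, DIVISION_FACTOR * mm[3],
                  mm[1], 1 - mm[2] - phi[2], 0,
                  0, mm[2], 1 - mm[3] - phi[3]), nrow = 3, byrow = TRUE)
    x <- x0
    for (k in seq_len(horizon)) x <- drop(A %*% x)
    sum(x) / control_total
  }, 0)
}

#' Fit a drug's dose-response parameters
#'
#' Least-squares estimation of the drug's transition-inhibition parameters
#' (`ec50`, `hill_n`) and, when `include_death`, the death-term parameters
#' (`emax_phi`, `ec50_phi`), by matching model-predicted to measured mean
#' relative cell counts at 72 h. Uses multi-start Levenberg-Marquardt with
#' box bounds (EC50s within 1e-5 to 1e3 uM, searched on the log10 scale;
#' Hill coefficient in (0, 10]; `emax_phi` bounded so that `mi + phii <= 1`
#' holds at every dose).
#'
#' @param data a [dose_response_data()].
#' @param base calibrated no-drug [transition_params()] of the matching
#'   cell line.
#' @param target_state cell-cycle state the drug acts on (1-3).
#' @param include_death fit the drug-induced death term (default TRUE).
#' @param n_starts number of random starts (default 20).
#' @param seed integer seed for the starts.
#' @param horizon assay endpoint in hours (default 72).
#' @return An object of class `drug_fit_result`: `params`
#'   ([drug_params()]), `sse`, `residuals` (predicted - observed),
#'   `log_likelihood`, `aic`, `n_free_params`, `include_death`,
#'   `predicted`, plus the input `data`.
#' @export
fit_drug_params <- function(data, base, target_state, include_death = TRUE,
                            n_starts = 20L, seed = 1L, horizon = 72L) {
  stopifnot(inherits(data, "dose_response_data"),
            inherits(base, "transition_params"), target_state %in% 1:3)
  doses <- data$doses
  obs <- data$mean_counts
  m <- c(base$m1, base$m2, base$m3)
  emax_ub <- min(1 - m) - 1e-9   # keeps mi + phii <= 1 at any dose
  lg_lo <- -5; lg_hi <- 3        # log10 uM bounds for both EC50s

  # parameter vector: (log10 ec50, hill_n [, emax_phi, log10 ec50_phi])
  resid_fun <- function(p) {
    predict_counts_for_fit(base, target_state, doses,
                           ec50 = 10^p[1], hill_n = p[2],
                           emax_phi = if (include_death) p[3] else 0,
                           ec50_phi = if (include_death) 10^p[4] else 1,
                           horizon = horizon) - obs
  }
  lower <- c(lg_lo, 1e-3)
  upper <- c(lg_hi, 10)
  if (include_death) {
    lower <- c(lower, 0, lg_lo)
    upper <- c(upper, emax_ub, lg_hi)
  }

  pos <- doses[doses > 0]
  set.seed(seed)
  starts <- replicate(n_starts, {
    p <- c(stats::runif(1, log10(min(pos)), log10(max(pos))),
           stats::runif(1, 0.3, 3))
    if (include_death)
      p <- c(p, stats::runif(1, 0, emax_ub / 2),
             stats::runif(1, log10(min(pos)), log10(max(pos))))
    p
  })

  best <- NULL; best_sse <- Inf; status <- character(n_starts)
  for (i in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[, i], lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) { status[i] <- "error"; next }
    sse <- sum(resid_fun(fit$par)^2)
    status[i] <- "ok"
    if (sse < best_sse) { best_sse <- sse; best <- fit$par }
  }
  if (is.null(best))
    stop("all ", n_starts, " starts failed: ",
         paste(unique(status), collapse = ", "), call. = FALSE)

  params <- drug_params(data$drug, target_state,
                        ec50 = 10^best[1], hill_n = best[2],
                        emax_phi = if (include_death) best[3] else 0,
                        ec50_phi = if (include_death) 10^best[4] else 1)
  predicted <- resid_fun(best) + obs
  residuals <- predicted - obs
  sds <- fit_sds(data)
  ll <- log_likelihood_normalized(residuals, sds)
  k <- if (include_death) 4L else 2L
  structure(list(params = params, sse = best_sse, residuals = residuals,
                 predicted = predicted, log_likelihood = ll,
                 n_free_params = k, aic = 2 * k - 2 * ll,
                 include_death = include_death, data = data,
                 start_status = status),
            class = "drug_fit_result")
}

# Per-dose sds for the likelihood, floored at 1% of the mean so that
# noise-free data do not yield infinite weights.
fit_sds <- function(data, floor_frac = 0.01) {
  sds <- data$sd
  if (is.null(sds)) sds <- rep(0, length(data$mean_counts))
  pmax(sds, floor_frac * data$mean_counts)
}

#' @export
print.drug_fit_result <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s, death %s): SSE = %.3g, AIC = %.2f\n",
              x$params$name, if (x$include_death) "on" else "off",
              x$sse, x$aic))
  print(x$params)
  invisible(x)
}

#' Log-likelihood of sd-normalised residuals under standard-normal errors
#'
#' Each residual is divided by its experimental standard deviation and
#' scored against the standard normal density; small or absent sds are
#' floored to avoid infinite weights.
#'
#' @param residuals numeric vector of model - data residuals.
#' @param sds experimental standard deviations, same length.
#' @param sd_floor absolute floor applied to `sds` (default `1e-8`; pass
#'   pre-floored sds from [fit_sds()] for the 1%-of-mean rule).
#' @return The summed log-likelihood.
#' @export
log_likelihood_normalized <- function(residuals, sds, sd_floor = 1e-8) {
  stopifnot(length(residuals) == length(sds))
  if (any(sds < 0)) stop("standard deviations must be positive", call. = FALSE)
  sds <- pmax(sds, sd_floor)
  sum(stats::dnorm(residuals / sds, log = TRUE))
}

#' Pooled AIC comparison of death vs no-death model variants
#'
#' Pools log-likelihoods and free-parameter counts over matched sets of
#' fits (e.g. 3 drugs x 2 cell lines: 24 free parameters with death terms
#' vs 12 without) and returns `AIC(death) - AIC(no death)`. Negative values
#' favour the model with drug-induced death.
#'
#' @param fits_death,fits_nodeath lists of [fit_drug_params()] results on
#'   identical data, with and without death terms.
#' @return A list: `delta_aic`, `aic_death`, `aic_nodeath`, `k_death`,
#'   `k_nodeath`.
#' @export
compare_aic <- function(fits_death, fits_nodeath) {
  if (inherits(fits_death, "drug_fit_result")) fits_death <- list(fits_death)
  if (inherits(fits_nodeath, "drug_fit_result")) fits_nodeath <- list(fits_nodeath)
  if (length(fits_death) != length(fits_nodeath))
    stop("fit sets must be matched one-to-one", call. = FALSE)
  for (i in seq_along(fits_death)) {
    d1 <- fits_death[[i]]$data; d0 <- fits_nodeath[[i]]$data
    if (!isTRUE(all.equal(d1$doses, d0$doses)) ||
        !isTRUE(all.equal(d1$mean_counts, d0$mean_counts)))
      stop("fit pair ", i, " was not computed on identical data", call. = FALSE)
  }
  ll_d <- sum(vapply(fits_death, `[[`, 0, "log_likelihood"))
  ll_0 <- sum(vapply(fits_nodeath, `[[`, 0, "log_likelihood"))
  k_d <- sum(vapply(fits_death, `[[`, 0L, "n_free_params"))
  k_0 <- sum(vapply(fits_nodeath, `[[`, 0L, "n_free_params"))
  aic_d <- 2 * k_d - 2 * ll_d
  aic_0 <- 2 * k_0 - 2 * ll_0
  list(delta_aic = aic_d - aic_0, aic_death = aic_d, aic_nodeath = aic_0,
       k_death = k_d, k_nodeath = k_0)
}

#' Pearson correlation between predicted and observed values
#'
#' @param predicted,observed equal-length numeric vectors, n >= 3.
#' @return Pearson r. Zero variance in either vector is an error (the
#'   correlation is undefined).
#' @export
goodness_of_fit <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  stats::cor(predicted, observed)
}
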