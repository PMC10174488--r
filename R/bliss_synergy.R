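#' Inhibition effect from relative cell counts
#'
#' The inhibition effect is defined as 1 minus the relative live-cell
#' count; stimulation (counts above 1) passes through as negative
#' inhibition unchanged.
#'
#' @param grid a [dose_grid()] or numeric matrix/vector of relative counts.
#' @return Matrix (or vector) of inhibition effects.
#' @export
inhibition_from_counts <- function(grid) {
  if (inherits(grid, "dose_grid")) 1 - grid$values else 1 - grid
}

# 4PL evaluated at dose D (value e_min exactly at D = 0).
fourpl_value <- function(D, e_min, e_max, ec50, hill_n) {
  h <- (D / ec50)^hill_n
  e_min + e_max * h / (1 + h)
}

#' Fit a four-parameter logistic curve to inhibition data
#'
#' Least-squares fit of `y = Emin + Emax (D/EC50)^n / (1 + (D/EC50)^n)` to
#' one row or column of an inhibition matrix, by multi-start
#' Levenberg-Marquardt under box bounds that keep the curve in a
#' physically meaningful inhibition range while tolerating noise:
#' `Emin` in \[-0.5, 1\], `Emax` in \[0, 1.5\], `EC50` within (min nonzero
#' dose)/10 to (max dose)x10 searched on the log10 scale, `n` in (0, 10\].
#' At dose 0 the fitted curve equals `Emin` exactly.
#'
#' @param doses dose vector in uM including 0.
#' @param inhibitions observed inhibition effects, same length.
#' @param seed integer seed for the random starts.
#' @param n_starts number of starts (default 12).
#' @return An object of class `fourpl_fit`: `e_min`, `e_max`, `ec50`,
#'   `hill_n`, `fitted` (values at `doses`), `sse`, `converged`,
#'   `degenerate` (TRUE for the constant-data fallback flat fit).
#' @export
fit_4pl <- function(doses, inhibitions, seed = 1L, n_starts = 12L) {
  stopifnot(length(doses) == length(inhibitions), any(doses == 0))
  pos <- doses[doses > 0]
  if (diff(range(inhibitions)) < 1e-10) {
    c0 <- mean(inhibitions)
    return(structure(list(e_min = c0, e_max = 0, ec50 = stats::median(pos),
                          hill_n = 1, fitted = rep(c0, length(doses)),
                          sse = sum((inhibitions - c0)^2),
                          converged = TRUE, degenerate = TRUE),
                     class = "fourpl_fit"))
  }
  lg_lo <- log10(min(pos) / 10); lg_hi <- log10(max(pos) * 10)
  resid_fun <- function(p)
    fourpl_value(doses, p[1], p[2], 10^p[3], p[4]) - inhibitions
  lower <- c(-0.5, 0, lg_lo, 1e-3)
  upper <- c(1, 1.5, lg_hi, 10)

  set.seed(seed)
  best <- NULL; best_sse <- Inf; converged <- FALSE
  for (i in seq_len(n_starts)) {
    p0 <- c(inhibitions[doses == 0][1] + stats::runif(1, -0.05, 0.05),
            max(0.05, diff(range(inhibitions))) * stats::runif(1, 0.5, 1.5),
            stats::runif(1, lg_lo, lg_hi),
            stats::runif(1, 0.3, 3))
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(resid_fun(fit$par)^2)
    converged <- TRUE
    if (sse < best_sse) { best_sse <- sse; best <- fit$par }
  }
  if (!converged)
    stop("4PL fit failed from every start", call. = FALSE)
  structure(list(e_min = best[1], e_max = best[2], ec50 = 10^best[3],
                 hill_n = best[4],
                 fitted = fourpl_value(doses, best[1], best[2], 10^best[3],
                                       best[4]),
                 sse = best_sse, converged = TRUE, degenerate = FALSE),
            class = "fourpl_fit")
}

#' Averaged row/column 4PL inhibition surface
#'
#' Fits a 4PL curve to each of the rows (inhibition vs dose B at fixed
#' dose A) and each of the columns (vs dose A at fixed dose B) of an
#' inhibition matrix — 16 fits for an 8x8 grid — and takes, at every cell,
#' the mean of its row-fit and column-fit values as the final fitted
#' inhibition. Smoothing through sigmoidal fits makes the downstream
#' Bliss analysis robust to noise in any single well.
#'
#' @param inhibition matrix of inhibition effects (rows index dose A).
#' @param doses_a,doses_b dose vectors in uM matching the matrix.
#' @param seed integer seed; per-fit seeds are derived from it.
#' @return A list: `surface` (averaged fitted matrix), `row_fits`,
#'   `col_fits` (lists of [fit_4pl()] results), `degenerate` (any flagged
#'   flat fits).
#' @export
fitted_surface <- function(inhibition, doses_a, doses_b, seed = 1L) {
  inhibition <- as.matrix(inhibition)
  stopifnot(nrow(inhibition) == length(doses_a),
            ncol(inhibition) == length(doses_b))
  row_fits <- lapply(seq_along(doses_a), function(i)
    fit_4pl(doses_b, inhibition[i, ], seed = seed + 101L * i))
  col_fits <- lapply(seq_along(doses_b), function(j)
    fit_4pl(doses_a, inhibition[, j], seed = seed + 211L * j))
  row_mat <- do.call(rbind, lapply(row_fits, `[[`, "fitted"))
  col_mat <- do.call(cbind, lapply(col_fits, `[[`, "fitted"))
  list(surface = (row_mat + col_mat) / 2,
       row_fits = row_fits, col_fits = col_fits,
       degenerate = any(vapply(c(row_fits, col_fits), `[[`, TRUE,
                               "degenerate")))
}

#' Bliss independence null
#'
#' Expected combined inhibition of two non-interacting drugs:
#' `y_A + y_B - y_A * y_B` (vectorised; with matrix-shaped recycling via
#' [outer()] left to the caller).
#'
#' @param y_a,y_b single-agent inhibition effects.
#' @return The Bliss null inhibition.
#' @export
bliss_independence <- function(y_a, y_b) {
  y_a + y_b - y_a * y_b
}

#' Excess-over-Bliss surface and summary score
#'
#' Takes the averaged fitted inhibition surface, extracts the single-agent
#' fitted inhibitions from its dose-0 margins (`y_A` from the dose-B = 0
#' column, `y_B` from the dose-A = 0 row), forms the Bliss null
#' `y_A + y_B - y_A y_B` at every dose pair, and scores each cell as
#' `EOB = y_AB - y_Bliss`. Positive values denote synergy, negative values
#' antagonism. Two summaries are reported: the mean (with its standard
#' error) over all grid cells, and over the cells where both doses are
#' nonzero (the margins have EOB near 0 by construction and dilute the
#' all-cell mean).
#'
#' @param surface averaged fitted inhibition matrix (from
#'   [fitted_surface()]).
#' @param doses_a,doses_b dose vectors in uM matching the matrix.
#' @return An object of class `eob_result`: `eob` (matrix), `bliss`,
#'   `y_a`, `y_b`, `surface`, `mean_eob`, `se_eob` (all cells),
#'   `mean_eob_nonzero`, `se_eob_nonzero` (both-doses-positive cells).
#' @export
eob_surface <- function(surface, doses_a, doses_b) {
  surface <- as.matrix(surface)
  stopifnot(nrow(surface) == length(doses_a),
            ncol(surface) == length(doses_b))
  j0 <- which(doses_b == 0); i0 <- which(doses_a == 0)
  if (length(i0) != 1 || length(j0) != 1)
    stop("grid must contain exactly one zero dose per drug", call. = FALSE)
  y_a <- surface[, j0]   # drug A alone, one value per dose_a
  y_b <- surface[i0, ]   # drug B alone, one value per dose_b
  bliss <- outer(y_a, y_b, bliss_independence)
  eob <- surface - bliss
  nz <- outer(doses_a > 0, doses_b > 0, `&`)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(eob = eob, bliss = bliss, y_a = y_a, y_b = y_b,
                 surface = surface,
                 mean_eob = mean(eob), se_eob = se(as.vector(eob)),
                 mean_eob_nonzero = mean(eob[nz]),
                 se_eob_nonzero = se(eob[nz])),
            class = "eob_result")
}

#' @export
print.eob_result <- function(x, ...) {
  cat(sprintf("Excess over Bliss: mean %.4f (SE %.4f) over all cells; %.4f (SE %.4f) over both-dose cells\n",
              x$mean_eob, x$se_eob, x$mean_eob_nonzero, x$se_eob_nonzero))
  invisible(x)
}

#' Full excess-over-Bliss analysis of a dose grid
#'
#' Convenience wrapper: counts -> inhibition -> row/column 4PL fits ->
#' averaged surface -> Bliss null -> EOB summary.
#'
#' @param grid a [dose_grid()] of relative cell counts.
#' @param seed integer seed for the 4PL fits.
#' @return An `eob_result` (see [eob_surface()]) with the
#'   [fitted_surface()] diagnostics attached as `fits`.
#' @export
eob_from_grid <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "dose_grid"))
  inh <- inhibition_from_counts(grid)
  fs <- fitted_surface(inh, grid$doses_a, grid$doses_b, seed = seed)
  out <- eob_surface(fs$surface, grid$doses_a, grid$doses_b)
  out$fits <- fs
  out
}
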