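#' Growth constraints of a cell line
#'
#' The two observables that calibrate the transition network in the absence
#' of drug: the population doubling time and the steady-state fractions of
#' cells in G0/G1, lateG1/S and G2/M. Fractions are renormalised if they
#' miss 1 by less than `1e-6`.
#'
#' @param doubling_time_h population doubling time in hours (> 0).
#' @param ratios length-3 nonnegative vector of steady-state cell-cycle
#'   fractions (G0/G1, lateG1/S, G2/M), summing to 1.
#' @param cell_line optional label.
#' @return An object of class `growth_constraints`.
#' @examples
#' growth_constraints(31.13, c(0.602, 0.235, 0.163), "U87")
#' @export
growth_constraints <- function(doubling_time_h, ratios, cell_line = NULL) {
  stopifnot(is.numeric(doubling_time_h), length(doubling_time_h) == 1,
            doubling_time_h > 0, length(ratios) == 3)
  if (any(ratios < 0)) stop("state ratios must be nonnegative", call. = FALSE)
  s <- sum(ratios)
  if (abs(s - 1) > 1e-6)
    stop("state ratios must sum to 1 (got ", signif(s, 6), ")", call. = FALSE)
  structure(list(doubling_time_h = doubling_time_h,
                 ratios = unname(ratios) / s,
                 cell_line = cell_line),
            class = "growth_constraints")
}

#' Target state populations after exponential growth
#'
#' Converts growth constraints into the calibration target: the number of
#' cells expected after `horizon` hours of exponential growth from
#' `x0_total` cells, `x0_total * exp(horizon * log(2) / tau_d)`, split over
#' the three states by the steady-state ratios.
#'
#' @param constraints a [growth_constraints()].
#' @param x0_total initial total cell count (default 100).
#' @param horizon horizon in hours (default 72).
#' @return Length-3 numeric vector of target counts per state.
#' @export
target_population <- function(constraints, x0_total = 100, horizon = 72) {
  stopifnot(inherits(constraints, "growth_constraints"))
  total <- x0_total * exp(horizon * log(2) / constraints$doubling_time_h)
  stats::setNames(total * constraints$ratios, STATE_NAMES)
}

#' Calibrate transition probabilities from growth constraints
#'
#' Estimates (M1, M2, M3) by least squares so that a deterministic
#' `horizon`-hour simulation started from `x0_total` cells split by the
#' steady-state ratios reproduces the [target_population()]. The three
#' constraints (doubling time plus two independent fractions) identify the
#' three parameters; the fit is repeated from `n_starts` random initial
#' guesses drawn uniformly on the unit cube and the best solution is
#' returned together with a uniqueness flag.
#'
#' @param constraints a [growth_constraints()].
#' @param n_starts number of random starts (default 5).
#' @param seed integer seed for the random starts.
#' @param x0_total initial total count (default 100).
#' @param horizon calibration horizon in hours (default 72).
#' @return An object of class `calibration_result`: `params`
#'   (a [transition_params()]), `sse`, `n_starts`, `all_solutions` (one row
#'   per start), `converged_unique` (TRUE iff the per-start solutions agree
#'   to within 1e-4 in every parameter), and the input `constraints`.
#' @examples
#' fit <- fit_transition_params(growth_constraints(31.13, c(0.602, 0.235, 0.163)),
#'                              seed = 1)
#' round(unlist(fit$params), 2)
#' @export
fit_transition_params <- function(constraints, n_starts = 5L, seed = NULL,
                                  x0_total = 100, horizon = 72) {
  stopifnot(inherits(constraints, "growth_constraints"))
  target <- target_population(constraints, x0_total, horizon)
  x0 <- x0_total * constraints$ratios
  horizon <- as.integer(horizon)

  resid_fun <- function(m) {
    A <- matrix(c(1 - m[1], 0,        DIVISION_FACTOR * m[3],
                  m[1],     1 - m[2], 0,
                  0,        m[2],     1 - m[3]),
                nrow = 3, byrow = TRUE)
    x <- x0
    for (k in seq_len(horizon)) x <- drop(A %*% x)
    x - target
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- matrix(stats::runif(3L * n_starts), ncol = 3)
  sols <- matrix(NA_real_, nrow = n_starts, ncol = 3,
                 dimnames = list(NULL, c("m1", "m2", "m3")))
  sses <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], lower = rep(0, 3), upper = rep(1, 3),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 1000)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      sols[i, ] <- fit$par
      sses[i] <- sum(resid_fun(fit$par)^2)
    }
  }
  if (all(is.na(sses)))
    stop("growth calibration failed from every start", call. = FALSE)
  ok <- which(!is.na(sses))
  best <- ok[which.min(sses[ok])]
  spread <- apply(sols[ok, , drop = FALSE], 2, function(z) diff(range(z)))
  structure(list(params = transition_params(sols[best, 1], sols[best, 2],
                                            sols[best, 3]),
                 sse = sses[best],
                 n_starts = n_starts,
                 all_solutions = cbind(sols, sse = sses),
                 converged_unique = length(ok) == n_starts &&
                   max(spread) < 1e-4,
                 constraints = constraints),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Growth calibration%s: SSE = %.3g over %d starts (unique: %s)\n",
              if (is.null(x$constraints$cell_line)) ""
              else paste0(" [", x$constraints$cell_line, "]"),
              x$sse, x$n_starts, x$converged_unique))
  print(x$params)
  invisible(x)
}

#' Built-in cell-line growth constraints
#'
#' Literature-derived doubling times and steady-state cell-cycle fractions
#' for the U87 and U251 glioma lines, with the minimum/maximum reported
#' values used by [sensitivity_sweep()], shipped as a package fixture.
#'
#' @return A `data.frame` with columns `cell_line`, `variant`
#'   (`baseline`/`min`/`max`), `doubling_time_h`, `g0g1`, `lateg1s`, `g2m`.
#' @export
cell_line_constraints <- function() {
  utils::read.csv(system.file("extdata", "growth_constraints.csv",
                              package = "cyclecombo"),
                  stringsAsFactors = FALSE)
}

#' Fetch one built-in constraint set as a growth_constraints object
#'
#' @param cell_line `"U87"` or `"U251"`.
#' @param variant `"baseline"`, `"min"` or `"max"`.
#' @export
builtin_constraints <- function(cell_line, variant = "baseline") {
  tab <- cell_line_constraints()
  row <- tab[tab$cell_line == cell_line & tab$variant == variant, ]
  if (nrow(row) != 1)
    stop("no built-in constraints for ", cell_line, "/", variant, call. = FALSE)
  growth_constraints(row$doubling_time_h, c(row$g0g1, row$lateg1s, row$g2m),
                     cell_line = cell_line)
}

#' Sensitivity sweep over growth-constraint variants
#'
#' Recalibrates the transition network for each constraint variant and, if
#' drug parameters and measured combination grids are supplied, re-predicts
#' each grid and reports the model-vs-data Pearson correlation, so the
#' stability of combination predictions against literature variability in
#' doubling time and cell-cycle fractions can be assessed.
#'
#' @param variants named list of [growth_constraints()].
#' @param drugs optional list of [drug_params()] used to rebuild the cell
#'   line model per variant.
#' @param grids optional named list of measured [dose_grid()]s; names are
#'   `"drugA|drugB"` pairs.
#' @param seed seed passed to each calibration.
#' @return A `data.frame` with one row per variant (x grid, if grids are
#'   given): fitted `m1, m2, m3`, `growth_factor`, `doubling_time_h`, and
#'   `pearson_r` where measured data were supplied. Calibration failures
#'   are reported as `NA` rows rather than aborting the sweep.
#' @export
sensitivity_sweep <- function(variants, drugs = NULL, grids = NULL, seed = 1L) {
  stopifnot(is.list(variants), length(variants) > 0)
  if (is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  rows <- list()
  for (nm in names(variants)) {
    fit <- try(fit_transition_params(variants[[nm]], seed = seed),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(variant = nm, pair = NA, m1 = NA, m2 = NA, m3 = NA,
                   growth_factor = NA, doubling_time_h = NA, pearson_r = NA)
      next
    }
    eig <- growth_eigensystem(fit$params)
    base_row <- data.frame(variant = nm, pair = NA_character_,
                           m1 = fit$params$m1, m2 = fit$params$m2,
                           m3 = fit$params$m3,
                           growth_factor = eig$growth_factor,
                           doubling_time_h = doubling_time(eig$growth_factor),
                           pearson_r = NA_real_)
    if (is.null(grids) || is.null(drugs)) {
      rows[[length(rows) + 1L]] <- base_row
    } else {
      model <- cell_line_model(variants[[nm]]$cell_line %||% nm,
                               fit$params, drugs)
      for (pair in names(grids)) {
        ab <- strsplit(pair, "|", fixed = TRUE)[[1]]
        g <- grids[[pair]]
        pred <- predict_grid(model, ab[1], ab[2], g$doses_a, g$doses_b)
        r <- compare_grids(pred, g)$pearson_r
        row <- base_row
        row$pair <- pair
        row$pearson_r <- r
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
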