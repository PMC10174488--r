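#' 8x8 combination dose grid of relative cell counts
#'
#' @param drug_a,drug_b drug labels (A varies along rows, B along columns).
#' @param doses_a,doses_b ascending dose vectors in uM, starting at 0.
#' @param values matrix of relative cell counts, `length(doses_a)` rows by
#'   `length(doses_b)` columns.
#' @param se optional matrix of per-cell standard errors (measured grids).
#' @param cell_line optional label.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(drug_a, drug_b, doses_a, doses_b, values, se = NULL,
                      cell_line = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(doses_a), ncol(values) == length(doses_b))
  if (is.unsorted(doses_a) || is.unsorted(doses_b))
    stop("dose vectors must be ascending", call. = FALSE)
  if (any(values <= 0))
    stop("relative counts must be positive", call. = FALSE)
  dimnames(values) <- list(paste0("a", signif(doses_a, 4)),
                           paste0("b", signif(doses_b, 4)))
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a = unname(doses_a), doses_b = unname(doses_b),
                 values = values, se = se, cell_line = cell_line),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("%s x %s dose grid (%d x %d)%s\n", x$drug_a, x$drug_b,
              length(x$doses_a), length(x$doses_b),
              if (is.null(x$cell_line)) "" else paste0(" [", x$cell_line, "]")))
  print(round(x$values, 3))
  invisible(x)
}

#' Predict a pairwise combination response surface
#'
#' Evaluates [relative_cell_count()] at every dose pair of the grid using
#' the calibrated single-drug model with no refitting: the only inputs are
#' the no-drug transition network and the two drugs' single-agent
#' dose-response parameters. Row 1 and column 1 (dose 0 of the partner)
#' reproduce the single-drug curves exactly.
#'
#' @param model a [cell_line_model()] containing both drugs.
#' @param drug_a,drug_b drug names in the model (distinct target states).
#' @param doses_a,doses_b dose vectors in uM; defaults to the 4-fold
#'   checkerboard series of [default_doses()].
#' @param horizon endpoint in hours (default 72).
#' @return A predicted [dose_grid()].
#' @export
predict_grid <- function(model, drug_a, drug_b, doses_a = NULL,
                         doses_b = NULL, horizon = 72L) {
  stopifnot(inherits(model, "cell_line_model"),
            drug_a %in% names(model$drugs), drug_b %in% names(model$drugs))
  if (model$drugs[[drug_a]]$target_state == model$drugs[[drug_b]]$target_state)
    stop("combination drugs must target distinct states", call. = FALSE)
  if (is.null(doses_a)) doses_a <- default_doses(drug_a, "combination")
  if (is.null(doses_b)) doses_b <- default_doses(drug_b, "combination")
  vals <- matrix(NA_real_, length(doses_a), length(doses_b))
  for (i in seq_along(doses_a))
    for (j in seq_along(doses_b))
      vals[i, j] <- relative_cell_count(
        model, stats::setNames(c(doses_a[i], doses_b[j]), c(drug_a, drug_b)),
        horizon)
  dose_grid(drug_a, drug_b, doses_a, doses_b, vals,
            cell_line = model$cell_line)
}

#' Compare a predicted grid with a measured grid
#'
#' @param predicted,measured [dose_grid()]s on matching dose vectors
#'   (relative tolerance `1e-6`).
#' @return A list: `pearson_r` over all paired cells, and `table`, a long
#'   `data.frame` (`dose_a_uM`, `dose_b_uM`, `predicted`, `measured`) for
#'   scatter plotting.
#' @export
compare_grids <- function(predicted, measured) {
  stopifnot(inherits(predicted, "dose_grid"), inherits(measured, "dose_grid"))
  for (ax in c("doses_a", "doses_b")) {
    da <- predicted[[ax]]; db <- measured[[ax]]
    if (length(da) != length(db) ||
        any(abs(da - db) > 1e-6 * pmax(da, db, 1e-12)))
      stop("dose mismatch on ", ax, " at position(s) ",
           paste(which(abs(da - db) > 1e-6 * pmax(da, db, 1e-12)),
                 collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(dose_a_uM = rep(predicted$doses_a,
                                    times = length(predicted$doses_b)),
                    dose_b_uM = rep(predicted$doses_b,
                                    each = length(predicted$doses_a)),
                    predicted = as.vector(predicted$values),
                    measured = as.vector(measured$values))
  list(pearson_r = goodness_of_fit(tab$predicted, tab$measured), table = tab)
}
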