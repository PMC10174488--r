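combo_doses <- function() c(0, 1.22, 4.88, 19.53, 78.13, 312.5, 1250, 5000) / 1000

# Bliss-consistent surface from separable 4PL marginals: every row and
# column of the result is itself an exact 4PL curve.
bliss_surface <- function(doses_a, doses_b,
                          a = c(0, 0.7, 0.05, 1), b = c(0, 0.6, 0.02, 1.2)) {
  ya <- fourpl_curve(doses_a, a[1], a[2], a[3], a[4])
  yb <- fourpl_curve(doses_b, b[1], b[2], b[3], b[4])
  outer(ya, yb, function(u, v) u + v - u * v)
}

test_that("inhibition is one minus the relative count, including stimulation", {
  expect_equal(inhibition_from_counts(matrix(1)), matrix(0))
  expect_equal(inhibition_from_counts(matrix(0.25)), matrix(0.75))
  expect_equal(inhibition_from_counts(matrix(1.2)), matrix(-0.2))
  g <- dose_grid("a", "b", c(0, 1), c(0, 1),
                 matrix(c(1, 0.5, 0.8, 0.25), 2))
  expect_equal(unname(inhibition_from_counts(g)),
               matrix(c(0, 0.5, 0.2, 0.75), 2))
})

test_that("Bliss independence follows the probabilistic union formula", {
  expect_equal(bliss_independence(0.5, 0.5), 0.75)
  expect_equal(bliss_independence(0, 0.37), 0.37)
  expect_equal(bliss_independence(1, 0.4), 1)
  expect_equal(bliss_independence(c(0.1, 0.2), c(0.3, 0.4)),
               c(0.1 + 0.3 - 0.03, 0.2 + 0.4 - 0.08))
})

test_that("4PL fitting recovers exact curves and handles degenerate rows", {
  doses <- combo_doses()
  y <- fourpl_curve(doses, 0.05, 0.8, 0.02, 1.4)
  fit <- fit_4pl(doses, y, seed = 4)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$e_min, 0.05, tolerance = 1e-3)
  expect_equal(fit$e_max, 0.8, tolerance = 1e-3)
  expect_equal(fit$ec50, 0.02, tolerance = 1e-3)
  expect_equal(fit$hill_n, 1.4, tolerance = 1e-3)
  # fitted value at dose 0 is e_min exactly
  expect_equal(fit$fitted[1], fit$e_min)

  flat <- fit_4pl(doses, rep(0.3, 8), seed = 4)
  expect_true(flat$degenerate)
  expect_equal(flat$fitted, rep(0.3, 8))

  # multi-start best never loses to a single-start fit
  set.seed(99)
  y2 <- y + rnorm(8, 0, 0.05)
  multi <- fit_4pl(doses, y2, seed = 7, n_starts = 12)
  single <- fit_4pl(doses, y2, seed = 8, n_starts = 1)
  expect_lte(multi$sse, single$sse + 1e-12)
})

test_that("averaged row/column surface reproduces separable inputs", {
  da <- combo_doses(); db <- combo_doses()
  y <- bliss_surface(da, db)
  fs <- fitted_surface(y, da, db, seed = 1)
  expect_equal(fs$surface, y, tolerance = 1e-4, ignore_attr = TRUE)
  expect_false(fs$degenerate)
  # cell value is the mean of its row-fit and column-fit estimates
  i <- 3; j <- 5
  expect_equal(fs$surface[i, j],
               (fs$row_fits[[i]]$fitted[j] + fs$col_fits[[j]]$fitted[i]) / 2)
  # symmetric input with identical dose axes gives a symmetric surface
  ys <- bliss_surface(da, da, a = c(0, 0.5, 0.1, 1), b = c(0, 0.5, 0.1, 1))
  fss <- fitted_surface(ys, da, da, seed = 2)
  expect_equal(fss$surface, t(fss$surface), tolerance = 1e-6)
})

test_that("EOB is null on Bliss-consistent surfaces and flags deviations", {
  da <- combo_doses(); db <- combo_doses()
  y <- bliss_surface(da, db)
  fs <- fitted_surface(y, da, db, seed = 3)
  res <- eob_surface(fs$surface, da, db)
  expect_lt(abs(res$mean_eob), 0.01)
  expect_lt(abs(res$mean_eob_nonzero), 0.01)

  # interior shifted +0.1 above Bliss (margins stay single-agent):
  # both-dose cells score ~+0.1, margin cells ~0
  up <- y
  up[-1, -1] <- up[-1, -1] + 0.1
  fs_up <- fitted_surface(up, da, db, seed = 3)
  res_up <- eob_surface(fs_up$surface, da, db)
  expect_lt(abs(res_up$mean_eob_nonzero - 0.1), 0.01)
  expect_lt(max(abs(res_up$eob[1, ])), 0.03)
  expect_lt(max(abs(res_up$eob[, 1])), 0.03)

  # mirror-image deviations from the Bliss null score with mirror-image
  # means: an interaction term c*yA*yB vanishes on the margins and keeps
  # every row and column an exact 4PL, so EOB is exactly +/- c*yA*yB
  ya <- fourpl_curve(da, 0, 0.7, 0.05, 1)
  yb <- fourpl_curve(db, 0, 0.6, 0.02, 1.2)
  bump <- 0.3 * outer(ya, yb)
  res_syn <- eob_surface(fitted_surface(y + bump, da, db, seed = 3)$surface,
                         da, db)
  res_ant <- eob_surface(fitted_surface(y - bump, da, db, seed = 3)$surface,
                         da, db)
  expect_equal(res_syn$eob, bump, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(res_ant$eob, -res_syn$eob, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(res_ant$mean_eob, -res_syn$mean_eob, tolerance = 1e-4)
})

test_that("model-predicted combination surfaces score as mildly antagonistic", {
  # sequential blockade of successive cell-cycle stages leaves fewer cells
  # for the partner drug to act on, so every pair sits just below the
  # Bliss null (negative mean EOB, small magnitude)
  for (cl in c("U87", "U251")) {
    model <- cell_line_model(cl, cached_calibration(cl)$params,
                             builtin_drug_params(cl))
    for (pair in utils::combn(names(model$drugs), 2, simplify = FALSE)) {
      res <- eob_from_grid(predict_grid(model, pair[1], pair[2]), seed = 1)
      expect_lt(res$mean_eob, 0)
      expect_gt(res$mean_eob, -0.15)
    }
  }
})

test_that("grid-level wrapper chains counts to an EOB summary", {
  da <- combo_doses()
  y <- bliss_surface(da, da)
  counts <- 1 - y
  grid <- dose_grid("A", "B", da, da, counts)
  res <- eob_from_grid(grid, seed = 5)
  expect_s3_class(res, "eob_result")
  expect_lt(abs(res$mean_eob), 0.01)
  expect_equal(dim(res$eob), c(8, 8))
  # deterministic given the seed
  res2 <- eob_from_grid(grid, seed = 5)
  expect_identical(res$mean_eob, res2$mean_eob)
})
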