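#' Stochastic integer-count simulation of the cell-state network
#'
#' Sampling counterpart of the deterministic engine for well-level noise:
#' each hour every cell independently stays, transitions, or dies with
#' probabilities `(1 - mi - phii, mi, phii)` (a multinomial split per
#' state), and each transitioning G2/M cell contributes two daughters to
#' G0/G1. Averaged over seeds this reproduces [simulate_population()].
#'
#' @param params a [transition_params()].
#' @param death a [death_rates()].
#' @param x0 length-3 vector of nonnegative integer counts.
#' @param horizon horizon in hours (default 72).
#' @param seed optional integer seed (set before sampling).
#' @return A list: `trajectory` (integer matrix, `horizon + 1` rows),
#'   `final` (length-3 counts), `total` (final live total), `dead`
#'   (cumulative death count).
#' @export
stochastic_simulate <- function(params, death = death_rates(), x0,
                                horizon = 72L, seed = NULL) {
  check_rates(params, death)
  stopifnot(length(x0) == 3, all(x0 >= 0), all(x0 == round(x0)))
  if (!is.null(seed)) set.seed(seed)
  m <- unlist(params[c("m1", "m2", "m3")])
  phi <- unlist(death[c("phi1", "phi2", "phi3")])
  x <- as.integer(round(x0))
  traj <- matrix(0L, nrow = horizon + 1L, ncol = 3,
                 dimnames = list(NULL, STATE_NAMES))
  traj[1L, ] <- x
  dead <- 0L
  for (t in seq_len(horizon)) {
    moved <- integer(3); stayed <- integer(3)
    for (i in 1:3) {
      if (x[i] == 0L) next
      draw <- stats::rmultinom(1, x[i], c(1 - m[i] - phi[i], m[i], phi[i]))
      stayed[i] <- draw[1L]; moved[i] <- draw[2L]; dead <- dead + draw[3L]
    }
    x <- c(stayed[1] + DIVISION_FACTOR * moved[3],
           stayed[2] + moved[1],
           stayed[3] + moved[2])
    traj[t + 1L, ] <- x
  }
  list(trajectory = traj, final = x, total = sum(x), dead = dead)
}

#' Specification of a synthetic 96-well plate
#'
#' Describes one plate layout generated from a ground-truth
#' [cell_line_model()]: either the single-drug layout (10 dose levels
#' including vehicle control, biological duplicate x technical triplicate)
#' or the 8x8 combination checkerboard (biological triplicate). Wells seed
#' 500 cells, grow 72 h, then live cells are counted as total-stain
#' (Hoechst) minus dead-stain (propidium iodide) nuclei. The noise model:
#' each nucleus is detected independently with probability `detect_p`,
#' both stain counts are scaled by a common mean-1 lognormal per-well
#' factor with coefficient of variation `noise_cv`, and only a fraction
#' `dead_retain` of cumulatively dead cells is still present to stain.
#'
#' @param model ground-truth [cell_line_model()].
#' @param layout `"single_drug"` or `"combination"`.
#' @param drug_a drug name (single-drug layout: the assayed drug).
#' @param drug_b second drug (combination layout).
#' @param doses_a,doses_b dose vectors in uM; default to [default_doses()].
#' @param seeded_cells integer cells per well (default 500).
#' @param detect_p per-nucleus detection probability (default 0.95).
#' @param noise_cv coefficient of variation of the multiplicative per-well
#'   factor (default 0.1).
#' @param dead_retain fraction of dead cells still stainable (default 0.5).
#' @param n_bio,n_tech biological / technical replicate counts (defaults:
#'   2 x 3 for single-drug, 3 x 1 for combination).
#' @param seed mandatory integer seed; every well's stream is derived
#'   from it.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(model, layout = c("single_drug", "combination"),
                       drug_a, drug_b = NULL, doses_a = NULL, doses_b = NULL,
                       seeded_cells = 500L, detect_p = 0.95, noise_cv = 0.1,
                       dead_retain = 0.5, n_bio = NULL, n_tech = NULL,
                       seed) {
  layout <- match.arg(layout)
  stopifnot(inherits(model, "cell_line_model"),
            drug_a %in% names(model$drugs))
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for plate generation", call. = FALSE)
  if (layout == "combination") {
    stopifnot(!is.null(drug_b), drug_b %in% names(model$drugs))
    if (is.null(doses_a)) doses_a <- default_doses(drug_a, "combination")
    if (is.null(doses_b)) doses_b <- default_doses(drug_b, "combination")
    if (is.null(n_bio)) n_bio <- 3L
    if (is.null(n_tech)) n_tech <- 1L
  } else {
    if (is.null(doses_a)) doses_a <- default_doses(drug_a, "single")
    if (is.null(n_bio)) n_bio <- 2L
    if (is.null(n_tech)) n_tech <- 3L
  }
  structure(list(model = model, layout = layout, drug_a = drug_a,
                 drug_b = drug_b, doses_a = doses_a, doses_b = doses_b,
                 seeded_cells = as.integer(seeded_cells),
                 detect_p = detect_p, noise_cv = noise_cv,
                 dead_retain = dead_retain, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), seed = as.integer(seed)),
            class = "plate_spec")
}

# Deterministic per-well seed derivation: all randomness flows from the
# spec seed through the well's linear index (documented contract).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 104729) %% 2147483647)
}

simulate_well <- function(spec, doses, well_seed) {
  set.seed(well_seed)
  props <- stationary_composition(spec$model)
  x0 <- drop(stats::rmultinom(1, spec$seeded_cells, props))
  eff <- effective_rates(spec$model, doses)
  sim <- stochastic_simulate(eff$params, eff$death, x0, horizon = 72L)
  dead_retained <- stats::rbinom(1, sim$dead, spec$dead_retain)
  detected_live <- stats::rbinom(1, sim$total, spec$detect_p)
  detected_dead <- stats::rbinom(1, dead_retained, spec$detect_p)
  # mean-1 lognormal well factor scales both stains identically, so the
  # dead-count never exceeds the total-count after rounding
  f <- if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else 1
  c(hoechst = round((detected_live + detected_dead) * f),
    pi = round(detected_dead * f))
}

#' Generate a synthetic plate of well records
#'
#' Runs [stochastic_simulate()] for every well of the layout under its
#' dose assignment and applies the counting-noise model of [plate_spec()].
#' Identical specs (including seed) produce byte-identical tables.
#'
#' @param spec a [plate_spec()].
#' @return A `data.frame` with one row per well: `well`, `cell_line`,
#'   `drug_a`, `dose_a_uM`, `drug_b`, `dose_b_uM`, `bio_rep`, `tech_rep`,
#'   `replicate_id`, `hoechst_count`, `pi_count`, `live_count`
#'   (= hoechst - pi).
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  if (spec$layout == "single_drug") {
    design <- expand.grid(dose_a_uM = spec$doses_a, dose_b_uM = NA_real_,
                          bio_rep = seq_len(spec$n_bio),
                          tech_rep = seq_len(spec$n_tech))
  } else {
    design <- expand.grid(dose_a_uM = spec$doses_a, dose_b_uM = spec$doses_b,
                          bio_rep = seq_len(spec$n_bio),
                          tech_rep = seq_len(spec$n_tech))
  }
  n <- nrow(design)
  hoechst <- integer(n); pi_cnt <- integer(n)
  for (k in seq_len(n)) {
    doses <- stats::setNames(design$dose_a_uM[k], spec$drug_a)
    if (spec$layout == "combination")
      doses <- c(doses, stats::setNames(design$dose_b_uM[k], spec$drug_b))
    counts <- simulate_well(spec, doses, derive_seed(spec$seed, k))
    hoechst[k] <- counts["hoechst"]; pi_cnt[k] <- counts["pi"]
  }
  data.frame(well = sprintf("W%03d", seq_len(n)),
             cell_line = spec$model$cell_line,
             drug_a = spec$drug_a, dose_a_uM = design$dose_a_uM,
             drug_b = if (is.null(spec$drug_b)) NA_character_ else spec$drug_b,
             dose_b_uM = design$dose_b_uM,
             bio_rep = design$bio_rep, tech_rep = design$tech_rep,
             replicate_id = sprintf("b%dt%d", design$bio_rep, design$tech_rep),
             hoechst_count = hoechst, pi_count = pi_cnt,
             live_count = hoechst - pi_cnt,
             stringsAsFactors = FALSE)
}

#' Summarise a single-drug plate into dose-response data
#'
#' Live counts are normalised to the mean vehicle-control live count of
#' the same biological replicate, then averaged per dose.
#'
#' @param plate a [generate_plate()] table (or CSV read back).
#' @return A [dose_response_data()].
#' @export
plate_to_dose_response <- function(plate) {
  stopifnot(all(c("dose_a_uM", "bio_rep", "live_count") %in% names(plate)))
  rel <- rep(NA_real_, nrow(plate))
  for (b in unique(plate$bio_rep)) {
    sel <- plate$bio_rep == b
    ctrl <- mean(plate$live_count[sel & plate$dose_a_uM == 0])
    if (!is.finite(ctrl) || ctrl <= 0)
      stop("no usable vehicle-control wells in biological replicate ", b,
           call. = FALSE)
    rel[sel] <- plate$live_count[sel] / ctrl
  }
  agg <- stats::aggregate(rel, list(dose = plate$dose_a_uM),
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  doses <- agg$dose
  mm <- agg$x[, "mean"]; ss <- agg$x[, "sd"]; nn <- agg$x[, "n"]
  dose_response_data(drug = plate$drug_a[1], cell_line = plate$cell_line[1],
                     doses = doses, mean_counts = mm, sd = ss,
                     se = ss / sqrt(nn),
                     replicates = data.frame(dose_uM = plate$dose_a_uM,
                                             replicate_id = plate$replicate_id,
                                             relative_count = rel))
}

#' Summarise a combination plate into a dose grid
#'
#' Per biological replicate, live counts are normalised to that
#' replicate's (0, 0) vehicle well, then averaged across replicates per
#' dose pair.
#'
#' @param plate a combination-layout [generate_plate()] table.
#' @return A measured [dose_grid()] with per-cell standard errors.
#' @export
plate_to_dose_grid <- function(plate) {
  stopifnot(all(c("dose_a_uM", "dose_b_uM", "bio_rep", "live_count")
                %in% names(plate)))
  doses_a <- sort(unique(plate$dose_a_uM))
  doses_b <- sort(unique(plate$dose_b_uM))
  bios <- unique(plate$bio_rep)
  arr <- array(NA_real_, c(length(doses_a), length(doses_b), length(bios)))
  for (bi in seq_along(bios)) {
    sel <- plate$bio_rep == bios[bi]
    ctrl <- mean(plate$live_count[sel & plate$dose_a_uM == 0 &
                                    plate$dose_b_uM == 0])
    for (i in seq_along(doses_a))
      for (j in seq_along(doses_b)) {
        w <- sel & plate$dose_a_uM == doses_a[i] & plate$dose_b_uM == doses_b[j]
        arr[i, j, bi] <- mean(plate$live_count[w]) / ctrl
      }
  }
  vals <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(length(bios))
  dose_grid(plate$drug_a[1], plate$drug_b[1], doses_a, doses_b, vals,
            se = se, cell_line = plate$cell_line[1])
}

#' One-call reproducible end-to-end synthetic fixture
#'
#' Builds a complete synthetic study for one cell line: growth calibration
#' from the built-in constraints, a ground-truth model carrying the
#' built-in drug parameters, three single-drug plates (one per drug) and
#' the three pairwise 8x8 combination plates, all generated from seeds
#' derived from `seed`.
#'
#' @param seed integer master seed.
#' @param cell_line `"U87"` (default) or `"U251"`.
#' @param noise_cv,detect_p noise settings passed to [plate_spec()].
#' @return A list: `constraints`, `calibration`, `truth` (the ground-truth
#'   [cell_line_model()]), `single_plates` (named by drug),
#'   `combo_plates` (named `"A|B"`), `seed`.
#' @export
end_to_end_fixture <- function(seed, cell_line = "U87", noise_cv = 0.1,
                               detect_p = 0.95) {
  constraints <- builtin_constraints(cell_line)
  calib <- fit_transition_params(constraints, seed = derive_seed(seed, 1L))
  truth <- cell_line_model(cell_line, calib$params,
                           builtin_drug_params(cell_line))
  drugs <- names(truth$drugs)
  single_plates <- stats::setNames(lapply(seq_along(drugs), function(i)
    generate_plate(plate_spec(truth, "single_drug", drugs[i],
                              noise_cv = noise_cv, detect_p = detect_p,
                              seed = derive_seed(seed, 10L + i)))), drugs)
  pairs <- utils::combn(drugs, 2, simplify = FALSE)
  combo_plates <- stats::setNames(lapply(seq_along(pairs), function(i)
    generate_plate(plate_spec(truth, "combination", pairs[[i]][1],
                              pairs[[i]][2], noise_cv = noise_cv,
                              detect_p = detect_p,
                              seed = derive_seed(seed, 20L + i)))),
    vapply(pairs, paste, "", collapse = "|"))
  list(constraints = constraints, calibration = calib, truth = truth,
       single_plates = single_plates, combo_plates = combo_plates,
       seed = seed)
}
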