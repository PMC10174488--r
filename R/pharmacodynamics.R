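#' Dose-response parameters of one drug on one cell line
#'
#' Each drug acts on exactly one cell-cycle transition: it inhibits the
#' hourly transition probability of its target state through a Hill
#' function (parameters `ec50`, `hill_n`) and induces death from that state
#' through a saturating hyperbola (parameters `emax_phi`, `ec50_phi`; Hill
#' coefficient fixed at 1).
#'
#' @param name drug label.
#' @param target_state index of the targeted state (1 = G0/G1,
#'   2 = lateG1/S, 3 = G2/M).
#' @param ec50 half-maximal transition-inhibition dose, uM (> 0).
#' @param hill_n Hill coefficient of the inhibition curve (> 0).
#' @param emax_phi maximal drug-induced death probability per hour, in
#'   \[0, 1\].
#' @param ec50_phi half-maximal death dose, uM (> 0).
#' @return An object of class `drug_params`.
#' @examples
#' drug_params("PD0325901", 1, ec50 = 0.10, hill_n = 0.50,
#'             emax_phi = 0.011, ec50_phi = 0.40)
#' @export
drug_params <- function(name, target_state, ec50, hill_n,
                        emax_phi = 0, ec50_phi = 1) {
  stopifnot(target_state %in% 1:3, ec50 > 0, hill_n > 0,
            emax_phi >= 0, emax_phi <= 1, ec50_phi > 0)
  structure(list(name = name, target_state = as.integer(target_state),
                 ec50 = ec50, hill_n = hill_n,
                 emax_phi = emax_phi, ec50_phi = ec50_phi),
            class = "drug_params")
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf(
    "%s (state %d): EC50 = %.4g uM, n = %.3g, Emax_phi = %.3g /h, EC50_phi = %.4g uM\n",
    x$name, x$target_state, x$ec50, x$hill_n, x$emax_phi, x$ec50_phi))
  invisible(x)
}

#' Cell-line model: calibrated base network plus drug actions
#'
#' @param cell_line label.
#' @param base calibrated no-drug [transition_params()].
#' @param drugs list of [drug_params()]; at most one drug per target state.
#' @return An object of class `cell_line_model`.
#' @export
cell_line_model <- function(cell_line, base, drugs = list()) {
  stopifnot(inherits(base, "transition_params"))
  if (inherits(drugs, "drug_params")) drugs <- list(drugs)
  stopifnot(all(vapply(drugs, inherits, TRUE, "drug_params")))
  targets <- vapply(drugs, `[[`, 1L, "target_state")
  if (anyDuplicated(targets))
    stop("at most one drug may target each cell-cycle state", call. = FALSE)
  names(drugs) <- vapply(drugs, `[[`, "", "name")
  structure(list(cell_line = cell_line, base = base, drugs = drugs),
            class = "cell_line_model")
}

#' Hill inhibition of a transition probability
#'
#' `m_base * (1 - (D/EC50)^n / (1 + (D/EC50)^n))`: equal to `m_base` at
#' dose 0, half of it at `D = EC50`, and decreasing towards 0 as the dose
#' grows.
#'
#' @param m_base drug-free transition probability per hour.
#' @param dose dose in uM (vectorised).
#' @param ec50 half-maximal dose, uM.
#' @param hill_n Hill coefficient.
#' @return Effective transition probability, same length as `dose`.
#' @export
transition_inhibition <- function(m_base, dose, ec50, hill_n) {
  stopifnot(all(dose >= 0))
  h <- (dose / ec50)^hill_n
  m_base * (1 - h / (1 + h))
}

#' Drug-induced death probability
#'
#' Saturating hyperbola `emax_phi * (D/EC50_phi) / (1 + D/EC50_phi)`
#' (Hill coefficient 1): zero at dose 0, half-maximal at `D = EC50_phi`,
#' approaching `emax_phi` at high dose.
#'
#' @param dose dose in uM (vectorised).
#' @param emax_phi maximal death probability per hour.
#' @param ec50_phi half-maximal death dose, uM.
#' @return Death probability per hour, same length as `dose`.
#' @export
death_rate <- function(dose, emax_phi, ec50_phi) {
  stopifnot(all(dose >= 0))
  r <- dose / ec50_phi
  emax_phi * r / (1 + r)
}

#' Effective hourly rates under a dose assignment
#'
#' Maps a named dose vector onto the network: for each state targeted by a
#' drug with a positive dose, the transition probability is Hill-inhibited
#' and the death probability set by that drug's death term; untargeted
#' states keep their base rates and zero death.
#'
#' @param model a [cell_line_model()].
#' @param doses named numeric vector, drug name -> dose in uM; absent
#'   drugs are dose 0.
#' @return A list with elements `params` ([transition_params()]) and
#'   `death` ([death_rates()]).
#' @export
effective_rates <- function(model, doses = numeric()) {
  stopifnot(inherits(model, "cell_line_model"))
  if (length(doses)) {
    stopifnot(!is.null(names(doses)), all(doses >= 0))
    unknown <- setdiff(names(doses), names(model$drugs))
    if (length(unknown))
      stop("dose given for drug(s) not in model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- c(model$base$m1, model$base$m2, model$base$m3)
  phi <- c(0, 0, 0)
  for (d in model$drugs) {
    dose <- if (d$name %in% names(doses)) doses[[d$name]] else 0
    i <- d$target_state
    m[i] <- transition_inhibition(m[i], dose, d$ec50, d$hill_n)
    phi[i] <- death_rate(dose, d$emax_phi, d$ec50_phi)
  }
  if (any(m + phi > 1))
    stop("mi + phii > 1 under this dose assignment; check drug parameters",
         call. = FALSE)
  list(params = transition_params(m[1], m[2], m[3]),
       death = death_rates(phi[1], phi[2], phi[3]))
}

#' Stationary no-drug composition of a cell-line model
#'
#' @param model a [cell_line_model()].
#' @return Length-3 vector of stationary state fractions.
#' @export
stationary_composition <- function(model) {
  growth_eigensystem(model$base)$proportions
}

#' Relative live-cell count under a dose assignment
#'
#' Treated-over-control total cell count after `horizon` hours, both
#' simulations starting from the no-drug stationary composition (the drug
#' is added after the cells settle overnight into balanced growth). By
#' linearity of the update, the initial total cancels in the ratio.
#'
#' @param model a [cell_line_model()].
#' @param doses named numeric vector of doses in uM.
#' @param horizon horizon in hours (default 72).
#' @return A single fraction; exactly 1 at all-zero doses.
#' @examples
#' base <- transition_params(0.05, 0.11, 0.14)
#' pd <- drug_params("PD0325901", 1, 0.10, 0.50, 0.011, 0.40)
#' m <- cell_line_model("U87", base, list(pd))
#' relative_cell_count(m, c(PD0325901 = 0.1))
#' @export
relative_cell_count <- function(model, doses = numeric(), horizon = 72L) {
  x0 <- population_state_from_vector(100 * stationary_composition(model), 0L)
  eff <- effective_rates(model, doses)
  treated <- simulate_population(eff$params, eff$death, x0, horizon)
  control <- simulate_population(model$base, death_rates(), x0, horizon)
  treated$total[horizon + 1L] / control$total[horizon + 1L]
}

#' Single-drug dose-response curve predicted by the model
#'
#' @param model a [cell_line_model()].
#' @param drug drug name present in the model.
#' @param doses numeric vector of doses in uM.
#' @param horizon horizon in hours.
#' @return Numeric vector of predicted relative cell counts.
#' @export
predict_single_drug <- function(model, drug, doses, horizon = 72L) {
  stopifnot(drug %in% names(model$drugs))
  vapply(doses, function(d)
    relative_cell_count(model, stats::setNames(d, drug), horizon), 0)
}

#' Built-in fitted drug parameters
#'
#' Best-fit dose-response parameters for PD0325901 (MEK1/2 inhibitor,
#' targeting G0/G1 exit), Abemaciclib (CDK4/6 inhibitor, lateG1/S exit) and
#' TAK-960 (PLK1 inhibitor, G2/M exit) on U87 and U251 cells, shipped as a
#' package fixture.
#'
#' @param cell_line optional filter (`"U87"` or `"U251"`).
#' @param as_list if TRUE (default) return a list of [drug_params()];
#'   otherwise the raw `data.frame`.
#' @export
builtin_drug_params <- function(cell_line = NULL, as_list = TRUE) {
  tab <- utils::read.csv(system.file("extdata", "drug_params.csv",
                                     package = "cyclecombo"),
                         stringsAsFactors = FALSE)
  if (!is.null(cell_line)) tab <- tab[tab$cell_line == cell_line, ]
  if (!as_list) return(tab)
  lapply(seq_len(nrow(tab)), function(i)
    drug_params(tab$drug[i], tab$target_state[i], tab$ec50_uM[i],
                tab$hill_n[i], tab$emax_phi_per_h[i], tab$ec50_phi_uM[i]))
}

#' Default experimental dose series
#'
#' `single`: 0 plus nine 3.16-fold dilutions from 0.001 to 10 uM (the
#' single-drug assay series). `combination`: the 8-point 4-fold series used
#' in the 8x8 checkerboards — 0 to 5 uM for PD0325901/Abemaciclib and 0 to
#' 0.05 uM for TAK-960.
#'
#' @param drug drug name (only relevant for `layout = "combination"`).
#' @param layout `"single"` or `"combination"`.
#' @return Numeric dose vector in uM, ascending, starting at 0.
#' @export
default_doses <- function(drug = "PD0325901", layout = c("single", "combination")) {
  layout <- match.arg(layout)
  if (layout == "single")
    return(c(0, 10^seq(-3, 1, by = 0.5)))
  if (drug == "TAK-960")
    c(0, 0.012, 0.049, 0.20, 0.78, 3.13, 12.5, 50) / 1000
  else
    c(0, 1.22, 4.88, 19.53, 78.13, 312.5, 1250, 5000) / 1000
}
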