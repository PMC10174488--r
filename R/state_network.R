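#' @keywords internal
"_PACKAGE"

# Cell-cycle state indices used throughout: 1 = G0/G1, 2 = lateG1/S, 3 = G2/M.
# A cell leaving G2/M divides, contributing two daughters to G0/G1.
DIVISION_FACTOR <- 2
STATE_NAMES <- c("g0g1", "lateg1s", "g2m")

#' Hourly transition probabilities of the three-state cell-cycle network
#'
#' The network is a directed cycle G0/G1 -> lateG1/S -> G2/M -> G0/G1 in
#' which the last edge carries cell division (one mother in G2/M yields two
#' daughters in G0/G1). `m1`, `m2`, `m3` are the proportions of cells taking
#' each edge per one-hour step; the complement `1 - mi` stays put.
#'
#' @param m1 probability per hour of the G0/G1 -> lateG1/S transition.
#' @param m2 probability per hour of the lateG1/S -> G2/M transition.
#' @param m3 probability per hour of the G2/M -> G0/G1 (division) transition.
#' @return An object of class `transition_params`.
#' @examples
#' transition_params(0.05, 0.11, 0.14)
#' @export
transition_params <- function(m1, m2, m3) {
  m <- c(m1 = unname(m1), m2 = unname(m2), m3 = unname(m3))
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  structure(as.list(m), class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat(sprintf("Hourly transition probabilities: M1 = %.4g, M2 = %.4g, M3 = %.4g\n",
              x$m1, x$m2, x$m3))
  invisible(x)
}

#' Per-state hourly death probabilities
#'
#' Death removes cells permanently from the live population. Paired with a
#' `transition_params` object, the retained fraction of state i each hour is
#' `1 - mi - phii`, which must remain nonnegative.
#'
#' @param phi1,phi2,phi3 probability per hour of death from each state.
#' @return An object of class `death_rates`.
#' @export
death_rates <- function(phi1 = 0, phi2 = 0, phi3 = 0) {
  phi <- c(phi1 = unname(phi1), phi2 = unname(phi2), phi3 = unname(phi3))
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("death probabilities must lie in [0, 1]", call. = FALSE)
  structure(as.list(phi), class = "death_rates")
}

check_rates <- function(params, death) {
  m <- unlist(params[c("m1", "m2", "m3")])
  phi <- unlist(death[c("phi1", "phi2", "phi3")])
  if (any(m + phi > 1 + 1e-12))
    stop("mi + phii exceeds 1 for state ", which(m + phi > 1 + 1e-12)[1],
         ": retained fraction would be negative", call. = FALSE)
  invisible(TRUE)
}

#' Population counts per cell-cycle state
#'
#' @param x1,x2,x3 nonnegative (real-valued) cell counts in G0/G1, lateG1/S
#'   and G2/M.
#' @param t integer time in hours.
#' @return An object of class `population_state`.
#' @export
population_state <- function(x1, x2, x3, t = 0L) {
  x <- c(x1, x2, x3)
  if (any(!is.finite(x)) || any(x < 0))
    stop("cell counts must be finite and nonnegative", call. = FALSE)
  structure(list(x = unname(x), t = as.integer(t)), class = "population_state")
}

#' Hourly population update matrix
#'
#' Builds the 3x3 linear map `A` such that `x_{t+1} = A x_t` under the
#' mean-field update: state i retains `(1 - mi - phii)` of its cells and
#' receives the inflow from its upstream state, with the G2/M -> G0/G1 edge
#' multiplied by the division factor 2.
#'
#' @inheritParams simulate_population
#' @return A 3x3 numeric matrix.
#' @export
update_matrix <- function(params, death = death_rates()) {
  check_rates(params, death)
  m <- unlist(params[c("m1", "m2", "m3")])
  phi <- unlist(death[c("phi1", "phi2", "phi3")])
  matrix(c(1 - m[1] - phi[1], 0,                 DIVISION_FACTOR * m[3],
           m[1],              1 - m[2] - phi[2], 0,
           0,                 m[2],              1 - m[3] - phi[3]),
         nrow = 3, byrow = TRUE,
         dimnames = list(STATE_NAMES, STATE_NAMES))
}

#' Advance the population by one hour
#'
#' @param state a [population_state()].
#' @param params a [transition_params()].
#' @param death a [death_rates()] (defaults to no death).
#' @return The updated `population_state` at `t + 1`.
#' @export
step_population <- function(state, params, death = death_rates()) {
  stopifnot(inherits(state, "population_state"))
  A <- update_matrix(params, death)
  population_state_from_vector(drop(A %*% state$x), state$t + 1L)
}

population_state_from_vector <- function(x, t) {
  structure(list(x = pmax(unname(x), 0), t = as.integer(t)),
            class = "population_state")
}

#' Simulate the deterministic population trajectory
#'
#' Propagates expected (real-valued) state counts hourly for `horizon`
#' hours. The update is linear, so trajectories scale with the initial
#' total: relative quantities are independent of seeding number.
#'
#' @param params a [transition_params()].
#' @param death a [death_rates()].
#' @param x0 a [population_state()] giving the initial composition.
#' @param horizon nonnegative integer horizon in hours (default 72, the
#'   endpoint of the viability assay the model describes).
#' @return A `data.frame` of class `trajectory` with columns `time_h`,
#'   `x_g0g1`, `x_lateg1s`, `x_g2m`, `total`, `p_g0g1`, `p_lateg1s`, `p_g2m`.
#' @examples
#' p <- transition_params(0.05, 0.11, 0.14)
#' traj <- simulate_population(p, x0 = population_state(60.2, 23.5, 16.3))
#' tail(traj, 1)
#' @export
simulate_population <- function(params, death = death_rates(), x0,
                                horizon = 72L) {
  stopifnot(inherits(x0, "population_state"))
  if (length(horizon) != 1 || horizon < 0 || horizon != round(horizon))
    stop("horizon must be a nonnegative integer number of hours", call. = FALSE)
  horizon <- as.integer(horizon)
  A <- update_matrix(params, death)
  out <- matrix(NA_real_, nrow = horizon + 1L, ncol = 3)
  x <- x0$x
  out[1L, ] <- x
  if (horizon > 0) {
    for (k in seq_len(horizon)) {
      x <- drop(A %*% x)
      out[k + 1L, ] <- x
    }
  }
  total <- rowSums(out)
  props <- out / ifelse(total > 0, total, NA_real_)
  traj <- data.frame(time_h = seq.int(0L, horizon) + x0$t,
                     x_g0g1 = out[, 1], x_lateg1s = out[, 2], x_g2m = out[, 3],
                     total = total,
                     p_g0g1 = props[, 1], p_lateg1s = props[, 2],
                     p_g2m = props[, 3])
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Write a trajectory to tidy CSV
#'
#' @param traj a trajectory from [simulate_population()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Asymptotic growth factor and stationary composition
#'
#' Closed-form counterpart of long simulation: the dominant eigenvalue of
#' the hourly update matrix is the per-hour population growth factor during
#' balanced exponential growth, and the associated right eigenvector
#' (normalised to sum 1) is the stationary distribution of cells over the
#' three cell-cycle states.
#'
#' @inheritParams simulate_population
#' @return A list with `growth_factor` (dominant eigenvalue) and
#'   `proportions` (length-3 nonnegative vector summing to 1).
#' @export
growth_eigensystem <- function(params, death = death_rates()) {
  A <- update_matrix(params, death)
  e <- eigen(A)
  # Perron root of a nonnegative matrix: the spectral radius is attained at
  # a real nonnegative eigenvalue with a sign-constant eigenvector.
  mod <- Mod(e$values)
  # several eigenvalues can share the spectral radius (e.g. the rigid
  # cycle m = (1,1,1)); the Perron root is the real nonnegative one
  cand <- which(mod > max(mod) * (1 - 1e-9))
  i <- cand[which.max(Re(e$values[cand]))]
  lambda <- Re(e$values[i])
  v <- Re(e$vectors[, i])
  v <- abs(v)
  s <- sum(v)
  v <- if (s > 0) v / s else rep(1 / 3, 3)
  names(v) <- STATE_NAMES
  list(growth_factor = lambda, proportions = v)
}

#' Population doubling time from an hourly growth factor
#'
#' @param growth_factor per-hour multiplicative growth factor (dominant
#'   eigenvalue of the update matrix).
#' @return Doubling time in hours: `log(2) / log(growth_factor)`. A
#'   non-growing population (factor <= 1) returns `Inf`.
#' @export
doubling_time <- function(growth_factor) {
  stopifnot(is.numeric(growth_factor), length(growth_factor) == 1)
  if (growth_factor <= 1) return(Inf)
  log(2) / log(growth_factor)
}
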