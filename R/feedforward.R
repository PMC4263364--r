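#' Parameters of the four-state equilibrium feedforward sensor
#'
#' A minimal adaptive sensor with binary activity `a` and binary memory
#' `m`, driven by a binary signal through a mutually-repressive feedforward
#' motif. It is built backwards from its target steady states: the memory
#' tracks the signal up to the memory error `eps_m`, the adapted activity
#' sits at `abar` up to the adaptation error `eps_a`, and the non-adapted
#' (pre-adaptation) activity tracks the signal up to the gain error
#' `eps_g`. Detailed balance plus two bare rates (`omega_a` fast,
#' `omega_m` slow) then fix the kinetics.
#'
#' @param eps_a adaptation error, in (0, 1/2).
#' @param eps_m memory error, in (0, 1/2).
#' @param eps_g gain error, in (0, 1/2).
#' @param abar adapted activity level, in (0, 1); default 1/2.
#' @param omega_a bare activity flip rate (1/time).
#' @param omega_m bare memory flip rate; well-separated time-scales need
#'   `omega_m / omega_a << 1` (warning above 0.1).
#' @param prior,kernel signal prior `P(l0)` and switch kernel `P(l1 | l0)`
#'   for the bundled protocol; default uniform and independent.
#' @return object of class `feedforward_params`.
#' @export
feedforward_params <- function(eps_a = 0.01, eps_m = 0.01, eps_g = 0.01,
                               abar = 0.5, omega_a = 1, omega_m = 1e-2,
                               prior = c(0.5, 0.5),
                               kernel = matrix(0.5, 2, 2)) {
  for (nmv in list(c("eps_a", eps_a), c("eps_m", eps_m), c("eps_g", eps_g))) {
    v <- as.numeric(nmv[2])
    if (!(v > 0 && v < 0.5)) {
      stop(sprintf("%s must lie strictly between 0 and 1/2", nmv[1]))
    }
  }
  if (!(abar > 0 && abar < 1)) stop("abar must lie in (0, 1)")
  if (abar + eps_a >= 1 || abar - eps_a <= 0) {
    stop("abar +/- eps_a must stay inside (0, 1)")
  }
  stopifnot(omega_a > 0, omega_m > 0)
  if (omega_m / omega_a > 0.1) {
    warning("omega_m / omega_a > 0.1: time-scale separation is weak")
  }
  structure(
    list(eps_a = eps_a, eps_m = eps_m, eps_g = eps_g, abar = abar,
         omega_a = omega_a, omega_m = omega_m,
         protocol = signal_protocol(c(0, 1), prior, kernel)),
    class = "feedforward_params"
  )
}

# state ordering used throughout: (a, m) = (0,0), (1,0), (0,1), (1,1)
.ff_space <- function() state_space(expand.grid(a = 0:1, m = 0:1))

#' Target steady states of the feedforward sensor
#'
#' For each signal `l` in `{0, 1}`:
#' `p(m = l | l) = 1 - eps_m`; on the adapted branch (`m = l`)
#' `p(a = 1 | m, l) = abar + (2 l - 1) eps_a`; on the non-adapted branch
#' (`m != l`) `p(a = l | m, l) = 1 - eps_g`. With `abar = 1/2` the mirror
#' symmetry `p(a, m | l) = p(1 - a, 1 - m | 1 - l)` is exact.
#'
#' @param params a [feedforward_params()].
#' @return `4 x 2` matrix of steady-state probabilities, columns named
#'   `"0"`, `"1"`, rows ordered as `(a, m)` = (0,0), (1,0), (0,1), (1,1).
#' @export
construct_steady_states <- function(params) {
  stopifnot(inherits(params, "feedforward_params"))
  sp <- .ff_space()
  av <- sp$coords$a
  mv <- sp$coords$m
  out <- matrix(NA_real_, 4, 2, dimnames = list(sp$labels, c("0", "1")))
  for (l in 0:1) {
    pm <- ifelse(mv == l, 1 - params$eps_m, params$eps_m)
    pa1 <- ifelse(
      mv == l,
      params$abar + (2 * l - 1) * params$eps_a,
      if (l == 1) 1 - params$eps_g else params$eps_g
    )
    pa <- ifelse(av == 1, pa1, 1 - pa1)
    out[, l + 1] <- pm * pa
  }
  out
}

#' Energy landscape from the target steady states
#'
#' Boltzmann inversion `E(a, m; l) = -log p_ss(a, m | l) + const` (kT,
#' `beta = 1`), with the reference chosen per signal so the most probable
#' (adapted) state has `E = 0`. For small errors the landscape reduces to
#' the coarse structure: a penalty `log((1 - eps_m)/eps_m)` for the memory
#' to mistrack the signal and an extra `log((1 - eps_g)/eps_g)` for the
#' activity to mistrack it while the memory is wrong.
#'
#' @inheritParams construct_steady_states
#' @return `4 x 2` energy matrix (kT).
#' @export
energies_from_steady_state <- function(params) {
  pss <- construct_steady_states(params)
  if (any(pss <= 0)) stop("zero-probability state: energies diverge")
  e <- -log(pss)
  sweep(e, 2L, apply(e, 2L, min), `-`)
}

#' Build the feedforward rate model
#'
#' Single-coordinate flips only; the symmetric local-detailed-balance
#' parameterization `W(x -> x') = omega * exp(-(E(x') - E(x)) / 2)` with
#' `omega = omega_a` for activity flips and `omega_m` for memory flips.
#' The model is detailed balanced by construction and its stationary
#' states reproduce [construct_steady_states()].
#'
#' @inheritParams construct_steady_states
#' @return a [rate_model()] with signals `"0"` and `"1"`.
#' @export
build_rates <- function(params) {
  stopifnot(inherits(params, "feedforward_params"))
  sp <- .ff_space()
  e <- energies_from_steady_state(params)
  av <- sp$coords$a
  mv <- sp$coords$m
  W <- list()
  for (l in 0:1) {
    w <- matrix(0, 4, 4)
    for (j in 1:4) {
      for (i in 1:4) {
        if (i == j) next
        da <- av[i] != av[j]
        dm <- mv[i] != mv[j]
        if (da + dm != 1L) next # no diagonal (double-flip) transitions
        omega <- if (da) params$omega_a else params$omega_m
        w[i, j] <- omega * exp(-(e[i, l + 1] - e[j, l + 1]) / 2)
      }
    }
    W[[as.character(l)]] <- w
  }
  rate_model(sp, W, energy = e)
}

#' Recover the error parameters from a built model
#'
#' Round-trip check: re-measures `eps_m`, `eps_a`, `eps_g` from the
#' stationary states of the rate model.
#'
#' @param model a feedforward [rate_model()].
#' @param abar adapted activity level the model was built with.
#' @return named vector `eps_m`, `eps_a`, `eps_g` (from the `l = 1` state;
#'   the `l = 0` state gives the mirror values).
#' @export
measure_errors <- function(model, abar = 0.5) {
  av <- coord_values(model$space, "a")
  mv <- coord_values(model$space, "m")
  p1 <- stationary_distribution(model, "1")
  eps_m <- sum(p1[mv == 0])
  p_a1_m1 <- sum(p1[av == 1 & mv == 1]) / sum(p1[mv == 1])
  p_a1_m0 <- sum(p1[av == 1 & mv == 0]) / sum(p1[mv == 0])
  c(eps_m = eps_m, eps_a = p_a1_m1 - abar, eps_g = 1 - p_a1_m0)
}

#' Run the one-bit feedforward sensing protocol
#'
#' Prepares the sensor in the steady state of a random initial signal,
#' switches the signal at `t = 0` according to the protocol, and returns
#' the ensemble trajectory with full information and thermodynamic
#' ledgers. The expected phenomenology: the average activity transiently
#' swings to about `1 - eps_g` (up-branch) on the `1/omega_a` scale, then
#' re-adapts to `abar +/- eps_a` on the `1/omega_m` scale while the memory
#' tracks the new signal; `I_meas` rises in the corresponding two stages.
#'
#' @inheritParams construct_steady_states
#' @param times grid starting at 0; default [default_time_grid()].
#' @param n_times grid size when `times` is `NULL`.
#' @return list with `model`, `trajectory`, `info` (ledger, nats),
#'   `thermo` (ledger), and `bounds` (report).
#' @export
run_feedforward_protocol <- function(params, times = NULL, n_times = 240) {
  model <- build_rates(params)
  if (is.null(times)) times <- default_time_grid(model, n = n_times)
  if (length(times) > 2 && times[2] > 0.2 / params$omega_a) {
    warning("time grid may be too coarse to resolve the activity response 1/omega_a")
  }
  traj <- ensemble_propagate(model, params$protocol, times)
  info <- information_decomposition(traj, "m", "a")
  thermo <- thermo_ledger(traj, mode = "quench")
  list(
    model = model, trajectory = traj, info = info, thermo = thermo,
    bounds = check_information_bounds(info, thermo)
  )
}
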