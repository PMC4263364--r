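#' Instantaneous entropy flow, heat and chemical work rates
#'
#' For a distribution `p` under the signal-`l` generator, using the
#' local-detailed-balance affinities `A(x -> x') = log(W_f / W_b)`:
#' the entropy flow rate into the reservoir is
#' `sum_{x != x'} W(x -> x') p(x) A(x -> x')` (k_B/time), the heat rate
#' into the system is its negative (kT/time, with T = 1), and the chemical
#' work rate is `dmu * sum flux * nu`. The mean-energy balance
#' `dE/dt = heat + chemical work` holds identically.
#'
#' @inheritParams generator
#' @param p distribution over states.
#' @return list with `entropy_flow_rate`, `heat_rate`, `chem_work_rate`,
#'   `energy_rate`, and `sigma_tot_rate` (the total entropy production
#'   rate `dS/dt + entropy flow`, k_B/time).
#' @export
entropy_flow_and_heat <- function(model, l, p) {
  id <- .signal_id(model, l)
  .check_distribution(p, "p", tol = 1e-9)
  w <- model$W[[id]]
  off <- w
  diag(off) <- 0
  sup <- off > 0
  aff <- affinity_of(model, id)$affinity
  flux <- sweep(off, 2L, pmax(p, 0), `*`) # flux[i, j] = W(j -> i) p(j)
  use <- sup & flux > 0
  sr <- sum(flux[use] * aff[use])
  chem <- model$dmu * sum(flux[sup] * model$nu[sup])
  # dS/dt = -sum dp log p over states with p > 0 (zero-p states contribute 0)
  dp <- as.vector(w %*% pmax(p, 0))
  pos <- p > 0
  dsdt <- -sum(dp[pos] * log(p[pos]))
  list(
    entropy_flow_rate = sr,
    heat_rate = -sr,
    chem_work_rate = chem,
    energy_rate = -sr + chem,
    sigma_tot_rate = dsdt + sr
  )
}

# linear-functional coefficient vectors: cumulative Q, W_chem are
# c %*% int p dt with these per-source-state rate coefficients
.ledger_coeffs <- function(model, id) {
  w <- model$W[[id]]
  off <- w
  diag(off) <- 0
  sup <- off > 0
  aff <- affinity_of(model, id)$affinity
  affs <- matrix(0, nrow(w), ncol(w))
  affs[sup] <- aff[sup]
  nus <- matrix(0, nrow(w), ncol(w))
  nus[sup] <- model$nu[sup]
  list(
    heat = -colSums(off * affs), # kT per unit time per unit occupation
    chem = model$dmu * colSums(off * nus)
  )
}

#' Full thermodynamic ledger of a signal-switch ensemble
#'
#' Computes, on the trajectory grid and with the reference at the switch
#' time `t = 0`: cumulative heat `Q` into the system and excess heat
#' `Q_ex` (Hatano-Sasa), chemical work `W_chem`, total/measurement/erasure
#' entropy productions `Sigma_tot = Sigma_mea + Sigma_era`, the
#' nonadiabatic/adiabatic split `Sigma_tot = Sigma_na + Sigma_a`, mean
#' internal energy `E`, nonequilibrium free energy `F = E - T S_x` (with
#' the unconditional system entropy), and the work account.
#'
#' Two internal-energy conventions are supported. In `"quench"` mode
#' (signal-dependent energy, e.g. the feedforward sensor) the work is the
#' instantaneous quench work `<E(x; l1) - E(x; l0)>` at `t = 0` plus any
#' chemical work, and the first law reads `E(t) - E_pre = W + Q`. In
#' `"excess"` mode (declared internal split, e.g. the receptor-only energy
#' of the chemoreceptor) the excess work is defined through
#' `W_ex = Delta E - Q_ex`. `"auto"` picks `"excess"` iff the model
#' declares `energy_internal`.
#'
#' Cumulative heats are exact linear functionals of the exactly-integrated
#' occupations carried by the trajectory, so the decomposition identities
#' hold to machine precision, not quadrature accuracy.
#'
#' @param traj an [ensemble_propagate()] result whose grid starts at 0.
#' @param mode `"auto"`, `"quench"` or `"excess"`.
#' @return data.frame of class `thermo_ledger`; attributes `E_pre`,
#'   `F_pre`, `mode`, `units = "nats"` (info columns; energies kT,
#'   entropies k_B with k_B = T = 1).
#' @export
thermo_ledger <- function(traj, mode = c("auto", "quench", "excess")) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  mode <- match.arg(mode)
  model <- traj$model
  if (is.null(model$energy)) {
    stop("thermo_ledger needs a model with energy bookkeeping")
  }
  if (mode == "auto") {
    mode <- if (!is.null(model$energy_internal)) "excess" else "quench"
  }
  if (mode == "excess" && is.null(model$energy_internal)) {
    stop("excess mode requires a declared internal-energy split")
  }
  if (abs(traj$times[1]) > 1e-12) {
    warning("trajectory grid does not start at 0; ledger reference is still the switch time")
  }
  ids <- traj$protocol$ids
  nk <- length(ids)
  nt <- length(traj$times)
  wts <- traj$weights
  emat <- model$energy
  eint <- model$energy_internal

  S_cond <- Q <- Q_ex <- W_chem <- D_ss <- E_t <- numeric(nt)
  E_pre <- 0
  W_quench <- 0
  pss1 <- lapply(ids, function(id) stationary_distribution(model, id))
  coeffs <- lapply(ids, function(id) .ledger_coeffs(model, id))
  S_cond0 <- 0
  D_ss0 <- 0
  for (j0 in seq_len(nk)) {
    p0 <- traj$p0[, j0]
    s0 <- shannon_entropy(p0)
    for (j1 in seq_len(nk)) {
      wt <- wts[j0, j1]
      if (wt == 0) next
      pk <- traj$p[, , j0, j1]
      ik <- traj$ip[, , j0, j1]
      cf <- coeffs[[j1]]
      lnp <- log(pss1[[j1]])
      S_cond <- S_cond + wt * apply(pk, 2L, shannon_entropy)
      Q <- Q + wt * as.vector(cf$heat %*% ik)
      W_chem <- W_chem + wt * as.vector(cf$chem %*% ik)
      Q_ex <- Q_ex - wt * as.vector(lnp %*% (pk - p0))
      D_ss <- D_ss + wt * apply(pk, 2L, relative_entropy, q = pss1[[j1]])
      D_ss0 <- D_ss0 + wt * relative_entropy(p0, pss1[[j1]])
      S_cond0 <- S_cond0 + wt * s0
      e1 <- if (mode == "excess") eint[, ids[j1]] else emat[, ids[j1]]
      e0 <- if (mode == "excess") eint[, ids[j0]] else emat[, ids[j0]]
      E_t <- E_t + wt * as.vector(e1 %*% pk)
      E_pre <- E_pre + wt * sum(e0 * p0)
      W_quench <- W_quench + wt * sum((emat[, ids[j1]] - emat[, ids[j0]]) * p0)
    }
  }
  info0 <- .info_at(traj, 0L)
  S_x <- I_meas <- I_era <- numeric(nt)
  for (k in seq_len(nt)) {
    ik <- .info_at(traj, k)
    S_x[k] <- ik$S_x
    I_meas[k] <- ik$I_meas
    I_era[k] <- ik$I_era
  }

  Sigma_tot <- (S_cond - S_cond0) - Q
  Sigma_era <- info0$I_era - I_era
  Sigma_mea <- (S_x - info0$S_x) - (I_meas - info0$I_meas) - Q
  Sigma_na <- (S_cond - S_cond0) - Q_ex
  Sigma_a <- Sigma_tot - Sigma_na
  F_t <- E_t - S_x
  F_pre <- E_pre - info0$S_x
  out <- data.frame(
    time = traj$times,
    E = E_t, F = F_t, Q = Q, Q_ex = Q_ex, W_chem = W_chem,
    S_x = S_x, S_cond = S_cond,
    I_meas = I_meas, I_era_remaining = I_era,
    Sigma_tot = Sigma_tot, Sigma_mea = Sigma_mea, Sigma_era = Sigma_era,
    Sigma_na = Sigma_na, Sigma_a = Sigma_a,
    D_to_ss = D_ss
  )
  if (mode == "quench") {
    out$W <- W_quench + W_chem
  } else {
    out$W_ex <- (E_t - E_pre) - Q_ex
  }
  attr(out, "E_pre") <- E_pre
  attr(out, "F_pre") <- F_pre
  attr(out, "I_meas_pre") <- info0$I_meas
  attr(out, "I_era_pre") <- info0$I_era
  attr(out, "S_x_pre") <- info0$S_x
  attr(out, "D_to_ss_pre") <- D_ss0
  attr(out, "mode") <- mode
  attr(out, "units") <- "nats"
  class(out) <- c("thermo_ledger", class(out))
  out
}

#' Total entropy production series
#'
#' Second-law accounting per signal pair, averaged over the switch
#' ensemble: `Sigma_tot(t) = Delta S(x | l0, l1) - Q(t)/T`, non-decreasing
#' and zero at the switch time.
#'
#' @inheritParams thermo_ledger
#' @return columns `time`, `S_cond`, `Q`, `Sigma_tot`.
#' @export
entropy_production_series <- function(traj) {
  led <- thermo_ledger(traj, mode = "quench")
  led[, c("time", "S_cond", "Q", "Sigma_tot")]
}

#' Measurement/erasure split of the entropy production
#'
#' `Sigma_era(t) = I(x_0; l0 | l1) - I(x_t; l0 | l1)` is purely entropic
#' (the information erased about the old signal);
#' `Sigma_mea(t) = Delta S(x) - Delta I(x_t; l1) - Q(t)/T` carries all the
#' energetics. Their sum is `Sigma_tot` identically.
#'
#' @inheritParams thermo_ledger
#' @return columns `time`, `Sigma_tot`, `Sigma_mea`, `Sigma_era`.
#' @export
split_measurement_erasure <- function(traj) {
  led <- thermo_ledger(traj, mode = "quench")
  led[, c("time", "Sigma_tot", "Sigma_mea", "Sigma_era")]
}

#' Nonadiabatic/adiabatic split of the entropy production
#'
#' `Sigma_na(t) = -Delta D(p_t || p_ss^{l1})` (per branch, averaged) is the
#' transient-relaxation part; `Sigma_a = Sigma_tot - Sigma_na` is the
#' housekeeping part, identically zero for detailed-balanced models. The
#' excess heat satisfies `dS/dt - dQ_ex/dt = dSigma_na/dt`.
#'
#' @inheritParams thermo_ledger
#' @return columns `time`, `Sigma_na`, `Sigma_a`, `Q_ex`, `D_to_ss`.
#' @export
nonadiabatic_adiabatic_split <- function(traj) {
  led <- thermo_ledger(traj, mode = "quench")
  led[, c("time", "Sigma_na", "Sigma_a", "Q_ex", "D_to_ss")]
}

#' Energy, free energy and (excess) work ledger
#'
#' @inheritParams thermo_ledger
#' @return columns `time`, `E`, `F`, `Q`, and `W` (quench mode) or
#'   `W_ex`, `Q_ex` (excess mode); attributes `E_pre`, `F_pre`.
#' @export
excess_work_ledger <- function(traj, mode = c("auto", "quench", "excess")) {
  led <- thermo_ledger(traj, mode = match.arg(mode))
  cols <- c("time", "E", "F", "Q",
            if (attr(led, "mode") == "quench") "W" else c("W_ex", "Q_ex"))
  out <- led[, cols]
  attr(out, "E_pre") <- attr(led, "E_pre")
  attr(out, "F_pre") <- attr(led, "F_pre")
  attr(out, "mode") <- attr(led, "mode")
  out
}

#' Check the information-thermodynamic bounds along a run
#'
#' Evaluates, at every grid time, the second-law statements tying the
#' ledgers together: total entropy production dominates the information
#' erased; the (excess) work over the free-energy change pays for at least
#' `kT` times the measured information; and every entropy-production
#' component is nonnegative. Violations beyond `tol` are reported, not
#' raised.
#'
#' @param info an [information_decomposition()] ledger (nats).
#' @param thermo a [thermo_ledger()] on the same grid.
#' @param tol numerical tolerance for `holds`.
#' @return data.frame with one row per bound: `bound`, `margin_min`
#'   (minimum over time of lhs - rhs), `t_at_min`, `holds`.
#' @export
check_information_bounds <- function(info, thermo, tol = 1e-9) {
  info <- to_nats(info)
  stopifnot(nrow(info) == nrow(thermo),
            max(abs(info$time - thermo$time)) < 1e-12)
  dI_meas <- info$I_meas - info$I_meas[1]
  dF <- thermo$F - attr(thermo, "F_pre")
  margins <- list(
    "Sigma_tot >= erased information (Sigma_era)" =
      thermo$Sigma_tot - thermo$Sigma_era,
    "Sigma_na >= erased information (Sigma_era)" =
      thermo$Sigma_na - thermo$Sigma_era,
    "Sigma_tot >= 0" = thermo$Sigma_tot,
    "Sigma_mea >= 0" = thermo$Sigma_mea,
    "Sigma_na >= 0" = thermo$Sigma_na,
    "Sigma_a >= 0" = thermo$Sigma_a
  )
  if (!is.null(thermo$W)) {
    margins[["W - dF >= kT * I_meas"]] <- (thermo$W - dF) - dI_meas
  }
  if (!is.null(thermo$W_ex)) {
    margins[["W_ex - dF >= kT * I_meas"]] <- (thermo$W_ex - dF) - dI_meas
  }
  idx <- vapply(margins, which.min, integer(1))
  out <- data.frame(
    bound = names(margins),
    margin_min = vapply(margins, min, numeric(1)),
    t_at_min = thermo$time[idx],
    holds = vapply(margins, function(m) min(m) >= -tol, logical(1)),
    row.names = NULL
  )
  class(out) <- c("bound_report", class(out))
  out
}
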