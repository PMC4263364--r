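#' Parameters of the ten-state E. coli chemoreceptor
#'
#' A single Tar-type MWC receptor with binary activity `a` (inactive /
#' active conformation) and methylation memory `m` in `{0, ..., 4}`.
#' Activity flips are thermal; methylation steps are catalysed by CheR
#' (on inactive receptors, `m -> m + 1`) and CheB (on active receptors,
#' `m -> m - 1`) and each forward step hydrolyses one SAM molecule,
#' releasing `dmu` kT of chemical drive. With `dmu > 0` the adapted state
#' is a genuine nonequilibrium steady state sustained by a dissipative
#' cycle in `(a, m)` space; `dmu = 0` recovers detailed balance.
#'
#' Defaults follow the consensus Tar-receptor parameterization:
#' `eps_r = 2` kT per methyl group, reference methylation `m0 = 1`,
#' dissociation constants `K_I = 18.2` uM (inactive) and `K_A = 3000` uM
#' (active), `dmu = 6` kT per SAM, and rate scales `omega_a = 1`,
#' `omega_m = 0.01` enforcing fast response / slow adaptation.
#'
#' @param eps_r receptor characteristic energy per methyl group (kT).
#' @param m0 reference methylation level.
#' @param K_I,K_A inactive/active ligand dissociation constants (uM),
#'   `K_I < K_A`.
#' @param dmu chemical potential per SAM hydrolysis (kT), `>= 0`.
#' @param omega_a activity attempt rate (1/time).
#' @param omega_m methylation attempt rate (1/time).
#' @param m_levels number of methylation levels (5 for a Tar monomer).
#' @param readapt_tol relative tolerance defining the re-adaptation time
#'   (first return of the mean activity to within this fraction of its new
#'   stationary value, after the transient excursion).
#' @return object of class `chemotaxis_params`.
#' @export
chemotaxis_params <- function(eps_r = 2, m0 = 1, K_I = 18.2, K_A = 3000,
                              dmu = 6, omega_a = 1, omega_m = 1e-2,
                              m_levels = 5L, readapt_tol = 0.05) {
  stopifnot(K_I > 0, K_A > 0, eps_r > 0, omega_a > 0, omega_m > 0,
            m_levels >= 2L, readapt_tol > 0)
  if (!(K_I < K_A)) stop("K_I must be smaller than K_A")
  if (dmu < 0) stop("dmu must be nonnegative")
  structure(
    list(eps_r = eps_r, m0 = m0, K_I = K_I, K_A = K_A, dmu = dmu,
         omega_a = omega_a, omega_m = omega_m,
         m_levels = as.integer(m_levels), readapt_tol = readapt_tol),
    class = "chemotaxis_params"
  )
}

.chemo_space <- function(params) {
  state_space(expand.grid(a = 0:1, m = 0:(params$m_levels - 1L)))
}

#' MWC free energy of the receptor coupled to its environment
#'
#' `F(a, m; L) = a * eps_r * (m0 - m) + a * log((1 + L/K_I)/(1 + L/K_A))`
#' in kT, with the inactive conformation as the zero reference. The first
#' term is the receptor's own (internal) energy; the second is the
#' ligand-reservoir interaction, treated as environmental in the
#' excess-work split. For `K_I < L < K_A` the ligand term is positive:
#' attractant binding favours the inactive conformation.
#'
#' @param params a [chemotaxis_params()].
#' @param a activity (0/1), vectorized.
#' @param m methylation level, vectorized.
#' @param L ligand concentration (uM), `> 0`.
#' @return free energy in kT.
#' @export
receptor_free_energy <- function(params, a, m, L) {
  if (any(L <= 0)) stop("ligand concentration must be positive")
  a * (params$eps_r * (params$m0 - m) + log((1 + L / params$K_I) / (1 + L / params$K_A)))
}

# internal (receptor-only) part of the free energy
.receptor_internal_energy <- function(params, a, m) {
  a * params$eps_r * (params$m0 - m)
}

#' Build the chemoreceptor rate model for one or more ligand levels
#'
#' Activity flips at fixed `m` are thermal with the symmetric
#' parameterization `omega_a * exp(-dF/2)` (`nu = 0`). Methylation steps
#' at fixed `a` carry one SAM per forward event — methylation (`m -> m+1`)
#' on inactive receptors, demethylation (`m -> m-1`) on active ones — with
#' `log(forward/backward) = dmu - dF` and attempt scale `omega_m` split
#' symmetrically. Boundary levels reflect. `dmu = 0` reduces to detailed
#' balance.
#'
#' @inheritParams receptor_free_energy
#' @param L ligand level(s) in uM; each becomes a signal id.
#' @return a [rate_model()] with the total free energy and the declared
#'   receptor-only internal energy split.
#' @export
build_chemotaxis_generator <- function(params, L) {
  stopifnot(inherits(params, "chemotaxis_params"))
  if (any(L <= 0)) stop("ligand concentration must be positive")
  sp <- .chemo_space(params)
  av <- sp$coords$a
  mv <- sp$coords$m
  n <- n_states(sp)
  nu <- matrix(0L, n, n)
  ids <- as.character(L)
  W <- stats::setNames(vector("list", length(ids)), ids)
  energy <- matrix(NA_real_, n, length(ids), dimnames = list(sp$labels, ids))
  for (q in seq_along(ids)) {
    e <- receptor_free_energy(params, av, mv, L[q])
    w <- matrix(0, n, n)
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        if (i == j) next
        da <- av[i] != av[j]
        dmstep <- mv[i] - mv[j]
        if (da && dmstep == 0L) {
          w[i, j] <- params$omega_a * exp(-(e[i] - e[j]) / 2)
        } else if (!da && abs(dmstep) == 1L) {
          # forward fuel-consuming direction: CheR up-step on inactive,
          # CheB down-step on active
          forward <- (av[j] == 0L && dmstep == 1L) ||
                     (av[j] == 1L && dmstep == -1L)
          nu[i, j] <- if (forward) 1L else -1L
          w[i, j] <- params$omega_m *
            exp((params$dmu * nu[i, j] - (e[i] - e[j])) / 2)
        }
      }
    }
    W[[q]] <- w
    energy[, q] <- e
  }
  eint <- matrix(.receptor_internal_energy(params, av, mv), n, length(ids),
                 dimnames = list(sp$labels, ids))
  rate_model(sp, W, energy = energy, energy_internal = eint,
             nu = nu, dmu = params$dmu)
}

#' Adapted activity and mean methylation across ligand levels
#'
#' Stationary `<a>` and `<m>` for each ligand concentration. Within the
#' adaptive range `K_I << L << K_A` the adapted activity varies weakly
#' with `L` while the methylation level shifts to absorb the ligand term;
#' outside it (near or beyond `K_A`, or at the methylation boundaries)
#' adaptation degrades.
#'
#' @inheritParams receptor_free_energy
#' @param L_grid positive ligand levels (uM).
#' @return data.frame with `L`, `a_mean`, `m_mean`.
#' @export
adaptation_curve <- function(params, L_grid) {
  stopifnot(all(L_grid > 0))
  sp <- .chemo_space(params)
  av <- sp$coords$a
  mv <- sp$coords$m
  out <- data.frame(L = L_grid, a_mean = NA_real_, m_mean = NA_real_)
  for (q in seq_along(L_grid)) {
    model <- build_chemotaxis_generator(params, L_grid[q])
    p <- stationary_distribution(model, as.character(L_grid[q]))
    out$a_mean[q] <- sum(av * p)
    out$m_mean[q] <- sum(mv * p)
  }
  out
}

#' Stationary SAM consumption and housekeeping dissipation
#'
#' At the nonequilibrium steady state the net flux over the fuel-driven
#' transitions gives the SAM consumption rate; the housekeeping
#' dissipation rate is `dmu` times it, and equals the stationary total
#' entropy production rate `T dSigma_tot/dt` (the nonadiabatic part
#' vanishes at stationarity).
#'
#' @inheritParams receptor_free_energy
#' @param L ligand level (uM).
#' @return list with `sam_rate` (molecules/time), `dissipation_rate`
#'   (kT/time) and `sigma_tot_rate` (k_B/time, flux formula).
#' @export
housekeeping_rate <- function(params, L) {
  model <- build_chemotaxis_generator(params, L)
  id <- as.character(L)
  p <- stationary_distribution(model, id)
  w <- model$W[[id]]
  off <- w
  diag(off) <- 0
  flux <- sweep(off, 2L, p, `*`) # flux[i, j] = W(j -> i) p(j)
  net <- flux - t(flux)
  fwd <- model$nu > 0
  sam <- sum(net[fwd]) # net fuel molecules consumed per unit time
  rates <- entropy_flow_and_heat(model, id, p)
  list(
    sam_rate = sam,
    dissipation_rate = params$dmu * sam,
    sigma_tot_rate = rates$sigma_tot_rate
  )
}

# re-adaptation time: after the extremal excursion of <a> from its new
# stationary value, first grid time back within readapt_tol (relative)
.readaptation_index <- function(times, a_mean, a_ss, tol) {
  dev <- abs(a_mean - a_ss)
  band <- tol * max(abs(a_ss), 1e-12)
  k_peak <- which.max(dev)
  k_back <- which(dev <= band & seq_along(dev) >= k_peak)
  if (!length(k_back)) NA_integer_ else k_back[1]
}

#' Run the binary ligand-step experiment
#'
#' Ensemble over the binary protocol `{L0, L1}` (uniform independent
#' prior/kernel by default), with the NESS machinery: nonadiabatic split,
#' excess heat, and excess work with the receptor-only internal energy.
#' The cost summary integrates over the re-adaptation window of the
#' up-step branch (`l0 = L0, l1 = L1`).
#'
#' The random-switch ensemble carries the information accounting; the cost
#' summary's energetics are evaluated on the deterministic up-step branch
#' `L0 -> L1` (the step experiment), where the sensing cost is the gross
#' excess work the cell supplies — the running maximum of cumulative
#' `W_ex` up to re-adaptation. Much of it has been consumed again (stored
#' free energy used up) by the time adaptation completes, so the net
#' `W_ex` at re-adaptation is also reported but is not the cost.
#'
#' @inheritParams receptor_free_energy
#' @param L0,L1 pre- and post-switch ligand levels (uM).
#' @param times grid starting at 0; default [default_time_grid()].
#' @param n_times grid size when `times` is `NULL`.
#' @param prior,kernel optional protocol overrides.
#' @return list with `model`, `trajectory`, `info`, `thermo`, `bounds`,
#'   `thermo_up` (deterministic up-step ledger), and `summary`
#'   (re-adaptation window, gross/net sensing cost `W_ex`, measured /
#'   erased information, housekeeping dissipation `T Sigma_a` over the
#'   window, their ratios, and the mean methylation change).
#' @export
run_chemotaxis_step <- function(params, L0 = 94, L1 = 720, times = NULL,
                                n_times = 200, prior = NULL, kernel = NULL) {
  model <- build_chemotaxis_generator(params, c(L0, L1))
  if (is.null(times)) times <- default_time_grid(model, n = n_times)
  protocol <- signal_protocol(c(L0, L1), prior = prior, kernel = kernel)
  traj <- ensemble_propagate(model, protocol, times)
  info <- information_decomposition(traj, "m", "a")
  thermo <- thermo_ledger(traj, mode = "excess")
  bounds <- check_information_bounds(info, thermo)

  # deterministic up-step sub-protocol for the step-experiment energetics
  up <- signal_protocol(c(L0, L1), prior = c(1, 0),
                        kernel = matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE))
  traj_up <- ensemble_propagate(model, up, times)
  thermo_up <- thermo_ledger(traj_up, mode = "excess")

  av <- coord_values(model$space, "a")
  mv <- coord_values(model$space, "m")
  a_up <- ensemble_mean(traj_up, av)
  pss1 <- stationary_distribution(model, as.character(L1))
  a_ss <- sum(av * pss1)
  k_re <- .readaptation_index(times, a_up, a_ss, params$readapt_tol)
  if (is.na(k_re)) {
    warning(sprintf(
      "grid too short for re-adaptation; slowest relaxation ~ %.3g",
      relaxation_time(model, as.character(L1))
    ))
    k_re <- length(times)
  }
  m_up <- ensemble_mean(traj_up, mv)
  nt <- length(times)
  sensing_gross <- max(thermo_up$W_ex[seq_len(k_re)])
  housekeeping <- thermo_up$Sigma_a[k_re] # kT over the window, since T = 1
  i_meas_re <- thermo$I_meas[k_re]
  i_meas_end <- thermo$I_meas[nt]
  i_erased_end <- attr(thermo, "I_era_pre") - thermo$I_era_remaining[nt]
  summary <- list(
    L0 = L0, L1 = L1,
    t_readapt = times[k_re],
    a_stationary = a_ss,
    W_ex_sensing_gross = sensing_gross,
    W_ex_readapt_net = thermo_up$W_ex[k_re],
    W_ex_final_net = thermo_up$W_ex[nt],
    housekeeping_kT = housekeeping,
    ratio_sensing_housekeeping = sensing_gross / housekeeping,
    I_meas_readapt_nats = i_meas_re,
    I_meas_final_nats = i_meas_end,
    I_meas_final_bits = i_meas_end / log(2),
    I_erased_final_nats = i_erased_end,
    I_erased_final_bits = i_erased_end / log(2),
    Sigma_na_readapt = thermo$Sigma_na[k_re],
    Sigma_na_final = thermo$Sigma_na[nt],
    dissipation_over_bound = thermo$Sigma_na[k_re] / i_meas_re,
    mean_dm_up = m_up[nt] - m_up[1],
    bits_per_methyl = (i_erased_end / log(2)) / abs(m_up[nt] - m_up[1])
  )
  list(model = model, trajectory = traj, info = info, thermo = thermo,
       thermo_up = thermo_up, bounds = bounds, summary = summary)
}

#' Information-dissipation trade-off across ligand step sizes
#'
#' One [run_chemotaxis_step()] per final ligand level: information
#' measured and erased (bits, at the end of the run), the transient
#' dissipation `Sigma_na`, total `Sigma_tot`, and the
#' sensing-vs-housekeeping ratio at re-adaptation. The erased information
#' stays below 1 bit and saturates once `L1` exceeds `K_A` (the receptor
#' is no longer sensitive); `Sigma_na` grows monotonically with the
#' information, linearly for small steps.
#'
#' @inheritParams receptor_free_energy
#' @param L0 base ligand level (uM).
#' @param L1_grid increasing final levels, starting near `L0`.
#' @param n_times per-run grid size.
#' @return data.frame with one row per step: `L1`, `step_ratio`,
#'   `bits_measured`, `bits_erased`, `I_meas_nats`, `I_era_nats`,
#'   `Sigma_na`, `Sigma_tot`, `ratio_sensing_housekeeping`.
#' @export
sweep_tradeoff <- function(params, L0 = 94, L1_grid = NULL, n_times = 160) {
  if (is.null(L1_grid)) {
    L1_grid <- L0 * exp(seq(log(1.02), log(250), length.out = 24))
  }
  if (is.unsorted(L1_grid, strictly = TRUE)) stop("L1_grid must be increasing")
  rows <- lapply(L1_grid, function(L1) {
    run <- run_chemotaxis_step(params, L0, L1, n_times = n_times)
    s <- run$summary
    nt <- nrow(run$thermo)
    data.frame(
      L1 = L1, step_ratio = L1 / L0,
      bits_measured = s$I_meas_final_bits,
      bits_erased = s$I_erased_final_bits,
      I_meas_nats = s$I_meas_final_nats,
      I_era_nats = s$I_erased_final_nats,
      Sigma_na = run$thermo$Sigma_na[nt],
      Sigma_tot = run$thermo$Sigma_tot[nt],
      ratio_sensing_housekeeping = s$ratio_sensing_housekeeping
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "L0") <- L0
  out
}
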