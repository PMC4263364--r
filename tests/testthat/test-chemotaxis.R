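test_that("receptor free energy has the MWC form with the right reference", {
  p <- chemotaxis_params()
  # inactive conformation is the zero of energy for every (m, L)
  expect_equal(receptor_free_energy(p, 0, 0:4, 500), rep(0, 5))
  # at m = m0 and vanishing ligand both terms vanish
  expect_lt(abs(receptor_free_energy(p, 1, p$m0, 1e-9)), 1e-9)
  # adaptive range: attractant raises the active-state energy
  L <- 300
  expect_equal(receptor_free_energy(p, 1, 2, L),
               p$eps_r * (p$m0 - 2) + log((1 + L / p$K_I) / (1 + L / p$K_A)),
               tolerance = 1e-15)
  expect_gt(log((1 + L / p$K_I) / (1 + L / p$K_A)), 0)
  expect_error(receptor_free_energy(p, 1, 2, -5), "positive")
  expect_error(chemotaxis_params(K_I = 100, K_A = 50), "smaller")
})

test_that("generator: undriven limit is Boltzmann, driven case cycles", {
  p0 <- chemotaxis_params(dmu = 0)
  m0 <- build_chemotaxis_generator(p0, 94)
  expect_true(is_detailed_balanced(m0, "94", tol = 1e-10)$balanced)
  boltz <- exp(-m0$energy[, "94"])
  boltz <- boltz / sum(boltz)
  expect_all_close(stationary_distribution(m0, "94"), boltz, 1e-10)

  p <- chemotaxis_params()
  m <- build_chemotaxis_generator(p, 94)
  expect_false(is_detailed_balanced(m, "94")$balanced)
  # positive net cyclic flux around the (a, m) loop: CheR edges run forward
  pss <- stationary_distribution(m, "94")
  w <- generator(m, "94")
  av <- coord_values(m$space, "a")
  mv <- coord_values(m$space, "m")
  j_up <- sum(vapply(0:3, function(mm) {
    from <- which(av == 0 & mv == mm)
    to <- which(av == 0 & mv == mm + 1)
    w[to, from] * pss[from] - w[from, to] * pss[to]
  }, numeric(1)))
  expect_gt(j_up, 1e-4)
  # Kolmogorov-type cycle check: affinity around an elementary square equals
  # dmu x (net fuel consumed on the cycle) = 2 dmu
  idx <- function(a, mm) which(av == a & mv == mm)
  cyc <- list(c(idx(0, 1), idx(0, 2)), c(idx(0, 2), idx(1, 2)),
              c(idx(1, 2), idx(1, 1)), c(idx(1, 1), idx(0, 1)))
  aff <- sum(vapply(cyc, function(e) log(w[e[2], e[1]] / w[e[1], e[2]]),
                    numeric(1)))
  expect_equal(aff, 2 * p$dmu, tolerance = 1e-10)
})

test_that("adaptation is accurate inside K_I << L << K_A and degrades outside", {
  p <- chemotaxis_params()
  ac <- adaptation_curve(p, c(94, 720, 5760))
  # adapted activity shift across the in-range step is much smaller than the
  # transient excursion of the step response
  run <- run_chemotaxis_step(p, 94, 720, n_times = 140)
  av <- coord_values(run$model$space, "a")
  a_up <- ensemble_mean(run$trajectory, av, l0 = 94, l1 = 720)
  excursion <- max(abs(a_up - a_up[length(a_up)]))
  shift_in <- abs(ac$a_mean[2] - ac$a_mean[1])
  expect_lt(shift_in, 0.2 * excursion)
  # methylation increases with ligand; adaptation degrades beyond K_A
  expect_true(all(diff(ac$m_mean) > 0))
  shift_out <- abs(ac$a_mean[3] - ac$a_mean[2])
  expect_gt(shift_out, shift_in)
  # more fuel, better adaptation — within the time-scale-separated regime
  # omega_m * exp(dmu/2) << omega_a (beyond it methylation attempts become
  # as fast as activity flips and the quasi-equilibrium scan breaks down)
  errs <- vapply(c(1, 2, 4, 6), function(dmu) {
    aci <- adaptation_curve(chemotaxis_params(dmu = dmu), c(94, 720))
    abs(diff(aci$a_mean))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("housekeeping: SAM flux times dmu equals the stationary dissipation", {
  p <- chemotaxis_params()
  hk <- housekeeping_rate(p, 94)
  expect_gt(hk$sam_rate, 0)
  expect_equal(hk$dissipation_rate, hk$sigma_tot_rate, tolerance = 1e-9)
  hk0 <- housekeeping_rate(chemotaxis_params(dmu = 0), 94)
  expect_lt(abs(hk0$sam_rate), 1e-12)
  expect_lt(abs(hk0$dissipation_rate), 1e-12)
  # flux roughly linear in the methylation attempt rate (fixed affinities)
  hk2 <- housekeeping_rate(chemotaxis_params(omega_m = 0.02), 94)
  expect_equal(hk2$dissipation_rate / hk$dissipation_rate, 2, tolerance = 0.05)
})

test_that("ligand step: NESS ledgers, early environmental work, late fuel", {
  p <- chemotaxis_params()
  run <- run_chemotaxis_step(p, 94, 720, n_times = 160)
  th <- run$thermo
  expect_true(all(run$bounds$holds))
  expect_all_close(th$Sigma_tot - th$Sigma_na - th$Sigma_a, 0, 1e-9)
  # free energy rises on the fast response scale, peaks before adaptation
  up <- run$thermo_up
  dF <- up$F - attr(up, "F_pre")
  t_peak <- up$time[which.max(dF)]
  expect_gt(max(dF), 0)
  expect_lt(t_peak, 5 / p$omega_a)
  expect_gt(run$summary$t_readapt, 3 * t_peak) # adaptation is the slow stage
  # late time: stored free energy consumed, housekeeping keeps accruing
  nt <- nrow(up)
  expect_lt(dF[nt], 0.25 * max(dF))
  expect_gt(up$Sigma_a[nt], up$Sigma_na[nt])
  # information-limited memory: distributions of m overlap between levels
  expect_lt(run$summary$I_meas_final_nats, log(2))
  mv <- coord_values(run$model$space, "m")
  pm <- vapply(c("94", "720"), function(id) {
    as.vector(rowsum(stationary_distribution(run$model, id), mv))
  }, numeric(5))
  expect_gt(sum(pmin(pm[, 1], pm[, 2])), 0.1) # sizable overlap
})

test_that("the dmu = 0 receptor passes the equilibrium-model suite", {
  p <- chemotaxis_params(dmu = 0)
  run <- run_chemotaxis_step(p, 94, 720, n_times = 120)
  th <- run$thermo
  expect_all_close(th$Sigma_a, 0, 1e-9)
  expect_all_close(th$Sigma_na - th$Sigma_tot, 0, 1e-9)
  expect_true(all(run$bounds$holds))
})

test_that("near-zero ligand steps carry vanishing information and dissipation", {
  p <- chemotaxis_params()
  sw <- sweep_tradeoff(p, L0 = 94, L1_grid = 94 * c(1.001, 1.5, 3), n_times = 100)
  expect_lt(sw$bits_erased[1], 1e-5)
  expect_lt(sw$Sigma_na[1], 1e-4)
  expect_true(all(diff(sw$bits_erased) > 0))
  expect_true(all(diff(sw$Sigma_na) > 0))
})
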