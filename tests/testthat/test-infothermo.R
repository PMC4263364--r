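test_that("shannon entropy, mutual and conditional information match their oracles", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-15)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  # direct formula evaluation for (1/4, 3/4)
  expect_equal(shannon_entropy(c(0.25, 0.75)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-15)
  expect_equal(shannon_entropy(c(0.25, 0.75)), 0.5623, tolerance = 1e-4)
  expect_error(shannon_entropy(c(1.1, -0.1)), "negative")

  expect_equal(mutual_information(outer(c(0.3, 0.7), c(0.6, 0.4))), 0)
  expect_equal(mutual_information(diag(2) / 2), log(2), tolerance = 1e-15)
  j <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  brute <- sum(j * log(j / outer(rowSums(j), colSums(j))))
  expect_equal(mutual_information(j), brute, tolerance = 1e-12)

  # x independent of l0 given l1 -> zero
  j3 <- array(0, c(2, 2, 2))
  for (z in 1:2) j3[, , z] <- outer(c(0.3, 0.7), c(0.5, 0.5)) * 0.5
  expect_equal(conditional_mutual_information(j3), 0)
  # l1 an invertible function of l0: conditioning on l1 reveals l0 exactly,
  # so the conditional information collapses to zero however correlated x is
  j3 <- array(0, c(2, 2, 2))
  j3[, 1, 1] <- c(0.45, 0.05) # l0 = 0 -> l1 = 0, x correlated with l0
  j3[, 2, 2] <- c(0.05, 0.45)
  expect_equal(conditional_mutual_information(j3), 0)
  # chain rule: I(x; l0, l1) = I(x; l1) + I(x; l0 | l1) on a random joint
  set.seed(2)
  r <- array(runif(3 * 2 * 2), c(3, 2, 2))
  r <- r / sum(r)
  i_joint <- mutual_information(matrix(r, nrow = 3))
  i_l1 <- mutual_information(apply(r, c(1, 3), sum))
  expect_equal(conditional_mutual_information(r), i_joint - i_l1,
               tolerance = 1e-12)
})

test_that("at t = 0 the ensemble knows l0 but not l1 (independent kernel)", {
  fx <- make_random_model_fixture(5, driven = FALSE, seed = 31)
  times <- times_grid(0.01, 10, n = 20)
  traj <- ensemble_propagate(fx$model, fx$protocol, times)
  info <- information_decomposition(traj, NULL, NULL)
  # I(x0; l0 | l1) equals I(x0; l0) since l1 is independent of (x0, l0)
  jx0 <- cbind(0.5 * traj$p0[, 1], 0.5 * traj$p0[, 2])
  expect_equal(info$I_era_remaining[1], mutual_information(jx0),
               tolerance = 1e-10)
  expect_equal(info$I_meas[1], 0, tolerance = 1e-12)
})

test_that("entropy_flow_and_heat: stationarity, closed-form flux, NESS balance", {
  # detailed-balanced model at stationarity: zero heat rate
  fx <- make_random_model_fixture(5, driven = FALSE, seed = 41)
  p <- stationary_distribution(fx$model, "0")
  r <- entropy_flow_and_heat(fx$model, "0", p)
  expect_lt(abs(r$heat_rate), 1e-12)
  expect_lt(abs(r$sigma_tot_rate), 1e-12)
  # two-state relaxation: heat rate = energy gap x net flux
  m <- two_state_model(k_up = 2, k_dn = 0.5)
  pm <- c(0.9, 0.1)
  rr <- entropy_flow_and_heat(m, "0", pm)
  net_flux_up <- 2 * 0.9 - 0.5 * 0.1
  gap <- m$energy[2, "0"] - m$energy[1, "0"]
  expect_equal(rr$heat_rate, gap * net_flux_up, tolerance = 1e-12)
  # driven model at its NESS: heat out balances chemical work in
  dr <- make_random_model_fixture(6, driven = TRUE, seed = 42)
  pn <- stationary_distribution(dr$model, "1")
  rn <- entropy_flow_and_heat(dr$model, "1", pn)
  expect_equal(rn$heat_rate, -rn$chem_work_rate, tolerance = 1e-9)
})

test_that("no-quench protocol on an equilibrium model produces nothing", {
  fx <- make_random_model_fixture(5, driven = FALSE, seed = 51)
  stay <- signal_protocol(c(0, 1), kernel = diag(2))
  traj <- ensemble_propagate(fx$model, stay, times_grid(0.01, 30, n = 25))
  th <- thermo_ledger(traj)
  for (col in c("Sigma_tot", "Sigma_mea", "Sigma_era", "Sigma_na", "Sigma_a",
                "Q", "W")) {
    expect_all_close(th[[col]], 0, 1e-10)
  }
  expect_all_close(th$F - attr(th, "F_pre"), 0, 1e-10)
  info <- information_decomposition(traj, NULL, NULL)
  rep <- check_information_bounds(info, th)
  expect_true(all(rep$holds))
  expect_all_close(rep$margin_min, 0, 1e-10) # bounds met with equality
})

test_that("decomposition identities and positivity hold on a driven quench", {
  fx <- make_random_model_fixture(6, driven = TRUE, seed = 61)
  traj <- ensemble_propagate(fx$model, fx$protocol,
                             default_time_grid(fx$model, n = 60))
  th <- thermo_ledger(traj)
  expect_all_close(th$Sigma_tot - th$Sigma_mea - th$Sigma_era, 0, 1e-9)
  expect_all_close(th$Sigma_tot - th$Sigma_na - th$Sigma_a, 0, 1e-9)
  # exact erasure bookkeeping: Sigma_era + I(x_t; l0 | l1) constant
  expect_all_close(th$Sigma_era + th$I_era_remaining - th$I_era_remaining[1],
                   0, 1e-9)
  for (col in c("Sigma_tot", "Sigma_mea", "Sigma_era", "Sigma_na", "Sigma_a")) {
    expect_true(all(diff(th[[col]]) >= -1e-9))
    expect_true(all(th[[col]] >= -1e-9))
  }
  # first law with the quench + chemical work account
  expect_all_close((th$E - attr(th, "E_pre")) - th$W - th$Q, 0, 1e-9)
  # erasure equals the drop of the conditional relative entropy route:
  # I(x_t; l0 | l1) is itself an averaged D(p(x|l0,l1) || p(x|l1))
  info <- information_decomposition(traj, NULL, NULL)
  expect_all_close(th$I_era_remaining, info$I_era_remaining, 1e-12)
})

test_that("two integration routes for Sigma_tot and Sigma_na agree", {
  # ledger route (exact linear functionals) vs independent trapezoid
  # quadrature of the instantaneous flux expressions on a fine grid
  fx <- make_random_model_fixture(5, driven = TRUE, seed = 71)
  model <- fx$model
  # dense two-segment grid: the integrands vary on the fastest jump scale
  # right after the quench, so most nodes go there
  times <- unique(c(seq(0, 0.25, length.out = 2001),
                    seq(0.25, 8, length.out = 1200)))
  traj <- ensemble_propagate(model, fx$protocol, times)
  th <- thermo_ledger(traj)
  sig_rate <- numeric(length(times))
  na_rate <- numeric(length(times))
  for (j0 in 1:2) {
    for (j1 in 1:2) {
      id1 <- c("0", "1")[j1]
      pss <- stationary_distribution(model, id1)
      w <- generator(model, id1)
      lr <- log(pss)
      for (k in seq_along(times)) {
        pk <- traj$p[, k, j0, j1]
        r <- entropy_flow_and_heat(model, id1, pk)
        sig_rate[k] <- sig_rate[k] + 0.25 * r$sigma_tot_rate
        dp <- as.vector(w %*% pk)
        na_rate[k] <- na_rate[k] - 0.25 * sum(dp * (log(pk) - lr))
      }
    }
  }
  expect_all_close(trapz(times, sig_rate), th$Sigma_tot, 1e-5)
  expect_all_close(trapz(times, na_rate), th$Sigma_na, 1e-5)
})

test_that("unit conversion between nats and bits is an exact factor log(2)", {
  fx <- make_random_model_fixture(4, driven = FALSE, seed = 81)
  traj <- ensemble_propagate(fx$model, fx$protocol, times_grid(0.1, 10, n = 10))
  info <- information_decomposition(traj, NULL, NULL)
  bits <- to_bits(info)
  expect_identical(bits$I_meas * log(2), info$I_meas)
  expect_identical(attr(bits, "units"), "bits")
  back <- to_nats(bits)
  expect_equal(back$I_meas, info$I_meas, tolerance = 1e-15)
  expect_identical(to_bits(bits), bits) # idempotent
})
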