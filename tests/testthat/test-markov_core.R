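test_that("state space and protocol constructors validate their invariants", {
  expect_error(state_space(data.frame(x = c(0, 0))), "unique")
  expect_error(state_space(data.frame(x = 1)), "at least 2")
  sp <- state_space(expand.grid(a = 0:1, m = 0:2))
  expect_equal(n_states(sp), 6L)
  expect_equal(coord_values(sp, "m"), rep(0:2, each = 2))
  expect_error(coord_values(sp, "z"), "not found")

  expect_error(signal_protocol(c(0, 1), prior = c(0.4, 0.4)), "sum to 1")
  expect_error(signal_protocol(c(0, 1), kernel = matrix(c(1, -0.1, 0, 1.1), 2)),
               "negative")
  expect_false(signal_protocol()$degenerate)
  det <- signal_protocol(c(0, 1), prior = c(1, 0),
                         kernel = matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE))
  expect_true(det$degenerate)
  expect_equal(sum(signal_protocol()$weights), 1)
})

test_that("rate_model enforces generator validity, reversibility, irreducibility", {
  sp <- state_space(data.frame(x = 0:2))
  w_irr <- matrix(c(0, 1, 0, 0, 0, 0, 0, 1, 0), 3, 3) # 0 -> 1 without reverse
  expect_error(rate_model(sp, list("0" = w_irr)), "reverse is zero")
  w_red <- matrix(0, 3, 3)
  w_red[2, 1] <- w_red[1, 2] <- 1 # state x=2 disconnected
  expect_error(rate_model(sp, list("0" = w_red)), "disconnected blocks.*x=2")
  m <- three_cycle_model()
  w <- generator(m, "0")
  expect_all_close(colSums(w), 0, 1e-12)
  off <- w; diag(off) <- 0
  expect_true(all(off >= 0))
  # inconsistent energies are rejected by the affinity decomposition check
  expect_error(
    rate_model(state_space(data.frame(x = 0:1)),
               list("0" = matrix(c(0, 2, 1, 0), 2, 2)),
               energy = cbind("0" = c(0, 0))),
    "affinity decomposition"
  )
})

test_that("stationary_distribution matches symmetry, Boltzmann and eigen oracles", {
  expect_equal(unname(stationary_distribution(two_state_model(1, 1), "0")),
               c(0.5, 0.5), tolerance = 1e-12)
  # detailed-balanced fixture: p_ss must be the Boltzmann distribution
  fx <- make_random_model_fixture(6, driven = FALSE, seed = 11)
  for (id in c("0", "1")) {
    boltz <- exp(-fx$model$energy[, id])
    boltz <- boltz / sum(boltz)
    expect_all_close(stationary_distribution(fx$model, id), boltz, 1e-10)
  }
  # driven 3-cycle against an independent eigen-decomposition null solve
  m <- three_cycle_model(cw = c(2, 3, 4), ccw = c(1, 0.5, 2))
  eg <- eigen(generator(m, "0"))
  k <- which.min(abs(eg$values))
  p_eig <- Re(eg$vectors[, k]); p_eig <- p_eig / sum(p_eig)
  expect_all_close(stationary_distribution(m, "0"), p_eig, 1e-10)
})

test_that("is_detailed_balanced separates equilibrium from driven models", {
  eq <- make_random_model_fixture(5, driven = FALSE, seed = 3)
  expect_true(is_detailed_balanced(eq$model, "0")$balanced)
  dr <- make_random_model_fixture(6, driven = TRUE, seed = 4)
  expect_gt(dr$model$dmu, 0)
  db <- is_detailed_balanced(dr$model, "0")
  expect_false(db$balanced)
  expect_gt(db$max_violation, 1e-6)
})

test_that("propagate reproduces the two-state closed form and relaxes to p_ss", {
  m <- two_state_model(k_up = 2, k_dn = 0.5)
  p0 <- c(1, 0)
  expect_equal(unname(propagate(m, "0", p0, 0)[, 1]), p0)
  times <- times_grid(1e-3, 20, n = 60)
  sol <- propagate(m, "0", p0, times)
  pss <- stationary_distribution(m, "0")
  closed <- sapply(times, function(t) pss + (p0 - pss) * exp(-2.5 * t))
  expect_all_close(sol, closed, 1e-8)
  expect_all_close(colSums(sol), 1, 1e-9)
  # spectral long-time bound on an arbitrary fixture
  fx <- make_random_model_fixture(7, driven = TRUE, seed = 9)
  t_long <- 50 * relaxation_time(fx$model, "1")
  p_end <- propagate(fx$model, "1", rep(1 / 7, 7), c(t_long))[, 1]
  expect_lt(sum(abs(p_end - stationary_distribution(fx$model, "1"))), 1e-6)
  expect_error(propagate(m, "0", c(0.7, 0.7), 1), "sum to 1")
  expect_error(propagate(m, "0", p0, c(-1, 1)), "negative")
})

test_that("generator spectra and the H-theorem hold on random fixtures", {
  for (seed in 1:6) {
    fx <- make_random_model_fixture(3 + seed, driven = seed %% 2L == 0L,
                                    seed = 100 + seed)
    for (id in c("0", "1")) {
      ev <- eigen(generator(fx$model, id), only.values = TRUE)$values
      nonzero <- ev[abs(ev) > 1e-9]
      expect_true(all(Re(nonzero) < 0))
      # D(p(t) || p_ss) non-increasing along fixed-signal relaxation
      pss <- stationary_distribution(fx$model, id)
      p0 <- stationary_distribution(fx$model, if (id == "0") "1" else "0")
      times <- default_time_grid(fx$model, n = 50)
      sol <- propagate(fx$model, id, p0, times)
      d <- apply(sol, 2, relative_entropy, q = pss)
      expect_true(all(diff(d) <= 1e-10))
    }
  }
})

test_that("ensemble_propagate: no-quench identity kernel freezes every branch", {
  fx <- make_random_model_fixture(5, driven = FALSE, seed = 21)
  stay <- signal_protocol(c(0, 1), kernel = diag(2))
  times <- times_grid(0.01, 50, n = 30)
  traj <- ensemble_propagate(fx$model, stay, times)
  for (j in 1:2) {
    pss <- stationary_distribution(fx$model, c("0", "1")[j])
    expect_all_close(traj$p[, , j, j], matrix(pss, 5, length(times)), 1e-9)
  }
  # uniform-protocol marginal stays normalized
  traj2 <- ensemble_propagate(fx$model, fx$protocol, times)
  expect_all_close(colSums(marginal_system(traj2)), 1, 1e-9)
  expect_equal(sum(traj2$weights), 1)
})

test_that("gillespie sampling is seed-deterministic and matches the master equation", {
  m <- two_state_model(k_up = 1.3, k_dn = 0.6)
  s1 <- gillespie_sample(m, "0", 1L, horizon = 50, seed = 42)
  s2 <- gillespie_sample(m, "0", 1L, horizon = 50, seed = 42)
  expect_identical(s1, s2)
  expect_gt(length(s1$times), 5)
  # occupancy oracle: empirical vs analytic within 3 binomial standard errors
  at <- c(0.5, 1.5, 4)
  occ <- gillespie_occupation(m, "0", c(1, 0), at, n_traj = 2000, seed = 7)
  ex <- propagate(m, "0", c(1, 0), at)
  se <- sqrt(ex[2, ] * (1 - ex[2, ]) / 2000)
  expect_true(all(abs(occ[2, ] - ex[2, ]) < 3 * se))
})

test_that("model JSON serialization round-trips exactly", {
  fx <- make_random_model_fixture(4, driven = TRUE, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(fx$model, path)
  back <- model_from_json(path)
  expect_equal(back$W, fx$model$W, tolerance = 0)
  expect_equal(unname(back$energy), unname(fx$model$energy), tolerance = 0)
  expect_equal(back$dmu, fx$model$dmu, tolerance = 0)
  expect_equal(back$nu, fx$model$nu)
})
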