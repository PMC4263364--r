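# Small models built in code, used across the suite.

# two-state model 0 <-> 1 with rates k_up (0 -> 1) and k_dn (1 -> 0),
# energies fixed by detailed balance (E(0) = 0)
two_state_model <- function(k_up = 1, k_dn = 1) {
  sp <- state_space(data.frame(x = 0:1))
  w <- matrix(c(0, k_up, k_dn, 0), 2, 2) # W[i, j]: j -> i
  e <- c(0, log(k_up / k_dn) * -1) # log(k_up/k_dn) = -(E2 - E1)
  rate_model(sp, list("0" = w, "1" = w), energy = cbind("0" = e, "1" = e))
}

# driven three-cycle with unequal clockwise / counterclockwise rates;
# no energy bookkeeping (used for the stationary-state eigen oracle)
three_cycle_model <- function(cw = c(2, 3, 4), ccw = c(1, 1, 1)) {
  sp <- state_space(data.frame(x = 0:2))
  w <- matrix(0, 3, 3)
  nxt <- c(2L, 3L, 1L)
  for (j in 1:3) {
    w[nxt[j], j] <- cw[j]
    w[j, nxt[j]] <- ccw[j]
  }
  rate_model(sp, list("0" = w))
}

# trapezoid rule, used as an independent (quadrature) integration oracle
trapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

expect_all_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
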