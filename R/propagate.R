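#' Time grids
#'
#' Geometric (log-spaced) grids are the default throughout: the bundled
#' sensors have a fast activity scale `1/omega_a` and a slow memory scale
#' `1/omega_m` separated by orders of magnitude, and a log grid resolves
#' both. A leading 0 is prepended so cumulative ledgers have their
#' reference at the switch time.
#'
#' @param t_min first positive time.
#' @param t_max last time.
#' @param n number of positive grid points.
#' @param spacing `"log"` (default) or `"linear"`.
#' @param include_zero prepend `t = 0` (default `TRUE`).
#' @return increasing numeric vector.
#' @export
times_grid <- function(t_min, t_max, n = 200, spacing = c("log", "linear"),
                       include_zero = TRUE) {
  spacing <- match.arg(spacing)
  stopifnot(t_min > 0, t_max > t_min, n >= 2)
  ts <- switch(spacing,
    log = exp(seq(log(t_min), log(t_max), length.out = n)),
    linear = seq(t_min, t_max, length.out = n)
  )
  if (include_zero) ts <- c(0, ts) else ts
}

#' Relaxation time of a signal-conditioned generator
#'
#' `1 / |Re lambda_2|` where `lambda_2` is the nonzero eigenvalue of `W_l`
#' closest to the imaginary axis.
#'
#' @inheritParams generator
#' @return slowest relaxation time (model time units).
#' @export
relaxation_time <- function(model, l) {
  w <- generator(model, l)
  ev <- eigen(w, only.values = TRUE)$values
  re <- Re(ev)
  nz <- re[re < -1e-12 * max(abs(re), 1)]
  if (!length(nz)) stop("generator has no relaxing mode")
  1 / abs(max(nz))
}

#' Default grid spanning response and adaptation of a model
#'
#' Runs from well below the fastest jump scale (`0.01 / max exit rate`) to
#' well beyond the slowest relaxation (`span_slow / |Re lambda_2|`, maximum
#' over signals), log-spaced.
#'
#' @param model a `rate_model`.
#' @param n number of positive grid points.
#' @param span_slow multiple of the slowest relaxation time to cover.
#' @return increasing time grid starting at 0.
#' @export
default_time_grid <- function(model, n = 240, span_slow = 30) {
  fastest <- max(vapply(model$W, function(w) max(-diag(w)), numeric(1)))
  slowest <- max(vapply(model$signals, function(id) relaxation_time(model, id),
                        numeric(1)))
  times_grid(0.01 / fastest, span_slow * slowest, n = n)
}

# Propagator steps that also return exact time integrals of p(t).
#
# exp([[W, 0], [I, 0]] dt) = [[e^{W dt}, 0], [int_0^dt e^{W s} ds, I]],
# so a single dense matrix exponential per step advances the distribution
# and accumulates int p dt with no quadrature error. All cumulative heat
# and work functionals in the thermo ledgers are linear in int p dt, which
# is what makes the decomposition identities hold to machine precision.
.step_ops <- function(w, dt) {
  n <- nrow(w)
  blk <- rbind(
    cbind(w * dt, matrix(0, n, n)),
    cbind(diag(dt, n), matrix(0, n, n))
  )
  m <- as.matrix(Matrix::expm(Matrix::Matrix(blk)))
  list(step = m[seq_len(n), seq_len(n), drop = FALSE],
       integral = m[n + seq_len(n), seq_len(n), drop = FALSE])
}

# p and int_0^t p dt on a grid, starting from p0 at t = 0
.propagate_int <- function(w, p0, times) {
  n <- length(p0)
  nt <- length(times)
  p <- matrix(NA_real_, n, nt)
  ip <- matrix(NA_real_, n, nt)
  cur <- p0
  icur <- numeric(n)
  tprev <- 0
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nt)) {
    dt <- times[k] - tprev
    if (dt > 0) {
      key <- sprintf("%.17g", dt)
      ops <- cache[[key]]
      if (is.null(ops)) {
        ops <- .step_ops(w, dt)
        cache[[key]] <- ops
      }
      icur <- icur + as.vector(ops$integral %*% cur)
      cur <- as.vector(ops$step %*% cur)
    }
    p[, k] <- cur
    ip[, k] <- icur
    tprev <- times[k]
  }
  list(p = p, ip = ip)
}

#' Solve the master equation on a time grid
#'
#' Propagates `p0` under the signal-`l` generator with dense matrix
#' exponentials (exact for the bundled, few-state models), returning the
#' distribution at every grid time.
#'
#' @inheritParams generator
#' @param p0 initial distribution at `t = 0`.
#' @param times increasing grid, `times[1] >= 0`.
#' @return `n_states x length(times)` matrix of distributions.
#' @export
propagate <- function(model, l, p0, times) {
  id <- .signal_id(model, l)
  .check_distribution(p0, "p0", tol = 1e-9)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("negative times are not allowed")
  out <- .propagate_int(model$W[[id]], p0, times)$p
  norm_err <- max(abs(colSums(out) - 1))
  if (norm_err > 1e-9) {
    stop(sprintf("propagation lost normalization (error %.3g)", norm_err))
  }
  dimnames(out) <- list(model$space$labels, NULL)
  out
}

#' Evolve the full signal-switch ensemble
#'
#' For every signal pair `(l0, l1)` the system starts in the pre-switch
#' steady state `p_ss^{l0}` and relaxes under the post-switch generator
#' `W_{l1}`; branch weights are `P(l0) P(l1 | l0)`. The returned object
#' also carries the exact running integrals of each conditional
#' distribution, used by the cumulative heat/work ledgers.
#'
#' @param model a `rate_model` whose signal ids include all protocol ids.
#' @param protocol a [signal_protocol()].
#' @param times increasing grid starting at (or near) 0.
#' @return object of class `ensemble_trajectory` with fields `times`,
#'   `p` (array `state x time x l0 x l1`), `ip` (running integrals),
#'   `p0` (pre-switch steady states per `l0`), `weights`, `model`,
#'   `protocol`, and `degenerate` flag.
#' @export
ensemble_propagate <- function(model, protocol, times) {
  stopifnot(inherits(protocol, "signal_protocol"))
  ids <- protocol$ids
  for (id in ids) .signal_id(model, id)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("negative times are not allowed")
  n <- n_states(model)
  nt <- length(times)
  k <- length(ids)
  p <- array(NA_real_, c(n, nt, k, k),
             dimnames = list(model$space$labels, NULL, ids, ids))
  ip <- array(NA_real_, c(n, nt, k, k))
  p0 <- vapply(ids, function(id) stationary_distribution(model, id), numeric(n))
  for (j1 in seq_len(k)) {
    w <- model$W[[ids[j1]]]
    for (j0 in seq_len(k)) {
      sol <- .propagate_int(w, p0[, j0], times)
      p[, , j0, j1] <- sol$p
      ip[, , j0, j1] <- sol$ip
    }
  }
  norm_err <- max(abs(apply(p, c(2, 3, 4), sum) - 1))
  if (norm_err > 1e-9) {
    stop(sprintf("ensemble propagation lost normalization (error %.3g)", norm_err))
  }
  structure(
    list(
      times = times, p = p, ip = ip, p0 = p0,
      weights = protocol$weights, model = model, protocol = protocol,
      degenerate = protocol$degenerate
    ),
    class = "ensemble_trajectory"
  )
}

#' @export
print.ensemble_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ensemble_trajectory> %d states, %d times in [%g, %g], signals {%s}%s\n",
    dim(x$p)[1], length(x$times), min(x$times), max(x$times),
    paste(x$protocol$ids, collapse = ", "),
    if (x$degenerate) " [degenerate protocol]" else ""
  ))
  invisible(x)
}

#' Marginal distribution of the system, `p(x, t)`
#' @param traj an `ensemble_trajectory`.
#' @return `n_states x n_times` matrix.
#' @export
marginal_system <- function(traj) {
  k <- length(traj$protocol$ids)
  n <- dim(traj$p)[1]
  nt <- length(traj$times)
  out <- matrix(0, n, nt)
  for (j0 in seq_len(k)) {
    for (j1 in seq_len(k)) {
      out <- out + traj$weights[j0, j1] * traj$p[, , j0, j1]
    }
  }
  rownames(out) <- traj$model$space$labels
  out
}

#' Ensemble average of a state observable
#' @param traj an `ensemble_trajectory`.
#' @param values numeric vector over states (e.g. the activity coordinate).
#' @param l0,l1 optional signal ids to condition on one branch.
#' @return numeric vector over times.
#' @export
ensemble_mean <- function(traj, values, l0 = NULL, l1 = NULL) {
  stopifnot(length(values) == dim(traj$p)[1])
  if (is.null(l0) && is.null(l1)) {
    return(as.vector(values %*% marginal_system(traj)))
  }
  ids <- traj$protocol$ids
  j0 <- if (is.null(l0)) seq_along(ids) else match(as.character(l0), ids)
  j1 <- if (is.null(l1)) seq_along(ids) else match(as.character(l1), ids)
  if (anyNA(c(j0, j1))) stop("unknown signal id in conditioning")
  wsub <- traj$weights[j0, j1, drop = FALSE]
  wsub <- wsub / sum(wsub)
  nt <- length(traj$times)
  out <- numeric(nt)
  for (a in seq_along(j0)) {
    for (b in seq_along(j1)) {
      out <- out + wsub[a, b] * as.vector(values %*% traj$p[, , j0[a], j1[b]])
    }
  }
  out
}

#' Exact stochastic simulation (Gillespie) of one trajectory
#'
#' Monte-Carlo oracle for the master equation: over many seeds the
#' empirical occupation statistics converge to [propagate()].
#'
#' @inheritParams generator
#' @param x0 initial state (integer index or state label).
#' @param horizon simulate jumps until this time.
#' @param seed integer seed (trajectory is reproducible under it).
#' @return list with `times` (jump times, starting at 0) and `states`
#'   (integer state indices occupied from each time on).
#' @export
gillespie_sample <- function(model, l, x0, horizon, seed) {
  id <- .signal_id(model, l)
  if (horizon <= 0) stop("horizon must be positive")
  w <- model$W[[id]]
  n <- nrow(w)
  if (is.character(x0)) x0 <- match(x0, model$space$labels)
  stopifnot(!is.na(x0), x0 >= 1, x0 <= n)
  set.seed(seed)
  .gillespie_core(w, x0, horizon)
}

.gillespie_core <- function(w, x0, horizon) {
  n <- nrow(w)
  out_rates <- -diag(w)
  if (any(out_rates <= 0)) {
    stop("model has an absorbing state; malformed sensor model")
  }
  jump_prob <- lapply(seq_len(n), function(j) {
    r <- w[, j]
    r[j] <- 0
    r / sum(r)
  })
  t_cur <- 0
  x <- x0
  times <- numeric(64)
  states <- integer(64)
  m <- 1L
  times[1] <- 0
  states[1] <- x
  repeat {
    t_cur <- t_cur + stats::rexp(1L, out_rates[x])
    if (t_cur > horizon) break
    x <- sample.int(n, 1L, prob = jump_prob[[x]])
    m <- m + 1L
    if (m > length(times)) {
      length(times) <- 2L * length(times)
      length(states) <- 2L * length(states)
    }
    times[m] <- t_cur
    states[m] <- x
  }
  list(times = times[seq_len(m)], states = states[seq_len(m)])
}

#' States occupied at given observation times
#' @param sample output of [gillespie_sample()].
#' @param at observation times within the simulated horizon.
#' @return integer state indices at each requested time.
#' @export
occupation_states <- function(sample, at) {
  sample$states[findInterval(at, sample$times)]
}

#' Empirical occupation frequencies from repeated simulation
#'
#' Convenience oracle: simulates `n_traj` trajectories from `p0` (or a
#' fixed `x0`) and tabulates state frequencies at each observation time.
#'
#' @inheritParams generator
#' @param p0 initial distribution to draw `x0` from.
#' @param at observation times.
#' @param n_traj number of trajectories.
#' @param seed integer seed.
#' @return `n_states x length(at)` matrix of frequencies.
#' @export
gillespie_occupation <- function(model, l, p0, at, n_traj, seed) {
  id <- .signal_id(model, l)
  w <- model$W[[id]]
  n <- nrow(w)
  .check_distribution(p0, "p0", tol = 1e-9)
  set.seed(seed)
  counts <- matrix(0, n, length(at))
  horizon <- max(at) * (1 + 1e-12) + 1e-12
  for (r in seq_len(n_traj)) {
    x0 <- sample.int(n, 1L, prob = p0)
    tr <- .gillespie_core(w, x0, horizon)
    occ <- tr$states[findInterval(at, tr$times)]
    counts[cbind(occ, seq_along(at))] <- counts[cbind(occ, seq_along(at))] + 1
  }
  counts / n_traj
}
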