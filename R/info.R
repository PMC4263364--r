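#' Shannon entropy in nats
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`. Entries below
#' `-1e-12` are an error; tiny negative round-off is clipped.
#'
#' @param p probability vector (sums to 1).
#' @return entropy in nats, in `[0, log(length(p))]`.
#' @export
shannon_entropy <- function(p) {
  .check_distribution(p, "p", tol = 1e-9)
  p <- pmax(p, 0)
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Relative entropy (Kullback-Leibler divergence) in nats
#' @param p,q probability vectors; `q` must be positive wherever `p` is.
#' @return `D(p || q) >= 0` in nats.
#' @export
relative_entropy <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- pmax(p, 0)
  pos <- p > 0
  if (any(q[pos] <= 0)) stop("D(p || q) undefined: q vanishes where p > 0")
  sum(p[pos] * (log(p[pos]) - log(q[pos])))
}

#' Mutual information of a two-way joint distribution
#'
#' `I(X; Y) = S(X) + S(Y) - S(X, Y)` in nats; zero iff the joint factorizes.
#'
#' @param joint matrix of joint probabilities `P(x, y)` (sums to 1).
#' @return mutual information in nats (clipped at 0 from round-off below
#'   `1e-12`).
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  mi <- shannon_entropy(rowSums(joint)) + shannon_entropy(colSums(joint)) -
    shannon_entropy(as.vector(joint))
  if (mi < -1e-9) stop(sprintf("mutual information came out negative (%.3g)", mi))
  max(mi, 0)
}

#' Conditional mutual information `I(X; Y | Z)`
#'
#' For a three-way joint array with dimensions `(x, y, z)`:
#' `I(X; Y | Z) = sum_z P(z) I(X; Y | Z = z)`, in nats. The third dimension
#' is always the conditioning variable.
#'
#' @param joint3 array `P(x, y, z)` (sums to 1).
#' @return conditional mutual information in nats.
#' @export
conditional_mutual_information <- function(joint3) {
  stopifnot(length(dim(joint3)) == 3L)
  pz <- apply(joint3, 3L, sum)
  out <- 0
  for (z in seq_along(pz)) {
    if (pz[z] <= 0) next
    out <- out + pz[z] * mutual_information(joint3[, , z] / pz[z])
  }
  max(out, 0)
}

# joint P(x, l0, l1) at time index k (k = 0 means the pre-switch ensemble,
# where x is drawn from p_ss^{l0} independently of l1 given l0)
.joint3_at <- function(traj, k) {
  ids <- traj$protocol$ids
  nk <- length(ids)
  n <- dim(traj$p)[1]
  out <- array(0, c(n, nk, nk))
  for (j0 in seq_len(nk)) {
    for (j1 in seq_len(nk)) {
      px <- if (k == 0L) traj$p0[, j0] else traj$p[, k, j0, j1]
      out[, j0, j1] <- traj$weights[j0, j1] * px
    }
  }
  out
}

# S_x, I(x; l1), I(x; l0 | l1) at one time index (0 = pre-switch)
.info_at <- function(traj, k) {
  j3 <- .joint3_at(traj, k)
  jx1 <- apply(j3, c(1, 3), sum)
  list(
    S_x = shannon_entropy(rowSums(jx1)),
    I_meas = mutual_information(jx1),
    I_era = conditional_mutual_information(j3)
  )
}

#' Information ledger of a signal-switch ensemble
#'
#' Tracks, on the trajectory grid, the system entropy `S_x` (of the
#' marginal over all branches), the measured information
#' `I_meas = I(x_t; l1)` about the new signal, the remaining information
#' `I_era_remaining = I(x_t; l0 | l1)` about the old signal (direct
#' correlations only), and — when the state space has the named memory and
#' activity coordinates — the chain-rule split
#' `I_meas = I(m_t; l1) + I(a_t; l1 | m_t) = I_mem + I_act`.
#'
#' All values are in nats; convert with [to_bits()] for reporting.
#'
#' @param traj an [ensemble_propagate()] result.
#' @param memory_coord,activity_coord coordinate names for the memory /
#'   activity split, or `NULL` to skip it (columns become `NA`).
#' @return data.frame of class `info_ledger` with columns `time`, `S_x`,
#'   `I_meas`, `I_era_remaining`, `I_mem`, `I_act`; attribute
#'   `units = "nats"`.
#' @export
information_decomposition <- function(traj, memory_coord = "m",
                                      activity_coord = "a") {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  nt <- length(traj$times)
  ids <- traj$protocol$ids
  nk <- length(ids)
  split_coords <- !is.null(memory_coord) && !is.null(activity_coord)
  if (split_coords) {
    mv <- coord_values(traj$model$space, memory_coord)
    av <- coord_values(traj$model$space, activity_coord)
    mlev <- sort(unique(mv))
    alev <- sort(unique(av))
    mi <- match(mv, mlev)
    ai <- match(av, alev)
  }
  S_x <- I_meas <- I_era <- I_mem <- I_act <- rep(NA_real_, nt)
  for (k in seq_len(nt)) {
    j3 <- .joint3_at(traj, k)
    jx1 <- apply(j3, c(1, 3), sum)
    S_x[k] <- shannon_entropy(rowSums(jx1))
    I_meas[k] <- mutual_information(jx1)
    I_era[k] <- conditional_mutual_information(j3)
    if (split_coords) {
      jm1 <- rowsum(jx1, mi, reorder = TRUE)
      I_mem[k] <- mutual_information(jm1)
      # joint (a, l1, m): conditioning variable last
      ja1m <- array(0, c(length(alev), nk, length(mlev)))
      for (s in seq_len(nrow(jx1))) {
        ja1m[ai[s], , mi[s]] <- ja1m[ai[s], , mi[s]] + jx1[s, ]
      }
      I_act[k] <- conditional_mutual_information(ja1m)
    }
  }
  out <- data.frame(
    time = traj$times, S_x = S_x, I_meas = I_meas,
    I_era_remaining = I_era, I_mem = I_mem, I_act = I_act
  )
  attr(out, "units") <- "nats"
  class(out) <- c("info_ledger", class(out))
  out
}

# columns measured in nats (entropies and informations) across ledgers
.info_unit_cols <- c(
  "S_x", "S_cond", "I_meas", "I_era_remaining", "I_mem", "I_act",
  "I_era_bits", "bits_measured", "bits_erased"
)

#' Convert an information ledger between nats and bits
#'
#' Divides (or multiplies) every entropy/information column by `log(2)`.
#' Thermodynamic columns (kT, k_B) are untouched.
#'
#' @param ledger a ledger data.frame with a `units` attribute.
#' @return the converted ledger.
#' @export
to_bits <- function(ledger) {
  units <- attr(ledger, "units")
  if (identical(units, "bits")) return(ledger)
  cols <- intersect(.info_unit_cols, names(ledger))
  ledger[cols] <- lapply(ledger[cols], function(v) v / log(2))
  attr(ledger, "units") <- "bits"
  ledger
}

#' @rdname to_bits
#' @export
to_nats <- function(ledger) {
  units <- attr(ledger, "units")
  if (identical(units, "nats")) return(ledger)
  cols <- intersect(.info_unit_cols, names(ledger))
  ledger[cols] <- lapply(ledger[cols], function(v) v * log(2))
  attr(ledger, "units") <- "nats"
  ledger
}
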