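#' Signal-conditioned continuous-time Markov rate model
#'
#' Bundles one rate matrix per signal level over a common state space,
#' together with the local-detailed-balance bookkeeping: per-state energies
#' `E(x; l)` (in kT) and an integer fuel stoichiometry `nu` per ordered
#' transition so that for every allowed jump
#' `log(W_l(x -> x') / W_l(x' -> x)) = -(E(x'; l) - E(x; l)) + dmu * nu(x -> x')`.
#'
#' Matrix convention: columns index source states, so probability column
#' vectors evolve as `dp/dt = W p`. Off-diagonals `W[i, j]` are the rates
#' `j -> i`; diagonals are set so columns sum to zero.
#'
#' @param space a [state_space()].
#' @param W named list (one entry per signal id) of square matrices of
#'   off-diagonal rates; diagonals are (re)computed by the constructor.
#' @param energy optional `n_states x n_signals` matrix of state energies in
#'   kT (columns named by signal id). Required by the heat/work ledgers.
#' @param energy_internal optional matrix of the same shape declaring the
#'   part of `energy` owned by the system (e.g. the receptor term of the
#'   chemoreceptor free energy); used by the excess-work ledger.
#' @param nu antisymmetric integer matrix of fuel molecules consumed on each
#'   jump `j -> i` (entry `[i, j]`); defaults to all zero (purely thermal).
#' @param dmu chemical potential per fuel molecule (kT); default 0.
#' @param check_affinity if `TRUE` (default) and `energy` is given, verify
#'   the local-detailed-balance decomposition to `tol_affinity`.
#' @param tol_affinity tolerance for the affinity decomposition check.
#' @return object of class `rate_model`.
#' @export
rate_model <- function(space, W, energy = NULL, energy_internal = NULL,
                       nu = NULL, dmu = 0,
                       check_affinity = TRUE, tol_affinity = 1e-10) {
  stopifnot(inherits(space, "state_space"))
  n <- n_states(space)
  if (is.null(names(W)) || any(!nzchar(names(W)))) {
    stop("W must be a named list: one rate matrix per signal id")
  }
  ids <- names(W)
  W <- lapply(W, function(w) {
    w <- as.matrix(w)
    if (!all(dim(w) == n)) stop("rate matrix dimension does not match state space")
    off <- w
    diag(off) <- 0
    if (any(off < 0)) stop("off-diagonal rates must be nonnegative")
    diag(w) <- 0
    diag(w) <- -colSums(w)
    dimnames(w) <- list(space$labels, space$labels)
    w
  })
  if (is.null(nu)) nu <- matrix(0L, n, n)
  nu <- as.matrix(nu)
  if (!all(dim(nu) == n)) stop("nu dimension does not match state space")
  if (max(abs(nu + t(nu))) > 0) stop("nu must be antisymmetric")
  if (max(abs(nu - round(nu))) > 1e-12) stop("nu must be integer-valued")
  for (id in ids) {
    .check_reversible(W[[id]], space, id)
    .check_irreducible(W[[id]], space, id)
  }
  if (!is.null(energy)) {
    energy <- as.matrix(energy)
    if (nrow(energy) != n || ncol(energy) != length(ids)) {
      stop("energy must be an n_states x n_signals matrix")
    }
    if (any(!is.finite(energy))) stop("energies must be finite")
    colnames(energy) <- ids
    rownames(energy) <- space$labels
  }
  if (!is.null(energy_internal)) {
    energy_internal <- as.matrix(energy_internal)
    if (nrow(energy_internal) != n || ncol(energy_internal) != length(ids)) {
      stop("energy_internal must be an n_states x n_signals matrix")
    }
    colnames(energy_internal) <- ids
    rownames(energy_internal) <- space$labels
  }
  model <- structure(
    list(
      space = space, signals = ids, W = W,
      energy = energy, energy_internal = energy_internal,
      nu = nu, dmu = dmu, beta = 1
    ),
    class = "rate_model"
  )
  if (check_affinity && !is.null(energy)) {
    for (id in ids) {
      dec <- affinity_decomposition_error(model, id)
      if (dec > tol_affinity) {
        stop(sprintf(
          "affinity decomposition fails for signal '%s': max |log-ratio - (-dE + dmu*nu)| = %.3g",
          id, dec
        ))
      }
    }
  }
  model
}

.check_reversible <- function(w, space, id) {
  off <- w
  diag(off) <- 0
  bad <- which((off > 0) != (t(off) > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "signal '%s': transition %s -> %s has a rate but its reverse is zero (irreversible jump)",
      id, space$labels[j], space$labels[i]
    ))
  }
}

.check_irreducible <- function(w, space, id) {
  comp <- .connected_components(w)
  if (max(comp) > 1L) {
    blocks <- split(space$labels, comp)
    stop(sprintf(
      "signal '%s': generator is reducible; disconnected blocks: %s",
      id,
      paste(vapply(blocks, function(b) paste0("{", paste(b, collapse = ", "), "}"),
                   character(1)), collapse = " ")
    ))
  }
}

# components of the (symmetrized) support graph, by breadth-first search
.connected_components <- function(w) {
  n <- nrow(w)
  adj <- (w > 0) | (t(w) > 0)
  diag(adj) <- FALSE
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[, v] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Generator matrix for one signal level
#' @param model a `rate_model`.
#' @param l signal value or id.
#' @return the `n x n` generator (columns sum to zero).
#' @export
generator <- function(model, l) {
  id <- .signal_id(model, l)
  model$W[[id]]
}

.signal_id <- function(model, l) {
  id <- as.character(l)
  if (!id %in% model$signals) {
    stop(sprintf(
      "unknown signal '%s'; model signals: %s",
      id, paste(model$signals, collapse = ", ")
    ))
  }
  id
}

#' Per-transition affinities and their decomposition
#'
#' For every allowed ordered transition `j -> i` returns the log rate ratio
#' `A[i, j] = log(W[i, j] / W[j, i])` together with its energetic part
#' `-(E[i] - E[j])` and chemical part `dmu * nu[i, j]` (both in units of
#' kT = k_B T with T = 1). Entries for disallowed transitions are `NA`.
#'
#' @inheritParams generator
#' @return list with matrices `affinity`, `energy_part`, `chemical_part`
#'   and logical `support`.
#' @export
affinity_of <- function(model, l) {
  id <- .signal_id(model, l)
  w <- model$W[[id]]
  off <- w
  diag(off) <- 0
  sup <- off > 0
  aff <- matrix(NA_real_, nrow(w), ncol(w))
  aff[sup] <- log(off[sup] / t(off)[sup])
  en <- ch <- matrix(NA_real_, nrow(w), ncol(w))
  if (!is.null(model$energy)) {
    e <- model$energy[, id]
    de <- outer(e, e, `-`) # de[i, j] = E[i] - E[j]
    en[sup] <- -de[sup]
    ch[sup] <- model$dmu * model$nu[sup]
  }
  list(affinity = aff, energy_part = en, chemical_part = ch, support = sup)
}

affinity_decomposition_error <- function(model, l) {
  a <- affinity_of(model, l)
  if (!any(a$support)) return(0)
  max(abs(a$affinity[a$support] - a$energy_part[a$support] - a$chemical_part[a$support]))
}

#' Stationary distribution of a signal-conditioned generator
#'
#' Solves `W_l p = 0` with `sum(p) = 1` by singular value decomposition,
#' taking the right singular vector of the smallest singular value. Small
#' negative entries (above `-1e-12`) are clipped to zero and the vector is
#' renormalized; larger negatives, a degenerate null space, or a residual
#' `max |W p|` above `1e-10` raise an error.
#'
#' @inheritParams generator
#' @return probability vector over states, named by state labels.
#' @export
stationary_distribution <- function(model, l) {
  id <- .signal_id(model, l)
  w <- model$W[[id]]
  sv <- svd(w)
  n <- nrow(w)
  if (n >= 2 && sv$d[n - 1] < 1e-10 * max(sv$d[1], 1)) {
    stop("generator has multiple null vectors (degenerate stationary state)")
  }
  p <- sv$v[, n]
  p <- p / sum(p)
  if (min(p) < -1e-12) {
    stop(sprintf(
      "stationary solve produced a negative probability (%.3g); generator ill-conditioned",
      min(p)
    ))
  }
  p[p < 0] <- 0
  p <- p / sum(p)
  resid <- max(abs(w %*% p))
  if (resid > 1e-10) {
    stop(sprintf("stationary residual %.3g exceeds 1e-10", resid))
  }
  stats::setNames(p, model$space$labels)
}

#' Detailed balance check
#'
#' Tests whether the stationary state of `W_l` carries zero net flux on
#' every transition: `max |W(x -> x') p_ss(x) - W(x' -> x) p_ss(x')| < tol`.
#'
#' @inheritParams generator
#' @param tol tolerance on the maximum stationary net flux.
#' @return list with `balanced` (logical) and `max_violation`.
#' @export
is_detailed_balanced <- function(model, l, tol = 1e-9) {
  id <- .signal_id(model, l)
  w <- model$W[[id]]
  off <- w
  diag(off) <- 0
  p <- stationary_distribution(model, id)
  flux <- sweep(off, 2L, p, `*`) # flux[i, j] = W(j -> i) p(j)
  viol <- max(abs(flux - t(flux)))
  list(balanced = viol < tol, max_violation = viol)
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(
    "<rate_model> %d states, signals {%s}, dmu = %g kT%s\n",
    n_states(x), paste(x$signals, collapse = ", "), x$dmu,
    if (is.null(x$energy)) " (no energy bookkeeping)" else ""
  ))
  invisible(x)
}

#' Serialize a rate model to JSON
#'
#' Writes state labels, per-signal dense rate matrices, per-state energies,
#' fuel stoichiometry, `beta` and `dmu` so the model can be rebuilt exactly.
#'
#' @param model a `rate_model`.
#' @param path file path; `NULL` returns the JSON string.
#' @return path (invisibly) or JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    coords = model$space$coords,
    labels = model$space$labels,
    signals = model$signals,
    W = lapply(model$W, unname),
    energy = if (is.null(model$energy)) NULL else unname(model$energy),
    energy_internal = if (is.null(model$energy_internal)) NULL else unname(model$energy_internal),
    nu = unname(model$nu),
    dmu = model$dmu,
    beta = model$beta
  )
  # I(17) = 17 significant digits: doubles round-trip exactly
  txt <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Rebuild a rate model from its JSON serialization
#' @param path file path or JSON string produced by [model_to_json()].
#' @return a `rate_model`.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  sp <- state_space(obj$coords)
  W <- lapply(obj$W, as.matrix)
  names(W) <- obj$signals
  rate_model(
    sp, W,
    energy = if (is.null(obj$energy)) NULL else as.matrix(obj$energy),
    energy_internal = if (is.null(obj$energy_internal)) NULL else as.matrix(obj$energy_internal),
    nu = as.matrix(obj$nu), dmu = obj$dmu
  )
}
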