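#' Binary signal-switch protocol
#'
#' The environment holds a random signal level `l0` drawn from `prior`; at
#' time 0 it is abruptly switched to `l1` drawn from `kernel[l0, ]` and then
#' held fixed. The ensemble over the four (or `k^2`) signal pairs is what
#' the information and entropy-production ledgers average over.
#'
#' The default prior and switch kernel are uniform and independent, so both
#' the "switch" and "stay" branches carry weight. A deterministic
#' (invertible) kernel makes the conditional information `I(x; l0 | l1)`
#' identically zero and degenerates the erasure ledger; such protocols are
#' allowed but flagged.
#'
#' @param values the signal levels, e.g. `c(0, 1)` or ligand concentrations
#'   in uM. Coerced to character ids internally.
#' @param prior probability vector `P(l0)` over `values`.
#' @param kernel row-stochastic matrix `P(l1 | l0)`; rows index `l0`.
#' @return object of class `signal_protocol`.
#' @examples
#' signal_protocol()
#' signal_protocol(c(94, 720))
#' @export
signal_protocol <- function(values = c(0, 1),
                            prior = NULL,
                            kernel = NULL) {
  k <- length(values)
  if (k < 2L) stop("a signal protocol needs at least two signal levels")
  ids <- as.character(values)
  if (anyDuplicated(ids)) stop("signal values must be distinct")
  if (is.null(prior)) prior <- rep(1 / k, k)
  if (is.null(kernel)) kernel <- matrix(1 / k, k, k)
  kernel <- as.matrix(kernel)
  stopifnot(length(prior) == k, all(dim(kernel) == k))
  .check_distribution(prior, "prior")
  for (i in seq_len(k)) .check_distribution(kernel[i, ], sprintf("kernel row %d", i))
  weights <- prior * kernel # P(l0, l1), rows l0
  dimnames(weights) <- list(l0 = ids, l1 = ids)
  structure(
    list(
      values = values, ids = ids, prior = stats::setNames(prior, ids),
      kernel = kernel, weights = weights, switch_time = 0,
      degenerate = any(weights == 1)
    ),
    class = "signal_protocol"
  )
}

.check_distribution <- function(p, what, tol = 1e-12) {
  if (any(p < -tol)) {
    stop(sprintf("%s has negative entries (min %.3g)", what, min(p)))
  }
  if (abs(sum(p) - 1) > max(tol, 1e-12)) {
    stop(sprintf("%s does not sum to 1 (sum %.15g)", what, sum(p)))
  }
  invisible(TRUE)
}

#' @export
print.signal_protocol <- function(x, ...) {
  cat(sprintf(
    "<signal_protocol> levels {%s}, prior (%s)%s\n",
    paste(x$ids, collapse = ", "),
    paste(signif(x$prior, 3), collapse = ", "),
    if (x$degenerate) " [degenerate: a branch has weight 1]" else ""
  ))
  invisible(x)
}
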