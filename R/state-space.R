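#' Discrete state space of a sensory module
#'
#' A finite, ordered collection of composite states. Each state is a row of
#' named coordinates, e.g. activity `a` in `{0, 1}` and memory `m` in
#' `{0, ..., M - 1}`. The row order fixes the integer index used by every
#' rate matrix and probability vector in the package.
#'
#' @param coords data.frame with one row per state and one column per named
#'   coordinate. Rows must be unique and there must be at least two states.
#' @return An object of class `state_space` with fields `coords` (the
#'   data.frame) and `labels` (character labels such as `"a=1,m=0"`).
#' @examples
#' sp <- state_space(expand.grid(a = 0:1, m = 0:1))
#' n_states(sp)
#' @export
state_space <- function(coords) {
  coords <- as.data.frame(coords)
  if (nrow(coords) < 2L) {
    stop("a state space needs at least 2 states")
  }
  if (is.null(names(coords)) || any(!nzchar(names(coords)))) {
    stop("every coordinate must be named")
  }
  labels <- apply(coords, 1L, function(row) {
    paste(sprintf("%s=%s", names(coords), row), collapse = ",")
  })
  if (anyDuplicated(labels)) {
    stop("state labels are not unique: duplicated coordinate rows")
  }
  structure(
    list(coords = coords, labels = unname(labels)),
    class = "state_space"
  )
}

#' Number of states
#' @param x a `state_space` or `rate_model`.
#' @return integer count of states.
#' @export
n_states <- function(x) UseMethod("n_states")

#' @export
n_states.state_space <- function(x) nrow(x$coords)

#' @export
n_states.rate_model <- function(x) nrow(x$space$coords)

#' Values of one coordinate across all states
#' @param space a `state_space`.
#' @param name coordinate name, e.g. `"m"`.
#' @return vector of that coordinate, ordered as the states.
#' @export
coord_values <- function(space, name) {
  if (!name %in% names(space$coords)) {
    stop(sprintf(
      "coordinate '%s' not found; available: %s",
      name, paste(names(space$coords), collapse = ", ")
    ))
  }
  space$coords[[name]]
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "<state_space> %d states over coordinates: %s\n",
    n_states(x), paste(names(x$coords), collapse = ", ")
  ))
  invisible(x)
}
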