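#' Joint state space of a set of subsystems
#'
#' A composite process evolves over the Cartesian product of finite
#' per-subsystem state domains.  The joint states are totally ordered
#' lexicographically: the first declared subsystem is the most significant
#' coordinate, and within each subsystem the declared domain order is used.
#' All generators, distributions and kernels in the package are indexed in
#' this order.
#'
#' @param domains named list; one entry per subsystem, each a vector of at
#'   least two distinct state labels (coerced to character).  Names give the
#'   subsystem identifiers and their order.
#' @return an object of class `state_space` with fields `subsystems`,
#'   `domains`, `states` (character matrix, one row per joint state),
#'   `labels` (comma-joined serialization of each joint state) and
#'   `n_states`.
#' @examples
#' sp <- state_space(list(A = c("0", "1"), B = c("0", "1")))
#' sp$labels
#' @export
state_space <- function(domains) {
  if (is.null(names(domains)) || any(names(domains) == ""))
    stop("state_space: domains must be a named list")
  if (anyDuplicated(names(domains)))
    stop("state_space: duplicated subsystem identifiers")
  domains <- lapply(domains, function(d) as.character(d))
  for (id in names(domains)) {
    d <- domains[[id]]
    if (length(d) < 2L)
      stop("state_space: subsystem '", id, "' needs at least 2 states")
    if (anyDuplicated(d))
      stop("state_space: subsystem '", id, "' has duplicated state labels")
  }
  subsystems <- names(domains)
  ## expand.grid varies the first factor fastest; feed it the reversed
  ## domain list and reverse the columns back to get lexicographic order
  ## with the first subsystem most significant.
  g <- expand.grid(rev(domains), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  states <- as.matrix(g[, rev(seq_along(domains)), drop = FALSE])
  colnames(states) <- subsystems
  labels <- apply(states, 1L, paste, collapse = ",")
  structure(
    list(subsystems = subsystems, domains = domains, states = states,
         labels = unname(labels), n_states = nrow(states),
         index = stats::setNames(seq_len(nrow(states)), labels)),
    class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", length(x$subsystems), " subsystems, ",
      x$n_states, " joint states\n", sep = "")
  for (id in x$subsystems)
    cat("  ", id, ": {", paste(x$domains[[id]], collapse = ", "), "}\n",
        sep = "")
  invisible(x)
}

#' Serialize a joint state to its canonical label
#'
#' @param space a [state_space()].
#' @param state named character vector with one entry per subsystem.
#' @return the comma-joined label in declared subsystem order.
#' @export
state_label <- function(space, state) {
  paste(state[space$subsystems], collapse = ",")
}

state_index <- function(space, state) {
  i <- space$index[[state_label(space, state)]]
  if (is.null(i)) stop("unknown state: ", state_label(space, state))
  i
}

#' Marginal state space of a subsystem subset
#'
#' @param space a [state_space()].
#' @param members subsystem identifiers to keep (order is normalized to the
#'   declared subsystem order).
#' @return a [state_space()] over the members.
#' @export
marginal_space <- function(space, members) {
  members <- normalize_members(space, members)
  state_space(space$domains[members])
}

## Subsystem subsets are always stored in declared order; validates names.
normalize_members <- function(space, members) {
  members <- unique(as.character(members))
  unknown <- setdiff(members, space$subsystems)
  if (length(unknown))
    stop("unknown subsystem identifier(s): ", paste(unknown, collapse = ", "))
  space$subsystems[space$subsystems %in% members]
}

## Integer map: full joint state index -> marginal state index over members.
projection_index <- function(space, members) {
  members <- normalize_members(space, members)
  sub <- marginal_space(space, members)
  lab <- apply(space$states[, members, drop = FALSE], 1L, paste,
               collapse = ",")
  unname(sub$index[lab])
}

#' Marginalize a joint distribution onto a subsystem subset
#'
#' @param p probability vector over the joint states of `space`.
#' @param space a [state_space()].
#' @param members subsystem identifiers of the marginal.
#' @return probability vector over [marginal_space()] states.
#' @export
marginalize <- function(p, space, members) {
  idx <- projection_index(space, members)
  n_sub <- prod(lengths(space$domains[normalize_members(space, members)]))
  as.vector(rowsum(p, group = factor(idx, levels = seq_len(n_sub))))
}

#' Uniform distribution over a state space
#' @param space a [state_space()].
#' @return probability vector.
#' @export
uniform_distribution <- function(space) {
  rep(1 / space$n_states, space$n_states)
}

#' Point (delta) distribution on a single joint state
#' @param space a [state_space()].
#' @param state named character vector or a canonical label.
#' @return probability vector.
#' @export
point_distribution <- function(space, state) {
  i <- if (is.character(state) && length(state) == 1L && is.null(names(state)))
    space$index[[state]] else state_index(space, state)
  if (is.null(i)) stop("unknown state label: ", state)
  p <- numeric(space$n_states)
  p[i] <- 1
  p
}
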