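#' Piecewise-constant periodic rate protocol
#'
#' Mechanism rates may be driven in time by a piecewise-constant periodic
#' protocol: the period `[0, period)` is split into segments starting at the
#' offsets in `times`, and each rate entry carries one rate per segment.
#' Constant mechanisms simply omit the protocol.
#'
#' @param period protocol period (finite, > 0).
#' @param times strictly increasing segment start offsets in `[0, period)`;
#'   the first must be 0.
#' @return an object of class `rate_protocol`.
#' @export
rate_protocol <- function(period, times = 0) {
  if (!is.finite(period) || period <= 0) stop("rate_protocol: period must be finite and > 0")
  times <- as.numeric(times)
  if (times[1] != 0) stop("rate_protocol: first segment must start at 0")
  if (any(diff(times) <= 0) || any(times >= period))
    stop("rate_protocol: times must be strictly increasing within [0, period)")
  structure(list(period = period, times = times,
                 n_segments = length(times)), class = "rate_protocol")
}

## Segment index active at time t (protocol NULL means a single segment).
protocol_segment <- function(protocol, t) {
  if (is.null(protocol)) return(1L)
  tt <- t - floor(t / protocol$period + 1e-12) * protocol$period
  findInterval(tt + 1e-12, protocol$times)
}

## All protocol switching times strictly inside (t0, t1).
protocol_breakpoints <- function(protocol, t0, t1) {
  if (is.null(protocol)) return(numeric(0))
  k0 <- floor(t0 / protocol$period) - 1
  k1 <- ceiling(t1 / protocol$period) + 1
  bp <- as.vector(outer(protocol$times, (k0:k1) * protocol$period, `+`))
  bp[bp > t0 + 1e-12 & bp < t1 - 1e-12]
}

#' Declare a mechanism of a composite process
#'
#' A mechanism is a coupling (reservoir) responsible for a class of
#' transitions.  It can reassign only the coordinates in its puppet set, and
#' its rates may depend on the source state only through its leader set
#' (the puppets together with their parents in the dependency network).
#'
#' @param id mechanism label.
#' @param puppets subsystem identifiers the mechanism can change.
#' @param rates list of entries `list(from = , to = , rate = )`, where
#'   `from` is a (possibly partial) named assignment of leader-set
#'   coordinates of the source state, `to` a (possibly partial) named
#'   assignment of puppet coordinates of the target state, and `rate` a
#'   nonnegative scalar (constant mechanism) or vector with one rate per
#'   protocol segment.
#' @param protocol optional [rate_protocol()].
#' @return an object of class `mechanism` (compiled against a state space
#'   when the process is constructed).
#' @export
mechanism <- function(id, puppets, rates, protocol = NULL) {
  if (!is.character(id) || length(id) != 1L) stop("mechanism: id must be a single string")
  puppets <- as.character(puppets)
  if (!length(puppets)) stop("mechanism '", id, "': empty puppet set")
  if (!is.null(protocol) && !inherits(protocol, "rate_protocol"))
    stop("mechanism '", id, "': protocol must be a rate_protocol")
  structure(list(id = id, puppets = puppets, rates = rates,
                 protocol = protocol), class = "mechanism")
}

## ---- compilation -----------------------------------------------------

## Expand the user-level rate entries of a mechanism into a canonical full
## table over (complete conditioning assignment, complete target puppet
## assignment).  The conditioning set always contains the puppets, so a
## partial `to` can be resolved against the source.  Duplicate expanded
## keys have their rates summed.
compile_mechanism <- function(mech, space) {
  n_seg <- if (is.null(mech$protocol)) 1L else mech$protocol$n_segments
  puppets <- normalize_members(space, mech$puppets)
  cond_names <- unique(unlist(lapply(mech$rates, function(e) names(e$from))))
  cond <- normalize_members(space, union(cond_names, puppets))

  from_rows <- list(); to_rows <- list(); rate_rows <- list()
  k <- 0L
  for (e in mech$rates) {
    if (is.null(e$rate) || any(e$rate < 0) || !length(e$rate))
      stop("mechanism '", mech$id, "': missing or negative rate")
    rate <- as.numeric(e$rate)
    if (length(rate) == 1L) rate <- rep(rate, n_seg)
    if (length(rate) != n_seg)
      stop("mechanism '", mech$id, "': rate vector length must match protocol segments")
    from <- as.character(e$from); names(from) <- names(e$from)
    to <- as.character(e$to); names(to) <- names(e$to)
    if (length(setdiff(names(to), puppets)))
      stop("mechanism '", mech$id, "': target reassigns non-puppet coordinate(s): ",
           paste(setdiff(names(to), puppets), collapse = ", "))
    for (nm in names(from))
      if (!from[[nm]] %in% space$domains[[nm]])
        stop("mechanism '", mech$id, "': unknown state '", from[[nm]],
             "' for subsystem '", nm, "'")
    for (nm in names(to))
      if (!to[[nm]] %in% space$domains[[nm]])
        stop("mechanism '", mech$id, "': unknown state '", to[[nm]],
             "' for subsystem '", nm, "'")
    ## expand the unspecified conditioning coordinates
    free <- setdiff(cond, names(from))
    grid <- if (length(free))
      expand.grid(space$domains[free], KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE)
    else data.frame(row.names = 1)
    for (r in seq_len(max(1L, nrow(grid)))) {
      src <- character(length(cond)); names(src) <- cond
      src[names(from)] <- from
      if (length(free)) src[free] <- unlist(grid[r, , drop = TRUE])
      tgt <- src[puppets]
      tgt[names(to)] <- to
      if (identical(unname(tgt), unname(src[puppets]))) next  # no state change
      k <- k + 1L
      from_rows[[k]] <- src
      to_rows[[k]] <- tgt
      rate_rows[[k]] <- rate
    }
  }
  if (k == 0L)
    stop("mechanism '", mech$id, "': no state-changing transitions")
  from_mat <- do.call(rbind, from_rows)
  to_mat <- matrix(unlist(to_rows), ncol = length(puppets), byrow = TRUE,
                   dimnames = list(NULL, puppets))
  rate_mat <- matrix(unlist(rate_rows), ncol = n_seg, byrow = TRUE)
  ## merge duplicates (same source conditioning + same target)
  key <- paste(apply(from_mat, 1L, paste, collapse = ","),
               apply(to_mat, 1L, paste, collapse = ","), sep = ">")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    rate_mat <- rowsum(rate_mat, group = key)[unique(key), , drop = FALSE]
    from_mat <- from_mat[keep, , drop = FALSE]
    to_mat <- to_mat[keep, , drop = FALSE]
    key <- key[keep]
  }
  nonzero <- rowSums(rate_mat) > 0
  structure(list(id = mech$id, puppets = puppets, cond = cond,
                 from = from_mat[nonzero, , drop = FALSE],
                 to = to_mat[nonzero, , drop = FALSE],
                 rate = rate_mat[nonzero, , drop = FALSE],
                 protocol = mech$protocol, n_segments = n_seg),
            class = "compiled_mechanism")
}

## ---- dependency networks ---------------------------------------------

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.list(edges) && !length(edges)))
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  if (is.matrix(edges)) {
    m <- edges
  } else if (is.data.frame(edges)) {
    m <- as.matrix(edges[, 1:2])
  } else if (is.list(edges)) {
    m <- do.call(rbind, lapply(edges, function(e) as.character(e[1:2])))
  } else stop("dependencies: cannot interpret edge list")
  colnames(m) <- c("from", "to")
  m <- unique(m)
  if (any(m[, 1] == m[, 2]))
    stop("dependency network: self-loops are not allowed (self-dependency is implicit)")
  m
}

dep_parents <- function(edges, i) unname(edges[edges[, 2] == i, 1])

#' Leader set of a mechanism
#'
#' The leader set is the union, over the mechanism's puppets, of each puppet
#' together with its parents in the dependency network.  It is always a
#' superset of the puppet set and is the largest set of coordinates the
#' mechanism's rates may depend on.
#'
#' @param process a [composite_process()].
#' @param id mechanism id.
#' @return character vector of subsystem identifiers in declared order.
#' @export
leader_set <- function(process, id) {
  m <- process$mechanisms[[id]]
  if (is.null(m)) stop("unknown mechanism id: ", id)
  m$leaders
}

compute_leaders <- function(space, edges, puppets) {
  l <- puppets
  for (i in puppets) l <- union(l, dep_parents(edges, i))
  normalize_members(space, l)
}

## ---- process ----------------------------------------------------------

#' Construct and validate a composite process
#'
#' A composite process is a continuous-time Markov chain over the joint
#' state space of several subsystems whose rate matrix is a sum of
#' mechanism-specific rate matrices.  Each mechanism reassigns only its
#' puppet-set coordinates and its rates depend on the source state only
#' through its leader set.  Validation enforces: declared dependency edges
#' cover every inferred rate dependence; conditioning coordinates lie inside
#' leader sets; every mechanism generator conserves probability; and every
#' mechanism is reversible (a transition has positive rate iff its reverse
#' does), which every entropy-production formula in the package requires.
#'
#' @param space a [state_space()].
#' @param mechanisms list of [mechanism()] declarations.
#' @param dependencies edge list (two-column matrix / data.frame / list of
#'   pairs `c(parent, child)`), or the string `"infer"` to adopt the edges
#'   inferred from the rate tables.
#' @param check if `FALSE`, skip the (quadratic) dependency-inference
#'   consistency check; structural and reversibility validation always runs.
#' @return an object of class `composite_process`.
#' @seealso [mechanism()], [full_generator()], [is_unit()]
#' @export
composite_process <- function(space, mechanisms, dependencies = "infer",
                              check = TRUE) {
  if (!inherits(space, "state_space")) stop("space must be a state_space")
  if (!length(mechanisms)) stop("composite_process: no mechanisms")
  compiled <- lapply(mechanisms, function(m) {
    if (!inherits(m, "mechanism")) stop("mechanisms must be mechanism objects")
    unknown <- setdiff(m$puppets, space$subsystems)
    if (length(unknown))
      stop("mechanism '", m$id, "': unknown subsystem identifier(s): ",
           paste(unknown, collapse = ", "))
    compile_mechanism(m, space)
  })
  ids <- vapply(compiled, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicated mechanism ids")
  names(compiled) <- ids

  inferred <- infer_edges(space, compiled)
  if (identical(dependencies, "infer")) {
    edges <- inferred
  } else {
    edges <- as_edge_matrix(dependencies)
    unknown <- setdiff(c(edges), space$subsystems)
    if (length(unknown))
      stop("dependency network: unknown subsystem identifier(s): ",
           paste(unknown, collapse = ", "))
    if (check) {
      missing <- setdiff(edge_keys(inferred), edge_keys(edges))
      if (length(missing))
        stop("declared dependency network is missing inferred edge(s): ",
             paste(missing, collapse = "; "))
      extra <- setdiff(edge_keys(edges), edge_keys(inferred))
      if (length(extra))
        warning("dependency edge(s) declared but not realized by any mechanism: ",
                paste(extra, collapse = "; "))
    }
  }

  for (m in compiled) {
    leaders <- compute_leaders(space, edges, m$puppets)
    bad <- setdiff(m$cond, leaders)
    if (length(bad))
      stop("mechanism '", m$id, "': rates condition on non-leader coordinate(s): ",
           paste(bad, collapse = ", "))
  }
  compiled <- lapply(compiled, function(m) {
    m$leaders <- compute_leaders(space, edges, m$puppets)
    m
  })

  proc <- structure(
    list(space = space, mechanisms = compiled, dependency = edges,
         cache = new.env(parent = emptyenv())),
    class = "composite_process")
  check_reversibility(proc)
  proc
}

edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(edges[, 1], edges[, 2], sep = "->")
}

#' @export
print.composite_process <- function(x, ...) {
  cat("<composite_process> ", length(x$space$subsystems), " subsystems (",
      x$space$n_states, " joint states), ", length(x$mechanisms),
      " mechanisms, ", nrow(x$dependency), " dependency edges\n", sep = "")
  for (m in x$mechanisms)
    cat("  ", m$id, ": puppets {", paste(m$puppets, collapse = ","),
        "}, leaders {", paste(m$leaders, collapse = ","), "}",
        if (!is.null(m$protocol))
          paste0(", periodic (", m$protocol$n_segments, " segments, period ",
                 format(m$protocol$period), ")"),
        "\n", sep = "")
  invisible(x)
}

## Every mechanism generator must have a symmetric off-diagonal support in
## every protocol segment.
check_reversibility <- function(process) {
  for (m in process$mechanisms) {
    for (seg in seq_len(m$n_segments)) {
      K <- mechanism_generator_segment(process, m$id, seg)
      sup <- K > 0
      bad <- which(sup & !t(sup), arr.ind = TRUE)
      if (nrow(bad)) {
        i <- bad[1, 1]; j <- bad[1, 2]
        stop("mechanism '", m$id, "' is irreversible in segment ", seg,
             ": transition ", process$space$labels[j], " -> ",
             process$space$labels[i], " has no reverse")
      }
    }
  }
  invisible(TRUE)
}

## ---- generators -------------------------------------------------------

## Build (and cache) the generator of one mechanism in one protocol
## segment, over the joint state space.  Convention: K[x, x'] is the rate
## from x' to x; the diagonal holds negative column sums.
mechanism_generator_segment <- function(process, id, seg) {
  key <- paste0("G:", id, ":", seg)
  if (!is.null(process$cache[[key]])) return(process$cache[[key]])
  m <- process$mechanisms[[id]]
  if (is.null(m)) stop("unknown mechanism id: ", id)
  sp <- process$space
  n <- sp$n_states
  K <- matrix(0, n, n)
  states <- sp$states
  for (r in seq_len(nrow(m$from))) {
    rate <- m$rate[r, seg]
    if (rate == 0) next
    sel <- rep(TRUE, n)
    for (cn in m$cond) sel <- sel & (states[, cn] == m$from[r, cn])
    src <- which(sel)
    if (!length(src)) next
    tgt_states <- states[src, , drop = FALSE]
    tgt_states[, m$puppets] <- matrix(m$to[r, ], nrow = length(src),
                                      ncol = length(m$puppets), byrow = TRUE)
    tgt <- unname(sp$index[apply(tgt_states, 1L, paste, collapse = ",")])
    K[cbind(tgt, src)] <- K[cbind(tgt, src)] + rate
  }
  diag(K) <- diag(K) - colSums(K)
  process$cache[[key]] <- K
  K
}

#' Mechanism-specific rate matrix over the joint state space
#'
#' Entry `(x, x')`, `x != x'`, holds the rate at which the mechanism carries
#' the system from `x'` to `x`; it is nonzero only when the two states agree
#' outside the puppet set.  The diagonal holds negative column sums, so each
#' column sums to zero.
#'
#' @param process a [composite_process()].
#' @param id mechanism id.
#' @param t time at which to evaluate a driven mechanism (default 0).
#' @return a dense square matrix, columns indexed by source state.
#' @export
mechanism_generator <- function(process, id, t = 0) {
  m <- process$mechanisms[[id]]
  if (is.null(m)) stop("unknown mechanism id: ", id)
  mechanism_generator_segment(process, id, protocol_segment(m$protocol, t))
}

#' Full rate matrix of a composite process
#'
#' The sum of all mechanism-specific rate matrices.
#'
#' @inheritParams mechanism_generator
#' @return a dense square matrix whose columns sum to zero.
#' @export
full_generator <- function(process, t = 0) {
  Reduce(`+`, lapply(names(process$mechanisms),
                     function(id) mechanism_generator(process, id, t)))
}

## All protocol breakpoints of the whole process inside (t0, t1), sorted.
process_breakpoints <- function(process, t0, t1) {
  bp <- unlist(lapply(process$mechanisms,
                      function(m) protocol_breakpoints(m$protocol, t0, t1)))
  sort(unique(bp))
}

## ---- dependency inference ---------------------------------------------

## Edge (j, i) is inferred iff some mechanism with i in its puppet set has
## rates that genuinely vary with the j-coordinate of the source.
infer_edges <- function(space, compiled) {
  rows <- list(); k <- 0L
  for (m in compiled) {
    for (j in m$cond) {
      if (!mechanism_depends_on(space, m, j)) next
      for (i in setdiff(m$puppets, j)) {
        k <- k + 1L
        rows[[k]] <- c(j, i)
      }
    }
  }
  as_edge_matrix(rows)
}

mechanism_depends_on <- function(space, m, j) {
  others <- setdiff(m$cond, j)
  base <- paste(apply(m$from[, others, drop = FALSE], 1L, paste, collapse = ","),
                apply(m$to, 1L, paste, collapse = ","), sep = ">")
  jvals <- m$from[, j]
  dom <- space$domains[[j]]
  for (b in unique(base)) {
    sel <- base == b
    ## rates per j-value, defaulting to zero for absent combinations
    rates <- matrix(0, length(dom), ncol(m$rate),
                    dimnames = list(dom, NULL))
    rates[jvals[sel], ] <- m$rate[sel, , drop = FALSE]
    if (any(abs(sweep(rates, 2, rates[1, ], `-`)) > 0)) return(TRUE)
  }
  FALSE
}

#' Infer the dependency network realized by the rate tables
#'
#' Reconstructs the edge `(j, i)` whenever some mechanism acting on `i`
#' has rates that change when only the `j`-coordinate of the source state is
#' varied.  The declared network of a validated process is always a superset
#' of this inferred network.
#'
#' @param process a [composite_process()].
#' @return two-column character matrix of edges (`from` = parent).
#' @export
infer_dependency_network <- function(process) {
  infer_edges(process$space, process$mechanisms)
}
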