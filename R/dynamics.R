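## Resolve the generator-producing object: either a composite process (full
## system or one of its units) or a constant square rate matrix.
generator_at <- function(object, t, unit = NULL) {
  if (inherits(object, "composite_process")) {
    if (is.null(unit)) full_generator(object, t) else unit_generator(object, t = t, members = unit)
  } else if (is.matrix(object)) object
  else stop("expected a composite_process or a rate matrix")
}

#' Propagate a distribution under the master equation
#'
#' Solves `dp/dt = K(t) p` exactly: for constant generators by one matrix
#' exponential, for piecewise-constant protocols by a product of matrix
#' exponentials over the protocol segments.  Optionally returns the whole
#' solution on a time grid.
#'
#' @param object a [composite_process()] or a constant rate matrix.
#' @param p0 initial probability vector (over the joint space, or over the
#'   unit's marginal space when `unit` is given).
#' @param t1 final time.
#' @param t0 initial time (default 0).
#' @param unit optional subsystem subset: propagate the unit's marginal
#'   under its own generator.
#' @param grid optional vector of times in `[t0, t1]` at which to record the
#'   solution.
#' @return the final distribution; if `grid` is given, a list with `p`
#'   (final), `times` and `path` (matrix, one column per grid time).
#' @export
propagate <- function(object, p0, t1, t0 = 0, unit = NULL, grid = NULL) {
  gen <- function(t) generator_at(object, t, unit)
  n <- nrow(gen(t0))
  if (length(p0) != n) stop("propagate: dimension mismatch between p0 and generator")
  p0 <- normalize_distribution(p0, what = "p0")
  if (t1 < t0) stop("propagate: t1 < t0")
  bp <- if (inherits(object, "composite_process"))
    process_breakpoints(object, t0, t1) else numeric(0)
  record <- !is.null(grid)
  times <- sort(unique(c(t0, bp, t1, if (record) grid)))
  path <- if (record) matrix(NA_real_, n, length(times)) else NULL
  p <- p0
  if (record) path[, 1] <- p
  for (k in seq_along(times)[-1]) {
    dt <- times[k] - times[k - 1]
    if (dt > 0) {
      ## evaluate the generator inside the segment to dodge breakpoint ties
      K <- gen(times[k - 1] + dt / 2)
      p <- as.vector(expm_dense(K * dt) %*% p)
      p <- normalize_distribution(p, tol = 1e-8, what = "propagated distribution")
    }
    if (record) path[, k] <- p
  }
  if (record) {
    keep <- times %in% sort(unique(c(t0, t1, grid)))
    list(p = p, times = times[keep], path = path[, keep, drop = FALSE])
  } else p
}

#' Stationary distribution of an irreducible generator
#'
#' Solves `K p = 0` with the normalization constraint; fails loudly when the
#' transition graph is not strongly connected rather than silently
#' returning one communicating class's stationary vector.
#'
#' @param K square rate matrix (columns sum to zero; entry `(x, x')` is the
#'   rate from `x'` to `x`).
#' @return probability vector with residual `max |K p| <= 1e-10`.
#' @export
steady_state <- function(K) {
  n <- nrow(K)
  adj <- (t(K) > 0) * 1  # adjacency: row = source
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    classes <- split(seq_len(n), comp$membership)
    stop("generator is reducible; strongly connected classes: ",
         paste(vapply(classes, function(cl) paste0("{", paste(cl, collapse = ","), "}"), ""),
               collapse = " "))
  }
  A <- K
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- solve(A, b)
  p <- normalize_distribution(p, tol = 1e-8, what = "steady state")
  res <- max(abs(K %*% p))
  if (res > 1e-10)
    stop("steady_state: residual ", format(res), " exceeds 1e-10")
  p
}

#' Discrete-time propagator over one period
#'
#' The conditional distribution of the state at time `lambda` given the
#' state at time 0, as a column-stochastic matrix (columns indexed by the
#' source state).  For a process with driven mechanisms, every protocol
#' period must divide `lambda`, so that iterating the kernel reproduces the
#' dynamics over multiple periods.
#'
#' @param object a [composite_process()] or a constant rate matrix.
#' @param lambda period (> 0).
#' @param unit optional unit to restrict to.
#' @return square matrix with columns summing to 1.
#' @export
period_propagator <- function(object, lambda, unit = NULL) {
  if (lambda < 0) stop("period_propagator: lambda must be >= 0")
  gen <- function(t) generator_at(object, t, unit)
  n <- nrow(gen(0))
  if (lambda == 0) return(diag(n))
  if (inherits(object, "composite_process")) {
    relevant <- if (is.null(unit)) names(object$mechanisms)
    else unit_mechanisms(object, unit)
    for (m in object$mechanisms[relevant]) {
      if (is.null(m$protocol)) next
      ratio <- lambda / m$protocol$period
      if (abs(ratio - round(ratio)) > 1e-9)
        stop("period_propagator: protocol of mechanism '", m$id,
             "' (period ", format(m$protocol$period),
             ") is incommensurate with lambda = ", format(lambda))
    }
  }
  bp <- if (inherits(object, "composite_process"))
    process_breakpoints(object, 0, lambda) else numeric(0)
  times <- sort(unique(c(0, bp, lambda)))
  P <- diag(n)
  for (k in seq_along(times)[-1]) {
    dt <- times[k] - times[k - 1]
    K <- gen(times[k - 1] + dt / 2)
    P <- expm_dense(K * dt) %*% P
  }
  bad <- abs(colSums(P) - 1) > 1e-10
  if (any(bad)) stop("period_propagator: column sums deviate from 1")
  P[P < 0] <- 0
  sweep(P, 2, colSums(P), `/`)
}

## ---- trajectory sampling ---------------------------------------------

## Per-segment jump tables: for each source state, the possible targets,
## their rates, and the responsible mechanism.  Cached on the process.
jump_tables <- function(process, seg_times) {
  key <- paste0("J:", paste(format(seg_times), collapse = "|"))
  if (!is.null(process$cache[[key]])) return(process$cache[[key]])
  n <- process$space$n_states
  tabs <- lapply(seg_times, function(tm) {
    rows <- list()
    for (mi in seq_along(process$mechanisms)) {
      id <- names(process$mechanisms)[mi]
      K <- mechanism_generator(process, id, tm)
      nz <- which(K > 0, arr.ind = TRUE)  # off-diagonal positives only
      nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
      if (nrow(nz))
        rows[[length(rows) + 1L]] <-
          cbind(src = nz[, 2], target = nz[, 1],
                rate = K[nz], mech = mi)
    }
    all_tr <- if (length(rows)) do.call(rbind, rows) else
      matrix(0, 0, 4, dimnames = list(NULL, c("src", "target", "rate", "mech")))
    per_state <- lapply(seq_len(n), function(s)
      all_tr[all_tr[, "src"] == s, , drop = FALSE])
    exit <- vapply(per_state, function(tb) sum(tb[, "rate"]), 0)
    list(per_state = per_state, exit = exit)
  })
  process$cache[[key]] <- tabs
  tabs
}

#' Sample jump trajectories by the Gillespie algorithm
#'
#' Exact stochastic simulation of the composite process: exponential
#' waiting times from the total exit rate, mechanism and target drawn
#' proportionally to their rates.  At a protocol breakpoint the waiting
#' time is redrawn from the new rates, which is exact by memorylessness.
#' Each trajectory uses its own deterministic seed stream derived from
#' `seed`, so results do not depend on how many paths are requested.
#'
#' @param process a [composite_process()].
#' @param p0 initial distribution over the joint state space.
#' @param tau time horizon (> 0).
#' @param n number of independent paths (> 0).
#' @param seed integer root seed.
#' @return a list of `trajectory` objects, each with fields `initial`
#'   (state index), `jumps` (data.frame `time`, `mechanism`, `from`, `to`
#'   with state indices), `tau` and `seed`.
#' @export
sample_trajectories <- function(process, p0, tau, n, seed) {
  if (n <= 0) stop("sample_trajectories: n must be positive")
  if (tau <= 0) stop("sample_trajectories: tau must be positive")
  p0 <- normalize_distribution(p0, what = "p0")
  bp <- process_breakpoints(process, 0, tau)
  seg_edges <- c(0, bp, tau)
  seg_mid <- (seg_edges[-length(seg_edges)] + seg_edges[-1]) / 2
  tabs <- jump_tables(process, seg_mid)
  mech_ids <- names(process$mechanisms)
  out <- vector("list", n)
  for (path in seq_len(n)) {
    set.seed((seed + path * 10007L) %% .Machine$integer.max)
    x <- sample.int(process$space$n_states, 1L, prob = p0)
    x0 <- x
    t <- 0
    jt <- numeric(0); jm <- integer(0); jf <- integer(0); jto <- integer(0)
    seg <- 1L
    repeat {
      seg_end <- seg_edges[seg + 1L]
      tab <- tabs[[seg]]
      R <- tab$exit[x]
      if (R <= 0) {
        t <- seg_end
      } else {
        dt <- stats::rexp(1L, R)
        if (t + dt > seg_end) {
          t <- seg_end  # cross the breakpoint; redraw under new rates
        } else {
          t <- t + dt
          tb <- tab$per_state[[x]]
          row <- if (nrow(tb) == 1L) 1L else
            sample.int(nrow(tb), 1L, prob = tb[, "rate"])
          jt <- c(jt, t); jm <- c(jm, tb[row, "mech"])
          jf <- c(jf, x); jto <- c(jto, tb[row, "target"])
          x <- tb[row, "target"]
          next
        }
      }
      if (t >= tau - 1e-15) break
      seg <- seg + 1L
    }
    out[[path]] <- structure(
      list(initial = x0,
           jumps = data.frame(time = jt, mechanism = mech_ids[jm],
                              from = jf, to = jto),
           tau = tau, seed = seed),
      class = "trajectory")
  }
  out
}

#' Final state index of a trajectory
#' @param traj a `trajectory`.
#' @return joint-state index at the horizon.
#' @export
trajectory_endpoint <- function(traj) {
  as.integer(if (nrow(traj$jumps)) traj$jumps$to[nrow(traj$jumps)]
             else traj$initial)
}

## ---- empirical currents -----------------------------------------------

#' Define a current over a unit's transitions
#'
#' A current is a linear functional of the probability currents, specified
#' by an antisymmetric weight matrix over the unit's marginal states.  A
#' jump contributes its weight `C[to, from]`; jumps that do not change the
#' unit's coordinates contribute nothing.  An optional mechanism restriction
#' keeps only jumps mediated by that mechanism.
#'
#' @param process a [composite_process()].
#' @param members the unit carrying the current.
#' @param weights antisymmetric square matrix over the unit's marginal
#'   states.
#' @param mechanism optional mechanism id restriction.
#' @return an object of class `current_spec`.
#' @export
current_spec <- function(process, members, weights, mechanism = NULL) {
  members <- normalize_members(process$space, members)
  sub <- marginal_space(process$space, members)
  if (!is.matrix(weights) || nrow(weights) != sub$n_states ||
      ncol(weights) != sub$n_states)
    stop("current_spec: weight matrix dimension mismatch")
  if (max(abs(weights + t(weights))) > 0)
    stop("current_spec: weight matrix must be antisymmetric")
  if (!is.null(mechanism) && !mechanism %in% names(process$mechanisms))
    stop("current_spec: unknown mechanism id")
  structure(list(members = members, weights = weights, mechanism = mechanism,
                 proj = projection_index(process$space, members)),
            class = "current_spec")
}

#' Embed a current of a smaller unit into a larger unit
#'
#' The lifted current assigns to a transition of the larger unit the weight
#' of the induced transition of the smaller unit when the complementary
#' coordinates are unchanged, and zero otherwise (a jump that moves both
#' inside and outside the smaller unit carries no weight).
#'
#' @param process a [composite_process()].
#' @param spec a [current_spec()] on some unit.
#' @param members a larger unit containing `spec$members`.
#' @return a [current_spec()] on `members`.
#' @export
lift_current_spec <- function(process, spec, members) {
  sp <- process$space
  members <- normalize_members(sp, members)
  if (!all(spec$members %in% members))
    stop("lift_current_spec: target unit must contain the current's unit")
  big <- marginal_space(sp, members)
  small <- marginal_space(sp, spec$members)
  inner <- unname(small$index[apply(big$states[, spec$members, drop = FALSE],
                                    1L, paste, collapse = ",")])
  comp <- setdiff(members, spec$members)
  outer <- if (length(comp))
    apply(big$states[, comp, drop = FALSE], 1L, paste, collapse = ",")
  else rep("", big$n_states)
  n <- big$n_states
  W <- matrix(0, n, n)
  for (x in seq_len(n)) for (xp in seq_len(n)) {
    if (x == xp || outer[x] != outer[xp]) next
    W[x, xp] <- spec$weights[inner[x], inner[xp]]
  }
  current_spec(process, members, W, mechanism = spec$mechanism)
}

#' Time-integrated current of sampled trajectories
#'
#' @param trajectories list of trajectories from [sample_trajectories()].
#' @param spec a [current_spec()].
#' @return list with `values` (per path), `mean`, `var` (unbiased), `se`.
#' @export
empirical_current <- function(trajectories, spec) {
  vals <- vapply(trajectories, function(tr) {
    j <- tr$jumps
    if (!is.null(spec$mechanism)) j <- j[j$mechanism == spec$mechanism, , drop = FALSE]
    if (!nrow(j)) return(0)
    sum(spec$weights[cbind(spec$proj[j$to], spec$proj[j$from])])
  }, 0)
  list(values = vals, mean = mean(vals), var = stats::var(vals),
       se = stats::sd(vals) / sqrt(length(vals)))
}

#' Expected instantaneous current from a distribution
#'
#' Evaluates the same linear functional as [empirical_current()] from the
#' net probability currents at a given time: the sum over unordered state
#' pairs of `J * C`.
#'
#' @param process a [composite_process()].
#' @param spec a [current_spec()].
#' @param p distribution on the unit's marginal space.
#' @param t evaluation time.
#' @return list with `total` and per-mechanism contributions `by_mechanism`.
#' @export
expected_current_rate <- function(process, spec, p, t = 0) {
  ids <- unit_mechanisms(process, spec$members)
  if (!is.null(spec$mechanism)) {
    if (!spec$mechanism %in% ids)
      stop("mechanism '", spec$mechanism, "' does not act inside the unit")
    ids <- spec$mechanism
  }
  by_mech <- vapply(ids, function(id) {
    J <- net_current_matrix(process, spec$members, id, p, t)
    sum((J * spec$weights)[upper.tri(J)])
  }, 0)
  list(total = sum(by_mech), by_mechanism = by_mech)
}

## ---- trajectory I/O ---------------------------------------------------

#' Write trajectories to a TSV file
#'
#' Columns `path_id`, `t`, `mechanism`, `from_state`, `to_state`, with
#' states in the canonical comma-joined serialization.
#'
#' @param trajectories list of trajectories.
#' @param process the process they were sampled from.
#' @param file output path or connection.
#' @export
write_trajectories_tsv <- function(trajectories, process, file) {
  labs <- process$space$labels
  rows <- lapply(seq_along(trajectories), function(i) {
    j <- trajectories[[i]]$jumps
    if (!nrow(j)) return(NULL)
    data.frame(path_id = i, t = j$time, mechanism = j$mechanism,
               from_state = labs[j$from], to_state = labs[j$to])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(path_id = integer(0), t = numeric(0),
                     mechanism = character(0), from_state = character(0),
                     to_state = character(0))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
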