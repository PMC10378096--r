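## Mechanism-resolved probability flows, dynamical activity, entropy
## production, and the inclusion-exclusion decomposition of EP over unit
## structures.  Entropy production is in nats; the convention
## 0*log(0/0) = 0 applies throughout, and a forward flow with vanishing
## reverse flow is a hard error (the process validator pre-empts it except
## when the distribution itself has zeros on the reverse source).

## Generator of one mechanism restricted to a unit's marginal space.
unit_mechanism_generator <- function(process, members, id, t = 0) {
  members <- normalize_members(process$space, members)
  m <- process$mechanisms[[id]]
  if (is.null(m)) stop("unknown mechanism id: ", id)
  if (!all(m$leaders %in% members))
    stop("mechanism '", id, "' does not act inside the unit")
  sub <- marginal_space(process$space, members)
  n <- sub$n_states
  K <- matrix(0, n, n)
  states <- sub$states
  seg <- protocol_segment(m$protocol, t)
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
    tgt <- unname(sub$index[apply(tgt_states, 1L, paste, collapse = ",")])
    K[cbind(tgt, src)] <- K[cbind(tgt, src)] + rate
  }
  diag(K) <- diag(K) - colSums(K)
  K
}

#' One-way probability flows of a mechanism within a unit
#'
#' The flow into state `x` from state `x'` due to mechanism `v` is
#' `K[x, x'](v) p[x']`.  The net current is the antisymmetrized flow.
#'
#' @param process a [composite_process()].
#' @param members a verified unit containing the mechanism's leader set.
#' @param id mechanism id.
#' @param p distribution on the unit's marginal space.
#' @param t evaluation time.
#' @return matrix of one-way flows (diagonal zero).
#' @export
flow_matrix <- function(process, members, id, p, t = 0) {
  K <- unit_mechanism_generator(process, members, id, t)
  A <- sweep(K, 2, p, `*`)
  diag(A) <- 0
  A
}

#' Net probability currents of a mechanism within a unit
#'
#' @inheritParams flow_matrix
#' @return antisymmetric matrix `J = A - t(A)`; the diagonal, where the
#'   current is not defined, is zero.
#' @export
net_current_matrix <- function(process, members, id, p, t = 0) {
  A <- flow_matrix(process, members, id, p, t)
  A - t(A)
}

#' Dynamical activity of a unit, split by mechanism
#'
#' The activity of mechanism `v` is the total one-way flux
#' `sum_{x != x'} K[x, x'](v) p[x']`; the unit's activity is the sum over
#' mechanisms whose leader set lies inside the unit.
#'
#' @inheritParams flow_matrix
#' @param p distribution on the unit's marginal space.
#' @return list with `total` and named vector `by_mechanism`.
#' @export
activity <- function(process, members, p, t = 0) {
  ids <- unit_mechanisms(process, members)
  by_mech <- vapply(ids, function(id)
    sum(flow_matrix(process, members, id, p, t)), 0)
  names(by_mech) <- ids
  list(total = sum(by_mech), by_mechanism = by_mech)
}

#' Entropy production rate of a unit, split by mechanism
#'
#' For each mechanism acting inside the unit, the EP rate contribution is
#' `sum_{x != x'} A[x, x'] log(A[x, x'] / A[x', x])` with the one-way flows
#' `A`; the unit's EP rate is the sum over those mechanisms.  Pairs with
#' both flows zero contribute nothing; a positive forward flow with zero
#' reverse flow makes the EP rate infinite and raises an error naming the
#' transition.
#'
#' @inheritParams activity
#' @return list with `total` (nats/time) and named vector `by_mechanism`.
#' @export
ep_rate <- function(process, members, p, t = 0) {
  members <- normalize_members(process$space, members)
  ids <- unit_mechanisms(process, members)
  sub_labels <- marginal_space(process$space, members)$labels
  by_mech <- vapply(ids, function(id) {
    A <- flow_matrix(process, members, id, p, t)
    fwd <- A; rev <- t(A)
    bad <- which(fwd > 0 & rev == 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("infinite EP: mechanism '", id, "' flow ",
           sub_labels[bad[1, 2]], " -> ", sub_labels[bad[1, 1]],
           " has no reverse flow")
    sum(xlogxy(fwd, rev))
  }, 0)
  names(by_mech) <- ids
  list(total = sum(by_mech), by_mechanism = by_mech)
}

## Shared grid machinery: propagate the full system over a composite
## Simpson grid and hand marginals to per-unit integrands.
ep_grid <- function(process, p0, tau, n_steps) {
  if (n_steps < 2L) n_steps <- 2L
  if (n_steps %% 2L == 1L) n_steps <- n_steps + 1L
  times <- seq(0, tau, length.out = n_steps + 1L)
  sol <- propagate(process, p0, t1 = tau, grid = times)
  list(times = sol$times, path = sol$path,
       weights = simpson_weights(length(sol$times), tau / n_steps))
}

#' Time-integrated entropy production of a unit
#'
#' Propagates the full system, marginalizes onto the unit, and integrates
#' the unit's EP rate by composite Simpson quadrature on an equally spaced
#' grid (protocol breakpoints should divide the step for driven processes).
#'
#' @inheritParams activity
#' @param p0 initial distribution over the full joint space (strictly
#'   positive entries recommended: EP diverges on transient zeros).
#' @param tau horizon.
#' @param n_steps even number of quadrature intervals (default 64).
#' @return list with `total`, `by_mechanism` (both integrated over
#'   `[0, tau]`), and the grid of instantaneous rates.
#' @export
integrated_ep <- function(process, members, p0, tau, n_steps = 64L) {
  members <- normalize_members(process$space, members)
  if (tau == 0) {
    ids <- unit_mechanisms(process, members)
    return(list(total = 0,
                by_mechanism = stats::setNames(rep(0, length(ids)), ids),
                times = 0, rate = 0))
  }
  g <- ep_grid(process, p0, tau, n_steps)
  ids <- unit_mechanisms(process, members)
  rates <- matrix(0, length(g$times), length(ids),
                  dimnames = list(NULL, ids))
  for (k in seq_along(g$times)) {
    pm <- marginalize(g$path[, k], process$space, members)
    rates[k, ] <- ep_rate(process, members, pm, g$times[k])$by_mechanism
  }
  by_mech <- colSums(rates * g$weights)
  list(total = sum(by_mech), by_mechanism = by_mech,
       times = g$times, rate = rowSums(rates))
}

## ---- inclusion-exclusion ----------------------------------------------

#' Inclusion-exclusion sum of unit-indexed values
#'
#' Evaluates the alternating sum over index tuples of the structure's
#' units: singles minus pairwise intersections plus triples, and so on.
#' Tuples whose intersection is empty contribute zero.  The value does not
#' depend on the order in which the units are indexed.
#'
#' @param values named numeric vector, one value per unit key of the
#'   structure (keys as in `structure$keys`; intersections are themselves
#'   units of the structure by closure).
#' @param structure a [unit_structure()].
#' @return the inclusion-exclusion sum.
#' @export
inex_sum <- function(values, structure) {
  total <- 0
  for (tp in inex_tuples(structure)) {
    if (!length(tp$members)) next
    if (!tp$key %in% names(values))
      stop("inex_sum: missing value for unit {", tp$key, "}")
    total <- total + tp$sign * values[[tp$key]]
  }
  total
}

#' In-ex information of a distribution over a unit structure
#'
#' The inclusion-exclusion sum of the units' marginal entropies minus the
#' global entropy, in nats.  For two disjoint units it is their mutual
#' information; for many disjoint units, the total correlation.
#'
#' @param p distribution over the full joint space.
#' @param space the [state_space()] of `p`.
#' @param structure a [unit_structure()].
#' @return in-ex information in nats.
#' @export
inex_information <- function(p, space, structure) {
  p <- normalize_distribution(p, what = "p")
  total <- 0
  for (tp in inex_tuples(structure)) {
    if (!length(tp$members)) next
    total <- total + tp$sign * shannon_entropy(marginalize(p, space, tp$members))
  }
  total - shannon_entropy(p)
}

#' Inclusion-exclusion decomposition of the global entropy production
#'
#' Computes, over `[0, tau]`: the global EP `sigma_N`; every unit's
#' integrated EP with its per-mechanism split; the in-ex sum of unit EPs;
#' the change in in-ex information; and the residual of the exact identity
#' `sigma_N = (in-ex sum of sigma_omega) - delta I`.  A residual beyond
#' `1e-6 * max(1, sigma_N)` signals an implementation or model bug and
#' raises an error.
#'
#' @param process a [composite_process()].
#' @param structure a [unit_structure()] covering all subsystems.
#' @param p0 strictly positive initial distribution over the joint space.
#' @param tau horizon.
#' @param n_steps even number of Simpson intervals to start from (default
#'   64); the grid is refined (doubled, up to `max_steps`) until the exact
#'   identity is resolved within tolerance.
#' @param max_steps refinement cap (default 1024).
#' @return object of class `ep_decomposition` with fields `sigma_global`,
#'   `sigma_units`, `by_mechanism`, `inex_sum`, `delta_inex_information`,
#'   `residual`.
#' @export
ep_inex_decomposition <- function(process, structure, p0, tau, n_steps = 64L,
                                  max_steps = 1024L) {
  if (!inherits(structure, "unit_structure")) stop("need a unit_structure")
  sp <- process$space
  res <- ep_inex_decomposition_once(process, structure, p0, tau, n_steps)
  while (abs(res$residual) > 1e-6 * max(1, abs(res$sigma_global)) &&
         n_steps < max_steps) {
    n_steps <- 2L * n_steps
    res <- ep_inex_decomposition_once(process, structure, p0, tau, n_steps)
  }
  tol <- 1e-6 * max(1, abs(res$sigma_global))
  if (abs(res$residual) > tol)
    stop("EP decomposition residual ", format(res$residual),
         " exceeds tolerance ", format(tol),
         " at ", n_steps, " quadrature intervals ",
         "(the identity is exact; this signals a model or implementation bug)")
  res
}

ep_inex_decomposition_once <- function(process, structure, p0, tau, n_steps) {
  sp <- process$space
  g <- ep_grid(process, p0, tau, n_steps)
  all_units <- c(structure$units, list(sp$subsystems))
  keys <- vapply(all_units, function(u) unit_key(sp, u), "")
  sigma <- stats::setNames(numeric(length(all_units)), keys)
  by_mech <- stats::setNames(vector("list", length(all_units)), keys)
  for (ui in seq_along(all_units)) {
    u <- all_units[[ui]]
    ids <- unit_mechanisms(process, u)
    rates <- matrix(0, length(g$times), length(ids))
    for (k in seq_along(g$times)) {
      pm <- marginalize(g$path[, k], sp, u)
      rates[k, ] <- ep_rate(process, u, pm, g$times[k])$by_mechanism
    }
    contrib <- stats::setNames(colSums(rates * g$weights), ids)
    sigma[ui] <- sum(contrib)
    by_mech[[ui]] <- contrib
  }
  global_key <- unit_key(sp, sp$subsystems)
  I0 <- inex_information(g$path[, 1], sp, structure)
  I1 <- inex_information(g$path[, ncol(g$path)], sp, structure)
  ie <- inex_sum(sigma[structure$keys], structure)
  sigma_global <- sigma[[global_key]]
  residual <- sigma_global - (ie - (I1 - I0))
  structure(list(sigma_global = sigma_global,
                 sigma_units = sigma[structure$keys],
                 by_mechanism = by_mech,
                 inex_sum = ie,
                 delta_inex_information = I1 - I0,
                 residual = residual, tau = tau),
            class = "ep_decomposition")
}

#' @export
print.ep_decomposition <- function(x, ...) {
  cat("<ep_decomposition> over [0, ", format(x$tau), "]\n", sep = "")
  cat("  global EP:          ", format(x$sigma_global), " nats\n", sep = "")
  for (k in names(x$sigma_units))
    cat("  sigma{", k, "}: ", format(x$sigma_units[[k]]), "\n", sep = "")
  cat("  in-ex sum:          ", format(x$inex_sum), "\n", sep = "")
  cat("  delta in-ex info:   ", format(x$delta_inex_information), "\n", sep = "")
  cat("  residual:           ", format(x$residual), "\n", sep = "")
  invisible(x)
}

## ---- information flow -------------------------------------------------

#' Information flow between two blocks of a unit
#'
#' The rate of decrease of the conditional entropy of block `B` given block
#' `A` attributable to jumps that change only `A`-coordinates:
#' the sum over unordered state pairs differing only in `A` of
#' `J * log[p(xB | xA) / p(xB | xA')]`.  Defined at a stationary state; a
#' warning is issued for non-stationary distributions, where the same
#' formula is computed but has no established interpretation.
#'
#' @param process a [composite_process()].
#' @param members a verified unit containing `A` and `B`.
#' @param A,B disjoint subsystem subsets of the unit.
#' @param p distribution on the unit's marginal space.
#' @param t evaluation time.
#' @param warn_nonstationary check stationarity of `p` under the unit
#'   generator and warn when it fails (default TRUE).
#' @return list with `total` and per-mechanism contributions
#'   `by_mechanism`.
#' @export
information_flow <- function(process, members, A, B, p, t = 0,
                             warn_nonstationary = TRUE) {
  sp <- process$space
  members <- normalize_members(sp, members)
  A <- normalize_members(sp, A)
  B <- normalize_members(sp, B)
  if (length(intersect(A, B))) stop("information_flow: A and B overlap")
  if (!all(c(A, B) %in% members))
    stop("information_flow: A and B must lie inside the unit")
  sub <- marginal_space(sp, members)
  if (warn_nonstationary) {
    K <- unit_generator(process, members, t)
    if (max(abs(K %*% p)) > 1e-8)
      warning("information_flow: p is not stationary for the unit; ",
              "the formula is evaluated but its interpretation is only ",
              "established at a steady state")
  }
  ## conditional p(xB | xA) from the AB-marginal of p
  subAB <- marginal_space(sp, c(A, B))
  subA <- marginal_space(sp, A)
  lab_AB_of_sub <- apply(sub$states[, normalize_members(sp, c(A, B)), drop = FALSE],
                         1L, paste, collapse = ",")
  idx_AB_of_sub <- unname(subAB$index[lab_AB_of_sub])
  lab_A_of_AB <- apply(subAB$states[, A, drop = FALSE], 1L, paste, collapse = ",")
  idx_A_of_AB <- unname(subA$index[lab_A_of_AB])
  pAB <- as.vector(rowsum(p, factor(idx_AB_of_sub, levels = seq_len(subAB$n_states))))
  pA <- as.vector(rowsum(pAB, factor(idx_A_of_AB, levels = seq_len(subA$n_states))))
  cond <- ifelse(pA[idx_A_of_AB] > 0, pAB / pA[idx_A_of_AB], NA_real_)

  ## weight matrix over unit states: nonzero only when the two states agree
  ## outside A (so B and everything else is unchanged)
  nonA <- setdiff(members, A)
  outside <- apply(sub$states[, nonA, drop = FALSE], 1L, paste, collapse = ",")
  n <- sub$n_states
  ABmem <- normalize_members(sp, c(A, B))
  ## AB-state index obtained when the A-coords of xp are combined with the
  ## (shared) B-coords of x
  W <- matrix(0, n, n)
  for (x in seq_len(n)) for (xp in seq_len(n)) {
    if (x == xp || outside[x] != outside[xp]) next
    ## p(xB | xA) at x vs at xp (B-coordinates are shared)
    st_x <- sub$states[x, ABmem]
    st_xp <- sub$states[x, ABmem]
    st_xp[A] <- sub$states[xp, A]
    cB_given_A <- cond[subAB$index[[paste(st_x, collapse = ",")]]]
    cB_given_Ap <- cond[subAB$index[[paste(st_xp, collapse = ",")]]]
    if (is.na(cB_given_A) || is.na(cB_given_Ap) ||
        cB_given_A == 0 || cB_given_Ap == 0) next
    W[x, xp] <- log(cB_given_A / cB_given_Ap)
  }
  W <- (W - t(W)) / 2  # exact antisymmetry against rounding in the logs
  ids <- unit_mechanisms(process, members)
  by_mech <- vapply(ids, function(id) {
    J <- net_current_matrix(process, members, id, p, t)
    sum((J * W)[upper.tri(J)])
  }, 0)
  names(by_mech) <- ids
  list(total = sum(by_mech), by_mechanism = by_mech, weights = W)
}
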