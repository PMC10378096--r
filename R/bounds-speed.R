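## Mechanism-resolved jump distributions and thermodynamic speed limits.

#' Concave comparison functions for speed limits
#'
#' A speed-limit comparison function `g` must be concave, nondecreasing,
#' nonnegative, with `g(0) = 0`, and dominate the total variation distance
#' as a function of the KL divergence.  The built-in choice is Pinsker's
#' `g(x) = sqrt(x / 2)`.  User-supplied functions are spot-checked for
#' monotonicity and concavity on a grid.
#'
#' @param name label for reports.
#' @param fn evaluator; vectorized over nonnegative inputs.
#' @return object of class `g_function`.
#' @export
g_function <- function(name, fn) {
  grid <- seq(0, 8, length.out = 200)
  v <- fn(grid)
  if (any(!is.finite(v)) || any(v < 0) || abs(fn(0)) > 1e-12)
    stop("g_function: must be finite, nonnegative, with g(0) = 0")
  if (any(diff(v) < -1e-12))
    stop("g_function: must be nondecreasing")
  if (any(diff(diff(v)) > 1e-9))
    stop("g_function: must be concave")
  structure(list(name = name, fn = fn), class = "g_function")
}

#' @rdname g_function
#' @export
g_pinsker <- function() g_function("pinsker", function(x) sqrt(x / 2))

#' Forward and reverse jump distributions of a mechanism
#'
#' Conditioning on a jump occurring at time `t` due to one mechanism, the
#' forward table gives the probability that the jump was from `x'` to `x`;
#' the reverse table is the same construction for the time-reversed
#' transition.  Both are flow tables normalized by the mechanism's
#' activity.  The identity `EP-rate contribution = activity * KL(W || Wrev)`
#' is verified to 1e-10, and the total variation distance between the
#' tables (treating the pair-indexed tables as distributions) is returned;
#' it is Pinsker-bounded by the KL divergence.
#'
#' @param process a [composite_process()].
#' @param members a verified unit containing the mechanism's leader set.
#' @param id mechanism id.
#' @param p distribution on the unit's marginal space.
#' @param t evaluation time.
#' @return object of class `jump_distributions` with fields `W`, `W_rev`,
#'   `activity`, `d_tv`, `kl`, `defined`.
#' @export
jump_distributions <- function(process, members, id, p, t = 0) {
  A <- flow_matrix(process, members, id, p, t)
  act <- sum(A)
  if (act <= 0)
    return(structure(list(W = NULL, W_rev = NULL, activity = 0,
                          d_tv = NA_real_, kl = NA_real_, defined = FALSE,
                          mechanism = id),
                     class = "jump_distributions"))
  W <- A / act
  W_rev <- t(A) / act
  off <- row(W) != col(W)
  kl <- sum(xlogxy(W[off], W_rev[off]))
  d_tv <- 0.5 * sum(abs(W[off] - W_rev[off]))
  zeta <- ep_rate(process, members, p, t)$by_mechanism[[id]]
  if (abs(zeta - act * kl) > 1e-10 * max(1, abs(zeta)))
    stop("jump_distributions: activity * KL does not reproduce the ",
         "mechanism EP rate (internal inconsistency)")
  structure(list(W = W, W_rev = W_rev, activity = act, d_tv = d_tv,
                 kl = kl, defined = TRUE, mechanism = id),
            class = "jump_distributions")
}

## Integrated activity and EP per mechanism on a Simpson grid.
integrated_activity_ep <- function(process, members, p0, tau, n_steps) {
  g <- ep_grid(process, p0, tau, n_steps)
  ids <- unit_mechanisms(process, members)
  act <- matrix(0, length(g$times), length(ids))
  eps <- matrix(0, length(g$times), length(ids))
  for (k in seq_along(g$times)) {
    pm <- marginalize(g$path[, k], process$space, members)
    act[k, ] <- activity(process, members, pm, g$times[k])$by_mechanism
    eps[k, ] <- ep_rate(process, members, pm, g$times[k])$by_mechanism
  }
  list(ids = ids,
       A_tot = stats::setNames(colSums(act * g$weights), ids),
       zeta = stats::setNames(colSums(eps * g$weights), ids),
       p0m = marginalize(g$path[, 1], process$space, members),
       p1m = marginalize(g$path[, ncol(g$path)], process$space, members))
}

#' Mechanism-resolved (composite) thermodynamic speed limit
#'
#' Bounds the total variation distance between the unit's initial and final
#' marginals by the mechanism-resolved sum
#' `sum_v A_tot(v) g(zeta_v / A_tot(v))`, where `A_tot(v)` is the
#' time-integrated activity of mechanism `v` within the unit and `zeta_v`
#' its contribution to the unit's EP.  Mechanisms with zero activity
#' contribute nothing.
#'
#' @param process a [composite_process()].
#' @param members a verified unit.
#' @param p0 initial distribution over the full joint space.
#' @param tau horizon.
#' @param g a [g_function()] (default Pinsker).
#' @param n_steps Simpson intervals.
#' @return object of class `speed_limit_report` with `lhs`, `rhs`,
#'   `slack`, `satisfied`, and the per-mechanism inputs.
#' @export
speed_limit_composite <- function(process, members, p0, tau,
                                  g = g_pinsker(), n_steps = 64L) {
  if (!inherits(g, "g_function")) stop("g must be a g_function")
  q <- integrated_activity_ep(process, members, p0, tau, n_steps)
  lhs <- total_variation(q$p0m, q$p1m)
  terms <- ifelse(q$A_tot > 0, q$A_tot * g$fn(pmax(q$zeta, 0) / q$A_tot), 0)
  rhs <- sum(terms)
  structure(list(lhs = lhs, rhs = rhs, slack = rhs - lhs,
                 satisfied = lhs <= rhs + 1e-10,
                 g = g$name, tau = tau, members = members,
                 A_tot = q$A_tot, zeta = q$zeta, terms = terms,
                 kind = "composite"),
            class = "speed_limit_report")
}

#' Unit-total (global) thermodynamic speed limit, with Jensen comparison
#'
#' The classical activity-EP speed limit applied to the unit's totals:
#' `lhs <= A_tot g(sigma / A_tot)`.  By Jensen's inequality this right-hand
#' side is never below the mechanism-resolved one of
#' [speed_limit_composite()]; both are reported.
#'
#' @inheritParams speed_limit_composite
#' @return object of class `speed_limit_report` with additional fields
#'   `rhs_composite` and `jensen_satisfied`.
#' @export
speed_limit_global <- function(process, members, p0, tau,
                               g = g_pinsker(), n_steps = 64L) {
  comp <- speed_limit_composite(process, members, p0, tau, g, n_steps)
  A_tot <- sum(comp$A_tot)
  sigma <- sum(comp$zeta)
  rhs <- if (A_tot > 0) A_tot * g$fn(max(sigma, 0) / A_tot) else 0
  structure(list(lhs = comp$lhs, rhs = rhs, slack = rhs - comp$lhs,
                 satisfied = comp$lhs <= rhs + 1e-10,
                 rhs_composite = comp$rhs,
                 jensen_satisfied = comp$rhs <= rhs + 1e-10,
                 g = comp$g, tau = tau, members = comp$members,
                 A_tot = comp$A_tot, zeta = comp$zeta,
                 kind = "global"),
            class = "speed_limit_report")
}

#' @export
print.speed_limit_report <- function(x, ...) {
  cat("<speed_limit_report> (", x$kind, ", g = ", x$g, ") unit {",
      paste(x$members, collapse = ","), "}, tau = ", format(x$tau), "\n",
      sep = "")
  cat("  lhs (total variation): ", format(x$lhs), "\n", sep = "")
  cat("  rhs:                   ", format(x$rhs), "\n", sep = "")
  cat("  satisfied:             ", x$satisfied, "\n", sep = "")
  if (!is.null(x$rhs_composite))
    cat("  mechanism-resolved rhs ", format(x$rhs_composite),
        " (Jensen: ", x$jensen_satisfied, ")\n", sep = "")
  invisible(x)
}

#' Lower bound on the duration of an observed transformation
#'
#' Given the distance actually covered by a unit's marginal over `[0, tau]`
#' and the time-averaged per-mechanism activities, the mechanism-resolved
#' speed limit with Pinsker's `g` is inverted numerically in the duration
#' variable: the bound for each unit is the largest duration below which
#' the speed limit would be violated.  The maximum over the supplied units
#' is the system-level bound; it never exceeds the actual `tau`.
#'
#' @param process a [composite_process()].
#' @param units list of verified units (or a [unit_structure()]).
#' @param p0 initial distribution over the joint space.
#' @param tau actual duration.
#' @param n_steps Simpson intervals.
#' @return list with `tau_star` (max over units), `per_unit` named vector,
#'   and `tau`.
#' @export
tau_lower_bound <- function(process, units, p0, tau, n_steps = 64L) {
  if (inherits(units, "unit_structure")) units <- units$units
  g <- g_pinsker()
  per_unit <- vapply(units, function(u) {
    q <- integrated_activity_ep(process, u, p0, tau, n_steps)
    lhs <- total_variation(q$p0m, q$p1m)
    if (lhs <= 0) return(0)
    mean_act <- q$A_tot / tau
    ## rhs(s) = sum_v sqrt(<A_v> s * zeta_v / 2), increasing in s
    rhs <- function(s) sum(sqrt(pmax(mean_act * s * pmax(q$zeta, 0) / 2, 0)))
    if (rhs(1) <= 0) return(Inf)  # distance covered with no dissipation/activity
    hi <- 1
    while (rhs(hi) < lhs && hi < 1e12) hi <- hi * 2
    stats::uniroot(function(s) rhs(s) - lhs, c(0, hi), tol = 1e-12)$root
  }, 0)
  names(per_unit) <- vapply(units, function(u)
    unit_key(process$space, u), "")
  list(tau_star = max(per_unit), per_unit = per_unit, tau = tau)
}
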