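## Mismatch-cost and periodicity lower bounds on entropy production.

#' Mismatch cost of running a kernel on the wrong prior
#'
#' The drop in Kullback-Leibler divergence `D(p || q) - D(Pp || Pq)`
#' incurred by running the discrete-time kernel `P` on the distribution `p`
#' rather than on the optimal prior `q`.  Nonnegative by the
#' data-processing inequality; `Inf` when `p` puts mass where `q` does not.
#'
#' @param P column-stochastic kernel (columns indexed by source state).
#' @param p,q distributions on the kernel's source space.
#' @return mismatch cost in nats (possibly `Inf`).
#' @export
mismatch_cost <- function(P, p, q) {
  if (nrow(P) != length(p) || length(p) != length(q))
    stop("mismatch_cost: dimension mismatch")
  d0 <- kl_divergence(p, q)
  if (!is.finite(d0)) return(Inf)
  d1 <- kl_divergence(as.vector(P %*% p), as.vector(P %*% q))
  d0 - d1
}

## Jensen-Shannon divergence of a weighted family of distributions:
## S(mixture) - weighted mean of S.
js_divergence <- function(members, weights) {
  mix <- as.vector(members %*% weights)
  shannon_entropy(mix) - sum(weights * apply(members, 2L, shannon_entropy))
}

#' Drop in Jensen-Shannon divergence under a kernel
#'
#' For a family of initial distributions with mixing weights, the decrease
#' in Jensen-Shannon divergence when every member is pushed through `P`.
#' This equals the minimum over priors `q` of the expected mismatch cost of
#' the family, the minimizer being the weighted mixture of the members.
#'
#' @param P column-stochastic kernel.
#' @param members matrix with one distribution per column.
#' @param weights mixing distribution over the columns (default uniform).
#' @return nonnegative drop in nats.
#' @export
jensen_shannon_drop <- function(P, members, weights = NULL) {
  if (!is.matrix(members) || !ncol(members))
    stop("jensen_shannon_drop: need at least one member distribution")
  weights <- weights %||% rep(1 / ncol(members), ncol(members))
  if (length(weights) != ncol(members)) stop("weights length mismatch")
  weights <- normalize_distribution(weights, what = "weights")
  js_divergence(members, weights) - js_divergence(P %*% members, weights)
}

## Minimize f over the probability simplex via a softmax parameterization,
## from several starts; returns the best value found.
minimize_over_simplex <- function(f, n, starts) {
  obj <- function(z) f(exp(z) / sum(exp(z)))
  best <- Inf
  for (s in starts) {
    z0 <- log(pmax(s, 1e-12))
    fit <- stats::optim(z0, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (fit$value < best) best <- fit$value
  }
  best
}

#' Periodicity lower bound on entropy production
#'
#' For a process whose dynamics over each of `N` consecutive periods is the
#' same kernel `P`, the EP over the `N` periods is bounded below by the
#' infimum over priors of the summed per-period mismatch costs.  The bound
#' is computed two ways: by numerical minimization over the simplex and by
#' the closed form `N` times the Jensen-Shannon drop of the uniform family
#' of iterates; the two must agree.
#'
#' @param P column-stochastic period kernel.
#' @param p0 initial distribution.
#' @param n_periods number of periods `N >= 1`.
#' @return object of class `periodic_bound_report` with fields `bound`
#'   (closed form), `bound_numeric` (simplex minimization), `agreement`
#'   (absolute difference), `iterates`.
#' @export
periodicity_ep_bound <- function(P, p0, n_periods) {
  if (n_periods < 1) stop("periodicity_ep_bound: n_periods must be >= 1")
  p0 <- normalize_distribution(p0, what = "p0")
  iterates <- matrix(NA_real_, length(p0), n_periods)
  iterates[, 1] <- p0
  if (n_periods > 1)
    for (tt in 2:n_periods)
      iterates[, tt] <- as.vector(P %*% iterates[, tt - 1])
  closed <- n_periods * jensen_shannon_drop(P, iterates)
  images <- P %*% iterates
  objective <- function(q) {
    tot <- 0
    Pq <- as.vector(P %*% q)
    for (tt in seq_len(n_periods)) {
      d0 <- kl_divergence(iterates[, tt], q)
      if (!is.finite(d0)) return(1e6)
      tot <- tot + d0 - kl_divergence(images[, tt], Pq)
    }
    tot
  }
  mixture <- rowMeans(iterates)
  starts <- list(rep(1 / length(p0), length(p0)), mixture,
                 normalize_distribution(mixture + 0.05))
  numeric_inf <- minimize_over_simplex(objective, length(p0), starts)
  structure(list(bound = max(0, closed), bound_numeric = max(0, numeric_inf),
                 agreement = abs(closed - numeric_inf),
                 n_periods = n_periods, iterates = iterates),
            class = "periodic_bound_report")
}

#' @export
print.periodic_bound_report <- function(x, ...) {
  cat("<periodic_bound_report> N = ", x$n_periods, "\n", sep = "")
  cat("  EP lower bound (closed form):   ", format(x$bound), " nats\n", sep = "")
  cat("  EP lower bound (numeric inf):   ", format(x$bound_numeric), " nats\n", sep = "")
  cat("  agreement:                      ", format(x$agreement), "\n", sep = "")
  if (!is.null(x$sigma_total))
    cat("  integrated EP of the process:   ", format(x$sigma_total), " nats\n", sep = "")
  invisible(x)
}

#' Composite periodicity bound for the nested three-subsystem construction
#'
#' For a process of three subsystems where `A` is frozen and, conditioned
#' on `A`, blocks `B` and `C` evolve periodically with commensurate periods
#' (`lambda_B = m lambda_C / n`, `m`, `n` coprime), the global EP over one
#' common period `tau = n lambda_B = m lambda_C` is bounded below by the
#' sum of the two periodicity bounds of the units `AB` and `AC` plus the
#' (nonnegative) decrease of the in-ex information of the structure
#' `{A, AB, AC}`.  Neither unit's bound alone, nor the periodicity bound of
#' the full system (which is zero over a single common period), yields a
#' positive bound.
#'
#' @param instance a `nested_periodic_instance` from
#'   [build_nested_periodic()].
#' @param n_steps Simpson intervals for the direct EP integration.
#' @return object of class `periodic_bound_report` with components
#'   `neg_delta_I`, `js_bound_AB`, `js_bound_AC`, `bound`, `sigma_total`,
#'   `satisfied`.
#' @export
nested_periodic_bound <- function(instance, n_steps = 96L) {
  if (!inherits(instance, "nested_periodic_instance"))
    stop("need a nested_periodic_instance (see build_nested_periodic)")
  proc <- instance$process
  sp <- proc$space
  ## structural assumptions: A frozen, units {A, AB, AC}, commensurate periods
  problems <- character(0)
  for (m in proc$mechanisms)
    if (instance$A %in% m$puppets)
      problems <- c(problems, paste0("subsystem ", instance$A,
                                     " is not frozen (mechanism ", m$id, " moves it)"))
  AB <- c(instance$A, instance$B)
  AC <- c(instance$A, instance$C)
  for (u in list(instance$A, AB, AC))
    if (!is_unit(proc, u))
      problems <- c(problems, paste0("{", paste(u, collapse = ","), "} is not a unit"))
  if (abs(instance$lambda_B - instance$m * instance$lambda_C / instance$n) > 1e-12)
    problems <- c(problems, "lambda_B != m * lambda_C / n")
  if (length(problems))
    stop("nested periodic structure violated: ", paste(problems, collapse = "; "))

  tau <- instance$tau
  P_AB <- period_propagator(proc, instance$lambda_B, unit = AB)
  P_AC <- period_propagator(proc, instance$lambda_C, unit = AC)
  p0_AB <- marginalize(instance$p0, sp, AB)
  p0_AC <- marginalize(instance$p0, sp, AC)
  rep_AB <- periodicity_ep_bound(P_AB, p0_AB, instance$n)
  rep_AC <- periodicity_ep_bound(P_AC, p0_AC, instance$m)
  p_tau <- propagate(proc, instance$p0, t1 = tau)
  structure_ <- unit_structure(proc, list(instance$A, AB, AC))
  I0 <- inex_information(instance$p0, sp, structure_)
  I1 <- inex_information(p_tau, sp, structure_)
  neg_dI <- -(I1 - I0)
  bound <- neg_dI + rep_AB$bound + rep_AC$bound
  sigma <- integrated_ep(proc, sp$subsystems, instance$p0, tau,
                         n_steps = n_steps)$total
  structure(list(bound = bound, neg_delta_I = neg_dI,
                 js_bound_AB = rep_AB$bound, js_bound_AC = rep_AC$bound,
                 report_AB = rep_AB, report_AC = rep_AC,
                 sigma_total = sigma, n_periods = instance$n,
                 satisfied = bound <= sigma + 1e-8,
                 bound_numeric = rep_AB$bound_numeric + rep_AC$bound_numeric + neg_dI,
                 agreement = rep_AB$agreement + rep_AC$agreement),
            class = "periodic_bound_report")
}
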