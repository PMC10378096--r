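## Thermodynamic uncertainty relations for composite processes, checked by
## trajectory simulation at a nonequilibrium steady state.  All stochastic
## reports carry standard errors; verdicts are phrased as "not violated
## beyond k standard errors".

## Verify that p is stationary for the full process and return sigma^omega
## at the NESS (rate * tau).
ness_ep <- function(process, members, tau) {
  K <- full_generator(process, 0)
  p <- steady_state(K)
  if (max(abs(K %*% p)) > 1e-10) stop("NESS residual too large")
  pm <- marginalize(p, process$space, members)
  list(p = p, p_unit = pm, sigma = tau * ep_rate(process, members, pm)$total)
}

tur_ratio_se <- function(vals, sigma) {
  n <- length(vals)
  m <- mean(vals); v <- stats::var(vals)
  ratio <- sigma * v / (2 * m^2)
  m4 <- mean((vals - m)^4)
  ## delta method in (mean, variance)
  se <- ratio * sqrt(4 * v / (n * m^2) + max(m4 - v^2, 0) / (n * v^2))
  list(ratio = ratio, se = se, mean = m, var = v,
       mean_se = sqrt(v / n))
}

#' Finite-time thermodynamic uncertainty relation at a steady state
#'
#' At a nonequilibrium steady state, any time-integrated current of a unit
#' (total or restricted to a single mechanism) obeys
#' `sigma^omega >= 2 <C>^2 / Var(C)`.  The current statistics are estimated
#' from sampled trajectories; the unit's EP is computed exactly from the
#' stationary EP rate.  When the mean current is indistinguishable from
#' zero the check is inconclusive rather than a verdict.
#'
#' @param process a [composite_process()] with constant rates.
#' @param spec a [current_spec()] on one of the process's units.
#' @param tau horizon per trajectory.
#' @param n_paths number of trajectories (>= 100).
#' @param seed integer seed.
#' @return object of class `tur_report` with fields `ratio`
#'   (`sigma * Var / (2 <C>^2)`), `se`, `sigma`, `satisfied`
#'   (ratio not below 1 beyond 3 SE), `conclusive`.
#' @export
finite_time_tur_check <- function(process, spec, tau, n_paths = 1000L, seed = 1L) {
  if (n_paths < 100L) stop("finite_time_tur_check: need n_paths >= 100")
  ness <- ness_ep(process, spec$members, tau)
  trajs <- sample_trajectories(process, ness$p, tau, n_paths, seed)
  emp <- empirical_current(trajs, spec)
  if (abs(emp$mean) <= 3 * emp$se)
    return(structure(list(ratio = NA_real_, se = NA_real_,
                          sigma = ness$sigma, mean = emp$mean,
                          mean_se = emp$se, var = emp$var,
                          conclusive = FALSE, satisfied = NA,
                          n_paths = n_paths, tau = tau),
                     class = "tur_report"))
  st <- tur_ratio_se(emp$values, ness$sigma)
  structure(list(ratio = st$ratio, se = st$se, sigma = ness$sigma,
                 mean = st$mean, mean_se = st$mean_se, var = st$var,
                 conclusive = TRUE,
                 satisfied = st$ratio >= 1 - 3 * st$se,
                 n_paths = n_paths, tau = tau),
            class = "tur_report")
}

#' Vector-valued thermodynamic uncertainty relation
#'
#' For a vector of linearly independent time-integrated currents of a unit
#' at a steady state, `<C>^T Xi^{-1} <C> <= sigma^omega / 2`, with `Xi` the
#' covariance matrix of the integrated currents.  The quadratic form and
#' its bootstrap standard error are estimated from trajectories.
#'
#' @param process a [composite_process()] with constant rates.
#' @param specs list of [current_spec()]s on the same unit.
#' @param tau horizon per trajectory.
#' @param n_paths number of trajectories.
#' @param seed integer seed.
#' @param n_boot bootstrap replicates for the standard error.
#' @return object of class `tur_report` with `lhs` (quadratic form), `rhs`
#'   (`sigma / 2`), `se`, `satisfied`.
#' @export
vector_tur_check <- function(process, specs, tau, n_paths = 1000L, seed = 1L,
                             n_boot = 200L) {
  members <- specs[[1]]$members
  for (s in specs)
    if (!identical(s$members, members))
      stop("vector_tur_check: all currents must live on the same unit")
  if (length(specs) == 1L)
    return(finite_time_tur_check(process, specs[[1]], tau, n_paths, seed))
  ness <- ness_ep(process, members, tau)
  trajs <- sample_trajectories(process, ness$p, tau, n_paths, seed)
  vals <- vapply(specs, function(s) empirical_current(trajs, s)$values,
                 numeric(n_paths))
  Xi <- stats::cov(vals)
  kappa <- kappa(Xi, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e8)
    stop("vector_tur_check: covariance matrix is (near-)singular; ",
         "the currents must not be linearly dependent")
  qf <- function(V) {
    m <- colMeans(V)
    as.numeric(m %*% solve(stats::cov(V), m))
  }
  lhs <- qf(vals)
  set.seed(seed + 777L)
  boots <- replicate(n_boot, {
    idx <- sample.int(n_paths, n_paths, replace = TRUE)
    tryCatch(qf(vals[idx, , drop = FALSE]), error = function(e) NA_real_)
  })
  se <- stats::sd(boots, na.rm = TRUE)
  rhs <- ness$sigma / 2
  structure(list(lhs = lhs, rhs = rhs, se = se, sigma = ness$sigma,
                 satisfied = lhs <= rhs + 3 * se, conclusive = TRUE,
                 n_paths = n_paths, tau = tau, ratio = rhs / lhs),
            class = "tur_report")
}

#' @export
print.tur_report <- function(x, ...) {
  cat("<tur_report> tau = ", format(x$tau), ", ", x$n_paths, " paths\n", sep = "")
  if (!is.null(x$lhs)) {
    cat("  <C>' Xi^-1 <C> = ", format(x$lhs), " vs sigma/2 = ",
        format(x$rhs), " (SE ", format(x$se), ")\n", sep = "")
  } else if (isFALSE(x$conclusive)) {
    cat("  inconclusive: mean current ", format(x$mean),
        " within 3 SE (", format(x$mean_se), ") of zero\n", sep = "")
  } else {
    cat("  sigma * Var / (2 <C>^2) = ", format(x$ratio), " (SE ",
        format(x$se), "), sigma = ", format(x$sigma), "\n", sep = "")
  }
  cat("  satisfied: ", format(x$satisfied), "\n", sep = "")
  invisible(x)
}

#' Uncertainty relation for an information flow
#'
#' At a steady state, the information flow from block `A` to block `B` is a
#' current whose weights are log-ratios of stationary conditionals; frozen
#' at their NESS values they define a bona fide antisymmetric current to
#' which the scalar TUR applies.  The flow's precision is checked against
#' the EP of every verified containing unit, smallest first: nested-unit
#' monotonicity of EP suggests the smallest containing unit gives the
#' tightest (best) bound, and the reports exhibit the empirical ordering.
#'
#' @param process a [composite_process()] with constant rates.
#' @param units candidate units (list of subsets or a [unit_structure()]);
#'   only those containing `A` and `B` are used, and the full system is
#'   always included.
#' @param A,B disjoint subsystem subsets.
#' @param tau horizon per trajectory.
#' @param n_paths number of trajectories.
#' @param seed integer seed.
#' @return list of `tur_report`s keyed by unit, ordered by unit size
#'   (smallest containing unit first).
#' @export
info_flow_tur_check <- function(process, units, A, B, tau,
                                n_paths = 1000L, seed = 1L) {
  sp <- process$space
  if (inherits(units, "unit_structure")) units <- units$units
  units <- c(units, list(sp$subsystems))
  keys <- vapply(units, function(u) unit_key(sp, u), "")
  units <- units[!duplicated(keys)]
  contain <- vapply(units, function(u) all(c(A, B) %in% u), TRUE)
  units <- units[contain]
  if (!length(units))
    stop("info_flow_tur_check: no verified unit contains A and B")
  units <- units[order(lengths(units))]
  smallest <- units[[1]]
  ness <- ness_ep(process, smallest, tau)
  flw <- information_flow(process, smallest, A, B, ness$p_unit,
                          warn_nonstationary = FALSE)
  spec <- current_spec(process, smallest, flw$weights)
  trajs <- sample_trajectories(process, ness$p, tau, n_paths, seed)
  emp <- empirical_current(trajs, spec)
  reports <- lapply(units, function(u) {
    sig <- ness_ep(process, u, tau)$sigma
    if (abs(emp$mean) <= 3 * emp$se)
      return(structure(list(ratio = NA_real_, se = NA_real_, sigma = sig,
                            mean = emp$mean, mean_se = emp$se,
                            conclusive = FALSE, satisfied = NA,
                            n_paths = n_paths, tau = tau),
                       class = "tur_report"))
    st <- tur_ratio_se(emp$values, sig)
    structure(list(ratio = st$ratio, se = st$se, sigma = sig,
                   mean = st$mean, mean_se = st$mean_se, var = st$var,
                   conclusive = TRUE,
                   satisfied = st$ratio >= 1 - 3 * st$se,
                   n_paths = n_paths, tau = tau),
              class = "tur_report")
  })
  names(reports) <- vapply(units, function(u) unit_key(sp, u), "")
  reports
}
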