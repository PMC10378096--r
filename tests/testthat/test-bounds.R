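test_that("mismatch cost evaluates the divergence drop and is nonnegative", {
  P <- cbind(c(0.9, 0.1), c(0.5, 0.5))
  p <- c(1, 0); q <- c(0.5, 0.5)
  ## direct-evaluation oracle: log 2 - D((0.9, 0.1) || (0.7, 0.3))
  oracle <- log(2) - (0.9 * log(0.9 / 0.7) + 0.1 * log(0.1 / 0.3))
  expect_equal(mismatch_cost(P, p, q), oracle, tolerance = 1e-12)
  expect_equal(mismatch_cost(P, q, q), 0)
  expect_equal(mismatch_cost(diag(2), p, q), 0)  # identity kernel
  expect_equal(mismatch_cost(P, p, c(0, 1)), Inf)
  expect_error(mismatch_cost(P, c(1, 0, 0), q), "dimension")
  ## data-processing: nonnegative on random instances
  set.seed(5)
  for (i in 1:20) {
    P <- matrix(rexp(9), 3); P <- sweep(P, 2, colSums(P), `/`)
    p <- rexp(3); p <- p / sum(p)
    q <- rexp(3) + 0.05; q <- q / sum(q)
    expect_gte(mismatch_cost(P, p, q), -1e-12)
  }
})

test_that("the Jensen-Shannon drop equals the minimized expected mismatch cost", {
  set.seed(8)
  for (i in 1:5) {
    P <- matrix(rexp(9), 3); P <- sweep(P, 2, colSums(P), `/`)
    members <- sapply(1:3, function(j) { v <- rexp(3) + 0.1; v / sum(v) })
    w <- c(0.5, 0.3, 0.2)
    drop <- jensen_shannon_drop(P, members, w)
    expect_gte(drop, -1e-12)
    ## optimizer oracle: minimize expected mismatch over the simplex
    obj <- function(z) {
      q <- exp(z) / sum(exp(z))
      sum(w * vapply(1:3, function(j)
        mismatch_cost(P, members[, j], q), 0))
    }
    fit <- optim(c(0, 0, 0), obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 5000))
    expect_equal(fit$value, drop, tolerance = 1e-6)
  }
  ## identical members or identity kernel: zero drop
  m1 <- matrix(rep(c(0.2, 0.3, 0.5), 3), 3)
  P <- matrix(rexp(9), 3); P <- sweep(P, 2, colSums(P), `/`)
  expect_equal(jensen_shannon_drop(P, m1), 0, tolerance = 1e-12)
  expect_equal(jensen_shannon_drop(diag(3), cbind(c(1, 0, 0), c(0, 1, 0))), 0,
               tolerance = 1e-12)
})

test_that("the periodicity bound matches its closed form and bounds the real EP", {
  proc <- random_composite_process(2, 2, seed = 19)
  lam <- 0.3; N <- 10
  P <- period_propagator(proc, lam)
  p0 <- random_interior_distribution(proc$space, 6)
  p0 <- p0^3 / sum(p0^3)
  rep <- periodicity_ep_bound(P, p0, N)
  expect_lt(rep$agreement, 1e-6)
  expect_gt(rep$bound, 0)
  ## a CTMC whose lambda-propagator is P dissipates at least the bound
  sigma <- integrated_ep(proc, proc$space$subsystems, p0, N * lam,
                         n_steps = 160)$total
  expect_lte(rep$bound, sigma + 1e-8)
  ## single period: the infimum is attained at q = p0 and vanishes
  expect_equal(periodicity_ep_bound(P, p0, 1)$bound, 0)
  ## stationary initial condition: all iterates coincide
  ss <- steady_state(full_generator(proc))
  expect_lt(periodicity_ep_bound(P, ss, 6)$bound, 1e-10)
})

test_that("the nested periodic construction yields a positive composite bound", {
  inst <- build_nested_periodic(3, 4, lambda_C = 1, seed = 3)
  expect_equal(inst$lambda_B, 3 / 4)
  expect_equal(inst$tau, 3)
  rep <- nested_periodic_bound(inst)
  expect_gte(rep$neg_delta_I, -1e-10)
  expect_gte(rep$js_bound_AB, 0)
  expect_gte(rep$js_bound_AC, 0)
  expect_gt(rep$bound, 0)          # nondegenerate kernels, non-stationary p0
  expect_lte(rep$bound, rep$sigma_total + 1e-8)
  expect_true(rep$satisfied)
  ## argument validation on the construction
  expect_error(build_nested_periodic(2, 3), "m > 2")
  expect_error(build_nested_periodic(3, 6), "coprime")
  expect_error(build_nested_periodic(4, 3), "n > m")
})

test_that("jump distributions reproduce the EP identity and the Pinsker bound", {
  p <- random_overlapping_unit_process(seed = 28)
  p0 <- random_interior_distribution(p$space, 9)
  N <- p$space$subsystems
  er <- ep_rate(p, N, p0)
  for (id in names(p$mechanisms)) {
    jd <- jump_distributions(p, N, id, p0)
    expect_true(jd$defined)
    expect_equal(jd$activity * jd$kl, er$by_mechanism[[id]], tolerance = 1e-10)
    expect_lte(jd$d_tv, sqrt(jd$kl / 2) + 1e-12)
    off <- row(jd$W) != col(jd$W)
    expect_equal(sum(jd$W[off]), 1, tolerance = 1e-12)
    expect_equal(sum(jd$W_rev[off]), 1, tolerance = 1e-12)
  }
  ## equilibrium: forward and reverse jump distributions coincide
  eq <- two_state_process(2, 1)
  jd_eq <- jump_distributions(eq, "A", "m", c(1 / 3, 2 / 3))
  expect_equal(jd_eq$d_tv, 0, tolerance = 1e-12)
  ## zero activity (a dormant protocol segment) flags undefined
  sp <- state_space(list(A = c("0", "1")))
  dormant <- composite_process(sp, list(mechanism("m", "A", list(
    list(from = c(A = "0"), to = c(A = "1"), rate = c(1, 0)),
    list(from = c(A = "1"), to = c(A = "0"), rate = c(1, 0))),
    protocol = rate_protocol(1, c(0, 0.5)))))
  jd_off <- jump_distributions(dormant, "A", "m", c(0.5, 0.5), t = 0.75)
  expect_false(jd_off$defined)
})

test_that("g functions are screened for concavity and monotonicity", {
  expect_s3_class(g_pinsker(), "g_function")
  expect_error(g_function("bad", function(x) x^2), "concave")
  expect_error(g_function("neg", function(x) -x), "nonnegative|nondecreasing")
  expect_silent(g_function("half", function(x) sqrt(x) / 2))
})

test_that("speed limits hold, and the mechanism-resolved bound is tighter", {
  ## frozen dynamics: both sides vanish
  inst <- build_nested_periodic(3, 4, 1, seed = 2)
  slA <- speed_limit_composite(inst$process, "A", inst$p0, tau = 1)
  expect_equal(slA$lhs, 0, tolerance = 1e-12)
  expect_equal(slA$rhs, 0)
  ## stationary initial condition: lhs = 0 <= rhs
  ring <- build_ring_process(3, 2, 1)
  ss <- steady_state(full_generator(ring))
  slr <- speed_limit_composite(ring, "R", ss, tau = 1)
  expect_equal(slr$lhs, 0, tolerance = 1e-10)
  expect_gte(slr$rhs, 0)
  ## single mechanism: composite and global right-hand sides coincide
  slg <- speed_limit_global(ring, "R", c(0.8, 0.1, 0.1), tau = 0.4)
  expect_equal(slg$rhs, slg$rhs_composite, tolerance = 1e-12)
  ## random instances: lhs <= composite rhs <= global rhs
  for (s in 1:10) {
    p <- random_composite_process(3, 3, seed = s + 60)
    p0 <- random_interior_distribution(p$space, s)
    g <- speed_limit_global(p, p$space$subsystems, p0, tau = 0.5, n_steps = 32)
    expect_true(g$satisfied)
    expect_true(g$jensen_satisfied)
    expect_lte(g$lhs, g$rhs_composite + 1e-10)
  }
})

test_that("duration bounds are self-consistent and match the closed form", {
  ring <- build_ring_process(3, 2, 1)
  p0 <- 0.8 * point_distribution(ring$space, "0") +
    0.2 * uniform_distribution(ring$space)
  tb <- tau_lower_bound(ring, list("R"), p0, tau = 0.5)
  ## single mechanism: algebraic inversion of L = sqrt(<A> s zeta / 2)
  q <- compthermo:::integrated_activity_ep(ring, "R", p0, 0.5, 64)
  L <- total_variation(q$p0m, q$p1m)
  closed <- L^2 / sum(sqrt((q$A_tot / 0.5) * q$zeta / 2))^2
  expect_equal(tb$tau_star, closed, tolerance = 1e-8)
  expect_lte(tb$tau_star, 0.5 + 1e-10)
  ## stationary initial condition: zero bound
  ss <- steady_state(full_generator(ring))
  expect_equal(tau_lower_bound(ring, list("R"), ss, tau = 1)$tau_star, 0)
  ## self-consistency across random instances and unit structures
  for (s in 1:10) {
    p <- random_overlapping_unit_process(seed = s + 70)
    st <- unit_structure(p, list("A", c("A", "B"), c("A", "C")))
    p0 <- random_interior_distribution(p$space, s)
    tb <- tau_lower_bound(p, st, p0, tau = 0.6, n_steps = 32)
    expect_lte(tb$tau_star, 0.6 + 1e-9)
  }
})

test_that("the finite-time uncertainty relation holds for ring and mechanism-restricted currents", {
  ring <- build_ring_process(3, 2, 1)
  spec <- ring_winding_current(ring)
  rep <- finite_time_tur_check(ring, spec, tau = 4, n_paths = 1500, seed = 12)
  expect_true(rep$conclusive)
  expect_true(rep$satisfied)
  expect_gte(rep$ratio, 1 - 3 * rep$se)
  ## equilibrium: inconclusive (no current to resolve)
  eq <- build_ring_process(3, 1, 1)
  rep_eq <- finite_time_tur_check(eq, ring_winding_current(eq), tau = 2,
                                  n_paths = 300, seed = 1)
  expect_false(rep_eq$conclusive)
  ## mechanism-restricted current on a two-mechanism two-state system
  tm <- two_mechanism_two_state()
  W <- matrix(c(0, -1, 1, 0), 2)
  spec_a <- current_spec(tm, "A", W, mechanism = "ma")
  rep_a <- finite_time_tur_check(tm, spec_a, tau = 4, n_paths = 1500, seed = 3)
  expect_true(rep_a$conclusive)
  expect_true(rep_a$satisfied)
  expect_error(finite_time_tur_check(ring, spec, tau = 1, n_paths = 10, seed = 1),
               "n_paths")
})

test_that("the vector uncertainty relation bounds independent currents jointly", {
  dr <- double_ring_process()
  s1 <- lift_current_spec(dr, current_spec(dr, "R1", winding_weights()),
                          c("R1", "R2"))
  s2 <- lift_current_spec(dr, current_spec(dr, "R2", winding_weights()),
                          c("R1", "R2"))
  rep <- vector_tur_check(dr, list(s1, s2), tau = 3, n_paths = 600, seed = 9)
  expect_true(rep$satisfied)
  expect_gt(rep$lhs, 0)
  ## duplicated current: singular covariance is refused
  expect_error(vector_tur_check(dr, list(s1, s1), tau = 3, n_paths = 200,
                                seed = 9), "linearly dependent")
  ## a single current reduces to the scalar check
  rep1 <- vector_tur_check(dr, list(s1), tau = 3, n_paths = 300, seed = 9)
  expect_s3_class(rep1, "tur_report")
  expect_false(is.null(rep1$ratio))
})

test_that("information-flow precision is bounded, best by the smallest containing unit", {
  sens <- sensor_process()
  reports <- info_flow_tur_check(sens, list(c("X", "Y")), "X", "Y",
                                 tau = 5, n_paths = 1200, seed = 21)
  expect_equal(names(reports), "X,Y")
  expect_true(reports[[1]]$conclusive)
  expect_true(reports[[1]]$satisfied)
  ## independent blocks: inconclusive (zero flow)
  ind <- independent_mpp(2)
  rep0 <- info_flow_tur_check(ind, list(c("A", "B")), "A", "B",
                              tau = 3, n_paths = 300, seed = 2)
  expect_false(rep0[["A,B"]]$conclusive)
})

test_that("nested units order the information-flow bound (sensor with bystander)", {
  ## add an independent driven third subsystem: sigma grows with the unit,
  ## so the TUR ratio is ordered with unit size
  sp <- state_space(list(X = c("0", "1"), Y = c("0", "1"), Z = c("0", "1", "2")))
  flip <- function(x) ifelse(x == "0", "1", "0")
  mx <- list(list(from = c(X = "0"), to = c(X = "1"), rate = 2),
             list(from = c(X = "1"), to = c(X = "0"), rate = 1))
  my <- list()
  for (x in c("0", "1")) for (y in c("0", "1"))
    my[[length(my) + 1L]] <- list(from = c(X = x, Y = y), to = c(Y = flip(y)),
                                  rate = if (x == y) 3 else 0.5)
  mz <- list()
  for (i in 1:3) {
    j <- i %% 3 + 1
    mz[[length(mz) + 1L]] <- list(from = c(Z = as.character(i - 1)),
                                  to = c(Z = as.character(j - 1)), rate = 2)
    mz[[length(mz) + 1L]] <- list(from = c(Z = as.character(j - 1)),
                                  to = c(Z = as.character(i - 1)), rate = 1)
  }
  p <- composite_process(sp, list(mechanism("mx", "X", mx),
                                  mechanism("my", "Y", my),
                                  mechanism("mz", "Z", mz)))
  reports <- info_flow_tur_check(p, list(c("X", "Y")), "X", "Y",
                                 tau = 5, n_paths = 1200, seed = 31)
  expect_equal(names(reports), c("X,Y", "X,Y,Z"))
  if (reports[[1]]$conclusive && reports[[2]]$conclusive) {
    ## smaller unit, smaller EP, tighter (smaller) ratio
    expect_lte(reports[["X,Y"]]$ratio, reports[["X,Y,Z"]]$ratio + 1e-9)
    expect_true(reports[["X,Y"]]$satisfied)
  }
})
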