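test_that("joint states are ordered lexicographically and serialize canonically", {
  sp <- state_space(list(A = c("a1", "a2"), B = c("b1", "b2", "b3")))
  expect_equal(sp$n_states, 6)
  expect_equal(sp$labels[1:3], c("a1,b1", "a1,b2", "a1,b3"))
  expect_equal(sp$labels[4], "a2,b1")
  expect_equal(state_label(sp, c(B = "b2", A = "a1")), "a1,b2")
  ## marginalization collapses the right coordinates
  p <- (1:6) / 21
  expect_equal(marginalize(p, sp, "A"), c(sum(p[1:3]), sum(p[4:6])))
  expect_error(state_space(list(A = "x")), "at least 2")
})

test_that("leader sets are puppets plus parents, not grandparents", {
  ## chain C -> B -> A; mechanism moves A, conditioning on B
  sp <- state_space(list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")))
  mA <- mechanism("mA", "A", list(
    list(from = c(A = "0", B = "0"), to = c(A = "1"), rate = 1),
    list(from = c(A = "1", B = "0"), to = c(A = "0"), rate = 1),
    list(from = c(A = "0", B = "1"), to = c(A = "1"), rate = 2),
    list(from = c(A = "1", B = "1"), to = c(A = "0"), rate = 2)))
  mB <- mechanism("mB", "B", list(
    list(from = c(B = "0", C = "0"), to = c(B = "1"), rate = 1),
    list(from = c(B = "1", C = "0"), to = c(B = "0"), rate = 1),
    list(from = c(B = "0", C = "1"), to = c(B = "1"), rate = 3),
    list(from = c(B = "1", C = "1"), to = c(B = "0"), rate = 3)))
  mC <- mechanism("mC", "C", list(
    list(from = c(C = "0"), to = c(C = "1"), rate = 1),
    list(from = c(C = "1"), to = c(C = "0"), rate = 1)))
  p <- composite_process(sp, list(mA, mB, mC))
  expect_equal(leader_set(p, "mA"), c("A", "B"))   # parent only, no C
  expect_equal(leader_set(p, "mB"), c("B", "C"))
  expect_equal(leader_set(p, "mC"), "C")
  ## empty dependency: leaders of a single puppet are itself
  ind <- independent_mpp(2)
  expect_equal(leader_set(ind, "mA"), "A")
  ## proper enlargement on the four-subsystem example
  br <- build_branched_dependency()
  expect_equal(leader_set(br, "v2"), c("A", "B", "C", "D"))
  expect_true(all(br$mechanisms$v2$puppets %in% leader_set(br, "v2")))
  expect_gt(length(leader_set(br, "v2")), length(br$mechanisms$v2$puppets))
})

test_that("mechanism generators have the Kronecker-delta support and conserve probability", {
  p <- random_composite_process(3, 3, seed = 42)
  sp <- p$space
  for (id in names(p$mechanisms)) {
    K <- mechanism_generator(p, id)
    expect_lt(max(abs(colSums(K))), 1e-10)
    ## entries between states differing outside the puppet set are zero
    pup <- p$mechanisms[[id]]$puppets
    rest <- setdiff(sp$subsystems, pup)
    if (length(rest)) {
      off <- apply(sp$states[, rest, drop = FALSE], 1, paste, collapse = ",")
      differs <- outer(off, off, `!=`)
      expect_true(all(K[differs] == 0))
    }
  }
  ## a singleton-puppet mechanism only connects states differing in one coordinate
  mpp <- random_composite_process(3, 3, seed = 7, mpp = TRUE)
  for (id in names(mpp$mechanisms)) {
    K <- mechanism_generator(mpp, id)
    nz <- which(K > 0, arr.ind = TRUE)
    ndiff <- apply(nz, 1, function(rc)
      sum(mpp$space$states[rc[1], ] != mpp$space$states[rc[2], ]))
    expect_true(all(ndiff == 1))
  }
})

test_that("the full generator is the sum of mechanism generators (brute-force oracle)", {
  p <- random_composite_process(3, 4, seed = 11)
  sp <- p$space
  ## independent assembly: enumerate all state pairs and match rate entries
  n <- sp$n_states
  K_oracle <- matrix(0, n, n)
  for (m in p$mechanisms) {
    for (x in seq_len(n)) for (xp in seq_len(n)) {
      if (x == xp) next
      rest <- setdiff(sp$subsystems, m$puppets)
      if (length(rest) && !all(sp$states[x, rest] == sp$states[xp, rest])) next
      for (r in seq_len(nrow(m$from))) {
        if (all(sp$states[xp, m$cond] == m$from[r, ]) &&
            all(sp$states[x, m$puppets] == m$to[r, ]))
          K_oracle[x, xp] <- K_oracle[x, xp] + m$rate[r, 1]
      }
    }
  }
  diag(K_oracle) <- diag(K_oracle) - colSums(K_oracle)
  expect_equal(full_generator(p), K_oracle, tolerance = 1e-12)
  ## disjoint puppet sets have disjoint off-diagonal supports
  ind <- independent_mpp(2)
  KA <- mechanism_generator(ind, "mA"); diag(KA) <- 0
  KB <- mechanism_generator(ind, "mB"); diag(KB) <- 0
  expect_true(all(KA * KB == 0))
})

test_that("units are recognized structurally with certificates", {
  p <- random_overlapping_unit_process(seed = 1)
  expect_true(is_unit(p, "A"))
  expect_true(is_unit(p, c("A", "B")))
  expect_true(is_unit(p, c("A", "B", "C")))  # the full system is a unit
  notB <- is_unit(p, "B")
  expect_false(notB)
  expect_true("mB" %in% attr(notB, "violations"))
  ## union and nonempty intersection of verified units are units
  expect_true(is_unit(p, union(c("A", "B"), c("A", "C"))))
  expect_true(is_unit(p, intersect(c("A", "B"), c("A", "C"))))
})

test_that("unit closure under union/intersection holds exhaustively on random instances", {
  for (s in 1:10) {
    p <- random_composite_process(4, 4, seed = s)
    subs <- p$space$subsystems
    all_subsets <- unlist(lapply(seq_along(subs), function(k)
      utils::combn(subs, k, simplify = FALSE)), recursive = FALSE)
    units <- Filter(function(u) isTRUE(is_unit(p, u)), all_subsets)
    for (a in units) for (b in units) {
      expect_true(is_unit(p, union(a, b)))
      if (length(intersect(a, b))) expect_true(is_unit(p, intersect(a, b)))
    }
  }
})

test_that("unit structures close under intersection and check the cover", {
  p <- random_overlapping_unit_process(seed = 5)
  st <- unit_structure(p, list(c("A", "B"), c("A", "C")))
  expect_equal(st$keys, c("A", "A,B", "A,C"))  # closure added {A}
  st1 <- unit_structure(p, list(c("A", "B", "C")))
  expect_equal(length(st1$units), 1L)
  ## disjoint cover adds nothing
  ind <- independent_mpp(3)
  st2 <- unit_structure(ind, list(c("A", "B"), "C"))
  expect_equal(st2$keys, c("A,B", "C"))
  ## cover failure
  expect_error(unit_structure(p, list(c("A", "B"))), "cover")
  expect_error(unit_structure(p, list("B")), "not a unit")
})

test_that("unit generators reproduce the marginal dynamics", {
  p <- random_overlapping_unit_process(seed = 3)
  ## full system's unit generator is the full generator
  expect_equal(unit_generator(p, p$space$subsystems), full_generator(p))
  ## independent subsystems: single-subsystem unit generator
  ind <- independent_mpp(2, rate = 1.5)
  KA <- unit_generator(ind, "A")
  expect_equal(KA, matrix(c(-1.5, 1.5, 1.5, -1.5), 2))
  expect_error(unit_generator(p, "B"), "not a unit")
})

test_that("rates ignore non-leader coordinates and inference reconstructs the network", {
  p <- random_overlapping_unit_process(seed = 9)
  inferred <- infer_dependency_network(p)
  expect_setequal(paste(inferred[, 1], inferred[, 2]), c("A B", "A C"))
  ## redeclaring with the inferred edges validates quietly
  expect_silent(composite_process(p$space, list(
    mechanism("mB", "B", list(
      list(from = c(A = "0", B = "0"), to = c(B = "1"), rate = 1),
      list(from = c(A = "0", B = "1"), to = c(B = "0"), rate = 2),
      list(from = c(A = "1", B = "0"), to = c(B = "1"), rate = 3),
      list(from = c(A = "1", B = "1"), to = c(B = "0"), rate = 4)),
    )), dependencies = list(c("A", "B"))))
  ## over-declared edge warns; missing edge errors
  expect_warning(composite_process(p$space, list(
    mechanism("mB", "B", list(
      list(from = c(B = "0"), to = c(B = "1"), rate = 1),
      list(from = c(B = "1"), to = c(B = "0"), rate = 2)))),
    dependencies = list(c("A", "B"))), "not realized")
  expect_error(composite_process(p$space, list(
    mechanism("mB", "B", list(
      list(from = c(A = "0", B = "0"), to = c(B = "1"), rate = 1),
      list(from = c(A = "0", B = "1"), to = c(B = "0"), rate = 2),
      list(from = c(A = "1", B = "0"), to = c(B = "1"), rate = 3),
      list(from = c(A = "1", B = "1"), to = c(B = "0"), rate = 4)))),
    dependencies = list()), "missing inferred edge")
  ## conditioning on a non-leader coordinate is rejected even when declared
  expect_error(composite_process(p$space, list(
    mechanism("mB", "B", list(
      list(from = c(C = "0", B = "0"), to = c(B = "1"), rate = 1),
      list(from = c(C = "0", B = "1"), to = c(B = "0"), rate = 2),
      list(from = c(C = "1", B = "0"), to = c(B = "1"), rate = 3),
      list(from = c(C = "1", B = "1"), to = c(B = "0"), rate = 4))),
    mechanism("mC", "C", list(
      list(from = c(C = "0"), to = c(C = "1"), rate = 1),
      list(from = c(C = "1"), to = c(C = "0"), rate = 1)))),
    dependencies = list()), "missing inferred edge")
})

test_that("irreversible mechanisms are rejected at validation", {
  sp <- state_space(list(A = c("0", "1")))
  expect_error(composite_process(sp, list(mechanism("m", "A", list(
    list(from = c(A = "0"), to = c(A = "1"), rate = 1))))),
    "irreversible")
})

test_that("randomizing an ignored coordinate leaves generators unchanged", {
  ## mB conditions on (A, B); the C coordinate never enters
  p <- random_overlapping_unit_process(seed = 21)
  K <- mechanism_generator(p, "mB")
  sp <- p$space
  ## permuting the C-blocks of the state order leaves the mB-entries equal
  perm <- order(sp$states[, "A"], sp$states[, "B"], rev(sp$states[, "C"]))
  expect_equal(K[perm, perm], K)
})

test_that("process JSON configs round-trip losslessly", {
  p <- build_nested_periodic(3, 4, 1, seed = 2)$process
  f <- withr::local_tempfile(fileext = ".json")
  write_process_json(p, f)
  p2 <- read_process_json(f)
  expect_identical(p2$space$labels, p$space$labels)
  expect_equal(sort(edge_str <- paste(p2$dependency[, 1], p2$dependency[, 2])),
               sort(paste(p$dependency[, 1], p$dependency[, 2])))
  for (id in names(p$mechanisms))
    for (t in c(0, 0.4))
      expect_equal(mechanism_generator(p2, id, t), mechanism_generator(p, id, t))
  ## and DOT export mentions every subsystem and mechanism
  dot <- export_dot(p)
  expect_true(all(vapply(c("A", "B", "C", "vB", "vC"), grepl, TRUE, x = dot,
                         fixed = TRUE)))
})
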