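## Builders for worked examples, a mass-action reaction-network compiler
## onto truncated count spaces, and seeded random-instance generators for
## property suites.

## ---- reaction networks ------------------------------------------------

#' Parse a reversible mass-action reaction network
#'
#' Accepts lines of the form `2 X1 + 1 X2 <-> 1 X3, 1.0, 1.0` (stoichiometric
#' coefficient, species, `<->`, then forward and backward rate constants).
#' Coefficients default to 1 when omitted.  Every reaction must be
#' reversible (both constants positive).  Species order is
#' first-appearance order.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return object of class `reaction_network` with `species` and
#'   `reactions` (each with named integer `reactants`, `products`, and
#'   rate constants `kf`, `kr`).
#' @export
parse_crn <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("parse_crn: empty reaction network")
  species <- character(0)
  parse_side <- function(s, lineno) {
    terms <- trimws(unlist(strsplit(s, "\\+")))
    out <- integer(0)
    for (term in terms) {
      mm <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z][A-Za-z0-9_]*)$", term))[[1]]
      if (!length(mm))
        stop("parse_crn: malformed term '", term, "' on line ", lineno)
      coef <- if (nzchar(mm[2])) as.integer(mm[2]) else 1L
      sp <- mm[3]
      out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
    }
    out
  }
  reactions <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- trimws(unlist(strsplit(lines[i], ",")))
    if (length(parts) != 3L)
      stop("parse_crn: line ", i, " must be 'reaction, kf, kr'")
    sides <- trimws(unlist(strsplit(parts[1], "<->", fixed = TRUE)))
    if (length(sides) != 2L)
      stop("parse_crn: line ", i, " is not a reversible reaction (need '<->')")
    kf <- suppressWarnings(as.numeric(parts[2]))
    kr <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(kf) || is.na(kr))
      stop("parse_crn: line ", i, " has non-numeric rate constants")
    if (kf <= 0 || kr <= 0)
      stop("parse_crn: line ", i, " is irreversible (both constants must be > 0)")
    reac <- parse_side(sides[1], i)
    prod <- parse_side(sides[2], i)
    for (sp in c(names(reac), names(prod)))
      if (!sp %in% species) species <- c(species, sp)
    reactions[[i]] <- list(reactants = reac, products = prod, kf = kf, kr = kr)
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' Serialize a reaction network back to its text format
#' @param network a [parse_crn()] result.
#' @return character vector, one line per reaction.
#' @export
serialize_crn <- function(network) {
  vapply(network$reactions, function(r) {
    side <- function(v) paste(paste(v, names(v)), collapse = " + ")
    paste0(side(r$reactants), " <-> ", side(r$products), ", ",
           format(r$kf), ", ", format(r$kr))
  }, "")
}

falling_factorial <- function(n, k) {
  if (k == 0L) return(rep(1, length(n)))
  out <- rep(1, length(n))
  for (j in 0:(k - 1L)) out <- out * pmax(n - j, 0)
  out
}

#' Compile a mass-action reaction network into a composite process
#'
#' Each species count becomes a subsystem with domain `0..cap`; each
#' reversible reaction becomes one mechanism whose puppet set is the
#' species with nonzero net stoichiometric change and whose rates are
#' mass-action propensities (rate constant times falling factorials of the
#' source counts).  Transitions that would leave the capped count box are
#' deleted together with their reverses (reflecting truncation), which
#' preserves per-mechanism reversibility.  Whenever some reaction changes
#' two or more species, the result is a composite process that is not
#' multipartite.
#'
#' @param network a [parse_crn()] result.
#' @param cap per-species count cap (default 5; must be at least the
#'   largest single-reaction change of any species).
#' @return a validated [composite_process()]; mechanism ids are `r1`,
#'   `r2`, ... in reaction order.
#' @export
crn_to_process <- function(network, cap = 5L) {
  cap <- as.integer(cap)
  domains <- stats::setNames(
    rep(list(as.character(0:cap)), length(network$species)),
    network$species)
  sp <- state_space(domains)
  mechs <- vector("list", length(network$reactions))
  for (ri in seq_along(network$reactions)) {
    r <- network$reactions[[ri]]
    all_sp <- union(names(r$reactants), names(r$products))
    net <- stats::setNames(integer(length(all_sp)), all_sp)
    net[names(r$products)] <- net[names(r$products)] + r$products
    net[names(r$reactants)] <- net[names(r$reactants)] - r$reactants
    if (any(abs(net) > cap))
      stop("crn_to_process: cap ", cap, " is smaller than the count change of ",
           "reaction ", ri)
    puppets <- names(net)[net != 0L]
    if (!length(puppets))
      stop("crn_to_process: reaction ", ri, " changes no species counts")
    cond <- network$species[network$species %in% all_sp]
    grid <- expand.grid(rep(list(0:cap), length(cond)),
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- cond
    entries <- list(); k <- 0L
    for (g in seq_len(nrow(grid))) {
      counts <- stats::setNames(as.integer(grid[g, ]), cond)
      ## forward direction
      tgt <- counts[puppets] + net[puppets]
      if (all(tgt >= 0L & tgt <= cap)) {
        rate <- r$kf
        for (s in names(r$reactants))
          rate <- rate * falling_factorial(counts[[s]], r$reactants[[s]])
        if (rate > 0) {
          k <- k + 1L
          entries[[k]] <- list(from = stats::setNames(as.character(counts), cond),
                               to = stats::setNames(as.character(tgt), puppets),
                               rate = rate)
        }
      }
      ## backward direction
      tgt <- counts[puppets] - net[puppets]
      if (all(tgt >= 0L & tgt <= cap)) {
        rate <- r$kr
        for (s in names(r$products))
          rate <- rate * falling_factorial(counts[[s]], r$products[[s]])
        if (rate > 0) {
          k <- k + 1L
          entries[[k]] <- list(from = stats::setNames(as.character(counts), cond),
                               to = stats::setNames(as.character(tgt), puppets),
                               rate = rate)
        }
      }
    }
    if (!k) stop("crn_to_process: reaction ", ri,
                 " has no feasible transitions within the cap")
    mechs[[ri]] <- mechanism(paste0("r", ri), puppets, entries)
  }
  composite_process(sp, mechs, dependencies = "infer")
}

## ---- worked-example builders -----------------------------------------

#' Toy chemical reaction network with shared multi-species mechanisms
#'
#' Four species, three reversible reactions; the first reaction changes
#' three species at once (counts -2, -1, +1), so the compiled process is a
#' composite process but not a multipartite one.  Rate constants are
#' placeholder values (1.0) unless overridden: the example fixes the
#' topology, not the numerics.
#'
#' @param cap per-species count cap (default 2, keeping the joint space
#'   small).
#' @param kf,kr rate constants applied to every reaction.
#' @return a validated [composite_process()].
#' @export
build_toy_crn <- function(cap = 2L, kf = 1, kr = 1) {
  txt <- c(paste0("2 X1 + 1 X2 <-> 1 X3, ", kf, ", ", kr),
           paste0("1 X3 <-> 1 X4, ", kf, ", ", kr),
           paste0("1 X1 + 1 X4 <-> 1 X2, ", kf, ", ", kr))
  crn_to_process(parse_crn(txt), cap = cap)
}

#' Toy circuit with two free conductors and three devices
#'
#' Two free conductors hold a discretized voltage each; two further
#' conductors are regulated (tied to fixed sources) and enter only as
#' fixed parameters.  Device mechanisms `dA` and `dC` move one conductor at
#' a time; device `dB` transfers charge between the two free conductors,
#' moving both voltages in opposite directions simultaneously.  The device
#' incidence beyond this is an assumption of the builder; rates are
#' placeholder constants.
#'
#' @param n_levels number of voltage levels per free conductor (default 3).
#' @param rate placeholder transition rate (default 1).
#' @return a validated [composite_process()].
#' @export
build_toy_circuit <- function(n_levels = 3L, rate = 1) {
  lv <- as.character(seq_len(n_levels) - 1L)
  sp <- state_space(list(c2 = lv, c3 = lv))
  hop_entries <- function(sub) {
    out <- list(); k <- 0L
    for (i in seq_len(n_levels - 1L)) {
      k <- k + 1L
      out[[k]] <- list(from = stats::setNames(lv[i], sub),
                       to = stats::setNames(lv[i + 1L], sub), rate = rate)
      k <- k + 1L
      out[[k]] <- list(from = stats::setNames(lv[i + 1L], sub),
                       to = stats::setNames(lv[i], sub), rate = rate)
    }
    out
  }
  transfer <- list(); k <- 0L
  for (i in seq_len(n_levels - 1L)) for (j in seq_len(n_levels - 1L)) {
    k <- k + 1L
    transfer[[k]] <- list(from = c(c2 = lv[i], c3 = lv[j + 1L]),
                          to = c(c2 = lv[i + 1L], c3 = lv[j]), rate = rate)
    k <- k + 1L
    transfer[[k]] <- list(from = c(c2 = lv[i + 1L], c3 = lv[j]),
                          to = c(c2 = lv[i], c3 = lv[j + 1L]), rate = rate)
  }
  composite_process(sp, list(
    mechanism("dA", "c2", hop_entries("c2")),
    mechanism("dB", c("c2", "c3"), transfer),
    mechanism("dC", "c3", hop_entries("c3"))),
    dependencies = "infer")
}

#' Four-subsystem example with a proper leader-set enlargement
#'
#' A mechanism `v2` jointly flips subsystems `A`, `C`, `D` at a rate that
#' depends on the state of `B`; the dependency edges `B -> A`, `B -> C`,
#' `B -> D` make the leader set `{A, B, C, D}` a strict superset of the
#' puppet set `{A, C, D}`.  A second mechanism `v1` flips `B` on its own.
#' Rates are validated placeholders.
#'
#' @return a validated [composite_process()].
#' @export
build_branched_dependency <- function() {
  sp <- state_space(list(A = c("0", "1"), B = c("0", "1"),
                         C = c("0", "1"), D = c("0", "1")))
  flip <- function(x) ifelse(x == "0", "1", "0")
  v2 <- list(); k <- 0L
  for (a in c("0", "1")) for (b in c("0", "1"))
    for (cc in c("0", "1")) for (d in c("0", "1")) {
      k <- k + 1L
      v2[[k]] <- list(from = c(A = a, B = b, C = cc, D = d),
                      to = c(A = flip(a), C = flip(cc), D = flip(d)),
                      rate = if (b == "0") 1 else 2)
    }
  v1 <- list(list(from = c(B = "0"), to = c(B = "1"), rate = 1),
             list(from = c(B = "1"), to = c(B = "0"), rate = 1))
  composite_process(sp, list(mechanism("v1", "B", v1),
                             mechanism("v2", c("A", "C", "D"), v2)),
                    dependencies = "infer")
}

#' Nested periodic three-subsystem instance
#'
#' Builds the composite process behind the nested periodicity bound: a
#' frozen binary subsystem `A` and binary subsystems `B` and `C` driven by
#' piecewise-constant periodic mechanisms whose rates depend on `A`.  The
#' periods satisfy `lambda_B = m lambda_C / n` with `m`, `n` coprime and
#' `n > m > 2`, so the full dynamics is periodic with
#' `tau = n lambda_B = m lambda_C` while each of the units `{A,B}` and
#' `{A,C}` completes `n` (resp. `m`) of its own periods.
#'
#' @param m,n coprime positive integers with `n > m > 2`.
#' @param lambda_C period of the `C` mechanism.
#' @param seed integer seed for the random (generically irreversible)
#'   segment rates and the random interior initial distribution.
#' @return object of class `nested_periodic_instance` with fields
#'   `process`, `A`, `B`, `C`, `lambda_B`, `lambda_C`, `m`, `n`, `tau`,
#'   `p0`.
#' @export
build_nested_periodic <- function(m = 3L, n = 4L, lambda_C = 1, seed = 1L) {
  m <- as.integer(m); n <- as.integer(n)
  gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)
  if (m <= 2L) stop("build_nested_periodic: need m > 2")
  if (n <= m) stop("build_nested_periodic: need n > m")
  if (gcd(n, m) != 1L) stop("build_nested_periodic: m and n must be coprime")
  lambda_B <- m * lambda_C / n
  tau <- m * lambda_C
  if (abs(n * lambda_B - tau) > 1e-12 * tau)
    stop("build_nested_periodic: period bookkeeping failed")
  set.seed(seed)
  sp <- state_space(list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")))
  flip_entries <- function(target, cond_extra, n_seg) {
    out <- list(); k <- 0L
    for (a in c("0", "1")) for (x in c("0", "1")) {
      k <- k + 1L
      from <- stats::setNames(c(a, x), c(cond_extra, target))
      out[[k]] <- list(from = from,
                       to = stats::setNames(ifelse(x == "0", "1", "0"), target),
                       rate = exp(stats::runif(n_seg, log(0.3), log(3))))
    }
    out
  }
  vB <- mechanism("vB", "B", flip_entries("B", "A", 2L),
                  protocol = rate_protocol(lambda_B, c(0, lambda_B / 2)))
  vC <- mechanism("vC", "C", flip_entries("C", "A", 2L),
                  protocol = rate_protocol(lambda_C, c(0, lambda_C / 2)))
  proc <- composite_process(sp, list(vB, vC), dependencies = "infer")
  p0 <- stats::runif(sp$n_states, 0.2, 1)
  p0 <- p0 / sum(p0)
  structure(list(process = proc, A = "A", B = "B", C = "C",
                 lambda_B = lambda_B, lambda_C = lambda_C,
                 m = m, n = n, tau = tau, p0 = p0),
            class = "nested_periodic_instance")
}

## ---- random instance generators --------------------------------------

#' Seeded random composite process
#'
#' Draws a reproducible composite process with random puppet sets, random
#' dependency enlargements, and strictly positive reversible rates; every
#' subsystem belongs to at least one puppet set, and puppet-configuration
#' moves form a connected graph, so the full generator is irreducible.
#'
#' @param n_subsystems number of subsystems (ids `S1`, `S2`, ...).
#' @param n_mechanisms number of mechanisms (at least enough to cover all
#'   subsystems given the puppet sizes used).
#' @param n_states states per subsystem (default 2).
#' @param density fraction of additional puppet-configuration pairs to
#'   couple beyond a connecting path (default 1).
#' @param seed integer seed.
#' @param mpp if `TRUE`, every puppet set is a singleton (multipartite
#'   process).
#' @return a validated [composite_process()].
#' @export
random_composite_process <- function(n_subsystems = 3L, n_mechanisms = 3L,
                                     n_states = 2L, density = 1,
                                     seed = 1L, mpp = FALSE) {
  set.seed(seed)
  subs <- paste0("S", seq_len(n_subsystems))
  dom <- as.character(seq_len(n_states) - 1L)
  sp <- state_space(stats::setNames(rep(list(dom), n_subsystems), subs))
  mechs <- vector("list", n_mechanisms)
  for (v in seq_len(n_mechanisms)) {
    anchor <- subs[(v - 1L) %% n_subsystems + 1L]  # guarantee coverage
    psize <- if (mpp) 1L else sample(1:min(2L, n_subsystems), 1L)
    puppets <- unique(c(anchor, sample(subs, psize)))[seq_len(psize)]
    puppets <- unique(c(anchor, puppets))
    extra <- setdiff(subs, puppets)
    cond <- puppets
    if (length(extra) && stats::runif(1) < 0.5)
      cond <- c(cond, sample(extra, 1L))
    psub <- marginal_space(sp, puppets)
    configs <- psub$labels
    nc <- length(configs)
    pairs <- if (nc > 1L) cbind(seq_len(nc - 1L), 2:nc) else NULL
    if (nc > 2L && density > 0) {
      others <- utils::combn(nc, 2L)
      others <- others[, others[2, ] - others[1, ] > 1L, drop = FALSE]
      keep <- stats::runif(ncol(others)) < density
      pairs <- rbind(pairs, t(others[, keep, drop = FALSE]))
    }
    cond <- normalize_members(sp, cond)
    csub <- marginal_space(sp, cond)
    entries <- list(); k <- 0L
    pup_of_cond <- apply(csub$states[, puppets, drop = FALSE], 1L,
                         paste, collapse = ",")
    for (ci in seq_len(csub$n_states)) {
      from <- stats::setNames(csub$states[ci, ], cond)
      for (pr in seq_len(nrow(pairs))) {
        here <- match(pup_of_cond[ci], configs)
        tgt_idx <- if (pairs[pr, 1] == here) pairs[pr, 2]
        else if (pairs[pr, 2] == here) pairs[pr, 1] else next
        k <- k + 1L
        entries[[k]] <- list(
          from = from,
          to = stats::setNames(psub$states[tgt_idx, ], puppets),
          rate = exp(stats::runif(1, log(0.3), log(3))))
      }
    }
    mechs[[v]] <- mechanism(paste0("v", v), puppets, entries)
  }
  composite_process(sp, mechs, dependencies = "infer")
}

#' Random three-subsystem process with the overlapping unit structure
#'
#' Binary subsystems `A`, `B`, `C` and three mechanisms: one flips `A`
#' depending only on `A`, one flips `B` depending on `(A, B)`, one flips
#' `C` depending on `(A, C)`.  By construction `{A}`, `{A,B}` and `{A,C}`
#' are units, so `{A, AB, AC}` is a valid (overlapping) unit structure.
#' Rates are strictly positive and log-uniform, so the process is
#' generically far from detailed balance.
#'
#' @param seed integer seed.
#' @param frozen_A if `TRUE`, omit the `A`-flipping mechanism, leaving `A`
#'   frozen.
#' @return a validated [composite_process()].
#' @export
random_overlapping_unit_process <- function(seed = 1L, frozen_A = FALSE) {
  set.seed(seed)
  sp <- state_space(list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")))
  flip <- function(x) ifelse(x == "0", "1", "0")
  rr <- function() exp(stats::runif(1, log(0.3), log(3)))
  entA <- list(); k <- 0L
  for (a in c("0", "1")) {
    k <- k + 1L
    entA[[k]] <- list(from = c(A = a), to = c(A = flip(a)), rate = rr())
  }
  two_site <- function(cond_id, target) {
    out <- list(); k <- 0L
    for (a in c("0", "1")) for (x in c("0", "1")) {
      k <- k + 1L
      out[[k]] <- list(from = stats::setNames(c(a, x), c(cond_id, target)),
                       to = stats::setNames(flip(x), target), rate = rr())
    }
    out
  }
  mechs <- list(mechanism("mB", "B", two_site("A", "B")),
                mechanism("mC", "C", two_site("A", "C")))
  if (!frozen_A) mechs <- c(list(mechanism("mA", "A", entA)), mechs)
  composite_process(sp, mechs, dependencies = "infer")
}

#' Random strictly positive (interior) distribution
#'
#' Entries uniform on `[0.2, 1]` before normalization, so entropy
#' production stays finite from time zero.
#'
#' @param space a [state_space()].
#' @param seed integer seed.
#' @return probability vector.
#' @export
random_interior_distribution <- function(space, seed = 1L) {
  set.seed(seed)
  p <- stats::runif(space$n_states, 0.2, 1)
  p / sum(p)
}

#' Biased ring process on a single subsystem
#'
#' A single subsystem with `n_states` arranged on a ring, one mechanism,
#' clockwise rate `forward` and counter-clockwise rate `backward`.  The
#' canonical driven process for current and uncertainty-relation tests:
#' the stationary state is uniform with a uniform circulating current.
#'
#' @param n_states ring size (default 3).
#' @param forward,backward hop rates.
#' @return a validated [composite_process()].
#' @export
build_ring_process <- function(n_states = 3L, forward = 2, backward = 1) {
  lv <- as.character(seq_len(n_states) - 1L)
  sp <- state_space(list(R = lv))
  ent <- list(); k <- 0L
  for (i in seq_len(n_states)) {
    j <- i %% n_states + 1L
    k <- k + 1L
    ent[[k]] <- list(from = c(R = lv[i]), to = c(R = lv[j]), rate = forward)
    k <- k + 1L
    ent[[k]] <- list(from = c(R = lv[j]), to = c(R = lv[i]), rate = backward)
  }
  composite_process(sp, list(mechanism("hop", "R", ent)),
                    dependencies = "infer")
}

#' Winding-number current on a ring process
#'
#' Weight +1 for each clockwise hop and -1 for each counter-clockwise hop.
#'
#' @param process a [build_ring_process()] result.
#' @return a [current_spec()].
#' @export
ring_winding_current <- function(process) {
  n <- process$space$n_states
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    C[j, i] <- 1
    C[i, j] <- -1
  }
  current_spec(process, process$space$subsystems, C)
}
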