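#' Test whether a subsystem subset is a unit
#'
#' A unit is a subsystem subset whose marginal distribution evolves under
#' its own rate matrix, autonomously of the rest of the system.  The test is
#' structural: for every mechanism, either the mechanism's leader set lies
#' inside the subset (the mechanism acts and is resolvable within it) or its
#' puppet set is disjoint from the subset (the mechanism never moves it).
#'
#' @param process a [composite_process()].
#' @param members candidate subsystem subset.
#' @return `TRUE`/`FALSE`; on `FALSE` the attribute `"violations"` lists the
#'   offending mechanism ids.
#' @export
is_unit <- function(process, members) {
  members <- normalize_members(process$space, members)
  if (!length(members)) stop("is_unit: empty subset")
  bad <- character(0)
  for (m in process$mechanisms) {
    if (all(m$leaders %in% members)) next
    if (!length(intersect(m$puppets, members))) next
    bad <- c(bad, m$id)
  }
  structure(length(bad) == 0L, violations = bad)
}

#' Marginal rate matrix of a unit
#'
#' The unit's generator is the sum, over mechanisms whose leader set lies
#' inside the unit, of the mechanism rate matrices restricted to the unit's
#' coordinates.  This is well defined because those rates depend only on
#' leader coordinates, all of which the unit contains.
#'
#' @param process a [composite_process()].
#' @param members a verified unit.
#' @param t evaluation time for driven mechanisms.
#' @return square matrix over the states of `marginal_space(space, members)`.
#' @export
unit_generator <- function(process, members, t = 0) {
  members <- normalize_members(process$space, members)
  ok <- is_unit(process, members)
  if (!ok)
    stop("{", paste(members, collapse = ","), "} is not a unit; mechanism(s) ",
         paste(attr(ok, "violations"), collapse = ", "),
         " straddle its boundary")
  sub <- marginal_space(process$space, members)
  n <- sub$n_states
  K <- matrix(0, n, n)
  states <- sub$states
  for (m in process$mechanisms) {
    if (!all(m$leaders %in% members)) next
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
  }
  diag(K) <- diag(K) - colSums(K)
  K
}

#' Mechanisms acting inside a unit
#'
#' Ids of the mechanisms whose leader set lies inside the given subsystem
#' subset; these are exactly the mechanisms contributing to the unit's
#' generator, activity and entropy production.
#'
#' @param process a [composite_process()].
#' @param members subsystem subset.
#' @return character vector of mechanism ids.
#' @export
unit_mechanisms <- function(process, members) {
  members <- normalize_members(process$space, members)
  ids <- vapply(process$mechanisms, `[[`, "", "id")
  keep <- vapply(process$mechanisms,
                 function(m) all(m$leaders %in% members), TRUE)
  unname(ids[keep])
}

unit_key <- function(space, members) {
  paste(normalize_members(space, members), collapse = ",")
}

#' Build a unit structure: an intersection-closed covering family of units
#'
#' Starting from the supplied units, repeatedly adds all nonempty pairwise
#' intersections until the family is closed, verifies that every element is
#' a unit and that the family covers all subsystems, and orders the units
#' canonically (lexicographically by their comma-joined member labels).
#'
#' @param process a [composite_process()].
#' @param units list of subsystem subsets, each a verified unit.
#' @return an object of class `unit_structure` with fields `units` (list of
#'   character vectors) and `keys`.
#' @export
unit_structure <- function(process, units) {
  sp <- process$space
  units <- lapply(units, function(u) normalize_members(sp, u))
  for (u in units) {
    ok <- is_unit(process, u)
    if (!ok)
      stop("{", paste(u, collapse = ","), "} is not a unit; mechanism(s) ",
           paste(attr(ok, "violations"), collapse = ", "),
           " straddle its boundary")
  }
  keys <- vapply(units, function(u) paste(u, collapse = ","), "")
  units <- units[!duplicated(keys)]
  repeat {
    added <- FALSE
    nu <- length(units)
    keys <- vapply(units, function(u) paste(u, collapse = ","), "")
    for (a in seq_len(nu)) for (b in seq_len(nu)) {
      if (b <= a) next
      inter <- intersect(units[[a]], units[[b]])
      if (!length(inter)) next
      key <- paste(normalize_members(sp, inter), collapse = ",")
      if (!key %in% keys) {
        ok <- is_unit(process, inter)
        if (!ok)
          stop("internal consistency error: intersection {", key,
               "} of two units is not a unit")
        units <- c(units, list(normalize_members(sp, inter)))
        keys <- c(keys, key)
        added <- TRUE
      }
    }
    if (!added) break
  }
  covered <- unique(unlist(units))
  uncovered <- setdiff(sp$subsystems, covered)
  if (length(uncovered))
    stop("unit structure does not cover subsystem(s): ",
         paste(uncovered, collapse = ", "))
  ord <- order(vapply(units, function(u) paste(u, collapse = ","), ""))
  units <- units[ord]
  structure(list(units = units,
                 keys = vapply(units, function(u) paste(u, collapse = ","), ""),
                 subsystems = sp$subsystems),
            class = "unit_structure")
}

#' @export
print.unit_structure <- function(x, ...) {
  cat("<unit_structure> ", length(x$units), " units: ",
      paste0("{", x$keys, "}", collapse = " "), "\n", sep = "")
  invisible(x)
}

## All nonempty index subsets of the structure's units with their
## inclusion-exclusion signs and the member intersection of each tuple.
## The sum runs over index tuples, not distinct sets, as in the defining
## combinatorial formula.
inex_tuples <- function(structure) {
  n <- length(structure$units)
  out <- list(); k <- 0L
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size, simplify = FALSE)
    for (cc in combs) {
      inter <- Reduce(intersect, structure$units[cc])
      k <- k + 1L
      out[[k]] <- list(indices = cc, sign = (-1)^(size + 1),
                       members = inter,
                       key = paste(inter, collapse = ","))
    }
  }
  out
}
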