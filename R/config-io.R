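## Declarative JSON configuration for composite processes, and DOT export
## of the dependency network.

#' Write a composite process to a JSON configuration
#'
#' The configuration lists subsystems with their state domains, dependency
#' edges, and mechanisms with their (canonically expanded) rate entries and
#' optional protocols.  Reading the file back reconstructs an equivalent
#' process: identical state space, dependency network, and mechanism
#' generators.
#'
#' @param process a [composite_process()].
#' @param file output path; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_process_json <- function(process, file = NULL) {
  sp <- process$space
  cfg <- list(
    subsystems = lapply(sp$subsystems, function(id)
      list(id = id, states = sp$domains[[id]])),
    dependencies = unname(apply(process$dependency, 1L, function(e)
      as.list(unname(e)), simplify = FALSE)),
    mechanisms = lapply(unname(process$mechanisms), function(m) {
      entry <- list(
        id = m$id, puppets = m$puppets,
        rates = lapply(seq_len(nrow(m$from)), function(r)
          list(from = as.list(m$from[r, , drop = TRUE]),
               to = as.list(m$to[r, , drop = TRUE]),
               rate = unname(m$rate[r, ]))))
      if (!is.null(m$protocol))
        entry$protocol <- list(period = m$protocol$period,
                               times = m$protocol$times)
      entry
    }))
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a composite process from a JSON configuration
#'
#' @param file path to a configuration written by [write_process_json()]
#'   (or hand-authored in the same schema; `from` entries may be partial
#'   leader assignments and `to` entries partial puppet assignments).
#' @return a validated [composite_process()].
#' @export
read_process_json <- function(file) {
  cfg <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  domains <- stats::setNames(
    lapply(cfg$subsystems, function(s) unlist(s$states)),
    vapply(cfg$subsystems, function(s) s$id, ""))
  sp <- state_space(domains)
  deps <- if (length(cfg$dependencies))
    do.call(rbind, lapply(cfg$dependencies, function(e)
      c(e[[1]], e[[2]])))
  else matrix(character(0), ncol = 2)
  mechs <- lapply(cfg$mechanisms, function(mc) {
    proto <- if (!is.null(mc$protocol))
      rate_protocol(mc$protocol$period, unlist(mc$protocol$times))
    rates <- lapply(mc$rates, function(e)
      list(from = unlist(e$from), to = unlist(e$to),
           rate = unlist(e$rate)))
    mechanism(mc$id, unlist(mc$puppets), rates, protocol = proto)
  })
  composite_process(sp, mechs, dependencies = deps)
}

#' Export the dependency network (and puppet hypergraph) as DOT
#'
#' Emits one node per subsystem and one directed edge per dependency; each
#' mechanism is drawn as a box node joined by dashed edges to its puppets,
#' rendering the puppet-set hypergraph.
#'
#' @param process a [composite_process()].
#' @param file optional output path.
#' @return the DOT source as a character string.
#' @export
export_dot <- function(process, file = NULL) {
  lines <- c("digraph dependency_network {",
             paste0("  \"", process$space$subsystems, "\" [shape=circle];"))
  if (nrow(process$dependency))
    lines <- c(lines, apply(process$dependency, 1L, function(e)
      paste0("  \"", e[1], "\" -> \"", e[2], "\";")))
  for (m in process$mechanisms) {
    mid <- paste0("mech_", m$id)
    lines <- c(lines,
               paste0("  \"", mid, "\" [shape=box,label=\"", m$id, "\"];"),
               paste0("  \"", mid, "\" -> \"", m$puppets,
                      "\" [style=dashed,dir=none];"))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  txt
}
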