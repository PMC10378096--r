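## Small process builders shared across tests; all fixtures are built in
## code.

## Single binary subsystem with one mechanism: up-rate k01 (0 -> 1) and
## down-rate k10.
two_state_process <- function(k01 = 2, k10 = 1, id = "m") {
  sp <- state_space(list(A = c("0", "1")))
  composite_process(sp, list(mechanism(id, "A", list(
    list(from = c(A = "0"), to = c(A = "1"), rate = k01),
    list(from = c(A = "1"), to = c(A = "0"), rate = k10)))))
}

## Binary subsystem driven by two mechanisms with opposite biases, so the
## NESS carries a circulating flux between the mechanisms.
two_mechanism_two_state <- function(k01a = 2, k10a = 0.5,
                                    k01b = 0.5, k10b = 2) {
  sp <- state_space(list(A = c("0", "1")))
  ent <- function(u, d) list(
    list(from = c(A = "0"), to = c(A = "1"), rate = u),
    list(from = c(A = "1"), to = c(A = "0"), rate = d))
  composite_process(sp, list(mechanism("ma", "A", ent(k01a, k10a)),
                             mechanism("mb", "A", ent(k01b, k10b))))
}

## Independent binary subsystems, one single-site mechanism each; every
## subsystem subset is a unit.
independent_mpp <- function(n = 2, rate = 1) {
  ids <- LETTERS[seq_len(n)]
  sp <- state_space(stats::setNames(rep(list(c("0", "1")), n), ids))
  mechs <- lapply(ids, function(id)
    mechanism(paste0("m", id), id, list(
      list(from = stats::setNames("0", id), to = stats::setNames("1", id), rate = rate),
      list(from = stats::setNames("1", id), to = stats::setNames("0", id), rate = rate))))
  composite_process(sp, mechs)
}

## Bipartite sensor: X flips autonomously, Y relaxes toward X.
sensor_process <- function(kx01 = 2, kx10 = 1, k_align = 3, k_mis = 0.5) {
  sp <- state_space(list(X = c("0", "1"), Y = c("0", "1")))
  flip <- function(x) ifelse(x == "0", "1", "0")
  mx <- list(list(from = c(X = "0"), to = c(X = "1"), rate = kx01),
             list(from = c(X = "1"), to = c(X = "0"), rate = kx10))
  my <- list()
  for (x in c("0", "1")) for (y in c("0", "1"))
    my[[length(my) + 1L]] <- list(
      from = c(X = x, Y = y), to = c(Y = flip(y)),
      rate = if (x == y) k_align else k_mis)
  composite_process(sp, list(mechanism("mx", "X", mx),
                             mechanism("my", "Y", my)))
}

## Two independent biased three-state rings as one composite process.
double_ring_process <- function(f1 = 2, b1 = 1, f2 = 3, b2 = 1) {
  sp <- state_space(list(R1 = c("0", "1", "2"), R2 = c("0", "1", "2")))
  ent <- function(sub, f, b) {
    out <- list()
    for (i in 1:3) {
      j <- i %% 3 + 1
      out[[length(out) + 1L]] <- list(
        from = stats::setNames(as.character(i - 1), sub),
        to = stats::setNames(as.character(j - 1), sub), rate = f)
      out[[length(out) + 1L]] <- list(
        from = stats::setNames(as.character(j - 1), sub),
        to = stats::setNames(as.character(i - 1), sub), rate = b)
    }
    out
  }
  composite_process(sp, list(mechanism("h1", "R1", ent("R1", f1, b1)),
                             mechanism("h2", "R2", ent("R2", f2, b2))))
}

## Winding current (+1 clockwise) for a three-state coordinate.
winding_weights <- function(n = 3) {
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    C[j, i] <- 1
    C[i, j] <- -1
  }
  C
}
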