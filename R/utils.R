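## Small numeric helpers shared across the package.  Entropies and
## divergences are in nats throughout (k_B = 1).

#' Shannon entropy of a probability vector (nats)
#'
#' Terms with `p == 0` contribute zero.
#'
#' @param p numeric probability vector.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Kullback-Leibler divergence D(p || q) in nats
#'
#' Returns `Inf` when `p` puts mass where `q` does not.
#'
#' @param p,q probability vectors on the same support.
#' @return divergence in nats.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("kl_divergence: length mismatch")
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * (log(p[pos]) - log(q[pos])))
}

#' Total variation distance between two probability vectors
#'
#' Uses the 1/2 sum-of-absolute-differences convention.
#'
#' @param p,q probability vectors on the same support.
#' @return distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (length(p) != length(q)) stop("total_variation: length mismatch")
  0.5 * sum(abs(p - q))
}

## Composite Simpson weights for an odd number of equally spaced nodes.
simpson_weights <- function(n_nodes, h) {
  if (n_nodes < 3L || n_nodes %% 2L == 0L)
    stop("simpson_weights: need an odd number of nodes (even interval count)")
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- 1
  w[n_nodes] <- 1
  w * h / 3
}

## Dense matrix exponential; Matrix::expm does the heavy lifting.
expm_dense <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE)))
}

## Renormalize a probability vector, failing if it is too far from a
## distribution to be a rounding artifact.
normalize_distribution <- function(p, tol = 1e-8, what = "distribution") {
  if (any(!is.finite(p))) stop(what, ": non-finite entries")
  if (any(p < -tol)) stop(what, ": negative probabilities beyond tolerance")
  p[p < 0] <- 0
  s <- sum(p)
  if (s <= 0) stop(what, ": zero total mass")
  p / s
}

## x * log(x / y) with the 0 * log(0/.) = 0 convention; positive x with
## zero y is the caller's error to raise.
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * (log(x[pos]) - log(y[pos]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
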