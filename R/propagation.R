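#' Restrict a score vector to the genes of a network
#'
#' Returns the scores in network node order. Genes absent from the network
#' are dropped; network nodes without a score are zero-filled so the
#' diffusion operator keeps its full dimension. Counts of dropped and
#' zero-filled genes are reported as messages.
#'
#' @param scores a [gene_scores()] object.
#' @param net a [ppi_network()].
#' @return A `gene_scores` object over `net$nodes`, same provenance.
#' @export
intersect_with_network <- function(scores, net) {
  stopifnot(inherits(scores, "gene_scores"), inherits(net, "ppi_network"))
  common <- intersect(names(scores), net$nodes)
  if (!length(common)) {
    stop("no overlap between score genes and network nodes; ",
         "are the identifier namespaces compatible?", call. = FALSE)
  }
  dropped <- length(scores) - length(common)
  filled <- length(net$nodes) - length(common)
  if (dropped > 0) message(dropped, " scored gene(s) absent from the network: dropped")
  if (filled > 0) message(filled, " network node(s) without a score: zero-filled")
  out <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  out[common] <- as.numeric(scores)[match(common, names(scores))]
  gene_scores(out, net$nodes, provenance = provenance(scores))
}

#' Network propagation by random walk with restart
#'
#' Diffuses non-negative gene scores over a network by iterating
#' \deqn{p_k = \alpha p_0 + (1 - \alpha) W p_{k-1}}
#' until the L1 difference between successive iterates is at most `tol` or
#' `max_iter` is reached. `W` is the symmetrically normalized adjacency
#' matrix ([normalize_symmetric()]), whose spectral radius is at most 1, so
#' the iteration contracts geometrically with ratio at most `1 - alpha`.
#' The restart probability `alpha` balances the initial scores against
#' diffused neighborhood information; `alpha = 1` returns the input
#' unchanged. The default `alpha = 0.2` favors network smoothing while
#' preserving the original signal.
#'
#' The input is not renormalized: downstream tests are rank-based and hence
#' scale invariant. Set `normalize_input = TRUE` to rescale `p0` to unit L1
#' norm for comparability across datasets.
#'
#' @param p0 a [gene_scores()] object with provenance `"absolute"`, aligned
#'   to `W$nodes`.
#' @param W a `normalized_adjacency` from [normalize_symmetric()].
#' @param alpha restart probability in (0, 1]; default 0.2.
#' @param tol L1 convergence tolerance; default 1e-6.
#' @param max_iter iteration cap; default 1000. Non-convergence produces a
#'   warning and the last iterate is returned, flagged via the `converged`
#'   attribute.
#' @param normalize_input rescale `p0` to sum 1 before propagation.
#' @return A `gene_scores` object with provenance `"propagated"` and
#'   attributes `iterations`, `residual`, `converged`.
#' @seealso [propagate_closed_form()] for the analytic fixed point.
#' @export
propagate_iterative <- function(p0, W, alpha = 0.2, tol = 1e-6,
                                max_iter = 1000L, normalize_input = FALSE) {
  check_propagation_inputs(p0, W, alpha)
  stopifnot(is.numeric(tol), length(tol) == 1L, tol >= 0,
            is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1)
  v0 <- as.numeric(p0)
  if (normalize_input && sum(v0) > 0) v0 <- v0 / sum(v0)
  p <- v0
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    p_next <- alpha * v0 + (1 - alpha) * as.numeric(W$W %*% p)
    residual <- sum(abs(p_next - p))
    p <- p_next
    if (residual <= tol) break
  }
  converged <- residual <= tol
  if (!converged) {
    warning("propagation did not converge in ", max_iter,
            " iterations (residual ", signif(residual, 3), ")", call. = FALSE)
  }
  out <- gene_scores(p, W$nodes, provenance = "propagated")
  attr(out, "iterations") <- iter
  attr(out, "residual") <- residual
  attr(out, "converged") <- converged
  out
}

#' Closed-form solution of the random walk with restart
#'
#' Solves the fixed point `p = alpha * (I - (1 - alpha) W)^(-1) p0` directly
#' with a dense linear solve. Primarily a reference solution for validating
#' the iterative solver on small networks; for isolated nodes the fixed
#' point is exactly `alpha * p0[i]`.
#'
#' @inheritParams propagate_iterative
#' @return A `gene_scores` object with provenance `"propagated"`.
#' @export
propagate_closed_form <- function(p0, W, alpha = 0.2, normalize_input = FALSE) {
  check_propagation_inputs(p0, W, alpha)
  v0 <- as.numeric(p0)
  if (normalize_input && sum(v0) > 0) v0 <- v0 / sum(v0)
  n <- length(W$nodes)
  A <- diag(n) - (1 - alpha) * as.matrix(W$W)
  p <- tryCatch(solve(A, alpha * v0),
                error = function(e) stop("linear system is singular: ",
                                         conditionMessage(e), call. = FALSE))
  gene_scores(as.numeric(p), W$nodes, provenance = "propagated")
}

check_propagation_inputs <- function(p0, W, alpha) {
  stopifnot(inherits(p0, "gene_scores"), inherits(W, "normalized_adjacency"))
  if (provenance(p0) != "absolute") {
    stop("propagation expects absolute scores (see to_absolute()); got '",
         provenance(p0), "'", call. = FALSE)
  }
  if (!identical(names(p0), W$nodes)) {
    stop("p0 is not aligned to the network node order; ",
         "use intersect_with_network() first", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}
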