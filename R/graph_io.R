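#' Protein-protein interaction networks
#'
#' A `ppi_network` is an undirected graph over gene identifiers with strictly
#' positive edge weights, stored as a symmetric sparse adjacency matrix `A`
#' together with the weighted degree vector (row sums of `A`). Self-loops are
#' kept only when explicitly present in the input and trigger a warning.
#'
#' @param from,to character vectors of endpoint gene identifiers.
#' @param weight numeric vector of positive edge weights (recycled scalar
#'   allowed; default all 1).
#' @param nodes optional character vector fixing the node set and order;
#'   defaults to first appearance order in `from`/`to`. Extra nodes are kept
#'   as isolated vertices.
#' @return A `ppi_network`: list with elements `nodes` (character),
#'   `edges` (data.frame `from`, `to`, `weight`, deduplicated, undirected),
#'   `adjacency` (symmetric `dgCMatrix`), and `degree` (named numeric).
#' @examples
#' net <- ppi_network(c("A", "B"), c("B", "C"))
#' net$degree
#' @export
ppi_network <- function(from = character(), to = character(),
                        weight = rep(1, length(from)), nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length", call. = FALSE)
  }
  weight <- rep_len(as.numeric(weight), length(from))
  if (length(weight) && (anyNA(weight) || any(weight <= 0))) {
    stop("edge weights must be strictly positive", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(from, to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("'nodes' must be unique", call. = FALSE)
    missing <- setdiff(unique(c(from, to)), nodes)
    if (length(missing)) {
      stop("edge endpoints absent from 'nodes': ",
           paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
    }
  }
  i <- match(from, nodes)
  j <- match(to, nodes)
  # undirected dedup: canonical orientation, duplicates keep the max weight
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (length(lo)) {
    key <- paste(lo, hi)
    keep <- !duplicated(key)
    w <- vapply(split(weight, key), max, 0)[key[keep]]
    lo <- lo[keep]; hi <- hi[keep]
    if (any(lo == hi)) {
      warning("input contains ", sum(lo == hi), " self-loop(s); preserved",
              call. = FALSE)
    }
  } else {
    w <- numeric()
  }
  n <- length(nodes)
  diag_sel <- lo == hi
  adjacency <- Matrix::sparseMatrix(
    i = c(lo[!diag_sel], hi[!diag_sel], lo[diag_sel]),
    j = c(hi[!diag_sel], lo[!diag_sel], hi[diag_sel]),
    x = c(w[!diag_sel], w[!diag_sel], w[diag_sel]),
    dims = c(n, n), dimnames = list(nodes, nodes))
  structure(list(
    nodes = nodes,
    edges = data.frame(from = nodes[lo], to = nodes[hi], weight = w,
                       stringsAsFactors = FALSE),
    adjacency = adjacency,
    degree = stats::setNames(Matrix::rowSums(adjacency), nodes)
  ), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI network from an edge-list file
#'
#' Accepts plain text with two or three whitespace- or tab-delimited columns
#' (`nodeA nodeB [weight]`); lines starting with `#` are comments. The SIF
#' dialect (`nodeA relation nodeB`) is detected when a line has exactly three
#' columns and the third is non-numeric, in which case the middle column is
#' ignored. Duplicate undirected edges keep the maximum weight; node order is
#' first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param weighted if `TRUE`, the third column is required to be a numeric
#'   weight; non-numeric values are a parse error. If `FALSE` (default) all
#'   edges get weight 1.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(ppi_network())
  from <- character(length(idx))
  to <- character(length(idx))
  wt <- rep(1, length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    fields <- strsplit(trimws(lines[ln]), "[\t ]+")[[1L]]
    if (length(fields) < 2L) {
      stop("line ", ln, ": fewer than 2 columns", call. = FALSE)
    }
    from[k] <- fields[1L]
    if (length(fields) == 3L &&
        is.na(suppressWarnings(as.numeric(fields[3L])))) {
      # SIF dialect: nodeA relation nodeB
      if (weighted) {
        stop("line ", ln, ": non-numeric weight '", fields[3L], "'",
             call. = FALSE)
      }
      to[k] <- fields[3L]
      next
    }
    to[k] <- fields[2L]
    if (weighted) {
      if (length(fields) < 3L) {
        stop("line ", ln, ": weighted = TRUE but no weight column",
             call. = FALSE)
      }
      w <- suppressWarnings(as.numeric(fields[3L]))
      if (is.na(w)) {
        stop("line ", ln, ": non-numeric weight '", fields[3L], "'",
             call. = FALSE)
      }
      wt[k] <- w
    }
  }
  ppi_network(from, to, wt)
}

#' Symmetric normalization of a network adjacency matrix
#'
#' Computes the diffusion operator `W = D^(-1/2) A D^(-1/2)`, where `A` is
#' the (weighted) adjacency matrix and `D` the diagonal matrix of weighted
#' degrees. `W` is symmetric with spectral radius at most 1. For isolated
#' nodes (degree 0) the `D^(-1/2)` entry is defined as 0, so their rows and
#' columns of `W` are zero and propagation remains well defined.
#'
#' @param net a [ppi_network()] with at least one node.
#' @return A `normalized_adjacency`: list with `W` (symmetric sparse matrix)
#'   and `nodes` (the node order `W` is indexed by).
#' @examples
#' net <- ppi_network(c("A", "B"), c("B", "C"))
#' normalize_symmetric(net)$W
#' @export
normalize_symmetric <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$nodes)) stop("network has no nodes", call. = FALSE)
  d <- net$degree
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dinv <- Matrix::Diagonal(x = dinv)
  W <- Dinv %*% net$adjacency %*% Dinv
  dimnames(W) <- list(net$nodes, net$nodes)
  structure(list(W = W, nodes = net$nodes), class = "normalized_adjacency")
}

#' @export
print.normalized_adjacency <- function(x, ...) {
  cat(sprintf("<normalized_adjacency> %d x %d, %d non-zero entries\n",
              length(x$nodes), length(x$nodes), Matrix::nnzero(x$W)))
  invisible(x)
}
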