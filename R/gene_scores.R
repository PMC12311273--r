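#' Gene score vectors
#'
#' A `gene_scores` object is a named numeric vector of per-gene scores with a
#' `provenance` attribute recording how the scores were produced:
#' \describe{
#'   \item{`raw`}{signed scores as read from a `.rnk` file (e.g. log2 fold
#'     changes);}
#'   \item{`absolute`}{element-wise absolute values of raw scores;}
#'   \item{`propagated`}{absolute scores diffused over a network by random
#'     walk with restart;}
#'   \item{`ngsea`}{absolute scores plus the average absolute score of each
#'     gene's immediate network neighbors.}
#' }
#' Scores with provenance `absolute`, `propagated` or `ngsea` are always
#' non-negative.
#'
#' @param scores numeric vector of scores; if `genes` is missing, `scores`
#'   must be named.
#' @param genes character vector of unique gene identifiers aligned to
#'   `scores`.
#' @param provenance one of `"raw"`, `"absolute"`, `"propagated"`, `"ngsea"`.
#' @return A `gene_scores` object.
#' @examples
#' gs <- gene_scores(c(TP53 = 2.5, BRCA1 = -1.1))
#' to_absolute(gs)
#' @export
gene_scores <- function(scores, genes = names(scores), provenance = "raw") {
  provenance <- match.arg(provenance, c("raw", "absolute", "propagated", "ngsea"))
  if (is.null(genes)) stop("gene identifiers are required", call. = FALSE)
  genes <- as.character(genes)
  scores <- as.numeric(scores)
  if (length(genes) != length(scores)) {
    stop("genes and scores must have equal length", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("gene identifiers must be unique; first duplicate: ",
         genes[duplicated(genes)][1L], call. = FALSE)
  }
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  if (provenance != "raw" && length(scores) && any(scores < 0)) {
    stop("provenance '", provenance, "' requires non-negative scores",
         call. = FALSE)
  }
  structure(stats::setNames(scores, genes),
            provenance = provenance,
            class = "gene_scores")
}

#' @rdname gene_scores
#' @param x a `gene_scores` object.
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "gene_scores"))
  attr(x, "provenance")
}

#' @export
print.gene_scores <- function(x, ...) {
  cat(sprintf("<gene_scores> %d genes, provenance: %s\n",
              length(x), attr(x, "provenance")))
  n <- min(6L, length(x))
  if (n > 0L) print(stats::setNames(as.numeric(x)[seq_len(n)], names(x)[seq_len(n)]))
  if (length(x) > n) cat("...\n")
  invisible(x)
}

#' Replace signed scores by their absolute values
#'
#' Used before network propagation so that up- and down-regulated genes both
#' contribute positive signal; pathways with mixed expression patterns are
#' then detectable.
#'
#' @param scores a `gene_scores` object with provenance `"raw"`.
#' @return A `gene_scores` object with provenance `"absolute"`, same gene
#'   order.
#' @export
to_absolute <- function(scores) {
  stopifnot(inherits(scores, "gene_scores"))
  if (provenance(scores) != "raw") {
    stop("to_absolute() expects raw scores, got provenance '",
         provenance(scores), "'", call. = FALSE)
  }
  gene_scores(abs(as.numeric(scores)), names(scores), provenance = "absolute")
}
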