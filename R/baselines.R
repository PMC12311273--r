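#' Neighbor-averaging score transform (NGSEA)
#'
#' For each gene i with score x_i and n_i immediate network neighbors,
#' computes `NS_i = |x_i| + mean_j |x_j|` over the neighbors j. Isolated
#' genes (n_i = 0) keep `NS_i = |x_i|`, the continuous limit of a vanishing
#' neighbor contribution. Neighborhoods are defined by edge presence; edge
#' weights do not enter the average.
#'
#' @param scores a [gene_scores()] vector aligned to `net`'s node order (use
#'   [intersect_with_network()]).
#' @param net a [ppi_network()].
#' @return A `gene_scores` vector with provenance `"ngsea"`.
#' @export
ngsea_transform <- function(scores, net) {
  stopifnot(inherits(scores, "gene_scores"), inherits(net, "ppi_network"))
  if (!identical(names(scores), net$nodes)) {
    stop("scores are not aligned to the network; ",
         "use intersect_with_network() first", call. = FALSE)
  }
  absx <- abs(as.numeric(scores))
  B <- net$adjacency
  B@x <- rep(1, length(B@x))   # binary adjacency: average ignores weights
  deg <- Matrix::rowSums(B)
  nb_sum <- as.numeric(B %*% absx)
  ns <- absx + ifelse(deg > 0, nb_sum / deg, 0)
  gene_scores(ns, net$nodes, provenance = "ngsea")
}

#' Absolute-value transform for preranked enrichment (ABS GSEA)
#'
#' Identical to [to_absolute()]; exposed under the baseline namespace so the
#' three comparator methods are uniform: identity (gsea), absolute value
#' (abs_gsea), neighbor averaging (ngsea).
#'
#' @inheritParams to_absolute
#' @return A `gene_scores` vector with provenance `"absolute"`.
#' @export
abs_transform <- function(scores) to_absolute(scores)

#' Preranked enrichment core (weighted Kolmogorov-Smirnov running sum)
#'
#' Classic preranked GSEA: genes are sorted by decreasing score (ties broken
#' by gene name); walking down the list, the running sum increases by
#' `|score|^weight / sum_members |score|^weight` at each pathway member and
#' decreases by `1/(N - m)` at each non-member. The enrichment score ES is
#' the signed maximum deviation from zero. The null distribution is obtained
#' by scoring `n_perm` random member sets of the same size on the same
#' ranked list; the nominal p-value is the add-one same-sign null tail, NES
#' is ES divided by the mean same-sign null ES, and FDR q follows the
#' standard pooled normalized-ES procedure with monotonicity enforcement.
#'
#' Pathways are ranked by (FDR q, nominal p, -|NES|, name).
#'
#' @param scores a [gene_scores()] vector (any provenance; the transform is
#'   the caller's responsibility, see [run_baseline()]).
#' @param col a [pathway_collection()].
#' @param n_perm permutations per pathway (default 1000).
#' @param weight score-weight exponent of the running sum; 0 gives the
#'   rank-only statistic, 1 (default) the classic weighted statistic.
#' @param seed master seed; per-pathway child seeds as in [run_cascade()].
#' @return A data.frame ordered by rank with columns `pathway`,
#'   `effective_size`, `ES`, `NES`, `nominal_p`, `fdr_q`, `rank`; skipped
#'   pathways (no effective members, or members = whole universe) in
#'   attribute `"skipped"`.
#' @export
prerank_enrichment <- function(scores, col, n_perm = 1000L, weight = 1,
                               seed = 1L) {
  stopifnot(inherits(scores, "gene_scores"), inherits(col, "pathway_collection"),
            n_perm >= 1, weight >= 0)
  v <- as.numeric(scores)
  genes <- names(scores)
  N <- length(v)
  ord <- order(-v, genes)        # descending score, name tie-break
  ranked_genes <- genes[ord]
  w <- abs(v[ord])^weight

  eff <- vapply(col$sets, function(m) sum(m %in% genes), 0L)
  testable <- eff >= 1L & eff < N
  skipped <- data.frame(
    pathway = names(eff)[!testable],
    reason = ifelse(eff[!testable] < 1L, "no effective members",
                    "pathway covers the whole universe"),
    stringsAsFactors = FALSE, row.names = NULL)
  nm <- names(eff)[testable]

  es_obs <- numeric(length(nm))
  null_es <- vector("list", length(nm))
  for (k in seq_along(nm)) {
    pos <- sort.int(match(intersect(col$sets[[nm[k]]], genes), ranked_genes))
    es_obs[k] <- running_sum_es(pos, w, N)
    m <- length(pos)
    null_es[[k]] <- with_seed(child_seed(seed, nm[k]), {
      vapply(seq_len(n_perm), function(b) {
        running_sum_es(sort.int(sample.int(N, m)), w, N)
      }, 0)
    })
  }

  # pathway-wise normalization by the mean same-sign null ES
  norm_pos <- vapply(null_es, function(z) {
    zp <- z[z >= 0]; if (length(zp) && mean(zp) > 0) mean(zp) else NA_real_
  }, 0)
  norm_neg <- vapply(null_es, function(z) {
    zn <- z[z < 0]; if (length(zn)) abs(mean(zn)) else NA_real_
  }, 0)
  nes_obs <- ifelse(es_obs >= 0, es_obs / norm_pos, es_obs / norm_neg)
  nominal_p <- vapply(seq_along(nm), function(k) {
    z <- null_es[[k]]
    if (es_obs[k] >= 0) {
      zp <- z[z >= 0]
      (1 + sum(zp >= es_obs[k])) / (1 + length(zp))
    } else {
      zn <- z[z < 0]
      (1 + sum(zn <= es_obs[k])) / (1 + length(zn))
    }
  }, 0)

  null_nes <- unlist(lapply(seq_along(nm), function(k) {
    z <- null_es[[k]]
    c(z[z >= 0] / norm_pos[k], z[z < 0] / norm_neg[k])
  }), use.names = FALSE)
  null_nes <- null_nes[is.finite(null_nes)]
  fdr_q <- gsea_fdr(nes_obs, null_nes)

  res <- data.frame(pathway = nm, effective_size = eff[testable],
                    ES = es_obs, NES = nes_obs,
                    nominal_p = nominal_p, fdr_q = fdr_q,
                    rank = NA_integer_, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (nrow(res)) {
    key_nes <- ifelse(is.na(res$NES), 0, abs(res$NES))
    ord_rank <- order(res$fdr_q, res$nominal_p, -key_nes, res$pathway)
    res$rank[ord_rank] <- seq_len(nrow(res))
    res <- res[order(res$rank), , drop = FALSE]
    row.names(res) <- NULL
  }
  attr(res, "skipped") <- skipped
  attr(res, "params") <- list(n_perm = as.integer(n_perm), weight = weight,
                              seed = seed)
  res
}

# ES of a member set given sorted hit positions, weights over the ranked
# list, and universe size N. The running sum is piecewise linear between
# hits, so its extrema occur just before or just after a hit.
running_sum_es <- function(pos, w, N) {
  m <- length(pos)
  miss_den <- N - m
  wm <- w[pos]
  nr <- sum(wm)
  inc <- if (nr > 0) cumsum(wm) / nr else seq_len(m) / m
  misses <- (pos - seq_len(m)) / miss_den
  after <- inc - misses
  before <- c(0, inc[-m]) - misses
  max_dev <- max(after)
  min_dev <- min(before)
  if (max_dev >= abs(min_dev)) max_dev else min_dev
}

# standard pooled-null FDR for normalized enrichment scores
gsea_fdr <- function(nes_obs, null_nes) {
  q <- rep(NA_real_, length(nes_obs))
  n_null_pos <- sum(null_nes >= 0)
  n_null_neg <- sum(null_nes < 0)
  n_obs_pos <- sum(nes_obs >= 0, na.rm = TRUE)
  n_obs_neg <- sum(nes_obs < 0, na.rm = TRUE)
  for (k in seq_along(nes_obs)) {
    s <- nes_obs[k]
    if (is.na(s)) next
    if (s >= 0) {
      if (n_null_pos == 0 || n_obs_pos == 0) { q[k] <- 1; next }
      null_frac <- sum(null_nes >= s) / n_null_pos
      obs_frac <- sum(nes_obs >= s, na.rm = TRUE) / n_obs_pos
    } else {
      if (n_null_neg == 0 || n_obs_neg == 0) { q[k] <- 1; next }
      null_frac <- sum(null_nes <= s) / n_null_neg
      obs_frac <- sum(nes_obs <= s, na.rm = TRUE) / n_obs_neg
    }
    q[k] <- min(1, null_frac / max(obs_frac, .Machine$double.eps))
  }
  # monotone: a more extreme NES never gets a larger q, per sign
  for (sgn in c(1, -1)) {
    sel <- which(!is.na(q) & ((sgn > 0 & nes_obs >= 0) | (sgn < 0 & nes_obs < 0)))
    if (length(sel) > 1L) {
      o <- sel[order(sgn * nes_obs[sel])]   # least extreme first
      q[o] <- cummin(q[o])
    }
  }
  q
}

#' Run a comparator enrichment method
#'
#' Applies the method's score transform, then the shared preranked
#' enrichment core:
#' \describe{
#'   \item{`gsea`}{raw signed scores, no transform;}
#'   \item{`abs_gsea`}{absolute values ([abs_transform()]);}
#'   \item{`ngsea`}{absolute values plus neighbor average
#'     ([ngsea_transform()]); requires a network and always runs on the
#'     network intersection.}
#' }
#' By default `gsea` and `abs_gsea` use the full score list; set
#' `restrict_to_network = TRUE` to run them on the network intersection so
#' that all methods share the same gene universe.
#'
#' @param method one of `"gsea"`, `"abs_gsea"`, `"ngsea"`.
#' @param scores a raw [gene_scores()] vector.
#' @param net a [ppi_network()]; required for `ngsea` or when
#'   `restrict_to_network = TRUE`.
#' @param col a [pathway_collection()].
#' @param restrict_to_network intersect scores with the network first.
#' @inheritParams prerank_enrichment
#' @return The [prerank_enrichment()] results table, with attribute
#'   `"method"`.
#' @export
run_baseline <- function(method = c("gsea", "abs_gsea", "ngsea"), scores,
                         net = NULL, col, n_perm = 1000L, weight = 1,
                         seed = 1L, restrict_to_network = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(scores, "gene_scores"))
  if (method == "ngsea" || restrict_to_network) {
    if (is.null(net)) {
      stop("method '", method, "' requires a network", call. = FALSE)
    }
    scores <- intersect_with_network(scores, net)
  }
  transformed <- switch(method,
    gsea = scores,
    abs_gsea = abs_transform(scores),
    ngsea = ngsea_transform(scores, net))
  res <- prerank_enrichment(transformed, col, n_perm = n_perm,
                            weight = weight, seed = seed)
  attr(res, "method") <- method
  res
}
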