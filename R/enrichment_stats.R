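#' Kolmogorov-Smirnov pathway test
#'
#' Two-sample K-S test comparing the propagated scores of a pathway's members
#' against the background of all other scored genes. Because propagation acts
#' on absolute scores, enrichment is one-directional: perturbed pathways have
#' stochastically larger scores. The default alternative is therefore
#' one-sided ("pathway scores greater"); `alternative = "two.sided"` restores
#' the symmetric test.
#'
#' @param scores a [gene_scores()] vector covering the scored universe.
#' @param pathway_members character vector of member gene identifiers; only
#'   members present in `scores` (the effective members) are used.
#' @param alternative `"greater"` (pathway scores stochastically greater,
#'   default) or `"two.sided"`.
#' @return The K-S p-value.
#' @export
ks_pathway_test <- function(scores, pathway_members,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  sp <- split_pathway(scores, pathway_members)
  if (length(unique(c(sp$inside, sp$outside))) == 1L) return(1)
  # R's ks.test "less" = CDF of x below y's = x stochastically greater
  ks_alt <- if (alternative == "greater") "less" else "two.sided"
  suppressWarnings(
    stats::ks.test(sp$inside, sp$outside, alternative = ks_alt)$p.value
  )
}

#' Mann-Whitney U pathway test
#'
#' Rank-based validation of a K-S hit: Wilcoxon rank-sum test of pathway
#' member scores against background scores, with tie correction. Sidedness as
#' in [ks_pathway_test()].
#'
#' @inheritParams ks_pathway_test
#' @return The Mann-Whitney U p-value.
#' @export
mw_pathway_test <- function(scores, pathway_members,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  sp <- split_pathway(scores, pathway_members)
  if (length(unique(c(sp$inside, sp$outside))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(sp$inside, sp$outside,
                       alternative = alternative)$p.value
  )
}

split_pathway <- function(scores, pathway_members) {
  stopifnot(inherits(scores, "gene_scores"))
  inside_sel <- names(scores) %in% pathway_members
  inside <- as.numeric(scores)[inside_sel]
  outside <- as.numeric(scores)[!inside_sel]
  if (length(inside) < 2L) {
    stop("pathway has fewer than 2 effective members", call. = FALSE)
  }
  if (length(outside) < 2L) {
    stop("background has fewer than 2 genes", call. = FALSE)
  }
  list(inside = inside, outside = outside)
}

#' Permutation test for a pathway's score level
#'
#' Compares the observed summary statistic (by default the mean) of the
#' pathway's effective member scores against a null distribution of the same
#' statistic over `n_perm` gene sets of the same size, sampled uniformly
#' without replacement from all scored genes. The empirical p-value uses the
#' add-one rank estimator `(1 + #{null >= observed}) / (1 + n_perm)`, which
#' is never exactly zero.
#'
#' @inheritParams ks_pathway_test
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @param stat summary statistic, `"mean"` (default) or `"median"`.
#' @return A list with `observed` (the statistic), `p` (empirical p-value),
#'   `null` (the n_perm null statistics), `n_perm` and `seed`.
#' @export
permutation_test <- function(scores, pathway_members, n_perm = 10000L,
                             seed = NULL, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(is.numeric(n_perm), length(n_perm) == 1L, n_perm >= 1)
  sp <- split_pathway(scores, pathway_members)
  v <- as.numeric(scores)
  m <- length(sp$inside)
  n <- length(v)
  if (m > n) stop("pathway larger than the scored universe", call. = FALSE)
  statfun <- if (stat == "mean") mean else stats::median
  observed <- statfun(sp$inside)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    statfun(v[sample.int(n, m)])
  }, 0))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(observed = observed, p = p, null = null,
       n_perm = as.integer(n_perm), seed = seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotonicity enforced), in input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  check_probabilities(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the three-stage enrichment cascade on propagated scores
#'
#' Stage 1 applies the K-S test to every testable pathway and adjusts across
#' all of them with Benjamini-Hochberg. Stage 2 applies the Mann-Whitney U
#' test only to pathways with K-S FDR at or below `threshold`, adjusting
#' within that subset. Stage 3 applies the permutation test only to pathways
#' with MW FDR at or below `threshold`, again adjusting within the subset.
#' A pathway is called significant when both its K-S FDR and its MW FDR are
#' at or below `threshold`; the permutation stage refines the ranking of the
#' significant pathways but does not change the call.
#'
#' Final ranking: significant pathways first, ordered by
#' (permutation FDR if present else Inf, MW FDR, K-S FDR, K-S p, name);
#' remaining pathways by (K-S FDR, K-S p, name). Ties end at the pathway
#' name, so the ordering is deterministic.
#'
#' Set `adjust_within_stage = FALSE` to correct stages 2 and 3 over all
#' stage-1 pathways instead of the tested subset.
#'
#' @param scores a [gene_scores()] vector with provenance `"propagated"`.
#' @param col a [pathway_collection()].
#' @param threshold adjusted-p cutoff for stage gating and significance
#'   (default 0.05).
#' @param n_perm permutations for stage 3 (default 10000).
#' @param seed master seed; each pathway gets a child seed derived from
#'   (seed, pathway name) so results do not depend on iteration order.
#' @param alternative test sidedness, see [ks_pathway_test()].
#' @param stat permutation summary statistic, see [permutation_test()].
#' @param min_size minimum effective pathway size (default 2).
#' @param raw_scores optional raw signed [gene_scores()] used to classify
#'   each pathway as up- or down-regulated (mean member score sign); if
#'   omitted the direction column is NA.
#' @param adjust_within_stage correct stages 2-3 within the tested subset
#'   (default) or across all stage-1 pathways.
#' @return A data.frame with one row per tested pathway, ordered by rank:
#'   columns `pathway`, `effective_size`, `direction`, `ks_p`, `ks_fdr`,
#'   `mw_p`, `mw_fdr`, `perm_p`, `perm_fdr`, `significant`, `rank`. Pathways
#'   that could not be tested are recorded in attribute `"skipped"`
#'   (data.frame of pathway and reason).
#' @export
run_cascade <- function(scores, col, threshold = 0.05, n_perm = 10000L,
                        seed = 1L, alternative = c("greater", "two.sided"),
                        stat = c("mean", "median"), min_size = 2L,
                        raw_scores = NULL, adjust_within_stage = TRUE) {
  stopifnot(inherits(scores, "gene_scores"), inherits(col, "pathway_collection"))
  alternative <- match.arg(alternative)
  stat <- match.arg(stat)
  if (provenance(scores) != "propagated") {
    stop("run_cascade() requires propagated scores; got provenance '",
         provenance(scores), "'. Run propagate_iterative() first.",
         call. = FALSE)
  }
  check_probabilities(threshold, "threshold")
  genes <- names(scores)
  n_universe <- length(genes)
  eff <- vapply(col$sets, function(m) sum(m %in% genes), 0L)

  testable <- eff >= min_size & (n_universe - eff) >= 2L
  skipped <- data.frame(
    pathway = names(eff)[!testable],
    reason = ifelse(eff[!testable] < min_size,
                    sprintf("effective size %d < %d", eff[!testable], min_size),
                    "background smaller than 2"),
    stringsAsFactors = FALSE, row.names = NULL)

  nm <- names(eff)[testable]
  res <- data.frame(
    pathway = nm, effective_size = eff[testable],
    direction = NA_character_,
    ks_p = NA_real_, ks_fdr = NA_real_,
    mw_p = NA_real_, mw_fdr = NA_real_,
    perm_p = NA_real_, perm_fdr = NA_real_,
    significant = FALSE, rank = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL)

  if (nrow(res)) {
    res$ks_p <- vapply(nm, function(p) {
      ks_pathway_test(scores, col$sets[[p]], alternative)
    }, 0)
    res$ks_fdr <- bh_adjust(res$ks_p)

    stage2 <- which(res$ks_fdr <= threshold)
    if (length(stage2)) {
      mw <- vapply(nm[stage2], function(p) {
        mw_pathway_test(scores, col$sets[[p]], alternative)
      }, 0)
      res$mw_p[stage2] <- mw
      res$mw_fdr[stage2] <- if (adjust_within_stage) bh_adjust(mw) else {
        bh_adjust(c(mw, rep(1, nrow(res) - length(stage2))))[seq_along(mw)]
      }
    }

    stage3 <- which(!is.na(res$mw_fdr) & res$mw_fdr <= threshold)
    if (length(stage3)) {
      perm <- vapply(nm[stage3], function(p) {
        permutation_test(scores, col$sets[[p]], n_perm = n_perm,
                         seed = child_seed(seed, p), stat = stat)$p
      }, 0)
      res$perm_p[stage3] <- perm
      res$perm_fdr[stage3] <- if (adjust_within_stage) bh_adjust(perm) else {
        bh_adjust(c(perm, rep(1, nrow(res) - length(stage3))))[seq_along(perm)]
      }
    }

    res$significant <- res$ks_fdr <= threshold &
      !is.na(res$mw_fdr) & res$mw_fdr <= threshold

    if (!is.null(raw_scores)) {
      res$direction <- vapply(nm, function(p) {
        classify_direction(raw_scores, col$sets[[p]])
      }, "")
    }

    res$rank <- cascade_ranks(res)
    res <- res[order(res$rank), , drop = FALSE]
    row.names(res) <- NULL
  }
  attr(res, "skipped") <- skipped
  attr(res, "params") <- list(threshold = threshold, n_perm = as.integer(n_perm),
                              seed = seed, alternative = alternative,
                              stat = stat, min_size = as.integer(min_size),
                              adjust_within_stage = adjust_within_stage)
  res
}

# deterministic final ordering: significant block first
cascade_ranks <- function(res) {
  inf_na <- function(x) ifelse(is.na(x), Inf, x)
  sig <- which(res$significant)
  other <- which(!res$significant)
  sig_ord <- sig[order(inf_na(res$perm_fdr[sig]), res$mw_fdr[sig],
                       res$ks_fdr[sig], res$ks_p[sig], res$pathway[sig])]
  other_ord <- other[order(res$ks_fdr[other], res$ks_p[other],
                           res$pathway[other])]
  ranks <- integer(nrow(res))
  ranks[c(sig_ord, other_ord)] <- seq_len(nrow(res))
  ranks
}

#' Write an enrichment results table as TSV
#'
#' Tab-delimited with a header; stages that were not reached are written as
#' `NA`. Works for both cascade results and baseline results.
#'
#' @param results a results data.frame (from [run_cascade()],
#'   [run_baseline()] or [peanut()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "peanut_result")) results <- results$results
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
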