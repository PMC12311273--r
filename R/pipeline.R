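#' Network-propagation pathway enrichment analysis
#'
#' End-to-end analysis of a preranked gene list against a pathway collection.
#' With `method = "peanut"` (default), the pipeline is: intersect the scores
#' with the network, take absolute values, diffuse by random walk with
#' restart ([propagate_iterative()]), then score pathways with the
#' three-stage cascade ([run_cascade()]): Kolmogorov-Smirnov test,
#' Mann-Whitney U validation of the K-S hits, permutation test of the
#' surviving pathways, each stage followed by Benjamini-Hochberg correction.
#' The comparator methods `"gsea"`, `"abs_gsea"` and `"ngsea"` run the
#' corresponding transform followed by the shared preranked enrichment core
#' ([run_baseline()]).
#'
#' @param scores a [gene_scores()] object or a path to a `.rnk` file.
#' @param network a [ppi_network()] or a path to an edge-list file; required
#'   for methods `"peanut"` and `"ngsea"`.
#' @param pathways a [pathway_collection()] or a path to a GMT file.
#' @param method one of `"peanut"`, `"gsea"`, `"abs_gsea"`, `"ngsea"`.
#' @param alpha restart probability of the propagation (default 0.2).
#' @param n_perm permutations for the permutation stage or the preranked
#'   null (default 10000).
#' @param threshold adjusted-p significance cutoff (default 0.05).
#' @param restrict_to_network run `gsea`/`abs_gsea` on the network
#'   intersection instead of the full score list.
#' @param min_size,max_size pathway size filter applied to the collection
#'   (inclusive; defaults 15 and 500). Use `min_size = 1` and a large
#'   `max_size` to disable.
#' @param tol,max_iter propagation convergence controls.
#' @param weight preranked running-sum exponent for the baseline methods.
#' @param seed master seed for all randomized stages.
#' @param ... further arguments passed to [run_cascade()] (e.g.
#'   `alternative`, `stat`) for `method = "peanut"`.
#' @return A `peanut_result` object: list with `results` (the ranked
#'   results data.frame), `method`, `skipped`, `filtered` (pathways removed
#'   by the size filter), and `manifest` (parameters, seed, input checksums,
#'   propagation diagnostics, package and R versions).
#' @examples
#' syn <- synth_generate(synth_config(n_genes = 120, n_pathways = 8,
#'                                    pathway_size_range = c(5, 10), seed = 7))
#' fit <- peanut(syn$scores, syn$network, syn$pathways,
#'               n_perm = 200, min_size = 1, seed = 7)
#' head(as.data.frame(fit))
#' rank_of_pathway(fit, "SIGNAL_PW_1")
#' @export
peanut <- function(scores, network = NULL, pathways,
                   method = c("peanut", "gsea", "abs_gsea", "ngsea"),
                   alpha = 0.2, n_perm = 10000L, threshold = 0.05,
                   restrict_to_network = FALSE,
                   min_size = 15L, max_size = 500L,
                   tol = 1e-6, max_iter = 1000L, weight = 1, seed = 1L, ...) {
  method <- match.arg(method)
  call <- match.call()
  checksums <- list()
  if (is.character(scores)) {
    checksums$rnk <- unname(tools::md5sum(scores))
    scores <- read_rnk(scores)
  }
  if (is.character(network)) {
    checksums$network <- unname(tools::md5sum(network))
    network <- read_edge_list(network)
  }
  if (is.character(pathways)) {
    checksums$gmt <- unname(tools::md5sum(pathways))
    pathways <- read_gmt(pathways)
  }
  stopifnot(inherits(scores, "gene_scores"),
            inherits(pathways, "pathway_collection"))
  if (method %in% c("peanut", "ngsea") && is.null(network)) {
    stop("method '", method, "' requires a network", call. = FALSE)
  }

  all_names <- names(pathways$sets)
  col <- filter_by_size(pathways, min_size = min_size, max_size = max_size)
  filtered <- setdiff(all_names, names(col$sets))

  prop_info <- NULL
  if (method == "peanut") {
    raw_net <- intersect_with_network(scores, network)
    p0 <- to_absolute(raw_net)
    W <- normalize_symmetric(network)
    prop <- propagate_iterative(p0, W, alpha = alpha, tol = tol,
                                max_iter = max_iter)
    prop_info <- list(iterations = attr(prop, "iterations"),
                      residual = attr(prop, "residual"),
                      converged = attr(prop, "converged"))
    results <- run_cascade(prop, col, threshold = threshold, n_perm = n_perm,
                           seed = seed, raw_scores = raw_net, ...)
  } else {
    results <- run_baseline(method, scores, net = network, col = col,
                            n_perm = n_perm, weight = weight, seed = seed,
                            restrict_to_network = restrict_to_network)
  }

  manifest <- list(
    method = method,
    params = list(alpha = alpha, n_perm = as.integer(n_perm),
                  threshold = threshold,
                  restrict_to_network = restrict_to_network,
                  min_size = as.integer(min_size),
                  max_size = as.integer(max_size),
                  tol = tol, max_iter = as.integer(max_iter),
                  weight = weight, seed = seed),
    input_checksums = checksums,
    n_genes_scored = length(scores),
    n_pathways_tested = nrow(results),
    propagation = prop_info,
    package_version = as.character(utils::packageVersion("peanut")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  structure(list(results = results, method = method,
                 skipped = attr(results, "skipped"),
                 filtered = filtered, manifest = manifest, call = call),
            class = "peanut_result")
}

#' @export
print.peanut_result <- function(x, ...) {
  cat(sprintf("<peanut_result> method: %s, %d pathways tested\n",
              x$method, nrow(x$results)))
  if (x$method == "peanut") {
    cat(sprintf("  significant at FDR %.3g: %d\n",
                x$manifest$params$threshold, sum(x$results$significant)))
  }
  n <- min(5L, nrow(x$results))
  if (n > 0L) {
    cat("  top pathways:\n")
    top <- x$results[seq_len(n), , drop = FALSE]
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.peanut_result <- function(object, ...) {
  r <- object$results
  cat(sprintf("Pathway enrichment by '%s'\n", object$method))
  cat(sprintf("  genes scored: %d\n", object$manifest$n_genes_scored))
  cat(sprintf("  pathways tested: %d (filtered by size: %d, skipped: %d)\n",
              nrow(r), length(object$filtered), nrow(object$skipped)))
  if (object$method == "peanut") {
    cat(sprintf("  K-S hits (FDR <= %.3g): %d\n",
                object$manifest$params$threshold,
                sum(r$ks_fdr <= object$manifest$params$threshold)))
    cat(sprintf("  significant (K-S and MW): %d\n", sum(r$significant)))
    pr <- object$manifest$propagation
    if (!is.null(pr)) {
      cat(sprintf("  propagation: %d iterations, residual %.3g\n",
                  pr$iterations, pr$residual))
    }
  } else {
    cat(sprintf("  FDR q <= 0.05: %d\n", sum(r$fdr_q <= 0.05, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
as.data.frame.peanut_result <- function(x, ...) {
  df <- x$results
  attr(df, "skipped") <- NULL
  attr(df, "params") <- NULL
  attr(df, "method") <- NULL
  df
}

#' Plot the strongest enrichment signals
#'
#' Horizontal bar chart of -log10 adjusted p (cascade: K-S FDR; baselines:
#' FDR q) for the top-ranked pathways.
#'
#' @param x a `peanut_result`.
#' @param n number of top pathways to show.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.peanut_result <- function(x, n = 10L, ...) {
  r <- x$results
  n <- min(n, nrow(r))
  if (n == 0L) {
    warning("nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  top <- r[seq_len(n), , drop = FALSE]
  v <- if (x$method == "peanut") top$ks_fdr else top$fdr_q
  v <- -log10(pmax(v, 1e-300))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(rev(v), names.arg = rev(top$pathway), horiz = TRUE,
                    las = 1, xlab = expression(-log[10] ~ "adjusted p"),
                    main = sprintf("Top pathways (%s)", x$method), ...)
  invisible(x)
}

#' Rank of a target pathway in a results table
#'
#' The 1-based position of `target` under the method's final deterministic
#' ordering; the standard benchmark readout when each dataset has one known
#' associated pathway (lower is better).
#'
#' @param result a `peanut_result` or a results data.frame with `pathway`
#'   and `rank` columns.
#' @param target pathway name.
#' @return Integer rank.
#' @export
rank_of_pathway <- function(result, target) {
  stopifnot(is.character(target), length(target) == 1L)
  if (inherits(result, "peanut_result")) {
    r <- result$results
    if (!target %in% r$pathway) {
      if (target %in% result$filtered) {
        stop("pathway '", target, "' was removed by the size filter",
             call. = FALSE)
      }
      if (target %in% result$skipped$pathway) {
        reason <- result$skipped$reason[result$skipped$pathway == target][1L]
        stop("pathway '", target, "' was not testable: ", reason,
             call. = FALSE)
      }
      stop("pathway '", target, "' is absent from the collection",
           call. = FALSE)
    }
  } else {
    r <- result
    if (!target %in% r$pathway) {
      stop("pathway '", target, "' is absent from the results", call. = FALSE)
    }
  }
  as.integer(r$rank[r$pathway == target][1L])
}

#' Classify a pathway as up- or down-regulated
#'
#' Sign of the mean raw (signed) score of the pathway's effective members:
#' `"up"` when the mean is >= 0 (ties count as up), `"down"` otherwise.
#'
#' @param raw_scores a [gene_scores()] vector with signed values.
#' @param pathway_members character vector of member identifiers.
#' @return `"up"` or `"down"`.
#' @export
classify_direction <- function(raw_scores, pathway_members) {
  stopifnot(inherits(raw_scores, "gene_scores"))
  v <- as.numeric(raw_scores)[names(raw_scores) %in% pathway_members]
  if (!length(v)) {
    stop("pathway has no effective members among the scored genes",
         call. = FALSE)
  }
  if (mean(v) >= 0) "up" else "down"
}

#' Compare methods by the ranks of known target pathways
#'
#' Given per-method vectors of ranks of the true pathway across the same
#' datasets, reports pairwise win counts, mean rank differences, and
#' two-sided Wilcoxon signed-rank p-values on the paired ranks. With a
#' single dataset, win counts are reported and the test is marked not
#' applicable (p = NA).
#'
#' @param ranks named list (one element per method) of equal-length numeric
#'   vectors of target-pathway ranks; elements must be aligned by dataset
#'   (identical names if named).
#' @return A `method_comparison`: list with `ranks` (datasets x methods
#'   data.frame) and `pairwise` (data.frame of method pairs with `n`,
#'   `wins_a`, `wins_b`, `mean_diff` = mean(rank_a - rank_b), `p_value`).
#' @export
compare_methods <- function(ranks) {
  stopifnot(is.list(ranks), length(ranks) >= 2L, !is.null(names(ranks)))
  lens <- lengths(ranks)
  if (length(unique(lens)) != 1L) {
    stop("methods cover different numbers of datasets", call. = FALSE)
  }
  nms <- lapply(ranks, names)
  if (!is.null(nms[[1L]])) {
    for (k in seq_along(nms)[-1L]) {
      if (!identical(sort(nms[[k]]), sort(nms[[1L]]))) {
        stop("methods cover different dataset sets", call. = FALSE)
      }
      ranks[[k]] <- ranks[[k]][nms[[1L]]]
    }
  }
  tab <- as.data.frame(ranks)
  methods <- names(ranks)
  pairs <- utils::combn(methods, 2L)
  pw <- data.frame(method_a = pairs[1L, ], method_b = pairs[2L, ],
                   n = lens[[1L]], wins_a = NA_integer_, wins_b = NA_integer_,
                   mean_diff = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- ranks[[pairs[1L, k]]]
    b <- ranks[[pairs[2L, k]]]
    d <- a - b
    pw$wins_a[k] <- sum(d < 0)   # lower rank = better
    pw$wins_b[k] <- sum(d > 0)
    pw$mean_diff[k] <- mean(d)
    if (length(d) >= 2L) {
      pw$p_value[k] <- if (all(d == 0)) 1 else {
        suppressWarnings(
          stats::wilcox.test(a, b, paired = TRUE,
                             alternative = "two.sided")$p.value)
      }
    }
  }
  structure(list(ranks = tab, pairwise = pw), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d methods, %d datasets\n",
              ncol(x$ranks), nrow(x$ranks)))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
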