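#' Configuration for the synthetic benchmark generator
#'
#' Defines a synthetic study: a random gene network, signed gene scores with
#' Gaussian background noise, and a pathway collection of random decoy sets
#' plus planted signal pathways. Signal genes receive scores of elevated
#' magnitude (`|N(0, noise_sd^2)| + signal_effect`) with random signs, so the
#' pathway carries a mixed expression pattern: strong in absolute value but
#' directionally incoherent, the regime where signed enrichment statistics
#' lose power. With `signal_connected = TRUE` the signal genes form a
#' connected subgraph (breadth-first growth from a random seed node), so
#' network diffusion concentrates score mass on them.
#'
#' Defaults are sized for seconds-scale runs: 500 genes, Erdos-Renyi edges
#' with p = 0.02, 50 pathways of 15-40 genes, one connected signal pathway
#' with a 3-standard-deviation magnitude shift.
#'
#' @param n_genes number of genes.
#' @param edge_model `"erdos_renyi"` (parameter = edge probability) or
#'   `"barabasi_albert"` (parameter = edges per new node).
#' @param edge_param parameter of the edge model.
#' @param n_pathways total number of pathways including signal pathways.
#' @param pathway_size_range inclusive (min, max) pathway sizes.
#' @param n_signal_pathways number of planted signal pathways.
#' @param signal_effect magnitude shift delta (>= 0) of signal-gene scores.
#' @param signal_connected plant each signal pathway as a connected subgraph.
#' @param noise_sd standard deviation sigma of the background scores.
#' @param seed integer seed; the whole triple is reproducible from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 500L, edge_model = c("erdos_renyi", "barabasi_albert"),
                         edge_param = 0.02, n_pathways = 50L,
                         pathway_size_range = c(15L, 40L),
                         n_signal_pathways = 1L, signal_effect = 3,
                         signal_connected = TRUE, noise_sd = 1, seed = 1L) {
  edge_model <- match.arg(edge_model)
  stopifnot(n_genes >= 1, n_pathways >= 0, n_signal_pathways >= 0,
            n_signal_pathways <= n_pathways, signal_effect >= 0, noise_sd > 0,
            length(pathway_size_range) == 2L,
            pathway_size_range[1] >= 1,
            pathway_size_range[1] <= pathway_size_range[2],
            pathway_size_range[2] <= n_genes,
            edge_param > 0)
  structure(list(n_genes = as.integer(n_genes), edge_model = edge_model,
                 edge_param = edge_param, n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_signal_pathways = as.integer(n_signal_pathways),
                 signal_effect = signal_effect,
                 signal_connected = isTRUE(signal_connected),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic network, score list and pathway collection
#'
#' Deterministic given `cfg$seed`: the same configuration always produces an
#' identical network, score vector, collection and truth table.
#'
#' @param cfg a [synth_config()].
#' @return A list with `network` ([ppi_network()]), `scores` (raw
#'   [gene_scores()]), `pathways` ([pathway_collection()]) and `truth`
#'   (data.frame `pathway`, `is_signal`).
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    gene_ids <- sprintf("G%0*d", nchar(as.character(cfg$n_genes)),
                        seq_len(cfg$n_genes))
    g <- switch(cfg$edge_model,
      erdos_renyi = igraph::sample_gnp(cfg$n_genes, cfg$edge_param),
      barabasi_albert = igraph::sample_pa(cfg$n_genes,
                                          m = max(1L, round(cfg$edge_param)),
                                          directed = FALSE))
    el <- igraph::as_edgelist(g, names = FALSE)
    net <- ppi_network(gene_ids[el[, 1]], gene_ids[el[, 2]], nodes = gene_ids)

    scores_v <- stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)

    sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                    cfg$n_pathways, replace = TRUE)
    sets <- vector("list", cfg$n_pathways)
    nms <- character(cfg$n_pathways)
    n_sig <- cfg$n_signal_pathways
    for (k in seq_len(cfg$n_pathways)) {
      if (k <= n_sig) {
        nms[k] <- sprintf("SIGNAL_PW_%d", k)
        members_idx <- if (cfg$signal_connected) {
          connected_module(g, sizes[k])
        } else {
          sample.int(cfg$n_genes, sizes[k])
        }
        # elevated magnitude, random sign: mixed expression pattern
        signs <- sample(c(-1, 1), sizes[k], replace = TRUE)
        scores_v[members_idx] <- signs *
          (abs(stats::rnorm(sizes[k], 0, cfg$noise_sd)) + cfg$signal_effect)
        sets[[k]] <- gene_ids[members_idx]
      } else {
        nms[k] <- sprintf("DECOY_PW_%03d", k - n_sig)
        sets[[k]] <- gene_ids[sample.int(cfg$n_genes, sizes[k])]
      }
    }
    names(sets) <- nms
    col <- if (cfg$n_pathways > 0) {
      pathway_collection(sets, rep("synthetic", cfg$n_pathways))
    } else {
      pathway_collection(list())
    }
    list(network = net,
         scores = gene_scores(scores_v, gene_ids, provenance = "raw"),
         pathways = col,
         truth = data.frame(pathway = nms,
                            is_signal = seq_len(cfg$n_pathways) <= n_sig,
                            stringsAsFactors = FALSE))
  })
}

# breadth-first growth of a connected gene module of the requested size
connected_module <- function(g, size) {
  comp <- igraph::components(g)
  big <- which(comp$csize >= size)
  if (!length(big)) {
    stop("no connected component of size >= ", size,
         "; use a denser edge model", call. = FALSE)
  }
  cid <- big[sample.int(length(big), 1L)]
  members <- which(comp$membership == cid)
  root <- members[sample.int(length(members), 1L)]
  ord <- igraph::bfs(g, root = root, unreachable = FALSE)$order
  ord <- ord[!is.na(ord)]
  as.integer(ord[seq_len(size)])
}

#' Write a synthetic dataset to disk
#'
#' Writes the generated triple as `scores.rnk`, `network.tsv` (edge list),
#' `pathways.gmt` and `truth.tsv` under `dir`, so synthetic fixtures double
#' as command-line smoke-test inputs.
#'
#' @param x the list returned by [synth_generate()].
#' @param dir output directory (created if missing).
#' @return The four file paths, invisibly.
#' @export
synth_write <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rnk = file.path(dir, "scores.rnk"),
             network = file.path(dir, "network.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_rnk(x$scores, paths[["rnk"]])
  writeLines(sprintf("%s\t%s\t%.17g", x$network$edges$from,
                     x$network$edges$to, x$network$edges$weight),
             paths[["network"]])
  write_gmt(x$pathways, paths[["gmt"]])
  utils::write.table(x$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
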