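#' Pathway collections
#'
#' A `pathway_collection` holds named gene sets with description strings, the
#' GMT semantics: unique pathway names, each with a deduplicated, non-empty
#' member set.
#'
#' @param sets named list of character vectors (member gene identifiers).
#' @param descriptions optional character vector of descriptions aligned to
#'   `sets` (default empty strings).
#' @return A `pathway_collection`: list with `sets`, `descriptions` and
#'   `filter_state` (NULL until [filter_by_size()] is applied).
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  nm <- names(sets)
  if (is.null(nm) && length(sets)) stop("'sets' must be named", call. = FALSE)
  if (anyDuplicated(nm)) {
    stop("pathway names must be unique; first duplicate: ",
         nm[duplicated(nm)][1L], call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (length(sets) && any(!lengths(sets))) {
    stop("every pathway must have at least one member", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(as.character(descriptions), nm),
                 filter_state = NULL),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways", length(x$sets)))
  if (length(x$sets)) {
    cat(sprintf(", sizes %d-%d", min(lengths(x$sets)), max(lengths(x$sets))))
  }
  cat("\n")
  if (!is.null(x$filter_state)) {
    fs <- x$filter_state
    cat(sprintf("  size filter [%d, %d]: %d -> %d pathways\n",
                fs$min_size, fs$max_size, fs$n_before, fs$n_after))
  }
  invisible(x)
}

#' Read a preranked gene list (.rnk)
#'
#' Two-column tab-delimited text: gene identifier, signed numeric score
#' (typically a log2 fold change). Lines starting with `#` are comments.
#' Duplicate genes keep the entry with the largest absolute score (warned).
#' Identifiers are whitespace-trimmed; set `uppercase = TRUE` to fold them to
#' upper case, which papers over the common symbol-case mismatch between
#' score lists and networks.
#'
#' @param path path to the .rnk file.
#' @param uppercase fold gene identifiers to upper case.
#' @return A [gene_scores()] object with provenance `"raw"`.
#' @export
read_rnk <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(idx)) stop("no data rows in ", path, call. = FALSE)
  genes <- character(length(idx))
  vals <- numeric(length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      fields <- strsplit(trimws(lines[ln]), "[\t ]+")[[1L]]
    }
    if (length(fields) < 2L) {
      stop("line ", ln, ": expected 2 columns (gene, score)", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(v)) {
      stop("line ", ln, ": non-numeric score '", fields[2L], "'", call. = FALSE)
    }
    genes[k] <- trimws(fields[1L])
    vals[k] <- v
  }
  if (uppercase) genes <- toupper(genes)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(length(dup), " duplicated gene(s); keeping the largest |score| ",
            "(e.g. ", dup[1L], ")", call. = FALSE)
    ord <- order(-abs(vals))   # stable: among equal |score|, first occurrence wins
    keep_first <- !duplicated(genes[ord])
    sel <- sort(ord[keep_first])
    genes <- genes[sel]
    vals <- vals[sel]
  }
  gene_scores(vals, genes, provenance = "raw")
}

#' Write a gene score vector as a .rnk file
#' @param scores a [gene_scores()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(scores, path) {
  stopifnot(inherits(scores, "gene_scores"))
  writeLines(sprintf("%s\t%.17g", names(scores), as.numeric(scores)), path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Each line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Members are
#' deduplicated per pathway. Lines with fewer than three fields are a parse
#' error; an empty file yields an empty collection with a warning.
#'
#' @param path path to the GMT file.
#' @param uppercase fold member identifiers to upper case.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*$", lines))
  if (!length(idx)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(pathway_collection(list()))
  }
  sets <- vector("list", length(idx))
  nms <- character(length(idx))
  desc <- character(length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("line ", ln, ": GMT requires name, description and >= 1 member",
           call. = FALSE)
    }
    nms[k] <- fields[1L]
    desc[k] <- fields[2L]
    members <- fields[-(1:2)]
    if (uppercase) members <- toupper(members)
    sets[[k]] <- unique(members)
  }
  names(sets) <- nms
  pathway_collection(sets, desc)
}

#' Write a pathway collection in GMT format
#' @param col a [pathway_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(col, path) {
  stopifnot(inherits(col, "pathway_collection"))
  lines <- vapply(names(col$sets), function(nm) {
    paste(c(nm, col$descriptions[[nm]], col$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter pathways by size
#'
#' Retains pathways whose full member set (before any network intersection)
#' has between `min_size` and `max_size` genes, inclusive. The defaults,
#' 15 and 500, are the standard database-side filter for curated pathway
#' collections.
#'
#' @param col a [pathway_collection()].
#' @param min_size,max_size inclusive size bounds.
#' @return The filtered collection, with `filter_state` recording the bounds
#'   and the before/after counts.
#' @export
filter_by_size <- function(col, min_size = 15L, max_size = 500L) {
  stopifnot(inherits(col, "pathway_collection"))
  if (!(min_size >= 1 && min_size <= max_size)) {
    stop("need 1 <= min_size <= max_size", call. = FALSE)
  }
  sizes <- lengths(col$sets)
  keep <- sizes >= min_size & sizes <= max_size
  out <- col
  out$sets <- col$sets[keep]
  out$descriptions <- col$descriptions[keep]
  out$filter_state <- list(min_size = as.integer(min_size),
                           max_size = as.integer(max_size),
                           n_before = length(col$sets),
                           n_after = sum(keep))
  out
}

#' Effective pathway sizes over a scored universe
#'
#' Counts, per pathway, the members present in `scored_genes`. Pathways whose
#' effective size falls below `floor` cannot be tested against a background
#' and are reported; exclusion itself happens in the testing stage.
#'
#' @param col a [pathway_collection()].
#' @param scored_genes character vector of gene identifiers with scores.
#' @param floor minimum effective size for testability (default 2).
#' @return Named integer vector of effective sizes for all pathways, with the
#'   below-floor names in attribute `"excluded"`.
#' @export
effective_pathway_sizes <- function(col, scored_genes, floor = 2L) {
  stopifnot(inherits(col, "pathway_collection"))
  scored_genes <- as.character(scored_genes)
  eff <- vapply(col$sets, function(m) sum(m %in% scored_genes), 0L)
  excluded <- names(eff)[eff < floor]
  if (length(excluded)) {
    message(length(excluded), " pathway(s) below the effective-size floor of ",
            floor, "; excluded from testing")
  }
  attr(eff, "excluded") <- excluded
  eff
}
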