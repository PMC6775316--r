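#' EASE score (modified one-tailed Fisher exact p-value)
#'
#' The EASE statistic penalizes the one-tailed Fisher exact test by removing
#' one gene from the overlap: with k genes of the n-gene query falling in a
#' K-gene set drawn from an N-gene universe, EASE = P(X >= k - 1) for
#' X ~ Hypergeometric(N, K, n).  Overlaps of 0 or 1 gene give p = 1, so a
#' single-gene overlap can never look significant.
#'
#' @param k overlap size(s).
#' @param n query (gene-list) size.
#' @param K gene-set size.
#' @param N universe size.
#' @return EASE p-value(s) in \[0, 1\].
#' @seealso [fisher_exact_p()] for the unmodified tail.
#' @export
ease_score <- function(k, n, K, N) {
  check_table(k, n, K, N)
  kp <- pmax(k - 1, 0)
  phyper(kp - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-tailed Fisher exact (hypergeometric upper tail) p-value
#' @inheritParams ease_score
#' @return P(X >= k) for X ~ Hypergeometric(N, K, n).
#' @export
fisher_exact_p <- function(k, n, K, N) {
  check_table(k, n, K, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_table <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 0) ||
      any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    stop("inconsistent 2x2 table: need 0 <= k <= min(n, K) <= N")
  }
  invisible(TRUE)
}

#' Gene-set over-representation for one module
#'
#' Tests every gene set with at least one gene overlapping the query
#' against the supplied background universe using the EASE statistic;
#' results carry the unmodified Fisher tail and BH-adjusted EASE values and
#' are sorted by increasing EASE p.
#'
#' Sets are restricted to the universe before testing.  The query must be a
#' subset of the background (the universe should be "all assembled genes",
#' not all genes in the annotation).
#'
#' @param genes character vector of query gene ids (a module's genes).
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector: the gene universe.
#' @return data.frame of class `enrichment_result`: `term`, `k`, `n`, `K`,
#'   `N`, `ease_p`, `fisher_p`, `fdr`, `overlap` (comma-separated ids).
#' @export
enrich_module <- function(genes, collection, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background universe is empty")
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, background)
  if (length(outside)) {
    stop("query genes absent from the background: ",
         paste(head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ...")
  }
  if (length(collection) == 0) stop("empty gene-set collection")
  sets <- lapply(collection, function(s) intersect(unique(s), background))
  N <- length(background)
  n <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- intersect(genes, s)
    k <- length(ov)
    if (k == 0) return(NULL)
    data.frame(term = nm, k = k, n = n, K = length(s), N = N,
               ease_p = ease_score(k, n, length(s), N),
               fisher_p = fisher_exact_p(k, n, length(s), N),
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), ease_p = numeric(0),
                      fisher_p = numeric(0), overlap = character(0),
                      stringsAsFactors = FALSE)
  }
  out$fdr <- bh_adjust(out$ease_p)
  out <- out[order(out$ease_p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Terms enriched in every group, with their common genes
#'
#' A term is kept when its EASE p-value is at or below `p_cut` in every
#' group.  For each kept term the common genes are the intersection over
#' groups of (term genes restricted to that group's module genes).
#'
#' @param results named list (one [enrich_module()] result per group).
#' @param collection the gene-set collection the results were computed from.
#' @param module_genes named list of per-group module gene vectors.
#' @param p_cut EASE threshold (inclusive), default 0.05.
#' @return data.frame with `term`, `max_ease_p`, `n_common_genes`,
#'   `common_genes` (comma-separated), plus a `common_gene_list` attribute
#'   (named list of character vectors).
#' @export
common_enriched <- function(results, collection, module_genes, p_cut = 0.05) {
  if (length(results) < 2) stop("need results from at least 2 groups")
  stopifnot(identical(names(results), names(module_genes)))
  sig <- lapply(results, function(r) r$term[r$ease_p <= p_cut])
  terms <- sort(Reduce(intersect, sig))
  gene_lists <- lapply(terms, function(tm) {
    per_group <- lapply(names(results), function(g) {
      intersect(collection[[tm]], module_genes[[g]])
    })
    sort(Reduce(intersect, per_group))
  })
  names(gene_lists) <- terms
  max_p <- vapply(terms, function(tm) {
    max(vapply(results, function(r) r$ease_p[r$term == tm], numeric(1)))
  }, numeric(1))
  out <- data.frame(
    term = terms,
    max_ease_p = unname(max_p),
    n_common_genes = vapply(gene_lists, length, integer(1)),
    common_genes = vapply(gene_lists, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "common_gene_list") <- gene_lists
  out
}
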