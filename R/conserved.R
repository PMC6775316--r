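#' Run the full multi-group conserved-interaction analysis
#'
#' For each treatment group: normalizes counts, builds the co-expression
#' network, selects the trait-associated module and its TOM; then tests
#' each group's module genes for gene-set over-representation, extracts the
#' commonly enriched terms and their common genes, and runs the
#' conserved-interaction funnel across groups.
#'
#' @param counts named list of per-group count matrices (transcripts x
#'   samples).
#' @param samples named list of per-group sample tables (`sample_id`,
#'   `group`, `trait`).
#' @param catalog an `lnc_catalog` (or its table) covering all transcripts.
#' @param collection named list of gene sets.
#' @param background gene universe for enrichment.
#' @param power,cut_height,min_module_size,roster_mm passed to
#'   [run_network()].
#' @param q,mode passed to the conserved funnel.
#' @param p_cut EASE threshold for commonly enriched terms.
#' @return list with `networks`, `enrichment` (per group), `common_terms`,
#'   `common_genes`, and `conserved` (the [conserved_pipeline()] result).
#' @export
run_conserved_analysis <- function(counts, samples, catalog, collection,
                                   background, power = NULL,
                                   cut_height = 0.9, min_module_size = 30,
                                   roster_mm = NULL, q = 0.2,
                                   p_cut = 0.05, mode = "any") {
  stopifnot(identical(names(counts), names(samples)))
  tab <- if (inherits(catalog, "lnc_catalog")) catalog$table else catalog
  nets <- list(); toms <- list(); mods <- list()
  enr <- list(); modgenes <- list()
  for (g in names(counts)) {
    X <- normalize_log(counts[[g]])
    trait <- setNames(samples[[g]]$trait, samples[[g]]$sample_id)
    net <- run_network(X, trait, power = power, cut_height = cut_height,
                       min_module_size = min_module_size,
                       roster_mm = roster_mm)
    nets[[g]] <- net
    toms[[g]] <- net$tom
    mods[[g]] <- net$roster
    modgenes[[g]] <- unique(na.omit(tab$gene_id[match(net$roster,
                                                      tab$transcript_id)]))
    enr[[g]] <- enrich_module(modgenes[[g]], collection, background)
  }
  common_terms <- common_enriched(enr, collection, modgenes, p_cut = p_cut)
  cg <- as.character(sort(unique(unlist(attr(common_terms,
                                             "common_gene_list")))))
  pip <- conserved_pipeline(toms, mods, catalog, cg, q = q, mode = mode)
  list(networks = nets, enrichment = enr, common_terms = common_terms,
       common_genes = cg, conserved = pip)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' All weighted interaction pairs of a module
#'
#' Every unordered off-diagonal pair of module transcripts, weighted by its
#' TOM similarity: the potential interactions of the module.  A module of m
#' transcripts yields m(m-1)/2 pairs.
#'
#' @param tom TOM similarity matrix (at least covering the module).
#' @param module_ids transcript ids of the module.
#' @return data.frame with `a`, `b` (a < b lexicographically), `weight`.
#' @export
interactions_from_module <- function(tom, module_ids = rownames(tom)) {
  missing <- setdiff(module_ids, rownames(tom))
  if (length(missing)) {
    stop("module transcripts absent from TOM: ",
         paste(head(missing, 5), collapse = ", "))
  }
  m <- length(module_ids)
  if (m < 2) {
    return(data.frame(a = character(0), b = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  tm <- unclass(tom)[module_ids, module_ids]
  idx <- which(upper.tri(tm), arr.ind = TRUE)
  i1 <- module_ids[idx[, 1]]
  i2 <- module_ids[idx[, 2]]
  data.frame(a = pmin(i1, i2), b = pmax(i1, i2),
             weight = tm[idx], stringsAsFactors = FALSE)
}

#' Intersect interaction pairs across groups
#'
#' Keeps the unordered pairs present in every group's pair list, carrying
#' each group's TOM weight.
#'
#' @param pair_lists named list of per-group pair data.frames
#'   (from [interactions_from_module()]).
#' @return data.frame of class `interaction_set`: `a`, `b`, one
#'   `weight_<group>` column per group.
#' @export
intersect_common <- function(pair_lists) {
  if (length(pair_lists) < 2) stop("need pair lists from at least 2 groups")
  if (is.null(names(pair_lists)) || any(!nzchar(names(pair_lists)))) {
    stop("pair_lists must be named by group")
  }
  keys <- lapply(pair_lists, function(p) pair_key(p$a, p$b))
  common <- Reduce(intersect, keys)
  first <- pair_lists[[1]]
  sel <- match(common, keys[[1]])
  out <- data.frame(a = first$a[sel], b = first$b[sel],
                    stringsAsFactors = FALSE)
  for (g in names(pair_lists)) {
    out[[paste0("weight_", g)]] <-
      pair_lists[[g]]$weight[match(common, keys[[g]])]
  }
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- names(pair_lists)
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Filter interactions by RNA-type and common-gene membership
#'
#' Retains mRNA-mRNA and lncRNA-mRNA pairs (lncRNA-lncRNA pairs are
#' dropped) that touch the common genes: by default at least one endpoint's
#' gene must belong to `common_genes`; `mode = "both"` requires both.
#'
#' @param iset interaction set from [intersect_common()].
#' @param catalog an `lnc_catalog` (or its `table`): supplies `gene_id` and
#'   lncRNA/mRNA type per transcript.
#' @param common_genes character vector of gene ids (e.g. the common genes
#'   of the commonly enriched terms).
#' @param mode `"any"` (default) or `"both"` endpoints in `common_genes`.
#' @return filtered interaction set with a `pair_type` column.
#' @export
filter_type_and_genes <- function(iset, catalog, common_genes,
                                  mode = c("any", "both")) {
  mode <- match.arg(mode)
  tab <- if (inherits(catalog, "lnc_catalog")) catalog$table else catalog
  ids <- unique(c(iset$a, iset$b))
  missing <- setdiff(ids, tab$transcript_id)
  if (length(missing)) {
    stop("interaction endpoints absent from catalog: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  }
  type_a <- tab$rna_type[match(iset$a, tab$transcript_id)]
  type_b <- tab$rna_type[match(iset$b, tab$transcript_id)]
  gene_a <- tab$gene_id[match(iset$a, tab$transcript_id)]
  gene_b <- tab$gene_id[match(iset$b, tab$transcript_id)]
  n_lnc <- (type_a == "lncRNA") + (type_b == "lncRNA")
  pair_type <- c("mRNA-mRNA", "lncRNA-mRNA", "lncRNA-lncRNA")[n_lnc + 1]
  in_a <- gene_a %in% common_genes
  in_b <- gene_b %in% common_genes
  gene_ok <- if (mode == "any") in_a | in_b else in_a & in_b
  keep <- pair_type %in% c("mRNA-mRNA", "lncRNA-mRNA") & gene_ok
  out <- iset[keep, , drop = FALSE]
  out$pair_type <- pair_type[keep]
  rownames(out) <- NULL
  attr(out, "groups") <- attr(iset, "groups")
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Simultaneous top-quantile filter on interaction weights
#'
#' For each group the (1 - q) quantile of that group's weights over the
#' current set is the threshold; a pair is retained only when its weight
#' reaches the threshold in EVERY group simultaneously.  Quantiles use the
#' type-7 (linear interpolation) convention and the threshold is inclusive.
#'
#' @param iset interaction set with `weight_<group>` columns.
#' @param q retained fraction per group, in (0, 1\]; default 0.20.
#' @return filtered interaction set.
#' @export
top_quantile_filter <- function(iset, q = 0.20) {
  if (length(q) != 1 || is.na(q) || q <= 0 || q > 1) {
    stop("q must lie in (0, 1]")
  }
  if (nrow(iset) == 0) stop("interaction set is empty")
  wcols <- grep("^weight_", names(iset), value = TRUE)
  if (length(wcols) == 0) stop("no per-group weight columns")
  keep <- rep(TRUE, nrow(iset))
  for (wc in wcols) {
    t_g <- quantile(iset[[wc]], probs = 1 - q, type = 7, names = FALSE)
    keep <- keep & iset[[wc]] >= t_g
  }
  out <- iset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- attr(iset, "groups")
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Assemble the conserved network from the final interaction set
#'
#' @param iset final interaction set.
#' @param catalog an `lnc_catalog` (or its `table`) for node annotation.
#' @param common_genes gene ids used by the gene filter (node annotation).
#' @return list of class `conserved_network` with `edges` (a, b, per-group
#'   weights, `mean_weight`, `pair_type`) and `nodes` (`transcript_id`,
#'   `gene_id`, `rna_type`, `in_common_genes`, `degree`).
#' @export
build_conserved_network <- function(iset, catalog, common_genes = character(0)) {
  tab <- if (inherits(catalog, "lnc_catalog")) catalog$table else catalog
  wcols <- grep("^weight_", names(iset), value = TRUE)
  edges <- as.data.frame(iset, stringsAsFactors = FALSE)
  edges$mean_weight <- if (nrow(edges)) {
    rowMeans(edges[, wcols, drop = FALSE])
  } else {
    numeric(0)
  }
  ids <- sort(unique(c(iset$a, iset$b)))
  deg <- table(factor(c(iset$a, iset$b), levels = ids))
  nodes <- data.frame(
    transcript_id = ids,
    gene_id = tab$gene_id[match(ids, tab$transcript_id)],
    rna_type = tab$rna_type[match(ids, tab$transcript_id)],
    stringsAsFactors = FALSE
  )
  nodes$in_common_genes <- nodes$gene_id %in% common_genes
  nodes$degree <- as.integer(deg)
  structure(list(edges = edges, nodes = nodes), class = "conserved_network")
}

#' @export
print.conserved_network <- function(x, ...) {
  cat("Conserved interaction network:", nrow(x$edges), "edges,",
      nrow(x$nodes), "nodes (",
      sum(x$nodes$rna_type == "lncRNA"), "lncRNA /",
      sum(x$nodes$rna_type == "mRNA"), "mRNA )\n")
  invisible(x)
}

#' Run the conserved-interaction funnel across groups
#'
#' Chains [interactions_from_module()], [intersect_common()],
#' [filter_type_and_genes()], [top_quantile_filter()] and
#' [build_conserved_network()], returning every intermediate stage so the
#' funnel (|common| >= |filtered| >= |final|) can be inspected.
#'
#' @param toms named list of per-group TOM matrices restricted to (or
#'   covering) each group's selected module.
#' @param modules named list of per-group module transcript-id vectors.
#' @param catalog an `lnc_catalog`.
#' @param common_genes gene ids from the commonly enriched terms.
#' @param q retained fraction for the top-quantile rule.
#' @param mode gene-membership mode, see [filter_type_and_genes()].
#' @return list with `common`, `filtered`, `final` interaction sets,
#'   `network`, and `funnel` (named sizes).
#' @export
conserved_pipeline <- function(toms, modules, catalog, common_genes,
                               q = 0.20, mode = "any") {
  stopifnot(identical(names(toms), names(modules)))
  pair_lists <- lapply(names(toms), function(g) {
    interactions_from_module(toms[[g]], modules[[g]])
  })
  names(pair_lists) <- names(toms)
  common <- intersect_common(pair_lists)
  filtered <- filter_type_and_genes(common, catalog, common_genes,
                                    mode = mode)
  final <- if (nrow(filtered)) top_quantile_filter(filtered, q = q) else filtered
  list(
    common = common, filtered = filtered, final = final,
    network = build_conserved_network(final, catalog, common_genes),
    funnel = c(common = nrow(common), filtered = nrow(filtered),
               final = nrow(final))
  )
}
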