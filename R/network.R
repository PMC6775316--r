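#' Flag outlier samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on the Euclidean distance
#' between their expression profiles; the tree is cut at `cut_height` and
#' every sample falling in a cluster smaller than `min_cluster` is flagged.
#'
#' @param X normalized expression matrix, transcripts x samples.
#' @param cut_height static cut height; `NULL` uses a robust default of
#'   median + 5 MAD of the merge heights, which flags nothing on
#'   homogeneous data (a small positive floor keeps degenerate
#'   all-identical input legal).
#' @param min_cluster clusters below this size are outliers.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(X, cut_height = NULL, min_cluster = 3) {
  X <- as.matrix(X)
  if (ncol(X) < 3) stop("need at least 3 samples")
  hc <- hclust(dist(t(X)), method = "average")
  if (is.null(cut_height)) {
    cut_height <- max(median(hc$height) + 5 * mad(hc$height),
                      .Machine$double.eps)
  }
  if (cut_height <= 0) stop("cut_height must be positive")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  flagged <- names(cl)[cl %in% as.integer(names(sizes)[sizes < min_cluster])]
  sort(flagged)
}

# scale-free topology fit: bin connectivity into ~equal-count bins, estimate
# the log density of k per bin, regress log10 density on log10 mean k.
# signed R^2 = R^2 * sign(-slope): positive only for a decaying p(k).
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  brk <- unique(quantile(k, probs = seq(0, 1, length.out = nbins + 1),
                         type = 7, names = FALSE))
  if (length(brk) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = nlevels(bin))
  width <- diff(brk)
  meank <- tapply(k, bin, mean)
  keep <- cnt > 0 & width > 0 & meank > 0
  if (sum(keep) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  dens <- cnt[keep] / (length(k) * width[keep])
  fit <- lm(log10(dens) ~ log10(meank[keep]))
  slope <- coef(fit)[[2]]
  r2 <- summary(fit)$r.squared
  c(r2 = r2 * sign(-slope), slope = slope)
}

#' Pick the soft-threshold power for a scale-free network
#'
#' For each candidate power beta the unsigned adjacency |cor|^beta is
#' formed, connectivity k_i = sum_{j != i} A_ij computed, and the
#' scale-free topology fit index (signed R^2 of log10 p(k) vs log10 k over
#' ~10 equal-count bins) evaluated.  The chosen power is the smallest beta
#' whose signed R^2 reaches `r2_target` while mean connectivity stays at or
#' above `min_mean_k`; when no candidate qualifies, the beta maximizing the
#' signed R^2 is reported with `converged = FALSE`.
#'
#' Candidates default to 1..15, the conventional cap for an undirected
#' network.  `min_mean_k` defaults to 1% of the number of transcripts (the
#' absolute "connectivity above 100" rule only makes sense at a fixed
#' transcriptome size).
#'
#' @param X normalized expression matrix, transcripts x samples.
#' @param candidates integer powers to scan.
#' @param r2_target scale-free fit target (default 0.8).
#' @param min_mean_k minimum mean connectivity.
#' @param nbins histogram bins for the fit.
#' @return object of class `soft_threshold_scan`: list with `scan`
#'   (data.frame power / r2_signed / mean_k), `chosen_power`, `converged`.
#' @export
pick_soft_threshold <- function(X, candidates = 1:15, r2_target = 0.8,
                                min_mean_k = NULL, nbins = 10) {
  X <- as.matrix(X)
  if (nrow(X) < 20) stop("need at least 20 transcripts")
  if (ncol(X) < 4) stop("need at least 4 samples")
  if (any(candidates < 1)) stop("powers must be >= 1")
  v <- apply(X, 1, var)
  if (all(v == 0)) stop("all transcripts have zero variance")
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance transcripts excluded from the scan")
    X <- X[v > 0, , drop = FALSE]
  }
  if (is.null(min_mean_k)) min_mean_k <- 0.01 * nrow(X)
  ac <- abs(cor(t(X), use = "pairwise.complete.obs"))
  diag(ac) <- 0
  scan <- data.frame(power = as.integer(candidates), r2_signed = NA_real_,
                     slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    k <- colSums(ac^candidates[i])
    f <- scale_free_fit(k, nbins = nbins)
    scan$r2_signed[i] <- f[["r2"]]
    scan$slope[i] <- f[["slope"]]
    scan$mean_k[i] <- mean(k)
  }
  ok <- !is.na(scan$r2_signed) & scan$r2_signed >= r2_target &
    scan$mean_k >= min_mean_k
  if (any(ok)) {
    chosen <- scan$power[which(ok)[1]]
    converged <- TRUE
  } else {
    converged <- FALSE
    if (all(is.na(scan$r2_signed))) {
      warning("scale-free fit degenerate for every power; ",
              "returning the smallest candidate")
      chosen <- scan$power[1]
    } else {
      warning("no power reaches the scale-free fit target; ",
              "returning the best-fitting power")
      chosen <- scan$power[which.max(scan$r2_signed)]
    }
  }
  structure(list(scan = scan, chosen_power = chosen, converged = converged,
                 r2_target = r2_target, min_mean_k = min_mean_k),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (target signed R^2 >=", x$r2_target,
      ", mean k >=", signif(x$min_mean_k, 3), ")\n")
  print(x$scan[, c("power", "r2_signed", "mean_k")], row.names = FALSE)
  cat(if (x$converged) "chosen power:" else "NOT CONVERGED; best power:",
      x$chosen_power, "\n")
  invisible(x)
}

#' Unsigned soft-thresholded adjacency
#'
#' A_ij = |cor_ij|^beta off the diagonal, A_ii = 1.  With `signed = TRUE`
#' the signed variant ((1 + cor)/2)^beta is used instead.
#'
#' @param corr symmetric correlation matrix with entries in \[-1, 1\].
#' @param beta soft-threshold power (>= 1).
#' @param signed use the signed adjacency transform.
#' @return adjacency matrix with unit diagonal.
#' @export
adjacency_matrix <- function(corr, beta, signed = FALSE) {
  if (beta < 1) stop("beta must be >= 1")
  corr <- as.matrix(corr)
  if (max(abs(corr), na.rm = TRUE) > 1 + 1e-8) {
    stop("correlations must lie in [-1, 1]")
  }
  A <- if (signed) ((1 + corr) / 2)^beta else abs(corr)^beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; TOM_ii = 1.
#' High topological overlap means two nodes share neighbours in the weighted
#' network beyond their direct connection.
#'
#' @param A symmetric adjacency matrix, entries in \[0, 1\], unit diagonal.
#' @return matrix of class `tom_matrix`, symmetric, in \[0, 1\], unit
#'   diagonal, dimnames preserved.
#' @export
tom_similarity <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-10) {
    stop("adjacency must be symmetric")
  }
  if (min(A) < -1e-12 || max(A) > 1 + 1e-12) {
    stop("adjacency entries must lie in [0, 1]")
  }
  B <- A
  diag(B) <- 0
  L <- B %*% B          # l_ij: u = i and u = j drop out (zero diagonal)
  k <- rowSums(B)
  kmin <- outer(k, k, pmin)
  tom <- (L + B) / (kmin + 1 - B)
  diag(tom) <- 1
  tom[tom > 1] <- 1     # guard numerical overshoot at ~1e-16
  class(tom) <- c("tom_matrix", class(tom))
  tom
}

#' Detect modules by static tree cut on TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut at a fixed
#' height; clusters of at least `min_module_size` transcripts become
#' modules, numbered by decreasing size (module 1 is the largest); all other
#' transcripts get label 0 (unassigned/grey).
#'
#' @param tom TOM similarity matrix (from [tom_similarity()]).
#' @param min_module_size smallest cluster kept as a module (>= 2).
#' @param cut_height static cut height on the 1 - TOM dendrogram (default 0.9
#'   sits in the gap between module and background dissimilarity across
#'   typical powers).
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.9) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  tom <- unclass(tom)
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(cl))
  for (i in seq_along(keep)) {
    labels[cl == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengene
#'
#' First principal component of the per-transcript standardized module
#' submatrix, scaled to unit variance and sign-oriented so that it
#' correlates non-negatively with the mean standardized module expression.
#' A single-transcript module returns that transcript's z-score.
#'
#' @param X_module expression submatrix, module transcripts x samples.
#' @return numeric vector, one value per sample, unit variance.
#' @export
module_eigengene <- function(X_module) {
  X_module <- as.matrix(X_module)
  Z <- t(scale(t(X_module)))
  if (anyNA(Z)) {
    keep <- rowSums(is.na(Z)) == 0
    if (!any(keep)) stop("module has no transcript with positive variance")
    Z <- Z[keep, , drop = FALSE]
  }
  if (nrow(Z) == 1) {
    return(as.numeric(Z))
  }
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (cor(e, colMeans(Z)) < 0) e <- -e
  as.numeric(scale(e))
}

#' Eigengenes for all modules
#'
#' @param X expression matrix, transcripts x samples.
#' @param labels module labels from [detect_modules()] (0 ignored).
#' @return samples x modules matrix; column `ME<i>` is module i's eigengene.
#' @export
module_eigengenes <- function(X, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules to summarize")
  E <- vapply(mods, function(m) {
    module_eigengene(X[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(X)))
  dimnames(E) <- list(colnames(X), paste0("ME", mods))
  E
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a binary trait, with a
#' two-sided p-value from t = r sqrt(n-2)/sqrt(1-r^2) on n - 2 degrees of
#' freedom (p = 0 when |r| = 1).
#'
#' @param eigengenes samples x modules matrix.
#' @param trait numeric 0/1 vector, one entry per sample.
#' @return data.frame with `module`, `r`, `pvalue`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  eigengenes <- as.matrix(eigengenes)
  n <- nrow(eigengenes)
  if (n < 4) stop("need at least 4 samples")
  if (length(trait) != n) stop("trait length must match sample count")
  if (var(trait) == 0) stop("trait is constant")
  r <- as.numeric(cor(eigengenes, trait))
  p <- vapply(r, function(ri) {
    if (abs(ri) >= 1 - 1e-12) return(0)
    tstat <- ri * sqrt(n - 2) / sqrt(1 - ri^2)
    2 * pt(-abs(tstat), df = n - 2)
  }, numeric(1))
  data.frame(
    module = as.integer(sub("^ME", "", colnames(eigengenes))),
    r = r, pvalue = p, stringsAsFactors = FALSE
  )
}

#' Module membership and gene significance
#'
#' MM = correlation of each transcript with its own module's eigengene (NA
#' for unassigned transcripts); GS = |correlation| of the transcript with
#' the trait.
#'
#' @param X expression matrix, transcripts x samples.
#' @param labels module labels.
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param trait numeric trait vector.
#' @return data.frame with `transcript_id`, `module`, `MM`, `GS`.
#' @export
module_membership_gene_significance <- function(X, labels, eigengenes, trait) {
  X <- as.matrix(X)
  labels <- labels[rownames(X)]
  gs <- abs(as.numeric(cor(t(X), trait)))
  mm <- rep(NA_real_, nrow(X))
  for (m in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == m)
    mm[idx] <- as.numeric(cor(t(X[idx, , drop = FALSE]),
                              eigengenes[, paste0("ME", m)]))
  }
  data.frame(transcript_id = rownames(X), module = as.integer(labels),
             MM = mm, GS = gs, stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full network stage for one group
#'
#' Drops zero-variance transcripts, optionally removes outlier samples,
#' picks (or accepts) the soft-threshold power, builds adjacency and TOM,
#' detects modules, computes eigengenes and module-trait correlations, and
#' selects the module with the strongest absolute trait correlation.
#'
#' @param X normalized expression matrix, transcripts x samples.
#' @param trait numeric 0/1 vector aligned with `colnames(X)`.
#' @param power soft threshold; `NULL` runs [pick_soft_threshold()].
#' @param candidates candidate powers for the scan.
#' @param r2_target,min_mean_k scan parameters.
#' @param min_module_size,cut_height module detection parameters.
#' @param drop_outliers flag and remove outlier samples first.
#' @param roster_mm optional module-membership cutoff: when set, the
#'   selected module's transcript roster (and its TOM slice) is defined as
#'   all transcripts with |MM| at or above this value with respect to the
#'   selected eigengene, the standard kME-based module definition; this is
#'   far more stable across groups than raw tree-cut labels.  `NULL` uses
#'   the tree-cut labels as the roster.
#' @param keep_tom retain the full TOM matrix in the result.
#' @return object of class `network_result`: list with `power`, `scan`,
#'   `labels`, `eigengenes`, `module_trait`, `selected_module`,
#'   `module_sizes`, `samples_used`, `outliers`, and `tom` (selected-module
#'   TOM, plus full TOM when `keep_tom = TRUE`).
#' @export
run_network <- function(X, trait, power = NULL, candidates = 1:15,
                        r2_target = 0.8, min_mean_k = NULL,
                        min_module_size = 30, cut_height = 0.9,
                        drop_outliers = FALSE, roster_mm = NULL,
                        keep_tom = FALSE) {
  X <- as.matrix(X)
  if (is.null(names(trait))) names(trait) <- colnames(X)
  outliers <- character(0)
  if (drop_outliers) {
    outliers <- detect_outlier_samples(X)
    if (length(outliers)) {
      X <- X[, setdiff(colnames(X), outliers), drop = FALSE]
    }
  }
  trait <- trait[colnames(X)]
  v <- apply(X, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance transcripts dropped")
    X <- X[v > 0, , drop = FALSE]
  }
  scan <- NULL
  if (is.null(power)) {
    scan <- pick_soft_threshold(X, candidates = candidates,
                                r2_target = r2_target,
                                min_mean_k = min_mean_k)
    power <- scan$chosen_power
  }
  corr <- cor(t(X), use = "pairwise.complete.obs")
  A <- adjacency_matrix(corr, power)
  tom <- tom_similarity(A)
  labels <- detect_modules(tom, min_module_size = min_module_size,
                           cut_height = cut_height)
  E <- module_eigengenes(X, labels)
  mt <- module_trait_correlation(E, trait)
  mt$size <- as.integer(table(factor(labels, levels = mt$module)))
  selected <- mt$module[which.max(abs(mt$r))]
  sel_ids <- names(labels)[labels == selected]
  if (!is.null(roster_mm)) {
    mm <- as.numeric(cor(t(X), E[, paste0("ME", selected)]))
    sel_ids <- rownames(X)[!is.na(mm) & abs(mm) >= roster_mm]
  }
  res <- list(
    power = power, scan = scan, labels = labels, eigengenes = E,
    module_trait = mt, selected_module = selected,
    roster = sel_ids,
    module_sizes = table(labels), samples_used = colnames(X),
    outliers = outliers,
    tom = tom[sel_ids, sel_ids],
    X = X, trait = trait
  )
  if (keep_tom) res$tom_full <- tom
  structure(res, class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat("Co-expression network: power", x$power, "|",
      sum(x$module_trait$size), "transcripts in",
      nrow(x$module_trait), "modules\n")
  best <- x$module_trait[x$module_trait$module == x$selected_module, ]
  cat(sprintf("selected module %d (%d transcripts): r = %.3f, p = %.2g\n",
              best$module, best$size, best$r, best$pvalue))
  invisible(x)
}
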