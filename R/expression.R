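#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference
#' transcripts g of counts[g, j] / geomean(counts[g, ]), where reference
#' transcripts are those with strictly positive counts in every sample
#' (positive geometric mean).
#'
#' @param counts non-negative count matrix, transcripts x samples.
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no transcript has positive counts in all samples; ",
         "median-of-ratios normalization needs at least one. ",
         "Filter samples or use a pseudocount upstream.")
  }
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2,
              function(cj) median(cj / exp(loggeo)))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factors; check the count matrix")
  }
  sf
}

#' Shifted-log normalization
#'
#' Divides each column by its size factor and applies log2(x + 1).  This is
#' a variance-stabilizing stand-in for the regularized log transform: the
#' downstream network analysis needs approximately homoskedastic values, not
#' bit-compatibility with any particular implementation.
#'
#' @param counts count matrix, transcripts x samples.
#' @param sf size factors (default computed by [size_factors()]).
#' @return numeric matrix of log2-scale normalized values.
#' @export
normalize_log <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts)) {
    stop("length(sf) must equal ncol(counts)")
  }
  if (any(sf <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, sf, `/`) + 1)
}

#' Negative-binomial Wald test, treated vs merged controls
#'
#' Per transcript: counts are normalized by median-of-ratios size factors;
#' dispersion alpha (Var = mu + alpha mu^2) is estimated by method of
#' moments within each condition and pooled (floored at 1e-8); the log2 fold
#' change uses a pseudo-count of 0.5 on each group mean; the Wald statistic
#' divides the log2 fold change by its delta-method standard error and is
#' referred to a t distribution with n1 + n0 - 2 degrees of freedom (a
#' small-sample correction for the plug-in variance).
#'
#' Treated samples are those with `trait == 1` (and `group == group` when a
#' group label is given); controls are all samples with `trait == 0`,
#' mirroring a merged-control design.
#'
#' @param counts count matrix, transcripts x samples (columns named by
#'   sample id).
#' @param samples data.frame with `sample_id`, `group`, `trait` (0/1).
#' @param group optional treatment-group label selecting the treated samples.
#' @param pseudo pseudo-count added to group means for the fold change.
#' @return data.frame of class `de_result`: `transcript_id`, `baseMean`,
#'   `log2fc`, `pvalue`, `fdr`.
#' @export
nb_wald_test <- function(counts, samples, group = NULL, pseudo = 0.5) {
  counts <- as.matrix(counts)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (anyNA(samples$sample_id)) stop("sample table does not cover all columns")
  treated <- samples$trait == 1L
  if (!is.null(group)) treated <- treated & samples$group == group
  control <- samples$trait == 0L
  n1 <- sum(treated); n0 <- sum(control)
  if (n1 < 2 || n0 < 2) stop("need at least 2 samples per condition")

  # normalized counts on the natural scale, restricted to the used samples
  sf <- size_factors(counts[, treated | control, drop = FALSE])
  ync <- sweep(counts[, treated | control, drop = FALSE], 2, sf, `/`)
  tt <- treated[treated | control]
  cc <- control[treated | control]

  m1 <- rowMeans(ync[, tt, drop = FALSE])
  m0 <- rowMeans(ync[, cc, drop = FALSE])
  v1 <- apply(ync[, tt, drop = FALSE], 1, var)
  v0 <- apply(ync[, cc, drop = FALSE], 1, var)
  a1 <- (v1 - m1) / m1^2
  a0 <- (v0 - m0) / m0^2
  a1[!is.finite(a1)] <- 0
  a0[!is.finite(a0)] <- 0
  alpha <- pmax(((n1 - 1) * a1 + (n0 - 1) * a0) / (n1 + n0 - 2), 1e-8)

  log2fc <- log2((m1 + pseudo) / (m0 + pseudo))
  # delta method: Var(log2(m + pseudo)) = Var(m) / ((m + pseudo) ln 2)^2
  var_m1 <- (m1 + alpha * m1^2) / n1
  var_m0 <- (m0 + alpha * m0^2) / n0
  se <- sqrt(var_m1 / ((m1 + pseudo) * log(2))^2 +
             var_m0 / ((m0 + pseudo) * log(2))^2)
  wald <- log2fc / se
  p <- 2 * pt(-abs(wald), df = n1 + n0 - 2)

  allzero <- m1 == 0 & m0 == 0
  log2fc[allzero] <- 0
  p[allzero | !is.finite(p)] <- 1

  out <- data.frame(
    transcript_id = rownames(counts),
    baseMean = rowMeans(ync),
    log2fc = log2fc,
    pvalue = p,
    fdr = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values (FDR), clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq.int(n, 1) * p[o]))[ro]
}

#' Flag significantly differentially expressed transcripts
#'
#' Default rule: raw p < 0.05 and fold change > 2 (|log2fc| > 1), i.e.
#' strict inequalities on both.  Set `use_fdr = TRUE` to threshold the
#' BH-adjusted values instead (FDR <= p_cut).
#'
#' @param de result of [nb_wald_test()].
#' @param p_cut p-value (or FDR) threshold.
#' @param fc_cut fold-change threshold on the natural scale.
#' @param use_fdr threshold `fdr` (inclusive) instead of raw `pvalue`
#'   (exclusive).
#' @return `de` with logical `significant` and `direction`
#'   (up/down/ns) columns appended.
#' @export
call_significant <- function(de, p_cut = 0.05, fc_cut = 2, use_fdr = FALSE) {
  stat_ok <- if (use_fdr) de$fdr <= p_cut else de$pvalue < p_cut
  sig <- stat_ok & abs(de$log2fc) > log2(fc_cut)
  de$significant <- sig
  de$direction <- ifelse(!sig, "ns", ifelse(de$log2fc > 0, "up", "down"))
  de
}
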