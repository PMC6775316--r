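# Independent oracles used across the suite.  These deliberately avoid the
# code paths of the implementations they check.

## ---- adjusted Rand index (contingency-table formula) ----
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

## ---- exact-integer hypergeometric tail oracle ----
# Arbitrary-size non-negative integers as little-endian base-1e7 limb
# matrices (limbs x values); every intermediate stays below 2^53 so all
# double arithmetic on limbs is exact.
LIMB <- 1e7

norm_limbs <- function(M) {
  repeat {
    carry <- floor(M / LIMB)
    if (all(carry == 0)) break
    M <- M - carry * LIMB
    M <- rbind(M, rep(0, ncol(M)))
    M[-1, ] <- M[-1, ] + carry
  }
  while (nrow(M) > 1 && all(M[nrow(M), ] == 0)) {
    M <- M[-nrow(M), , drop = FALSE]
  }
  M
}

big_add <- function(A, B) {
  r <- max(nrow(A), nrow(B))
  pad <- function(M) rbind(M, matrix(0, r - nrow(M), ncol(M)))
  norm_limbs(pad(A) + pad(B))
}

big_mul_cols <- function(A, B) {
  # column-wise product of two limb matrices (same number of columns)
  out <- matrix(0, nrow(A) + nrow(B), ncol(A))
  for (p in seq_len(nrow(A))) {
    for (q in seq_len(nrow(B))) {
      out[p + q - 1, ] <- out[p + q - 1, ] + A[p, ] * B[q, ]
    }
  }
  norm_limbs(out)
}

big_cumsum_rev <- function(M) {
  # suffix sums over columns: S[, k] = sum of columns k..m
  S <- M[, rev(seq_len(ncol(M))), drop = FALSE]
  S <- apply(S, 1, cumsum)
  S <- if (is.matrix(S)) t(S) else matrix(S, nrow = 1)
  norm_limbs(S[, rev(seq_len(ncol(S))), drop = FALSE])
}

big_to_num <- function(M) {
  colSums(M * LIMB^(seq_len(nrow(M)) - 1))
}

# Pascal triangle rows 0..nmax as limb matrices (exact binomials)
pascal_rows <- function(nmax) {
  rows <- vector("list", nmax + 1)
  rows[[1]] <- matrix(1, 1, 1)
  for (n in seq_len(nmax)) {
    prev <- rows[[n]]
    left <- cbind(matrix(0, nrow(prev), 1), prev)
    right <- cbind(prev, matrix(0, nrow(prev), 1))
    rows[[n + 1]] <- big_add(left, right)
  }
  rows
}

# P(X >= k) for X ~ Hypergeometric(N, K, n), exactly, for all k = 0..n.
# Returns numeric vector tail[k + 1] = P(X >= k).
hyper_tail_oracle <- function(N, K, n, rows) {
  rowK <- rows[[K + 1]]
  rowM <- rows[[N - K + 1]]
  i <- 0:n
  colA <- matrix(0, nrow(rowK), n + 1)
  ok <- i <= K
  colA[, ok] <- rowK[, i[ok] + 1]
  colB <- matrix(0, nrow(rowM), n + 1)
  ok2 <- (n - i) <= (N - K)
  colB[, ok2] <- rowM[, n - i[ok2] + 1]
  terms <- big_mul_cols(colA, colB)
  suffix <- big_cumsum_rev(terms)
  denom <- big_to_num(rows[[N + 1]][, n + 1, drop = FALSE])
  big_to_num(suffix) / denom
}

## ---- O(n^3) TOM oracle ----
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(A[i, -i])
  out <- diag(n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

rand_adjacency <- function(n) {
  r <- matrix(runif(n * n), n)
  A <- (r + t(r)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}

## ---- brute-force Benjamini-Hochberg ----
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(n), function(i) {
    min(1, min(n * ps[i:n] / (i:n)))
  }, numeric(1))
  out <- numeric(n)
  out[o] <- adj
  out
}

## ---- exhaustive ORF scanner ----
orf_oracle <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n, by = 3L)
    starts <- starts[starts + 2L <= n]
    if (!length(starts)) next
    cods <- substring(s, starts, starts + 2L)
    for (ai in which(cods == "ATG")) {
      len <- 0L
      for (j in ai:length(cods)) {
        if (j > ai && cods[j] %in% c("TAA", "TAG", "TGA")) break
        len <- len + 1L
      }
      best <- max(best, len)
    }
  }
  best
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## ---- shared fixtures ----
# catalog straight from generator ground truth (bypasses the cascade)
truth_catalog <- function(truth) {
  structure(list(table = data.frame(
    transcript_id = names(truth$class),
    gene_id = unname(truth$gene_id),
    class = ifelse(truth$class == "lncRNA", "novel_lncRNA", "known_mRNA"),
    rna_type = unname(truth$class),
    stringsAsFactors = FALSE
  )), class = "lnc_catalog")
}

# two planted blocks with given within-block correlation
two_block_data <- function(n_per = 50, n_samp = 30, rho = 0.9) {
  h <- matrix(rnorm(2 * n_samp), 2)
  X <- rbind(
    sqrt(rho) * rep(1, n_per) %o% h[1, ],
    sqrt(rho) * rep(1, n_per) %o% h[2, ]
  ) + sqrt(1 - rho) * matrix(rnorm(2 * n_per * n_samp), 2 * n_per)
  rownames(X) <- sprintf("g%03d", seq_len(2 * n_per))
  colnames(X) <- sprintf("s%02d", seq_len(n_samp))
  X
}

# the small-sample analysis profile used by the synthetic recovery studies
recovery_network <- function(X, trait, ...) {
  run_network(X, trait, power = 9, cut_height = 0.97,
              min_module_size = 20, ...)
}
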