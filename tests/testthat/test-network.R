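test_that("outlier detection flags shifted samples and nothing else", {
  set.seed(1)
  X <- matrix(rnorm(100 * 10), 100, dimnames = list(NULL, sprintf("s%02d", 1:10)))
  expect_length(detect_outlier_samples(X), 0)
  # all samples identical -> none flagged
  same <- X[, rep(1, 5)]
  colnames(same) <- paste0("c", 1:5)
  expect_length(detect_outlier_samples(same), 0)
  # one sample shifted by +10 SD on all genes is flagged at the default cut
  Xo <- X
  Xo[, 3] <- Xo[, 3] + 10
  expect_equal(detect_outlier_samples(Xo), "s03")
  # flags do not depend on sample order
  perm <- sample(10)
  expect_equal(detect_outlier_samples(Xo[, perm]), "s03")
  expect_error(detect_outlier_samples(Xo, cut_height = -1), "positive")
  expect_error(detect_outlier_samples(X[, 1:2]), "3 samples")
})

test_that("soft-threshold scan passes on scale-free data and caps at 15", {
  set.seed(11)
  rho <- runif(300)
  h <- rnorm(50)
  X <- rho %o% h + sqrt(1 - rho^2) * matrix(rnorm(300 * 50), 300)
  dimnames(X) <- list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:50))
  scan <- pick_soft_threshold(X)
  expect_true(scan$converged)
  chosen <- scan$scan[scan$scan$power == scan$chosen_power, ]
  expect_gte(chosen$r2_signed, 0.8)
  expect_lte(scan$chosen_power, 15)
  expect_equal(max(scan$scan$power), 15)
  # chosen power is the smallest satisfying both rules
  ok <- scan$scan$r2_signed >= 0.8 & scan$scan$mean_k >= scan$min_mean_k
  expect_equal(scan$chosen_power, min(scan$scan$power[ok]))
})

test_that("soft-threshold scan degenerates gracefully", {
  # all genes identical -> single connectivity value -> failure flag
  v <- rnorm(20)
  X <- matrix(rep(v, each = 30), 30, byrow = FALSE)
  X <- X + 0  # constant rows across genes
  dimnames(X) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20))
  expect_warning(scan <- pick_soft_threshold(X), "degenerate|target")
  expect_false(scan$converged)
  # all-constant input errors
  Xc <- matrix(1, 30, 20, dimnames = dimnames(X))
  expect_error(suppressWarnings(pick_soft_threshold(Xc)), "zero variance")
})

test_that("adjacency transform follows |cor|^beta", {
  corr <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(adjacency_matrix(corr, 4)[1, 2], 0.0625)
  expect_equal(adjacency_matrix(matrix(c(1, -0.5, -0.5, 1), 2), 4)[1, 2],
               0.0625)
  ones <- matrix(1, 3, 3)
  expect_equal(adjacency_matrix(ones, 7), ones)
  expect_error(adjacency_matrix(corr, 0.5), ">= 1")
  expect_error(adjacency_matrix(matrix(c(1, 2, 2, 1), 2), 2), "\\[-1, 1\\]")
  # increasing beta weakly decreases every off-diagonal entry
  set.seed(3)
  r <- matrix(runif(64, -0.99, 0.99), 8)
  corr <- (r + t(r)) / 2
  diag(corr) <- 1
  a2 <- adjacency_matrix(corr, 2)
  a5 <- adjacency_matrix(corr, 5)
  expect_true(all(a5[upper.tri(a5)] <= a2[upper.tri(a2)]))
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # 2-node network: TOM_12 = A_12
  A2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(tom_similarity(A2)[1, 2], 0.3)
  # complete unit graph: all TOM = 1
  An <- matrix(1, 5, 5)
  expect_true(all(abs(unclass(tom_similarity(An)) - 1) < 1e-12))
  # oracle equivalence on random valid adjacencies
  set.seed(5)
  for (n in c(2, 3, 7, 12)) {
    A <- rand_adjacency(n)
    tom <- unclass(tom_similarity(A))
    expect_equal(tom, tom_oracle(A), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
  }
  bad <- rand_adjacency(4)
  bad[1, 2] <- 0.9
  expect_error(tom_similarity(bad), "symmetric")
  neg <- rand_adjacency(4)
  neg[1, 2] <- neg[2, 1] <- -0.2
  expect_error(tom_similarity(neg), "\\[0, 1\\]")
})

test_that("module detection recovers planted blocks exactly", {
  set.seed(9)
  X <- two_block_data(50, 30, 0.9)
  tom <- tom_similarity(adjacency_matrix(cor(t(X)), 6))
  labels <- detect_modules(tom, min_module_size = 20)
  truth <- rep(1:2, each = 50)
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_equal(ari(labels, truth), 1.0)
})

test_that("i.i.d. noise stays unassigned and small blocks are dropped", {
  set.seed(10)
  X <- matrix(rnorm(500 * 20), 500,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:20)))
  tom <- tom_similarity(adjacency_matrix(cor(t(X)), 6))
  labels <- detect_modules(tom)
  expect_gte(mean(labels == 0), 0.9)
  # a block one short of min_module_size is labeled 0
  set.seed(12)
  Xb <- two_block_data(n_per = 29, n_samp = 30, rho = 0.9)
  Xb <- rbind(Xb[1:29, ], matrix(rnorm(100 * 30), 100,
    dimnames = list(sprintf("n%03d", 1:100), colnames(Xb))))
  tomb <- tom_similarity(adjacency_matrix(cor(t(Xb)), 6))
  lab <- detect_modules(tomb, min_module_size = 30)
  expect_true(all(lab[1:29] == 0))
  expect_error(detect_modules(tom, min_module_size = 1), ">= 2")
})

test_that("module eigengene equals the PC1 oracle up to sign", {
  set.seed(13)
  Xm <- matrix(rnorm(30 * 10), 30,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  e <- module_eigengene(Xm)
  expect_equal(sd(e), 1)
  Z <- t(scale(t(Xm)))
  ev <- eigen(crossprod(Z))$vectors[, 1]
  expect_equal(abs(cor(e, ev)), 1, tolerance = 1e-10)
  # orientation: non-negative correlation with mean standardized expression
  expect_gte(cor(e, colMeans(Z)), 0)
  # rank-1 case: all transcripts identical to v -> z-score of v
  v <- rnorm(10)
  X1 <- matrix(rep(v, each = 5), 5, byrow = FALSE)
  dimnames(X1) <- list(letters[1:5], sprintf("s%02d", 1:10))
  expect_equal(module_eigengene(X1), as.numeric(scale(v)), tolerance = 1e-10)
  # single-transcript module returns its z-score
  expect_equal(module_eigengene(X1[1, , drop = FALSE]),
               as.numeric(scale(v)), tolerance = 1e-10)
})

test_that("module-trait correlation uses the Student-t closed form", {
  set.seed(14)
  e <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "ME1"))
  trait <- rep(c(1, 0), each = 10)
  # eigengene equal to the trait -> r = 1, p = 0
  mt <- module_trait_correlation(matrix(trait, 20, 1,
    dimnames = list(NULL, "ME1")), trait)
  expect_equal(mt$r, 1)
  expect_equal(mt$pvalue, 0)
  # independent t-distribution oracle by numeric integration of the density
  mt2 <- module_trait_correlation(e, trait)
  r <- mt2$r
  tstat <- r * sqrt(18) / sqrt(1 - r^2)
  tdens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p_oracle <- 2 * integrate(tdens, abs(tstat), Inf, df = 18)$value
  expect_equal(mt2$pvalue, p_oracle, tolerance = 1e-8)
  # r = 0.6, n = 20 reference value
  y <- as.numeric(scale(rnorm(20)))
  expect_error(module_trait_correlation(e, rep(1, 20)), "constant")
  expect_error(module_trait_correlation(e[1:3, , drop = FALSE], trait[1:3]),
               "4 samples")
})

test_that("module membership and gene significance behave as correlations", {
  set.seed(15)
  X <- two_block_data(20, 16, 0.8)
  labels <- setNames(rep(1:2, each = 20), rownames(X))
  E <- module_eigengenes(X, labels)
  trait <- rep(c(1, 0), each = 8)
  mg <- module_membership_gene_significance(X, labels, E, trait)
  expect_true(all(abs(mg$MM) <= 1 & mg$GS >= 0 & mg$GS <= 1))
  # a transcript equal to its module eigengene has MM = 1
  X2 <- rbind(X, eig = E[, "ME1"])
  labels2 <- c(labels, eig = 1L)
  mg2 <- module_membership_gene_significance(X2, labels2, E, trait)
  expect_equal(mg2$MM[mg2$transcript_id == "eig"], 1, tolerance = 1e-10)
  # MM and GS invariant under affine rescaling of a transcript profile
  X3 <- X
  X3[1, ] <- 5 * X3[1, ] + 2
  mg3 <- module_membership_gene_significance(X3, labels, E, trait)
  expect_equal(mg3$MM[1], mg$MM[1], tolerance = 1e-10)
  expect_equal(mg3$GS[1], mg$GS[1], tolerance = 1e-10)
  # unassigned transcripts have no module membership
  labels0 <- labels
  labels0[1] <- 0L
  mg0 <- module_membership_gene_significance(X, labels0, E, trait)
  expect_true(is.na(mg0$MM[1]))
})

test_that("run_network selects the strongest trait module", {
  set.seed(16)
  cfg <- syn_config(n_mrna = 240, n_lncrna = 60, n_modules = 3,
                    module_sizes = c(40, 40, 40), n_conserved_pairs = 5,
                    within_module_cor = 0.8, trait_effect = 2, seed = 16)
  g <- generate_counts(cfg)
  X <- normalize_log(g$counts$CAR)
  trait <- setNames(g$samples$CAR$trait, g$samples$CAR$sample_id)
  res <- suppressWarnings(recovery_network(X, trait))
  sel <- res$module_trait[res$module_trait$module == res$selected_module, ]
  expect_equal(sel$r, max(abs(res$module_trait$r)) * sign(sel$r))
  expect_true(abs(sel$r) == max(abs(res$module_trait$r)))
  # eigengene columns have unit variance
  expect_equal(unname(apply(res$eigengenes, 2, sd)),
               rep(1, ncol(res$eigengenes)))
  # membership roster mode returns a roster containing the module core
  res2 <- suppressWarnings(recovery_network(X, trait, roster_mm = 0.5))
  core <- names(res$labels)[res$labels == res$selected_module]
  expect_gte(mean(core %in% res2$roster), 0.9)
})
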