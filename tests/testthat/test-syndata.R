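small_cfg <- function(...) {
  syn_config(n_mrna = 160, n_lncrna = 40, n_modules = 3,
             module_sizes = c(30, 30, 30), n_conserved_pairs = 5,
             n_samples_treated = 10, n_samples_control = 10, ...)
}

test_that("config validation rejects inconsistent worlds", {
  expect_s3_class(syn_config(), "syn_config")
  expect_error(syn_config(n_samples_treated = 1), "dimensions")
  expect_error(syn_config(n_modules = 2, module_sizes = c(10, 10, 10)),
               "length")
  expect_error(syn_config(n_mrna = 20, n_lncrna = 5,
                          module_sizes = c(30, 120, 100, 80, 60)),
               "exceeds")
  expect_error(syn_config(trait_effect = -1), ">= 0")
  expect_error(syn_config(within_module_cor = 1), "\\[0, 1\\)")
  expect_error(syn_config(nb_dispersion = 0), "> 0")
  expect_error(syn_config(mean_log_expr_lnc = 6), "below")
  expect_error(syn_config(hub_module_cor = 0.9, pair_cor = 0.8,
                          within_module_cor = 0.8), "hub_module_cor")
  expect_error(syn_config(seed = 3e9), "seed")
})

test_that("generation is deterministic given the seed", {
  cfg <- small_cfg(seed = 99)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  ra <- generate_transcript_records(cfg)
  rb <- generate_transcript_records(cfg)
  expect_identical(ra, rb)
  # a different seed changes the data
  c_ <- generate_counts(small_cfg(seed = 100))
  expect_false(identical(a$counts, c_$counts))
})

test_that("counts follow the NB mean-variance relation", {
  # alpha = 0.5, mu = 100: sample variance within 15% of mu + alpha mu^2
  set.seed(202)
  draws <- rnbinom(10000, mu = 100, size = 1 / 0.5)
  expect_lt(abs(var(draws) - 5100) / 5100, 0.15)
  # the generator's own counts at a planted constant mean
  cfg <- small_cfg(seed = 3, nb_dispersion = 0.3)
  g <- generate_counts(cfg)
  noise <- names(g$truth$module)[g$truth$module == 0 &
                                 g$truth$class == "mRNA"]
  x <- g$counts$CAR[noise, ]
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  # method-of-moments alpha across noise transcripts recovers the input
  alpha_hat <- median((v - m) / m^2, na.rm = TRUE)
  expect_lt(abs(alpha_hat - 0.3), 0.15)
})

test_that("zero trait effect carries no trait information", {
  # mean |cor(module eigengene, trait)| over replicates stays at noise level
  r <- numeric(50)
  for (s in 1:50) {
    cfg <- syn_config(n_mrna = 160, n_lncrna = 40, n_modules = 1,
                      module_sizes = 30, n_conserved_pairs = 0,
                      n_samples_treated = 10, n_samples_control = 10,
                      trait_effect = 0, seed = 1000 + s)
    g <- generate_counts(cfg)
    X <- normalize_log(g$counts$CAR)
    e <- module_eigengene(X[names(g$truth$module)[g$truth$module == 1], ])
    r[s] <- abs(cor(e, g$samples$CAR$trait))
  }
  expect_lt(mean(r), 0.3)
})

test_that("module-trait correlation is monotone in the trait effect", {
  effects <- c(0, 0.5, 1, 2)
  meanr <- sapply(effects, function(d) {
    mean(sapply(1:20, function(s) {
      cfg <- small_cfg(trait_effect = d, seed = 2000 + s)
      g <- generate_counts(cfg)
      X <- normalize_log(g$counts$CAR)
      e <- module_eigengene(X[names(g$truth$module)[g$truth$module == 1], ])
      abs(cor(e, g$samples$CAR$trait))
    }))
  })
  expect_true(all(diff(meanr) > 0))
})

test_that("ground truth has the promised structure", {
  cfg <- small_cfg(seed = 7)
  g <- generate_counts(cfg)
  truth <- g$truth
  expect_equal(sum(truth$module > 0), sum(cfg$module_sizes))
  # planted pairs are lncRNA-mRNA and share the trait module
  tp <- truth$conserved_pairs
  expect_equal(nrow(tp), 5)
  expect_setequal(unname(truth$class[tp$a]), "lncRNA")
  expect_setequal(unname(truth$class[tp$b]), "mRNA")
  expect_true(all(truth$module[tp$a] == truth$trait_modules[1]))
  expect_true(all(truth$module[tp$b] == truth$trait_modules[1]))
  # shared control block: control columns identical across groups
  ctrl <- grep("^CTRL", colnames(g$counts[[1]]), value = TRUE)
  expect_identical(g$counts[[1]][, ctrl], g$counts[[2]][, ctrl])
  # sample tables mark exactly the treated samples
  s1 <- g$samples[[1]]
  expect_equal(sum(s1$trait), cfg$n_samples_treated)
  expect_true(all(s1$trait[s1$group == "control"] == 0))
})

test_that("planted pairs realize their target correlations", {
  cfg <- syn_config(within_module_cor = 0.8, trait_effect = 2,
                    n_samples_treated = 50, n_samples_control = 50,
                    seed = 11)
  g <- generate_counts(cfg)
  X <- normalize_log(g$counts$CAR)
  tp <- g$truth$conserved_pairs
  pair_r <- mapply(function(a, b) cor(X[a, ], X[b, ]), tp$a, tp$b)
  expect_gt(mean(pair_r), 0.9)
  # ordinary within-module correlation sits near its target
  tmod <- names(g$truth$module)[g$truth$module == 1]
  ord <- setdiff(tmod, c(tp$a, tp$b))
  C <- cor(t(X[ord, ]))
  expect_lt(abs(mean(C[upper.tri(C)]) - cfg$within_module_cor), 0.1)
})

test_that("transcript records realize the lncRNA/mRNA contrasts", {
  cfg <- small_cfg(seed = 5)
  recs <- generate_transcript_records(cfg)
  is_l <- recs$true_class == "lncRNA"
  expect_true(all(recs$length_nt == nchar(recs$sequence)))
  expect_true(all(recs$length_nt[is_l] > 200))
  # lncRNAs: shorter, fewer exons, ORF below 100 aa, no coding evidence
  expect_lt(mean(recs$length_nt[is_l]), mean(recs$length_nt[!is_l]))
  expect_lt(mean(recs$exon_count[is_l]), mean(recs$exon_count[!is_l]))
  expect_true(all(longest_orf_length(recs$sequence[is_l]) < 100))
  expect_false(any(recs$protein_db_hit[is_l] | recs$cpc_coding[is_l] |
                   recs$pfam_hit[is_l]))
  # mRNAs carry a planted ORF of at least the configured length
  expect_true(all(longest_orf_length(recs$sequence[!is_l]) >=
                  cfg$mrna_orf_aa))
  # expression contrast: lncRNAs lower than mRNAs (Fig 2-style pattern)
  g <- generate_counts(cfg)
  cls <- g$truth$class
  expect_lt(mean(log10(rowMeans(g$counts$CAR)[cls == "lncRNA"] + 1)),
            mean(log10(rowMeans(g$counts$CAR)[cls == "mRNA"] + 1)))
})

test_that("all-mRNA worlds are fully classifiable as coding", {
  cfg <- syn_config(n_mrna = 40, n_lncrna = 0, n_modules = 1,
                    module_sizes = 20, n_conserved_pairs = 0, seed = 9)
  recs <- generate_transcript_records(cfg)
  cat_ <- build_catalog(recs)
  expect_true(all(cat_$table$rna_type == "mRNA"))
})

test_that("gene sets plant the hub pathway and respect the universe", {
  cfg <- small_cfg(seed = 13)
  g <- generate_counts(cfg)
  sets <- generate_gene_sets(cfg, g$truth)
  planted <- sets$sets$planted_set
  tm_genes <- unique(unname(g$truth$gene_id[names(g$truth$module)[
    g$truth$module == 1]]))
  # at least 80% of the planted set comes from the trait module
  expect_gte(mean(planted %in% tm_genes), 0.8)
  # the hub mRNA genes are all members
  hub_genes <- unique(unname(g$truth$gene_id[g$truth$conserved_pairs$b]))
  expect_true(all(hub_genes %in% planted))
  expect_true(all(unlist(sets$sets) %in% sets$universe))
  # empty background errors
  bad_truth <- g$truth
  bad_truth$gene_id <- character(0)
  expect_error(generate_gene_sets(cfg, bad_truth), "empty")
})

test_that("syn_dataset writes a complete round-trippable bundle", {
  cfg <- syn_config(n_mrna = 40, n_lncrna = 12, n_modules = 2,
                    module_sizes = c(16, 12), n_conserved_pairs = 3,
                    n_samples_treated = 4, n_samples_control = 4,
                    n_groups = 2, seed = 17)
  ds <- syn_dataset(cfg)
  out <- file.path(tempdir(), "synbundle")
  write_syndata(ds, out)
  expect_true(all(file.exists(file.path(out, c(
    "counts_CAR.tsv", "samples_CAR.tsv", "counts_CHL.tsv",
    "transcripts.fa", "transcripts.gtf", "evidence.tsv", "sets.gmt",
    "background_genes.txt", "truth.json")))))
  # counts round-trip
  cts <- read_counts(file.path(out, "counts_CAR.tsv"))
  expect_equal(cts, ds$counts$CAR, ignore_attr = TRUE)
  expect_equal(rownames(cts), rownames(ds$counts$CAR))
  # FASTA and GTF round-trip through the catalog readers
  fa <- read_transcript_fasta(file.path(out, "transcripts.fa"))
  expect_equal(sort(fa$transcript_id), sort(ds$records$transcript_id))
  ann <- read_transcript_gtf(file.path(out, "transcripts.gtf"))
  expect_equal(sort(ann$transcript_id), sort(ds$records$transcript_id))
  i <- match(ann$transcript_id, ds$records$transcript_id)
  expect_equal(ann$exon_count, ds$records$exon_count[i])
  expect_equal(ann$gene_id, ds$records$gene_id[i])
  # biotypes survive where present
  expect_equal(is.na(ann$known_biotype), is.na(ds$records$known_biotype[i]))
  # evidence and gene sets round-trip
  ev <- read_evidence(file.path(out, "evidence.tsv"),
                      transcript_ids = ds$records$transcript_id)
  expect_equal(ev$protein_db_hit, ds$records$protein_db_hit)
  sets <- read_gmt(file.path(out, "sets.gmt"))
  expect_equal(sets, lapply(ds$gene_sets$sets, as.character),
               ignore_attr = TRUE)
  unlink(out, recursive = TRUE)
})
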