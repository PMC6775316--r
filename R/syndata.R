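#' Synthetic-data configuration
#'
#' Describes a multi-group treated-vs-control transcriptome with planted
#' co-expression modules, a trait effect on selected modules, lncRNAs with
#' lower expression and shorter, exon-poorer transcripts than mRNAs, and
#' planted conserved lncRNA-mRNA hub pairs shared by all groups.
#'
#' The generative model is a single latent factor per module: module m has
#' a per-sample factor f_m ~ N(0, 1); treated samples receive
#' `+trait_effect` (in latent-SD units) on trait-associated modules; gene g
#' in module m has mean mu_gs = exp(base_g + lambda_g f_m(s)) and counts are
#' drawn NB(mu, alpha) with Var = mu + alpha mu^2.  Loadings lambda_g are
#' set so the expected log-scale correlation between module genes equals
#' `within_module_cor`; planted hub pairs share an additional pair factor
#' raising their mutual correlation to `pair_cor`.  Control samples form a
#' single block shared by every group (a merged-control design), so module
#' structure and conserved pairs are common to all groups by construction.
#'
#' @param n_samples_treated treated samples per group.
#' @param n_samples_control shared (merged) control samples.
#' @param n_groups number of treatment groups (default 3).
#' @param n_mrna,n_lncrna transcript counts per class.
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of length `n_modules`.
#' @param trait_effect latent-factor shift in treated samples (>= 0; 0
#'   means the trait carries no information).
#' @param within_module_cor target log-scale correlation between module
#'   genes, in \[0, 1).
#' @param nb_dispersion NB dispersion alpha (> 0) in Var = mu + alpha mu^2.
#' @param mean_log_expr_mrna,mean_log_expr_lnc natural-log baseline means
#'   (lncRNA mean must be below the mRNA mean).
#' @param base_log_sd SD of per-gene log baselines.
#' @param n_conserved_pairs planted conserved lncRNA-mRNA hub pairs.
#' @param pair_cor target within-pair correlation of hub pairs.
#' @param hub_module_cor target correlation of hub transcripts with
#'   ordinary members of their module (controls how firmly the hub pairs
#'   are embedded in the module; requires
#'   `pair_cor > hub_module_cor^2 / within_module_cor`).
#' @param trait_modules module ids carrying the trait effect (default 1).
#' @param mrna_orf_aa length (aa) of the ORF planted in mRNA sequences.
#' @param frac_known_mrna,frac_known_lnc fraction of each class carrying an
#'   annotation biotype.
#' @param seed RNG seed (integer below 2^31 - 10).
#' @return validated list of class `syn_config`.
#' @export
syn_config <- function(n_samples_treated = 8, n_samples_control = 8,
                       n_groups = 3, n_mrna = 1200, n_lncrna = 300,
                       n_modules = 5,
                       module_sizes = c(30, 120, 100, 80, 60),
                       trait_effect = 2, within_module_cor = 0.7,
                       nb_dispersion = 0.1, mean_log_expr_mrna = 5,
                       mean_log_expr_lnc = 3.5, base_log_sd = 1,
                       n_conserved_pairs = 10, pair_cor = 0.95,
                       hub_module_cor = 0.75,
                       trait_modules = 1L, mrna_orf_aa = 150,
                       frac_known_mrna = 0.7, frac_known_lnc = 0.4,
                       seed = 1) {
  if (!is.finite(seed) || seed < 0 || seed > .Machine$integer.max - 10) {
    stop("seed must be a non-negative integer below 2^31 - 10")
  }
  cfg <- list(
    n_samples_treated = as.integer(n_samples_treated),
    n_samples_control = as.integer(n_samples_control),
    n_groups = as.integer(n_groups), n_mrna = as.integer(n_mrna),
    n_lncrna = as.integer(n_lncrna), n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    trait_effect = trait_effect, within_module_cor = within_module_cor,
    nb_dispersion = nb_dispersion,
    mean_log_expr_mrna = mean_log_expr_mrna,
    mean_log_expr_lnc = mean_log_expr_lnc, base_log_sd = base_log_sd,
    n_conserved_pairs = as.integer(n_conserved_pairs), pair_cor = pair_cor,
    hub_module_cor = hub_module_cor,
    trait_modules = as.integer(trait_modules),
    mrna_orf_aa = as.integer(mrna_orf_aa),
    frac_known_mrna = frac_known_mrna, frac_known_lnc = frac_known_lnc,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_samples_treated < 2 || n_samples_control < 2 || n_groups < 1 ||
        n_mrna < 1 || n_lncrna < 0) {
      stop("non-positive dimensions in synthetic config")
    }
    if (length(module_sizes) != n_modules) {
      stop("module_sizes must have length n_modules")
    }
    if (sum(module_sizes) > n_mrna + n_lncrna) {
      stop("sum(module_sizes) exceeds the transcript count")
    }
    if (trait_effect < 0) stop("trait_effect must be >= 0")
    if (within_module_cor < 0 || within_module_cor >= 1) {
      stop("within_module_cor must lie in [0, 1)")
    }
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (mean_log_expr_lnc >= mean_log_expr_mrna) {
      stop("lncRNA mean log expression must be below the mRNA mean")
    }
    if (pair_cor <= 0 || pair_cor >= 1) stop("pair_cor must lie in (0, 1)")
    if (hub_module_cor < 0 || hub_module_cor >= 1) {
      stop("hub_module_cor must lie in [0, 1)")
    }
    if (within_module_cor > 0 &&
        pair_cor <= hub_module_cor^2 / within_module_cor) {
      stop("pair_cor too small for the requested hub_module_cor ",
           "(need pair_cor > hub_module_cor^2 / within_module_cor)")
    }
    if (!all(trait_modules %in% seq_len(n_modules))) {
      stop("trait_modules must index planted modules")
    }
    if (seed < 0 || seed > .Machine$integer.max - 10) {
      stop("seed must be a non-negative integer below 2^31 - 10")
    }
  })
  structure(cfg, class = "syn_config")
}

# deterministic (RNG-free) transcript/module layout for a config
syn_layout <- function(config) {
  ids <- c(sprintf("TM%05d", seq_len(config$n_mrna)),
           sprintf("TL%05d", seq_len(config$n_lncrna)))
  class <- rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
  n <- length(ids)
  lnc_frac <- config$n_lncrna / n
  module <- integer(n)
  mrna_pool <- which(class == "mRNA")
  lnc_pool <- which(class == "lncRNA")
  trait_mod <- config$trait_modules[1]
  for (m in seq_len(config$n_modules)) {
    size <- config$module_sizes[m]
    n_lnc <- round(size * lnc_frac)
    if (m == trait_mod) n_lnc <- max(n_lnc, config$n_conserved_pairs)
    n_lnc <- min(n_lnc, length(lnc_pool), size)
    n_mrna <- size - n_lnc
    if (n_mrna > length(mrna_pool)) stop("not enough mRNAs for the modules")
    take_m <- mrna_pool[seq_len(n_mrna)]
    take_l <- lnc_pool[seq_len(n_lnc)]
    mrna_pool <- mrna_pool[-seq_len(n_mrna)]
    if (n_lnc > 0) lnc_pool <- lnc_pool[-seq_len(n_lnc)]
    module[c(take_m, take_l)] <- m
  }
  names(module) <- ids
  names(class) <- ids
  # planted conserved pairs: lncRNA-mRNA hubs inside the trait module
  tm_lnc <- ids[module == trait_mod & class == "lncRNA"]
  tm_mrna <- ids[module == trait_mod & class == "mRNA"]
  npair <- config$n_conserved_pairs
  if (npair > 0 &&
      (length(tm_lnc) < npair || length(tm_mrna) < npair)) {
    stop("trait module too small for the requested conserved pairs")
  }
  pairs <- if (npair > 0) {
    data.frame(a = pmin(tm_lnc[seq_len(npair)], tm_mrna[seq_len(npair)]),
               b = pmax(tm_lnc[seq_len(npair)], tm_mrna[seq_len(npair)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }
  list(ids = ids, class = class, module = module, pairs = pairs,
       gene_id = setNames(sub("^T", "G", ids), ids))
}

group_names <- function(n_groups) {
  base <- c("CAR", "CHL", "THI")
  if (n_groups <= 3) base[seq_len(n_groups)]
  else c(base, sprintf("G%02d", seq.int(4, n_groups)))
}

#' Generate synthetic counts, sample tables and ground truth
#'
#' Draws one shared control block and per-group treated samples from the
#' latent-factor negative-binomial model described in [syn_config()].
#' Deterministic given `config$seed`.
#'
#' @param config a [syn_config()].
#' @return list with `counts` (named list of integer matrices, transcripts
#'   x samples, one per group; control columns identical across groups),
#'   `samples` (named list of sample tables with `sample_id`, `group`,
#'   `trait`), and `truth` (module labels, trait module ids, planted
#'   conserved pairs, per-transcript class, planted gene-set name).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  lay <- syn_layout(config)
  n <- length(lay$ids)
  alpha <- config$nb_dispersion
  set.seed(config$seed)

  base_mean <- ifelse(lay$class == "mRNA", config$mean_log_expr_mrna,
                      config$mean_log_expr_lnc)
  base <- rnorm(n, base_mean, config$base_log_sd)
  tau2 <- 1 / exp(base) + alpha
  cc <- config$within_module_cor
  # the trait shift adds variance delta^2 phi (1 - phi) to every module
  # factor as seen across a group's treated + control samples; loadings are
  # deflated by that factor so within_module_cor / pair_cor describe the
  # correlations actually realized in the data, trait effect included
  phi <- config$n_samples_treated /
    (config$n_samples_treated + config$n_samples_control)
  V <- 1 + config$trait_effect^2 * phi * (1 - phi)
  lambda <- ifelse(lay$module > 0, sqrt(cc / (1 - cc) * tau2 / V), 0)
  # hub pairs: module loading lambda' and pair factor eta jointly chosen so
  # that cor(hub_a, hub_b) = pair_cor while cor(hub, ordinary member) =
  # hub_module_cor (hubs must remain module members for the pairs to appear
  # in the selected module at all)
  pc <- config$pair_cor
  h <- config$hub_module_cor
  eta <- numeric(n)
  hub_rows <- match(c(lay$pairs$a, lay$pairs$b), lay$ids)
  if (length(hub_rows) > 0) {
    tau_h <- sqrt(tau2[hub_rows])
    if (cc > 0) {
      lambda[hub_rows] <- h * tau_h / sqrt(cc * (1 - pc) * V)
      eta[hub_rows] <- tau_h * sqrt((pc - h^2 / cc) / (1 - pc))
    } else {
      lambda[hub_rows] <- 0
      eta[hub_rows] <- tau_h * sqrt(pc / (1 - pc))
    }
  }
  pair_of <- integer(n)
  pair_of[match(lay$pairs$a, lay$ids)] <- seq_len(nrow(lay$pairs))
  pair_of[match(lay$pairs$b, lay$ids)] <- seq_len(nrow(lay$pairs))

  draw_block <- function(n_samp, shift_trait) {
    f <- matrix(rnorm(config$n_modules * n_samp), config$n_modules, n_samp)
    if (shift_trait) {
      f[config$trait_modules, ] <- f[config$trait_modules, , drop = FALSE] +
        config$trait_effect
    }
    p <- if (nrow(lay$pairs) > 0) {
      matrix(rnorm(nrow(lay$pairs) * n_samp), nrow(lay$pairs), n_samp)
    } else {
      matrix(0, 0, n_samp)
    }
    logmu <- matrix(base, n, n_samp)
    inmod <- lay$module > 0
    logmu[inmod, ] <- logmu[inmod, , drop = FALSE] +
      lambda[inmod] * f[lay$module[inmod], , drop = FALSE]
    ishub <- pair_of > 0
    if (any(ishub)) {
      logmu[ishub, ] <- logmu[ishub, , drop = FALSE] +
        eta[ishub] * p[pair_of[ishub], , drop = FALSE]
    }
    matrix(rnbinom(n * n_samp, mu = exp(logmu), size = 1 / alpha), n, n_samp)
  }

  nc <- config$n_samples_control
  ctrl <- draw_block(nc, shift_trait = FALSE)
  colnames(ctrl) <- sprintf("CTRL_%02d", seq_len(nc))
  rownames(ctrl) <- lay$ids

  groups <- group_names(config$n_groups)
  counts <- list()
  samples <- list()
  nt <- config$n_samples_treated
  for (g in groups) {
    tr <- draw_block(nt, shift_trait = TRUE)
    colnames(tr) <- sprintf("%s_T%02d", g, seq_len(nt))
    rownames(tr) <- lay$ids
    counts[[g]] <- cbind(tr, ctrl)
    samples[[g]] <- data.frame(
      sample_id = colnames(counts[[g]]),
      group = rep(c(g, "control"), c(nt, nc)),
      trait = rep(c(1L, 0L), c(nt, nc)),
      stringsAsFactors = FALSE
    )
  }
  truth <- list(
    module = lay$module,
    trait_modules = config$trait_modules,
    conserved_pairs = lay$pairs,
    class = lay$class,
    gene_id = lay$gene_id,
    planted_set = "planted_set"
  )
  list(counts = counts, samples = samples, truth = truth)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.codons_no_stop <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# ATG + (aa - 1) sense codons + TAA  ->  longest ORF >= aa
planted_orf <- function(aa) {
  paste0("ATG",
         paste(sample(.codons_no_stop, aa - 1, replace = TRUE), collapse = ""),
         "TAA")
}

# mutate a sequence until every ATG-initiated ORF is below `max_aa` amino
# acids, by dropping an in-frame stop 50 codons into each offending ORF
ablate_orfs <- function(s, max_aa = 100) {
  for (iter in 1:100) {
    hit <- find_long_orf(s, max_aa)
    if (is.null(hit)) return(s)
    at <- hit$start + 3L * min(50L, hit$aa %/% 2L)
    substr(s, at, at + 2L) <- "TAA"
  }
  stop("failed to ablate long ORFs")
}

# first ORF with peptide >= max_aa: list(start = 1-based nt position of its
# ATG, aa = peptide length), or NULL
find_long_orf <- function(s, max_aa) {
  n <- nchar(s)
  for (off in 0:2) {
    first <- seq.int(1L + off, n - 2L, by = 3L)
    if (length(first) == 0L) next
    codons <- substring(s, first, first + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    nxt <- stops[findInterval(atg, stops) + 1L]
    pep <- ifelse(is.na(nxt), length(codons) - atg + 1L, nxt - atg)
    bad <- which(pep >= max_aa)
    if (length(bad)) {
      i <- bad[1]
      return(list(start = first[atg[i]], aa = pep[i]))
    }
  }
  NULL
}

#' Generate synthetic transcript records
#'
#' Produces one record per transcript of the layout implied by `config`:
#' mRNAs get sequences containing a planted ORF of `mrna_orf_aa` amino
#' acids, log-normal lengths around 1.8 kb and ~8 exons; lncRNAs get
#' shorter (around 0.7 kb, always > 200 nt), exon-poorer (~2) sequences
#' whose longest ORF is kept below 100 amino acids by stop-codon ablation
#' and which carry no coding evidence.  A `frac_known_*` share of each
#' class is annotated with a biotype; unannotated mRNAs carry a
#' protein-database hit for half of them (the rest are caught by the ORF
#' filter).  Deterministic given `config$seed`.
#'
#' @param config a [syn_config()].
#' @return data.frame with `transcript_id`, `gene_id`, `sequence`,
#'   `length_nt`, `exon_count`, `known_biotype`, `protein_db_hit`,
#'   `cpc_coding`, `pfam_hit`, `true_class` (lncRNA/mRNA) and
#'   `expected_class` (the class the catalog cascade should assign).
#' @export
generate_transcript_records <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  lay <- syn_layout(config)
  set.seed(config$seed + 1L)
  n <- length(lay$ids)
  is_m <- lay$class == "mRNA"
  min_mrna_len <- 3L * (config$mrna_orf_aa + 2L) + 60L
  length_nt <- integer(n)
  length_nt[is_m] <- pmax(round(rlnorm(sum(is_m), log(1800), 0.45)),
                          min_mrna_len)
  length_nt[!is_m] <- pmax(round(rlnorm(sum(!is_m), log(700), 0.5)), 250)
  exon_count <- integer(n)
  exon_count[is_m] <- 1L + rpois(sum(is_m), 7)
  exon_count[!is_m] <- 1L + rpois(sum(!is_m), 1)

  known <- logical(n)
  known[is_m] <- runif(sum(is_m)) < config$frac_known_mrna
  known[!is_m] <- runif(sum(!is_m)) < config$frac_known_lnc
  biotype <- rep(NA_character_, n)
  biotype[is_m & known] <- "protein_coding"
  lnc_bts <- c("antisense", "non_coding", "processed_transcript", "lincRNA")
  biotype[!is_m & known] <- sample(lnc_bts, sum(!is_m & known),
                                   replace = TRUE)
  db_hit <- logical(n)
  novel_m <- which(is_m & !known)
  db_hit[novel_m] <- seq_along(novel_m) %% 2L == 1L

  sequence <- character(n)
  for (i in seq_len(n)) {
    len <- length_nt[i]
    if (is_m[i]) {
      orf <- planted_orf(config$mrna_orf_aa)
      pre_len <- sample.int(max(1L, len - nchar(orf) - 1L), 1)
      sequence[i] <- paste0(random_dna(pre_len), orf,
                            random_dna(max(0L, len - pre_len - nchar(orf))))
      length_nt[i] <- nchar(sequence[i])
    } else {
      sequence[i] <- ablate_orfs(random_dna(len), 100)
    }
  }

  expected <- character(n)
  expected[is_m & known] <- "known_mRNA"
  expected[is_m & !known & db_hit] <- "coding_discard"
  expected[is_m & !known & !db_hit] <- "orf_discard"
  expected[!is_m & known] <- "known_lncRNA"
  expected[!is_m & !known] <- "novel_lncRNA"

  data.frame(
    transcript_id = lay$ids,
    gene_id = unname(lay$gene_id),
    sequence = sequence,
    length_nt = length_nt,
    exon_count = exon_count,
    known_biotype = biotype,
    protein_db_hit = db_hit,
    cpc_coding = FALSE,
    pfam_hit = FALSE,
    true_class = unname(lay$class),
    expected_class = expected,
    stringsAsFactors = FALSE
  )
}

#' Generate a gene-set collection with one planted enriched set
#'
#' The planted set is the trait module's "core pathway": it contains the
#' mRNA genes of every planted conserved hub pair, topped up with further
#' trait-module genes until at least `planted_frac` of its members come
#' from the trait module, plus background filler.  It is therefore strongly
#' over-represented in the trait module, and its genes are exactly the
#' common genes the conserved-interaction funnel conditions on.  Decoy sets
#' are uniform draws from the background universe.  Deterministic given
#' `config$seed`.
#'
#' @param config a [syn_config()].
#' @param truth ground truth from [generate_counts()].
#' @param n_decoy number of decoy sets.
#' @param set_size genes per set (default 12: the 10 hub mRNA genes of the
#'   default config plus background filler).
#' @param planted_frac minimum fraction of the planted set drawn from the
#'   trait module.
#' @return list with `sets` (named list; first element `planted_set`) and
#'   `universe` (all gene ids).
#' @export
generate_gene_sets <- function(config, truth, n_decoy = 20, set_size = 12,
                               planted_frac = 0.8) {
  universe <- unique(unname(truth$gene_id))
  if (length(universe) == 0) stop("empty background universe")
  set.seed(config$seed + 2L)
  tm <- config$trait_modules[1]
  tm_genes <- unique(unname(truth$gene_id[names(truth$module)[
    truth$module == tm]]))
  hub_members <- unique(c(truth$conserved_pairs$a, truth$conserved_pairs$b))
  hub_members <- hub_members[truth$class[hub_members] == "mRNA"]
  hub_mrna <- intersect(unique(unname(truth$gene_id[hub_members])), tm_genes)
  n_in <- min(max(ceiling(planted_frac * set_size), length(hub_mrna)),
              length(tm_genes))
  in_module <- hub_mrna
  if (n_in > length(in_module)) {
    in_module <- c(in_module,
                   sample(setdiff(tm_genes, in_module),
                          n_in - length(in_module)))
  }
  set_size <- max(set_size, length(in_module))
  planted <- c(in_module,
               sample(setdiff(universe, tm_genes),
                      set_size - length(in_module)))
  sets <- c(list(planted_set = sort(planted)),
            lapply(seq_len(n_decoy), function(i) sort(sample(universe,
                                                             set_size))))
  names(sets) <- c("planted_set", sprintf("decoy_%02d", seq_len(n_decoy)))
  list(sets = sets, universe = universe)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_counts()],
#' [generate_transcript_records()] and [generate_gene_sets()] with one
#' config.
#'
#' @param config a [syn_config()].
#' @return list with `config`, `counts`, `samples`, `truth`, `records`,
#'   `gene_sets`.
#' @export
syn_dataset <- function(config = syn_config()) {
  gc_ <- generate_counts(config)
  records <- generate_transcript_records(config)
  sets <- generate_gene_sets(config, gc_$truth)
  list(config = config, counts = gc_$counts, samples = gc_$samples,
       truth = gc_$truth, records = records, gene_sets = sets)
}

#' Write a synthetic dataset to disk
#'
#' Emits per-group counts TSVs, a combined sample TSV, transcript FASTA and
#' GTF, a coding-evidence TSV, the gene sets as GMT and the ground truth as
#' JSON.
#'
#' @param dataset result of [syn_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_syndata <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(dataset$counts)) {
    write_matrix_tsv(dataset$counts[[g]],
                     file.path(outdir, paste0("counts_", g, ".tsv")))
    write.table(dataset$samples[[g]],
                file.path(outdir, paste0("samples_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rec <- dataset$records
  write_transcript_fasta(rec, file.path(outdir, "transcripts.fa"))
  write_transcript_gtf(rec, file.path(outdir, "transcripts.gtf"))
  ev <- rec[, c("transcript_id", "protein_db_hit", "cpc_coding", "pfam_hit")]
  for (col in names(ev)[-1]) ev[[col]] <- as.integer(ev[[col]])
  write.table(ev, file.path(outdir, "evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(dataset$gene_sets$sets, file.path(outdir, "sets.gmt"))
  writeLines(dataset$gene_sets$universe,
             file.path(outdir, "background_genes.txt"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(module = as.list(truth$module),
         trait_modules = truth$trait_modules,
         conserved_pairs = truth$conserved_pairs,
         class = as.list(truth$class),
         planted_set = truth$planted_set),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}
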