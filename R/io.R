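#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return data.frame with `transcript_id`, `sequence`, `length_nt`.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  data.frame(transcript_id = ids,
             sequence = as.character(seqs),
             length_nt = Biostrings::width(seqs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write transcript sequences to FASTA
#' @param records data.frame with `transcript_id` and `sequence`.
#' @param path output file.
#' @export
write_transcript_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$transcript_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read transcript annotation from GTF
#'
#' Parses an Ensembl-dialect GTF: one row per transcript with `gene_id`,
#' `transcript_biotype` (NA when absent) and the number of exon features.
#'
#' @param path GTF file.
#' @return data.frame with `transcript_id`, `gene_id`, `known_biotype`,
#'   `exon_count`.
#' @export
read_transcript_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  tid <- as.character(m$transcript_id)
  is_tx <- type == "transcript"
  is_ex <- type == "exon"
  exon_n <- table(tid[is_ex])
  out <- data.frame(
    transcript_id = tid[is_tx],
    gene_id = as.character(m$gene_id[is_tx]),
    known_biotype = if ("transcript_biotype" %in% names(m)) {
      as.character(m$transcript_biotype[is_tx])
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
  out$exon_count <- as.integer(exon_n[out$transcript_id])
  out$exon_count[is.na(out$exon_count)] <- 1L
  out
}

#' Write a transcript annotation GTF
#'
#' Emits one `transcript` feature plus `exon_count` exon features per
#' transcript on a synthetic linear coordinate system (transcripts laid end
#' to end on one sequence).  `transcript_biotype` is written only for
#' annotated records.
#'
#' @param records data.frame with `transcript_id`, `gene_id`, `length_nt`,
#'   `exon_count`, optional `known_biotype`.
#' @param path output GTF file.
#' @export
write_transcript_gtf <- function(records, path) {
  n <- nrow(records)
  starts <- cumsum(c(1, head(records$length_nt + 100L, -1L)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    len <- records$length_nt[i]
    k <- max(1L, records$exon_count[i])
    # split the transcript into k contiguous exon blocks
    bounds <- unique(round(seq(0L, len, length.out = k + 1L)))
    k <- length(bounds) - 1L
    ex_start <- starts[i] + bounds[-length(bounds)]
    ex_end <- starts[i] + bounds[-1L] - 1L
    rows[[i]] <- GenomicRanges::GRanges(
      seqnames = "chrS",
      ranges = IRanges::IRanges(
        start = c(starts[i], ex_start),
        end = c(starts[i] + len - 1L, ex_end)
      ),
      strand = "+",
      type = c("transcript", rep("exon", k)),
      gene_id = records$gene_id[i],
      transcript_id = records$transcript_id[i]
    )
  }
  gr <- do.call(c, rows)
  if ("known_biotype" %in% names(records)) {
    bt <- records$known_biotype[match(S4Vectors::mcols(gr)$transcript_id,
                                      records$transcript_id)]
    S4Vectors::mcols(gr)$transcript_biotype <- bt
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a coding-evidence table
#'
#' TSV with columns `transcript_id`, `protein_db_hit`, `cpc_coding`,
#' `pfam_hit` (0/1).  Transcripts absent from the table get all-FALSE
#' evidence.
#'
#' @param path evidence TSV.
#' @param transcript_ids optional ids to reindex against (missing -> FALSE).
#' @return data.frame of logical evidence flags keyed by `transcript_id`.
#' @export
read_evidence <- function(path, transcript_ids = NULL) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "protein_db_hit", "cpc_coding", "pfam_hit")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("evidence file lacks columns: ",
                         paste(miss, collapse = ", "))
  for (col in need[-1]) ev[[col]] <- as.logical(as.integer(ev[[col]]))
  if (!is.null(transcript_ids)) {
    i <- match(transcript_ids, ev$transcript_id)
    ev <- data.frame(transcript_id = transcript_ids,
                     protein_db_hit = ev$protein_db_hit[i],
                     cpc_coding = ev$cpc_coding[i],
                     pfam_hit = ev$pfam_hit[i],
                     stringsAsFactors = FALSE)
    for (col in need[-1]) ev[[col]][is.na(ev[[col]])] <- FALSE
  }
  ev
}

#' Read a count matrix TSV (transcripts x samples)
#' @param path TSV whose first column is `transcript_id`.
#' @return integer matrix with transcript ids as rownames.
#' @export
read_counts <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("count matrix has negative entries")
  m
}

#' Write a matrix as TSV with an id first column
#' @param m matrix with rownames.
#' @param path output file.
#' @param id_col name of the first column (default `transcript_id`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "transcript_id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table TSV (`sample_id`, `group`, `trait`)
#' @param path TSV file.
#' @return data.frame; `trait` coerced to integer 0/1.
#' @export
read_samples <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "trait")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "))
  s$trait <- as.integer(s$trait)
  if (!all(s$trait %in% c(0L, 1L))) stop("trait must be 0 (control) or 1 (treated)")
  s
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
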