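#' Length of the longest ATG-initiated open reading frame
#'
#' Scans the three forward reading frames (optionally also the reverse
#' complement) for the longest open reading frame that starts at an ATG and
#' runs to the first in-frame stop codon (TAA/TAG/TGA).  The returned length
#' is in amino acids and excludes the stop codon.  An ORF with no in-frame
#' stop still counts and ends at the last complete codon.  `N` bases are
#' allowed but never match a start or stop codon.
#'
#' Assembled transcripts are strand-resolved, so the default scans forward
#' frames only; set `both_strands = TRUE` for a six-frame scan.
#'
#' @param sequence character vector of nucleotide sequences (A/C/G/T/N,
#'   case-insensitive).
#' @param both_strands logical; also scan the reverse complement.
#' @return integer vector of peptide lengths (0 when no ATG-initiated ORF).
#' @export
#' @examples
#' longest_orf_length("ATGAAATAG")  # M K stop -> 2
longest_orf_length <- function(sequence, both_strands = FALSE) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    if (grepl("[^ACGTN]", s)) {
      stop("sequence contains characters other than A/C/G/T/N")
    }
    best <- orf_scan_forward(s)
    if (both_strands) {
      best <- max(best, orf_scan_forward(revcomp(s)))
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

# longest ORF over the 3 forward frames of one uppercase sequence
orf_scan_forward <- function(s) {
  n <- nchar(s)
  if (n < 3L) return(0L)
  best <- 0L
  for (off in 0:2) {
    first <- seq.int(1L + off, n - 2L, by = 3L)
    if (length(first) == 0L) next
    codons <- substring(s, first, first + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    # first stop strictly after each ATG; no stop -> run to last complete codon
    nxt <- stops[findInterval(atg, stops) + 1L]
    pep <- ifelse(is.na(nxt), length(codons) - atg + 1L, nxt - atg)
    best <- max(best, pep)
  }
  as.integer(best)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# biotype strings are compared case-insensitively with '_'/'-'/' ' collapsed
normalize_biotype <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ _-]+", " ", x)
}

.lnc_biotypes <- c("antisense", "non coding", "processed transcript", "lincrna")
.coding_biotypes <- c("protein coding", "mrna")

#' Classify transcripts by the stepwise lncRNA identification cascade
#'
#' Applies, in order: (1) known lncRNA biotype (antisense, non-coding,
#' processed transcript, lincRNA) with length > 200 nt -> `known_lncRNA`;
#' (2) protein-coding biotype -> `known_mRNA`; (3) protein-database hit ->
#' `coding_discard`; (4) length <= 200 nt -> `short_discard`; (5) longest
#' ORF >= 100 amino acids -> `orf_discard`; (6) coding-potential or protein
#' domain flag -> `coding_discard`; (7) otherwise `novel_lncRNA`.
#'
#' Annotation trumps evidence: a transcript with a known lncRNA biotype is
#' kept as `known_lncRNA` even if a coding-evidence flag is set.  Absent
#' fields are treated as negative evidence.
#'
#' @param length_nt integer vector of transcript lengths (nt).
#' @param known_biotype character vector (NA when unannotated).
#' @param protein_db_hit,cpc_coding,pfam_hit logical vectors of coding
#'   evidence (stand-ins for BLASTx / CPC / Pfam results).
#' @param orf_aa integer vector of longest-ORF lengths in amino acids; if
#'   `NULL`, computed from `sequence`.
#' @param sequence character vector of sequences (used when `orf_aa` is NULL).
#' @return factor of assigned classes with levels
#'   `known_lncRNA, known_mRNA, coding_discard, short_discard, orf_discard,
#'   novel_lncRNA`.
#' @export
classify_transcript <- function(length_nt, known_biotype = NA,
                                protein_db_hit = FALSE, cpc_coding = FALSE,
                                pfam_hit = FALSE, orf_aa = NULL,
                                sequence = NULL) {
  n <- length(length_nt)
  known_biotype <- rep_len(as.character(known_biotype), n)
  protein_db_hit <- rep_len(isTRUE_vec(protein_db_hit), n)
  cpc_coding <- rep_len(isTRUE_vec(cpc_coding), n)
  pfam_hit <- rep_len(isTRUE_vec(pfam_hit), n)
  if (is.null(orf_aa)) {
    if (is.null(sequence)) stop("provide either orf_aa or sequence")
    orf_aa <- longest_orf_length(sequence)
  }
  orf_aa <- rep_len(as.integer(orf_aa), n)

  bt <- normalize_biotype(known_biotype)
  cls <- rep(NA_character_, n)
  is_lnc_bt <- !is.na(bt) & bt %in% .lnc_biotypes & length_nt > 200
  cls[is_lnc_bt] <- "known_lncRNA"
  todo <- is.na(cls)
  is_cod_bt <- todo & !is.na(bt) & bt %in% .coding_biotypes
  cls[is_cod_bt] <- "known_mRNA"
  todo <- is.na(cls)
  cls[todo & protein_db_hit] <- "coding_discard"
  todo <- is.na(cls)
  cls[todo & length_nt <= 200] <- "short_discard"
  todo <- is.na(cls)
  cls[todo & orf_aa >= 100] <- "orf_discard"
  todo <- is.na(cls)
  cls[todo & (cpc_coding | pfam_hit)] <- "coding_discard"
  cls[is.na(cls)] <- "novel_lncRNA"
  factor(cls, levels = catalog_classes())
}

isTRUE_vec <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  x
}

#' Catalog class levels
#' @return character vector of the six assigned classes, in cascade order.
#' @export
catalog_classes <- function() {
  c("known_lncRNA", "known_mRNA", "coding_discard", "short_discard",
    "orf_discard", "novel_lncRNA")
}

#' Build the transcript catalog
#'
#' Joins transcript sequences, annotation and coding evidence, runs the
#' classification cascade on every transcript and returns the per-transcript
#' class map plus per-class counts.  The lncRNA set is the union of
#' `known_lncRNA` and `novel_lncRNA`; `known_mRNA` plus the coding discards
#' form the mRNA side.
#'
#' @param records data.frame with columns `transcript_id`, `gene_id`,
#'   `sequence` (or `length_nt` and `orf_aa`), optional `exon_count`,
#'   `known_biotype`, `protein_db_hit`, `cpc_coding`, `pfam_hit`.
#' @param both_strands passed to [longest_orf_length()].
#' @return object of class `lnc_catalog`: list with `table` (one row per
#'   transcript: ids, class, length, exon count, ORF length, simple
#'   lncRNA/mRNA `rna_type`) and `counts` (named integer vector per class).
#' @export
build_catalog <- function(records, both_strands = FALSE) {
  stopifnot(is.data.frame(records), "transcript_id" %in% names(records))
  if (anyDuplicated(records$transcript_id)) {
    stop("duplicate transcript_id in records: ",
         paste(unique(records$transcript_id[duplicated(records$transcript_id)]),
               collapse = ", "))
  }
  n <- nrow(records)
  get <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  sequence <- get("sequence", NA_character_)
  length_nt <- get("length_nt", NA_integer_)
  if (all(is.na(length_nt))) length_nt <- nchar(sequence)
  orf_aa <- if ("orf_aa" %in% names(records)) {
    records$orf_aa
  } else if (!all(is.na(sequence))) {
    longest_orf_length(sequence, both_strands = both_strands)
  } else {
    stop("records must carry either sequences or precomputed orf_aa")
  }
  cls <- classify_transcript(
    length_nt = length_nt,
    known_biotype = get("known_biotype", NA_character_),
    protein_db_hit = get("protein_db_hit", FALSE),
    cpc_coding = get("cpc_coding", FALSE),
    pfam_hit = get("pfam_hit", FALSE),
    orf_aa = orf_aa
  )
  tab <- data.frame(
    transcript_id = records$transcript_id,
    gene_id = as.character(get("gene_id", NA_character_)),
    class = as.character(cls),
    length_nt = as.integer(length_nt),
    exon_count = as.integer(get("exon_count", NA_integer_)),
    longest_orf_aa = as.integer(orf_aa),
    stringsAsFactors = FALSE
  )
  tab$rna_type <- ifelse(tab$class %in% c("known_lncRNA", "novel_lncRNA"),
                         "lncRNA", "mRNA")
  counts <- table(factor(tab$class, levels = catalog_classes()))
  structure(list(table = tab, counts = c(unclass(counts))),
            class = "lnc_catalog")
}

#' @export
print.lnc_catalog <- function(x, ...) {
  cat("Transcript catalog:", nrow(x$table), "transcripts\n")
  for (cl in names(x$counts)) {
    cat(sprintf("  %-15s %6d\n", cl, x$counts[[cl]]))
  }
  n_lnc <- sum(x$counts[c("known_lncRNA", "novel_lncRNA")])
  cat("  lncRNA set (known + novel):", n_lnc, "\n")
  invisible(x)
}
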