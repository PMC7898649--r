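#' Classify transcripts into annotation/novelty classes
#'
#' Transcripts fall into four classes: `annotated` (maps to a reference gene
#' annotation); `unannotated_not_novel` (unannotated, but with significant
#' homology outside the genus Bombus); `novel_noncoding` and `novel_coding`
#' (unannotated, taxonomically restricted — homology hits at
#' E <= `evalue_threshold` are confined to Bombus in both nucleotide and
#' protein searches). Features with no hits at all satisfy the
#' no-other-genus condition and are classed novel ("no-hit novel",
#' reported via `n_hits = 0` for transparency).
#'
#' @param features Data frame with columns `feature_id`, `gff_annotated`
#'   (logical) and `coding` (logical; see [coding_status()]).
#' @param hits Homology hit table (BLAST outfmt-6 style) with at least
#'   columns `qseqid`, `sseqid`, `evalue`, `subject_genus`; optionally
#'   `search_type` (`"nucl"`/`"prot"`). May be empty.
#' @param evalue_threshold Significance threshold for homology (default
#'   1e-5).
#' @param own_genus Genus whose hits do not count as outside homology
#'   (default `"Bombus"`).
#' @return Data frame: `feature_id`, `annotation_class`, `is_novel`,
#'   `coding`, `best_evalue_own`, `best_evalue_other`, `n_hits`.
#' @export
classify_features <- function(features, hits,
                              evalue_threshold = 1e-5,
                              own_genus = "Bombus") {
  stopifnot(all(c("feature_id", "gff_annotated", "coding") %in% names(features)))
  hits <- as.data.frame(hits)
  if (nrow(hits)) {
    req <- c("qseqid", "evalue", "subject_genus")
    missing <- setdiff(req, names(hits))
    if (length(missing)) stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
    ev <- suppressWarnings(as.numeric(hits$evalue))
    if (anyNA(ev)) stop("malformed E-value in hit table")
    if (any(ev < 0)) stop("negative E-value in hit table")
    hits$evalue <- ev
  }
  n <- nrow(features)
  best_own <- rep(NA_real_, n)
  best_other <- rep(NA_real_, n)
  n_hits <- rep(0L, n)
  if (nrow(hits)) {
    own <- hits$subject_genus == own_genus
    idx <- match(hits$qseqid, features$feature_id)
    for (grp in list(list(sel = own, store = "own"),
                     list(sel = !own, store = "other"))) {
      h <- hits[grp$sel, , drop = FALSE]
      i <- idx[grp$sel]
      if (!nrow(h)) next
      mins <- tapply(h$evalue, factor(i, levels = seq_len(n)), min)
      if (grp$store == "own") best_own <- as.numeric(mins) else best_other <- as.numeric(mins)
    }
    n_hits <- as.integer(table(factor(idx, levels = seq_len(n))))
  }
  has_other <- !is.na(best_other) & best_other <= evalue_threshold
  cls <- ifelse(features$gff_annotated, "annotated",
         ifelse(has_other, "unannotated_not_novel",
         ifelse(features$coding, "novel_coding", "novel_noncoding")))
  data.frame(feature_id = features$feature_id,
             annotation_class = cls,
             is_novel = cls %in% c("novel_coding", "novel_noncoding"),
             coding = features$coding,
             best_evalue_own = best_own,
             best_evalue_other = best_other,
             n_hits = n_hits,
             stringsAsFactors = FALSE)
}

#' ORF-based coding status of a nucleotide sequence
#'
#' A sequence is called protein-coding when its longest open reading frame
#' (ATG through a stop codon, scanning all three frames on both strands)
#' spans at least `min_codons` codons (stop codon excluded). This is a
#' simple, configurable coding heuristic in the spirit of standard lncRNA
#' screens; ambiguous bases (N) are treated as neither start nor stop.
#'
#' @param sequence Nucleotide string over the alphabet ACGTN
#'   (case-insensitive).
#' @param min_codons Minimum ORF length in codons (default 100).
#' @return `TRUE` if coding.
#' @examples
#' coding_status(paste0("ATG", strrep("GCT", 150), "TAA"))  # TRUE
#' coding_status("ACGTACGTACGT")                            # FALSE
#' @export
coding_status <- function(sequence, min_codons = 100) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) stop("invalid character in sequence (alphabet ACGTN)")
  longest_orf(s, min_codons) || longest_orf(revcomp(s), min_codons)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# TRUE when any frame of `s` holds an ATG..stop ORF of >= min_codons codons.
longest_orf <- function(s, min_codons) {
  n <- nchar(s)
  for (frame in 0:2) {
    len <- ((n - frame) %/% 3) * 3
    if (len < 3) next
    codons <- substring(s, frame + seq(1, len, 3), frame + seq(3, len + 2, 3))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (st in starts) {
      nxt <- stops[stops > st]
      if (!length(nxt)) next
      if (nxt[1] - st >= min_codons) return(TRUE)
    }
  }
  FALSE
}

#' Test enrichment of novel genes between caste pathways
#'
#' Within each developmental stage, compares the representation of novel
#' (taxonomically restricted) genes among the queen-up and worker-up HDEGs
#' with a two-sided Fisher's exact test. The default table layout
#' (`"novel_vs_total"`) compares novel counts against the total
#' upregulated-HDEG counts of each pathway; `"novel_vs_rest"` uses the
#' strict novel / non-novel 2x2 partition. A stage where either pathway has
#' no HDEGs is reported untestable.
#'
#' @param calls DE calls with `is_hdeg` filled ([call_hdegs()]).
#' @param annotations Output of [classify_features()].
#' @param layout `"novel_vs_total"` (default) or `"novel_vs_rest"`.
#' @return Data frame per stage: novel and total HDEG counts per caste,
#'   `p` (two-sided Fisher), `testable`.
#' @export
novelty_enrichment <- function(calls, annotations,
                               layout = c("novel_vs_total", "novel_vs_rest")) {
  layout <- match.arg(layout)
  novel <- stats::setNames(annotations$is_novel, annotations$feature_id)
  stages <- unique(calls$stage)
  out <- data.frame(stage = stages, n_novel_w = NA_integer_, n_w = NA_integer_,
                    n_novel_q = NA_integer_, n_q = NA_integer_,
                    p = NA_real_, testable = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    hd <- calls[calls$stage == stages[i] & calls$is_hdeg %in% TRUE, , drop = FALSE]
    wf <- hd$feature_id[hd$direction == "W"]
    qf <- hd$feature_id[hd$direction == "Q"]
    out$n_w[i] <- length(wf); out$n_q[i] <- length(qf)
    out$n_novel_w[i] <- sum(novel[wf], na.rm = TRUE)
    out$n_novel_q[i] <- sum(novel[qf], na.rm = TRUE)
    if (!length(wf) || !length(qf)) next
    out$testable[i] <- TRUE
    out$p[i] <- novelty_fisher(out$n_novel_w[i], out$n_w[i],
                               out$n_novel_q[i], out$n_q[i], layout)
  }
  out
}

#' Fisher test on novel-gene representation from printed counts
#'
#' @param novel_w,n_w Novel and total upregulated HDEG counts, worker
#'   pathway.
#' @param novel_q,n_q Same for the queen pathway.
#' @param layout See [novelty_enrichment()].
#' @return Two-sided Fisher exact p-value.
#' @examples
#' novelty_fisher(7, 14, 5, 40)   # late-instar comparison
#' novelty_fisher(14, 92, 7, 54)  # mid-instar comparison
#' @export
novelty_fisher <- function(novel_w, n_w, novel_q, n_q,
                           layout = c("novel_vs_total", "novel_vs_rest")) {
  layout <- match.arg(layout)
  tab <- if (layout == "novel_vs_total") {
    matrix(c(novel_w, n_w, novel_q, n_q), 2, byrow = TRUE)
  } else {
    matrix(c(novel_w, n_w - novel_w, novel_q, n_q - novel_q), 2, byrow = TRUE)
  }
  stats::fisher.test(tab)$p.value
}
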