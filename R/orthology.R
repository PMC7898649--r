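#' Reciprocal-best-hit (RBH) orthologue map
#'
#' From two directional hit tables (A vs B and B vs A), pairs (a, b) such
#' that b is a's best hit and a is b's best hit. Best = lowest E-value, ties
#' broken by highest bitscore, then lexicographically smallest subject id,
#' giving a deterministic one-to-one map.
#'
#' @param hits_ab,hits_ba BLAST outfmt-6-style data frames with columns
#'   `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @param max_evalue Optional E-value ceiling applied to both tables before
#'   pairing (default `NULL`, off).
#' @return Data frame `id_a`, `id_b`, one row per orthologue pair, sorted by
#'   `id_a`.
#' @export
rbh <- function(hits_ab, hits_ba, max_evalue = NULL) {
  best_ab <- best_hits(hits_ab, max_evalue)
  best_ba <- best_hits(hits_ba, max_evalue)
  if (!nrow(best_ab) || !nrow(best_ba)) {
    return(data.frame(id_a = character(), id_b = character()))
  }
  back <- stats::setNames(best_ba$sseqid, best_ba$qseqid)
  mutual <- !is.na(back[best_ab$sseqid]) & back[best_ab$sseqid] == best_ab$qseqid
  out <- data.frame(id_a = best_ab$qseqid[mutual],
                    id_b = best_ab$sseqid[mutual],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best hit per query under the evalue -> bitscore -> subject-id tie-break.
# Duplicate (query, subject) rows are collapsed to the best-scoring row with
# a warning.
best_hits <- function(hits, max_evalue = NULL) {
  hits <- as.data.frame(hits)
  req <- c("qseqid", "sseqid", "evalue", "bitscore")
  missing <- setdiff(req, names(hits))
  if (length(missing)) stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.null(max_evalue)) hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  dup <- duplicated(hits[, c("qseqid", "sseqid")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (query, subject) row(s) collapsed to best score")
    hits <- hits[!dup, , drop = FALSE]
  }
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Project DE calls into orthologue space (DEOs/HDEOs)
#'
#' Restricts per-phenotype DEG and HDEG lists to features with a
#' reciprocal-best-hit orthologue in the comparison species, optionally
#' translating ids into the partner namespace.
#'
#' @param calls DE calls ([call_degs()] / [call_hdegs()]).
#' @param map Orthologue map from [rbh()].
#' @param translate If `TRUE`, returned ids are the partner species' ids.
#' @return `calls` filtered to mapped features, with an `orthologue` column;
#'   if `translate`, `feature_id` is replaced by the orthologue id.
#' @export
project_lists <- function(calls, map, translate = FALSE) {
  partner <- stats::setNames(map$id_b, map$id_a)
  keep <- calls$feature_id %in% map$id_a
  out <- calls[keep, , drop = FALSE]
  out$orthologue <- unname(partner[out$feature_id])
  if (translate) {
    out$feature_id <- out$orthologue
  }
  rownames(out) <- NULL
  out
}
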