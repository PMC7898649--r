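#' Offset fold change (OFC)
#'
#' Conservative log2 effect-size bound between an up-regulated and a
#' down-regulated group: the minimum normalized count of the up-group over
#' the maximum of the down-group, each offset by a base level (default 20)
#' so that the ranking of OFCs is not dominated by low-abundance features.
#'
#' @param min_k Minimum normalized count across replicates of the
#'   up-regulated group.
#' @param max_kprime Maximum normalized count across replicates of the
#'   down-regulated group.
#' @param offset Base-level offset (default 20).
#' @return `log2((min_k + offset) / (max_kprime + offset))`. Vectorised.
#' @examples
#' ofc(236, 108)   # log2(256/128) = 1
#' ofc(5, 5)       # 0
#' @export
ofc <- function(min_k, max_kprime, offset = 20) {
  if (any(min_k < 0) || any(max_kprime < 0)) stop("counts must be non-negative")
  log2((min_k + offset) / (max_kprime + offset))
}

#' Replicate min-max intervals per feature and phenotype
#'
#' For every feature and phenotype group the interval spanned by the minimum
#' and maximum normalized count across that phenotype's biological
#' replicates. These "maximal confidence intervals" drive the DEG call:
#' castes whose intervals are disjoint within a stage are called
#' differentially expressed.
#'
#' @param x A normalized [caste_counts] object with >= 2 replicates per
#'   phenotype.
#' @return Data frame with columns `feature_id`, `stage`, `caste`,
#'   `min_count`, `max_count`, `n_replicates`.
#' @export
group_intervals <- function(x) {
  stopifnot(inherits(x, "caste_counts"))
  ph <- paste(x$samples$stage, x$samples$caste, sep = ".")
  out <- vector("list", length(unique(ph)))
  names(out) <- unique(ph)
  for (p in unique(ph)) {
    cols <- which(ph == p)
    if (length(cols) < 2) {
      stop("phenotype ", p, " has a single replicate; interval undefined")
    }
    sub <- x$counts[, cols, drop = FALSE]
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    out[[p]] <- data.frame(feature_id = rownames(x$counts),
                           stage = parts[1], caste = parts[2],
                           min_count = row_min(sub), max_count = row_max(sub),
                           n_replicates = length(cols),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call differentially expressed genes by interval disjointness
#'
#' A feature is a DEG between caste pathways within a stage when the
#' replicate min-max intervals of the two castes do not overlap; touching
#' endpoints count as overlap (not DEG). The OFC is computed with the
#' up-regulated caste's interval minimum over the down-regulated caste's
#' interval maximum, so a DEG always has OFC > 0.
#'
#' @param intervals Output of [group_intervals()].
#' @param stages Stages to call (default: all present); both castes must be
#'   present at each.
#' @param offset OFC base-level offset (default 20).
#' @return Data frame of DE calls: `feature_id`, `stage`, `direction`
#'   (`"Q"`, `"W"` or `"none"`), `is_deg`, `ofc`, `is_hdeg` (`NA` until
#'   [call_hdegs()]), plus the four interval bounds. The `ofc` of a non-DEG
#'   is the (non-positive) bound computed towards the caste with the higher
#'   interval.
#' @export
call_degs <- function(intervals, stages = NULL, offset = 20) {
  stages <- stages %||% unique(intervals$stage)
  res <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    st <- stages[i]
    q <- intervals[intervals$stage == st & intervals$caste == "Q", , drop = FALSE]
    w <- intervals[intervals$stage == st & intervals$caste == "W", , drop = FALSE]
    if (!nrow(q) || !nrow(w)) stop("stage ", st, " lacks one caste")
    w <- w[match(q$feature_id, w$feature_id), , drop = FALSE]
    if (anyNA(w$feature_id)) stop("feature sets differ between castes at stage ", st)
    # Up-group = caste with the higher interval (max, then min as tiebreak).
    up_q <- q$max_count > w$max_count |
      (q$max_count == w$max_count & q$min_count > w$min_count)
    tie <- q$max_count == w$max_count & q$min_count == w$min_count
    min_up <- ifelse(up_q, q$min_count, w$min_count)
    max_dn <- ifelse(up_q, w$max_count, q$max_count)
    o <- ofc(min_up, max_dn, offset)
    is_deg <- o > 0 & !tie
    res[[i]] <- data.frame(
      feature_id = q$feature_id, stage = st,
      direction = ifelse(is_deg, ifelse(up_q, "Q", "W"), "none"),
      is_deg = is_deg, ofc = o, is_hdeg = NA,
      min_q = q$min_count, max_q = q$max_count,
      min_w = w$min_count, max_w = w$max_count,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "offset") <- offset
  out
}

#' Call highly differentially expressed genes (HDEGs)
#'
#' HDEGs are DEGs with OFC > 1 (strictly), after accounting for multiple
#' unannotated exon features that make up one longer multi-exon transcript:
#' unannotated candidate features belonging to the same transcript unit are
#' merged — their normalized counts are summed, the interval and OFC are
#' recomputed on the sums — and the unit counts as a single HDEG, carried by
#' a representative member. Annotated features pass through unmerged.
#'
#' @param calls Output of [call_degs()].
#' @param x The normalized [caste_counts] the calls were derived from
#'   (needed to recompute merged-unit counts). May be `NULL` when `units`
#'   is `NULL`.
#' @param annotated Logical vector named by feature id (or data frame with
#'   columns `feature_id`, `annotated`); `NULL` treats all unit members as
#'   unannotated (units are normally built over unannotated features only).
#' @param units Transcript-unit table with columns `unit_id`, `feature_id`
#'   (see [build_transcript_units()]), or `NULL` for no merging.
#' @param offset OFC offset (default 20).
#' @return `calls` with `is_hdeg` filled and columns `unit_id` and
#'   `unit_ofc` added; merged units contribute exactly one `is_hdeg = TRUE`
#'   row (the member with the highest individual OFC).
#' @export
call_hdegs <- function(calls, x = NULL, annotated = NULL, units = NULL,
                       offset = NULL) {
  offset <- offset %||% attr(calls, "offset") %||% 20
  calls$is_hdeg <- calls$is_deg & calls$ofc > 1
  calls$unit_id <- NA_character_
  calls$unit_ofc <- NA_real_
  if (is.null(units) || !nrow(units)) return(calls)
  stopifnot(inherits(x, "caste_counts"))
  if (is.data.frame(annotated)) {
    annotated <- stats::setNames(annotated$annotated, annotated$feature_id)
  }
  unknown <- setdiff(units$feature_id, rownames(x$counts))
  if (length(unknown)) {
    stop("transcript unit references unknown feature id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  is_unann <- if (is.null(annotated)) {
    stats::setNames(rep(TRUE, nrow(x$counts)), rownames(x$counts))
  } else !annotated
  ph <- paste(x$samples$stage, x$samples$caste, sep = ".")
  for (u in unique(units$unit_id)) {
    members <- units$feature_id[units$unit_id == u]
    members <- members[is_unann[members]]
    for (st in unique(calls$stage)) {
      rows <- which(calls$stage == st & calls$feature_id %in% members &
                      calls$is_hdeg)
      if (length(rows) < 2) next
      # merge: recompute interval + OFC on summed member counts
      summed <- colSums(x$counts[calls$feature_id[rows], , drop = FALSE])
      iv <- lapply(c("Q", "W"), function(cs) {
        v <- summed[ph == paste(st, cs, sep = ".")]
        c(min = min(v), max = max(v))
      })
      names(iv) <- c("Q", "W")
      up <- if (iv$Q["max"] > iv$W["max"]) "Q" else "W"
      dn <- setdiff(c("Q", "W"), up)
      u_ofc <- ofc(iv[[up]]["min"], iv[[dn]]["max"], offset)
      calls$unit_id[rows] <- u
      calls$unit_ofc[rows] <- u_ofc
      rep_row <- rows[which.max(calls$ofc[rows])]
      calls$is_hdeg[rows] <- FALSE
      calls$is_hdeg[rep_row] <- u_ofc > 1
    }
  }
  calls
}

#' Group unannotated exon features into transcript units
#'
#' Default merging rule when no unit file is supplied: unannotated features
#' on the same strand of the same sequence, separated by at most `max_gap`
#' bases, whose normalized expression profiles correlate at Pearson r >=
#' `min_cor`, are chained into one unit. The rule is configurable and the
#' resulting units are recorded in the output of [call_hdegs()].
#'
#' @param features Data frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `annotated`.
#' @param x Normalized [caste_counts] supplying expression profiles.
#' @param max_gap Maximum genomic gap between consecutive members (default
#'   1000 bases).
#' @param min_cor Minimum expression-profile correlation (default 0.9).
#' @return Data frame `unit_id`, `feature_id`, covering only features placed
#'   in units of size >= 2.
#' @export
build_transcript_units <- function(features, x, max_gap = 1000, min_cor = 0.9) {
  stopifnot(inherits(x, "caste_counts"))
  f <- features[!features$annotated, , drop = FALSE]
  f <- f[order(f$chrom, f$strand, f$start), , drop = FALSE]
  if (!nrow(f)) return(data.frame(unit_id = character(), feature_id = character()))
  unit <- integer(nrow(f))
  current <- 1L
  unit[1] <- current
  for (i in seq_len(nrow(f))[-1]) {
    same_block <- f$chrom[i] == f$chrom[i - 1] && f$strand[i] == f$strand[i - 1]
    gap_ok <- same_block && (f$start[i] - f$end[i - 1]) <= max_gap
    cor_ok <- FALSE
    if (gap_ok) {
      a <- x$counts[f$feature_id[i], ]
      b <- x$counts[f$feature_id[i - 1], ]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) {
        cor_ok <- stats::cor(a, b) >= min_cor
      }
    }
    if (!gap_ok || !cor_ok) current <- current + 1L
    unit[i] <- current
  }
  keep <- unit %in% unit[duplicated(unit)]
  if (!any(keep)) return(data.frame(unit_id = character(), feature_id = character()))
  data.frame(unit_id = sprintf("TU%04d", unit[keep]),
             feature_id = f$feature_id[keep], stringsAsFactors = FALSE)
}

#' Select genes of interest across stages
#'
#' Applies five overlapping criteria to the full set of DE calls:
#' (a) top OFC among each phenotype's up-regulated DEGs (ties all flagged);
#' (b) HDEG in at least one stage; (c) HDEG in at least two stages;
#' (d) member of a gene family containing another HDEG; (e) member of a
#' user-supplied literature list. A feature is selected when it satisfies
#' (a) and/or at least two of (b)-(e).
#'
#' @param calls DE calls for all three stages with `is_hdeg` filled
#'   ([call_hdegs()]).
#' @param families Optional data frame `feature_id`, `family`; when absent,
#'   criterion (d) is always `FALSE`.
#' @param literature Character vector of feature ids linked to caste by
#'   published studies (criterion (e)).
#' @return Data frame, one row per feature, with logical columns
#'   `crit_a` .. `crit_e` and `selected`.
#' @export
genes_of_interest <- function(calls, families = NULL, literature = character()) {
  stopifnot(all(c("is_deg", "is_hdeg", "ofc", "direction") %in% names(calls)))
  feats <- unique(calls$feature_id)
  crit_a <- stats::setNames(rep(FALSE, length(feats)), feats)
  degs <- calls[calls$is_deg, , drop = FALSE]
  if (nrow(degs)) {
    for (key in unique(paste(degs$stage, degs$direction))) {
      sub <- degs[paste(degs$stage, degs$direction) == key, , drop = FALSE]
      top <- sub$feature_id[sub$ofc == max(sub$ofc)]
      crit_a[top] <- TRUE
    }
  }
  hd_stages <- tapply(calls$is_hdeg, calls$feature_id,
                      function(v) sum(v, na.rm = TRUE))[feats]
  crit_b <- hd_stages >= 1
  crit_c <- hd_stages >= 2
  crit_d <- stats::setNames(rep(FALSE, length(feats)), feats)
  if (!is.null(families) && nrow(families)) {
    hdeg_feats <- unique(calls$feature_id[calls$is_hdeg %in% TRUE])
    fam_hdegs <- tapply(families$feature_id %in% hdeg_feats, families$family, sum)
    fam_of <- stats::setNames(families$family, families$feature_id)
    in_fam <- feats %in% families$feature_id
    n_other <- ifelse(in_fam,
                      fam_hdegs[fam_of[feats]] - (feats %in% hdeg_feats), 0)
    crit_d[] <- n_other >= 1
  }
  crit_e <- stats::setNames(feats %in% literature, feats)
  n_bcde <- crit_b + crit_c + crit_d + crit_e
  data.frame(feature_id = feats,
             crit_a = unname(crit_a), crit_b = unname(crit_b),
             crit_c = unname(crit_c), crit_d = unname(crit_d),
             crit_e = unname(crit_e),
             selected = unname(crit_a | n_bcde >= 2),
             stringsAsFactors = FALSE)
}
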