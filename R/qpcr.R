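#' Inter-plate calibration of Cq values
#'
#' Removes between-plate offsets using the inter-plate calibrator (IPC)
#' wells: each plate's deviation of its mean IPC Cq from the grand mean of
#' IPC Cqs across plates is subtracted from every well on that plate.
#' Within-plate Cq differences are preserved exactly.
#'
#' @param plates Long-format data frame with columns `plate_id`, `well`,
#'   `gene_id`, `sample_id`, `Cq`, `is_IPC`.
#' @return The same data frame with `Cq` calibrated (IPC wells included).
#' @export
calibrate_plates <- function(plates) {
  req <- c("plate_id", "gene_id", "sample_id", "Cq", "is_IPC")
  missing <- setdiff(req, names(plates))
  if (length(missing)) stop("plate table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(plates$Cq <= 0)) stop("Cq values must be positive")
  ids <- unique(plates$plate_id)
  if (length(ids) == 1L) return(plates)
  ipc <- plates[plates$is_IPC, , drop = FALSE]
  no_ipc <- setdiff(ids, unique(ipc$plate_id))
  if (length(no_ipc)) stop("plate(s) missing an IPC well: ", paste(no_ipc, collapse = ", "))
  plate_ipc <- tapply(ipc$Cq, ipc$plate_id, mean)
  shift <- plate_ipc - mean(plate_ipc)
  plates$Cq <- as.numeric(plates$Cq - shift[as.character(plates$plate_id)])
  plates
}

# Genes x samples matrix of calibrated Cq means (technical replicates
# averaged); IPC wells excluded. Errors on genes absent everywhere.
cq_matrix <- function(plates, genes = NULL) {
  d <- plates[!plates$is_IPC, , drop = FALSE]
  if (!is.null(genes)) {
    absent <- setdiff(genes, unique(d$gene_id))
    if (length(absent)) stop("gene(s) absent from plates: ", paste(absent, collapse = ", "))
    d <- d[d$gene_id %in% genes, , drop = FALSE]
  }
  tapply(d$Cq, list(d$gene_id, d$sample_id), mean)
}

#' Reference-gene stability (geNorm M, pairwise variation, BestKeeper SD)
#'
#' geNorm stability M of a candidate is the mean, over all other candidates,
#' of the standard deviation across samples of their pairwise log2
#' expression ratios; stable references have low M. Candidates are ranked by
#' iteratively excluding the highest-M gene. The pairwise variations
#' V(n/n+1) between normalization factors built from the best n and n+1
#' genes determine how many references are needed: the smallest n with
#' V(n/n+1) below `v_threshold` (floor 2). BestKeeper-style SD is the
#' per-gene standard deviation of calibrated Cq.
#'
#' @param plates Calibrated plate table ([calibrate_plates()]).
#' @param candidates Character vector of >= 3 candidate reference gene ids.
#' @param efficiencies Named numeric vector or data frame (`gene_id`, `E`)
#'   of amplification efficiencies (fold per cycle); missing genes default
#'   to 2.
#' @param v_threshold Pairwise-variation cutoff (default 0.15, the geNorm
#'   convention).
#' @return List of class `stability_report`: `M` (named, full-panel M
#'   values), `ranking` (most stable first; the final two genes share rank
#'   1-2), `pairwise_variation` (named `V2/3`, ...), `bestkeeper_sd`,
#'   `n_recommended`, `recommended_references`.
#' @export
genorm_stability <- function(plates, candidates, efficiencies = NULL,
                             v_threshold = 0.15) {
  if (length(candidates) < 3) stop("need >= 3 candidate reference genes")
  cq <- cq_matrix(plates, candidates)
  if (anyNA(cq)) stop("candidate reference genes must be measured in all samples")
  if (ncol(cq) < 2) stop("need >= 2 samples")
  eff <- efficiency_vector(efficiencies, rownames(cq))
  # log2 relative quantity; a gene's constant term cancels in ratios
  logq <- -cq * log2(eff[rownames(cq)])

  m_values <- function(lq) {
    g <- nrow(lq)
    vapply(seq_len(g), function(j) {
      mean(vapply(setdiff(seq_len(g), j),
                  function(k) stats::sd(lq[j, ] - lq[k, ]), numeric(1)))
    }, numeric(1))
  }

  M_full <- stats::setNames(m_values(logq), rownames(logq))
  # stepwise exclusion ranking
  remaining <- rownames(logq)
  excluded <- character(0)
  while (length(remaining) > 2) {
    M <- stats::setNames(m_values(logq[remaining, , drop = FALSE]), remaining)
    worst <- names(which.max(M))
    excluded <- c(worst, excluded)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(sort(remaining), excluded)  # final two tie at rank 1-2

  # pairwise variation V(n/n+1) from gene-centred normalization factors
  centred <- logq - rowMeans(logq)
  V <- numeric(0)
  if (length(ranking) >= 3) {
    nf <- function(n) colMeans(centred[ranking[seq_len(n)], , drop = FALSE])
    V <- vapply(2:(length(ranking) - 1),
                function(n) stats::sd(nf(n) - nf(n + 1)), numeric(1))
    names(V) <- paste0("V", 2:(length(ranking) - 1), "/", 3:length(ranking))
  }
  n_rec <- if (length(V) && any(V < v_threshold)) {
    max(2L, 1L + which(V < v_threshold)[1])
  } else if (!length(V)) 2L else length(ranking)
  structure(list(M = M_full, ranking = ranking, pairwise_variation = V,
                 bestkeeper_sd = apply(cq, 1, stats::sd),
                 n_recommended = n_rec,
                 recommended_references = ranking[seq_len(n_rec)]),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Reference-gene stability (geNorm M; lower = more stable)\n")
  print(round(sort(x$M), 4))
  cat("Pairwise variation:\n"); print(round(x$pairwise_variation, 4))
  cat("Recommended references:", paste(x$recommended_references, collapse = ", "), "\n")
  invisible(x)
}

efficiency_vector <- function(efficiencies, genes, default = 2) {
  if (is.data.frame(efficiencies)) {
    efficiencies <- stats::setNames(efficiencies$E, efficiencies$gene_id)
  }
  eff <- stats::setNames(rep(default, length(genes)), genes)
  if (!is.null(efficiencies)) {
    known <- intersect(genes, names(efficiencies))
    eff[known] <- efficiencies[known]
  }
  if (any(eff <= 1 | eff > 2.2)) stop("amplification efficiencies must lie in (1, 2.2]")
  eff
}

#' Efficiency-corrected relative quantification
#'
#' For each gene g and sample s, the relative quantity is
#' `RQ(g, s) = E_g^(mean(Cq_g) - Cq_(g,s))`, i.e. calibrated against the
#' gene's mean Cq over all samples. Target RQs are divided by the sample's
#' normalization factor, the geometric mean of the reference genes' RQs.
#'
#' @param plates Calibrated plate table.
#' @param targets Character vector of target gene ids.
#' @param references Character vector of >= 2 reference gene ids.
#' @param efficiencies Per-gene efficiencies (see [genorm_stability()]);
#'   default 2 where absent.
#' @return Data frame `gene_id`, `sample_id`, `ratio` (> 0); samples
#'   missing any reference measurement are dropped with a warning.
#' @export
relative_quantify <- function(plates, targets, references, efficiencies = NULL) {
  if (length(references) < 2) stop("need >= 2 reference genes")
  cq <- cq_matrix(plates, c(targets, references))
  eff <- efficiency_vector(efficiencies, rownames(cq))
  ref_cq <- cq[references, , drop = FALSE]
  bad <- colnames(cq)[colSums(is.na(ref_cq)) > 0]
  if (length(bad)) {
    warning("dropping sample(s) missing a reference Cq: ", paste(bad, collapse = ", "))
    cq <- cq[, setdiff(colnames(cq), bad), drop = FALSE]
  }
  rq <- cq
  for (g in rownames(cq)) {
    rq[g, ] <- eff[g]^(mean(cq[g, ], na.rm = TRUE) - cq[g, ])
  }
  nf <- apply(rq[references, , drop = FALSE], 2, geometric_mean)
  out <- expand.grid(gene_id = targets, sample_id = colnames(cq),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$ratio <- mapply(function(g, s) rq[g, s] / nf[s], out$gene_id, out$sample_id)
  out[!is.na(out$ratio), , drop = FALSE]
}

#' Mann-Whitney caste comparison of relative expression
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) U test of relative expression
#' ratios between queen- and worker-destined larvae within each stage, per
#' target gene. The exact distribution is used for tie-free data; with ties
#' the normal approximation with mid-ranks is used and flagged.
#'
#' @param ratios Output of [relative_quantify()].
#' @param metadata Sample metadata (`sample_id`, `stage`, `caste`).
#' @param stages Stages to test (default all in `metadata`).
#' @return Data frame `gene_id`, `stage`, `U` (statistic for the Q group),
#'   `p`, `median_q`, `median_w`, `ties` (logical), `n_q`, `n_w`.
#' @export
caste_rank_test <- function(ratios, metadata, stages = NULL) {
  check_metadata_basic(metadata)
  stages <- stages %||% unique(metadata$stage)
  st_of <- stats::setNames(metadata$stage, metadata$sample_id)
  caste_of <- stats::setNames(metadata$caste, metadata$sample_id)
  grid <- expand.grid(gene_id = unique(ratios$gene_id), stage = stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- ratios[ratios$gene_id == grid$gene_id[i] &
                  st_of[ratios$sample_id] == grid$stage[i], , drop = FALSE]
    qv <- r$ratio[caste_of[r$sample_id] == "Q"]
    wv <- r$ratio[caste_of[r$sample_id] == "W"]
    if (length(qv) < 3 || length(wv) < 3) {
      stop("need >= 3 samples per caste for ", grid$gene_id[i], " at ",
           grid$stage[i])
    }
    ties <- anyDuplicated(c(qv, wv)) > 0
    wt <- suppressWarnings(
      stats::wilcox.test(qv, wv, exact = !ties, correct = ties))
    data.frame(gene_id = grid$gene_id[i], stage = grid$stage[i],
               U = unname(wt$statistic), p = wt$p.value,
               median_q = stats::median(qv), median_w = stats::median(wv),
               ties = ties, n_q = length(qv), n_w = length(wv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

check_metadata_basic <- function(metadata) {
  req <- c("sample_id", "stage", "caste")
  missing <- setdiff(req, names(metadata))
  if (length(missing)) stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  invisible(metadata)
}

#' Score congruence between mRNA-seq and qRT-PCR results
#'
#' For every target gene and stage, classifies each platform's outcome as
#' significantly up in Q, up in W, or not significant (mRNA-seq: HDEG call
#' and direction; qRT-PCR: Mann-Whitney p < `alpha` and the caste with the
#' higher median), and records whether the platforms agree: a match is both
#' significant in the same direction or both not significant.
#'
#' @param rank_tests Output of [caste_rank_test()].
#' @param de_calls DE calls with `is_hdeg` filled, covering the same stages.
#' @param genes Target gene ids (must appear on both platforms to be
#'   scored; absent ones are marked missing and excluded from totals).
#' @param alpha qRT-PCR significance threshold (default 0.05).
#' @return Data frame `gene_id`, `stage`, `seq_result`, `pcr_result`,
#'   `match` (`NA` when missing on either platform).
#' @export
platform_congruence <- function(rank_tests, de_calls, genes, alpha = 0.05) {
  stages <- unique(rank_tests$stage)
  grid <- expand.grid(gene_id = genes, stage = stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene_id[i]; st <- grid$stage[i]
    seq_row <- de_calls[de_calls$feature_id == g & de_calls$stage == st, , drop = FALSE]
    pcr_row <- rank_tests[rank_tests$gene_id == g & rank_tests$stage == st, , drop = FALSE]
    if (!nrow(seq_row) || !nrow(pcr_row)) {
      return(data.frame(gene_id = g, stage = st, seq_result = NA_character_,
                        pcr_result = NA_character_, match = NA,
                        stringsAsFactors = FALSE))
    }
    seq_res <- if (seq_row$is_hdeg[1] %in% TRUE) {
      paste0("sig_up_", seq_row$direction[1])
    } else "not_sig"
    pcr_res <- if (pcr_row$p[1] < alpha) {
      paste0("sig_up_", if (pcr_row$median_q[1] > pcr_row$median_w[1]) "Q" else "W")
    } else "not_sig"
    data.frame(gene_id = g, stage = st, seq_result = seq_res,
               pcr_result = pcr_res, match = seq_res == pcr_res,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
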