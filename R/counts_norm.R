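#' Aggregate per-read alignment records into a raw count matrix
#'
#' Gene/transcript expression is summarised as the algebraic sum of the
#' abundances of reads incident to each feature: for collapsed (deduplicated)
#' reads the `abundance` column carries the read multiplicity.
#'
#' @param records Data frame of alignment records with columns `read_id`,
#'   `sample_id`, `feature_id` and `abundance` (integer >= 1).
#' @param features Character vector of all known feature ids; features with
#'   no incident reads receive zero counts.
#' @param samples Sample metadata data frame (see [caste_counts()]).
#' @return A raw [caste_counts] object.
#' @examples
#' recs <- data.frame(read_id = c("r1", "r2", "r3"), sample_id = "s1",
#'                    feature_id = c("g1", "g1", "g2"), abundance = c(3, 2, 1))
#' meta <- data.frame(sample_id = "s1", stage = "mid", caste = "Q", replicate = 1)
#' aggregate_counts(recs, c("g1", "g2", "g3"), meta)$counts
#' @export
aggregate_counts <- function(records, features, samples) {
  records <- as.data.frame(records)
  req <- c("read_id", "sample_id", "feature_id", "abundance")
  missing <- setdiff(req, names(records))
  if (length(missing)) stop("records lack column(s): ", paste(missing, collapse = ", "))
  check_metadata(samples)
  m <- matrix(0, nrow = length(features), ncol = nrow(samples),
              dimnames = list(features, samples$sample_id))
  if (nrow(records)) {
    unknown <- setdiff(unique(records$feature_id), features)
    if (length(unknown)) {
      stop("alignment records reference unknown feature id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    unknown_s <- setdiff(unique(records$sample_id), samples$sample_id)
    if (length(unknown_s)) {
      stop("alignment records reference unknown sample id(s): ",
           paste(utils::head(unknown_s, 5), collapse = ", "))
    }
    if (any(records$abundance < 1)) stop("read abundance must be >= 1")
    agg <- tapply(records$abundance,
                  list(factor(records$feature_id, levels = features),
                       factor(records$sample_id, levels = samples$sample_id)),
                  sum)
    agg[is.na(agg)] <- 0
    m <- m + agg
  }
  caste_counts(m, samples, normalized = FALSE)
}

# One exact multivariate-hypergeometric draw of `target` reads (without
# replacement) from a library with per-feature counts `counts`: sample read
# indices uniformly and map them back to features through the cumulative
# count boundaries.
hypergeom_draw <- function(counts, target) {
  total <- sum(counts)
  if (target == total) return(counts)
  idx <- sample.int(total, target)
  feat <- findInterval(idx - 0.5, c(0, cumsum(counts)))
  tabulate(feat, nbins = length(counts))
}

#' Subsampling (multivariate hypergeometric) library normalization
#'
#' Equalises sequencing depth nonparametrically: each library is repeatedly
#' subsampled without replacement to a common target depth and the
#' per-feature mean across draws is returned. Each individual draw is an
#' exact multivariate hypergeometric sample, so its column sum equals the
#' target depth exactly; averaging over draws reduces subsampling noise.
#'
#' @param x A raw [caste_counts] object with integer counts.
#' @param target_depth Common depth to subsample to, or `"min"` (default) for
#'   the smallest library total. Must not exceed any library total.
#' @param n_draws Number of independent subsamples per library (default 10).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [caste_counts] object with `normalized = TRUE`; counts are means
#'   over draws (non-integer in general).
#' @export
subsample_normalize <- function(x, target_depth = "min", n_draws = 10, seed = 1) {
  stopifnot(inherits(x, "caste_counts"))
  if (x$normalized) stop("count matrix is already normalized")
  if (any(x$counts != round(x$counts))) stop("raw counts must be integers")
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("zero-depth library: ", paste(colnames(x$counts)[totals == 0], collapse = ", "))
  }
  if (identical(target_depth, "min")) target_depth <- min(totals)
  target_depth <- as.numeric(target_depth)
  stopifnot(length(target_depth) == 1L, target_depth > 0)
  if (any(totals < target_depth)) {
    stop("target depth ", target_depth, " exceeds library total of: ",
         paste(colnames(x$counts)[totals < target_depth], collapse = ", "))
  }
  stopifnot(n_draws >= 1)
  norm <- local_seed(seed, {
    out <- x$counts * 0
    for (j in seq_len(ncol(x$counts))) {
      acc <- numeric(nrow(x$counts))
      for (d in seq_len(n_draws)) {
        acc <- acc + hypergeom_draw(x$counts[, j], target_depth)
      }
      out[, j] <- acc / n_draws
    }
    out
  })
  res <- caste_counts(norm, x$samples, normalized = TRUE)
  attr(res, "target_depth") <- target_depth
  attr(res, "n_draws") <- n_draws
  attr(res, "seed") <- seed
  res
}

#' Replicate-correlation quality control
#'
#' Flags libraries whose mean Pearson correlation (on log2 counts with a +20
#' offset, mirroring the OFC offset) with same-phenotype replicates falls
#' below `min_corr`. The report lists flagged libraries; removal is left to
#' the user via [drop_samples()] — nothing is dropped silently.
#'
#' @param x A normalized [caste_counts] object.
#' @param min_corr Minimum acceptable mean within-phenotype correlation
#'   (default 0.9).
#' @param offset Log-offset added before taking logs (default 20).
#' @return Data frame with one row per sample: `sample_id`, `phenotype`,
#'   `mean_corr` and `status` (`"pass"`, `"fail"`, or `"unassessable"` for
#'   phenotypes with a single library).
#' @export
replicate_qc <- function(x, min_corr = 0.9, offset = 20) {
  stopifnot(inherits(x, "caste_counts"))
  ph <- phenotype_labels(x)
  lg <- log2(x$counts + offset)
  out <- data.frame(sample_id = colnames(x$counts), phenotype = ph,
                    mean_corr = NA_real_, status = "pass",
                    stringsAsFactors = FALSE)
  for (p in unique(ph)) {
    cols <- which(ph == p)
    if (length(cols) < 2) {
      out$status[cols] <- "unassessable"
      next
    }
    cm <- stats::cor(lg[, cols, drop = FALSE])
    mc <- (rowSums(cm) - 1) / (length(cols) - 1)
    out$mean_corr[cols] <- mc
    out$status[cols] <- ifelse(mc < min_corr, "fail", "pass")
  }
  out
}
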