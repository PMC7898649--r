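#' Count matrix container with phenotype metadata
#'
#' Bundles a features x samples count matrix with per-sample phenotype
#' metadata (developmental stage, caste pathway, replicate id), in the style
#' of edgeR's `DGEList`. All downstream callers operate on this container.
#'
#' @param counts Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Counts must be non-negative.
#' @param samples Data frame with columns `sample_id`, `stage`
#'   (`"early"`, `"mid"` or `"late"`), `caste` (`"Q"` or `"W"`) and
#'   `replicate`. One row per column of `counts`.
#' @param normalized Logical; `TRUE` once library depths have been equalised
#'   by [subsample_normalize()].
#'
#' @return An object of class `caste_counts`: a list with elements `counts`,
#'   `samples` and `normalized`.
#' @examples
#' m <- matrix(rpois(20, 10), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    stage = "mid", caste = rep(c("Q", "W"), each = 2),
#'                    replicate = c(1, 2, 1, 2))
#' caste_counts(m, meta)
#' @export
caste_counts <- function(counts, samples, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  samples <- as.data.frame(samples)
  check_metadata(samples)
  if (!setequal(samples$sample_id, colnames(counts))) {
    stop("sample metadata does not match count matrix columns")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples,
                 normalized = isTRUE(normalized)),
            class = "caste_counts")
}

#' @export
dim.caste_counts <- function(x) dim(x$counts)

#' @export
print.caste_counts <- function(x, ...) {
  cat(sprintf("caste_counts: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  tab <- table(phenotype = paste0(toupper(substr(x$samples$stage, 1, 1)),
                                  x$samples$caste))
  print(tab)
  invisible(x)
}

#' Phenotype label (stage initial + caste) per sample
#' @param x A [caste_counts] object.
#' @return Character vector, one label (e.g. `"MQ"`) per sample.
#' @export
phenotype_labels <- function(x) {
  paste0(toupper(substr(x$samples$stage, 1, 1)), x$samples$caste)
}

#' Drop samples from a count set
#'
#' Libraries flagged by QC (see [replicate_qc()]) are removed by an explicit
#' user decision, never silently.
#'
#' @param x A [caste_counts] object.
#' @param sample_ids Character vector of sample ids to remove.
#' @return A [caste_counts] object without the given samples.
#' @export
drop_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "caste_counts"))
  unknown <- setdiff(sample_ids, colnames(x$counts))
  if (length(unknown)) stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(x$counts), sample_ids)
  caste_counts(x$counts[, keep, drop = FALSE],
               x$samples[x$samples$sample_id %in% keep, , drop = FALSE],
               normalized = x$normalized)
}
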