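#' Fisher overlap test between two gene lists over a background
#'
#' Builds the 2x2 table of joint membership over a shared background
#' (orthologue universe) and applies a two-sided Fisher's exact test with
#' Bonferroni correction for the comparison family.
#'
#' @param list_a,list_b Character vectors of feature ids; must be subsets of
#'   `background`.
#' @param background Character vector, the shared feature universe.
#' @param family_size Number of comparisons in the Bonferroni family
#'   (default 1; supplied per batch, e.g. 36 or 18, never inferred).
#' @param comparison_id Optional label carried into results.
#' @return An object of class `overlap_test`: list with `table` (2x2),
#'   `odds_ratio` (conditional MLE), `p`, `p_adjusted`
#'   (`min(1, p * family_size)`), `family_size`, and the input sets.
#' @export
overlap_test <- function(list_a, list_b, background, family_size = 1,
                         comparison_id = NA_character_) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  stopifnot(family_size >= 1)
  for (nm in c("list_a", "list_b")) {
    out <- setdiff(get(nm), background)
    if (length(out)) {
      stop(nm, " contains id(s) outside the background: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  ab <- length(intersect(list_a, list_b))
  tab <- matrix(c(ab, length(list_a) - ab,
                  length(list_b) - ab,
                  length(background) - length(union(list_a, list_b))),
                2, 2, byrow = TRUE,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  ft <- stats::fisher.test(tab)
  structure(list(comparison_id = comparison_id, table = tab,
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 p_adjusted = min(1, ft$p.value * family_size),
                 family_size = family_size,
                 list_a = list_a, list_b = list_b, background = background),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Gene-list overlap (Fisher exact, two-sided)\n")
  print(x$table)
  cat(sprintf("odds ratio %.3g, p = %.3g, Bonferroni-adjusted p = %.3g (family %d)\n",
              x$odds_ratio, x$p, x$p_adjusted, x$family_size))
  invisible(x)
}

#' Re-run an overlap test with a gene set excluded
#'
#' Removes an exclusion set (e.g. diapause-associated genes) from both lists
#' and the background, then recomputes the Fisher test with the same family
#' size.
#'
#' @param test An [overlap_test()] result.
#' @param exclusion Character vector of feature ids to drop.
#' @return A new `overlap_test` object.
#' @export
exclude_and_retest <- function(test, exclusion) {
  stopifnot(inherits(test, "overlap_test"))
  bg <- setdiff(test$background, exclusion)
  if (!length(bg)) stop("exclusion empties the background")
  overlap_test(setdiff(test$list_a, exclusion),
               setdiff(test$list_b, exclusion),
               bg, test$family_size, test$comparison_id)
}

#' Mutual recovery between two pipelines' DEG sets
#'
#' @param calls_x,calls_y Character vectors of features called by each
#'   pipeline (shared universe).
#' @return Named list: `recovery_of_y` = |x ∩ y| / |y| (fraction of y's
#'   calls that x recovers) and `recovery_of_x` = |x ∩ y| / |x|. `NA` when
#'   the respective set is empty.
#' @export
pipeline_concordance <- function(calls_x, calls_y) {
  calls_x <- unique(calls_x); calls_y <- unique(calls_y)
  common <- length(intersect(calls_x, calls_y))
  list(recovery_of_y = if (length(calls_y)) common / length(calls_y) else NA_real_,
       recovery_of_x = if (length(calls_x)) common / length(calls_x) else NA_real_)
}

#' Exact binomial test of cross-platform congruence
#'
#' Tests whether the proportion of matching mRNA-seq / qRT-PCR outcomes
#' exceeds chance (0.5). One-sided by default.
#'
#' @param records Either a data frame of congruence records with a logical
#'   `match` column (see [platform_congruence()]), or the number of matches
#'   (with `n_total` supplied).
#' @param n_total Total comparisons when `records` is a count.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return List `n_match`, `n_total`, `p`.
#' @examples
#' congruence_binomial(38, 48)   # p ~ 3.1e-5
#' @export
congruence_binomial <- function(records, n_total = NULL,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(records)) {
    records <- records[!is.na(records$match), , drop = FALSE]
    n_match <- sum(records$match)
    n_total <- nrow(records)
  } else {
    n_match <- records
    stopifnot(!is.null(n_total))
  }
  stopifnot(n_total >= 1, n_match >= 0, n_match <= n_total)
  p <- stats::binom.test(n_match, n_total, p = 0.5,
                         alternative = alternative)$p.value
  list(n_match = n_match, n_total = n_total, p = p)
}
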