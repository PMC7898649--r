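#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the package
#' defaults: subsampling normalization to the minimum library depth averaged
#' over 10 draws, OFC offset 20 with touching intervals counting as overlap,
#' homology threshold 1e-5, 100-codon ORF rule, and a 0.05 qRT-PCR
#' significance level.
#'
#' @param excluded_samples Sample ids to drop before normalization (QC
#'   decisions are explicit, never automatic).
#' @param target_depth,n_draws,seed Passed to [subsample_normalize()].
#' @param offset OFC base-level offset.
#' @param min_corr Replicate-QC correlation threshold.
#' @param evalue_threshold,orf_codons Annotation options.
#' @param family_size Bonferroni family size for overlap tests.
#' @param qpcr_references `"auto"` (use the geNorm recommendation) or a
#'   character vector of reference gene ids.
#' @param alpha qRT-PCR significance threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(excluded_samples = character(),
                            target_depth = "min", n_draws = 10, seed = 1,
                            offset = 20, min_corr = 0.9,
                            evalue_threshold = 1e-5, orf_codons = 100,
                            family_size = 1,
                            qpcr_references = "auto", alpha = 0.05) {
  structure(list(excluded_samples = excluded_samples,
                 target_depth = target_depth, n_draws = n_draws, seed = seed,
                 offset = offset, min_corr = min_corr,
                 evalue_threshold = evalue_threshold, orf_codons = orf_codons,
                 family_size = family_size,
                 qpcr_references = qpcr_references, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full caste-expression pipeline
#'
#' Orchestrates normalize -> QC -> DE call -> HDEG merge -> annotate ->
#' orthologue projection -> overlap test -> qRT-PCR arm on a study bundle
#' (real inputs or [simulate_study()] output), and assembles a summary
#' report: per-phenotype DEG/HDEG counts with top OFC, annotation-class
#' counts among HDEGs, novelty enrichment per stage, and (when qPCR data
#' are present) reference stability, caste tests and platform congruence.
#' Every stochastic step's seed is recorded in the report. A stage failure
#' propagates with the stage name; results computed so far are attached to
#' the error condition.
#'
#' @param data List with elements `counts` (raw [caste_counts]); optional
#'   `features` (`feature_id`, `gff_annotated`), `hits`, `sequences`,
#'   `units`, `families`, `literature`, `ortho_ab`/`ortho_ba` (directional
#'   hit tables) or `ortho_map`, `partner_de` (comparison-species DE list),
#'   `qpcr` (list `plates`, `efficiencies`, `metadata`, and optionally
#'   `targets`).
#' @param config A [pipeline_config()].
#' @return List of class `caste_report`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config)
  stage_ctx <- "input"
  run <- function(name, expr) {
    stage_ctx <<- name
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s",
                                  name, conditionMessage(e)))
      cond$partial_report <- report
      stop(cond)
    })
  }

  counts <- data$counts
  if (length(config$excluded_samples)) {
    counts <- run("exclude", drop_samples(counts, config$excluded_samples))
  }
  norm <- run("normalize",
              subsample_normalize(counts, config$target_depth,
                                  config$n_draws, config$seed))
  report$normalized <- norm
  report$qc <- run("qc", replicate_qc(norm, config$min_corr, config$offset))

  intervals <- run("de-call", group_intervals(norm))
  calls <- run("de-call", call_degs(intervals, offset = config$offset))

  annotated <- NULL
  if (!is.null(data$features)) {
    annotated <- stats::setNames(data$features$gff_annotated,
                                 data$features$feature_id)
  }
  calls <- run("hdeg", call_hdegs(calls, norm, annotated, data$units,
                                  config$offset))
  report$calls <- calls

  if (!is.null(data$hits) && !is.null(data$features)) {
    coding <- if (!is.null(data$sequences)) {
      vapply(data$sequences[data$features$feature_id], coding_status,
             logical(1), min_codons = config$orf_codons)
    } else rep(FALSE, nrow(data$features))
    feats <- data.frame(feature_id = data$features$feature_id,
                        gff_annotated = data$features$gff_annotated,
                        coding = coding, stringsAsFactors = FALSE)
    report$annotations <- run("annotate",
                              classify_features(feats, data$hits,
                                                config$evalue_threshold))
    report$novelty <- run("annotate",
                          novelty_enrichment(calls, report$annotations))
  }

  ortho_map <- data$ortho_map
  if (is.null(ortho_map) && !is.null(data$ortho_ab) && !is.null(data$ortho_ba)) {
    ortho_map <- run("rbh", rbh(data$ortho_ab, data$ortho_ba))
  }
  if (!is.null(ortho_map)) {
    report$ortho_map <- ortho_map
    deg_proj <- run("project", project_lists(calls[calls$is_deg, ], ortho_map))
    report$deos <- deg_proj
    if (!is.null(data$partner_de)) {
      report$overlap <- run("overlap", {
        bg <- ortho_map$id_b
        lapply(split(deg_proj, deg_proj$stage), function(sub) {
          overlap_test(unique(sub$orthologue),
                       intersect(data$partner_de, bg), bg,
                       config$family_size,
                       comparison_id = sub$stage[1])
        })
      })
    }
  }

  if (!is.null(data$qpcr)) {
    qp <- data$qpcr
    cal <- run("qpcr", calibrate_plates(qp$plates))
    cand <- grep("^ref", unique(cal$gene_id[!cal$is_IPC]), value = TRUE)
    report$stability <- run("qpcr",
                            genorm_stability(cal, cand, qp$efficiencies))
    refs <- if (identical(config$qpcr_references, "auto")) {
      report$stability$recommended_references
    } else config$qpcr_references
    targets <- qp$targets %||%
      setdiff(unique(cal$gene_id[!cal$is_IPC]), cand)
    report$ratios <- run("qpcr",
                         relative_quantify(cal, targets, refs, qp$efficiencies))
    report$rank_tests <- run("qpcr",
                             caste_rank_test(report$ratios, qp$metadata))
    report$congruence <- run("qpcr",
                             platform_congruence(report$rank_tests, calls,
                                                 targets, config$alpha))
    scored <- report$congruence[!is.na(report$congruence$match), , drop = FALSE]
    if (nrow(scored)) {
      report$congruence_test <- run("qpcr", congruence_binomial(scored))
    }
  }

  report$summary <- summarise_calls(calls)
  if (!is.null(report$annotations)) {
    hd <- calls$feature_id[calls$is_hdeg %in% TRUE]
    cls <- report$annotations$annotation_class[
      match(hd, report$annotations$feature_id)]
    report$class_summary <- as.data.frame(table(annotation_class = cls),
                                          stringsAsFactors = FALSE)
  }
  class(report) <- "caste_report"
  report
}

# Table-1-style per-phenotype summary: DEG/HDEG counts and top OFC.
summarise_calls <- function(calls) {
  grid <- expand.grid(stage = stage_levels(), caste = caste_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$stage %in% unique(calls$stage), , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- calls[calls$stage == grid$stage[i] &
                   calls$direction == grid$caste[i] & calls$is_deg, , drop = FALSE]
    data.frame(phenotype = paste0(toupper(substr(grid$stage[i], 1, 1)),
                                  grid$caste[i]),
               stage = grid$stage[i], caste = grid$caste[i],
               n_deg = nrow(sub),
               n_hdeg = sum(sub$is_hdeg %in% TRUE),
               top_ofc = if (nrow(sub)) max(sub$ofc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.caste_report <- function(x, ...) {
  cat("caste-expression pipeline report\n")
  cat(sprintf("  normalization: target %s, %d draws, seed %s\n",
              format(attr(x$normalized, "target_depth")),
              attr(x$normalized, "n_draws"), format(attr(x$normalized, "seed"))))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$congruence_test)) {
    ct <- x$congruence_test
    cat(sprintf("  platform congruence: %d/%d matches (binomial p = %.3g)\n",
                ct$n_match, ct$n_total, ct$p))
  }
  invisible(x)
}

#' Write a pipeline report as TSV files
#'
#' Each table is written with a commented header recording the package
#' version and the run's seeds and options, so any output can be traced to
#' its configuration. Reruns with the same config are byte-identical.
#'
#' @param report A `caste_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "caste_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  header <- c(sprintf("# casteDE %s", as.character(utils::packageVersion("casteDE"))),
              sprintf("# seed=%s target_depth=%s n_draws=%d offset=%g evalue=%g",
                      format(cfg$seed), format(cfg$target_depth), cfg$n_draws,
                      cfg$offset, cfg$evalue_threshold))
  tables <- list(summary = report$summary, calls = report$calls,
                 qc = report$qc, novelty = report$novelty,
                 class_summary = report$class_summary,
                 annotations = report$annotations,
                 rank_tests = report$rank_tests,
                 congruence = report$congruence)
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(tables[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
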