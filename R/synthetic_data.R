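#' Synthetic study design
#'
#' Describes a simulated six-phenotype larval study: three developmental
#' stages (early, mid, late) crossed with two caste pathways (Q, W), each
#' with 2-4 biological replicates. The defaults emulate the 17-library
#' configuration of the motivating study (MQ, LQ and MW each lost one
#' replicate to QC) with mid-instar larvae carrying the bulk of true
#' caste-associated expression and early instars none.
#'
#' @param n_features Number of gene/transcript features (default 15000).
#' @param replicates Named integer vector of replicates per phenotype, names
#'   `EQ`, `EW`, `MQ`, `MW`, `LQ`, `LW` (default `c(3, 3, 3, 2, 3, 3)`).
#' @param depth_range Library depth range in reads, `c(min, max)` (default
#'   `c(9e5, 1.1e6)`).
#' @param de_spec Data frame of true caste effects: columns `stage`,
#'   `direction` (caste that is up), `n` (number of features), `lfc`
#'   (log2 fold change), `dispersion` (negative binomial dispersion of the
#'   affected features). Default: 100 Q-up and 100 W-up at mid (lfc 4), 50
#'   each at late (lfc 3), none at early.
#' @param dispersion Background NB dispersion (default 0.05).
#' @param stage_frac Fraction of features carrying a shared stage effect
#'   (default 0.6) so stage-wise clustering dominates caste-wise structure,
#'   as observed in real replicate ordinations.
#' @param stage_sd Log-normal sd of the stage effect (default 1).
#' @param frac_unannotated Fraction of features lacking a reference
#'   annotation (default 0.525).
#' @param frac_novel_of_unannotated Fraction of unannotated features that
#'   are novel, i.e. taxonomically restricted (default 0.314).
#' @param frac_coding_of_novel Fraction of novel features that are
#'   protein-coding (default 0.03).
#' @param ortho_frac Fraction of features with a one-to-one orthologue in
#'   the comparison species (default 0.5).
#' @param ortho_shared_de_rate Probability that the orthologue of a true-DE
#'   feature is also DE in the comparison species (default 0.02).
#' @param seed Integer seed.
#' @return List of class `sim_design`.
#' @export
sim_design <- function(n_features = 15000,
                       replicates = c(EQ = 3, EW = 3, MQ = 3, MW = 2,
                                      LQ = 3, LW = 3),
                       depth_range = c(9e5, 1.1e6),
                       de_spec = data.frame(
                         stage = c("mid", "mid", "late", "late"),
                         direction = c("Q", "W", "Q", "W"),
                         n = c(100, 100, 50, 50),
                         lfc = c(4, 4, 3, 3),
                         dispersion = 0.05),
                       dispersion = 0.05,
                       stage_frac = 0.6, stage_sd = 1,
                       frac_unannotated = 0.525,
                       frac_novel_of_unannotated = 0.314,
                       frac_coding_of_novel = 0.03,
                       ortho_frac = 0.5,
                       ortho_shared_de_rate = 0.02,
                       seed = 1) {
  stopifnot(n_features >= 1, all(replicates >= 2),
            length(depth_range) == 2, depth_range[1] <= depth_range[2])
  props <- c(stage_frac, frac_unannotated, frac_novel_of_unannotated,
             frac_coding_of_novel, ortho_frac, ortho_shared_de_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (nrow(de_spec)) {
    stopifnot(all(de_spec$direction %in% caste_levels()),
              all(de_spec$stage %in% stage_levels()),
              all(is.finite(de_spec$lfc)), all(de_spec$n >= 0))
    if (sum(de_spec$n) > n_features) {
      stop("more true-DE features requested than features simulated")
    }
  }
  structure(list(n_features = n_features, replicates = replicates,
                 depth_range = depth_range, de_spec = de_spec,
                 dispersion = dispersion, stage_frac = stage_frac,
                 stage_sd = stage_sd,
                 frac_unannotated = frac_unannotated,
                 frac_novel_of_unannotated = frac_novel_of_unannotated,
                 frac_coding_of_novel = frac_coding_of_novel,
                 ortho_frac = ortho_frac,
                 ortho_shared_de_rate = ortho_shared_de_rate,
                 seed = seed),
            class = "sim_design")
}

sample_sheet <- function(design) {
  ph <- names(design$replicates)
  stage_map <- c(E = "early", M = "mid", L = "late")
  do.call(rbind, lapply(ph, function(p) {
    n <- design$replicates[[p]]
    data.frame(sample_id = paste0(p, seq_len(n)),
               stage = unname(stage_map[substr(p, 1, 1)]),
               caste = substr(p, 2, 2), replicate = seq_len(n),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a count matrix with known caste effects
#'
#' Negative-binomial counts with (i) a log-normal baseline abundance per
#' feature, (ii) a shared stage effect on a majority of features (so
#' replicates cluster by stage first), (iii) caste effects only on the
#' designated true-DE features at their designated stage, and (iv) library
#' depths drawn uniformly from the design's depth range. Ground truth
#' (true-DE features per stage and direction, annotation classes,
#' orthologue pairs and a comparison-species DE list) is returned alongside.
#'
#' @param design A [sim_design()].
#' @return List with elements `counts` (raw [caste_counts]) and `truth`
#'   (list: `true_de` data frame `feature_id`, `stage`, `direction`, `lfc`;
#'   `classes` data frame `feature_id`, `annotation_class`;
#'   `orthologues` data frame `id_a`, `id_b`; `partner_de` character vector
#'   of comparison-species DE gene ids).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  local_seed(design$seed, {
    nf <- design$n_features
    feats <- sprintf("g%05d", seq_len(nf))
    samples <- sample_sheet(design)

    base <- stats::rlnorm(nf, meanlog = log(30), sdlog = 1.6)
    stage_var <- seq_len(nf) %in% sample.int(nf, round(design$stage_frac * nf))
    stage_fac <- sapply(stage_levels(), function(s) {
      f <- rep(1, nf)
      f[stage_var] <- stats::rlnorm(sum(stage_var), 0, design$stage_sd)
      f
    })

    # allocate disjoint true-DE feature sets
    truth_de <- NULL
    disp <- rep(design$dispersion, nf)
    caste_fac <- array(1, dim = c(nf, 3, 2),
                       dimnames = list(NULL, stage_levels(), caste_levels()))
    if (nrow(design$de_spec)) {
      pool <- sample.int(nf, sum(design$de_spec$n))
      off <- 0
      rows <- vector("list", nrow(design$de_spec))
      for (i in seq_len(nrow(design$de_spec))) {
        sp <- design$de_spec[i, ]
        idx <- pool[off + seq_len(sp$n)]
        off <- off + sp$n
        caste_fac[idx, sp$stage, sp$direction] <- 2^sp$lfc
        disp[idx] <- sp$dispersion
        rows[[i]] <- data.frame(feature_id = feats[idx], stage = sp$stage,
                                direction = sp$direction, lfc = sp$lfc,
                                stringsAsFactors = FALSE)
      }
      truth_de <- do.call(rbind, rows)
    }

    counts <- matrix(0L, nf, nrow(samples),
                     dimnames = list(feats, samples$sample_id))
    depths <- round(stats::runif(nrow(samples), design$depth_range[1],
                                 design$depth_range[2]))
    for (j in seq_len(nrow(samples))) {
      mu_rel <- base * stage_fac[, samples$stage[j]] *
        caste_fac[, samples$stage[j], samples$caste[j]]
      mu <- depths[j] * mu_rel / sum(mu_rel)
      counts[, j] <- stats::rnbinom(nf, mu = mu, size = 1 / disp)
    }

    # annotation truth
    n_un <- round(design$frac_unannotated * nf)
    un <- sample.int(nf, n_un)
    n_nov <- round(design$frac_novel_of_unannotated * n_un)
    nov <- sample(un, n_nov)
    n_cod <- round(design$frac_coding_of_novel * n_nov)
    cod <- if (n_cod) sample(nov, n_cod) else integer(0)
    cls <- rep("annotated", nf)
    cls[un] <- "unannotated_not_novel"
    cls[nov] <- "novel_noncoding"
    cls[cod] <- "novel_coding"
    classes <- data.frame(feature_id = feats, annotation_class = cls,
                          stringsAsFactors = FALSE)

    # orthology truth + a comparison-species DE list with tunable sharing
    n_or <- round(design$ortho_frac * nf)
    ortho_idx <- sort(sample.int(nf, n_or))
    orthologues <- data.frame(id_a = feats[ortho_idx],
                              id_b = sprintf("Amel%05d", seq_len(n_or)),
                              stringsAsFactors = FALSE)
    partner_de <- character(0)
    if (!is.null(truth_de)) {
      de_orth <- orthologues[orthologues$id_a %in% truth_de$feature_id, , drop = FALSE]
      shared <- stats::runif(nrow(de_orth)) < design$ortho_shared_de_rate
      bg <- orthologues[!orthologues$id_a %in% truth_de$feature_id, , drop = FALSE]
      bg_pick <- stats::runif(nrow(bg)) < 0.05
      partner_de <- c(de_orth$id_b[shared], bg$id_b[bg_pick])
    }

    list(counts = caste_counts(counts, samples, normalized = FALSE),
         truth = list(true_de = truth_de, classes = classes,
                      orthologues = orthologues, partner_de = partner_de))
  })
}

#' Simulate homology hit tables consistent with annotation truth
#'
#' Emits BLAST-outfmt-6-style rows with a `subject_genus` and `search_type`
#' column such that applying the novelty rule (hits at E <= 1e-5 restricted
#' to Bombus) recovers the design's true annotation classes exactly:
#' non-novel features receive at least one non-Bombus hit at E <= 1e-5;
#' novel features receive only Bombus hits below threshold, plus decoy
#' non-Bombus hits above it. Annotation membership (`gff_annotated`) and a
#' nucleotide sequence whose ORF content matches the coding truth are
#' returned alongside.
#'
#' @param truth Truth list from [simulate_counts()].
#' @param seed Integer seed.
#' @return List: `hits` (data frame with outfmt-6 columns `qseqid`,
#'   `sseqid`, `pident`, `length`, `evalue`, `bitscore`, plus
#'   `subject_genus`, `search_type`), `features` (data frame `feature_id`,
#'   `gff_annotated`), `sequences` (named character vector).
#' @export
simulate_hit_tables <- function(truth, seed = 1) {
  local_seed(seed, {
    cls <- truth$classes
    n <- nrow(cls)
    is_novel <- cls$annotation_class %in% c("novel_coding", "novel_noncoding")
    other_genera <- c("Apis", "Megachile", "Drosophila", "Nasonia")

    # every feature keeps a within-genus hit well below threshold
    bombus <- hit_rows(cls$feature_id, paste0("Bt_", cls$feature_id),
                       "Bombus", 10^stats::runif(n, -40, -10), "nucl")
    # non-novel features get a significant outside-genus hit
    nn <- which(!is_novel)
    strong <- hit_rows(cls$feature_id[nn], paste0("Xo_", cls$feature_id[nn]),
                       sample(other_genera, length(nn), replace = TRUE),
                       10^stats::runif(length(nn), -30, -6), "prot")
    # half the novel features get a decoy outside-genus hit above threshold
    nv <- which(is_novel)
    nv <- nv[stats::runif(length(nv)) < 0.5]
    weak <- hit_rows(cls$feature_id[nv], paste0("Xw_", cls$feature_id[nv]),
                     sample(other_genera, length(nv), replace = TRUE),
                     10^stats::runif(length(nv), -4, 1), "prot")

    coding <- cls$annotation_class %in%
      c("annotated", "unannotated_not_novel", "novel_coding")
    seqs <- vapply(coding, random_transcript, character(1))
    names(seqs) <- cls$feature_id
    list(hits = rbind(bombus, strong, weak),
         features = data.frame(feature_id = cls$feature_id,
                               gff_annotated = cls$annotation_class == "annotated",
                               stringsAsFactors = FALSE),
         sequences = seqs)
  })
}

hit_rows <- function(q, s, genus, evalue, type) {
  n <- length(q)
  data.frame(qseqid = q, sseqid = s,
             pident = round(stats::runif(n, 70, 100), 1),
             length = sample(80:500, n, replace = TRUE), evalue = evalue,
             bitscore = round(stats::runif(n, 50, 400), 1),
             subject_genus = genus, search_type = type,
             stringsAsFactors = FALSE)
}

# Random transcript with or without a long (120-codon) ORF. Non-coding
# sequences avoid ATG entirely so no ORF can start.
random_transcript <- function(coding, orf_codons = 120) {
  if (coding) {
    body <- paste(sample(c("GCT", "GGA", "CTG", "TCC", "AAG", "GAC"),
                         orf_codons, replace = TRUE), collapse = "")
    paste0("CCTC", "ATG", body, "TAA", "GATTC")
  } else {
    paste(sample(c("C", "G", "T"), 300, replace = TRUE), collapse = "")
  }
}

#' Simulate qRT-PCR Cq plates
#'
#' Generates long-format Cq plates for six biological replicates of each of
#' the six phenotypes: eight candidate reference genes of graded stability
#' (the first two near-proportional, i.e. near-constant pairwise ratio),
#' target genes with known caste fold-changes, per-plate offsets with an
#' inter-plate calibrator well, and per-gene amplification efficiencies in
#' [1.8, 2.1].
#'
#' @param design A [sim_design()] (stages/castes reused; six qPCR replicates
#'   per phenotype regardless of the mRNA-seq replicate counts).
#' @param seed Integer seed.
#' @param n_replicates Biological replicates per phenotype (default 6).
#' @param ref_noise_sd Per-gene Cq noise of the eight reference candidates,
#'   most stable first (default `c(0.05, 0.05, 0.3, 0.4, 0.5, 0.6, 0.8, 1)`).
#' @param target_effects Data frame `gene_id`, `stage`, `direction`, `lfc`
#'   of true target effects (default: `tgt1` 4-fold up in Q at mid, `tgt2`
#'   2-fold up in W at late).
#' @param target_noise_sd Cq noise of target genes (default 0.25).
#' @param n_plates Number of plates the samples are split across (default 2).
#' @param ipc_noise_sd Measurement noise of the IPC wells (default 0.05).
#' @return List: `plates` (long data frame `plate_id`, `well`, `gene_id`,
#'   `sample_id`, `Cq`, `is_IPC`), `efficiencies` (data frame `gene_id`,
#'   `E`), `metadata` (sample sheet), `truth` (the effect table and noise
#'   levels).
#' @export
simulate_cq_plates <- function(design, seed = 1, n_replicates = 6,
                               ref_noise_sd = c(0.05, 0.05, 0.3, 0.4,
                                                0.5, 0.6, 0.8, 1),
                               target_effects = data.frame(
                                 gene_id = c("tgt1", "tgt2"),
                                 stage = c("mid", "late"),
                                 direction = c("Q", "W"),
                                 lfc = c(2, 1)),
                               target_noise_sd = 0.25,
                               n_plates = 2, ipc_noise_sd = 0.05) {
  stopifnot(inherits(design, "sim_design"), length(ref_noise_sd) >= 8)
  local_seed(seed, {
    refs <- sprintf("ref%02d", seq_along(ref_noise_sd))
    targets <- unique(target_effects$gene_id)
    genes <- c(refs, targets)
    eff <- stats::setNames(round(stats::runif(length(genes), 1.8, 2.1), 3), genes)

    meta <- do.call(rbind, lapply(stage_levels(), function(st) {
      do.call(rbind, lapply(caste_levels(), function(cs) {
        data.frame(sample_id = sprintf("%s%s_%d", toupper(substr(st, 1, 1)),
                                       cs, seq_len(n_replicates)),
                   stage = st, caste = cs, replicate = seq_len(n_replicates),
                   stringsAsFactors = FALSE)
      }))
    }))
    ns <- nrow(meta)
    loading <- stats::rnorm(ns, 0, 0.5)  # shared template-amount variation
    base_cq <- stats::setNames(stats::runif(length(genes), 18, 26), genes)
    noise_sd <- stats::setNames(c(ref_noise_sd,
                                  rep(target_noise_sd, length(targets))), genes)

    plate_of <- rep(seq_len(n_plates), length.out = ns)
    plate_offset <- stats::rnorm(n_plates, 0, 0.3)

    rows <- vector("list", length(genes) * ns + n_plates)
    r <- 0
    for (g in genes) {
      lfc_gs <- matrix(0, 3, 2, dimnames = list(stage_levels(), caste_levels()))
      te <- target_effects[target_effects$gene_id == g, , drop = FALSE]
      for (i in seq_len(nrow(te))) lfc_gs[te$stage[i], te$direction[i]] <- te$lfc[i]
      for (j in seq_len(ns)) {
        logq <- loading[j] + lfc_gs[meta$stage[j], meta$caste[j]] +
          stats::rnorm(1, 0, noise_sd[g])
        cq <- base_cq[g] - logq / log2(eff[g]) + plate_offset[plate_of[j]]
        r <- r + 1
        rows[[r]] <- data.frame(plate_id = paste0("P", plate_of[j]),
                                well = sprintf("%s_%s", g, meta$sample_id[j]),
                                gene_id = g, sample_id = meta$sample_id[j],
                                Cq = cq, is_IPC = FALSE,
                                stringsAsFactors = FALSE)
      }
    }
    for (pl in seq_len(n_plates)) {
      r <- r + 1
      rows[[r]] <- data.frame(plate_id = paste0("P", pl), well = "IPC",
                              gene_id = "IPC", sample_id = "IPC",
                              Cq = 20 + plate_offset[pl] +
                                stats::rnorm(1, 0, ipc_noise_sd),
                              is_IPC = TRUE, stringsAsFactors = FALSE)
    }
    plates <- do.call(rbind, rows)
    rownames(plates) <- NULL
    list(plates = plates,
         efficiencies = data.frame(gene_id = genes, E = unname(eff),
                                   stringsAsFactors = FALSE),
         metadata = meta,
         truth = list(target_effects = target_effects,
                      ref_noise_sd = stats::setNames(ref_noise_sd, refs)))
  })
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper producing every input the pipeline consumes: raw
#' counts with truth, homology hit tables with annotation membership and
#' sequences, and qRT-PCR plates. Seeds for the sub-generators are derived
#' deterministically from the design seed.
#'
#' @param design A [sim_design()].
#' @return List `counts`, `truth`, `hits`, `features`, `sequences`,
#'   `qpcr` (see the individual generators).
#' @export
simulate_study <- function(design) {
  sim <- simulate_counts(design)
  hit <- simulate_hit_tables(sim$truth, seed = design$seed + 1)
  qp <- simulate_cq_plates(design, seed = design$seed + 2)
  list(counts = sim$counts, truth = sim$truth, hits = hit$hits,
       features = hit$features, sequences = hit$sequences, qpcr = qp)
}
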