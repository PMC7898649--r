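mk_plate <- function(plate_id, genes, samples, cq, ipc_cq = NULL) {
  wells <- expand.grid(gene_id = genes, sample_id = samples,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wells$plate_id <- plate_id
  wells$well <- paste(wells$gene_id, wells$sample_id, sep = "_")
  wells$Cq <- cq
  wells$is_IPC <- FALSE
  if (!is.null(ipc_cq)) {
    wells <- rbind(wells, data.frame(gene_id = "IPC", sample_id = "IPC",
                                     plate_id = plate_id, well = "IPC",
                                     Cq = ipc_cq, is_IPC = TRUE))
  }
  wells
}

test_that("inter-plate calibration removes plate offsets exactly", {
  p1 <- mk_plate("P1", c("gA", "gB"), c("s1", "s2"), c(20, 22, 24, 26), 20)
  p2 <- mk_plate("P2", c("gA", "gB"), c("s3", "s4"), c(21, 23, 25, 27), 22)
  cal <- calibrate_plates(rbind(p1, p2))
  # plate 1 shifted by +1, plate 2 by -1
  expect_equal(cal$Cq[cal$plate_id == "P1" & !cal$is_IPC], c(20, 22, 24, 26) + 1)
  expect_equal(cal$Cq[cal$plate_id == "P2" & !cal$is_IPC], c(21, 23, 25, 27) - 1)
  # calibrated IPC values equal across plates
  expect_equal(length(unique(cal$Cq[cal$is_IPC])), 1)
  # within-plate differences preserved
  expect_equal(diff(cal$Cq[cal$plate_id == "P1" & !cal$is_IPC]),
               diff(p1$Cq[!p1$is_IPC]))
  # single plate is identity
  expect_identical(calibrate_plates(p1), p1)
  p3 <- mk_plate("P3", "gA", "s5", 20)
  expect_error(calibrate_plates(rbind(p1, p3)), "IPC")
})

test_that("geNorm M ranks proportional references above noisy genes", {
  set.seed(6)
  samples <- paste0("s", 1:12)
  base <- rnorm(12, 24, 1)  # shared loading profile
  plates <- rbind(
    mk_plate("P1", "gA", samples, base),
    mk_plate("P1", "gB", samples, base + 2),          # constant Cq offset
    mk_plate("P1", "gC", samples, base + rnorm(12, 0, 1.5)))
  plates$is_IPC <- FALSE
  stab <- genorm_stability(plates, c("gA", "gB", "gC"))
  expect_lt(stab$M[["gA"]], stab$M[["gC"]])
  expect_lt(stab$M[["gB"]], stab$M[["gC"]])
  expect_setequal(stab$ranking[1:2], c("gA", "gB"))
  expect_gt(stab$bestkeeper_sd[["gC"]], stab$bestkeeper_sd[["gA"]])

  # all genes identical across samples: all M = 0, recommendation floor 2
  const <- rbind(mk_plate("P1", "gA", samples, 20),
                 mk_plate("P1", "gB", samples, 22),
                 mk_plate("P1", "gC", samples, 24))
  s2 <- genorm_stability(const, c("gA", "gB", "gC"))
  expect_equal(unname(s2$M), c(0, 0, 0))
  expect_equal(s2$n_recommended, 2)
  expect_error(genorm_stability(const, c("gA", "gB")), ">= 3")
})

test_that("removing the least stable candidate never raises mean M", {
  set.seed(31)
  for (i in 1:100) {
    samples <- paste0("s", 1:8)
    genes <- paste0("g", 1:5)
    plates <- do.call(rbind, lapply(genes, function(g) {
      mk_plate("P1", g, samples, rnorm(8, 24, runif(1, 0.1, 1.5)))
    }))
    cq <- casteDE:::cq_matrix(plates, genes)
    logq <- -cq  # E = 2
    m_of <- function(lq) {
      vapply(seq_len(nrow(lq)), function(j) {
        mean(vapply(setdiff(seq_len(nrow(lq)), j),
                    function(k) sd(lq[j, ] - lq[k, ]), numeric(1)))
      }, numeric(1))
    }
    M <- m_of(logq)
    M_after <- m_of(logq[-which.max(M), , drop = FALSE])
    expect_lte(mean(M_after), mean(M) + 1e-12)
  }
})

test_that("relative quantification is efficiency-corrected and normalized", {
  samples <- paste0("s", 1:4)
  # all Cq identical everywhere -> all ratios 1
  flat <- rbind(mk_plate("P1", "ref1", samples, 20),
                mk_plate("P1", "ref2", samples, 21),
                mk_plate("P1", "tgt", samples, 25))
  rq <- relative_quantify(flat, "tgt", c("ref1", "ref2"))
  expect_equal(rq$ratio, rep(1, 4))
  # target one cycle below its own mean in s1, references flat -> ratio 2 at E=2
  shifted <- flat
  shifted$Cq[shifted$gene_id == "tgt"] <- c(24, 25, 25, 26)
  rq2 <- relative_quantify(shifted, "tgt", c("ref1", "ref2"))
  expect_equal(rq2$ratio[rq2$sample_id == "s1"], 2)
  # invariant to a constant added to one gene's Cq values
  shifted2 <- shifted
  shifted2$Cq[shifted2$gene_id == "ref1"] <- shifted2$Cq[shifted2$gene_id == "ref1"] + 3
  expect_equal(relative_quantify(shifted2, "tgt", c("ref1", "ref2"))$ratio,
               rq2$ratio)
  expect_error(relative_quantify(flat, "tgt", "ref1"), ">= 2 reference")
})

test_that("Mann-Whitney caste test matches the enumeration oracle", {
  meta <- data.frame(sample_id = paste0("s", 1:12), stage = "mid",
                     caste = rep(c("Q", "W"), each = 6))
  ratios <- data.frame(gene_id = "tgt", sample_id = meta$sample_id,
                       ratio = c(1:6, 7:12))
  res <- caste_rank_test(ratios, meta)
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 924)
  expect_equal(res$p, mw_enum_oracle(1:6, 7:12))
  # label swap leaves p unchanged
  meta2 <- transform(meta, caste = rep(c("W", "Q"), each = 6))
  expect_equal(caste_rank_test(ratios, meta2)$p, res$p)
  # random tie-free group sizes <= 7 against the oracle
  set.seed(9)
  for (i in 1:10) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    v <- sample(1000, n1 + n2) + runif(n1 + n2)
    meta_i <- data.frame(sample_id = paste0("s", seq_len(n1 + n2)),
                         stage = "mid", caste = rep(c("Q", "W"), c(n1, n2)))
    r_i <- data.frame(gene_id = "g", sample_id = meta_i$sample_id, ratio = v)
    expect_equal(caste_rank_test(r_i, meta_i)$p,
                 mw_enum_oracle(v[1:n1], v[(n1 + 1):(n1 + n2)]))
  }
  # identical groups: p in the non-significant region, ties flagged
  r_t <- data.frame(gene_id = "g", sample_id = meta$sample_id, ratio = rep(1:6, 2))
  res_t <- caste_rank_test(r_t, meta)
  expect_true(res_t$ties)
  expect_gte(res_t$p, 0.99)
})

test_that("platform congruence scores matches, mismatches and missing genes", {
  rank_tests <- data.frame(gene_id = rep(c("g1", "g2", "g3"), 2),
                           stage = rep(c("mid", "late"), each = 3),
                           U = 1,
                           p = c(0.01, 0.5, 0.02, 0.6, 0.7, 0.8),
                           median_q = c(4, 1, 1, 1, 1, 1),
                           median_w = c(1, 1, 2, 1, 1, 1))
  de_calls <- expand.grid(feature_id = c("g1", "g2", "g3"),
                          stage = c("mid", "late"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  de_calls$direction <- c("Q", "none", "Q", "none", "none", "none")
  de_calls$is_deg <- de_calls$direction != "none"
  de_calls$ofc <- ifelse(de_calls$is_deg, 2, 0)
  de_calls$is_hdeg <- de_calls$is_deg
  rec <- platform_congruence(rank_tests, de_calls, c("g1", "g2", "g3", "g4"))
  get <- function(g, st) rec[rec$gene_id == g & rec$stage == st, ]
  expect_true(get("g1", "mid")$match)            # both Q-up
  expect_true(get("g2", "mid")$match)            # both not significant
  expect_false(get("g3", "mid")$match)           # HDEG Q-up vs qPCR W-up
  expect_true(get("g1", "late")$match)           # both not significant
  expect_true(is.na(get("g4", "mid")$match))     # absent from qPCR platform
  # accounting: matches + mismatches + missing = stages x genes
  expect_equal(sum(rec$match, na.rm = TRUE) + sum(!rec$match, na.rm = TRUE) +
                 sum(is.na(rec$match)), 2 * 4)
})
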