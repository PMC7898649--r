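# Minimal normalized count set builder: values per phenotype given as a
# list of replicate vectors, one feature per row of `vals`.
mini_counts <- function(vals_q, vals_w, stage = "mid") {
  nf <- nrow(vals_q)
  m <- cbind(vals_q, vals_w)
  rownames(m) <- paste0("g", seq_len(nf))
  colnames(m) <- c(paste0("q", seq_len(ncol(vals_q))),
                   paste0("w", seq_len(ncol(vals_w))))
  meta <- data.frame(sample_id = colnames(m), stage = stage,
                     caste = rep(c("Q", "W"), c(ncol(vals_q), ncol(vals_w))),
                     replicate = c(seq_len(ncol(vals_q)), seq_len(ncol(vals_w))))
  caste_counts(m, meta, normalized = TRUE)
}

test_that("OFC follows the offset log-ratio identities", {
  expect_equal(ofc(236, 108), 1)
  expect_equal(ofc(0, 0), 0)
  for (x in c(0, 1, 17, 500.5)) expect_equal(ofc(x, x), 0)
  expect_error(ofc(-1, 5), "non-negative")
  expect_equal(ofc(10, 15), log2(30 / 35))
})

test_that("group intervals span replicate min to max", {
  x <- mini_counts(rbind(c(5, 5, 5), c(2, 9, 4)), rbind(c(1, 2, 3), c(7, 8, 9)))
  iv <- group_intervals(x)
  g1q <- iv[iv$feature_id == "g1" & iv$caste == "Q", ]
  expect_equal(c(g1q$min_count, g1q$max_count), c(5, 5))
  g2q <- iv[iv$feature_id == "g2" & iv$caste == "Q", ]
  expect_equal(c(g2q$min_count, g2q$max_count), c(2, 9))
  expect_true(all(iv$min_count <= iv$max_count))

  solo <- mini_counts(rbind(c(1, 2)), rbind(c(3, 4)))
  solo$counts <- solo$counts[, -1, drop = FALSE]
  solo$samples <- solo$samples[-1, ]
  expect_error(group_intervals(solo), "single replicate")
})

test_that("DEG calls require strictly disjoint intervals", {
  x <- mini_counts(rbind(c(10, 12, 15),   # disjoint below W -> W-up DEG
                         c(10, 15, 20),   # overlapping -> no DEG
                         c(0, 2, 5),      # touching endpoint -> no DEG
                         c(30, 35, 40)),  # disjoint above W -> Q-up DEG
                   rbind(c(16, 18, 20),
                         c(15, 20, 25),
                         c(5, 7, 9),
                         c(5, 10, 15)))
  calls <- call_degs(group_intervals(x))
  expect_equal(calls$is_deg, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$direction, c("W", "none", "none", "Q"))
  expect_equal(calls$ofc[1], log2(36 / 35))
  expect_equal(calls$ofc[4], log2(50 / 35))
  expect_true(all(calls$ofc[calls$is_deg] > 0))
})

test_that("caste-label swap mirrors direction and preserves |OFC|", {
  sim <- toy_counts(n_features = 300, seed = 8)
  norm <- subsample_normalize(sim$counts, seed = 1)
  calls <- call_degs(group_intervals(norm))
  swapped <- norm
  swapped$samples$caste <- chartr("QW", "WQ", swapped$samples$caste)
  calls_sw <- call_degs(group_intervals(swapped))
  key <- paste(calls$feature_id, calls$stage)
  calls_sw <- calls_sw[match(key, paste(calls_sw$feature_id, calls_sw$stage)), ]
  expect_equal(calls$is_deg, calls_sw$is_deg)
  expect_equal(calls$ofc[calls$is_deg], calls_sw$ofc[calls_sw$is_deg])
  expect_equal(chartr("QW", "WQ", calls$direction[calls$is_deg]),
               calls_sw$direction[calls_sw$is_deg])
})

test_that("raising the losing caste weakens or removes a W-up call", {
  base_q <- c(10, 12, 15); base_w <- c(30, 35, 40)
  prev_ofc <- Inf
  for (bump in c(0, 5, 10, 14, 20)) {
    x <- mini_counts(rbind(base_q + bump), rbind(base_w))
    cl <- call_degs(group_intervals(x))
    if (cl$is_deg) {
      expect_lte(cl$ofc, prev_ofc)
      prev_ofc <- cl$ofc
    } else {
      prev_ofc <- 0
    }
  }
  # once intervals overlap the call is gone for good
  x <- mini_counts(rbind(base_q + 25), rbind(base_w))
  expect_false(call_degs(group_intervals(x))$is_deg)
})

test_that("null false-positive rate matches 2/C(n1+n2, n1)", {
  set.seed(77)
  n <- 20000
  for (reps in list(c(3, 3), c(4, 4))) {
    m <- matrix(runif(n * sum(reps)), n)
    rownames(m) <- paste0("g", 1:n)
    colnames(m) <- paste0("s", seq_len(sum(reps)))
    meta <- data.frame(sample_id = colnames(m), stage = "mid",
                       caste = rep(c("Q", "W"), reps),
                       replicate = c(seq_len(reps[1]), seq_len(reps[2])))
    x <- caste_counts(m, meta, normalized = TRUE)
    rate <- mean(call_degs(group_intervals(x))$is_deg)
    p0 <- null_deg_rate(reps[1], reps[2])
    mc_se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(rate - p0), 3 * mc_se)
  }
})

test_that("HDEGs are DEGs with OFC strictly above 1", {
  x <- mini_counts(rbind(c(236, 240, 250),  # ofc exactly 1 -> not HDEG
                         c(300, 320, 350),  # ofc > 1 -> HDEG
                         c(50, 60, 70)),    # DEG but ofc < 1
                   rbind(c(100, 104, 108),
                         c(100, 110, 120),
                         c(20, 25, 30)))
  calls <- call_hdegs(call_degs(group_intervals(x)))
  expect_equal(calls$is_hdeg, c(FALSE, TRUE, FALSE))
  expect_true(all(which(calls$is_hdeg) %in% which(calls$is_deg)))
})

test_that("unannotated exon candidates merge into one HDEG per unit", {
  # three exon features of one transcript, each individually OFC > 1
  vals_q <- rbind(c(300, 320, 350), c(280, 300, 330), c(310, 330, 340),
                  c(400, 420, 450))
  vals_w <- rbind(c(50, 60, 70), c(45, 55, 65), c(52, 62, 72),
                  c(80, 90, 100))
  x <- mini_counts(vals_q, vals_w)
  units <- data.frame(unit_id = "TU0001", feature_id = c("g1", "g2", "g3"))
  calls <- call_hdegs(call_degs(group_intervals(x)), x,
                      annotated = setNames(c(FALSE, FALSE, FALSE, TRUE),
                                           paste0("g", 1:4)),
                      units = units)
  expect_equal(sum(calls$is_hdeg), 2)  # one merged unit + g4
  expect_equal(sum(calls$is_hdeg[calls$feature_id %in% c("g1", "g2", "g3")]), 1)
  expect_equal(unique(calls$unit_id[calls$feature_id %in% c("g1", "g2", "g3")]),
               "TU0001")
  expect_error(call_hdegs(call_degs(group_intervals(x)), x,
                          units = data.frame(unit_id = "U", feature_id = "gX")),
               "unknown feature")
})

test_that("transcript units chain nearby correlated unannotated features", {
  sim <- toy_counts(n_features = 6, seed = 5)
  norm <- subsample_normalize(sim$counts, seed = 1)
  ids <- rownames(norm$counts)
  # features 1,2 adjacent + proportional profiles; 3 far away; 4 adjacent to
  # 3 but uncorrelated; 5 annotated; 6 on another chromosome
  norm$counts[2, ] <- norm$counts[1, ] * 2
  norm$counts[4, ] <- rev(norm$counts[3, ])
  feats <- data.frame(feature_id = ids,
                      chrom = c("c1", "c1", "c1", "c1", "c1", "c2"),
                      start = c(0, 600, 10000, 10600, 1200, 0),
                      end = c(500, 1100, 10500, 11100, 1700, 500),
                      strand = "+",
                      annotated = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  units <- build_transcript_units(feats, norm, max_gap = 1000, min_cor = 0.9)
  expect_setequal(units$feature_id, ids[1:2])
  expect_equal(length(unique(units$unit_id)), 1)
})

test_that("genes of interest follow the (a) or two-of-(b..e) rule", {
  mk_call <- function(f, st, dir, deg, ofc_v, hdeg) {
    data.frame(feature_id = f, stage = st, direction = dir, is_deg = deg,
               ofc = ofc_v, is_hdeg = hdeg)
  }
  calls <- rbind(
    mk_call("gA", "mid", "Q", TRUE, 3.0, TRUE),    # top OFC in MQ -> (a)
    mk_call("gB", "mid", "Q", TRUE, 1.5, TRUE),    # HDEG mid + late -> (b)+(c)
    mk_call("gB", "late", "Q", TRUE, 1.2, TRUE),
    mk_call("gF", "mid", "W", TRUE, 2.0, TRUE),    # top OFC in MW -> (a)
    mk_call("gC", "mid", "W", TRUE, 1.4, TRUE),    # HDEG once, no support
    mk_call("gG", "late", "W", TRUE, 0.8, FALSE),  # top OFC in LW -> (a)
    mk_call("gD", "late", "W", TRUE, 0.5, FALSE),  # family + literature
    mk_call("gE", "early", "Q", FALSE, -0.1, FALSE))
  goi <- genes_of_interest(calls,
                           families = data.frame(feature_id = c("gD", "gB"),
                                                 family = "fam1"),
                           literature = "gD")
  sel <- setNames(goi$selected, goi$feature_id)
  expect_true(sel[["gA"]])            # criterion (a)
  expect_true(sel[["gB"]])            # (b) + (c)
  expect_false(sel[["gC"]])           # only (b): one HDEG stage, no family
  expect_true(sel[["gD"]])            # (d) family HDEG + (e) literature
  expect_false(sel[["gE"]])           # never a DEG
  expect_true(goi$crit_d[goi$feature_id == "gD"])
  expect_true(goi$crit_e[goi$feature_id == "gD"])
  expect_false(goi$crit_a[goi$feature_id == "gC"])
})
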