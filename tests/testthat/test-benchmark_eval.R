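# Gene scoring, ROC-AUC, dAUC, recall/FDR maps, pseudocount export.

scores_tbl <- function(score, label, id = sprintf("e%03d", seq_along(score))) {
  tibble::tibble(entity_id = id, score = score, level = "gene", label = label,
                 n_guides = 1L, any_reliable = TRUE)
}

metrics_tbl <- function(gene, v, reliable = TRUE) {
  tibble::tibble(guide_id = sprintf("sg%03d", seq_along(v)), gene = gene,
                 role = "targeting", fc_raw = NA_real_, fc_norm = v,
                 indel_obs = NA_real_, x_raw = NA_real_, x_adj = NA_real_,
                 clipped = FALSE, v = v, reliable = reliable, qc_pass = TRUE)
}

test_that("gene_scores aggregates guides as configured", {
  m <- metrics_tbl(gene = c("A", "A", "A", "B"), v = c(0.1, 0.2, 0.9, 0.4))
  med <- gene_scores(m, metric = "v", agg = "median")
  expect_equal(med$score[med$entity_id == "A"], 0.2)
  expect_equal(med$score[med$entity_id == "B"], 0.4)  # single-guide gene

  mn <- gene_scores(m, metric = "v", agg = "mean")
  expect_equal(mn$score[mn$entity_id == "A"], mean(c(0.1, 0.2, 0.9)))
  expect_false(isTRUE(all.equal(mn$score[1], med$score[1])))  # skewed triple

  sb <- gene_scores(m, metric = "v", agg = "second_best")
  expect_equal(sb$score[sb$entity_id == "A"], 0.2)
  expect_equal(sb$score[sb$entity_id == "B"], 0.4)

  # unreliable guides are excluded when a reliable one exists
  m2 <- metrics_tbl(gene = c("A", "A"), v = c(5, 0.3),
                    reliable = c(FALSE, TRUE))
  expect_equal(gene_scores(m2)$score, 0.3)
  expect_true(gene_scores(m2)$any_reliable)
  m3 <- metrics_tbl(gene = "A", v = 5, reliable = FALSE)
  expect_equal(gene_scores(m3)$score, 5)  # flagged, scored from all guides
  expect_false(gene_scores(m3)$any_reliable)

  expect_error(gene_scores(metrics_tbl(character(0), numeric(0))),
               "no scorable guides")
})

test_that("roc_auc equals the brute-force Mann-Whitney pair count", {
  # perfect separation and all-ties sanity points
  s <- scores_tbl(c(0.1, 0.2, 0.8, 0.9),
                  c("essential", "essential", "nonessential", "nonessential"))
  expect_equal(roc_auc(s)$auc, 1)
  s_tie <- scores_tbl(rep(0.5, 6), rep(c("essential", "nonessential"), 3))
  expect_equal(roc_auc(s_tie)$auc, 0.5)
  expect_error(roc_auc(scores_tbl(1:3, rep("essential", 3))), "at least one")

  # O(n^2) oracle: count essential-nonessential pairs, half credit for ties
  auc_oracle <- function(scores) {
    e <- scores$score[scores$label == "essential"]
    n <- scores$score[scores$label == "nonessential"]
    tot <- 0
    for (a in e) for (b in n) tot <- tot + (a < b) + 0.5 * (a == b)
    tot / (length(e) * length(n))
  }
  set.seed(31)
  for (i in 1:100) {
    sc <- scores_tbl(sample(round(rnorm(40), 1)),  # rounding forces ties
                     sample(rep(c("essential", "nonessential"), 20)))
    expect_equal(roc_auc(sc)$auc, auc_oracle(sc))
  }
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(5)
  sc <- scores_tbl(rnorm(60), sample(rep(c("essential", "nonessential"), 30)))
  base <- roc_auc(sc)$auc
  for (f in list(function(x) 3 * x - 7, function(x) exp(x),
                 function(x) x^3)) {
    sc2 <- sc; sc2$score <- f(sc$score)
    expect_equal(roc_auc(sc2)$auc, base)
  }
  # pROC cross-check (independent implementation)
  if (requireNamespace("pROC", quietly = TRUE)) {
    r <- pROC::roc(response = sc$label == "essential",
                   predictor = -sc$score, quiet = TRUE,
                   direction = "<")
    expect_equal(base, as.numeric(pROC::auc(r)))
  }
})

test_that("dauc matches the closed form for block rankings and is ~0 under shuffles", {
  # essential genes occupying the first n_E ranks: auc_E = 1 - n_E / (2N),
  # verified by direct summation of the recovery curve
  n_e <- 10; n_n <- 15; n_o <- 25
  sc <- scores_tbl(seq_len(n_e + n_n + n_o),
                   c(rep("essential", n_e), rep("nonessential", n_n),
                     rep("other", n_o)))
  d <- dauc(sc)
  n_tot <- n_e + n_n + n_o
  direct <- {
    hits <- cumsum(rep(c(1, 0), c(n_e, n_tot - n_e))) / n_e
    curve <- c(0, hits)
    sum((curve[-1] + curve[-(n_tot + 1)]) / 2) / n_tot
  }
  expect_equal(d$auc_essential, direct)
  expect_equal(d$auc_essential, 1 - n_e / (2 * n_tot))
  expect_gt(d$dauc, 0)

  # essential genes ranked last: negative separation
  sc_rev <- sc
  sc_rev$score[sc$label == "essential"] <- 100 + seq_len(n_e)
  expect_lt(dauc(sc_rev)$dauc, 0)

  # random scores with shuffled labels: mean dAUC over shuffles ~ 0
  set.seed(17)
  base_scores <- rnorm(30)
  mean_d <- mean(vapply(1:200, function(i) {
    dauc(scores_tbl(base_scores,
                    sample(rep(c("essential", "nonessential"), 15))))$dauc
  }, numeric(1)))
  expect_lt(abs(mean_d), 0.02)
})

test_that("recall/FDR maps equal the exhaustive threshold sweep", {
  sweep_oracle <- function(scores, fdr_levels, recall_levels) {
    s <- scores[scores$label != "other", ]
    s <- s[order(s$score, s$entity_id), ]
    n_e <- sum(s$label == "essential")
    best_recall <- setNames(numeric(length(fdr_levels)), format(fdr_levels))
    best_fdr <- setNames(rep(NA_real_, length(recall_levels)),
                         format(recall_levels))
    for (k in seq_len(nrow(s))) {
      tp <- sum(s$label[1:k] == "essential")
      fp <- k - tp
      fdr <- fp / k
      rec <- tp / n_e
      for (j in seq_along(fdr_levels)) {
        if (fdr <= fdr_levels[j]) best_recall[j] <- max(best_recall[j], rec)
      }
      for (j in seq_along(recall_levels)) {
        if (rec >= recall_levels[j]) {
          best_fdr[j] <- min(best_fdr[j], fdr, na.rm = TRUE)
        }
      }
    }
    list(recall_at_fdr = best_recall, fdr_at_recall = best_fdr)
  }

  # perfect separation: full recall at 20% FDR, zero FDR at full recall
  s <- scores_tbl(1:20, rep(c("essential", "nonessential"), each = 10))
  rf <- recall_fdr(s, fdr_levels = 0.2, recall_levels = 1)
  expect_equal(unname(rf$recall_at_fdr), 1)
  expect_equal(unname(rf$fdr_at_recall), 0)

  # alternating labels and random instances vs the oracle
  alt <- scores_tbl(1:20, rep(c("essential", "nonessential"), 10))
  set.seed(41)
  for (sc in c(list(alt), lapply(1:100, function(i) {
    scores_tbl(sample(round(rnorm(30), 1)),
               sample(c(rep("essential", 10), rep("nonessential", 15),
                        rep("other", 5))))
  }))) {
    got <- recall_fdr(sc, fdr_levels = c(0.1, 0.2, 0.5),
                      recall_levels = c(0.5, 0.95, 1))
    want <- sweep_oracle(sc, c(0.1, 0.2, 0.5), c(0.5, 0.95, 1))
    expect_equal(got$recall_at_fdr, want$recall_at_fdr)
    expect_equal(got$fdr_at_recall, want$fdr_at_recall)
  }
})

test_that("v-based guide ranking beats FC under guide-activity heterogeneity", {
  # the property behind the method: with X_true ~ U(0.2, 0.95) low-activity
  # guides drag essential guides toward neutral fold changes, while v
  # corrects for the activity; ROC is drawn at guide level with gene-set
  # labels (as in tiling screens, where the positives are the guides of the
  # known essential genes) and v should win in >= 9 of 10 seeds
  wins <- 0
  aucs <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("v", "fc")))
  for (i in 1:10) {
    run <- run_sim_screen(seed = 100 + i, n_genes = 500, guides_per_gene = 3,
                          n_controls = 100, essential_frac = 0.2,
                          v_essential = 0.2, x_range = c(0.2, 0.95))
    ref <- gene_reference(
      run$truth$genes$gene[run$truth$genes$class == "essential"],
      run$truth$genes$gene[run$truth$genes$class == "neutral"])
    auc_v <- roc_auc(guide_scores(run$metrics, "v", gene_ref = ref))$auc
    auc_fc <- roc_auc(guide_scores(run$metrics, "fc", gene_ref = ref))$auc
    aucs[i, ] <- c(auc_v, auc_fc)
    if (auc_v > auc_fc) wins <- wins + 1
  }
  expect_gte(wins, 9)
  # dAUC and ROC-AUC agree on the sign of separation
  expect_true(all(aucs > 0.5))
})

test_that("export_pseudocounts scales, floors and rounds half-up", {
  init <- counts_tbl(c(g1 = 1000L, g2 = 333L, g3 = 500L, g4 = 10L),
                     sample_id = "plasmid", timepoint = 0)
  m <- tibble::tibble(guide_id = c("g1", "g2", "g3"),
                      gene = c("A", "B", "C"),
                      fc_norm = c(0.25, 1.5, 2), v = c(0.25, 1.5, -0.1))
  out_v <- export_pseudocounts(init, m, metric = "v")
  expect_equal(out_v$v[out_v$sgRNA == "g1"], 250L)
  expect_equal(out_v$v[out_v$sgRNA == "g2"], 500L)  # 499.5 rounds half-up
  expect_equal(out_v$v[out_v$sgRNA == "g3"], 0L)    # negative floors at zero
  expect_false("g4" %in% out_v$sgRNA)               # missing metric dropped

  out_c <- export_pseudocounts(init, m, metric = "fc", missing = "carry")
  expect_equal(out_c[[4]][out_c$sgRNA == "g4"], 10L)
  # MAGeCK layout: sgRNA and gene lead the table
  expect_equal(names(out_c)[1:2], c("sgRNA", "gene"))
})
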