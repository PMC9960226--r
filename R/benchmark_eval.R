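# Gene-level scoring and benchmark metrics: ROC-AUC (tie-corrected
# Mann-Whitney), dAUC (difference of rank-prefix recovery AUCs for the
# essential and non-essential sets), recall at fixed FDR and FDR at fixed
# recall, plus MAGeCK/DrugZ-compatible pseudocount export.
#
# Convention: lower score = more depleted; essential genes are the positive
# class and should rank first (ascending).

#' Aggregate guide metrics into gene-level scores
#'
#' @param metrics metrics tibble from [correct_screen()].
#' @param metric which per-guide score to aggregate: `"v"` (default) or
#'   `"fc"` (normalized fold change).
#' @param agg aggregation: `"median"` (default), `"mean"` or
#'   `"second_best"` (second-smallest guide score; the smallest for
#'   single-guide genes).
#' @param gene_ref optional [gene_reference()] used to label entities.
#' @param reliable_only use only guides flagged reliable when a gene has at
#'   least one (genes with none are flagged `any_reliable = FALSE` and
#'   scored from all their guides). Default TRUE.
#' @return `entity_scores` tibble: `entity_id`, `score`, `level = "gene"`,
#'   `label` (`essential`/`nonessential`/`other`), `n_guides`,
#'   `any_reliable`.
#' @export
gene_scores <- function(metrics, metric = c("v", "fc"),
                        agg = c("median", "mean", "second_best"),
                        gene_ref = NULL, reliable_only = TRUE) {
  metric <- match.arg(metric)
  agg <- match.arg(agg)
  col <- if (metric == "v") "v" else "fc_norm"
  m <- metrics[metrics$role == "targeting" & metrics$qc_pass &
                 !is.na(metrics[[col]]), , drop = FALSE]
  if (nrow(m) == 0) stop("no scorable guides", call. = FALSE)
  agg_fun <- switch(agg,
    median = function(x) stats::median(x),
    mean = function(x) mean(x),
    second_best = function(x) sort(x)[min(2L, length(x))])
  sp <- split(m, m$gene)
  out <- tibble::tibble(
    entity_id = names(sp),
    score = unname(vapply(sp, function(d) {
      x <- d[[col]]
      if (reliable_only && any(d$reliable)) x <- x[d$reliable]
      agg_fun(x)
    }, numeric(1))),
    level = "gene",
    n_guides = unname(vapply(sp, nrow, integer(1))),
    any_reliable = unname(vapply(sp, function(d) any(d$reliable), logical(1)))
  )
  out$label <- label_entities(out$entity_id, gene_ref)
  out[, c("entity_id", "score", "level", "label", "n_guides", "any_reliable")]
}

#' Guide-level scores (no aggregation)
#'
#' The ROC in these screens can also be drawn at guide level with gene-set
#' labels; this returns one entity per guide, labelled by its gene.
#' @inheritParams gene_scores
#' @return `entity_scores` tibble with `level = "guide"`.
#' @export
guide_scores <- function(metrics, metric = c("v", "fc"), gene_ref = NULL) {
  metric <- match.arg(metric)
  col <- if (metric == "v") "v" else "fc_norm"
  m <- metrics[metrics$role == "targeting" & metrics$qc_pass &
                 !is.na(metrics[[col]]), , drop = FALSE]
  if (nrow(m) == 0) stop("no scorable guides", call. = FALSE)
  tibble::tibble(entity_id = m$guide_id, score = m[[col]], level = "guide",
                 label = label_entities(m$gene, gene_ref),
                 n_guides = 1L, any_reliable = m$reliable)
}

label_entities <- function(genes, gene_ref) {
  if (is.null(gene_ref)) return(rep("other", length(genes)))
  stopifnot(inherits(gene_ref, "gene_reference"))
  ifelse(genes %in% gene_ref$essential, "essential",
         ifelse(genes %in% gene_ref$nonessential, "nonessential", "other"))
}

check_two_classes <- function(scores) {
  lab <- scores$label
  n_e <- sum(lab == "essential")
  n_n <- sum(lab == "nonessential")
  if (n_e < 1 || n_n < 1) {
    stop("need at least one essential and one nonessential labeled entity",
         call. = FALSE)
  }
  invisible(c(n_e, n_n))
}

#' ROC-AUC for essential-gene recovery
#'
#' Positives are the essential entities, ranked most-depleted (smallest
#' score) first. The AUC is computed as the tie-corrected Mann-Whitney
#' pair probability `P(score_ess < score_non) + P(score_ess = score_non)/2`,
#' which equals the trapezoid area under the ROC curve and is invariant to
#' any strictly monotone transform of the scores.
#'
#' @param scores an `entity_scores` tibble (`score`, `label`); unlabeled
#'   (`other`) entities are ignored.
#' @return list with `auc` and `curve` (tibble `fpr`, `tpr`).
#' @export
roc_auc <- function(scores) {
  check_two_classes(scores)
  s <- scores[scores$label %in% c("essential", "nonessential"), , drop = FALSE]
  pos <- s$label == "essential"
  r <- rank(s$score, ties.method = "average")
  n_e <- sum(pos); n_n <- sum(!pos)
  # sum of positive ranks counts pairs where essential scores HIGHER;
  # depletion means essential should score lower, so take the complement
  u_higher <- sum(r[pos]) - n_e * (n_e + 1) / 2
  auc <- 1 - u_higher / (n_e * n_n)
  ord <- order(s$score, s$entity_id)
  tpr <- cumsum(pos[ord]) / n_e
  fpr <- cumsum(!pos[ord]) / n_n
  # collapse tied-score thresholds so the curve is a function of threshold
  sc <- s$score[ord]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  list(auc = auc,
       curve = tibble::tibble(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep])))
}

#' dAUC: difference of rank-prefix recovery AUCs
#'
#' All entities (labeled or not) are ranked ascending by score (ties broken
#' by id for determinism). For each prefix fraction `t = k/N` the recovery
#' curve of a gene set is the fraction of that set found within the top `k`
#' ranks; its AUC is the trapezoid area over `t` in `[0, 1]`. `dauc =
#' auc_essential - auc_nonessential` quantifies how much earlier essential
#' genes drop out than non-essential ones.
#'
#' @param scores an `entity_scores` tibble.
#' @return list with `auc_essential`, `auc_nonessential`, `dauc`, and
#'   `curves` (tibble `t`, `recovery_essential`, `recovery_nonessential`).
#' @export
dauc <- function(scores) {
  check_two_classes(scores)
  ord <- order(scores$score, scores$entity_id)
  lab <- scores$label[ord]
  n <- length(lab)
  prefix_auc <- function(set) {
    hits <- cumsum(lab == set) / sum(lab == set)
    curve <- c(0, hits)                      # at t = 0..1 in steps of 1/n
    sum((curve[-1] + curve[-(n + 1)]) / 2) / n
  }
  auc_e <- prefix_auc("essential")
  auc_n <- prefix_auc("nonessential")
  list(auc_essential = auc_e, auc_nonessential = auc_n,
       dauc = auc_e - auc_n,
       curves = tibble::tibble(
         t = seq_len(n) / n,
         recovery_essential = cumsum(lab == "essential") /
           sum(lab == "essential"),
         recovery_nonessential = cumsum(lab == "nonessential") /
           sum(lab == "nonessential")))
}

#' Recall at fixed FDR and FDR at fixed recall
#'
#' Sweeps the rank threshold `k` over labeled entities sorted ascending by
#' score (ties broken by id). With `TP` = essential and `FP` = nonessential
#' entities in the top `k`: `FDR(k) = FP / (TP + FP)`, `recall(k) = TP /
#' n_essential`. `recall_at_fdr[q]` is the maximum recall over thresholds
#' with `FDR <= q` (0 when none qualifies); `fdr_at_recall[r]` is the
#' minimum FDR over thresholds reaching recall `>= r` (NA when unreachable).
#'
#' @param scores an `entity_scores` tibble.
#' @param fdr_levels FDR thresholds q (default 0.2).
#' @param recall_levels recall thresholds r (default 0.95, 0.975, 0.98).
#' @return list with named numeric vectors `recall_at_fdr`, `fdr_at_recall`
#'   and the full `sweep` tibble (`k`, `fdr`, `recall`).
#' @export
recall_fdr <- function(scores, fdr_levels = 0.2,
                       recall_levels = c(0.95, 0.975, 0.98)) {
  check_two_classes(scores)
  s <- scores[scores$label %in% c("essential", "nonessential"), , drop = FALSE]
  ord <- order(s$score, s$entity_id)
  pos <- (s$label == "essential")[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  fdr <- fp / (tp + fp)
  recall <- tp / sum(pos)
  recall_at_fdr <- vapply(fdr_levels, function(q) {
    ok <- fdr <= q
    if (any(ok)) max(recall[ok]) else 0
  }, numeric(1))
  fdr_at_recall <- vapply(recall_levels, function(r) {
    ok <- recall >= r
    if (any(ok)) min(fdr[ok]) else NA_real_
  }, numeric(1))
  list(recall_at_fdr = setNames(recall_at_fdr, format(fdr_levels)),
       fdr_at_recall = setNames(fdr_at_recall, format(recall_levels)),
       sweep = tibble::tibble(k = seq_along(fdr), fdr = fdr, recall = recall))
}

#' Full benchmark over one score set
#'
#' Convenience wrapper bundling [roc_auc()], [dauc()] and [recall_fdr()].
#' @inheritParams recall_fdr
#' @return list with `roc_auc`, `auc_essential`, `auc_nonessential`, `dauc`,
#'   `recall_at_fdr`, `fdr_at_recall` and the underlying curves.
#' @export
benchmark_scores <- function(scores, fdr_levels = 0.2,
                             recall_levels = c(0.95, 0.975, 0.98)) {
  r <- roc_auc(scores)
  d <- dauc(scores)
  rf <- recall_fdr(scores, fdr_levels, recall_levels)
  list(roc_auc = r$auc,
       auc_essential = d$auc_essential,
       auc_nonessential = d$auc_nonessential,
       dauc = d$dauc,
       recall_at_fdr = rf$recall_at_fdr,
       fdr_at_recall = rf$fdr_at_recall,
       roc_curve = r$curve, recovery_curves = d$curves, sweep = rf$sweep)
}

#' Export metric-scaled pseudocounts for MAGeCK / DrugZ
#'
#' Emits a MAGeCK-layout count table in which the final-sample column is the
#' initial (plasmid/reference) count multiplied by the chosen per-guide
#' metric: `count_out = round_half_up(max(0, initial * metric))`. Feeding
#' `v`-scaled counts to MAGeCK or DrugZ lets those tools rank genes on the
#' activity-corrected viability instead of the raw fold change.
#'
#' @param initial_counts reference count tibble (`guide_id`, `n_total`).
#' @param metrics metrics tibble from [correct_screen()].
#' @param metric `"fc"` (normalized fold change) or `"v"`.
#' @param missing what to do with guides lacking the metric: `"drop"`
#'   (default) or `"carry"` (emit the initial count unchanged).
#' @param sample_name name for the scaled-count column (default the metric).
#' @return tibble with columns `sgRNA`, `gene`, `initial`, `<sample_name>`.
#' @export
export_pseudocounts <- function(initial_counts, metrics,
                                metric = c("fc", "v"),
                                missing = c("drop", "carry"),
                                sample_name = NULL) {
  metric <- match.arg(metric)
  missing <- match.arg(missing)
  col <- if (metric == "v") "v" else "fc_norm"
  if (is.null(sample_name)) sample_name <- metric
  m <- metrics[, c("guide_id", "gene", col)]
  out <- dplyr::left_join(
    tibble::tibble(sgRNA = initial_counts$guide_id,
                   initial = initial_counts$n_total),
    setNames(m, c("sgRNA", "gene", ".metric")), by = "sgRNA")
  if (missing == "drop") {
    out <- out[!is.na(out$.metric), , drop = FALSE]
    scaled <- round_half_up(pmax(0, out$initial * out$.metric))
  } else {
    scaled <- ifelse(is.na(out$.metric), out$initial,
                     round_half_up(pmax(0, out$initial * out$.metric)))
  }
  res <- tibble::tibble(sgRNA = out$sgRNA, gene = out$gene,
                        initial = out$initial)
  res[[sample_name]] <- as.integer(scaled)
  res
}

# deterministic half-up rounding (round() would round half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Write a MAGeCK-format count table
#' @param tbl output of [export_pseudocounts()].
#' @param path TSV path.
#' @export
write_mageck_counts <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
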