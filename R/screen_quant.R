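# Per-guide quantification: frequencies, raw fold changes, observed reporter
# indel frequencies, representation QC, replicate concordance, moving-median
# diagnostic.

#' Compute per-guide frequencies, fold changes and observed indel frequency
#'
#' Frequencies are computed after adding a pseudocount to every guide's read
#' count in both samples (so frequencies still sum to 1 per sample and fold
#' changes stay finite for complete dropouts); `fc_raw = freq_final /
#' freq_ref`. The observed indel frequency is taken from the final sample:
#' `indel_obs = n_edited / n_coupled`, `NA` when no coupled reads exist.
#' `rpt_ref` is raw (un-pseudocounted) reads per thousand in the reference
#' sample, the quantity the representation filter acts on.
#'
#' @param ref,final count tibbles (see [count_sample()]) over the same guide
#'   universe; `ref` is the plasmid/day-0 reference, `final` the terminal
#'   timepoint.
#' @param pseudocount added to each guide's `n_total` before frequency
#'   normalization (default 0.5).
#' @return tibble with `guide_id`, `freq_ref`, `freq_final`, `rpt_ref`,
#'   `fc_raw`, `indel_obs`, `n_coupled_final`, `qc_pass` (initialized TRUE;
#'   see [apply_qc()]).
#' @export
compute_quant <- function(ref, final, pseudocount = 0.5) {
  validate_counts(ref); validate_counts(final)
  if (!setequal(ref$guide_id, final$guide_id)) {
    stop("reference and final samples must share one guide universe",
         call. = FALSE)
  }
  final <- final[match(ref$guide_id, final$guide_id), , drop = FALSE]
  if (sum(ref$n_total) == 0 || sum(final$n_total) == 0) {
    stop("sample with zero total reads", call. = FALSE)
  }
  a_ref <- ref$n_total + pseudocount
  a_fin <- final$n_total + pseudocount
  freq_ref <- a_ref / sum(a_ref)
  freq_final <- a_fin / sum(a_fin)
  tibble::tibble(
    guide_id = ref$guide_id,
    freq_ref = freq_ref,
    freq_final = freq_final,
    rpt_ref = 1000 * ref$n_total / sum(ref$n_total),
    fc_raw = freq_final / freq_ref,
    indel_obs = ifelse(final$n_coupled > 0,
                       final$n_edited / final$n_coupled, NA_real_),
    n_coupled_final = final$n_coupled,
    qc_pass = TRUE
  )
}

#' Representation QC filter
#'
#' Flags guides with fewer than `min_rpt` reads per thousand in the reference
#' sample; such guides show large replicate-to-replicate drift and are
#' excluded from all downstream fits and scores (carried in the table with
#' `qc_pass = FALSE`, never dropped). Idempotent.
#'
#' @param quant output of [compute_quant()].
#' @param min_rpt reads-per-thousand threshold (default 0.1).
#' @return `quant` with `qc_pass` set.
#' @export
apply_qc <- function(quant, min_rpt = 0.1) {
  quant$qc_pass <- quant$rpt_ref >= min_rpt
  quant
}

#' Replicate concordance (Pearson) for log2 fold change and indel frequency
#'
#' @param a,b quant tibbles for two replicates (QC applied); computed over
#'   the guides passing QC in both.
#' @param log_base base for the fold-change log transform (default 2).
#' @return list with `lfc` and `indel`, each `list(r, p, n)` from a
#'   two-tailed Pearson test, and `n_shared`.
#' @export
replicate_concordance <- function(a, b, log_base = 2) {
  shared <- intersect(a$guide_id[a$qc_pass], b$guide_id[b$qc_pass])
  if (length(shared) < 3) {
    stop("fewer than 3 shared QC-passing guides", call. = FALSE)
  }
  ia <- match(shared, a$guide_id); ib <- match(shared, b$guide_id)
  pearson <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3) return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
  }
  list(
    lfc = pearson(log(a$fc_raw[ia], log_base), log(b$fc_raw[ib], log_base)),
    indel = pearson(a$indel_obs[ia], b$indel_obs[ib]),
    n_shared = length(shared)
  )
}

#' Average quant tables across replicates
#'
#' Fold changes and observed indel frequencies of replicates are averaged at
#' the metric level; a guide passes QC only if it passes in every replicate.
#'
#' @param quants list of quant tibbles over the same guide universe.
#' @return one quant tibble of the same shape.
#' @export
average_quants <- function(quants) {
  stopifnot(length(quants) >= 1)
  base <- quants[[1]]
  if (length(quants) == 1) return(base)
  for (q in quants[-1]) {
    if (!setequal(q$guide_id, base$guide_id)) {
      stop("replicates must share one guide universe", call. = FALSE)
    }
  }
  aligned <- lapply(quants, function(q) q[match(base$guide_id, q$guide_id), ])
  pick <- function(col) rowMeans(sapply(aligned, `[[`, col), na.rm = TRUE)
  out <- base
  for (col in c("freq_ref", "freq_final", "rpt_ref", "fc_raw", "indel_obs")) {
    out[[col]] <- pick(col)
  }
  out$indel_obs[is.nan(out$indel_obs)] <- NA_real_
  out$qc_pass <- Reduce(`&`, lapply(aligned, `[[`, "qc_pass"))
  out
}

#' Moving median over the k nearest x-neighbors
#'
#' For each point i, the median of `y` over the `k` points (self included)
#' with the smallest `|x_j - x_i|` — the diagnostic used to visualize how a
#' score drifts with guide activity.
#'
#' @param x,y numeric vectors of equal length `n >= k`.
#' @param k neighborhood size (default 20).
#' @return numeric vector of length `n`, in the original point order.
#' @export
moving_median <- function(x, y, k = 20) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < k) stop("need at least k points", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  res <- numeric(n)
  for (i in seq_len(n)) {
    # the k nearest neighbors in x form a contiguous window containing i in
    # sorted order; scan the <= k candidate windows for the tightest one
    lo_min <- max(1L, i - k + 1L)
    lo_max <- min(i, n - k + 1L)
    best_lo <- lo_min
    best_span <- Inf
    for (lo in lo_min:lo_max) {
      hi <- lo + k - 1L
      span <- max(xs[i] - xs[lo], xs[hi] - xs[i])
      if (span < best_span) {
        best_span <- span
        best_lo <- lo
      }
    }
    res[i] <- stats::median(ys[best_lo:(best_lo + k - 1L)])
  }
  out <- numeric(n)
  out[o] <- res
  out
}

#' Write / read a quant table (TSV)
#' @param quant a quant tibble.
#' @param path TSV path.
#' @export
write_quant <- function(quant, path) {
  utils::write.table(as.data.frame(quant), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant
#' @export
read_quant <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
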