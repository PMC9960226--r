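# Coupled-editing dropout screen simulator.
#
# Model: a cell carrying guide g edits its target (and, faithfully, its
# reporter) with probability X_true[g]. An edited cell's relative terminal
# abundance is v_eff = v_true(gene) * (1 + s) for targeting guides and
# (1 + s) for negative controls, where s (ddr_slope) is the mild fitness
# cost of Cas9 cutting itself. Growth is a single terminal multiplier, so
#   fc_expected = (1 - X) + X * v_eff
# and among surviving cells P(target edited) = X * v_eff / fc_expected.
# Two decoupling processes degrade the reporter readout:
#  * coupling_fidelity (kappa): with prob 1 - kappa a cell's reporter edit
#    state is drawn independently, Bernoulli(X) — undetectable in reads, so
#    indel_obs_expected = kappa * X * v_eff / fc + (1 - kappa) * X;
#  * swap_rate: fraction of reads whose reporter derives from a different
#    cassette (template switching / PCR chimeras). These carry another
#    guide's protospacer, are detectable, and are excluded from indel stats.

#' Simulator configuration for a reporter-coupled dropout screen
#'
#' Defaults emulate the screens the method was developed on: per-guide
#' activity spread over most of the unit interval (unoptimized tiling-style
#' guides), 94% cell-level reporter/target coupling, ~80% of reads with a
#' correctly paired reporter, a mild DNA-damage-response fitness cost of
#' cutting (slope -0.1), and log-normal library representation with
#' `sdlog = 0.43` (about 89% of guides within twofold of the median).
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per targeted gene.
#' @param n_controls number of negative-control guides (active cutters with
#'   no gene-level fitness effect, e.g. safe-harbor/neutral-gene guides).
#' @param essential_frac fraction of genes drawn as essential.
#' @param v_essential range (min, max) of true viability v for essential
#'   genes; a single number fixes v exactly.
#' @param v_neutral true viability of neutral genes (default 1).
#' @param x_range range of per-guide true editing activity X_true,
#'   drawn uniformly.
#' @param coupling_fidelity kappa in `[0,1]`: probability that a cell's
#'   reporter edit state equals its target state (default 0.94).
#' @param swap_rate fraction of reads whose reporter belongs to a different
#'   cassette (default 0.2).
#' @param ddr_slope s: relative viability of an edited neutral cell is
#'   `1 + s` (default -0.1).
#' @param abundance_sdlog sdlog of log-normal initial guide abundance.
#' @param read_depth reads per sample.
#' @param seq_error_rate iid per-base substitution error rate for emitted
#'   FASTQ.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 100,
                       guides_per_gene = 4,
                       n_controls = 100,
                       essential_frac = 0.2,
                       v_essential = c(0.1, 0.3),
                       v_neutral = 1,
                       x_range = c(0.05, 0.95),
                       coupling_fidelity = 0.94,
                       swap_rate = 0.2,
                       ddr_slope = -0.1,
                       abundance_sdlog = 0.43,
                       read_depth = 2e6,
                       seq_error_rate = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_controls = as.integer(n_controls),
              essential_frac = essential_frac,
              v_essential = rep_len(v_essential, 2L),
              v_neutral = v_neutral,
              x_range = rep_len(x_range, 2L),
              coupling_fidelity = coupling_fidelity,
              swap_rate = swap_rate,
              ddr_slope = ddr_slope,
              abundance_sdlog = abundance_sdlog,
              read_depth = read_depth,
              seq_error_rate = seq_error_rate,
              seed = as.integer(seed))
  probs <- c(essential_frac = cfg$essential_frac,
             coupling_fidelity = cfg$coupling_fidelity,
             swap_rate = cfg$swap_rate,
             seq_error_rate = cfg$seq_error_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities out of [0,1]: ", paste(names(probs)[bad], collapse = ", "),
         call. = FALSE)
  }
  if (cfg$read_depth <= 0) stop("read_depth must be > 0", call. = FALSE)
  if (any(cfg$x_range < 0) || any(cfg$x_range > 1) ||
      cfg$x_range[1] > cfg$x_range[2]) {
    stop("x_range must be an increasing range within [0,1]", call. = FALSE)
  }
  if (cfg$n_genes < 0 || cfg$guides_per_gene < 1 || cfg$n_controls < 0) {
    stop("invalid library dimensions", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Draw the ground truth of a simulated screen
#'
#' Deterministic given `config$seed`. Closed-form expected per-guide
#' quantities are populated alongside the draws:
#' `fc_expected = (1 - X) + X * v_eff` and
#' `indel_obs_expected = kappa * X * v_eff / fc + (1 - kappa) * X`.
#'
#' @param config a [sim_config()].
#' @return a `sim_truth` list with elements `genes` (gene, class, v_true),
#'   `guides` (guide_id, gene, role, v_true, x_true, v_eff, fc_expected,
#'   indel_obs_expected, abundance0) and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ess <- round(config$n_genes * config$essential_frac)
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  cls <- rep("neutral", config$n_genes)
  if (n_ess > 0) cls[sample.int(config$n_genes, n_ess)] <- "essential"
  v_gene <- ifelse(cls == "essential",
                   runif(config$n_genes, config$v_essential[1],
                         config$v_essential[2]),
                   config$v_neutral)
  genes <- tibble::tibble(gene = gene_ids, class = cls, v_true = v_gene)

  n_t <- config$n_genes * config$guides_per_gene
  guides <- tibble::tibble(
    guide_id = c(sprintf("sg%05d", seq_len(n_t)),
                 sprintf("ctrl%04d", seq_len(config$n_controls))),
    gene = c(rep(gene_ids, each = config$guides_per_gene),
             rep("NEG_CTRL", config$n_controls)),
    role = rep(c("targeting", "negative_control"),
               c(n_t, config$n_controls))
  )
  guides$v_true <- ifelse(guides$role == "targeting",
                          v_gene[match(guides$gene, gene_ids)], 1)
  n_all <- nrow(guides)
  guides$x_true <- runif(n_all, config$x_range[1], config$x_range[2])
  guides$v_eff <- guides$v_true * (1 + config$ddr_slope)
  guides$fc_expected <- (1 - guides$x_true) + guides$x_true * guides$v_eff
  kap <- config$coupling_fidelity
  guides$indel_obs_expected <-
    kap * guides$x_true * guides$v_eff / guides$fc_expected +
    (1 - kap) * guides$x_true
  guides$abundance0 <- rlnorm(n_all, 0, config$abundance_sdlog)

  structure(list(genes = genes, guides = guides, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$guides), " guides (",
      sum(x$guides$role == "negative_control"), " controls), ",
      nrow(x$genes), " genes, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Sample reference and final count tables from simulated truth
#'
#' Reference counts are multinomial over initial abundances; final counts are
#' multinomial over `abundance0 * fc_expected` (renormalized). Per guide,
#' coupled reads are binomial with rate `1 - swap_rate` and edited-among-
#' coupled reads binomial with rate `indel_obs_expected` (zero in the
#' reference sample — editing has not occurred at the reference timepoint).
#'
#' @param truth a `sim_truth`.
#' @param config optional [sim_config()] override (defaults to
#'   `truth$config`).
#' @param depth optional read depth override.
#' @return list with `ref` and `final` count tibbles (`sample_id`,
#'   `timepoint_days`, `guide_id`, `n_total`, `n_coupled`, `n_edited`).
#' @export
sample_counts <- function(truth, config = truth$config, depth = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(depth)) depth <- config$read_depth
  set.seed(config$seed + 1L)
  g <- truth$guides
  p_ref <- g$abundance0 / sum(g$abundance0)
  w_fin <- g$abundance0 * g$fc_expected
  p_fin <- w_fin / sum(w_fin)
  draw <- function(p, depth) {
    if (depth == 0) rep(0L, length(p)) else as.integer(rmultinom(1, depth, p))
  }
  n_ref <- draw(p_ref, depth)
  n_fin <- draw(p_fin, depth)
  couple_rate <- 1 - config$swap_rate
  make_tbl <- function(sample_id, timepoint, n_total, edited_rate) {
    n_coupled <- rbinom(length(n_total), n_total, couple_rate)
    n_edited <- rbinom(length(n_total), n_coupled, edited_rate)
    tibble::tibble(sample_id = sample_id, timepoint_days = timepoint,
                   guide_id = g$guide_id, n_total = n_total,
                   n_coupled = n_coupled, n_edited = n_edited)
  }
  list(ref = make_tbl("ref", 0, n_ref, 0),
       final = make_tbl("final", 21, n_fin, g$indel_obs_expected))
}

# fixed flanks shared by every simulated reporter; the classifier sees these
# as the constant context around the variable protospacer+PAM core.
SIM_LEFT_FLANK <- "TGGAGGCTTGCTGA"
SIM_RIGHT_FLANK <- "GTTTAAGAGCTATG"
SIM_R2_ANCHOR <- "GGACGAAACACCG"
SIM_R2_SCAFFOLD <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTG"

#' Build a guide-reporter library matching simulated truth
#'
#' Random distinct 20-nt spacers are embedded as `flank + spacer + PAM(NGG) +
#' flank`; the SpCas9 blunt cut falls between protospacer positions 17 and
#' 18, so `cut_offset = nchar(left flank) + 17`.
#'
#' @param truth a `sim_truth`.
#' @return a validated `guide_library` aligned row-by-row with
#'   `truth$guides`.
#' @export
sim_library <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$config$seed + 2L)
  n <- nrow(truth$guides)
  spacers <- random_spacers(n)
  pam <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), "GG")
  reporter <- paste0(SIM_LEFT_FLANK, spacers, pam, SIM_RIGHT_FLANK)
  guide_library(tibble::tibble(
    guide_id = truth$guides$guide_id,
    gene = truth$guides$gene,
    spacer = spacers,
    reporter_seq = reporter,
    cut_offset = nchar(SIM_LEFT_FLANK) + 17L,
    role = truth$guides$role
  ))
}

# distinct random 20-mers; re-draws on the (rare) collision or on accidental
# matches inside the fixed flank context
random_spacers <- function(n, len = 20L) {
  draw <- function(m) {
    vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  }
  out <- draw(n)
  for (iter in 1:20) {
    bad <- duplicated(out) |
      vapply(out, function(s) {
        ctx <- paste0(SIM_LEFT_FLANK, s, "AGG", SIM_RIGHT_FLANK)
        length(str_find_all(ctx, s)) + length(str_find_all(ctx, revcomp(s))) != 1
      }, logical(1))
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  out
}

#' Emit paired FASTQ files for a simulated sample
#'
#' Read 2 carries `anchor + spacer + scaffold`; read 1 carries the reporter.
#' Per guide, the emitted composition follows the supplied count rows
#' exactly: `n_coupled` of `n_total` reads keep their own reporter
#' (`n_edited` of those with a 1-3 nt deletion at the cut site), and the
#' remaining reads carry a random other guide's reporter (cassette swap).
#' iid substitution errors are applied at `config$seq_error_rate`.
#'
#' @param truth a `sim_truth`.
#' @param counts one count tibble (e.g. `sample_counts(...)$final`), possibly
#'   down-scaled via `n_pairs`.
#' @param library the matching [sim_library()] (or compatible
#'   `guide_library`).
#' @param config optional [sim_config()] override.
#' @param dir output directory (created if needed).
#' @param n_pairs optional total read pairs; guides are down-sampled
#'   proportionally to `counts$n_total`.
#' @param read_len read length (default 100); must fit the templates.
#' @param prefix file name prefix.
#' @return list with `r1`, `r2` (FASTQ paths) and `truth_table`, a per-read
#'   tibble (`read_id`, `guide_id`, `coupled`, `edited`).
#' @export
emit_fastq <- function(truth, counts, library, config = truth$config,
                       dir = tempdir(), n_pairs = NULL, read_len = 100L,
                       prefix = "sim") {
  stopifnot(inherits(truth, "sim_truth"), inherits(library, "guide_library"))
  set.seed(config$seed + 3L)
  lib <- as.data.frame(library)
  counts <- counts[counts$n_total > 0, , drop = FALSE]
  if (!is.null(n_pairs)) {
    tot <- sum(counts$n_total)
    if (n_pairs > tot) stop("n_pairs exceeds available counts", call. = FALSE)
    keep <- as.integer(rmultinom(1, n_pairs, counts$n_total / tot))
    p_coupled <- ifelse(counts$n_total > 0,
                        counts$n_coupled / counts$n_total, 0)
    p_edited <- ifelse(counts$n_coupled > 0,
                       counts$n_edited / pmax(counts$n_coupled, 1), 0)
    counts$n_coupled <- rbinom(nrow(counts), keep, p_coupled)
    counts$n_edited <- rbinom(nrow(counts), counts$n_coupled, p_edited)
    counts$n_total <- keep
    counts <- counts[counts$n_total > 0, , drop = FALSE]
  }
  idx <- match(counts$guide_id, lib$guide_id)
  if (anyNA(idx)) stop("counts contain guides absent from library", call. = FALSE)
  need <- max(max(nchar(lib$reporter_seq)),
              nchar(SIM_R2_ANCHOR) + max(nchar(lib$spacer)))
  if (read_len < need) {
    stop("read length ", read_len, " shorter than the required template (",
         need, " nt)", call. = FALSE)
  }

  per_read <- tibble::tibble(
    guide_id = rep(counts$guide_id, counts$n_total),
    lib_row = rep(idx, counts$n_total),
    coupled = unlist(lapply(seq_len(nrow(counts)), function(i) {
      n <- counts$n_total[i]
      c(rep(TRUE, counts$n_coupled[i]), rep(FALSE, n - counts$n_coupled[i]))
    })),
    edited = unlist(lapply(seq_len(nrow(counts)), function(i) {
      c(rep(TRUE, counts$n_edited[i]),
        rep(FALSE, counts$n_coupled[i] - counts$n_edited[i]),
        rep(FALSE, counts$n_total[i] - counts$n_coupled[i]))
    }))
  )
  n_reads <- nrow(per_read)
  ord <- sample.int(n_reads)  # shuffle so pairs are not grouped by guide
  per_read <- per_read[ord, ]
  per_read$read_id <- sprintf("read%07d", seq_len(n_reads))

  # reporter (read 1): own reporter, edited gets a 1-3 nt deletion at the cut;
  # swapped reads take another cassette's reporter unchanged
  rep_seq <- lib$reporter_seq[per_read$lib_row]
  cut <- lib$cut_offset[per_read$lib_row]
  ed <- which(per_read$edited & per_read$coupled)
  if (length(ed) > 0) {
    del <- sample(1:3, length(ed), replace = TRUE)
    shift <- sample(0:1, length(ed), replace = TRUE)  # deletion may start 1 nt 5' of the cut
    rep_seq[ed] <- paste0(substr(rep_seq[ed], 1L, cut[ed] - shift),
                          substring(rep_seq[ed], cut[ed] - shift + del + 1L))
  }
  sw <- which(!per_read$coupled)
  if (length(sw) > 0) {
    other <- vapply(per_read$lib_row[sw], function(i) {
      j <- sample.int(nrow(lib), 1L)
      while (j == i && nrow(lib) > 1) j <- sample.int(nrow(lib), 1L)
      j
    }, integer(1))
    rep_seq[sw] <- lib$reporter_seq[other]
  }
  r1 <- pad_reads(rep_seq, read_len)
  r2 <- pad_reads(paste0(SIM_R2_ANCHOR, lib$spacer[per_read$lib_row],
                         SIM_R2_SCAFFOLD), read_len)
  if (config$seq_error_rate > 0) {
    r1 <- add_substitutions(r1, config$seq_error_rate)
    r2 <- add_substitutions(r2, config$seq_error_rate)
  }

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  write_fastq(per_read$read_id, r1, p1)
  write_fastq(per_read$read_id, r2, p2)
  list(r1 = p1, r2 = p2,
       truth_table = per_read[, c("read_id", "guide_id", "coupled", "edited")])
}

pad_reads <- function(seqs, read_len) {
  over <- nchar(seqs) > read_len
  seqs[over] <- substr(seqs[over], 1L, read_len)
  pad_n <- pmax(0L, read_len - nchar(seqs))
  filler <- strrep("A", max(pad_n, 0L))
  paste0(seqs, substr(rep(filler, length(seqs)), 1L, pad_n))
}

add_substitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(ids) > 0) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con, sep = "\n")
  }
  invisible(path)
}

#' Noiseless quant table from simulated truth
#'
#' Bypasses read sampling: `fc_raw` and `indel_obs` are set to their
#' closed-form expected values. Feeding this into [correct_screen()] must
#' recover `v_true` and `x_true` exactly (to numerical precision) when
#' `coupling_fidelity = 1`, the algebraic identity at the heart of the
#' correction.
#'
#' @param truth a `sim_truth`.
#' @return a quant tibble compatible with [correct_screen()].
#' @export
expected_quant <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$guides
  tibble::tibble(
    guide_id = g$guide_id,
    freq_ref = g$abundance0 / sum(g$abundance0),
    freq_final = g$abundance0 * g$fc_expected /
      sum(g$abundance0 * g$fc_expected),
    rpt_ref = 1000 * g$abundance0 / sum(g$abundance0),
    fc_raw = g$fc_expected,
    indel_obs = g$indel_obs_expected,
    n_coupled_final = NA_integer_,
    qc_pass = TRUE
  )
}
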