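# Shared fixtures: a tiny hand-built guide library and convenience wrappers
# around the simulator. All fixtures are built in code at test time.

FLANK_L <- "TGGAGGCTTGCTGA"   # matches the simulator's fixed reporter flanks
FLANK_R <- "GTTTAAGAGCTATG"

make_reporter <- function(spacer, pam = "TGG") {
  paste0(FLANK_L, spacer, pam, FLANK_R)
}

# four well-separated spacers; cut between protospacer positions 17|18
tiny_library <- function() {
  spacers <- c(
    g1 = "ACGTACGTACGTACGTACGT",
    g2 = "TTTTCCCCGGGGAAAATTTT",
    g3 = "GATCGATCGATCGATCGATC",
    g4 = "CCAACCAAGGTTGGTTCCAA"
  )
  guide_library(tibble::tibble(
    guide_id = names(spacers),
    gene = c("GENEA", "GENEA", "GENEB", "NEG"),
    spacer = unname(spacers),
    reporter_seq = make_reporter(unname(spacers)),
    cut_offset = nchar(FLANK_L) + 17L,
    role = c("targeting", "targeting", "targeting", "negative_control")
  ))
}

# counts table from named vectors (n_coupled defaults to n_total, n_edited 0)
counts_tbl <- function(n_total, n_coupled = n_total, n_edited = 0 * n_total,
                       sample_id = "s", timepoint = 21) {
  tibble::tibble(sample_id = sample_id, timepoint_days = timepoint,
                 guide_id = names(n_total), n_total = unname(n_total),
                 n_coupled = unname(n_coupled), n_edited = unname(n_edited))
}

# simulated screen (counts level) with its correction result bundled
run_sim_screen <- function(seed, ..., min_rpt = 0.1) {
  cfg <- sim_config(..., seed = seed)
  truth <- simulate_truth(cfg)
  cnt <- sample_counts(truth)
  quant <- apply_qc(compute_quant(cnt$ref, cnt$final), min_rpt = min_rpt)
  res <- correct_screen(quant, truth$guides[, c("guide_id", "gene", "role")])
  list(config = cfg, truth = truth, counts = cnt, quant = quant,
       metrics = res$metrics, fit = res$fit)
}

# delete `del` bases starting at 0-based position `at` (default: the cut)
delete_at <- function(seq, at, del) {
  paste0(substr(seq, 1, at), substring(seq, at + del + 1))
}
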