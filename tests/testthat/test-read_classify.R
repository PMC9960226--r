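# Guide assignment, reporter classification, and FASTQ counting.

make_read2 <- function(spacer, anchor = "GGACGAAACACCG") {
  paste0("TTTCTT", anchor, spacer, "GTTTTAGAGCTAGAAATAGCAAG")
}

test_that("assign_guide handles exact, 1-mismatch, tie and missing-anchor reads", {
  lib <- tiny_library()
  p <- classify_params()

  expect_equal(assign_guide(make_read2(lib$spacer[2]), lib, p), "g2")

  mm1 <- lib$spacer[3]
  substr(mm1, 5, 5) <- if (substr(mm1, 5, 5) == "A") "C" else "A"
  expect_equal(assign_guide(make_read2(mm1), lib, p), "g3")

  # two mismatches exceed the default tolerance
  mm2 <- mm1
  substr(mm2, 9, 9) <- if (substr(mm2, 9, 9) == "G") "T" else "G"
  expect_true(is.na(assign_guide(make_read2(mm2), lib, p)))

  # a 20-mer equidistant from two spacers is an ambiguous tie
  tie_lib <- guide_library(tibble::tibble(
    guide_id = c("a", "b"),
    gene = c("X", "Y"),
    spacer = c("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAC"),
    reporter_seq = make_reporter(c("AAAAAAAAAAAAAAAAAAAA",
                                   "AAAAAAAAAAAAAAAAAAAC")),
    cut_offset = nchar(FLANK_L) + 17L,
    role = "targeting"
  ))
  halfway <- "AAAAAAAAAAAAAAAAAAAG"  # 1 mismatch from both
  expect_true(is.na(assign_guide(make_read2(halfway), tie_lib, p)))

  expect_true(is.na(assign_guide("ACGTACGTACGTACGTACGTACGTACGT", lib, p)))
})

test_that("classify_reporter calls coupled/edited states per the indel window", {
  lib <- tiny_library()
  p <- classify_params()
  rep1 <- lib$reporter_seq[1]
  cut <- lib$cut_offset[1]

  # pristine reporter: coupled, unedited
  cls <- classify_reporter(rep1, "g1", lib, p)
  expect_equal(cls$coupling, "coupled")
  expect_equal(cls$edit, "unedited")

  # 2-nt deletion at the cut: coupled, edited
  del2 <- delete_at(rep1, cut, 2)
  cls <- classify_reporter(del2, "g1", lib, p)
  expect_equal(cls$coupling, "coupled")
  expect_equal(cls$edit, "edited")

  # 1-nt insertion at the cut: edited
  ins1 <- paste0(substr(rep1, 1, cut), "T", substring(rep1, cut + 1))
  cls <- classify_reporter(ins1, "g1", lib, p)
  expect_equal(cls$edit, "edited")

  # substitutions only: unedited, not discarded
  sub1 <- rep1
  substr(sub1, cut, cut) <- if (substr(sub1, cut, cut) == "A") "G" else "A"
  cls <- classify_reporter(sub1, "g1", lib, p)
  expect_equal(cls$coupling, "coupled")
  expect_equal(cls$edit, "unedited")

  # deletion inside the core but left of the +/-10 nt cut window: unedited
  far <- delete_at(rep1, nchar(FLANK_L) + 1L, 1)  # 2nd protospacer base
  cls <- classify_reporter(far, "g1", lib, p)
  expect_equal(cls$coupling, "coupled")
  expect_equal(cls$edit, "unedited")

  # another guide's reporter under g1's identity: uncoupled
  cls <- classify_reporter(lib$reporter_seq[3], "g1", lib, p)
  expect_equal(cls$coupling, "uncoupled")
  expect_equal(cls$edit, "unclassified")

  # unassigned read stays indeterminate
  cls <- classify_reporter(rep1, NA_character_, lib, p)
  expect_equal(cls$coupling, "indeterminate")
  expect_equal(cls$edit, "unclassified")

  # flanks unrecognizable: indeterminate
  cls <- classify_reporter(strrep("A", 60), "g1", lib, p)
  expect_equal(cls$coupling, "indeterminate")
})

test_that("count_sample matches the simulator's per-read truth at zero error", {
  cfg <- sim_config(n_genes = 8, guides_per_gene = 2, n_controls = 4,
                    read_depth = 4000, seq_error_rate = 0, seed = 17)
  truth <- simulate_truth(cfg)
  lib <- sim_library(truth)
  cnt <- sample_counts(truth)
  fq <- emit_fastq(truth, cnt$final, lib, n_pairs = 1500,
                   dir = withr::local_tempdir())
  res <- count_sample(fq$r1, fq$r2, lib, sample_id = "final",
                      timepoint_days = 21)

  tt <- fq$truth_table
  agg <- tt %>%
    dplyr::group_by(guide_id) %>%
    dplyr::summarise(n_total = dplyr::n(), n_coupled = sum(coupled),
                     n_edited = sum(coupled & edited), .groups = "drop")
  merged <- dplyr::left_join(agg, res$counts, by = "guide_id",
                             suffix = c(".true", ".obs"))
  expect_equal(merged$n_total.obs, merged$n_total.true)
  expect_equal(merged$n_coupled.obs, merged$n_coupled.true)
  expect_equal(merged$n_edited.obs, merged$n_edited.true)

  # count conservation: assigned + unassigned = pairs
  expect_equal(sum(res$counts$n_total) + res$report$n_unassigned,
               res$report$n_pairs)
  # SampleCounts invariant
  expect_true(all(res$counts$n_edited <= res$counts$n_coupled))
  expect_true(all(res$counts$n_coupled <= res$counts$n_total))
})

test_that("classification degrades gracefully with sequencing error", {
  base <- list(n_genes = 6, guides_per_gene = 2, n_controls = 3,
               read_depth = 2000)
  acc <- vapply(c(0, 0.01, 0.03), function(err) {
    cfg <- do.call(sim_config, c(base, seq_error_rate = err, seed = 23))
    truth <- simulate_truth(cfg)
    lib <- sim_library(truth)
    cnt <- sample_counts(truth)
    fq <- emit_fastq(truth, cnt$final, lib, n_pairs = 600,
                     dir = withr::local_tempdir())
    gid <- assign_guide(
      as.character(Biostrings::readDNAStringSet(fq$r2, format = "fastq")),
      lib)
    cls <- classify_reporter(
      as.character(Biostrings::readDNAStringSet(fq$r1, format = "fastq")),
      gid, lib)
    tt <- fq$truth_table
    pred_coupled <- cls$coupling == "coupled"
    pred_edited <- cls$edit == "edited"
    ok <- !is.na(gid) & gid == tt$guide_id & pred_coupled == tt$coupled &
      pred_edited == (tt$coupled & tt$edited)
    mean(ok)  # unassigned / misclassified reads count as errors
  }, numeric(1))
  expect_equal(acc[1], 1)                  # exact at zero error
  expect_true(all(diff(acc) <= 1e-9))      # monotone non-increasing
  expect_gt(acc[2], 0.95)
})

test_that("count_sample rejects mate mismatches and survives empty files", {
  lib <- tiny_library()
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.fastq"); f2 <- file.path(dir, "r2.fastq")

  writeLines(character(0), f1); writeLines(character(0), f2)
  res <- count_sample(f1, f2, lib)
  expect_equal(sum(res$counts$n_total), 0L)
  expect_equal(nrow(res$counts), nrow(lib))

  writeLines(c("@a", lib$reporter_seq[1], "+", strrep("I", nchar(lib$reporter_seq[1]))), f1)
  writeLines(character(0), f2)
  expect_error(count_sample(f1, f2, lib), "mate count mismatch")
})

test_that("count tables round-trip through TSV and enforce invariants", {
  cnt <- counts_tbl(c(g1 = 10L, g2 = 5L), n_coupled = c(8L, 5L),
                    n_edited = c(3L, 0L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cnt, path)
  back <- read_counts(path)
  expect_equal(back$n_coupled, cnt$n_coupled)
  bad <- cnt; bad$n_edited[1] <- 9L  # edited > coupled
  write_counts(bad, path)
  expect_error(read_counts(path), "invariant")
})
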