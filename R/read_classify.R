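# Paired-end read classification: guide assignment (read 2), reporter
# coupling and edit status (read 1). This is the sgRNA counter / reporter
# indel detector behind count_sample().

#' Classification parameters
#'
#' @param anchor fixed sequence immediately 5' of the spacer in read 2
#'   (default matches the simulator's U6-style cassette end).
#' @param max_mismatch maximum Hamming distance for spacer assignment
#'   (default 1); equidistant ties are left unassigned.
#' @param flank_len length of the fixed reporter flanks used to locate the
#'   variable core in read 1 (default 12).
#' @param flank_mm mismatches tolerated per flank (default 2).
#' @param window indel-window half-width w around the cut site (default 10):
#'   an indel whose footprint intersects `[cut_offset - w, cut_offset + w)`
#'   calls the read edited.
#' @param couple_max_dist edit distance to the guide's own reporter core at
#'   or below which the read is accepted as coupled without scanning other
#'   guides (default 6; a cassette swap lies far beyond this for any
#'   Hamming-separated library, a 1-3 nt indel plus sequencing error well
#'   within it).
#' @param gap_opening,gap_extension affine gap penalties for the global
#'   alignment of the reporter core (gap opening far above the mismatch
#'   penalty so one indel is preferred over many substitutions).
#' @param mismatch_penalty substitution penalty (match score is +1).
#' @param min_mean_q optional mean base-quality threshold; `NULL` (default)
#'   disables quality filtering.
#' @return a `classify_params` list.
#' @export
classify_params <- function(anchor = "GGACGAAACACCG",
                            max_mismatch = 1L,
                            flank_len = 12L,
                            flank_mm = 2L,
                            window = 10L,
                            couple_max_dist = 6L,
                            gap_opening = 10,
                            gap_extension = 0.5,
                            mismatch_penalty = -1,
                            min_mean_q = NULL) {
  structure(list(anchor = toupper(anchor), max_mismatch = as.integer(max_mismatch),
                 flank_len = as.integer(flank_len), flank_mm = as.integer(flank_mm),
                 window = as.integer(window),
                 couple_max_dist = as.integer(couple_max_dist),
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 mismatch_penalty = mismatch_penalty, min_mean_q = min_mean_q),
            class = "classify_params")
}

#' Assign read-2 sequences to library guides by spacer match
#'
#' Extracts the 20-mer following the cassette anchor and matches it against
#' the library spacers, first exactly, then within `max_mismatch` Hamming
#' distance. A read whose best hit is shared by two or more spacers
#' (ambiguous tie), or whose anchor is absent, is left unassigned (`NA`).
#'
#' @param reads2 character vector of read-2 sequences.
#' @param library a `guide_library`.
#' @param params a [classify_params()].
#' @return character vector of `guide_id` (NA = unassigned), same length as
#'   `reads2`.
#' @export
assign_guide <- function(reads2, library, params = classify_params()) {
  reads2 <- toupper(as.character(reads2))
  spacers <- library$spacer
  slen <- unique(nchar(spacers))
  if (length(slen) != 1) stop("library spacers must share one length", call. = FALSE)
  lookup <- setNames(library$guide_id, spacers)

  pos <- regexpr(params$anchor, reads2, fixed = TRUE)
  miss <- which(pos <= 0)
  if (length(miss) > 0) {
    # sequencing error in the anchor: fall back to a 1-mismatch search
    anc <- Biostrings::DNAString(params$anchor)
    pos[miss] <- vapply(reads2[miss], function(r) {
      m <- Biostrings::matchPattern(anc, Biostrings::DNAString(r),
                                    max.mismatch = 1)
      if (length(m) == 1) Biostrings::start(m)[1] else -1L
    }, integer(1), USE.NAMES = FALSE)
  }
  cand <- rep(NA_character_, length(reads2))
  ok <- pos > 0
  start <- pos[ok] + nchar(params$anchor)
  cand[ok] <- substr(reads2[ok], start, start + slen - 1L)
  cand[!is.na(cand) & nchar(cand) < slen] <- NA_character_

  out <- unname(lookup[cand])
  if (params$max_mismatch > 0) {
    todo <- which(!is.na(cand) & is.na(out))
    if (length(todo) > 0) {
      sp_mat <- do.call(rbind, strsplit(spacers, "", fixed = TRUE))
      for (i in todo) {
        d <- hamming_to_all(cand[i], sp_mat)
        best <- min(d)
        if (best <= params$max_mismatch && sum(d == best) == 1) {
          out[i] <- library$guide_id[which.min(d)]
        }
      }
    }
  }
  out
}

hamming_to_all <- function(x, sp_mat) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  rowSums(sp_mat != matrix(xs, nrow(sp_mat), length(xs), byrow = TRUE))
}

#' Classify reporter reads for their assigned guides
#'
#' For each read: (1) locate the fixed reporter flanks (allowing
#' `flank_mm` mismatches each) — failure leaves the read indeterminate /
#' unclassified; (2) test coupling: a between-flank core closer (Levenshtein)
#' to a different guide's reporter core than to its own is a cassette swap,
#' `uncoupled`; (3) globally align the coupled core to its reference with
#' affine gaps and call `edited` iff an insertion or deletion footprint
#' intersects the cut-site window. Substitution-only reads are `unedited`.
#'
#' @param reads1 character vector of read-1 (reporter) sequences.
#' @param guide_ids assigned guide per read (from [assign_guide()]); NA reads
#'   come back indeterminate/unclassified.
#' @param library a `guide_library`.
#' @param params a [classify_params()].
#' @return tibble with `coupling` (`coupled`/`uncoupled`/`indeterminate`) and
#'   `edit` (`edited`/`unedited`/`unclassified`); `edit` is only
#'   `edited`/`unedited` when `coupling == "coupled"`.
#' @export
classify_reporter <- function(reads1, guide_ids, library,
                              params = classify_params()) {
  reads1 <- toupper(as.character(reads1))
  n <- length(reads1)
  stopifnot(length(guide_ids) == n)
  coupling <- rep("indeterminate", n)
  edit <- rep("unclassified", n)

  lib <- as.data.frame(library)
  geom <- reporter_geometry(lib, params)
  row_of <- setNames(seq_len(nrow(lib)), lib$guide_id)

  for (g in unique(guide_ids[!is.na(guide_ids)])) {
    ridx <- which(!is.na(guide_ids) & guide_ids == g)
    li <- row_of[[g]]
    core <- extract_cores(reads1[ridx], geom, li, params)
    found <- !is.na(core)
    # coupling: accept near-own cores outright, scan the library otherwise
    d_own <- rep(NA_integer_, length(ridx))
    d_own[found] <- as.integer(utils::adist(core[found], geom$core_ref[li]))
    near <- found & d_own <= params$couple_max_dist
    far <- found & !near
    if (any(far)) {
      d_all <- utils::adist(core[far], geom$core_ref)  # |far| x n_lib
      d_other <- if (ncol(d_all) > 1) {
        apply(d_all[, -li, drop = FALSE], 1, min)
      } else {
        rep(Inf, sum(far))
      }
      swapped <- d_other < d_own[far]
      coupling[ridx[far][swapped]] <- "uncoupled"
      coupling[ridx[far][!swapped]] <- "coupled"
    }
    coupling[ridx[near]] <- "coupled"
    # edit call on coupled reads
    cp <- which(found & coupling[ridx] == "coupled")
    if (length(cp) > 0) {
      hit <- core_edited(core[cp], geom$core_ref[li],
                         geom$win_lo[li], geom$win_hi[li], params)
      edit[ridx[cp]] <- ifelse(hit, "edited", "unedited")
    }
  }
  tibble::tibble(coupling = coupling, edit = edit)
}

# per-library-row geometry: flanks, variable core reference, and the indel
# window translated into 1-based core coordinates
reporter_geometry <- function(lib, params) {
  fl <- params$flank_len
  len <- nchar(lib$reporter_seq)
  if (any(len < 2L * fl + 1L)) {
    stop("reporter_seq shorter than twice the flank length", call. = FALSE)
  }
  left <- substr(lib$reporter_seq, 1L, fl)
  right <- substr(lib$reporter_seq, len - fl + 1L, len)
  core_ref <- substr(lib$reporter_seq, fl + 1L, len - fl)
  # cut_offset is 0-based in the reporter; the window [cut-w, cut+w) in core
  # coordinates (1-based) spans:
  win_lo <- lib$cut_offset - params$window + 1L - fl
  win_hi <- lib$cut_offset + params$window - fl
  list(left = left, right = right, core_ref = core_ref,
       win_lo = pmax(win_lo, 1L), win_hi = pmin(win_hi, nchar(core_ref)))
}

# between-flank core of each read, NA when either flank is not found.
# Exact flank hits are located vectorized; only reads failing that go
# through the per-read mismatch-tolerant search.
extract_cores <- function(reads, geom, li, params) {
  fl <- nchar(geom$left[li])
  lpos <- regexpr(geom$left[li], reads, fixed = TRUE)
  rpos <- regexpr(geom$right[li], reads, fixed = TRUE)
  s <- ifelse(lpos > 0, lpos + fl, NA_integer_)
  e <- ifelse(rpos > 0, rpos - 1L, NA_integer_)
  out <- ifelse(!is.na(s) & !is.na(e) & e >= s & rpos > lpos,
                substr(reads, s, e), NA_character_)
  todo <- which(is.na(out))
  if (length(todo) > 0 && params$flank_mm > 0) {
    out[todo] <- vapply(reads[todo], function(r) {
      sub <- Biostrings::DNAString(r)
      lm <- Biostrings::matchPattern(geom$left[li], sub,
                                     max.mismatch = params$flank_mm)
      rm_ <- Biostrings::matchPattern(geom$right[li], sub,
                                      max.mismatch = params$flank_mm)
      if (length(lm) == 0 || length(rm_) == 0) return(NA_character_)
      s1 <- Biostrings::end(lm)[1] + 1L
      e1 <- Biostrings::start(rm_)[length(rm_)] - 1L
      if (e1 < s1) return(NA_character_)
      substr(r, s1, e1)
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

# TRUE per read iff an indel footprint intersects the window [lo, hi]
# (1-based, inclusive, in core-reference coordinates). Fast path works on
# the flat indel ranges of the whole alignment set; reads with mixed or
# terminal gaps (which indel() does not report) fall back to a column walk
# of the aligned strings.
core_edited <- function(cores, core_ref, lo, hi, params) {
  out <- logical(length(cores))
  todo <- which(cores != core_ref)  # identical cores are unedited, skip
  if (length(todo) == 0) return(out)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = params$mismatch_penalty, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(cores[todo]), Biostrings::DNAString(core_ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  ind <- Biostrings::indel(aln)
  insL <- Biostrings::insertion(ind)  # ranges in pattern coordinates
  delL <- Biostrings::deletion(ind)   # ranges in subject coordinates
  n_ins <- S4Vectors::elementNROWS(insL)
  n_del <- S4Vectors::elementNROWS(delL)
  m <- length(todo)
  hit <- rep(NA, m)  # NA = undecided, needs fallback

  simple <- !(n_ins > 0 & n_del > 0)
  # deletions: footprint is the subject range itself
  if (any(simple & n_del > 0)) {
    fd <- unlist(delL)
    grp <- rep(seq_len(m), n_del)
    keep <- simple[grp]
    dhit <- IRanges::start(fd) <= hi & IRanges::end(fd) >= lo
    agg <- tapply(dhit[keep], grp[keep], any)
    hit[as.integer(names(agg))] <- unname(agg)
  }
  # insertions only: convert pattern starts to the subject junction they
  # fall into; an insertion between subject j and j+1 intersects the window
  # iff lo - 1 <= j <= hi
  if (any(simple & n_ins > 0)) {
    fi <- unlist(insL)
    grp <- rep(seq_len(m), n_ins)
    keep <- simple[grp] & n_del[grp] == 0
    if (any(keep)) {
      st <- IRanges::start(fi)
      w <- IRanges::width(fi)
      prior <- st
      for (g in unique(grp[keep])) {
        sel <- which(grp == g & keep)
        cw <- cumsum(c(0, w[sel][-length(sel)]))
        j <- st[sel] - 1L - cw
        hit[g] <- any(j >= lo - 1L & j <= hi)
      }
    }
  }
  # length change that indel() failed to report = terminal gap; substitution-
  # only reads have equal lengths and no ranges
  plain <- is.na(hit) & simple & n_ins == 0 & n_del == 0
  same_len <- nchar(cores[todo]) == nchar(core_ref)
  hit[plain & same_len] <- FALSE
  walk <- which(is.na(hit))
  if (length(walk) > 0) {
    ap <- as.character(Biostrings::alignedPattern(aln[walk]))
    as_ <- as.character(Biostrings::alignedSubject(aln[walk]))
    hit[walk] <- mapply(function(p, s) {
      pc <- strsplit(p, "", fixed = TRUE)[[1]]
      sc <- strsplit(s, "", fixed = TRUE)[[1]]
      spos <- cumsum(sc != "-")  # subject coordinate at each column
      any(pc == "-" & spos >= lo & spos <= hi) ||
        any(sc == "-" & spos >= lo - 1L & spos <= hi)
    }, ap, as_, USE.NAMES = FALSE)
  }
  out[todo] <- hit
  out
}

#' Count a paired-FASTQ sample into per-guide read classes
#'
#' Reads mate-paired FASTQ files (plain or gzipped), assigns each pair to a
#' guide via read 2, classifies the reporter via read 1, and tallies per
#' guide: `n_total` (reads assigned), `n_coupled` (reporter correctly paired)
#' and `n_edited` (edited among coupled). Guides present in the library but
#' absent from the data get zero rows, so the count table always spans the
#' full library.
#'
#' @param fastq_r1,fastq_r2 paths to the reporter (R1) and spacer (R2) FASTQ
#'   files; must contain the same number of reads in mate order.
#' @param library a `guide_library`.
#' @param params a [classify_params()].
#' @param sample_id,timepoint_days sample annotation carried into the output.
#' @return list with `counts` (tibble `sample_id`, `timepoint_days`,
#'   `guide_id`, `n_total`, `n_coupled`, `n_edited`) and `report` (read
#'   totals and assigned/coupled/edited fractions; the coupling rate is the
#'   number to compare against the >70-80% correct pairing expected of these
#'   libraries).
#' @export
count_sample <- function(fastq_r1, fastq_r2, library,
                         params = classify_params(),
                         sample_id = "sample", timepoint_days = NA_real_) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq_r1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq_r2, format = "fastq"))
  if (length(r1) != length(r2)) {
    stop("mate count mismatch: ", length(r1), " reads in R1 vs ",
         length(r2), " in R2", call. = FALSE)
  }
  gid <- if (length(r2) > 0) assign_guide(r2, library, params) else character(0)
  cls <- if (length(r1) > 0) {
    classify_reporter(r1, gid, library, params)
  } else {
    tibble::tibble(coupling = character(0), edit = character(0))
  }
  per_read <- tibble::tibble(guide_id = gid, coupling = cls$coupling,
                             edit = cls$edit)
  assigned <- per_read[!is.na(per_read$guide_id), , drop = FALSE]
  agg <- if (nrow(assigned) > 0) {
    assigned %>%
      dplyr::group_by(guide_id) %>%
      dplyr::summarise(
        n_total = dplyr::n(),
        n_coupled = sum(coupling == "coupled"),
        n_edited = sum(coupling == "coupled" & edit == "edited"),
        .groups = "drop")
  } else {
    tibble::tibble(guide_id = character(0), n_total = integer(0),
                   n_coupled = integer(0), n_edited = integer(0))
  }
  counts <- tibble::tibble(sample_id = sample_id,
                           timepoint_days = timepoint_days,
                           guide_id = library$guide_id) %>%
    dplyr::left_join(agg, by = "guide_id")
  counts[c("n_total", "n_coupled", "n_edited")] <-
    lapply(counts[c("n_total", "n_coupled", "n_edited")],
           function(v) as.integer(ifelse(is.na(v), 0L, v)))
  n_pairs <- length(r1)
  n_assigned <- nrow(assigned)
  report <- list(
    n_pairs = n_pairs,
    n_assigned = n_assigned,
    n_unassigned = n_pairs - n_assigned,
    frac_assigned = if (n_pairs > 0) n_assigned / n_pairs else NA_real_,
    frac_coupled = if (n_assigned > 0) {
      sum(assigned$coupling == "coupled") / n_assigned
    } else NA_real_,
    frac_edited_among_coupled = {
      nc <- sum(assigned$coupling == "coupled")
      if (nc > 0) sum(assigned$coupling == "coupled" &
                        assigned$edit == "edited") / nc else NA_real_
    })
  list(counts = counts, report = report)
}

#' Write / read a per-sample count table (TSV)
#' @param counts a count tibble as produced by [count_sample()] or
#'   [sample_counts()].
#' @param path TSV path.
#' @return `path` (write) or the count tibble (read).
#' @export
write_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE))
  validate_counts(df)
  df
}

validate_counts <- function(df) {
  need <- c("guide_id", "n_total", "n_coupled", "n_edited")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("count table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- df$n_edited > df$n_coupled | df$n_coupled > df$n_total |
    df$n_edited < 0
  if (any(bad)) {
    stop("count invariant 0 <= n_edited <= n_coupled <= n_total violated",
         call. = FALSE)
  }
  invisible(df)
}
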