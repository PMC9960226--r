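# Guide-reporter library: definition, validation, I/O.
#
# A library row describes one cassette: a 20-nt spacer, the reporter amplicon
# that embeds the matching protospacer (+PAM) in fixed flanks, the 0-based
# position of the expected blunt cut within the reporter, and the guide's
# role (targeting vs negative control). Coordinates are 0-based, half-open
# throughout; `cut_offset` is the index of the first base 3' of the cut.

LIB_REQUIRED_COLS <- c("guide_id", "gene", "spacer", "reporter_seq",
                       "cut_offset", "role")
LIB_OPTIONAL_COLS <- c("coding_pos_pct", "offtarget_rank_pct")
LIB_ROLES <- c("targeting", "negative_control")

#' Construct and validate a guide-reporter library
#'
#' @param df data frame with columns `guide_id`, `gene`, `spacer`,
#'   `reporter_seq`, `cut_offset` (0-based index of the first base 3' of the
#'   expected blunt cut), `role` (`"targeting"` or `"negative_control"`), and
#'   optionally `coding_pos_pct`, `offtarget_rank_pct`.
#' @return a `guide_library` tibble (validated).
#' @details Validation enforces: unique `guide_id`; each spacer present
#'   exactly once in its reporter (either strand); `0 <= cut_offset <
#'   nchar(reporter_seq)`; known roles; DNA alphabet (ACGT) for spacer and
#'   reporter.
#' @export
guide_library <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(LIB_REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("guide library is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$guide_id <- as.character(df$guide_id)
  df$gene <- as.character(df$gene)
  df$spacer <- toupper(as.character(df$spacer))
  df$reporter_seq <- toupper(as.character(df$reporter_seq))
  df$cut_offset <- as.integer(df$cut_offset)
  df$role <- as.character(df$role)

  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup) > 0) {
    stop("duplicated guide_id in library: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), LIB_ROLES)
  if (length(bad_role) > 0) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         "; expected one of: ", paste(LIB_ROLES, collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", df$spacer)) || any(grepl("[^ACGT]", df$reporter_seq))) {
    stop("spacer and reporter_seq must be plain ACGT strings", call. = FALSE)
  }
  bad_cut <- df$cut_offset < 0L | df$cut_offset >= nchar(df$reporter_seq) |
    is.na(df$cut_offset)
  if (any(bad_cut)) {
    stop("cut_offset out of range for guide(s): ",
         paste(df$guide_id[bad_cut], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    hit <- tryCatch(
      locate_protospacer(df$spacer[i], df$reporter_seq[i]),
      error = function(e) NULL
    )
    if (is.null(hit)) {
      stop("spacer not found exactly once in reporter_seq for guide '",
           df$guide_id[i], "'", call. = FALSE)
    }
  }
  class(df) <- c("guide_library", class(df))
  df
}

#' Read a guide-reporter library from a TSV/CSV file
#'
#' @param path path to a delimited file with a header row; tab-delimited by
#'   default, comma-delimited if the file ends in `.csv`.
#' @return a validated `guide_library` tibble. Optional columns absent from
#'   the file are left unset (absent).
#' @export
read_guide_library <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  guide_library(df)
}

#' Write a guide library to a TSV file
#'
#' `read_guide_library(write_guide_library(lib, path))` round-trips to
#' identical records.
#'
#' @param lib a `guide_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guide_library <- function(lib, path) {
  utils::write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Locate a spacer's protospacer within a reporter sequence
#'
#' Searches both strands for the 20-nt spacer and returns the match as a
#' 0-based, half-open interval in reporter coordinates, plus the strand.
#'
#' @param spacer spacer sequence (given 5'->3' as expressed).
#' @param reporter_seq the reporter amplicon in sequencing-read orientation.
#' @return list with `start`, `end` (0-based half-open; `substr(reporter,
#'   start+1, end)` equals the spacer or its reverse complement) and `strand`
#'   (`"+"` when the spacer matches as given, `"-"` for the reverse
#'   complement).
#' @details Errors when the spacer occurs zero times or more than once across
#'   both strands; `guide_library()` precludes this for validated libraries.
#' @export
locate_protospacer <- function(spacer, reporter_seq) {
  if (inherits(spacer, "data.frame")) {  # accept a single library row
    reporter_seq <- spacer$reporter_seq
    spacer <- spacer$spacer
  }
  spacer <- toupper(spacer)
  reporter_seq <- toupper(reporter_seq)
  rc <- revcomp(spacer)
  fwd <- str_find_all(reporter_seq, spacer)
  rev <- if (identical(rc, spacer)) integer(0) else str_find_all(reporter_seq, rc)
  n_hits <- length(fwd) + length(rev)
  if (n_hits == 0) stop("spacer not found in reporter_seq", call. = FALSE)
  if (n_hits > 1) stop("spacer matches reporter_seq more than once", call. = FALSE)
  if (length(fwd) == 1) {
    list(start = fwd - 1L, end = fwd - 1L + nchar(spacer), strand = "+")
  } else {
    list(start = rev - 1L, end = rev - 1L + nchar(spacer), strand = "-")
  }
}

# all 1-based start positions of fixed pattern in x
str_find_all <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Reverse complement of a DNA string
#' @param x character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Reference gene sets for benchmarking
#'
#' @param essential character vector of essential gene symbols.
#' @param nonessential character vector of non-essential gene symbols; must be
#'   disjoint from `essential`.
#' @return a `gene_reference` object.
#' @export
gene_reference <- function(essential, nonessential) {
  essential <- unique(as.character(essential))
  nonessential <- unique(as.character(nonessential))
  both <- intersect(essential, nonessential)
  if (length(both) > 0) {
    stop("gene sets overlap: ", paste(both, collapse = ", "), call. = FALSE)
  }
  structure(list(essential = essential, nonessential = nonessential),
            class = "gene_reference")
}

#' Read a gene list (one symbol per line)
#' @param path plain-text file, one gene symbol per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read essential/non-essential reference sets from two files
#' @param essential_path,nonessential_path one-symbol-per-line files.
#' @return a `gene_reference`.
#' @export
read_gene_reference <- function(essential_path, nonessential_path) {
  gene_reference(read_gene_list(essential_path),
                 read_gene_list(nonessential_path))
}

#' @export
print.gene_reference <- function(x, ...) {
  cat("<gene_reference> ", length(x$essential), " essential, ",
      length(x$nonessential), " non-essential genes\n", sep = "")
  invisible(x)
}
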