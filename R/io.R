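#' Read sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped, possibly gzip-compressed) multi-record
#' FASTA file. Sequence case is preserved verbatim -- case handling is the
#' scanner's job. The record identifier is the first whitespace-delimited
#' token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) rlang::abort("empty FASTA file")
    return(tibble::tibble(
      seq_id = vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1),
      seq = unname(as.character(ss))
    ))
  }
  # plain-text fallback
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) rlang::abort("malformed FASTA: no header line")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  tibble::tibble(seq_id = ids, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with `seq_id` and `seq` (or a named character
#'   vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- .as_seq_tbl(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$seq_id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Accepts 3+ column BED; columns beyond the sixth are ignored. Comment
#' (`#`), `track` and `browser` lines are skipped.
#'
#' @param path Path to a BED file.
#' @return A tibble with `seq_id`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  if (ncol < 3L) rlang::abort("BED needs at least 3 columns")
  col <- function(i) vapply(parts, `[[`, character(1), i)
  out <- tibble::tibble(seq_id = col(1),
                        start = as.integer(col(2)),
                        end = as.integer(col(3)))
  if (ncol >= 4L) out$name <- col(4)
  if (ncol >= 5L) out$score <- suppressWarnings(as.numeric(col(5)))
  if (ncol >= 6L) out$strand <- col(6)
  out
}

# commented header recording provenance; deterministic output
.header_lines <- function(params = NULL, extra = character(0)) {
  v <- as.character(utils::packageVersion("dsquad"))
  h <- paste0("# dsquad ", v)
  if (!is.null(params)) {
    h <- c(h, sprintf(
      "# params: min_tract=%d same_loop=%d-%d cross_gap=%d-%d case=%s ambiguous_in_loops=%s",
      params$min_tract, params$same_loop_min, params$same_loop_max,
      params$cross_gap_min, params$cross_gap_max, params$case_mode,
      params$ambiguous_in_loops))
  }
  c(h, extra)
}

#' Write PQS records in the one-line-per-match text dialect
#'
#' One match per line, tab-separated: sequence id, topology class, 1-based
#' start position, matched sequence. (BED output, in contrast, is 0-based
#' half-open; both conventions are deliberate.)
#'
#' @param records PQS records from [scan_pqs()].
#' @param path Output path.
#' @param params Optional [scan_params()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_pqs_text <- function(records, path, params = NULL) {
  records <- dplyr::arrange(records, .data$seq_id, .data$start, .data$class)
  lines <- c(.header_lines(params),
             sprintf("%s\t%s\t%d\t%s", records$seq_id, records$class,
                     records$start + 1L, records$matched))
  writeLines(lines, path)
  invisible(path)
}

#' Write PQS records as BED6
#'
#' Name is `<class>:<cao_number>` (`<class>:SS` for the intrastrand class),
#' score 0. Strand is `"."` for interstrand records -- a DS-PQS has no
#' single strand -- and `"+"`/`"-"` for `AAAA` depending on whether the
#' G-run or C-run alternative matched.
#'
#' @inheritParams write_pqs_text
#' @export
write_pqs_bed <- function(records, path, params = NULL) {
  records <- dplyr::arrange(records, .data$seq_id, .data$start, .data$end)
  name <- ifelse(records$class == "AAAA", paste0(records$class, ":SS"),
                 paste0(records$class, ":", records$cao_number))
  lines <- c(.header_lines(params),
             sprintf("%s\t%d\t%d\t%s\t0\t%s", records$seq_id, records$start,
                     records$end, name, records$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Write generic intervals as BED
#'
#' @param x A tibble with `seq_id`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  x <- dplyr::arrange(x, .data$seq_id, .data$start, .data$end)
  nm <- if ("name" %in% names(x)) x$name else
    if ("classes" %in% names(x)) x$classes else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", x$seq_id, as.integer(x$start),
                     as.integer(x$end), nm), path)
  invisible(path)
}

#' Read sequence lengths
#'
#' Accepts a samtools `.fai` index (uses columns 1--2) or any tab-separated
#' table whose first two columns are sequence id and length.
#'
#' @param path Path to the table.
#' @return A tibble with `seq_id` and `length`.
#' @export
read_seq_lengths <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  tibble::tibble(seq_id = as.character(df[[1]]), length = as.numeric(df[[2]]))
}
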