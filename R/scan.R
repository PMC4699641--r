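#' Scan a sequence for one topology class
#'
#' Runs the class expression over a single nucleotide sequence with global
#' (Perl `m//g`) semantics: repeated leftmost matching, each search resuming
#' at the end of the previous match, so matches of one class never overlap
#' each other. Matches of different classes may overlap; resolving those is
#' the job of [merge_sites()].
#'
#' @param seq A single nucleotide string.
#' @param seq_id Identifier recorded on each match.
#' @param cls Topology class name.
#' @param params A [scan_params()] object.
#' @return A tibble of PQS records, one row per match, with columns
#'   `seq_id`, `start`, `end` (0-based half-open on the scanned strand),
#'   `class`, `cao_number`, `pattern` (the member tract pattern that
#'   matched), `matched` (the matched substring), `strand` (`"+"`/`"-"` for
#'   `AAAA` according to whether the G-run or C-run alternative matched,
#'   `"."` for interstrand classes), `tract_start` and `tract_width` (list
#'   columns of 4 integers; 0-based tract starts) and `n_guanines`.
#' @examples
#' scan_class("GGGAGGGACCCACCC", "chr1", "AABB")
#' @export
scan_class <- function(seq, seq_id, cls, params = scan_params()) {
  params <- .as_params(params)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  subject <- if (params$case_mode == "fold") toupper(seq) else seq
  spec <- class_regex(cls, params)
  row <- .class_row(cls)

  m <- gregexpr(spec$regex, subject, perl = TRUE)[[1]]
  if (m[1] == -1L) return(.empty_records())

  starts1 <- as.integer(m)                       # 1-based
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")

  n <- length(starts1)
  pattern <- character(n)
  tract_start <- vector("list", n)
  tract_width <- vector("list", n)
  for (k in seq_len(n)) {
    alt <- NULL
    for (a in spec$alts) {
      if (cs[k, a$tract_groups[1]] > 0L) { alt <- a; break }
    }
    if (is.null(alt)) rlang::abort("internal: no alternative attributed to match")
    pattern[k] <- alt$member
    tract_start[[k]] <- as.integer(cs[k, alt$tract_groups] - 1L)  # 0-based
    tract_width[[k]] <- as.integer(cl[k, alt$tract_groups])
  }

  strand <- if (cls == "AAAA") ifelse(substr(pattern, 1, 1) == "A", "+", "-")
            else rep(".", n)

  tibble::tibble(
    seq_id = seq_id,
    start = starts1 - 1L,
    end = starts1 - 1L + lens,
    class = cls,
    cao_number = row$cao_number,
    pattern = pattern,
    matched = substring(seq, starts1, starts1 + lens - 1L),
    strand = strand,
    tract_start = tract_start,
    tract_width = tract_width,
    n_guanines = vapply(tract_width, sum, integer(1))
  )
}

.empty_records <- function() {
  tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    class = character(), cao_number = integer(), pattern = character(),
    matched = character(), strand = character(),
    tract_start = list(), tract_width = list(), n_guanines = integer()
  )
}

#' Scan sequences for PQS of all (or selected) topology classes
#'
#' The workhorse predictor: runs [scan_class()] for every requested topology
#' class over every input sequence and binds the results. A separate
#' one-step search is performed per class, so predictions of different
#' classes may overlap; use [merge_sites()] to reduce them to unique sites.
#' Matches never span sequence-record boundaries.
#'
#' @param x Input sequences: a data frame with columns `seq_id` and `seq`, a
#'   named character vector, or the path to a FASTA file (read with
#'   [read_fasta()]).
#' @param params A [scan_params()] object.
#' @param classes `"all"` (default) or a character vector of class names.
#' @return A tibble of PQS records (see [scan_class()]), ordered by
#'   sequence, start and class.
#' @examples
#' scan_pqs(c(chr1 = "GGGAGGGACCCACCC"))
#' @export
scan_pqs <- function(x, params = scan_params(), classes = "all") {
  params <- .as_params(params)
  seqs <- .as_seq_tbl(x)
  if (identical(classes, "all")) classes <- .class_table()$class
  invisible(lapply(classes, .class_row))  # validate names early

  out <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    purrr::map_dfr(classes, function(cl) {
      scan_class(seqs$seq[i], seqs$seq_id[i], cl, params)
    })
  })
  if (nrow(out) == 0L) return(.empty_records())
  dplyr::arrange(out, .data$seq_id, .data$start, .data$end, .data$class)
}

# normalize sequence input to tibble(seq_id, seq)
.as_seq_tbl <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("seq_id", "seq") %in% names(x))) {
      rlang::abort("sequence data frame needs columns 'seq_id' and 'seq'")
    }
    return(tibble::as_tibble(x[, c("seq_id", "seq")]))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_fasta(x))
  }
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      rlang::abort("character sequences must be named (names become seq_id)")
    }
    return(tibble::tibble(seq_id = names(x), seq = unname(x)))
  }
  rlang::abort("unsupported sequence input")
}

#' Guanines contributed by both strands of a quadruplex
#'
#' Sums the four tract lengths of each PQS record. A `B` (cytosine) tract on
#' the scanned strand contributes its guanines from the complementary
#' strand, so the sum counts the guanines available to the quadruplex cage
#' from the duplex as a whole. With minimal tracts of 3 nt this is 12.
#'
#' @param records A PQS record tibble from [scan_pqs()].
#' @return Integer vector, one total per record.
#' @examples
#' pqs_guanines(scan_pqs(c(s = "GGGAGGGACCCACCC")))
#' @export
pqs_guanines <- function(records) {
  vapply(records$tract_width, function(w) as.integer(sum(w)), integer(1))
}
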