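#' Validate PQS records against the motif rules
#'
#' Checks every record invariant by direct inspection of the sequence,
#' independently of the matching engine: interval width equals the matched
#' string; the four tracts are ordered, disjoint, inside the interval, at
#' least `min_tract` long and composed purely of `G` (letter `A`) or `C`
#' (letter `B`) on the scanned strand; all tracts of one letter repeat the
#' first tract's length; and every inter-tract gap respects the same-letter
#' or cross-letter bounds.
#'
#' @param records PQS records from [scan_pqs()].
#' @param seqs The scanned sequences (any input accepted by [scan_pqs()]).
#' @param params The [scan_params()] used for the scan.
#' @return `TRUE` invisibly; aborts with a message on the first violation.
#' @export
validate_pqs <- function(records, seqs, params = scan_params()) {
  params <- .as_params(params)
  seqs <- .as_seq_tbl(seqs)
  lookup <- stats::setNames(seqs$seq, seqs$seq_id)
  base <- c(A = "G", B = "C")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    s <- lookup[[r$seq_id]]
    if (is.null(s)) rlang::abort(paste0("record on unknown sequence ", r$seq_id))
    fold <- params$case_mode == "fold"
    subject <- if (fold) toupper(s) else s
    fail <- function(what) {
      rlang::abort(sprintf("record %d (%s %d-%d %s): %s",
                           i, r$seq_id, r$start, r$end, r$class, what))
    }
    if (r$end - r$start != nchar(r$matched)) fail("width != matched length")
    if (substr(s, r$start + 1L, r$end) != r$matched) fail("matched string mismatch")
    ts <- r$tract_start[[1]]; tw <- r$tract_width[[1]]
    ch <- .pattern_chars(r$pattern)
    if (length(ts) != 4L || length(tw) != 4L) fail("need 4 tract spans")
    if (any(tw < params$min_tract)) fail("tract shorter than min_tract")
    if (ts[1] != r$start || ts[4] + tw[4] != r$end) fail("tracts not flush with interval")
    for (k in 1:4) {
      tract <- substr(subject, ts[k] + 1L, ts[k] + tw[k])
      if (tract != strrep(base[[ch[k]]], tw[k])) fail("tract content mismatch")
    }
    for (l in c("A", "B")) {
      w <- tw[ch == l]
      if (length(w) > 1L && length(unique(w)) != 1L) {
        fail("tracts of one letter differ in length (backreference rule)")
      }
    }
    for (k in 1:3) {
      g <- ts[k + 1L] - (ts[k] + tw[k])
      b <- .gap_bounds(ch[k], ch[k + 1L], params)
      if (g < b[1] || g > b[2]) fail("gap outside adjacency bounds")
    }
  }
  invisible(TRUE)
}
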