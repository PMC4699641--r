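#' Scan parameters
#'
#' Bundles the tunable parameters of the PQS motif definition. The defaults
#' give the standard motif: guanine/cytosine tracts of at least 3 nt, loops
#' of 1--7 nt between tracts of the same letter and gaps of 0--7 nt between
#' tracts of different letters. Setting `loop_max_alt = 12` reproduces the
#' relaxed variant used for functional analyses, where both maxima are
#' raised to 12.
#'
#' @param min_tract Minimum tract length in nucleotides (>= 2, default 3).
#' @param same_loop_min,same_loop_max Loop length bounds between two tracts
#'   of the same letter (defaults 1 and 7; the minimum must be >= 1 so that
#'   consecutive same-letter tracts stay distinct runs).
#' @param cross_gap_min,cross_gap_max Gap length bounds between tracts of
#'   different letters (defaults 0 and 7; abutting tracts are allowed).
#' @param loop_max_alt Optional relaxed maximum replacing both
#'   `same_loop_max` and `cross_gap_max` (e.g. 12). `NULL` to disable.
#' @param case_mode `"fold"` (default) uppercases sequence before scanning,
#'   so soft-masked lowercase matches; `"strict"` scans case-sensitively and
#'   lowercase bases can never be part of a tract (loops still accept any
#'   character).
#' @param ambiguous_in_loops Should `N` and other non-ACGT letters be
#'   allowed inside loops/gaps (default `TRUE`, the any-character semantics
#'   of the motif)? Tracts never admit ambiguity codes.
#' @return A list of class `"dsquad_params"`.
#' @examples
#' scan_params()
#' scan_params(loop_max_alt = 12)
#' @export
scan_params <- function(min_tract = 3L,
                        same_loop_min = 1L, same_loop_max = 7L,
                        cross_gap_min = 0L, cross_gap_max = 7L,
                        loop_max_alt = NULL,
                        case_mode = c("fold", "strict"),
                        ambiguous_in_loops = TRUE) {
  case_mode <- match.arg(case_mode)
  min_tract <- as.integer(min_tract)
  same_loop_min <- as.integer(same_loop_min)
  same_loop_max <- as.integer(same_loop_max)
  cross_gap_min <- as.integer(cross_gap_min)
  cross_gap_max <- as.integer(cross_gap_max)
  if (!is.null(loop_max_alt)) {
    same_loop_max <- cross_gap_max <- as.integer(loop_max_alt)
  }
  if (min_tract < 2L) rlang::abort("min_tract must be >= 2")
  if (same_loop_min < 1L || same_loop_min > same_loop_max) {
    rlang::abort("need 1 <= same_loop_min <= same_loop_max")
  }
  if (cross_gap_min < 0L || cross_gap_min > cross_gap_max) {
    rlang::abort("need 0 <= cross_gap_min <= cross_gap_max")
  }
  structure(
    list(min_tract = min_tract,
         same_loop_min = same_loop_min, same_loop_max = same_loop_max,
         cross_gap_min = cross_gap_min, cross_gap_max = cross_gap_max,
         case_mode = case_mode,
         ambiguous_in_loops = isTRUE(ambiguous_in_loops)),
    class = "dsquad_params"
  )
}

#' @export
print.dsquad_params <- function(x, ...) {
  cat("PQS scan parameters\n")
  cat("  tract: ", x$min_tract, "+ nt\n", sep = "")
  cat("  same-letter loop: ", x$same_loop_min, "-", x$same_loop_max, " nt\n", sep = "")
  cat("  cross-letter gap: ", x$cross_gap_min, "-", x$cross_gap_max, " nt\n", sep = "")
  cat("  case: ", x$case_mode,
      if (x$ambiguous_in_loops) ", ambiguity codes allowed in loops" else
        ", loops restricted to ACGT", "\n", sep = "")
  invisible(x)
}

.as_params <- function(params) {
  if (inherits(params, "dsquad_params")) params else
    rlang::abort("params must be created with scan_params()")
}

# gap bounds implied by the letters flanking a loop
.gap_bounds <- function(l1, l2, params) {
  if (l1 == l2) c(params$same_loop_min, params$same_loop_max)
  else c(params$cross_gap_min, params$cross_gap_max)
}
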