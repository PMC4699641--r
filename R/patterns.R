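#' Build the matcher expression for a topology class
#'
#' Constructs the Perl-compatible regular expression that defines a topology
#' class: four tracts in the order of each member pattern, each `A` a
#' guanine run `G{min_tract,}` and each `B` a cytosine run, loops between
#' same-letter tracts bounded by `[same_loop_min, same_loop_max]` and gaps
#' between different-letter tracts by `[cross_gap_min, cross_gap_max]`.
#' Second and later occurrences of a letter are backreferences to the first
#' capture of that letter, so they repeat that tract's exact matched string
#' (subject to backtracking). Classes with two member patterns are expressed
#' as an alternation with the canonical pattern first; `AAAA` is the
#' alternation of the all-G and all-C intrastrand expressions.
#'
#' Every tract and loop is additionally wrapped in its own capture group so
#' tract positions can be recovered from match metadata; this does not
#' change the language matched.
#'
#' @param cls A topology class name (see [topology_classes()]).
#' @param params A [scan_params()] object.
#' @return A list of class `"dsquad_pattern"` with elements `class`,
#'   `regex` (the full PCRE string), and `alts` -- per-alternative metadata
#'   (member pattern, absolute capture-group indices of the four tracts).
#' @examples
#' class_regex("AABB")$regex
#' @export
class_regex <- function(cls, params = scan_params()) {
  params <- .as_params(params)
  row <- .class_row(cls)
  members <- if (cls == "AAAA") c("AAAA", "BBBB") else
    c(row$canonical, if (!is.na(row$alternative)) row$alternative)

  loop_atom <- if (params$ambiguous_in_loops) "." else "[ACGTacgt]"
  tract_base <- c(A = "G", B = "C")

  group <- 0L
  alts <- list()
  pieces <- character(0)
  for (mem in members) {
    ch <- .pattern_chars(mem)
    first_group <- integer(0)          # letter -> group index of first capture
    names(first_group) <- character(0)
    tract_groups <- integer(4)
    expr <- character(0)
    for (i in 1:4) {
      if (i > 1L) {
        b <- .gap_bounds(ch[i - 1L], ch[i], params)
        group <- group + 1L
        expr <- c(expr, sprintf("(%s{%d,%d})", loop_atom, b[1], b[2]))
      }
      group <- group + 1L
      tract_groups[i] <- group
      if (is.na(first_group[ch[i]])) {
        first_group[ch[i]] <- group
        expr <- c(expr, sprintf("(%s{%d,})", tract_base[[ch[i]]], params$min_tract))
      } else {
        expr <- c(expr, sprintf("(\\%d)", first_group[ch[i]]))
      }
    }
    pieces <- c(pieces, paste(expr, collapse = ""))
    alts[[length(alts) + 1L]] <- list(member = mem, tract_groups = tract_groups)
  }

  structure(
    list(class = cls, regex = paste(pieces, collapse = "|"), alts = alts),
    class = "dsquad_pattern"
  )
}

#' @export
print.dsquad_pattern <- function(x, ...) {
  cat("class ", x$class, ": /", x$regex, "/g\n", sep = "")
  invisible(x)
}
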