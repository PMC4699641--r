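#' Random nucleotide sequence with a given GC content
#'
#' Letters are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Sequence length (>= 1).
#' @param gc GC fraction in \[0, 1\].
#' @param seed Optional integer; when given, the global RNG state is saved,
#'   seeded, and restored, making the call reproducible and side-effect
#'   free.
#' @return A single character string.
#' @examples
#' random_sequence(20, 0.5, seed = 1)
#' @export
random_sequence <- function(length, gc, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) {
    old <- .hold_rng()
    on.exit(.release_rng(old), add = TRUE)
    set.seed(seed)
  }
  paste(sample(c("G", "C", "A", "T"), length, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

.hold_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.release_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specification of a motif to plant
#'
#' Describes one PQS motif to be written into a synthetic sequence: its
#' topology class, the four tract lengths, the three intervening loop/gap
#' lengths, the position, and which member pattern of the class to use.
#' Gap lengths are validated against the class's adjacency bounds
#' (same-letter loops need `same_loop_min`--`same_loop_max` nt, cross-letter
#' gaps `cross_gap_min`--`cross_gap_max` nt).
#'
#' @param class Topology class name.
#' @param tracts Integer vector of 4 tract lengths, each >= `min_tract`.
#' @param gaps Integer vector of 3 loop/gap lengths.
#' @param at 0-based position at which the motif starts.
#' @param member `"canonical"` or `"alternative"` member pattern.
#' @param params A [scan_params()] object supplying the bounds.
#' @return A list of class `"dsquad_plant"` with the validated fields plus
#'   the member letters and total motif width.
#' @export
plant_spec <- function(class, tracts = c(3L, 3L, 3L, 3L), gaps = c(1L, 1L, 1L),
                       at = 0L, member = c("canonical", "alternative"),
                       params = scan_params()) {
  member <- match.arg(member)
  params <- .as_params(params)
  row <- .class_row(class)
  pat <- if (member == "canonical") row$canonical else {
    if (class == "AAAA") "BBBB"
    else if (is.na(row$alternative)) {
      rlang::abort(paste0("class ", class, " has no distinct alternative pattern"))
    } else row$alternative
  }
  tracts <- as.integer(tracts); gaps <- as.integer(gaps); at <- as.integer(at)
  stopifnot(length(tracts) == 4L, length(gaps) == 3L, at >= 0L)
  if (any(tracts < params$min_tract)) {
    rlang::abort("all tract lengths must be >= min_tract")
  }
  ch <- .pattern_chars(pat)
  for (i in 1:3) {
    b <- .gap_bounds(ch[i], ch[i + 1L], params)
    if (gaps[i] < b[1] || gaps[i] > b[2]) {
      rlang::abort(sprintf(
        "gap %d (%d nt) violates the %s-letter bounds [%d, %d] for %s-%s",
        i, gaps[i], if (ch[i] == ch[i + 1]) "same" else "cross",
        b[1], b[2], ch[i], ch[i + 1]))
    }
  }
  structure(list(class = class, pattern = pat, letters = ch,
                 tracts = tracts, gaps = gaps, at = at,
                 width = sum(tracts) + sum(gaps)),
            class = "dsquad_plant")
}

#' Build the motif string described by a plant specification
#'
#' Tracts become runs of `G` (letter `A`) or `C` (letter `B`); loops are
#' filled by recycling `loop_alphabet`. The default alphabet \{A, T\}
#' guarantees loops can never extend a tract.
#'
#' @param spec A [plant_spec()].
#' @param loop_alphabet Characters used to fill loops.
#' @return The motif as a single string of width `spec$width`.
#' @examples
#' motif_sequence(plant_spec("AABB", gaps = c(1, 1, 1)), loop_alphabet = "A")
#' @export
motif_sequence <- function(spec, loop_alphabet = c("A", "T")) {
  stopifnot(inherits(spec, "dsquad_plant"))
  fill <- function(k) {
    if (k == 0L) return("")
    paste(rep_len(loop_alphabet, k), collapse = "")
  }
  base <- c(A = "G", B = "C")
  out <- character(0)
  for (i in 1:4) {
    out <- c(out, strrep(base[[spec$letters[i]]], spec$tracts[i]))
    if (i < 4L) out <- c(out, fill(spec$gaps[i]))
  }
  paste(out, collapse = "")
}

#' Plant a PQS motif into a sequence
#'
#' Overwrites the window `[at, at + width)` of `seq` with the motif built
#' from `spec` and returns both the modified sequence and the ground-truth
#' record of the planted site.
#'
#' @param seq A nucleotide string.
#' @param spec A [plant_spec()] (its `at` field gives the 0-based position).
#' @param loop_alphabet Loop filler characters, see [motif_sequence()].
#' @return A list with `seq` (modified sequence) and `truth` (a one-row
#'   tibble: `start`, `end`, `class`, `pattern`, `tract_start`,
#'   `tract_width`).
#' @export
plant_pqs <- function(seq, spec, loop_alphabet = c("A", "T")) {
  stopifnot(is.character(seq), length(seq) == 1L,
            inherits(spec, "dsquad_plant"))
  n <- nchar(seq)
  if (spec$at + spec$width > n) {
    rlang::abort("planted motif does not fit within the sequence")
  }
  motif <- motif_sequence(spec, loop_alphabet)
  out <- paste0(substr(seq, 1L, spec$at),
                motif,
                substr(seq, spec$at + spec$width + 1L, n))
  tract_start <- spec$at + c(0L, cumsum(spec$tracts[1:3] + spec$gaps))
  truth <- tibble::tibble(
    start = spec$at, end = spec$at + spec$width,
    class = spec$class, pattern = spec$pattern,
    tract_start = list(as.integer(tract_start)),
    tract_width = list(spec$tracts)
  )
  list(seq = out, truth = truth)
}

# ---- brute-force placement oracle ---------------------------------------
# Independent reference for the scanner: enumerates tract placements
# directly from the tract/gap rules, sharing no matching machinery with the
# regex engine. Backreference semantics are mirrored by requiring all
# tracts of a letter to have the exact length of that letter's first tract;
# surplus run letters fall into the adjacent gaps.

# per-position maximal run length of a letter, honoring case_mode
.run_lengths <- function(seq, letter, params) {
  s <- if (params$case_mode == "fold") toupper(seq) else seq
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  is_l <- ch == letter
  n <- length(ch)
  run <- integer(n)
  acc <- 0L
  for (i in rev(seq_len(n))) {
    acc <- if (is_l[i]) acc + 1L else 0L
    run[i] <- acc
  }
  run
}

# letters of the member patterns to try for a class
.oracle_members <- function(cls) {
  row <- .class_row(cls)
  if (cls == "AAAA") c("AAAA", "BBBB")
  else c(row$canonical, if (!is.na(row$alternative)) row$alternative)
}

#' Does a sequence admit any valid tract placement for a class?
#'
#' Fast existence version of [brute_force_placements()]: enumerates the two
#' tract lengths (one per letter) and propagates the set of feasible tract
#' start positions through the chain of gap constraints. Exact for
#' existence, since the constraints only couple consecutive tracts.
#'
#' @inheritParams brute_force_placements
#' @return `TRUE` if at least one placement exists.
#' @export
has_placement <- function(seq, cls, params = scan_params()) {
  params <- .as_params(params)
  n <- nchar(seq)
  if (n == 0L) return(FALSE)
  run <- list(A = .run_lengths(seq, "G", params),
              B = .run_lengths(seq, "C", params))
  for (mem in .oracle_members(cls)) {
    ch <- .pattern_chars(mem)
    present <- unique(ch)
    maxlen <- vapply(present, function(l) max(run[[l]]), integer(1))
    if (any(maxlen < params$min_tract)) next
    lens <- lapply(present, function(l) params$min_tract:maxlen[[l]])
    names(lens) <- present
    combos <- expand.grid(lens)
    for (r in seq_len(nrow(combos))) {
      len_of <- as.integer(combos[r, , drop = TRUE])
      names(len_of) <- names(combos)
      if (.placement_reachable(ch, len_of, run, n, params)) return(TRUE)
    }
  }
  FALSE
}

.placement_reachable <- function(ch, len_of, run, n, params) {
  S <- which(run[[ch[1]]] >= len_of[[ch[1]]])
  for (i in 2:4) {
    if (length(S) == 0L) return(FALSE)
    b <- .gap_bounds(ch[i - 1L], ch[i], params)
    leni <- len_of[[ch[i]]]
    cand <- unique(as.vector(outer(S + len_of[[ch[i - 1L]]], b[1]:b[2], "+")))
    cand <- cand[cand >= 1L & cand + leni - 1L <= n]
    S <- cand[run[[ch[i]]][cand] >= leni]
  }
  length(S) > 0L
}

#' Enumerate all valid tract placements for a class
#'
#' Exhaustive reference oracle: every assignment of four ordered,
#' non-overlapping tracts (letters following either member pattern of the
#' class, lengths >= `min_tract`, all tracts of one letter repeating the
#' first tract's exact length) with every gap inside its adjacency bounds.
#' Intended for short sequences only.
#'
#' @param seq A nucleotide string.
#' @param cls Topology class name.
#' @param params A [scan_params()] object.
#' @param max_len Guard on sequence length (default 500).
#' @return A tibble with one row per placement: `start`, `end`, `pattern`,
#'   `tract_start` and `tract_width` list columns.
#' @examples
#' nrow(brute_force_placements("GGGAGGGACCCACCC", "AABB")) # >= 1
#' @export
brute_force_placements <- function(seq, cls, params = scan_params(),
                                   max_len = 500L) {
  params <- .as_params(params)
  n <- nchar(seq)
  if (n > max_len) {
    rlang::abort("sequence too long for exhaustive placement enumeration")
  }
  empty <- tibble::tibble(start = integer(), end = integer(),
                          pattern = character(),
                          tract_start = list(), tract_width = list())
  if (n == 0L) return(empty)
  run <- list(A = .run_lengths(seq, "G", params),
              B = .run_lengths(seq, "C", params))

  rows <- list()
  for (mem in .oracle_members(cls)) {
    ch <- .pattern_chars(mem)
    present <- unique(ch)
    maxlen <- vapply(present, function(l) max(run[[l]]), integer(1))
    if (any(maxlen < params$min_tract)) next
    lens <- lapply(present, function(l) params$min_tract:maxlen[[l]])
    names(lens) <- present
    combos <- expand.grid(lens)
    for (r in seq_len(nrow(combos))) {
      len_of <- as.integer(combos[r, , drop = TRUE])
      names(len_of) <- names(combos)
      L <- vapply(ch, function(l) len_of[[l]], integer(1))
      s1s <- which(run[[ch[1]]] >= L[1])
      for (s1 in s1s) {
        for (s2 in .next_starts(s1, L[1], ch[1], ch[2], L[2], run, n, params)) {
          for (s3 in .next_starts(s2, L[2], ch[2], ch[3], L[3], run, n, params)) {
            for (s4 in .next_starts(s3, L[3], ch[3], ch[4], L[4], run, n, params)) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                start = s1 - 1L, end = unname(s4 + L[4] - 1L),
                pattern = mem,
                tract_start = list(c(s1, s2, s3, s4) - 1L),
                tract_width = list(unname(L))
              )
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$end)
}

.next_starts <- function(s_prev, len_prev, l_prev, l_next, len_next, run, n,
                         params) {
  b <- .gap_bounds(l_prev, l_next, params)
  cand <- s_prev + len_prev + b[1]:b[2]
  cand <- cand[cand >= 1L & cand + len_next - 1L <= n]
  cand[run[[l_next]][cand] >= len_next]
}
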