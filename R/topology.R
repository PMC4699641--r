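#' Tract-order topology classes of quadruplex-forming sequences
#'
#' A putative quadruplex-forming sequence (PQS) in double-stranded DNA is a
#' succession of four base tracts, each either a guanine run on the scanned
#' strand (letter `A`) or a cytosine run on the scanned strand (letter `B`,
#' i.e. a guanine run on the complementary strand), read from the 5' end of
#' the scanned strand. Because the duplex can be read from either strand,
#' reverse-complement tract orders describe the same physical site and are
#' not distinguished: the 16 four-letter words over \{A, B\} collapse into 10
#' topology classes -- the classical intrastrand class `AAAA` (with `BBBB`,
#' its reading from the other strand) plus 9 interstrand classes in which
#' both strands contribute guanines.
#'
#' @name topology
NULL

.tract_letters <- c("A", "B")

# split "AABB" -> c("A","A","B","B"), with validation
.pattern_chars <- function(p) {
  stopifnot(is.character(p), length(p) == 1L, nchar(p) == 4L)
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  if (!all(ch %in% .tract_letters)) {
    rlang::abort(paste0("tract pattern must use letters A/B only, got '", p, "'"))
  }
  ch
}

#' Reverse complement of a tract pattern
#'
#' Reverses the tract order and exchanges `A` (guanine tract) with `B`
#' (cytosine tract), giving the tract pattern seen when the same duplex site
#' is read from the complementary strand. Patterns related by this operation
#' describe the same topology class (e.g. `AABA` and `BABB`).
#'
#' @param p Character vector of 4-letter tract patterns over \{A, B\}.
#' @return Character vector of the same length with each pattern reverse
#'   complemented. The operation is an involution.
#' @examples
#' rc_pattern("AABA") # "BABB"
#' rc_pattern("AABB") # self-reverse-complementary
#' @export
rc_pattern <- function(p) {
  vapply(p, function(x) {
    ch <- rev(.pattern_chars(x))
    paste(ifelse(ch == "A", "B", "A"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Strand swap of a tract pattern
#'
#' Exchanges `A` and `B` at every position without reversing, i.e. maps a
#' quadruplex starting from the positive strand onto the one starting from
#' the negative strand. Interstrand classes group into 5 pairs/singletons
#' under this relation.
#'
#' @inheritParams rc_pattern
#' @return Character vector of letter-swapped patterns (an involution).
#' @examples
#' swap_pattern("AABB") # "BBAA"
#' @export
swap_pattern <- function(p) {
  vapply(p, function(x) {
    ch <- .pattern_chars(x)
    paste(ifelse(ch == "A", "B", "A"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# canonical class names in the field's published order, with the legacy
# (Cao et al.) class numbers; AAAA is the intrastrand case
.class_order <- c("AAAA", "BAAA", "ABBB", "BBAA", "AABB",
                  "BABA", "ABAB", "ABBA", "ABAA", "BABB")
.cao_numbers <- c(NA, 1, 2, 3, 4, 5, 6, 7, 8, 9)

#' Enumerate the quadruplex topology classes
#'
#' Partitions all sixteen 4-letter tract patterns into equivalence classes
#' under [rc_pattern()] and returns one row per class: the single
#' intrastrand class `AAAA` plus the 9 interstrand classes. Class names
#' follow the published nomenclature; when a class contains two member
#' patterns the canonical name is the published one and the other member is
#' recorded as the alternative pattern.
#'
#' @return A tibble with one row per class and columns:
#' \describe{
#'   \item{class}{canonical class name.}
#'   \item{cao_number}{legacy class number 1--9, `NA` for `AAAA`.}
#'   \item{canonical}{canonical member pattern (equals `class`).}
#'   \item{alternative}{the reverse-complement member pattern when distinct
#'     from the canonical one, otherwise `NA`.}
#'   \item{members}{list column of all member patterns.}
#'   \item{interstrand}{`TRUE` for the nine classes using both strands.}
#'   \item{swap_partner}{class containing the strand-swapped canonical
#'     pattern.}
#' }
#' @examples
#' cls <- topology_classes()
#' sum(cls$interstrand) # 9
#' @export
topology_classes <- function() {
  all16 <- apply(expand.grid(rep(list(.tract_letters), 4)), 1, paste, collapse = "")
  canon_of <- vapply(all16, function(p) {
    mem <- unique(c(p, rc_pattern(p)))
    # the published name is the member that appears in .class_order; the
    # AAAA/BBBB pair canonicalizes to AAAA
    hit <- mem[mem %in% .class_order]
    if (length(hit) != 1L) rlang::abort("pattern does not canonicalize uniquely")
    hit
  }, character(1))

  out <- tibble::tibble(
    class = .class_order,
    cao_number = .cao_numbers,
    canonical = .class_order,
    alternative = vapply(.class_order, function(nm) {
      rc <- rc_pattern(nm)
      if (rc == nm) NA_character_ else rc
    }, character(1), USE.NAMES = FALSE),
    members = lapply(.class_order, function(nm) {
      sort(names(canon_of)[canon_of == nm])
    }),
    interstrand = .class_order != "AAAA"
  )
  out$swap_partner <- unname(canon_of[swap_pattern(out$canonical)])
  out
}

# class table is pure combinatorics; compute once per session
.dsquad_cache <- new.env(parent = emptyenv())

.class_table <- function() {
  if (is.null(.dsquad_cache$classes)) .dsquad_cache$classes <- topology_classes()
  .dsquad_cache$classes
}

# fetch one class row, erroring on unknown names
.class_row <- function(cls) {
  tab <- .class_table()
  i <- match(cls, tab$class)
  if (is.na(i)) rlang::abort(paste0("unknown topology class '", cls, "'"))
  tab[i, ]
}
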