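#' Merge overlapping PQS records into unique sites
#'
#' Predictions of different topology classes may overlap; a unique site is a
#' maximal connected component of records under the ">= 1 shared base"
#' overlap relation (0-based half-open intervals: `start < other end` both
#' ways; abutting intervals do not overlap). Records are sorted by
#' coordinate and swept left to right, an O(N log N) operation.
#'
#' @param records PQS records ([scan_pqs()]) or any tibble with `seq_id`,
#'   `start`, `end`; a `class` column is used for filtering and reporting
#'   when present.
#' @param classes Which records enter the merge: `"interstrand"` (default;
#'   the nine two-strand classes, giving unique DS-PQS sites),
#'   `"intrastrand"` (`AAAA` only), `"all"`, or a character vector of class
#'   names.
#' @return A tibble of site groups: `seq_id`, `start`, `end` (the covering
#'   span), `n_members`, and `classes` (comma-separated class names present,
#'   when the input carries classes), in coordinate order.
#' @examples
#' r <- scan_pqs(c(s = "GGGAGGGACCCACCCAGGGACCCAGGGACCC"))
#' merge_sites(r, "all")
#' @export
merge_sites <- function(records, classes = "interstrand") {
  stopifnot(all(c("seq_id", "start", "end") %in% names(records)))
  records <- .filter_classes(records, classes)
  if (nrow(records) == 0L) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), n_members = integer(),
                          classes = character()))
  }
  has_class <- "class" %in% names(records)
  records |>
    dplyr::arrange(.data$seq_id, .data$start, .data$end) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::mutate(
      # new group whenever a record starts at or after the running max end
      # (half-open intervals: abutting records share no base)
      .grp = cumsum(.data$start >= dplyr::lag(cummax(as.numeric(.data$end)),
                                              default = -Inf))
    ) |>
    dplyr::group_by(.data$seq_id, .data$.grp) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_members = dplyr::n(),
      classes = if (has_class)
        paste(sort(unique(.data$class)), collapse = ",") else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::select(-".grp") |>
    dplyr::arrange(.data$seq_id, .data$start)
}

.filter_classes <- function(records, classes) {
  if (identical(classes, "all") || !"class" %in% names(records)) return(records)
  keep <- if (identical(classes, "interstrand")) {
    records$class != "AAAA"
  } else if (identical(classes, "intrastrand")) {
    records$class == "AAAA"
  } else {
    invisible(lapply(classes, .class_row))
    records$class %in% classes
  }
  records[keep, , drop = FALSE]
}

#' Per-chromosome PQS summary statistics
#'
#' For each sequence: the intrastrand (`AAAA`) record count, the unique
#' interstrand site count (overlap-merged over the nine interstrand classes
#' only), densities per megabase of sequence length, and the
#' intrastrand/interstrand ratio. A genome-wide row computed from the summed
#' counts (and summed lengths) is appended when `total = TRUE`.
#'
#' @param records PQS records from [scan_pqs()] over every sequence.
#' @param seq_lengths A data frame with columns `seq_id` and `length` (bp);
#'   every `seq_id` present in `records` must appear.
#' @param total Append the genome-wide summary row (`seq_id = "genome"`)?
#' @return A tibble with columns `seq_id`, `length_bp`, `n_interstrand`
#'   (unique sites), `inter_per_mb`, `n_intrastrand`, `intra_per_mb` and
#'   `intra_inter_ratio` (NaN when there are no interstrand sites).
#' @export
chrom_stats <- function(records, seq_lengths, total = TRUE) {
  stopifnot(all(c("seq_id", "length") %in% names(seq_lengths)))
  missing <- setdiff(unique(records$seq_id), seq_lengths$seq_id)
  if (length(missing) > 0L) {
    rlang::abort(paste0("no length given for sequence(s): ",
                        paste(missing, collapse = ", ")))
  }

  inter <- merge_sites(records, "interstrand") |>
    dplyr::count(.data$seq_id, name = "n_interstrand")
  intra <- records |>
    dplyr::filter(.data$class == "AAAA") |>
    dplyr::count(.data$seq_id, name = "n_intrastrand")

  out <- tibble::tibble(seq_id = seq_lengths$seq_id,
                        length_bp = as.numeric(seq_lengths$length)) |>
    dplyr::left_join(inter, by = "seq_id") |>
    dplyr::left_join(intra, by = "seq_id") |>
    dplyr::mutate(dplyr::across(c("n_interstrand", "n_intrastrand"),
                                ~ dplyr::coalesce(.x, 0L)))
  if (total) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      seq_id = "genome",
      length_bp = sum(out$length_bp),
      n_interstrand = sum(out$n_interstrand),
      n_intrastrand = sum(out$n_intrastrand)
    ))
  }
  out |>
    dplyr::mutate(
      inter_per_mb = .data$n_interstrand / (.data$length_bp / 1e6),
      intra_per_mb = .data$n_intrastrand / (.data$length_bp / 1e6),
      intra_inter_ratio = .data$n_intrastrand / .data$n_interstrand
    ) |>
    dplyr::select("seq_id", "length_bp",
                  "n_interstrand", "inter_per_mb",
                  "n_intrastrand", "intra_per_mb", "intra_inter_ratio")
}

#' Asymptotic Poisson z-score
#'
#' `(observed - expected) / sqrt(expected)`, the normal approximation to a
#' Poisson count with the given expectation; used to compare per-chromosome
#' or per-class counts against a genome-wide expectation.
#'
#' @param observed,expected Numeric vectors (expected > 0).
#' @return Numeric z-scores.
#' @examples
#' poisson_z(120, 100) # 2
#' @export
poisson_z <- function(observed, expected) {
  if (any(expected <= 0)) rlang::abort("expected counts must be > 0")
  (observed - expected) / sqrt(expected)
}
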