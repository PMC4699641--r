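#' Count peaks overlapping at least one site
#'
#' A peak "has a hit" when it shares at least one base with at least one
#' site (0-based half-open intervals); each peak is counted at most once.
#' The definition is directional: swapping the roles of peaks and sites
#' counts a different thing.
#'
#' @param peaks,sites Data frames with `seq_id`, `start`, `end`.
#' @return Integer: number of peaks with a hit.
#' @examples
#' peaks_with_hit(data.frame(seq_id = "c", start = 0, end = 100),
#'                data.frame(seq_id = "c", start = 99, end = 120)) # 1
#' @export
peaks_with_hit <- function(peaks, sites) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(peaks)),
            all(c("seq_id", "start", "end") %in% names(sites)))
  if (nrow(peaks) == 0L || nrow(sites) == 0L) return(0L)
  sum(.peak_hit_flags(peaks, sites))
}

# logical vector over the rows of peaks: does the peak overlap >=1 site?
# sweep over the merged site list per seq_id -- O((P+S) log(P+S))
.peak_hit_flags <- function(peaks, sites) {
  flags <- logical(nrow(peaks))
  merged <- merge_sites(sites, "all")
  for (sid in unique(peaks$seq_id)) {
    pi <- which(peaks$seq_id == sid)
    ms <- merged[merged$seq_id == sid, ]
    if (nrow(ms) == 0L) next
    # a peak overlaps some site iff among sites starting before the peak's
    # end, the furthest-reaching end exceeds the peak's start
    ord_end <- cummax(ms$end)
    pos <- findInterval(peaks$end[pi] - 1L, ms$start)
    hit <- rep(FALSE, length(pi))
    sel <- pos > 0L
    hit[sel] <- ord_end[pos[sel]] > peaks$start[pi][sel]
    flags[pi] <- hit
  }
  flags
}

#' Background probability that a random peak overlaps a site
#'
#' Closed-form probability that an interval of a given length, placed
#' uniformly at random on the genome, shares at least one base with at
#' least one of a set of non-overlapping sites: the sum over sites of
#' `site_length + peak_length - 1`, divided by the total genome length and
#' capped at 1.
#'
#' @param sites Merged, non-overlapping site intervals (`seq_id`, `start`,
#'   `end`), e.g. from [merge_sites()].
#' @param seq_lengths Data frame with `seq_id` and `length`.
#' @param peak_length Representative peak length (>= 1); conventionally the
#'   median length of the peak set under analysis.
#' @return A probability in \[0, 1\].
#' @examples
#' background_probability(data.frame(seq_id = "c", start = 100, end = 110),
#'                        data.frame(seq_id = "c", length = 1000), 11) # 0.02
#' @export
background_probability <- function(sites, seq_lengths, peak_length) {
  stopifnot(peak_length >= 1)
  total <- sum(as.numeric(seq_lengths$length))
  if (total <= 0) rlang::abort("empty genome: total sequence length is 0")
  if (nrow(sites) == 0L) return(0)
  widths <- sites$end - sites$start
  min(1, sum(widths + peak_length - 1) / total)
}

#' Upper-tail binomial enrichment test
#'
#' For `k` peaks with a hit among `n` peaks and background hit probability
#' `p`: the upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p)`
#' (including `k` itself) and the enrichment ratio `(k/n) / p`.
#'
#' @param k Number of peaks with a hit (0 <= k <= n).
#' @param n Number of peaks.
#' @param p Background probability.
#' @return A tibble with columns `p_upper` and `enrichment`.
#' @examples
#' binomial_enrichment(7, 10, 0.3)
#' @export
binomial_enrichment <- function(k, n, p) {
  stopifnot(all(k >= 0), all(k <= n), all(p >= 0), all(p <= 1))
  p_upper <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  tibble::tibble(p_upper = p_upper, enrichment = (k / n) / p)
}

# record subsets behind the category argument shared by the enrichment
# functions: "intrastrand" = AAAA records, "interstrand" = DS classes,
# "any" = union of all records, or a single class name
.category_records <- function(records, category) {
  if (identical(category, "any")) return(records)
  .filter_classes(records, switch(category,
                                  intrastrand = "intrastrand",
                                  interstrand = "interstrand",
                                  category))
}

#' Peak-set enrichment in PQS sites
#'
#' For each requested PQS category, counts the peaks overlapping at least
#' one prediction, estimates the background hit probability (closed form,
#' or by Monte-Carlo re-placement of the peaks), and reports the upper-tail
#' binomial p-value and enrichment ratio.
#'
#' @param peaks Peak intervals (`seq_id`, `start`, `end`).
#' @param records PQS records from [scan_pqs()].
#' @param seq_lengths Data frame with `seq_id`, `length`.
#' @param categories Character vector from `"intrastrand"`, `"interstrand"`,
#'   `"any"`, or topology class names.
#' @param null `"closed_form"` (default) or `"shuffle"` (uniform random
#'   re-placement of the peaks, `n_shuffle` draws).
#' @param n_shuffle Number of Monte-Carlo draws for `null = "shuffle"`.
#' @param peak_set Label stored with the result.
#' @return An object of class `"dsquad_enrichment"`: a list with the
#'   per-category results tibble (`$table`) and metadata; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
enrich_peaks <- function(peaks, records, seq_lengths,
                         categories = c("intrastrand", "interstrand", "any"),
                         null = c("closed_form", "shuffle"),
                         n_shuffle = 1000L,
                         peak_set = "peaks") {
  null <- match.arg(null)
  n_peaks <- nrow(peaks)
  if (n_peaks == 0L) rlang::abort("empty peak set")
  peak_len <- stats::median(peaks$end - peaks$start)

  rows <- purrr::map_dfr(categories, function(cat) {
    sub <- .category_records(records, cat)
    sites <- merge_sites(sub, "all")
    k <- peaks_with_hit(peaks, sites)
    p0 <- if (null == "closed_form") {
      background_probability(sites, seq_lengths, peak_len)
    } else {
      .shuffle_background(peaks, sites, seq_lengths, n_shuffle)
    }
    be <- binomial_enrichment(k, n_peaks, p0)
    tibble::tibble(
      peak_set = peak_set, category = cat,
      n_peaks = n_peaks, n_with_hit = k,
      fraction_with_hit = k / n_peaks,
      background_p = p0,
      p_upper = be$p_upper, enrichment = be$enrichment
    )
  })

  structure(list(table = rows, null = null, peak_length = peak_len),
            class = "dsquad_enrichment")
}

# Monte-Carlo background: fraction of uniformly re-placed peaks (original
# widths, random seq_id weighted by length, random start) that hit a site
.shuffle_background <- function(peaks, sites, seq_lengths, n_shuffle) {
  widths <- peaks$end - peaks$start
  lens <- as.numeric(seq_lengths$length)
  hits <- 0
  tot <- 0
  for (i in seq_len(n_shuffle)) {
    sid <- sample(seq_lengths$seq_id, length(widths), replace = TRUE,
                  prob = lens / sum(lens))
    maxstart <- pmax(lens[match(sid, seq_lengths$seq_id)] - widths, 0)
    start <- floor(stats::runif(length(widths), 0, maxstart + 1))
    fake <- tibble::tibble(seq_id = sid, start = start, end = start + widths)
    hits <- hits + sum(.peak_hit_flags(fake, sites))
    tot <- tot + length(widths)
  }
  hits / tot
}

#' @export
print.dsquad_enrichment <- function(x, ...) {
  cat("PQS enrichment (", x$null, " null, representative peak length ",
      x$peak_length, " nt)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dsquad_enrichment <- function(x, ...) x$table

#' @export
glance.dsquad_enrichment <- function(x, ...) {
  tibble::tibble(
    n_peaks = x$table$n_peaks[1],
    n_categories = nrow(x$table),
    min_p_upper = min(x$table$p_upper),
    max_enrichment = max(x$table$enrichment),
    null = x$null
  )
}

#' @export
autoplot.dsquad_enrichment <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$category, y = .data$enrichment,
                                    fill = .data$p_upper < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "enrichment ratio", fill = "p < 0.05") +
    ggplot2::facet_wrap(ggplot2::vars(.data$peak_set)) +
    ggplot2::theme_minimal()
}

#' Fraction of sequence records containing a PQS
#'
#' Scans each record of a sequence set (e.g. fixed-width promoter regions)
#' independently and returns the fraction of records containing at least
#' one PQS of the requested category.
#'
#' @param x Sequences as accepted by [scan_pqs()].
#' @param params A [scan_params()] object.
#' @param category `"intrastrand"`, `"interstrand"`, `"any"` or a class
#'   name.
#' @return A fraction in \[0, 1\].
#' @export
fraction_with_pqs <- function(x, params = scan_params(), category = "any") {
  seqs <- .as_seq_tbl(x)
  if (nrow(seqs) == 0L) rlang::abort("no sequence records")
  recs <- scan_pqs(seqs, params)
  recs <- .category_records(recs, category)
  length(unique(recs$seq_id)) / nrow(seqs)
}

#' Topology-class composition of PQS in peaks versus genome-wide
#'
#' Compares the topology-class spectrum of the PQS falling inside a peak set
#' with the genome-wide spectrum. All overlapping predictions are counted
#' (no unique-site merging), since any of the overlapping PQS can be the
#' functional one. For each class, the in-peak count is tested against the
#' expectation obtained by scaling the genome-wide class fraction to the
#' in-peak total, with an asymptotic Poisson z-score ([poisson_z()]);
#' negative z denotes depletion. Fractions and z-scores are computed over
#' two denominators: all PQS, and interstrand (DS) PQS only (`NA` for
#' `AAAA` under the DS denominator).
#'
#' @param peak_records PQS records overlapping the peak set (e.g. rows of
#'   the genome-wide scan whose interval overlaps a peak).
#' @param genome_records Genome-wide PQS records (the reference spectrum).
#' @return A tibble with one row per topology class: counts, in-peak and
#'   genome-wide fractions over both denominators, and `z_all` / `z_ds`.
#'   Classes absent from both sets get z = 0 and `degenerate = TRUE`.
#' @export
topology_composition <- function(peak_records, genome_records) {
  cls <- .class_table()$class
  cnt <- function(records) {
    vapply(cls, function(cl) sum(records$class == cl), integer(1))
  }
  n_peak <- cnt(peak_records)
  n_gen <- cnt(genome_records)

  frac <- function(n, ds_only) {
    use <- if (ds_only) cls != "AAAA" else rep(TRUE, length(cls))
    denom <- sum(n[use])
    out <- ifelse(use, n / max(denom, 1L), NA_real_)
    if (denom == 0L) out[use] <- 0
    out
  }
  z_for <- function(ds_only) {
    use <- if (ds_only) cls != "AAAA" else rep(TRUE, length(cls))
    expected <- frac(n_gen, ds_only) * sum(n_peak[use])
    z <- rep(NA_real_, length(cls))
    ok <- use & expected > 0
    z[ok] <- poisson_z(n_peak[ok], expected[ok])
    z[use & !ok] <- 0  # class absent genome-wide: degenerate, flagged
    z
  }

  tibble::tibble(
    class = cls,
    n_in_peaks = n_peak,
    n_genome = n_gen,
    frac_all_peaks = frac(n_peak, FALSE),
    frac_all_genome = frac(n_gen, FALSE),
    frac_ds_peaks = frac(n_peak, TRUE),
    frac_ds_genome = frac(n_gen, TRUE),
    z_all = z_for(FALSE),
    z_ds = z_for(TRUE),
    degenerate = n_peak == 0L & n_gen == 0L
  )
}
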