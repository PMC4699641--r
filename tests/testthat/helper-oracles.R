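# Independent reference implementations used across the suite. These are
# deliberately naive (quadratic / union-find) so they share no logic with
# the package's sweep-line and regex code paths.

# connected components of the pairwise-overlap graph via union-find
uf_overlap_groups <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) break
      if (df$seq_id[i] == df$seq_id[j] &&
          df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  length(unique(roots))
}

# quadratic all-pairs count of peaks overlapping >= 1 site
quadratic_peaks_with_hit <- function(peaks, sites) {
  hits <- 0L
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(sites))) {
      if (peaks$seq_id[i] == sites$seq_id[j] &&
          peaks$start[i] < sites$end[j] && sites$start[j] < peaks$end[i]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# direct binomial upper-tail mass summation
sum_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# a synthetic chromosome: A/T background (certified free of any placement
# because no G or C run can exist) with one motif of each requested class
# planted `spacing` nt apart; returns the sequence and the truth table
planted_genome <- function(classes, n_per_class = 1L, spacing = 1000L,
                           seed = 1L, gaps = c(2L, 2L, 2L)) {
  n_motifs <- length(classes) * n_per_class
  len <- spacing * (n_motifs + 1L)
  seq <- random_sequence(len, gc = 0, seed = seed)
  stopifnot(!grepl("[GCgc]", seq))
  truths <- list()
  k <- 0L
  for (cl in classes) {
    for (r in seq_len(n_per_class)) {
      k <- k + 1L
      # gap length 2 satisfies both the same-letter and cross-letter bounds
      sp <- plant_spec(cl, tracts = c(3L, 3L, 3L, 3L), gaps = gaps,
                       at = spacing * k)
      planted <- plant_pqs(seq, sp)
      seq <- planted$seq
      truths[[k]] <- planted$truth
    }
  }
  list(seq = seq, truth = dplyr::bind_rows(truths))
}
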