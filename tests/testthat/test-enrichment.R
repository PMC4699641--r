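iv <- function(seq_id, start, end) {
  tibble::tibble(seq_id = seq_id, start = as.integer(start),
                 end = as.integer(end))
}

test_that("a peak hits a site with one shared base, not when abutting", {
  expect_equal(peaks_with_hit(iv("c", 0, 100), iv("c", 99, 120)), 1L)
  expect_equal(peaks_with_hit(iv("c", 0, 100), iv("c", 100, 120)), 0L)
  expect_equal(peaks_with_hit(iv("c", 0, 100), iv("other", 0, 100)), 0L)
  expect_equal(peaks_with_hit(iv("c", c(0, 200), c(100, 300)),
                              iv("c", c(50, 250, 260), c(60, 255, 270))), 2L)
})

test_that("peak hit counting agrees with the quadratic all-pairs oracle", {
  set.seed(5)
  for (rep in 1:3) {
    ps <- sample.int(100000L, 500L, replace = TRUE)
    ss <- sample.int(100000L, 500L, replace = TRUE)
    peaks <- iv(sample(c("c1", "c2"), 500, TRUE), ps,
                ps + sample.int(200L, 500L, TRUE))
    sites <- iv(sample(c("c1", "c2"), 500, TRUE), ss,
                ss + sample.int(40L, 500L, TRUE))
    expect_equal(peaks_with_hit(peaks, sites),
                 quadratic_peaks_with_hit(peaks, sites))
    # the definition is directional: swapped roles count sites, not peaks
    expect_equal(peaks_with_hit(sites, peaks),
                 quadratic_peaks_with_hit(sites, peaks))
  }
})

test_that("background probability follows the closed length-aware form", {
  lens <- tibble::tibble(seq_id = "c", length = 1000)
  expect_equal(background_probability(iv("c", 100, 110), lens, 11), 0.02)
  expect_equal(background_probability(iv("c", 0, 1000), lens, 50), 1) # capped
  expect_equal(background_probability(iv(character(), integer(), integer()),
                                      lens, 50), 0)
  expect_error(background_probability(iv("c", 0, 10),
                                      tibble::tibble(seq_id = "c", length = 0),
                                      5), "empty genome")
})

test_that("the upper-tail binomial matches direct mass summation", {
  expect_equal(binomial_enrichment(0, 10, 0.3)$p_upper, 1)
  expect_equal(binomial_enrichment(8, 8, 0.5)$p_upper, 0.5^8)
  expect_equal(binomial_enrichment(7, 10, 0.3)$p_upper,
               sum_binom_upper(7, 10, 0.3))
  set.seed(6)
  for (i in 1:25) {
    n <- sample.int(1000L, 1)
    k <- sample.int(n, 1)
    p <- stats::runif(1)
    expect_equal(binomial_enrichment(k, n, p)$p_upper,
                 sum_binom_upper(k, n, p), tolerance = 1e-12)
  }
  # non-increasing in k
  pu <- binomial_enrichment(0:20, 20, 0.4)$p_upper
  expect_true(all(diff(pu) <= 0))
  # degenerate null
  z <- binomial_enrichment(3, 10, 0)
  expect_equal(z$p_upper, 0)
  expect_equal(z$enrichment, Inf)
})

test_that("fraction of records with a PQS reflects planted truth", {
  set.seed(8)
  clean <- vapply(1:4, function(i) random_sequence(1000, 0), character(1))
  with_ds <- vapply(1:6, function(i) {
    plant_pqs(random_sequence(1000, 0),
              plant_spec("ABBA", gaps = c(2L, 2L, 2L), at = 400L))$seq
  }, character(1))
  seqs <- stats::setNames(c(with_ds, clean), paste0("r", 1:10))
  expect_equal(fraction_with_pqs(seqs, category = "interstrand"), 0.6)
  expect_equal(fraction_with_pqs(seqs, category = "intrastrand"), 0)
  expect_equal(fraction_with_pqs(seqs, category = "any"), 0.6)

  all_n <- c(n1 = strrep("N", 500), n2 = strrep("N", 500))
  expect_equal(fraction_with_pqs(all_n), 0)

  fifteen <- c(a = "GGGAGGGACCCACCC", b = "TTGGGAGGGACCCACCCTT")
  expect_equal(fraction_with_pqs(fifteen, category = "interstrand"), 1)
  expect_equal(fraction_with_pqs(fifteen, category = "intrastrand"), 0)
})

test_that("topology composition z-scores flag planted class bias", {
  classes <- topology_classes()$class
  genome <- tibble::tibble(class = rep(classes, each = 20))
  # identical spectra: all z exactly 0
  comp0 <- topology_composition(genome, genome)
  expect_true(all(comp0$z_all == 0))
  expect_true(all(comp0$z_ds[comp0$class != "AAAA"] == 0))
  expect_equal(sum(comp0$frac_all_peaks), 1)
  expect_equal(sum(comp0$frac_ds_peaks, na.rm = TRUE), 1)

  # peaks covering only BABB records
  comp1 <- topology_composition(tibble::tibble(class = rep("BABB", 30)), genome)
  expect_gt(comp1$z_all[comp1$class == "BABB"], 0)
  expect_true(all(comp1$z_all[comp1$class != "BABB"] < 0))

  # class absent everywhere: degenerate, z 0 by convention
  g2 <- tibble::tibble(class = rep(setdiff(classes, "ABAB"), each = 5))
  comp2 <- topology_composition(g2, g2)
  expect_equal(comp2$z_all[comp2$class == "ABAB"], 0)
  expect_true(comp2$degenerate[comp2$class == "ABAB"])
})

test_that("enrich_peaks detects planted association and supports tidy/glance/autoplot", {
  g <- planted_genome(rep(c("AABB", "BAAA"), 10), spacing = 500L, seed = 31)
  recs <- scan_pqs(c(chrT = g$seq))
  lens <- tibble::tibble(seq_id = "chrT", length = nchar(g$seq))
  # peaks centred on the first 10 planted motifs: strong association
  truth <- g$truth[1:10, ]
  peaks <- iv("chrT", truth$start - 20L, truth$end + 20L)
  e <- enrich_peaks(peaks, recs, lens, categories = c("interstrand", "any"))
  tab <- tidy(e)
  expect_s3_class(tab, "tbl_df")
  expect_equal(tab$n_with_hit, c(10L, 10L))
  expect_true(all(tab$enrichment > 1))
  expect_true(all(tab$p_upper < 1e-6))
  gl <- glance(e)
  expect_equal(gl$n_peaks, 10L)
  expect_s3_class(ggplot2::autoplot(e), "ggplot")

  # shuffle null approximates the closed form
  set.seed(9)
  es <- enrich_peaks(peaks, recs, lens, categories = "interstrand",
                     null = "shuffle", n_shuffle = 300L)
  expect_equal(es$table$background_p, tab$background_p[1], tolerance = 0.35)
})
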