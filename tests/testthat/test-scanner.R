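test_that("the canonical interstrand 15-mer yields one AABB match and nothing else", {
  seq <- "GGGAGGGACCCACCC"
  r <- scan_pqs(c(chr1 = seq))
  expect_equal(nrow(r), 1L)
  expect_equal(r$class, "AABB")
  expect_equal(r$start, 0L)
  expect_equal(r$end, 15L)
  expect_equal(r$matched, seq)
  expect_equal(r$tract_start[[1]], c(0L, 4L, 8L, 12L))
  expect_equal(r$tract_width[[1]], c(3L, 3L, 3L, 3L))
  expect_equal(pqs_guanines(r), 12L)
  expect_equal(nrow(scan_class(seq, "s", "AAAA")), 0L)
})

test_that("zero-length cross-strand gaps are legal", {
  r <- scan_pqs(c(s = "GGGCCCGGGCCC"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$class, "ABAB")
  expect_equal(r$start, 0L)
  expect_equal(r$end, 12L)
  expect_equal(pqs_guanines(r), 12L)
})

test_that("sequences without guanine or cytosine runs yield no matches", {
  r <- scan_pqs(c(s = "AAAAAAAAAAAAAAA"))
  expect_equal(nrow(r), 0L)
})

test_that("intrastrand matches report the strand of the matching alternative", {
  g <- scan_class("GGGAGGGAGGGAGGG", "s", "AAAA")
  expect_equal(g$pattern, "AAAA")
  expect_equal(g$strand, "+")
  c <- scan_class("CCCTCCCTCCCTCCC", "s", "AAAA")
  expect_equal(c$pattern, "BBBB")
  expect_equal(c$strand, "-")
  # interstrand records carry no single strand
  expect_equal(scan_class("GGGAGGGACCCACCC", "s", "AABB")$strand, ".")
})

test_that("alternative member patterns are matched and attributed", {
  # AABA is the reverse complement of BABB and belongs to that class
  sp <- plant_spec("BABB", gaps = c(1L, 1L, 1L), member = "alternative")
  expect_equal(sp$pattern, "AABA")
  motif <- motif_sequence(sp, loop_alphabet = "T")
  r <- scan_class(motif, "s", "BABB")
  expect_equal(nrow(r), 1L)
  expect_equal(r$pattern, "AABA")
  expect_equal(r$class, "BABB")
})

test_that("backreferences force exact tract repetition, with surplus absorbed into loops", {
  # first guanine run is 4 nt but later runs are 3 nt; the first capture
  # must backtrack to GGG and the surplus G joins the loop
  seq <- "GGGGAGGGACCCACCC"
  r <- scan_class(seq, "s", "AABB")
  expect_equal(nrow(r), 1L)
  expect_equal(r$tract_width[[1]], c(3L, 3L, 3L, 3L))
  expect_equal(r$tract_start[[1]], c(0L, 5L, 9L, 13L))
  validate_pqs(r, c(s = seq))

  # a long unbroken run supplies several same-letter tracts with G loops
  run <- strrep("G", 15)
  rr <- scan_class(run, "s", "AAAA")
  expect_equal(nrow(rr), 1L)
  validate_pqs(rr, c(s = run))
})

test_that("global matching within a class is non-overlapping and resumes at match end", {
  seq <- paste0("GGGAGGGACCCACCC", strrep("T", 10), "GGGAGGGACCCACCC")
  r <- scan_class(seq, "s", "AABB")
  expect_equal(nrow(r), 2L)
  expect_true(all(r$start[-1] >= utils::head(r$end, -1)))
  expect_equal(r$start, c(0L, 25L))
})

test_that("records of different classes may overlap before merging", {
  # AABB motif directly followed by more C tracts creates overlapping
  # predictions of several classes on the same span
  seq <- "GGGAGGGACCCACCCACCCACCC"
  r <- scan_pqs(c(s = seq))
  expect_gt(nrow(r), 1L)
  classes <- unique(r$class)
  expect_true("AABB" %in% classes)
  validate_pqs(r, c(s = seq))
})

test_that("case handling: fold rescues soft-masked motifs, strict rejects them", {
  masked <- tolower("GGGAGGGACCCACCC")
  up <- scan_pqs(c(s = masked), scan_params(case_mode = "fold"))
  expect_equal(nrow(up), 1L)
  expect_equal(up$matched, masked) # original case preserved verbatim
  strict <- scan_pqs(c(s = masked), scan_params(case_mode = "strict"))
  expect_equal(nrow(strict), 0L)
  # uppercase scans identically in both modes
  plain <- scan_pqs(c(s = toupper(masked)), scan_params(case_mode = "strict"))
  expect_equal(plain$start, up$start)
  expect_equal(plain$class, up$class)
})

test_that("ambiguity codes may sit in loops but never in tracts", {
  seq <- "GGGNGGGNCCCNCCC"
  r <- scan_class(seq, "s", "AABB")
  expect_equal(nrow(r), 1L)
  strict_loops <- scan_class(seq, "s", "AABB",
                             scan_params(ambiguous_in_loops = FALSE))
  expect_equal(nrow(strict_loops), 0L)
  # N interrupting a tract leaves runs too short
  expect_equal(nrow(scan_class("GGNAGGGACCCACCC", "s", "AABB")), 0L)
})

test_that("relaxed 12 nt loops extend but never lose matches", {
  base <- scan_params()
  relaxed <- scan_params(loop_max_alt = 12)
  expect_equal(relaxed$same_loop_max, 12L)
  expect_equal(relaxed$cross_gap_max, 12L)
  # a 10 nt loop is only found under the relaxed bounds
  seq <- paste0("GGG", strrep("T", 10), "GGGACCCACCC")
  expect_equal(nrow(scan_class(seq, "s", "AABB", base)), 0L)
  expect_equal(nrow(scan_class(seq, "s", "AABB", relaxed)), 1L)

  set.seed(101)
  for (i in 1:40) {
    s <- random_sequence(150, 0.55)
    for (cl in c("AAAA", "AABB", "ABAA", "BABB")) {
      if (nrow(scan_class(s, "s", cl, base)) > 0) {
        expect_gt(nrow(scan_class(s, "s", cl, relaxed)), 0L)
      }
    }
  }
})

test_that("every scanned record satisfies the motif invariants (engine-independent check)", {
  set.seed(7)
  for (gc in c(0.4, 0.6)) {
    for (i in 1:25) {
      s <- stats::setNames(random_sequence(300, gc), paste0("s", i))
      r <- scan_pqs(s)
      expect_silent(validate_pqs(r, s))
      if (nrow(r) > 0) {
        expect_equal(r$end - r$start, nchar(r$matched))
        expect_equal(pqs_guanines(r), r$n_guanines)
      }
    }
  }
})

test_that("interstrand classes are closed under reverse complement of the sequence", {
  revcomp <- function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(11)
  cls <- topology_classes()$class
  for (i in 1:30) {
    s <- random_sequence(150, 0.6)
    rc <- revcomp(s)
    for (cl in cls) {
      expect_equal(nrow(scan_class(s, "s", cl)) > 0,
                   nrow(scan_class(rc, "s", cl)) > 0,
                   info = paste(cl, s))
    }
  }
})

test_that("scan_pqs accepts data frames, named vectors and FASTA paths", {
  seqs <- c(a = "GGGAGGGACCCACCC", b = "GGGCCCGGGCCC")
  r1 <- scan_pqs(seqs)
  r2 <- scan_pqs(tibble::tibble(seq_id = names(seqs), seq = unname(seqs)))
  expect_equal(r1, r2)
  tf <- tempfile(fileext = ".fa")
  write_fasta(seqs, tf)
  r3 <- scan_pqs(tf)
  expect_equal(r1, r3)
  expect_error(scan_pqs(unname(seqs)), "named")
  expect_error(scan_pqs(seqs, scan_params(), classes = "XYZ"), "unknown")
})

test_that("matcher expressions mirror the published construction rules", {
  p <- scan_params()
  # strip the span-recovery groups to compare the generated language shape
  bare <- function(cls) gsub("[()]", "", class_regex(cls, p)$regex)
  expect_equal(bare("AABB"), "G{3,}.{1,7}\\1.{0,7}C{3,}.{1,7}\\5")
  expect_match(class_regex("ABBA", p)$regex, "\\|") # two-member alternation
  expect_false(grepl("\\|", class_regex("AABB", p)$regex)) # single member
  expect_equal(length(class_regex("AAAA", p)$alts), 2L) # G and C alternatives
  expect_error(class_regex("ABCD"), "A/B|unknown")
})
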