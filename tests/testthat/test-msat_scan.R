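test_that("repeat-class enumeration matches exhaustive necklace counting", {
  cls4 <- enumerate_repeat_classes(list(c(4L, 4L)))
  cls3 <- enumerate_repeat_classes(list(c(3L, 5L)))
  expect_equal(nrow(cls4), 66L)
  expect_equal(nrow(cls3), 20L)

  # oracle: canonical rotations of all 256 / 64 units, homopolymers removed
  enumerate_oracle <- function(k) {
    units <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                         stringsAsFactors = FALSE))
    units <- units[!vapply(units, function(u) {
      ch <- strsplit(u, "")[[1]]; all(ch == ch[1])
    }, logical(1))]
    sort(unique(unname(vapply(units, function(u) min(rotations_of(u)), character(1)))))
  }
  expect_equal(cls4$unit, enumerate_oracle(4))
  expect_equal(cls3$unit, enumerate_oracle(3))

  # GGAA and all its rotations share the canonical unit AAGG
  expect_true(all(vapply(c("GGAA", "GAAG", "AAGG", "AGGA"),
                         canonical_rotation, character(1)) == "AAGG"))
  # the GGAA class and its reverse complement class point at each other
  g <- ggaa_classes()
  expect_setequal(g$unit, c("AAGG", "CCTT"))
  expect_equal(g$rc_partner[match("AAGG", g$unit)], "CCTT")
  expect_equal(g$rc_partner[match("CCTT", g$unit)], "AAGG")
})

test_that("microsatellite runs are maximal, thresholded, and broken at N", {
  g <- ggaa_classes()
  hits <- find_repeats("GGAAGGAAGGAAGGAA", g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_repeats, 4L)
  expect_equal(c(hits$start, hits$end), c(0L, 16L))

  expect_equal(nrow(find_repeats("GGAAGGAAGGAA", g)), 0L)

  seven <- find_repeats(paste0(strrep("C", 5), strrep("GGAA", 7), strrep("C", 5)), g)
  expect_equal(nrow(seven), 1L)  # one maximal run, not four overlapping hits
  expect_equal(seven$n_repeats, 7L)

  broken <- find_repeats(paste0(strrep("GGAA", 2), "N", strrep("GGAA", 4)), g)
  expect_equal(nrow(broken), 1L)
  expect_equal(broken$n_repeats, 4L)
})

test_that("hit sets equal the regex oracle and respect flanking/reverse-complement symmetry", {
  classes <- enumerate_repeat_classes()
  set.seed(31)
  for (rep in 1:30) {
    s <- random_seq(2000)
    for (p in 1:3) {
      cl <- classes[sample(nrow(classes), 1), ]
      run <- strrep(cl$unit, cl$min_repeats + sample(0:4, 1))
      pos <- sample(2000 - nchar(run) - 1, 1)
      substr(s, pos, pos + nchar(run) - 1) <- run
    }
    impl <- find_repeats(s, classes)
    expect_equal(hit_key(impl), hit_key(oracle_repeat_hits(s, classes)))

    # flanking invariance: prepending unrelated sequence shifts, never changes
    flank <- strrep("N", 7)
    shifted <- find_repeats(paste0(flank, s), classes)
    expect_equal(hit_key(impl), hit_key(within(as.data.frame(shifted), {
      start <- start - 7L; end <- end - 7L
    })))

    # reverse-complementing maps each class to its rc_partner, same counts
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    tab_fwd <- table(impl$unit)
    tab_rc <- table(find_repeats(rc, classes)$unit)
    mapped <- classes$rc_partner[match(names(tab_fwd), classes$unit)]
    expect_equal(as.integer(tab_rc[mapped]), as.integer(tab_fwd))
  }
})

test_that("per-region counts are length-normalized per kilobase", {
  s <- random_seq(2000)
  for (pos in c(100, 700, 1500)) {
    substr(s, pos, pos + 15) <- strrep("GGAA", 4)
  }
  genome <- toy_genome(chr1 = s)
  reg <- region_tbl("chr1", 0L, 2000L)
  x <- count_msats_in_regions(reg, genome, ggaa_classes())
  expect_equal(x$msat_count, 3L)
  expect_equal(x$msat_per_kb, 1.5)

  empty <- count_msats_in_regions(region_tbl("chr1", 1900L, 2000L), genome,
                                  ggaa_classes())
  expect_equal(empty$msat_count, 0L)

  # normalized counts scale inversely with region length
  half <- count_msats_in_regions(region_tbl("chr1", 0L, 1000L), genome,
                                 ggaa_classes())
  expect_equal(half$msat_per_kb, half$msat_count * 1000 / 1000)
  expect_error(count_msats_in_regions(region_tbl("chr1", 0L, 3000L), genome),
               "beyond")
})

test_that("fusion-TF peaks are flagged by tandem GGAA content per mode", {
  s <- paste0(random_seq(50), strrep("GGAA", 4), random_seq(50),
              strrep("TTCC", 5), random_seq(50))
  genome <- toy_genome(chr1 = s)
  pk <- region_tbl("chr1", c(40L, 110L), c(80L, 140L))
  expect_equal(flag_msat_peaks(pk, genome, "rotation_rc"), c(TRUE, TRUE))
  expect_equal(flag_msat_peaks(pk, genome, "literal"), c(TRUE, FALSE))

  # interleaved GGAA/TTCC without 4 tandem copies of one unit never flags
  g2 <- toy_genome(chr1 = paste0("GGAAGGAATTCCGGAA", random_seq(20)))
  pk2 <- region_tbl("chr1", 0L, 16L)
  expect_equal(flag_msat_peaks(pk2, g2, "literal"), FALSE)
  expect_equal(flag_msat_peaks(pk2, g2, "rotation_rc"), FALSE)

  # random peaks agree with the regex oracle
  set.seed(32)
  cls <- ggaa_classes()
  for (rep in 1:20) {
    s <- random_seq(400)
    if (rep %% 2 == 0) {
      substr(s, 100, 100 + 15) <- strrep("GGAA", 4)
    }
    genome <- toy_genome(chr1 = s)
    pk <- region_tbl("chr1", 0L, 400L)
    expect_equal(flag_msat_peaks(pk, genome, "rotation_rc"),
                 nrow(oracle_repeat_hits(s, cls)) > 0)
  }
})

test_that("the paired enrichment test matches the exact signed-rank null", {
  se <- c(2.1, 1.8, 2.5, 3.0, 1.9, 2.2, 2.8, 2.4, 2.0, 2.6)
  enh <- se - runif(10, 0.1, 0.5)
  res <- paired_enrichment_test(se, enh)
  expect_equal(res$p_value, 2 / 1024)  # all 10 differences positive, exact null
  expect_equal(res$n_pairs, 10L)

  expect_error(paired_enrichment_test(rep(1, 10), rep(1, 10)), "insufficient")
  expect_error(paired_enrichment_test(1:3, 4:6), "insufficient")
  expect_error(paired_enrichment_test(1:4, 1:3), "equal length")
})

test_that("the fraction of regions with a microsatellite is a plain percentage", {
  s <- paste0(strrep("GGAA", 5), random_seq(100), strrep("GGAA", 6), random_seq(300))
  genome <- toy_genome(chr1 = s)
  regs <- region_tbl("chr1", c(0L, 50L, 120L, 300L), c(30L, 110L, 150L, 400L))
  expect_equal(fraction_with_msat(regs, genome), 50)
  none <- region_tbl("chr1", c(200L, 300L), c(250L, 350L))
  expect_equal(fraction_with_msat(none, genome), 0)
  expect_error(fraction_with_msat(region_tbl(character(), integer(), integer()),
                                  genome), "empty")
})
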