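scored_tbl <- function(signals) {
  tibble::tibble(chrom = "chr1",
                 start = as.integer(seq_along(signals) * 10000L),
                 end = as.integer(seq_along(signals) * 10000L + 500L),
                 n_constituents = 1L,
                 constituents = vector("list", length(signals)),
                 net_signal = signals)
}

test_that("stitching merges peaks within the gap and drops TSS-contained peaks", {
  pk <- region_tbl("chr1", c(0L, 5000L), c(1000L, 6000L))
  st <- stitch_peaks(pk, 12500)
  expect_equal(nrow(st), 1L)
  expect_equal(st$start, 0L)
  expect_equal(st$end, 6000L)
  expect_equal(st$n_constituents, 2L)

  pk2 <- region_tbl("chr1", c(0L, 21000L), c(1000L, 22000L))
  expect_equal(nrow(stitch_peaks(pk2, 12500)), 2L)

  # a peak fully inside the exclusion window is dropped; a partial overlap kept
  excl <- region_tbl("chr1", 400L, 5500L)
  st3 <- stitch_peaks(region_tbl("chr1", c(500L, 5000L), c(900L, 6000L)), 12500, excl)
  expect_equal(nrow(st3), 1L)
  expect_equal(st3$start, 5000L)
})

test_that("stitching equals the O(n^2) gap-merge oracle and partitions the peaks", {
  set.seed(21)
  pk <- region_tbl(
    chrom = sample(c("chr1", "chr2"), 200, TRUE),
    start = s <- sample.int(3e5, 200),
    end = s + sample.int(3000, 200)
  )
  st <- stitch_peaks(pk, 12500)
  expect_equal(sum(st$n_constituents), nrow(pk))  # partition property
  groups <- lapply(st$constituents, function(cc) {
    sort(match(paste(cc$chrom, cc$start, cc$end),
               paste(pk$chrom, pk$start, pk$end)))
  })
  expect_equal(partition_key(groups),
               partition_key(oracle_stitch_partition(pk, 12500)))
})

test_that("region scoring sums input-subtracted coverage, floored at zero", {
  st <- stitch_peaks(region_tbl("chr1", 0L, 10L), 0)
  tr <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, value = 3.0)
  expect_equal(score_regions(st, tr)$net_signal, 30)
  ctl <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, value = 5.0)
  tr2 <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, value = 2.0)
  expect_equal(score_regions(st, tr2, ctl)$net_signal, 0)

  set.seed(22)
  for (i in 1:20) {
    bounds <- sort(sample.int(500, 9))
    track <- tibble::tibble(chrom = "chr1",
                            start = c(0L, bounds), end = c(bounds, 520L),
                            value = round(runif(10, 0, 5), 3))
    reg <- region_tbl("chr1", s <- sample.int(400, 1), s + sample.int(100, 1))
    st <- stitch_peaks(reg, 0)
    expect_equal(score_regions(st, track)$net_signal,
                 oracle_signal_sum(reg, track), tolerance = 1e-9)
  }
})

test_that("the tangent cutoff flags only the steep tail of the ranked curve", {
  p <- call_superenhancers(scored_tbl(c(0, 1, 2, 3, 100)), "s")
  expect_equal(p$regions$net_signal[p$regions$is_super], 100)
  expect_equal(p$cutoff_signal, 3)

  flat <- call_superenhancers(scored_tbl(rep(7, 10)), "s")
  expect_equal(sum(flat$regions$is_super), 0L)

  expect_error(call_superenhancers(scored_tbl(5)), "insufficient")
})

test_that("the cutoff lands at the planted elbow of a 1000-point hockey stick", {
  i <- 1:1000
  s <- ifelse(i <= 950, i, 950 + (i - 950) * 3000)
  p <- call_superenhancers(scored_tbl(s), "s")
  cut_rank <- max(p$regions$rank[!p$regions$is_super])
  expect_lte(abs(cut_rank - 950L), 1L)
  expect_equal(oracle_cutoff_index(s), 950L)
  # agreement with the independent slope scan on random curves
  set.seed(23)
  for (rep in 1:20) {
    sig <- sort(rlnorm(sample(50:500, 1), 3, 1.5))
    p <- call_superenhancers(scored_tbl(sig), "s")
    oi <- oracle_cutoff_index(sig)
    expect_equal(sum(p$regions$is_super), sum(sig > sig[oi]))
  }
})

test_that("normalization scales to the sample maximum and truncates to top n", {
  p <- call_superenhancers(scored_tbl(c(50, 200)), "s")
  p <- normalize_profile(p)
  expect_equal(p$regions$normalized_intensity, c(0.25, 1.0))

  big <- make_profile("s", "chr1", (1:600) * 10000L, (1:600) * 10000L + 500L,
                      intensity = seq(0.1, 1, length.out = 600))
  big$regions$net_signal <- big$regions$normalized_intensity
  trunc <- normalize_profile(big, top_n = 500)
  expect_equal(sum(trunc$regions$is_super), 500L)
  # the demoted regions are the weakest
  expect_false(any(trunc$regions$is_super[1:100]))
  expect_identical(normalize_profile(trunc, top_n = 500)$regions, trunc$regions)
})

test_that("consensus building merges transitively and records contributor intensities", {
  p1 <- make_profile("a", "chr1", 1000L, 2000L, 0.8)
  p2 <- make_profile("b", "chr1", 1000L, 2000L, 0.6)
  cons <- build_consensus(list(p1, p2))
  expect_equal(nrow(cons$regions), 1L)
  expect_equal(unname(cons$values[1, ]), c(0.8, 0.6))

  p3 <- make_profile("b", "chr1", 50000L, 60000L, 0.5)
  cons2 <- build_consensus(list(p1, p3))
  expect_equal(nrow(cons2$regions), 2L)
  expect_equal(sort(as.numeric(cons2$values)), c(0, 0, 0.5, 0.8))

  set.seed(24)
  for (rep in 1:50) {
    profs <- lapply(1:3, function(s) {
      n <- sample(3:8, 1)
      st <- sample.int(50000, n)
      make_profile(paste0("s", s), "chr1", st, st + sample.int(3000, n) + 500L,
                   runif(n))
    })
    cons <- build_consensus(profs, min_overlap = 0.5)
    ses <- dplyr::bind_rows(lapply(profs, function(p) p$regions))
    # oracle: transitive closure over pairwise >=50% of-smaller overlap
    n <- nrow(ses)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] == comp[j]) next
        ov <- min(ses$end[i], ses$end[j]) - max(ses$start[i], ses$start[j])
        if (ov / min(ses$end[i] - ses$start[i], ses$end[j] - ses$start[j]) >= 0.5) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    spans <- vapply(split(seq_len(n), comp), function(idx) {
      paste(min(ses$start[idx]), max(ses$end[idx]))
    }, character(1))
    expect_setequal(paste(cons$regions$start, cons$regions$end), unname(spans))
    # matrix values come from a contributing sample's own intensity (or 0)
    for (gi in seq_len(nrow(cons$regions))) {
      for (s in cons$samples) {
        v <- cons$values[gi, s]
        if (v > 0) {
          p <- profs[[match(s, vapply(profs, `[[`, "", "sample_id"))]]
          expect_true(any(abs(p$regions$normalized_intensity - v) < 1e-12))
        }
      }
    }
  }
})

test_that("PCA coordinates are deterministic, separate planted groups, and bound variance", {
  p1 <- make_profile("a", "chr1", (1:5) * 20000L, (1:5) * 20000L + 1000L, rep(0.9, 5))
  cons <- build_consensus(list(p1, make_profile("b", "chr1", (1:5) * 20000L,
                                                (1:5) * 20000L + 1000L, rep(0.9, 5))))
  pca <- pca_profiles(cons, 1)
  expect_equal(pca$scores$PC1[1], pca$scores$PC1[2])
  expect_error(pca_profiles(cons, 5), "exceeds")

  # two groups of samples with disjoint SE repertoires separate on PC1
  set.seed(25)
  profs <- c(
    lapply(1:4, function(i) make_profile(paste0("g1_", i), "chr1",
                                         (1:50) * 20000L, (1:50) * 20000L + 1000L,
                                         runif(50, 0.5, 1))),
    lapply(1:4, function(i) make_profile(paste0("g2_", i), "chr2",
                                         (1:50) * 20000L, (1:50) * 20000L + 1000L,
                                         runif(50, 0.5, 1)))
  )
  cons <- build_consensus(profs)
  pca <- pca_profiles(cons, 2)
  g <- rep(1:2, each = 4)
  r1 <- range(pca$scores$PC1[g == 1])
  r2 <- range(pca$scores$PC1[g == 2])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
  expect_true(all(pca$var_explained >= 0))
  expect_lte(sum(pca$var_explained), 1 + 1e-9)
})

test_that("the rank curve is the sorted cross-sample mean intensity", {
  p1 <- make_profile("a", "chr1", c(10000L, 40000L), c(12000L, 42000L), c(0.2, 0.8))
  p2 <- make_profile("b", "chr1", c(10000L, 40000L), c(12000L, 42000L), c(0.4, 0.6))
  cons <- build_consensus(list(p1, p2))
  curve <- se_rank_curve(cons)
  expect_equal(curve$mean_intensity, c(0.3, 0.7))
  expect_true(all(diff(curve$mean_intensity) >= 0))
  one <- se_rank_curve(cons, "a")
  expect_equal(one$mean_intensity, c(0.2, 0.8))
})
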