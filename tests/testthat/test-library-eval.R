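eval_regions <- tibble::tibble(
  seq_id = c("chr1", "cp"),
  region_class = c("genomic", "chloroplast"),
  length = c(10000L, 3000L)
)
eval_rrna <- tibble::tibble(seq_id = "chr1", start = 8000L, end = 9000L)

test_that("mapped-pair classification respects regions, rRNA overlap and filters", {
  pairs <- tibble::tibble(
    seq_id = c("cp", "cp", "chr1", "chr1"),
    start = c(0L, 100L, 500L, 8500L),
    end = c(300L, 400L, 800L, 8800L),
    mapq = c(30, 30, 30, 30)
  )
  all_cp <- classify_mapped_reads(pairs[1:2, ], eval_regions)
  expect_equal(all_cp$proportion[all_cp$class == "chloroplast"], 1)

  mix <- classify_mapped_reads(pairs, eval_regions, rrna = eval_rrna,
                               n_unmapped = 4)
  expect_equal(sum(mix$proportion), 1)
  expect_equal(mix$n_pairs, c(1L, 2L, 1L, 4L))

  expect_warning(
    empty <- classify_mapped_reads(pairs, eval_regions, min_mapq = 99),
    "No read pairs")
  expect_equal(nrow(empty), 0L)

  expect_error(
    classify_mapped_reads(tibble::tibble(seq_id = "zz", start = 0L, end = 5L),
                          eval_regions),
    "absent")
})

test_that("fragment lengths come from outer spans and window membership is inclusive", {
  pairs <- tibble::tibble(start = c(100L, 0L, 0L, 0L),
                          end = c(250L, 224L, 424L, 425L))
  fl <- fragment_length_distribution(pairs)
  expect_equal(sort(tidy(fl)$length), c(150L, 224L, 424L, 425L))
  expect_equal(glance(fl)$fraction_in_window, 0.5)
  all_in <- fragment_length_distribution(pairs[2:3, ])
  expect_equal(all_in$fraction_in_window, 1)
})

test_that("depth summary matches a brute-force per-base array", {
  set.seed(31)
  len <- 2000L
  pairs <- tibble::tibble(
    seq_id = "chr1",
    start = sample(0:(len - 150), 120, replace = TRUE),
    sample_id = rep(c("s1", "s2", "s3"), each = 40)
  )
  pairs$end <- pairs$start + sample(100:300, 120, replace = TRUE)
  pairs$end <- pmin(pairs$end, len)
  sel <- tibble::tibble(seq_id = "chr1", start = c(200L, 900L),
                        end = c(600L, 1500L))
  ds <- depth_summary(pairs, c(chr1 = len), selected_regions = sel,
                      thresholds = c(1, 2, 10), deep_threshold = 2,
                      min_samples = 2)
  mask <- logical(len)
  mask[c(201:600, 901:1500)] <- TRUE
  deep_count <- integer(len)
  for (s in unique(pairs$sample_id)) {
    p <- pairs[pairs$sample_id == s, ]
    depth <- oracle_depth(p$start, p$end, len)
    for (t in c(1, 2, 10)) {
      got <- ds$per_sample$covered_bp[ds$per_sample$sample_id == s &
                                        ds$per_sample$scope == "genome" &
                                        ds$per_sample$threshold == t]
      expect_equal(got, sum(depth >= t))
      got_sel <- ds$per_sample$covered_bp[ds$per_sample$sample_id == s &
                                            ds$per_sample$scope == "selected" &
                                            ds$per_sample$threshold == t]
      expect_equal(got_sel, sum(depth >= t & mask))
    }
    deep_count <- deep_count + (oracle_depth(p$start, p$end, len) >= 2)
  }
  expect_equal(ds$consistency$bp[ds$consistency$scope == "genome"],
               sum(deep_count >= 2))
  expect_equal(ds$consistency$bp[ds$consistency$scope == "selected"],
               sum(deep_count >= 2 & mask))
  # covered bp is monotone non-increasing in the threshold
  per <- tidyr::pivot_wider(ds$per_sample, names_from = "threshold",
                            values_from = "covered_bp")
  expect_true(all(per$`1` >= per$`2` & per$`2` >= per$`10`))
})

test_that("stacked pairs reach the deep threshold only on their own fragment", {
  pairs <- tibble::tibble(
    seq_id = "chr1",
    start = rep(100L, 10), end = rep(400L, 10),
    sample_id = "s1"
  )
  ds <- depth_summary(pairs, c(chr1 = 1000L), thresholds = c(1, 10))
  got <- tidyr::pivot_wider(ds$per_sample, names_from = "threshold",
                            values_from = "covered_bp")
  expect_equal(got$`1`, 300)
  expect_equal(got$`10`, 300)
  one <- depth_summary(pairs[1, ], c(chr1 = 1000L), thresholds = c(1, 2))
  got1 <- tidyr::pivot_wider(one$per_sample, names_from = "threshold",
                             values_from = "covered_bp")
  expect_equal(got1$`1`, 300)
  expect_equal(got1$`2`, 0)
})

test_that("bin marker coverage equals a brute-force bin scan", {
  lens <- c(chr1 = 1000L, chr2 = 700L)
  full <- bin_marker_coverage(
    tibble::tibble(seq_id = rep("chr1", 10), pos = seq(50, 950, by = 100)),
    c(chr1 = 1000L), n_bins = 10)
  expect_equal(full$summary$fraction, 1)
  none <- bin_marker_coverage(tibble::tibble(seq_id = character(0),
                                             pos = integer(0)),
                              lens, bin_size = 100)
  expect_equal(none$summary$n_covered, 0L)

  set.seed(4)
  pos <- tibble::tibble(
    seq_id = sample(names(lens), 60, replace = TRUE),
    pos = sample(0:699, 60, replace = TRUE)
  )
  got <- bin_marker_coverage(pos, lens, bin_size = 150)
  brute <- 0L
  for (i in seq_len(nrow(got$bins))) {
    b <- got$bins[i, ]
    hit <- any(pos$seq_id == b$seq_id & pos$pos >= b$start & pos$pos < b$end)
    brute <- brute + hit
    expect_equal(b$n_markers > 0, hit)
  }
  expect_equal(got$summary$n_covered, brute)

  expect_warning(
    oob <- bin_marker_coverage(tibble::tibble(seq_id = "chr1", pos = 5000L),
                               lens, bin_size = 100),
    "outside")
  expect_equal(oob$summary$n_covered, 0L)
})
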