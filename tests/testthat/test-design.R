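small_sim <- function(seed = 21) {
  simulate_genome(
    n_chromosomes = 1, chromosome_length = 6e4,
    n_fragments_per_chromosome = 20,
    chloroplast_length = 2e4, n_chloroplast_fragments = 5,
    rrna_unit_length = 4000, n_rrna_fragments = 2,
    n_polymorphisms = 30, seed = seed
  )
}

test_that("first-round search recovers the planted design and ranks by the criteria", {
  sim <- small_sim()
  res <- first_round_search(sim$regions, default_enzyme_catalog(),
                            min_regions = 20, rrna = sim$rrna,
                            polymorphisms = sim$truth$polymorphisms)
  expect_equal(nrow(res), 10L)  # C(4,2) pairs + C(4,3) triples
  em <- dplyr::filter(res, enzymes == "EcoRI+MspI")
  # background is site-free for the planted pair, so selection is exact
  expect_equal(em$selected_fragments, 27L)       # 20 genomic + 5 cp + 2 rRNA
  expect_equal(em$organellar_selected, 7L)
  expect_equal(em$detectable_variants,
               nrow(sim$truth$polymorphisms))
  expect_true(em$meets_min_regions)
  expect_true(all(res$organellar_selected <= res$selected_fragments))
  expect_true(all(res$selected_fragments <= res$total_fragments))
  # ranking: among combos meeting the minimum, organellar count ascends
  meets <- dplyr::filter(res, meets_min_regions)
  expect_true(!is.unsorted(meets$organellar_selected))
})

test_that("first-round statistics are invariant to sequence order", {
  sim <- small_sim(33)
  res1 <- first_round_search(sim$regions, default_enzyme_catalog(),
                             min_regions = 20, rrna = sim$rrna)
  res2 <- first_round_search(sim$regions[rev(seq_len(nrow(sim$regions))), ],
                             default_enzyme_catalog(),
                             min_regions = 20, rrna = sim$rrna)
  expect_equal(res1, res2)
})

test_that("a site-free genome ranks combinations by tie-break alone, with a warning", {
  g <- tibble::tibble(seq_id = "chr", sequence = strrep("ACAC", 500))
  expect_warning(
    res <- first_round_search(g, default_enzyme_catalog(), min_regions = 10),
    "No combination"
  )
  expect_true(all(res$selected_fragments == 0L))
  expect_equal(res$enzymes, sort(res$enzymes))
})

test_that("second-round search matches unpruned brute force on random instances", {
  cat8 <- dplyr::filter(default_enzyme_catalog(),
                        name %in% c("SnaBI", "StuI", "TfiI", "HhaI", "HinfI",
                                    "AvaII", "MseI", "AluI"))
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    frags <- tibble::tibble(
      sequence = vapply(seq_len(n), function(i) random_dna(sample(60:180, 1)),
                        character(1)),
      region_class = sample(c("genomic", "chloroplast", "rRNA"), n,
                            replace = TRUE, prob = c(0.6, 0.25, 0.15))
    )
    if (!any(frags$region_class != "genomic")) {
      frags$region_class[1] <- "chloroplast"
    }
    got <- suppressWarnings(
      second_round_search(frags, cat8, max_combo = 3, top_k = Inf))
    want <- oracle_second_round(frags, setNames(cat8$site, cat8$name),
                                max_combo = 3)
    expect_equal(got$complete[[1]], want$complete[[1]])
    expect_equal(got$genomic_intact[[1]], want$genomic_intact[[1]])
    expect_equal(got$organellar_cut[[1]], want$organellar_cut[[1]])
    if (want$complete[[1]]) expect_equal(got$enzymes[[1]], want$enzymes[[1]])
    # pruning soundness: every complete subset found by brute force over
    # pruned enzymes only, when the package searched a pruned space
    expect_true(all(c("enzymes", "genomic_intact") %in% names(got)))
  }
})

test_that("second-round search handles the vacuous and infeasible covers", {
  frags <- tibble::tibble(sequence = c("GAATTCAA", "CCGGAATT"),
                          region_class = c("genomic", "genomic"))
  res <- second_round_search(frags, default_enzyme_catalog())
  expect_equal(res$enzymes, "")
  expect_true(res$complete)
  expect_equal(res$genomic_intact, 2L)

  # an organellar fragment no catalog enzyme can cut internally
  frags2 <- tibble::tibble(sequence = c("AAAAACAAACAAAAC", random_dna(150)),
                           region_class = c("chloroplast", "genomic"))
  tiny_cat <- dplyr::filter(default_enzyme_catalog(), name == "EcoRI")
  expect_warning(res2 <- second_round_search(frags2, tiny_cat),
                 "No (catalog enzyme|enzyme subset)")
  expect_false(res2$complete[[1]])
})

test_that("read-proportion model reproduces the reference dilution arithmetic", {
  dip <- predict_read_proportions(20745, 4, 40, 700, 1200, ploidy = 2)
  expect_equal(dip$copies_per_cell, c(41490, 5600, 48000))
  expect_equal(attr(dip, "total_copies"), 95090)
  expect_equal(dip$percent, c(43.6, 5.9, 50.5))

  tet <- predict_read_proportions(20745, 4, 40, 700, 1200, ploidy = 4)
  expect_equal(tet$copies_per_cell, c(82980, 11200, 48000))
  expect_equal(attr(tet, "total_copies"), 142180)
  expect_equal(tet$percent[1:2], c(58.4, 7.9))
  # 48000/142180 = 33.76%, i.e. 33.8 under half-up rounding
  expect_equal(tet$percent[[3]], 33.8)

  solo <- predict_read_proportions(1234, 0, 0, ploidy = 3)
  expect_equal(solo$proportion, c(1, 0, 0))
  expect_error(predict_read_proportions(0, 0, 0), "zero")
})

test_that("read proportions sum to one and genomic share grows with ploidy", {
  set.seed(3)
  for (rep in 1:20) {
    m <- predict_read_proportions(sample(1e5, 1), sample(0:10, 1),
                                  sample(0:60, 1),
                                  rrna_copies_per_haploid = sample(2000, 1),
                                  chloroplast_copies_per_cell = sample(3000, 1),
                                  ploidy = sample(1:6, 1))
    expect_equal(sum(m$proportion), 1, tolerance = 1e-12)
  }
  shares <- vapply(1:6, function(p) {
    predict_read_proportions(20745, 4, 40, ploidy = p)$proportion[[1]]
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("coverage planning follows the reads-per-fragment arithmetic", {
  expect_equal(expected_coverage(1.25e6, 10000), 125)
  expect_equal(expected_coverage(2e6, 10000), 200)
  expect_equal(expected_coverage(0, 5000), 0)
  expect_error(expected_coverage(1e6, 0), ">=")
  expect_equal(expected_sample_share(12), 1 / 12)
  expect_equal(round(100 * expected_sample_share(12), 2), 8.33)
  expect_equal(expected_sample_share(1), 1)
  expect_error(expected_sample_share(0), ">=")
})

test_that("polymorphism coverage counting is half-open and matches a brute scan", {
  frags <- tibble::tibble(seq_id = "c1", start = c(0L, 40L), end = c(10L, 60L))
  pos <- tibble::tibble(seq_id = "c1", pos = c(5L, 50L))
  expect_equal(count_covered_polymorphisms(frags, pos), 2L)
  # position at the end coordinate is outside (half-open)
  expect_equal(count_covered_polymorphisms(
    frags, tibble::tibble(seq_id = "c1", pos = c(10L, 60L))), 0L)
  expect_warning(
    n <- count_covered_polymorphisms(
      frags, tibble::tibble(seq_id = c("c1", "zz"), pos = c(5L, 5L))),
    "skipped")
  expect_equal(n, 1L)

  set.seed(8)
  rfr <- tibble::tibble(seq_id = "c1",
                        start = sort(sample(0:900, 20)) * 10L)
  rfr$end <- rfr$start + sample(5:80, 20, replace = TRUE)
  rpos <- tibble::tibble(seq_id = "c1", pos = sample(0:10000, 300))
  brute <- sum(vapply(rpos$pos, function(p) {
    any(p >= rfr$start & p < rfr$end)
  }, logical(1)))
  expect_equal(count_covered_polymorphisms(rfr, rpos), brute)
})
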