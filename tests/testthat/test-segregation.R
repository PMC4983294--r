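test_that("expected class frequencies match the cross models", {
  expect_equal(unname(expected_genotype_freqs("diploid_F2")),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(expected_genotype_freqs("diploid_F1_AAxAa")),
               c(0.5, 0.5, 0))
  expect_equal(unname(expected_genotype_freqs("tetraploid_F2", alpha = 0)),
               c(1 / 36, 34 / 36, 1 / 36))
  expect_equal(unname(expected_genotype_freqs("tetraploid_F1", alpha = 0)),
               c(0, 0.5, 0.5))
  expect_error(expected_genotype_freqs("diploid_F2", alpha = -0.1))
  expect_error(expected_genotype_freqs("tetraploid_F2", alpha = 0.2), "1/6|0.1667")
})

test_that("tetraploid F2 frequencies agree with gamete enumeration across alpha", {
  for (a in seq(0, 1 / 6, length.out = 7)) {
    expect_equal(expected_genotype_freqs("tetraploid_F2", alpha = a),
                 oracle_tetraploid_f2(a), tolerance = 1e-12)
  }
})

test_that("frequencies sum to one and homozygote classes rise with alpha", {
  grid <- seq(0, 1 / 6, length.out = 9)
  for (pop in c("diploid_F2", "diploid_F1_AAxAa", "tetraploid_F2",
                "tetraploid_F1")) {
    a_grid <- if (grepl("^tetraploid", pop)) grid else 0
    for (a in a_grid) {
      expect_equal(sum(expected_genotype_freqs(pop, a)), 1, tolerance = 1e-12)
    }
  }
  hom_f2 <- vapply(grid, function(a)
    expected_genotype_freqs("tetraploid_F2", a)[["homP1"]], numeric(1))
  hom_f1 <- vapply(grid, function(a)
    expected_genotype_freqs("tetraploid_F1", a)[["homP2"]], numeric(1))
  expect_true(all(diff(hom_f2) > 0))
  expect_true(all(diff(hom_f1) > 0))
})

test_that("the goodness-of-fit statistic follows the printed equation", {
  exact <- chisq_gof(c(25, 50, 25), c(1, 2, 1) / 4)
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)
  expect_equal(exact$df, 2L)

  # (30-25)^2/25 + (48-50)^2/50 + (22-25)^2/25 = 1 + 0.08 + 0.36
  manual <- chisq_gof(c(30, 48, 22), c(1, 2, 1) / 4)
  expect_equal(manual$statistic, 1.44)

  expect_error(chisq_gof(c(0, 0, 0), c(1, 2, 1) / 4), "zero")
  # a zero-expectation class with observations is inconsistent, not tested
  inc <- chisq_gof(c(10, 45, 45), c(0, 0.5, 0.5))
  expect_false(inc$tested)
  expect_true(is.na(inc$p_value))
  # ... and is dropped (df 1) when unobserved
  red <- chisq_gof(c(0, 40, 60), c(0, 0.5, 0.5))
  expect_equal(red$df, 1L)
  expect_equal(red$statistic, (40 - 50)^2 / 50 + (60 - 50)^2 / 50)
})

test_that("the statistic and p-value agree with stats::chisq.test", {
  set.seed(12)
  for (rep in 1:25) {
    f <- as.vector(stats::rgamma(3, 2)); f <- f / sum(f)
    o <- as.vector(stats::rmultinom(1, sample(50:400, 1), f))
    got <- chisq_gof(o, f)
    want <- suppressWarnings(stats::chisq.test(o, p = f))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
  }
})

test_that("the Sidak threshold follows its closed form and decreases in m", {
  expect_equal(sidak_threshold(0.05, 1), 0.05)
  expect_equal(sidak_threshold(0.05, 848), 1 - 0.95^(1 / 848))
  expect_equal(sidak_threshold(0.05, 848), 6.048555e-5, tolerance = 1e-6)
  ms <- c(1, 2, 10, 100, 848, 5000)
  expect_true(all(diff(sidak_threshold(0.05, ms)) < 0))
  expect_error(sidak_threshold(0.05, 0), ">=")
})

test_that("the marker scan tests each marker at the Sidak level", {
  sim <- simulate_population_vcf(n_markers = 300, n_offspring = 200,
                                 seed = 42)
  cc <- genotype_class_counts(sim$genotypes)
  scan <- segregation_scan(cc, population = "diploid_F2")
  g <- glance(scan)
  expect_equal(g$n_tested, 300L)
  expect_equal(g$sidak_threshold, sidak_threshold(0.05, 300))
  # under the null, family-wise significance is rare
  expect_lte(g$n_significant, 2L)
  expect_equal(g$mean_homP1 + g$mean_het + g$mean_homP2, 1, tolerance = 1e-12)
  expect_equal(tidy(scan)$p_value,
               purrr::map_dbl(seq_len(nrow(cc)), function(i) {
                 chisq_gof(unlist(cc[i, c("homP1", "het", "homP2")]),
                           c(1, 2, 1) / 4)$p_value
               }))
})

test_that("strong segregation distortion is detected", {
  sim <- simulate_population_vcf(n_markers = 80, n_offspring = 200,
                                 truth_freqs = c(homP1 = 0.45, het = 0.45,
                                                 homP2 = 0.10),
                                 seed = 17)
  cc <- genotype_class_counts(sim$genotypes)
  scan <- segregation_scan(cc, population = "diploid_F2")
  expect_gt(glance(scan)$n_significant, 40L)
})

test_that("an empty marker set yields an empty scan", {
  empty <- segregation_scan(tibble::tibble(homP1 = integer(0),
                                           het = integer(0),
                                           homP2 = integer(0)))
  expect_equal(nrow(tidy(empty)), 0L)
  expect_equal(glance(empty)$n_tested, 0L)
})

test_that("homozygote excess correlates with centromere distance as designed", {
  cen <- tibble::tibble(seq_id = "chr1", pos = 0L)
  lin <- tibble::tibble(seq_id = "chr1", pos = seq(1e4, 5e5, length.out = 20),
                        hom_freq = seq(0.05, 0.4, length.out = 20))
  r <- homozygote_centromere_correlation(lin, cen)
  expect_equal(r$estimate, 1)

  flat <- dplyr::mutate(lin, hom_freq = 0.2)
  expect_warning(r0 <- homozygote_centromere_correlation(flat, cen),
                 "Zero variance")
  expect_true(is.na(r0$estimate))

  set.seed(23)
  n <- 500
  pos <- runif(n, 0, 1e6)
  alpha <- (pos / 1e6) * (1 / 6)  # double reduction grows with distance
  hom <- vapply(alpha, function(a) {
    f <- expected_genotype_freqs("tetraploid_F2", a)
    mean(stats::rbinom(1, 50, 2 * f[["homP1"]])) / 50
  }, numeric(1))
  sim <- tibble::tibble(seq_id = "chr1", pos = pos, hom_freq = hom)
  rr <- homozygote_centromere_correlation(sim, cen)
  expect_gt(rr$estimate, 0.1)
  expect_lt(rr$p_value, 0.01)

  expect_error(homozygote_centromere_correlation(lin[1:2, ], cen), "at least 3")
})
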