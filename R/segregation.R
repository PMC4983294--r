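# Segregation models (including autotetraploid double reduction),
# chi-square goodness-of-fit testing and the marker-wide scan.

#' Expected genotype-class frequencies for a segregating population
#'
#' Returns the expected frequencies of the three allele-presence classes
#' (`homP1`, `het`, `homP2`) for common cross designs:
#'
#' * `diploid_F2` (AA x aa, F2): 1/4, 1/2, 1/4.
#' * `diploid_F1_AAxAa` (homozygous x heterozygous parent, F1):
#'   1/2, 1/2, 0.
#' * `tetraploid_F2`: F2 of an AAAA x aaaa cross, i.e. a duplex x duplex
#'   (AAaa x AAaa) mating. A duplex parent produces a homozygous gamete
#'   (AA or aa) with frequency `g = (1 + 2 * alpha) / 6`, where `alpha`
#'   is the coefficient of double reduction (the chance a gamete carries
#'   two copies of the same parental chromosome segment): without double
#'   reduction the six chromosome pairings give AA with probability 1/6,
#'   while a double-reduction gamete duplicates one of the four alleles
#'   and is homozygous AA with probability 1/2, so
#'   `g = (1 - alpha)/6 + alpha/2`. An offspring shows only the `A`
#'   (or only the `a`) allele when both gametes are the matching
#'   homozygote, hence `homP1 = homP2 = g^2` and `het = 1 - 2 g^2`
#'   (1/36, 34/36, 1/36 at `alpha = 0`).
#' * `tetraploid_F1`: simplex x nulliplex (Aaaa x aaaa). The simplex
#'   parent's gametes are aa with frequency `(1 - alpha)/2 + 3*alpha/4`,
#'   so `homP1 = 0`, `het = (2 - alpha)/4`, `homP2 = (2 + alpha)/4`
#'   (0, 1/2, 1/2 at `alpha = 0`).
#'
#' `alpha` ranges over `[0, 1/6]`, the theoretical maximum under complete
#' equational separation; homozygote classes increase with `alpha`, which
#' is why double reduction shows up as homozygote excess at markers far
#' from the centromere.
#'
#' @param population One of `"diploid_F2"`, `"diploid_F1_AAxAa"`,
#'   `"tetraploid_F2"`, `"tetraploid_F1"`.
#' @param alpha Double-reduction coefficient (tetraploid populations
#'   only).
#' @param alpha_max Upper bound enforced for `alpha` (default 1/6).
#' @return Named numeric vector `c(homP1, het, homP2)` summing to 1.
#' @export
#' @examples
#' expected_genotype_freqs("diploid_F2")
#' expected_genotype_freqs("tetraploid_F2", alpha = 1/6)
expected_genotype_freqs <- function(population = c("diploid_F2",
                                                   "diploid_F1_AAxAa",
                                                   "tetraploid_F2",
                                                   "tetraploid_F1"),
                                    alpha = 0, alpha_max = 1 / 6) {
  population <- rlang::arg_match(population)
  if (alpha < 0 || alpha > alpha_max) {
    abort(sprintf("`alpha` must lie in [0, %.4g].", alpha_max))
  }
  f <- switch(population,
    diploid_F2 = c(1 / 4, 1 / 2, 1 / 4),
    diploid_F1_AAxAa = c(1 / 2, 1 / 2, 0),
    tetraploid_F2 = {
      g <- (1 + 2 * alpha) / 6
      c(g^2, 1 - 2 * g^2, g^2)
    },
    tetraploid_F1 = c(0, (2 - alpha) / 4, (2 + alpha) / 4)
  )
  setNames(f, c("homP1", "het", "homP2"))
}

#' Pearson chi-square goodness-of-fit test for genotype-class counts
#'
#' Computes `X^2 = sum_i (O_i - E_i)^2 / E_i` with `E_i = n * f_i`, and an
#' upper-tail chi-square p-value. With three positive expected classes the
#' test has 2 degrees of freedom. A class with expected frequency zero is
#' dropped (reducing the degrees of freedom) when its observed count is
#' zero; when such a class is observed, the marker is flagged as
#' inconsistent with the model rather than tested (`tested = FALSE`,
#' `p_value = NA`).
#'
#' @param observed Numeric vector of 3 class counts (`homP1`, `het`,
#'   `homP2`).
#' @param expected_freqs Expected class frequencies (length 3, summing
#'   to 1), e.g. from [expected_genotype_freqs()].
#' @return One-row tibble: `n`, `statistic`, `df`, `p_value`, `tested`.
#' @export
#' @examples
#' chisq_gof(c(25, 50, 25), c(1, 2, 1) / 4)  # perfect fit: X^2 = 0, p = 1
chisq_gof <- function(observed, expected_freqs) {
  if (length(observed) != 3L || length(expected_freqs) != 3L) {
    abort("`observed` and `expected_freqs` must have length 3.")
  }
  if (any(observed < 0) || any(expected_freqs < 0)) {
    abort("Counts and frequencies must be non-negative.")
  }
  if (abs(sum(expected_freqs) - 1) > 1e-8) {
    abort("`expected_freqs` must sum to 1.")
  }
  n <- sum(observed)
  if (n == 0) abort("All observed counts are zero.")
  pos <- expected_freqs > 0
  if (any(observed[!pos] > 0)) {
    return(tibble(n = n, statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_, tested = FALSE))
  }
  e <- n * expected_freqs[pos]
  stat <- sum((observed[pos] - e)^2 / e)
  df <- sum(pos) - 1L
  tibble(n = n, statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE), tested = TRUE)
}

#' Sidak-corrected per-test significance threshold
#'
#' For `m` independent tests at family-wise level `family_alpha`, the
#' per-test threshold is `1 - (1 - family_alpha)^(1/m)`.
#'
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (>= 1; vectorised).
#' @return Per-test p-value threshold.
#' @export
#' @examples
#' sidak_threshold(0.05, 848)
sidak_threshold <- function(family_alpha = 0.05, m) {
  if (!is.numeric(m) || length(m) < 1L || anyNA(m) || any(m < 1)) {
    abort("`m` must be numeric with every element >= 1.")
  }
  if (family_alpha <= 0 || family_alpha >= 1) {
    abort("`family_alpha` must be in (0, 1).")
  }
  1 - (1 - family_alpha)^(1 / m)
}

#' Marker-wide segregation-distortion scan
#'
#' Runs the chi-square goodness-of-fit test at every marker against the
#' expected genotype-class frequencies of the population model, applying
#' the Sidak correction with `m` equal to the number of testable markers.
#'
#' @param counts Per-marker class counts: tibble with columns `homP1`,
#'   `het`, `homP2` (plus any identifier columns, which are carried
#'   through), e.g. from [genotype_class_counts()].
#' @param population,alpha Population model passed to
#'   [expected_genotype_freqs()]; ignored when `expected` is given.
#' @param expected Optional explicit class frequencies (length 3).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return A `rad_segscan` object. `tidy()` returns the per-marker table
#'   with `statistic`, `df`, `p_value`, `tested` and `significant`;
#'   `glance()` the scan summary (markers tested, Sidak threshold, number
#'   significant, mean observed class frequencies).
#' @export
segregation_scan <- function(counts, population = "diploid_F2", alpha = 0,
                             expected = NULL, family_alpha = 0.05) {
  if (!all(c("homP1", "het", "homP2") %in% names(counts))) {
    abort("`counts` needs columns homP1, het, homP2.")
  }
  f <- expected %||% expected_genotype_freqs(population, alpha)
  if (abs(sum(f) - 1) > 1e-8) abort("Expected frequencies must sum to 1.")
  out <- counts
  if (nrow(out) == 0L) {
    res <- dplyr::mutate(out, n = integer(0), statistic = numeric(0),
                         df = integer(0), p_value = numeric(0),
                         tested = logical(0), significant = logical(0))
    return(structure(list(results = res, m = 0L, threshold = NA_real_,
                          family_alpha = family_alpha, expected = f),
                     class = "rad_segscan"))
  }
  o <- as.matrix(out[, c("homP1", "het", "homP2")])
  n <- rowSums(o)
  pos <- f > 0
  inconsistent <- rowSums(o[, !pos, drop = FALSE]) > 0
  e <- outer(n, f[pos])
  stat <- rowSums((o[, pos, drop = FALSE] - e)^2 / e)
  df <- sum(pos) - 1L
  p <- pchisq(stat, df, lower.tail = FALSE)
  tested <- !inconsistent & n > 0
  stat[!tested] <- NA_real_
  p[!tested] <- NA_real_
  m <- sum(tested)
  thr <- if (m > 0) sidak_threshold(family_alpha, m) else NA_real_
  out$n <- n
  out$statistic <- stat
  out$df <- ifelse(tested, df, NA_integer_)
  out$p_value <- p
  out$tested <- tested
  out$significant <- !is.na(p) & p < thr
  structure(
    list(results = out, m = m, threshold = thr,
         family_alpha = family_alpha, expected = f),
    class = "rad_segscan"
  )
}

#' @export
print.rad_segscan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Segregation scan: %d markers tested, Sidak threshold %.3g, %d significant\n",
    g$n_tested, x$threshold, g$n_significant))
  cat(sprintf("mean observed class frequencies: %.3f / %.3f / %.3f (homP1/het/homP2)\n",
              g$mean_homP1, g$mean_het, g$mean_homP2))
  invisible(x)
}

#' @rdname segregation_scan
#' @param x A `rad_segscan` object.
#' @param ... Unused.
#' @export
tidy.rad_segscan <- function(x, ...) x$results

#' @rdname segregation_scan
#' @export
glance.rad_segscan <- function(x, ...) {
  r <- x$results
  freq <- if (nrow(r) == 0L || sum(r$n) == 0) c(NA_real_, NA_real_, NA_real_)
          else colMeans(r[r$n > 0, c("homP1", "het", "homP2")] / r$n[r$n > 0])
  tibble(
    n_markers = nrow(r), n_tested = x$m,
    n_significant = sum(r$significant),
    sidak_threshold = x$threshold, family_alpha = x$family_alpha,
    mean_homP1 = freq[[1]], mean_het = freq[[2]], mean_homP2 = freq[[3]]
  )
}

#' Correlation of homozygote frequency with centromere distance
#'
#' Double reduction inflates homozygote frequencies more at loci far from
#' the centromere, so a positive Pearson correlation between a marker's
#' homozygote-class frequency and its distance to the nearest centromere
#' is a genome-wide signature of double reduction.
#'
#' @param markers Tibble with `seq_id`, `pos` and `hom_freq` (observed
#'   homozygote-class frequency at the marker).
#' @param centromeres Tibble with `seq_id`, `pos` (one or more centromere
#'   coordinates per chromosome).
#' @return One-row tibble: `estimate` (Pearson r), `p_value`, `n`. With
#'   zero variance in either variable the correlation is undefined; `NA`
#'   is returned with a warning.
#' @export
homozygote_centromere_correlation <- function(markers, centromeres) {
  if (nrow(markers) < 3L) abort("Need at least 3 markers.")
  dist <- purrr::map_dbl(seq_len(nrow(markers)), function(i) {
    cen <- centromeres$pos[centromeres$seq_id == markers$seq_id[[i]]]
    if (length(cen) == 0L) return(NA_real_)
    min(abs(markers$pos[[i]] - cen))
  })
  ok <- !is.na(dist)
  if (sum(ok) < 3L) abort("Fewer than 3 markers have a centromere on their chromosome.")
  x <- dist[ok]
  y <- markers$hom_freq[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance in distances or homozygote frequencies; correlation undefined.")
    return(tibble(estimate = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
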