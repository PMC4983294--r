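# Post-mapping library evaluation: read-class proportions, fragment-length
# recovery, depth coverage and genome-bin marker density.

# Normalise seq_lengths input: named numeric vector, or a regions tibble.
as_seq_lengths <- function(seq_lengths) {
  if (is.data.frame(seq_lengths)) {
    if ("length" %in% names(seq_lengths)) {
      return(setNames(seq_lengths$length, seq_lengths$seq_id))
    }
    if ("sequence" %in% names(seq_lengths)) {
      return(setNames(nchar(seq_lengths$sequence), seq_lengths$seq_id))
    }
    abort("`seq_lengths` data frame needs a `length` or `sequence` column.")
  }
  if (is.null(names(seq_lengths))) abort("`seq_lengths` must be named by seq_id.")
  seq_lengths
}

#' Classify mapped read pairs by genome region
#'
#' Applies mapping-quality (and, when available, base-quality) filters,
#' then classifies each surviving pair's outer span as `chloroplast`
#' (pairs on a chloroplast sequence), `rRNA` (any overlap with an rRNA
#' interval wins over genomic) or `genomic`. Proportions are reported over
#' surviving pairs plus the separately supplied unmapped count; alignment
#' itself is external to this toolkit.
#'
#' @param pairs Tibble of mapped pair spans: `seq_id`, `start`, `end`
#'   (0-based half-open outer span), optional `mapq` and `baseq`.
#' @param regions Tibble mapping `seq_id` to `region_class` (a regions
#'   tibble; `sequence` not required if a `length` column is present).
#' @param rrna Optional rRNA interval tibble (`seq_id`, `start`, `end`).
#' @param n_unmapped Number of unmapped pairs (default 0).
#' @param min_mapq,min_baseq Quality thresholds (default 20 each; a filter
#'   is skipped when the corresponding column is absent).
#' @return Tibble with one row per class (`genomic`, `chloroplast`,
#'   `rRNA`, `unmapped`): `n_pairs` and `proportion` (sums to 1). If every
#'   pair is filtered out and there are no unmapped reads, a zero-row
#'   tibble is returned with a warning.
#' @export
classify_mapped_reads <- function(pairs, regions, rrna = NULL,
                                  n_unmapped = 0, min_mapq = 20,
                                  min_baseq = 20) {
  if ("mapq" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$mapq >= min_mapq)
  if ("baseq" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$baseq >= min_baseq)
  total <- nrow(pairs) + n_unmapped
  if (total == 0) {
    warn("No read pairs survive the quality filters and no unmapped count was supplied.")
    return(tibble(class = character(0), n_pairs = integer(0),
                  proportion = numeric(0)))
  }
  cls <- rep("genomic", nrow(pairs))
  if (nrow(pairs) > 0L) {
    class_lookup <- as_region_class(regions)
    idx <- match(pairs$seq_id, names(class_lookup))
    if (anyNA(idx)) {
      abort(sprintf("Pair seq_id '%s' absent from `regions`.",
                    pairs$seq_id[which(is.na(idx))[1]]))
    }
    cls <- unname(class_lookup[idx])
    if (!is.null(rrna) && nrow(rrna) > 0L) {
      hit <- overlaps_any(pairs, rrna)
      cls[hit & cls == "genomic"] <- "rRNA"
    }
  }
  counts <- c(
    genomic = sum(cls == "genomic"),
    chloroplast = sum(cls == "chloroplast"),
    rRNA = sum(cls == "rRNA"),
    unmapped = n_unmapped
  )
  tibble(class = names(counts), n_pairs = unname(counts),
         proportion = unname(counts) / total)
}

as_region_class <- function(regions) {
  if (!is.data.frame(regions) || !"seq_id" %in% names(regions)) {
    abort("`regions` must be a data frame with a `seq_id` column.")
  }
  cls <- regions$region_class %||% rep("genomic", nrow(regions))
  setNames(cls, regions$seq_id)
}

#' Fragment-length distribution of sequenced pairs
#'
#' Fragment length is the outer mapped span of a pair
#' (`end - start`). Reports the per-length histogram and the fraction of
#' pairs falling inside the (inclusive) target size window, the headline
#' measure of how precisely size selection worked.
#'
#' @param pairs Mapped-pair tibble (`start`, `end`).
#' @param window Inclusive target window (default 224-424 bp).
#' @return A `rad_fraglen` object; `tidy()` gives the histogram tibble
#'   (`length`, `n`), `glance()` a one-row summary with
#'   `fraction_in_window`.
#' @export
fragment_length_distribution <- function(pairs, window = c(224, 424)) {
  lens <- pairs$end - pairs$start
  hist_tbl <- dplyr::count(tibble(length = lens), .data$length)
  structure(
    list(
      histogram = hist_tbl,
      n_pairs = length(lens),
      window = window,
      fraction_in_window =
        if (length(lens) == 0) NA_real_
        else mean(lens >= window[[1]] & lens <= window[[2]])
    ),
    class = "rad_fraglen"
  )
}

#' @export
print.rad_fraglen <- function(x, ...) {
  cat(sprintf("%d pairs; %.1f%% within the %d-%d bp window\n",
              x$n_pairs, 100 * x$fraction_in_window,
              x$window[[1]], x$window[[2]]))
  invisible(x)
}

#' @rdname fragment_length_distribution
#' @param x A `rad_fraglen` object.
#' @param ... Unused.
#' @export
tidy.rad_fraglen <- function(x, ...) x$histogram

#' @rdname fragment_length_distribution
#' @export
glance.rad_fraglen <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, window_min = x$window[[1]],
         window_max = x$window[[2]],
         fraction_in_window = x$fraction_in_window)
}

# Per-seq coverage Rle list from pair outer spans.
coverage_rle <- function(pairs, seq_lengths) {
  out <- lapply(names(seq_lengths), function(sid) {
    p <- pairs[pairs$seq_id == sid, , drop = FALSE]
    IRanges::coverage(IRanges::IRanges(start = p$start + 1L, end = p$end),
                      width = seq_lengths[[sid]])
  })
  setNames(out, names(seq_lengths))
}

bp_at_least <- function(cov_list, threshold, mask_list = NULL) {
  sum(vapply(names(cov_list), function(sid) {
    deep <- cov_list[[sid]] >= threshold
    if (!is.null(mask_list)) deep <- deep & mask_list[[sid]]
    sum(S4Vectors::runLength(deep)[S4Vectors::runValue(deep)])
  }, numeric(1)))
}

#' Depth-of-coverage summary per sample and cross-sample consistency
#'
#' Counts, for each sample, the genomic bp covered by at least each depth
#' threshold - genome-wide and restricted to the bioinformatically
#' selected regions. Depth is fragment-level: the number of pair outer
#' spans covering a base. Consistency reports the bp deeply covered
#' (depth >= `deep_threshold`) in at least `min_samples` of the samples.
#'
#' @param pairs Mapped-pair tibble with a `sample_id` column.
#' @param seq_lengths Named vector of sequence lengths, or a regions
#'   tibble.
#' @param selected_regions Optional BED-like tibble (`seq_id`, `start`,
#'   `end`) of selected fragments; overlapping intervals are merged with a
#'   warning.
#' @param thresholds Depth thresholds (default `c(2, 10)`).
#' @param deep_threshold Depth defining "deeply covered" for the
#'   consistency summary (default 10).
#' @param min_samples Minimum samples for the consistency count (default
#'   `number of samples - 2`, i.e. 10 of a 12-sample pool).
#' @return A list with `per_sample` (long tibble: `sample_id`, `scope`,
#'   `threshold`, `covered_bp`) and `consistency` (tibble: `scope`,
#'   `min_samples`, `bp`).
#' @export
depth_summary <- function(pairs, seq_lengths, selected_regions = NULL,
                          thresholds = c(2, 10), deep_threshold = 10,
                          min_samples = NULL) {
  seq_lengths <- as_seq_lengths(seq_lengths)
  samples <- sort(unique(pairs$sample_id))
  if (length(samples) == 0L) abort("`pairs` needs a non-empty `sample_id` column.")
  min_samples <- min_samples %||% max(1L, length(samples) - 2L)

  mask_list <- NULL
  if (!is.null(selected_regions)) {
    mask_list <- lapply(names(seq_lengths), function(sid) {
      r <- selected_regions[selected_regions$seq_id == sid, , drop = FALSE]
      ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
      if (length(IRanges::reduce(ir)) < length(ir)) {
        warn("Overlapping selected regions were merged.")
      }
      IRanges::coverage(IRanges::reduce(ir), width = seq_lengths[[sid]]) >= 1L
    })
    names(mask_list) <- names(seq_lengths)
  }

  per_sample <- list()
  deep_sum <- NULL
  for (s in samples) {
    cov <- coverage_rle(pairs[pairs$sample_id == s, , drop = FALSE], seq_lengths)
    for (t in thresholds) {
      per_sample[[length(per_sample) + 1L]] <- tibble(
        sample_id = s, scope = "genome", threshold = t,
        covered_bp = bp_at_least(cov, t)
      )
      if (!is.null(mask_list)) {
        per_sample[[length(per_sample) + 1L]] <- tibble(
          sample_id = s, scope = "selected", threshold = t,
          covered_bp = bp_at_least(cov, t, mask_list)
        )
      }
    }
    deep <- lapply(cov, function(x) as(x >= deep_threshold, "Rle"))
    deep_sum <- if (is.null(deep_sum)) {
      lapply(deep, function(x) as(x, "Rle") * 1L)
    } else {
      purrr::map2(deep_sum, deep, function(a, b) a + (b * 1L))
    }
  }

  consistency <- tibble(
    scope = "genome", min_samples = as.integer(min_samples),
    bp = bp_at_least(deep_sum, min_samples)
  )
  if (!is.null(mask_list)) {
    consistency <- dplyr::bind_rows(consistency, tibble(
      scope = "selected", min_samples = as.integer(min_samples),
      bp = bp_at_least(deep_sum, min_samples, mask_list)
    ))
  }
  list(per_sample = dplyr::bind_rows(per_sample), consistency = consistency)
}

#' Marker coverage of equal genome bins
#'
#' Tiles each chromosome with equal half-open bins - either a fixed
#' `bin_size` (last bin may be short) or a genome-wide `n_bins` divided
#' among chromosomes in proportion to length - and counts the bins holding
#' at least one marker. This is the "at least one marker per interval"
#' uniformity measure used to check designs targeting, e.g., one marker
#' per cM.
#'
#' @param positions Marker positions: tibble (`seq_id`, `pos`, 0-based).
#' @param seq_lengths Named lengths vector or regions tibble.
#' @param n_bins Total number of bins across the genome (approximately
#'   honoured; each chromosome gets at least one).
#' @param bin_size Alternative: fixed bin width in bp.
#' @return List: `summary` (one-row tibble `n_bins`, `n_covered`,
#'   `fraction`) and `bins` (tibble `seq_id`, `start`, `end`,
#'   `n_markers`). Markers outside the chromosome extent are ignored with
#'   a warning.
#' @export
bin_marker_coverage <- function(positions, seq_lengths, n_bins = NULL,
                                bin_size = NULL) {
  seq_lengths <- as_seq_lengths(seq_lengths)
  if (is.null(n_bins) == is.null(bin_size)) {
    abort("Supply exactly one of `n_bins` or `bin_size`.")
  }
  total_len <- sum(seq_lengths)
  bins <- purrr::imap(as.list(seq_lengths), function(len, sid) {
    k <- if (!is.null(bin_size)) max(1L, ceiling(len / bin_size))
         else max(1L, round(n_bins * len / total_len))
    edges <- if (!is.null(bin_size)) {
      c(seq(0, len - 1, by = bin_size), len)
    } else {
      round(seq(0, len, length.out = k + 1L))
    }
    edges <- unique(edges)
    tibble(seq_id = sid, start = edges[-length(edges)], end = edges[-1])
  })
  bins <- dplyr::bind_rows(bins)

  known <- positions$seq_id %in% names(seq_lengths)
  in_range <- known & positions$pos >= 0 &
    positions$pos < unname(seq_lengths[positions$seq_id])
  if (any(!in_range)) {
    warn(sprintf("%d marker(s) outside the chromosome extent were ignored.",
                 sum(!in_range)))
  }
  pos <- positions[in_range, , drop = FALSE]
  bins$n_markers <- 0L
  for (sid in unique(pos$seq_id)) {
    bi <- which(bins$seq_id == sid)
    p <- pos$pos[pos$seq_id == sid]
    idx <- findInterval(p, bins$start[bi], rightmost.closed = FALSE)
    bins$n_markers[bi] <- tabulate(idx, nbins = length(bi))
  }
  covered <- sum(bins$n_markers > 0L)
  list(
    summary = tibble(n_bins = nrow(bins), n_covered = covered,
                     fraction = covered / nrow(bins)),
    bins = bins
  )
}
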