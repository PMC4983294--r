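# Inline-barcode demultiplexing of pooled paired-end reads and pool
# read-balance statistics.

#' Validate an inline barcode table
#'
#' Checks that barcodes are unique, equal length, and (when mismatches are
#' tolerated) pairwise Hamming distance at least `2 * tolerance + 1`, which
#' guarantees unambiguous assignment.
#'
#' @param barcodes Tibble with columns `sample_id`, `barcode` and
#'   optionally `anchor` (expected sequence immediately after the barcode,
#'   e.g. the regenerated `AATT` overhang of an EcoRI cut).
#' @param mismatch_tolerance Allowed substitutions when matching (0 or 1).
#' @return The validated tibble, invisibly barcode-uppercased.
#' @export
validate_barcodes <- function(barcodes, mismatch_tolerance = 0) {
  if (!all(c("sample_id", "barcode") %in% names(barcodes))) {
    abort("`barcodes` needs columns `sample_id` and `barcode`.")
  }
  barcodes <- as_tibble(barcodes)
  barcodes$barcode <- toupper(barcodes$barcode)
  if (anyDuplicated(barcodes$sample_id)) abort("Duplicate sample_id in barcode table.")
  if (anyDuplicated(barcodes$barcode)) abort("Duplicate barcode in barcode table.")
  L <- unique(nchar(barcodes$barcode))
  if (length(L) != 1L) abort("All barcodes must have the same length.")
  if (mismatch_tolerance > 0 && nrow(barcodes) > 1L) {
    need <- 2 * mismatch_tolerance + 1
    bm <- do.call(rbind, strsplit(barcodes$barcode, "", fixed = TRUE))
    for (i in seq_len(nrow(bm) - 1L)) {
      d <- rowSums(bm[(i + 1):nrow(bm), , drop = FALSE] !=
                     matrix(bm[i, ], nrow = nrow(bm) - i, ncol = ncol(bm),
                            byrow = TRUE))
      if (any(d < need)) {
        abort(sprintf(
          "Barcode table is ambiguous at mismatch tolerance %d: pairwise Hamming distance must be >= %d.",
          mismatch_tolerance, need))
      }
    }
  }
  invisible(barcodes)
}

read_fastq_pair <- function(r1, r2) {
  f1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  f2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(f1) != length(f2)) abort("Mate files differ in read count.")
  strip <- function(ids) sub("/[12]$", "", sub("\\s.*$", "", ids))
  if (!identical(strip(names(f1)), strip(names(f2)))) {
    abort("Mate files are desynchronised: read ids do not pair up in order.")
  }
  list(r1 = f1, r2 = f2)
}

write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = S4Vectors::mcols(reads)$qualities)
}

#' Demultiplex a pooled paired-end library by inline barcodes
#'
#' Matches the first `L` bases of read 1 (where `L` is the barcode length)
#' against the barcode table. A pair is assigned when exactly one barcode
#' matches within `mismatch_tolerance`; everything else (no match, or a
#' read 1 shorter than the barcode) goes to the `unassigned` sink. With
#' `check_anchor = TRUE` the bases immediately following the barcode must
#' equal the barcode's `anchor` (the enzyme overhang regenerated at the
#' fragment start). With `trim = TRUE` the barcode - and nothing else - is
#' removed from read 1 and its qualities.
#'
#' @param r1,r2 Paths to the mate FASTQ files (synchronised order).
#' @param barcodes Barcode table (see [validate_barcodes()]).
#' @param mismatch_tolerance 0 (default) or 1 substitutions.
#' @param trim Remove the barcode from read 1 (default `TRUE`).
#' @param check_anchor Require the post-barcode anchor (default `FALSE`).
#' @param output_dir If non-`NULL`, per-sample FASTQ pairs
#'   (`<sample>_R1.fastq`, `<sample>_R2.fastq`) and the `unassigned` pair
#'   are written there.
#' @return A `rad_demux` object; [generics::tidy()] gives per-sample pair
#'   counts and fractions, [generics::glance()] the totals. Counts are
#'   conserved: assigned + unassigned = input pairs.
#' @export
demultiplex <- function(r1, r2, barcodes, mismatch_tolerance = 0,
                        trim = TRUE, check_anchor = FALSE,
                        output_dir = NULL) {
  if (!mismatch_tolerance %in% c(0, 1)) {
    abort("`mismatch_tolerance` must be 0 or 1.")
  }
  barcodes <- validate_barcodes(barcodes, mismatch_tolerance)
  fq <- read_fastq_pair(r1, r2)
  n <- length(fq$r1)
  L <- nchar(barcodes$barcode[[1]])

  assign <- rep(NA_integer_, n)
  long_enough <- Biostrings::width(fq$r1) >= L
  if (any(long_enough)) {
    prefixes <- as.character(Biostrings::subseq(fq$r1[long_enough], 1L, L))
    pm <- do.call(rbind, strsplit(prefixes, "", fixed = TRUE))
    nhit <- integer(length(prefixes))
    hit <- rep(NA_integer_, length(prefixes))
    for (b in seq_len(nrow(barcodes))) {
      bc <- strsplit(barcodes$barcode[[b]], "", fixed = TRUE)[[1]]
      d <- rowSums(pm != matrix(bc, nrow = nrow(pm), ncol = L, byrow = TRUE))
      ok <- d <= mismatch_tolerance
      if (check_anchor && "anchor" %in% names(barcodes)) {
        anchor <- toupper(barcodes$anchor[[b]])
        if (!is.na(anchor) && nzchar(anchor)) {
          wa <- nchar(anchor)
          idx1 <- fq$r1[long_enough]
          ok <- ok & Biostrings::width(idx1) >= L + wa &
            as.character(Biostrings::subseq(idx1, L + 1L,
                                            pmin(Biostrings::width(idx1), L + wa))) == anchor
        }
      }
      nhit <- nhit + ok
      hit[ok] <- b
    }
    hit[nhit != 1L] <- NA_integer_
    assign[long_enough] <- hit
  }

  counts <- tabulate(assign, nbins = nrow(barcodes))
  report <- tibble(
    sample_id = barcodes$sample_id,
    n_pairs = counts,
    fraction = if (n > 0) counts / n else 0
  )
  out <- structure(
    list(report = report, n_unassigned = sum(is.na(assign)), n_total = n,
         assignment = assign, barcodes = barcodes, files = NULL),
    class = "rad_demux"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    groups <- c(barcodes$sample_id, "unassigned")
    keys <- ifelse(is.na(assign), length(groups), assign)
    files <- purrr::map(seq_along(groups), function(g) {
      sel <- which(keys == g)
      reads1 <- fq$r1[sel]
      reads2 <- fq$r2[sel]
      if (trim && g <= nrow(barcodes) && length(sel) > 0L) {
        q <- S4Vectors::mcols(reads1)$qualities
        reads1 <- Biostrings::subseq(reads1, L + 1L)
        S4Vectors::mcols(reads1)$qualities <- Biostrings::subseq(q, L + 1L)
      }
      p1 <- file.path(output_dir, paste0(groups[[g]], "_R1.fastq"))
      p2 <- file.path(output_dir, paste0(groups[[g]], "_R2.fastq"))
      write_fastq(reads1, p1)
      write_fastq(reads2, p2)
      c(r1 = p1, r2 = p2)
    })
    out$files <- setNames(files, groups)
  }
  out
}

#' @export
print.rad_demux <- function(x, ...) {
  cat(sprintf("Demultiplexed %d read pairs: %d assigned (%.1f%%), %d unassigned (%.1f%%)\n",
              x$n_total, x$n_total - x$n_unassigned,
              100 * (1 - x$n_unassigned / max(x$n_total, 1)),
              x$n_unassigned, 100 * x$n_unassigned / max(x$n_total, 1)))
  print(x$report, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname demultiplex
#' @param x A `rad_demux` object.
#' @param ... Unused.
#' @export
tidy.rad_demux <- function(x, ...) x$report

#' @rdname demultiplex
#' @export
glance.rad_demux <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_assigned = x$n_total - x$n_unassigned,
    n_unassigned = x$n_unassigned,
    unassigned_fraction = x$n_unassigned / max(x$n_total, 1)
  )
}

#' Read-balance statistics of a pooled library
#'
#' Summarises how evenly reads are spread across the barcoded samples of a
#' pool: per-sample fractions, the coefficient of variation (sample sd over
#' mean) and a two-sided one-sample t-test of the counts against the
#' expected per-sample mean `total / pool_size`. When every sample of the
#' pool is included the counts average to that mean by construction and the
#' t statistic is 0; the test is informative when counts come from one lane
#' or a subset of samples.
#'
#' @param counts Numeric vector of per-sample read(-pair) counts, ideally
#'   named; or a `rad_demux` object.
#' @param pool_size Number of samples the pool was designed for (default
#'   `length(counts)`; must be >= 2).
#' @return One-row tibble: `pool_size`, `total`, `cv`, `t_statistic`,
#'   `p_value`, and a `fractions` list-column of per-sample fractions.
#' @export
read_balance_report <- function(counts, pool_size = NULL) {
  if (inherits(counts, "rad_demux")) {
    counts <- setNames(counts$report$n_pairs, counts$report$sample_id)
  }
  pool_size <- pool_size %||% length(counts)
  if (pool_size < 2 || length(counts) < 2) {
    abort("Read-balance statistics need a pool of at least 2 samples.")
  }
  total <- sum(counts)
  expected_mean <- total / pool_size
  if (sd(counts) == 0) {
    # perfectly even pool: the t statistic is 0/0; report an exact fit
    # when the constant equals the expected mean
    t_stat <- if (counts[[1]] == expected_mean) 0 else NA_real_
    p_val <- if (counts[[1]] == expected_mean) 1 else NA_real_
  } else {
    tt <- t.test(counts, mu = expected_mean)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  tibble(
    pool_size = as.integer(pool_size),
    total = total,
    cv = sd(counts) / mean(counts),
    t_statistic = t_stat,
    p_value = p_val,
    fractions = list(counts / total)
  )
}
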