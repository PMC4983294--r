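# Design optimization: first-round enzyme-combination ranking, second-round
# exhaustive organellar-removal search, read-dilution model and coverage
# planning.

#' Rank first-round enzyme combinations
#'
#' Evaluates every combination of 2..`max_combo` candidate enzymes by
#' complete digestion of the supplied sequences, inclusive size selection
#' and region classification, then ranks the combinations by the two design
#' criteria: recover at least `min_regions` fragments in the size window,
#' and minimise fragments derived from chloroplast DNA and rRNA genes. When
#' a table of known polymorphic positions is supplied, combinations
#' covering more of them are preferred.
#'
#' Ranking order: combinations meeting `min_regions` first, then ascending
#' organellar selected fragments, then descending detectable variants (if
#' supplied), then descending selected fragments, ties broken by the
#' alphabetical enzyme-set label.
#'
#' @param regions Regions tibble (`seq_id`, `sequence`, `region_class`);
#'   include the chloroplast sequence as a `chloroplast` region.
#' @param catalog Enzyme catalog tibble.
#' @param candidates Enzyme names to combine (default the four widely used
#'   cutters EcoRI, HindIII, MspI and MseI).
#' @param min_regions Minimum number of selected fragments the design needs
#'   (default 10,000).
#' @param window Inclusive size-selection window (default 224-424 bp).
#' @param max_combo Largest combination size tried (default 3).
#' @param rrna Optional rRNA interval tibble (see [classify_fragments()]).
#' @param polymorphisms Optional tibble of known polymorphic positions
#'   (`seq_id`, `pos`, 0-based).
#' @param end_mode,barcoded,universal End-composition filter applied before
#'   counting selected fragments (see [filter_by_end_composition()];
#'   default `"all"`, i.e. no filter).
#' @param include_terminal Count fragments bounded by a sequence end
#'   (default `FALSE`).
#' @return Tibble of per-combination statistics, best design first:
#'   `enzymes`, `n_enzymes`, `total_fragments`, `total_coverage_fraction`,
#'   `selected_fragments`, `selected_coverage_fraction`,
#'   `organellar_selected`, `detectable_variants`, `meets_min_regions`.
#'   Coverage fractions are genomic-fragment bp over total genomic bp.
#' @export
first_round_search <- function(regions, catalog,
                               candidates = c("EcoRI", "HindIII", "MspI", "MseI"),
                               min_regions = 10000, window = c(224, 424),
                               max_combo = 3, rrna = NULL,
                               polymorphisms = NULL,
                               end_mode = "all", barcoded = character(),
                               universal = character(),
                               include_terminal = FALSE) {
  regions <- as_regions(regions)
  enz <- catalog_subset(catalog, candidates)
  assert_scalar_number(min_regions, "min_regions", min = 1)
  max_combo <- min(max_combo, nrow(enz))
  if (max_combo < 2L) abort("Need at least 2 candidate enzymes.")
  genome_bp <- sum(nchar(regions$sequence[regions$region_class == "genomic"]))

  # one scan per (enzyme, sequence); combos then only merge cut vectors
  site_cache <- purrr::map(seq_len(nrow(regions)), function(r) {
    seq_raw <- charToRaw(regions$sequence[[r]])
    setNames(purrr::map(seq_len(nrow(enz)), function(i) {
      cut_sites_raw(seq_raw, enz$recognition[[i]], enz$cut_offset[[i]],
                    enz$palindromic[[i]])
    }), enz$name)
  })

  combos <- unlist(lapply(2:max_combo, function(k) {
    combn(sort(enz$name), k, simplify = FALSE)
  }), recursive = FALSE)

  stats <- purrr::map(combos, function(combo) {
    frags <- purrr::map(seq_len(nrow(regions)), function(r) {
      per_enz <- site_cache[[r]][combo]
      cuts <- sort(unique(unlist(per_enz, use.names = FALSE)))
      f <- fragments_from_cuts(regions$seq_id[[r]],
                               nchar(regions$sequence[[r]]),
                               cuts, label_cuts(per_enz, cuts))
      f$region_class <- regions$region_class[[r]]
      f
    })
    frags <- dplyr::bind_rows(frags)
    if (!include_terminal) frags <- drop_terminal_fragments(frags)
    if (!is.null(rrna)) {
      hit <- overlaps_any(frags, rrna)
      frags$region_class[hit & frags$region_class == "genomic"] <- "rRNA"
    }
    frags <- filter_by_end_composition(frags, barcoded, universal, end_mode)
    sel <- size_select(frags, window)
    sel_genomic <- dplyr::filter(sel, .data$region_class == "genomic")
    tibble(
      enzymes = paste(combo, collapse = "+"),
      n_enzymes = length(combo),
      total_fragments = nrow(frags),
      total_coverage_fraction =
        if (genome_bp > 0)
          sum(frags$length[frags$region_class == "genomic"]) / genome_bp
        else NA_real_,
      selected_fragments = nrow(sel),
      selected_coverage_fraction =
        if (genome_bp > 0) sum(sel_genomic$length) / genome_bp else NA_real_,
      organellar_selected = sum(sel$region_class %in% c("chloroplast", "rRNA")),
      detectable_variants =
        if (is.null(polymorphisms)) NA_integer_
        else count_covered_polymorphisms(sel_genomic, polymorphisms),
      meets_min_regions = nrow(sel) >= min_regions
    )
  })
  out <- dplyr::bind_rows(stats)
  if (all(out$selected_fragments == 0L)) {
    warn("No combination yields any fragment in the size window.")
  }
  dplyr::arrange(out, dplyr::desc(.data$meets_min_regions),
                 .data$organellar_selected,
                 dplyr::desc(dplyr::coalesce(.data$detectable_variants, -1L)),
                 dplyr::desc(.data$selected_fragments), .data$enzymes)
}

#' Search second-round enzyme sets that destroy all organellar fragments
#'
#' Exhaustively enumerates enzyme subsets of size 1..`max_combo` and scores
#' each by how many chloroplast/rRNA fragments it cuts (a fragment is cut
#' when at least one enzyme of the subset has a cut site strictly inside
#' it) versus how many genomic fragments it leaves intact. Cut incidence is
#' precomputed once per (enzyme, fragment), so subset evaluation is a pure
#' union of incidence rows; enzymes that cut no organellar fragment are
#' pruned up front, since adding one can only destroy genomic fragments.
#'
#' @param fragments Selected fragments with `sequence` and `region_class`
#'   columns (from `digest(..., with_sequence = TRUE)` piped through
#'   [classify_fragments()] and [size_select()]).
#' @param catalog Enzyme catalog to draw the second-round enzymes from.
#' @param max_combo Largest subset size (default 3).
#' @param top_k Number of top-ranked subsets returned (default 10;
#'   `Inf` for all).
#' @param polymorphisms Optional known-polymorphism positions; adds an
#'   `intact_variants` count over intact genomic fragments.
#' @return Tibble ranked best-first: `enzymes` (label), `enzyme_set`
#'   (list-column), `n_enzymes`, `organellar_cut`, `organellar_total`,
#'   `genomic_cut`, `genomic_intact`, `complete`, and optionally
#'   `intact_variants`. Complete covers rank first (by descending
#'   `genomic_intact`, then fewer enzymes, then label); incomplete covers
#'   rank by descending organellar coverage before intactness. With no
#'   organellar fragments in the input the optimum is the empty enzyme
#'   set. If no subset achieves complete removal, the best partial
#'   subsets are returned with a warning.
#' @export
second_round_search <- function(fragments, catalog, max_combo = 3,
                                top_k = 10, polymorphisms = NULL) {
  if (nrow(fragments) == 0L) abort("`fragments` is empty.")
  if (!all(c("sequence", "region_class") %in% names(fragments))) {
    abort("`fragments` needs `sequence` and `region_class` columns.")
  }
  organellar <- fragments$region_class %in% c("chloroplast", "rRNA")
  n_org <- sum(organellar)
  n_gen <- sum(!organellar)
  empty_res <- tibble(
    enzymes = "", enzyme_set = list(character(0)), n_enzymes = 0L,
    organellar_cut = 0L, organellar_total = n_org,
    genomic_cut = 0L, genomic_intact = n_gen, complete = n_org == 0L
  )
  if (n_org == 0L) {
    if (!is.null(polymorphisms)) {
      empty_res$intact_variants <- count_covered_polymorphisms(
        fragments[!organellar, , drop = FALSE], polymorphisms)
    }
    return(empty_res)
  }

  inc <- cut_incidence(fragments$sequence, catalog)
  # prune to enzymes that cut at least one organellar fragment
  useful <- rowSums(inc[, organellar, drop = FALSE]) > 0L
  inc <- inc[useful, , drop = FALSE]
  if (nrow(inc) == 0L) {
    warn("No catalog enzyme cuts any organellar fragment.")
    empty_res$complete <- FALSE
    return(empty_res)
  }
  enz_names <- rownames(inc)
  subsets <- unlist(lapply(seq_len(min(max_combo, length(enz_names))),
                           function(k) combn(enz_names, k, simplify = FALSE)),
                    recursive = FALSE)
  res <- purrr::map(subsets, function(ss) {
    cut <- colSums(inc[ss, , drop = FALSE]) > 0L
    org_cut <- sum(cut & organellar)
    gen_cut <- sum(cut & !organellar)
    tibble(
      enzymes = paste(sort(ss), collapse = "+"),
      enzyme_set = list(sort(ss)), n_enzymes = length(ss),
      organellar_cut = org_cut, organellar_total = n_org,
      genomic_cut = gen_cut, genomic_intact = n_gen - gen_cut,
      complete = org_cut == n_org
    )
  })
  out <- dplyr::bind_rows(res)
  # complete covers first, ranked by intact genomic fragments; among
  # incomplete covers, organellar coverage dominates (otherwise a subset
  # cutting nothing would "win" on intactness alone)
  out <- dplyr::arrange(out, dplyr::desc(.data$complete),
                        dplyr::desc(.data$organellar_cut),
                        dplyr::desc(.data$genomic_intact),
                        .data$n_enzymes, .data$enzymes)
  if (!out$complete[[1]]) {
    warn("No enzyme subset removes every organellar fragment; returning best partial covers.")
  }
  out <- head(out, top_k)
  if (!is.null(polymorphisms)) {
    out$intact_variants <- purrr::map_int(out$enzyme_set, function(ss) {
      cut <- if (length(ss) == 0L) rep(FALSE, ncol(inc))
             else colSums(inc[ss, , drop = FALSE]) > 0L
      count_covered_polymorphisms(
        fragments[!organellar & !cut, , drop = FALSE], polymorphisms)
    })
  }
  out
}

# Logical enzyme x fragment matrix: does the enzyme cut strictly inside the
# fragment residue? One scan per (enzyme, fragment).
cut_incidence <- function(sequences, catalog) {
  raws <- lapply(toupper(sequences), charToRaw)
  inc <- vapply(seq_len(nrow(catalog)), function(i) {
    vapply(raws, function(sr) {
      cuts <- cut_sites_raw(sr, catalog$recognition[[i]],
                            catalog$cut_offset[[i]], catalog$palindromic[[i]])
      any(cuts > 0L & cuts < length(sr))
    }, logical(1))
  }, logical(length(raws)))
  inc <- matrix(inc, nrow = length(raws))
  inc <- t(inc)
  rownames(inc) <- catalog$name
  inc
}

#' Predict read-class proportions from per-cell fragment copy numbers
#'
#' Models the dilution of genomic sequencing reads by high-copy organellar
#' DNA. Reads are assumed proportional to per-cell copies of each selected
#' fragment: genomic fragments occur once per haploid genome (so `ploidy`
#' copies per cell), rRNA-gene fragments `rrna_copies_per_haploid` times
#' per haploid genome, and chloroplast fragments
#' `chloroplast_copies_per_cell` times per cell regardless of ploidy.
#'
#' @param n_genomic,n_rrna,n_chloroplast Selected fragment counts per
#'   haploid genome (genomic, rRNA) or per organelle genome (chloroplast).
#' @param rrna_copies_per_haploid rRNA gene copies per haploid genome
#'   (default 700, as measured in Arabidopsis leaf tissue).
#' @param chloroplast_copies_per_cell Chloroplast genome copies per cell
#'   (default 1200, midpoint of the 1000-1500 range reported for
#'   Arabidopsis leaf).
#' @param ploidy Nuclear ploidy (>= 1).
#' @return Tibble with one row per class (`genomic`, `rRNA`,
#'   `chloroplast`): `n_fragments`, `copies_per_cell`, `proportion`
#'   (sums to 1) and `percent` (proportion rounded half-up to 1 decimal).
#'   The per-cell total is attached as attribute `total_copies`.
#' @export
#' @examples
#' predict_read_proportions(20745, 4, 40, ploidy = 2)
predict_read_proportions <- function(n_genomic, n_rrna, n_chloroplast,
                                     rrna_copies_per_haploid = 700,
                                     chloroplast_copies_per_cell = 1200,
                                     ploidy = 2) {
  for (v in c("n_genomic", "n_rrna", "n_chloroplast",
              "rrna_copies_per_haploid", "chloroplast_copies_per_cell")) {
    assert_scalar_number(get(v), v, min = 0)
  }
  assert_scalar_number(ploidy, "ploidy", min = 1)
  copies <- c(
    genomic = n_genomic * ploidy,
    rRNA = n_rrna * ploidy * rrna_copies_per_haploid,
    chloroplast = n_chloroplast * chloroplast_copies_per_cell
  )
  total <- sum(copies)
  if (total == 0) abort("All fragment copy numbers are zero.")
  out <- tibble(
    class = names(copies),
    n_fragments = c(n_genomic, n_rrna, n_chloroplast),
    copies_per_cell = unname(copies),
    proportion = unname(copies) / total,
    percent = round_half_up(100 * unname(copies) / total, 1)
  )
  attr(out, "total_copies") <- total
  out
}

#' Expected mean coverage of targeted fragments
#'
#' @param read_pairs_per_sample Read pairs collected per sample.
#' @param target_fragments Number of targeted fragments (>= 1).
#' @return Expected read pairs per fragment (mean coverage, x-fold).
#' @export
#' @examples
#' expected_coverage(1.25e6, 10000)  # 125
expected_coverage <- function(read_pairs_per_sample, target_fragments) {
  assert_scalar_number(read_pairs_per_sample, "read_pairs_per_sample", min = 0)
  assert_scalar_number(target_fragments, "target_fragments", min = 1)
  read_pairs_per_sample / target_fragments
}

#' Expected per-sample read share in an equimolar pool
#'
#' @param pool_size Number of barcoded samples pooled in one library.
#' @return Expected fraction of reads per sample, `1 / pool_size`.
#' @export
#' @examples
#' expected_sample_share(12)  # 0.0833
expected_sample_share <- function(pool_size) {
  assert_scalar_number(pool_size, "pool_size", min = 1)
  1 / pool_size
}

#' Count known polymorphic positions covered by fragments
#'
#' Counts positions falling inside any fragment interval (0-based,
#' half-open: a position equal to a fragment's `end` is outside). Each
#' position is counted once even if fragments overlap. Positions on
#' sequences absent from `fragments` are skipped with a warning.
#'
#' @param fragments Fragment tibble (`seq_id`, `start`, `end`).
#' @param polymorphisms Tibble of positions: `seq_id`, `pos` (0-based).
#' @return Integer count.
#' @export
count_covered_polymorphisms <- function(fragments, polymorphisms) {
  if (nrow(polymorphisms) == 0L || nrow(fragments) == 0L) return(0L)
  known <- polymorphisms$seq_id %in% unique(fragments$seq_id)
  if (any(!known)) {
    warn(sprintf("%d polymorphism position(s) on sequences without fragments were skipped.",
                 sum(!known)))
  }
  pm <- polymorphisms[known, , drop = FALSE]
  if (nrow(pm) == 0L) return(0L)
  covered <- logical(nrow(pm))
  for (sid in unique(pm$seq_id)) {
    fi <- fragments[fragments$seq_id == sid, , drop = FALSE]
    pi <- which(pm$seq_id == sid)
    pr <- IRanges::IRanges(start = pm$pos[pi] + 1L, width = 1L)
    fr <- IRanges::IRanges(start = fi$start + 1L, end = fi$end)
    covered[pi] <- IRanges::overlapsAny(pr, fr)
  }
  sum(covered)
}
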