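# In-silico digestion: fragmentation, size selection, region classification
# and adapter end-composition filtering.

SEQ_END <- "SEQ_END"

# Validate/normalise a regions tibble: seq_id, sequence, region_class.
as_regions <- function(regions) {
  if (!is.data.frame(regions) || !all(c("seq_id", "sequence") %in% names(regions))) {
    abort("`regions` must be a data frame with columns `seq_id` and `sequence`.")
  }
  regions <- as_tibble(regions)
  if (nrow(regions) == 0L) abort("`regions` is empty.")
  if (anyDuplicated(regions$seq_id)) abort("`regions$seq_id` must be unique.")
  if (!"region_class" %in% names(regions)) regions$region_class <- "genomic"
  bad <- setdiff(unique(regions$region_class), c("genomic", "chloroplast", "rRNA"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown region_class '%s'.", bad[[1]]))
  }
  regions$sequence <- toupper(regions$sequence)
  regions
}

# Build the fragment tibble for one sequence from its 0-based cut
# coordinates. `cut_labels` maps coordinate -> "+"-joined enzyme names.
fragments_from_cuts <- function(seq_id, seq_len, cuts, cut_labels) {
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < seq_len], seq_len))
  bounds <- sort(bounds)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  label_of <- function(coord) {
    ifelse(coord %in% c(0L, seq_len) & !(coord %in% cuts),
           SEQ_END, cut_labels[as.character(coord)])
  }
  left <- label_of(starts)
  right <- label_of(ends)
  # A cut exactly at coordinate 0 or seq_len leaves no fragment on one side;
  # the adjacent terminal boundary is then enzyme-labelled, not SEQ_END.
  left[is.na(left)] <- SEQ_END
  right[is.na(right)] <- SEQ_END
  tibble(
    seq_id = seq_id, start = starts, end = ends,
    length = ends - starts, left_cutter = left, right_cutter = right
  )
}

#' Digest sequences with a set of restriction enzymes
#'
#' Performs a complete in-silico digestion: per sequence, the cut
#' coordinates of all enzymes are pooled and fragments are the intervals
#' between consecutive cuts (plus the terminal intervals, whose outer
#' boundary is labelled `SEQ_END`). Fragments tile each sequence exactly.
#' Boundaries produced by several enzymes carry all names joined with `+`
#' in alphabetical order. Fragment lengths are measured cut-to-cut on the
#' top strand, ignoring overhang stagger.
#'
#' @param regions Tibble with columns `seq_id`, `sequence` and optionally
#'   `region_class` (`genomic` default, `chloroplast`, or `rRNA`).
#' @param enzymes Catalog tibble rows (see [read_enzyme_catalog()]); at
#'   least one enzyme.
#' @param with_sequence If `TRUE`, attach each fragment's residues as a
#'   `sequence` column (needed by [second_round_search()]).
#' @return Tibble of fragments: `seq_id`, `start`, `end` (0-based,
#'   half-open), `length`, `left_cutter`, `right_cutter`, `region_class`.
#' @export
#' @examples
#' enz <- default_enzyme_catalog()
#' g <- tibble::tibble(seq_id = "chr", sequence = "GAATTCAAAACCGGT")
#' digest(g, dplyr::filter(enz, name %in% c("EcoRI", "MspI")))
digest <- function(regions, enzymes, with_sequence = FALSE) {
  regions <- as_regions(regions)
  if (!is.data.frame(enzymes) || nrow(enzymes) == 0L) {
    abort("`enzymes` must contain at least one enzyme.")
  }
  frags <- purrr::pmap(
    list(regions$seq_id, regions$sequence, regions$region_class),
    function(sid, seq, cls) {
      seq_raw <- charToRaw(seq)
      per_enz <- lapply(seq_len(nrow(enzymes)), function(i) {
        cut_sites_raw(seq_raw, enzymes$recognition[[i]],
                      enzymes$cut_offset[[i]], enzymes$palindromic[[i]])
      })
      names(per_enz) <- enzymes$name
      cuts <- sort(unique(unlist(per_enz, use.names = FALSE)))
      labels <- label_cuts(per_enz, cuts)
      out <- fragments_from_cuts(sid, length(seq_raw), cuts, labels)
      out$region_class <- cls
      out
    })
  out <- dplyr::bind_rows(frags)
  if (with_sequence) {
    seq_lookup <- setNames(regions$sequence, regions$seq_id)
    out$sequence <- substr(seq_lookup[out$seq_id], out$start + 1L, out$end)
  }
  out
}

label_cuts <- function(per_enz, cuts) {
  if (length(cuts) == 0L) return(character(0))
  lab <- vapply(cuts, function(cc) {
    hit <- sort(names(per_enz)[vapply(per_enz, function(v) cc %in% v, logical(1))])
    paste(hit, collapse = "+")
  }, character(1))
  setNames(lab, as.character(cuts))
}

#' Retain fragments within a size window
#'
#' Filters fragments to `min_bp <= length <= max_bp`; both bounds are
#' inclusive and order is preserved.
#'
#' @param fragments Fragment tibble from [digest()].
#' @param window Length-2 numeric `c(min_bp, max_bp)`; defaults to the
#'   224-424 bp window suited to paired-end Illumina libraries.
#' @return The filtered fragment tibble.
#' @export
size_select <- function(fragments, window = c(224, 424)) {
  if (length(window) != 2L || window[[1]] < 1 || window[[1]] > window[[2]]) {
    abort("`window` must be c(min_bp, max_bp) with 1 <= min <= max.")
  }
  dplyr::filter(fragments, .data$length >= window[[1]],
                .data$length <= window[[2]])
}

#' Classify fragments as genomic, chloroplast or rRNA
#'
#' A fragment on a chloroplast sequence is `chloroplast`; a fragment
#' overlapping (by at least 1 bp) an annotated rRNA interval is `rRNA`;
#' everything else is `genomic`.
#'
#' @param fragments Fragment tibble.
#' @param regions Regions tibble used for the digestion (supplies each
#'   sequence's `region_class`).
#' @param rrna Optional tibble of rRNA gene intervals on genomic sequences:
#'   columns `seq_id`, `start`, `end` (0-based half-open).
#' @return `fragments` with its `region_class` column (re)computed.
#' @export
classify_fragments <- function(fragments, regions, rrna = NULL) {
  regions <- as_regions(regions)
  idx <- match(fragments$seq_id, regions$seq_id)
  if (anyNA(idx)) {
    abort(sprintf("Fragment seq_id '%s' absent from `regions`.",
                  fragments$seq_id[which(is.na(idx))[1]]))
  }
  cls <- regions$region_class[idx]
  if (!is.null(rrna) && nrow(rrna) > 0L && nrow(fragments) > 0L) {
    hit <- overlaps_any(fragments, rrna)
    cls[hit & cls == "genomic"] <- "rRNA"
  }
  fragments$region_class <- cls
  fragments
}

# Rows of `x` (seq_id,start,end half-open) overlapping >=1 interval of `y`.
overlaps_any <- function(x, y) {
  common <- intersect(unique(x$seq_id), unique(y$seq_id))
  out <- logical(nrow(x))
  for (sid in common) {
    xi <- which(x$seq_id == sid)
    yi <- y[y$seq_id == sid, , drop = FALSE]
    xr <- IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    yr <- IRanges::IRanges(start = yi$start + 1L, end = yi$end)
    out[xi] <- IRanges::overlapsAny(xr, yr)
  }
  out
}

#' Filter fragments by adapter end composition
#'
#' In a ddRAD library one end of each sequenceable fragment carries the
#' barcoded adapter (ligated at the rare-cutter site) and the other the
#' universal adapter. Modes: `all` keeps everything; `one_rare_end` keeps
#' fragments with at least one end cut by a barcoded-adapter enzyme;
#' `mixed_ends` keeps fragments with exactly one barcoded end and one
#' universal end. Sequence termini (`SEQ_END`) never qualify as either.
#'
#' @param fragments Fragment tibble.
#' @param barcoded Character vector of enzyme names carrying barcoded
#'   adapters.
#' @param universal Character vector of enzyme names carrying the universal
#'   adapter.
#' @param mode One of `"all"`, `"one_rare_end"`, `"mixed_ends"`.
#' @return The filtered fragment tibble.
#' @export
filter_by_end_composition <- function(fragments, barcoded = character(),
                                      universal = character(),
                                      mode = c("all", "one_rare_end",
                                               "mixed_ends")) {
  mode <- rlang::arg_match(mode)
  if (mode == "all") return(fragments)
  # a "+"-joined boundary label counts as barcoded/universal if any of its
  # enzymes belongs to the set
  in_set <- function(label, set) {
    label != SEQ_END &
      purrr::map_lgl(strsplit(label, "+", fixed = TRUE),
                     ~ any(.x %in% set))
  }
  lb <- in_set(fragments$left_cutter, barcoded)
  rb <- in_set(fragments$right_cutter, barcoded)
  if (mode == "one_rare_end") {
    return(fragments[lb | rb, , drop = FALSE])
  }
  lu <- in_set(fragments$left_cutter, universal)
  ru <- in_set(fragments$right_cutter, universal)
  keep <- (lb & !rb & ru) | (rb & !lb & lu)
  fragments[keep, , drop = FALSE]
}

#' Drop terminal fragments
#'
#' Removes fragments bounded by a sequence end: they lack a ligatable
#' restriction overhang on one side and are excluded from design statistics
#' by default.
#'
#' @param fragments Fragment tibble.
#' @return The filtered fragment tibble.
#' @export
drop_terminal_fragments <- function(fragments) {
  dplyr::filter(fragments, .data$left_cutter != SEQ_END,
                .data$right_cutter != SEQ_END)
}
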