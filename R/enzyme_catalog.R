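# Restriction-enzyme catalog: parsing, validation and cut-site location.

#' Read a restriction-enzyme catalog
#'
#' Parses a tab-separated catalog of type IIP restriction enzymes. Each
#' non-comment line holds `name<TAB>site`, where `site` is the recognition
#' sequence in uppercase IUPAC code with a single caret (`^`) marking the
#' top-strand cut position, e.g. `EcoRI  G^AATTC` (cut after the first base)
#' or `Sse9I  ^AATT` (cut before the site). Lines starting with `#` are
#' comments. Enzymes that cut outside their recognition site (type IIS/IIB)
#' cannot be expressed in this notation and are not supported: two-round
#' digestion design relies on within-site cutters, whose cut is regenerated
#' at fragment ends.
#'
#' @param path Path to the catalog TSV.
#' @return A tibble with one row per enzyme and columns `name`, `site`
#'   (caret notation), `recognition` (site without the caret), `cut_offset`
#'   (0-based top-strand cut position relative to the site start) and
#'   `palindromic` (is the site its own IUPAC reverse complement).
#' @seealso [default_enzyme_catalog()], [find_cut_sites()]
#' @export
read_enzyme_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  entries <- which(keep)
  if (length(entries) == 0L) abort("Catalog contains no enzyme entries.")
  fields <- strsplit(lines[entries], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("Catalog line %d is not `name<TAB>site`.", entries[bad[1]]))
  }
  cat_tbl <- purrr::map2(fields, entries, function(f, line) {
    parse_enzyme_entry(trimws(f[[1]]), trimws(f[[2]]), line)
  })
  out <- dplyr::bind_rows(cat_tbl)
  dup <- out$name[duplicated(out$name)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate enzyme name in catalog: %s.", dup[[1]]))
  }
  out
}

parse_enzyme_entry <- function(name, site, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (catalog line %d)", line)
  if (!nzchar(name)) abort(sprintf("Empty enzyme name%s.", where))
  n_caret <- lengths(regmatches(site, gregexpr("^", site, fixed = TRUE)))
  if (n_caret != 1L) {
    abort(sprintf(
      "Site '%s' for %s%s must contain exactly one '^' cut marker; type IIS/IIB enzymes cutting outside the recognition site are not supported.",
      site, name, where))
  }
  cut_offset <- as.integer(regexpr("^", site, fixed = TRUE)) - 1L
  recognition <- sub("^", "", site, fixed = TRUE)
  chars <- strsplit(recognition, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    abort(sprintf("Empty recognition site for %s%s.", name, where))
  }
  invalid <- setdiff(chars, .iupac_chars)
  if (length(invalid) > 0L) {
    abort(sprintf("Invalid IUPAC symbol '%s' in site '%s' for %s%s.",
                  invalid[[1]], site, name, where))
  }
  tibble(
    name = name, site = site, recognition = recognition,
    cut_offset = cut_offset,
    palindromic = identical(revcomp(recognition), recognition)
  )
}

#' Bundled restriction-enzyme catalog
#'
#' Loads the catalog of commercially available type IIP enzymes shipped with
#' the package (`extdata/enzymes.tsv`, compiled from the public REBASE
#' listing). It includes the enzymes used throughout the worked examples:
#' EcoRI, HindIII, MspI, MseI, SnaBI, StuI, TfiI, HhaI, HinfI, AvaII, Sse9I,
#' CviJI and BfuCI.
#'
#' @return A tibble in the format of [read_enzyme_catalog()].
#' @export
default_enzyme_catalog <- function() {
  read_enzyme_catalog(system.file("extdata", "enzymes.tsv", package = "radopt",
                                  mustWork = TRUE))
}

# Fetch catalog rows by enzyme name, erroring on unknown names.
catalog_subset <- function(catalog, names) {
  idx <- match(names, catalog$name)
  if (anyNA(idx)) {
    abort(sprintf("Enzyme(s) not in catalog: %s.",
                  paste(names[is.na(idx)], collapse = ", ")))
  }
  catalog[idx, , drop = FALSE]
}

# Accept an enzyme given as a one-row tibble/list (name, recognition,
# cut_offset) or as a caret-notation string like "G^AATTC".
as_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L) {
    return(parse_enzyme_entry("enzyme", enzyme))
  }
  if (is.data.frame(enzyme)) {
    if (nrow(enzyme) != 1L) abort("`enzyme` must be a single enzyme.")
    enzyme <- as.list(enzyme)
  }
  if (is.null(enzyme$recognition) || is.null(enzyme$cut_offset)) {
    abort("`enzyme` needs `recognition` and `cut_offset` (or caret notation).")
  }
  if (is.null(enzyme$palindromic)) {
    enzyme$palindromic <- identical(revcomp(enzyme$recognition),
                                    enzyme$recognition)
  }
  enzyme
}

#' Locate the cut sites of an enzyme in a sequence
#'
#' Scans `sequence` for occurrences of the enzyme's recognition site,
#' honouring IUPAC degeneracy in the site (a site `N` matches any base; an
#' ambiguous base such as `N` in the sequence matches nothing). For
#' non-palindromic sites both strands are scanned and reverse-strand cuts are
#' mapped onto top-strand coordinates. Overlapping occurrences are all
#' reported; coincident cuts from the two strands are merged.
#'
#' @param sequence A single nucleotide string (lowercase is normalised).
#' @param enzyme A one-row tibble from a catalog (see
#'   [read_enzyme_catalog()]), or a caret-notation string such as
#'   `"G^AATTC"`.
#' @return Sorted integer vector of 0-based cut coordinates: the position
#'   before which the top strand is cut, each in `[0, nchar(sequence)]`.
#' @export
#' @examples
#' find_cut_sites("AAGAATTCTT", "G^AATTC")  # 4
#' find_cut_sites("GAATCGATTC", "G^AWTC")   # 1, 6
find_cut_sites <- function(sequence, enzyme) {
  enz <- as_enzyme(enzyme)
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single string.")
  }
  seq_raw <- charToRaw(toupper(sequence))
  cut_sites_raw(seq_raw, enz$recognition, enz$cut_offset, enz$palindromic)
}

# Core scanner on raw bytes; shared by digest and the design searches.
cut_sites_raw <- function(seq_raw, recognition, cut_offset, palindromic) {
  m <- nchar(recognition)
  starts <- match_site_starts(seq_raw, recognition)
  cuts <- starts + cut_offset
  if (!palindromic) {
    rstarts <- match_site_starts(seq_raw, revcomp(recognition))
    cuts <- c(cuts, rstarts + (m - cut_offset))
  }
  sort(unique(as.integer(cuts)))
}
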