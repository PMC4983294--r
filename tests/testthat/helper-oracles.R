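# Independent oracles used across the suite. They deliberately take a
# different route from the package implementation: Biostrings pattern
# matching for cut sites (on unambiguous ACGT sequences), naive string
# splitting for digestion, unpruned enumeration for the second-round
# search, and dense per-base arrays for depth.

suppressPackageStartupMessages({
  library(Biostrings)
})

# 0-based cut coordinates via Biostrings::matchPattern. ACGT-only
# subjects: Biostrings lets a pattern N match a subject N, whereas the
# package convention is that an ambiguous genome base matches nothing.
oracle_cut_sites <- function(sequence, site) {
  stopifnot(grepl("\\^", site))
  cut_offset <- regexpr("^", site, fixed = TRUE) - 1L
  recognition <- sub("^", "", site, fixed = TRUE)
  m <- nchar(recognition)
  subj <- Biostrings::DNAString(toupper(sequence))
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(recognition), subj, fixed = "subject")) - 1L
  cuts <- fwd + cut_offset
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
  if (!identical(rc, recognition)) {
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(rc), subj, fixed = "subject")) - 1L
    cuts <- c(cuts, rev + (m - cut_offset))
  }
  sort(unique(as.integer(cuts)))
}

# Naive string-splitting digestion: fragment boundaries are the pooled
# oracle cut sites plus the sequence ends.
oracle_digest <- function(sequence, sites) {
  L <- nchar(sequence)
  cuts <- sort(unique(unlist(lapply(sites, oracle_cut_sites,
                                    sequence = sequence))))
  bounds <- sort(unique(c(0L, cuts[cuts > 0L & cuts < L], L)))
  tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
}

# Unpruned brute-force second-round search over ALL subsets of size
# 1..max_combo, using oracle incidence; same ranking contract.
oracle_second_round <- function(fragments, catalog_sites, max_combo = 3) {
  organellar <- fragments$region_class %in% c("chloroplast", "rRNA")
  inc <- sapply(names(catalog_sites), function(nm) {
    vapply(fragments$sequence, function(s) {
      cuts <- oracle_cut_sites(s, catalog_sites[[nm]])
      any(cuts > 0L & cuts < nchar(s))
    }, logical(1))
  })
  inc <- matrix(inc, nrow = nrow(fragments),
                dimnames = list(NULL, names(catalog_sites)))
  subsets <- unlist(lapply(seq_len(min(max_combo, ncol(inc))), function(k) {
    combn(colnames(inc), k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    cut <- rowSums(inc[, ss, drop = FALSE]) > 0
    tibble::tibble(
      enzymes = paste(sort(ss), collapse = "+"),
      n_enzymes = length(ss),
      organellar_cut = sum(cut & organellar),
      genomic_intact = sum(!organellar) - sum(cut & !organellar),
      complete = sum(cut & organellar) == sum(organellar)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(complete), dplyr::desc(organellar_cut),
                 dplyr::desc(genomic_intact), n_enzymes, enzymes)
}

# Dense per-base depth from pair spans on one sequence.
oracle_depth <- function(starts, ends, len) {
  depth <- integer(len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Offspring genotype-class probabilities for a duplex x duplex (AAaa x
# AAaa) tetraploid F2 by explicit gamete enumeration under double
# reduction alpha.
oracle_tetraploid_f2 <- function(alpha) {
  parent <- c("A", "A", "a", "a")
  pairs <- combn(4, 2, simplify = FALSE)
  gam <- c(AA = 0, Aa = 0, aa = 0)
  for (p in pairs) {
    g <- paste(sort(parent[p], decreasing = TRUE), collapse = "")
    g <- chartr("aA", "aA", g)
    key <- if (g %in% names(gam)) g else "Aa"
    gam[key] <- gam[key] + (1 - alpha) / length(pairs)
  }
  for (i in 1:4) {  # double-reduction gamete duplicates one allele
    key <- paste0(parent[i], parent[i])
    gam[key] <- gam[key] + alpha / 4
  }
  hom1 <- gam[["AA"]]^2
  hom2 <- gam[["aa"]]^2
  c(homP1 = hom1, het = 1 - hom1 - hom2, homP2 = hom2)
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
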