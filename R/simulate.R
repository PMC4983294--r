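# Synthetic-data generators: genomes with planted restriction fragments,
# barcoded read pools weighted by per-cell copy number, and
# segregating-population genotype matrices. All ground truth is returned in
# manifests so downstream modules can be tested without any downloads.

#' Deterministic inline barcode table
#'
#' Returns `n` 5-bp barcodes chosen greedily (in a fixed enumeration order,
#' no randomness) so that every pair differs at >= 3 positions, which keeps
#' single-mismatch demultiplexing unambiguous.
#'
#' @param n Number of samples (default 12, one pooled library).
#' @param length Barcode length in bases (default 5).
#' @param min_distance Minimum pairwise Hamming distance (default 3).
#' @return Tibble with `sample_id` (`S01`, `S02`, ...) and `barcode`.
#' @export
default_barcode_table <- function(n = 12, length = 5, min_distance = 3) {
  bases <- c("A", "C", "G", "T")
  chosen <- matrix(character(0), ncol = length)
  idx <- rep(1L, length)
  repeat {
    cand <- bases[idx]
    if (nrow(chosen) == 0L ||
        all(rowSums(chosen != matrix(cand, nrow = nrow(chosen), ncol = length,
                                     byrow = TRUE)) >= min_distance)) {
      chosen <- rbind(chosen, cand)
      if (nrow(chosen) >= n) break
    }
    # next word in base-4 counting order
    j <- length
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 4L) break
      idx[j] <- 1L
      j <- j - 1L
      if (j == 0L) abort(sprintf("Cannot build %d barcodes at distance %d.",
                                 n, min_distance))
    }
  }
  tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    barcode = unname(apply(chosen, 1, paste, collapse = ""))[seq_len(n)]
  )
}

# Does joining `left` and `right` create a match of any pattern that spans
# the junction? Matches lying entirely within one side are that side's own
# business (e.g. the planted site at the start of a block) and are ignored.
junction_dirty <- function(left, right, forbidden) {
  mmax <- max(c(2L, nchar(forbidden)))
  tail_part <- substr(left, max(1L, nchar(left) - mmax + 2L), nchar(left))
  head_part <- substr(right, 1L, mmax - 1L)
  probe <- charToRaw(paste0(tail_part, head_part))
  boundary <- nchar(tail_part)
  for (p in forbidden) {
    starts <- match_site_starts(probe, p)
    if (any(starts < boundary & starts + nchar(p) > boundary)) return(TRUE)
  }
  FALSE
}

# Random background sequence of length n free of every `forbidden` IUPAC
# pattern, including windows spanning the junctions with `context`
# (preceding bases) and `next_head` (following bases). Chunked rejection
# sampling keeps generation linear in n.
build_clean_seq <- function(n, base_probs, forbidden, context = "",
                            next_head = "", chunk = 80L, max_tries = 500L) {
  if (n <= 0L) {
    if (nzchar(next_head) &&
        junction_dirty(context, next_head, forbidden)) {
      abort("Could not sample a clean junction.")
    }
    return("")
  }
  bases <- c("A", "C", "G", "T")
  pieces <- character(0)
  prev <- context
  built <- 0L
  while (built < n) {
    take <- min(chunk, n - built)
    last <- built + take >= n
    for (try in seq_len(max_tries)) {
      cand <- paste(sample(bases, take, replace = TRUE, prob = base_probs),
                    collapse = "")
      ok <- !contains_any_site(charToRaw(cand), forbidden) &&
        !junction_dirty(prev, cand, forbidden) &&
        (!last || !nzchar(next_head) ||
           !junction_dirty(cand, next_head, forbidden))
      if (ok) break
      if (try == max_tries) abort("Could not sample site-free background sequence.")
    }
    pieces <- c(pieces, cand)
    built <- built + take
    prev <- cand
  }
  paste(pieces, collapse = "")
}

# Both-strand IUPAC patterns whose presence implies a cut by any of the
# given enzymes.
forbidden_patterns <- function(enzymes) {
  unique(c(enzymes$recognition,
           revcomp(enzymes$recognition[!enzymes$palindromic])))
}

# A concrete ACGT realisation of an IUPAC site (first base of each set).
concrete_site <- function(recognition) {
  chars <- strsplit(recognition, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) .iupac_sets[[ch]][[1]], character(1)),
        collapse = "")
}

# One planted block: left site + interior + right site. The interior
# avoids all `forbidden` patterns and optionally carries one `insert`
# sequence (the second-round cut site of organellar fragments). The
# finished block is verified with the real scanner: no enzyme in
# `verify_enzymes` cuts strictly inside the fragment interval, and
# `require_cut` (if given) does cut there.
planted_block <- function(frag_len, e1, e2, base_probs, forbidden,
                          insert = NULL, verify_enzymes = NULL,
                          require_cut = NULL) {
  m1 <- nchar(e1$recognition); o1 <- e1$cut_offset
  o2 <- e2$cut_offset
  interior_len <- frag_len - m1 - o2 + o1
  ins <- if (is.null(insert)) "" else insert
  if (interior_len < nchar(ins) + 2L) {
    abort("Fragment length too short for the requested planted block.")
  }
  left_site <- concrete_site(e1$recognition)
  right_site <- concrete_site(e2$recognition)
  lpad_len <- (interior_len - nchar(ins)) %/% 2L
  rpad_len <- interior_len - nchar(ins) - lpad_len
  frag_start <- o1
  frag_end <- o1 + frag_len
  strictly_inside <- function(block_raw, enz_row) {
    cuts <- cut_sites_raw(block_raw, enz_row$recognition, enz_row$cut_offset,
                          enz_row$palindromic)
    cuts[cuts > frag_start & cuts < frag_end]
  }
  for (try in 1:50) {
    lpad <- build_clean_seq(lpad_len, base_probs, forbidden,
                            context = left_site, next_head = ins)
    rpad <- build_clean_seq(rpad_len, base_probs, forbidden,
                            context = paste0(left_site, lpad, ins),
                            next_head = right_site)
    block <- paste0(left_site, lpad, ins, rpad, right_site)
    block_raw <- charToRaw(block)
    ok <- TRUE
    if (!is.null(verify_enzymes)) {
      for (i in seq_len(nrow(verify_enzymes))) {
        if (length(strictly_inside(block_raw, as.list(verify_enzymes[i, ]))) > 0L) {
          ok <- FALSE; break
        }
      }
    }
    if (ok && !is.null(require_cut) &&
        length(strictly_inside(block_raw, as.list(require_cut[1, ]))) == 0L) {
      ok <- FALSE
    }
    if (ok) {
      return(list(block = block,
                  frag_start = frag_start,
                  frag_len = frag_len,
                  block_len = nchar(block)))
    }
  }
  abort("Could not assemble a planted fragment without spurious sites.")
}

# Assemble one sequence of total length `seq_len` carrying `blocks` planted
# blocks separated by site-free spacers (each >= min_spacer bp).
assemble_sequence <- function(seq_id, seq_len, frag_lens, e1, e2, base_probs,
                              forbidden, insert = NULL, region_class = "genomic",
                              min_spacer = 600L, verify_enzymes = NULL,
                              require_cut = NULL) {
  blocks <- lapply(frag_lens, function(l) {
    planted_block(l, e1, e2, base_probs, forbidden, insert,
                  verify_enzymes = verify_enzymes, require_cut = require_cut)
  })
  block_total <- sum(vapply(blocks, `[[`, numeric(1), "block_len"))
  n_sp <- length(blocks) + 1L
  spare <- seq_len - block_total
  if (spare < min_spacer * n_sp) {
    abort("Sequence too short for the requested planted fragments.")
  }
  w <- runif(n_sp, 0.6, 1.4)
  sp_len <- floor(spare * w / sum(w))
  sp_len[n_sp] <- spare - sum(sp_len[-n_sp])
  pieces <- character(0)
  frag_rows <- list()
  cursor <- 0L
  ctx <- ""
  for (i in seq_along(blocks)) {
    head_next <- substr(blocks[[i]]$block, 1L, 12L)
    sp <- build_clean_seq(sp_len[[i]], base_probs, forbidden, context = ctx,
                          next_head = head_next)
    pieces <- c(pieces, sp, blocks[[i]]$block)
    block_start <- cursor + nchar(sp)
    frag_rows[[i]] <- tibble(
      seq_id = seq_id,
      start = block_start + blocks[[i]]$frag_start,
      end = block_start + blocks[[i]]$frag_start + blocks[[i]]$frag_len,
      length = blocks[[i]]$frag_len,
      left_cutter = e1$name, right_cutter = e2$name,
      region_class = region_class
    )
    cursor <- block_start + blocks[[i]]$block_len
    ctx <- blocks[[i]]$block
  }
  sp <- build_clean_seq(sp_len[[n_sp]], base_probs, forbidden, context = ctx)
  pieces <- c(pieces, sp)
  list(sequence = paste(pieces, collapse = ""),
       fragments = dplyr::bind_rows(frag_rows))
}

#' Simulate a genome with planted restriction fragments
#'
#' Generates nuclear chromosomes, a chloroplast sequence and an rRNA gene
#' array with fully known digestion truth: each planted fragment is
#' bounded by concrete sites of the two first-round enzymes and its
#' interior is guaranteed free of spurious sites of those enzymes, while
#' the background between fragments is site-free, so a complete digestion
#' plus size selection recovers exactly the planted fragments. Organellar
#' (chloroplast and rRNA) fragments each carry one cut site of
#' `second_round_enzyme` in their interior and genomic fragments carry
#' none, making the designed second-round optimum known by construction.
#'
#' @param n_chromosomes,chromosome_length Nuclear genome shape (defaults
#'   5 chromosomes of 1 Mb).
#' @param gc_content Background GC fraction (default 0.36, typical of a
#'   small plant nuclear genome).
#' @param n_fragments_per_chromosome Planted genomic fragments per
#'   chromosome (default 200).
#' @param fragment_length_range Planted fragment lengths are drawn
#'   uniformly from this inclusive range (default 224-424 bp).
#' @param enzymes Two catalog rows: left (barcoded-adapter) and right
#'   (universal-adapter) cutter of every planted fragment; default EcoRI
#'   and MspI.
#' @param chloroplast_length,n_chloroplast_fragments Chloroplast genome
#'   size and planted fragment count (defaults 150 kb, 40).
#' @param rrna_unit_length,n_rrna_fragments rRNA array: one planted
#'   fragment per repeat unit (defaults 10 kb units, 4 fragments),
#'   appended to chromosome 1 and annotated as an rRNA interval.
#' @param second_round_enzyme Catalog name of the enzyme whose site is
#'   planted inside every organellar fragment (default `"SnaBI"`); `NULL`
#'   to plant none.
#' @param n_polymorphisms Known polymorphic positions planted inside
#'   genomic fragments (default 100).
#' @param catalog Enzyme catalog (default [default_enzyme_catalog()]).
#' @param seed Optional RNG seed; fixed seed gives identical output.
#' @return List: `regions` (tibble `seq_id`, `sequence`, `region_class`,
#'   `length`), `rrna` (interval tibble), `truth` (list with `fragments`
#'   and `polymorphisms` tibbles), `enzymes`, `second_round_enzyme`.
#' @export
simulate_genome <- function(n_chromosomes = 5, chromosome_length = 1e6,
                            gc_content = 0.36,
                            n_fragments_per_chromosome = 200,
                            fragment_length_range = c(224, 424),
                            enzymes = NULL,
                            chloroplast_length = 150000,
                            n_chloroplast_fragments = 40,
                            rrna_unit_length = 10000, n_rrna_fragments = 4,
                            second_round_enzyme = "SnaBI",
                            n_polymorphisms = 100,
                            catalog = default_enzyme_catalog(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(enzymes)) enzymes <- catalog_subset(catalog, c("EcoRI", "MspI"))
  if (nrow(enzymes) == 1L) enzymes <- enzymes[c(1, 1), ]
  e1 <- as.list(enzymes[1, ]); e2 <- as.list(enzymes[2, ])
  base_probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
                  (1 - gc_content) / 2)

  killer <- NULL
  insert <- NULL
  if (!is.null(second_round_enzyme)) {
    killer <- catalog_subset(catalog, second_round_enzyme)
    insert <- concrete_site(killer$recognition[[1]])
  }
  # planted interiors and background must stay free of the digestion
  # enzymes; genomic interiors additionally avoid the second-round site so
  # that the designed second round leaves them intact
  forb_digest <- forbidden_patterns(enzymes)
  forb_genomic <- unique(c(forb_digest,
                           if (!is.null(killer)) forbidden_patterns(killer)))

  chrom_ids <- sprintf("chr%d", seq_len(n_chromosomes))
  regions <- list(); frag_rows <- list(); rrna_tbl <- NULL

  verify_genomic <- dplyr::bind_rows(enzymes, killer)
  for (i in seq_len(n_chromosomes)) {
    lens <- sample(seq(fragment_length_range[[1]], fragment_length_range[[2]]),
                   n_fragments_per_chromosome, replace = TRUE)
    asm <- assemble_sequence(chrom_ids[[i]], as.integer(chromosome_length),
                             lens, e1, e2, base_probs, forb_genomic,
                             verify_enzymes = verify_genomic)
    seq_i <- asm$sequence
    frags_i <- asm$fragments
    if (i == 1L && n_rrna_fragments > 0L) {
      array_len <- as.integer(rrna_unit_length) * n_rrna_fragments
      rl <- sample(seq(fragment_length_range[[1]], fragment_length_range[[2]]),
                   n_rrna_fragments, replace = TRUE)
      arr <- assemble_sequence(chrom_ids[[i]], array_len, rl, e1, e2,
                               base_probs, forb_genomic, insert = insert,
                               region_class = "rRNA",
                               verify_enzymes = enzymes, require_cut = killer)
      offset <- nchar(seq_i)
      arr$fragments$start <- arr$fragments$start + offset
      arr$fragments$end <- arr$fragments$end + offset
      rrna_tbl <- tibble(seq_id = chrom_ids[[i]], start = offset,
                         end = offset + nchar(arr$sequence))
      seq_i <- paste0(seq_i, arr$sequence)
      frags_i <- dplyr::bind_rows(frags_i, arr$fragments)
    }
    regions[[length(regions) + 1L]] <-
      tibble(seq_id = chrom_ids[[i]], sequence = seq_i,
             region_class = "genomic")
    frag_rows[[length(frag_rows) + 1L]] <- frags_i
  }

  if (n_chloroplast_fragments > 0L) {
    cl <- sample(seq(fragment_length_range[[1]], fragment_length_range[[2]]),
                 n_chloroplast_fragments, replace = TRUE)
    cp <- assemble_sequence("chloroplast", as.integer(chloroplast_length), cl,
                            e1, e2, base_probs, forb_genomic, insert = insert,
                            region_class = "chloroplast",
                            verify_enzymes = enzymes, require_cut = killer)
    regions[[length(regions) + 1L]] <-
      tibble(seq_id = "chloroplast", sequence = cp$sequence,
             region_class = "chloroplast")
    frag_rows[[length(frag_rows) + 1L]] <- cp$fragments
  }

  regions <- dplyr::bind_rows(regions)
  regions$length <- nchar(regions$sequence)
  fragments <- dplyr::bind_rows(frag_rows)

  genomic_frags <- dplyr::filter(fragments, .data$region_class == "genomic")
  polymorphisms <- NULL
  if (n_polymorphisms > 0L && nrow(genomic_frags) > 0L) {
    pick <- sample(nrow(genomic_frags), n_polymorphisms,
                   replace = n_polymorphisms > nrow(genomic_frags))
    polymorphisms <- tibble(
      seq_id = genomic_frags$seq_id[pick],
      pos = genomic_frags$start[pick] +
        floor(runif(length(pick), 8, genomic_frags$length[pick] - 8))
    )
    polymorphisms <- dplyr::distinct(polymorphisms)
  }

  list(
    regions = regions,
    rrna = rrna_tbl %||% tibble(seq_id = character(0), start = integer(0),
                                end = integer(0)),
    truth = list(fragments = fragments,
                 polymorphisms = polymorphisms %||%
                   tibble(seq_id = character(0), pos = integer(0))),
    enzymes = enzymes$name,
    second_round_enzyme = second_round_enzyme
  )
}

#' Attach residue sequences to fragment intervals
#'
#' @param fragments Fragment tibble (`seq_id`, `start`, `end`).
#' @param regions Regions tibble with `sequence`.
#' @return `fragments` with a `sequence` column.
#' @export
fragment_sequences <- function(fragments, regions) {
  regions <- as_regions(regions)
  seq_lookup <- setNames(regions$sequence, regions$seq_id)
  fragments$sequence <- substr(seq_lookup[fragments$seq_id],
                               fragments$start + 1L, fragments$end)
  fragments
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  k <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(nchar(seqs[[i]]), k[[i]])
    for (p in pos) {
      cur <- substr(seqs[[i]], p, p)
      substr(seqs[[i]], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate a barcoded pooled read library
#'
#' Draws paired-end reads from the supplied fragments with probability
#' proportional to each fragment's per-cell copy number (genomic x ploidy;
#' rRNA x ploidy x `rrna_copies_per_haploid`; chloroplast x
#' `chloroplast_copies_per_cell`) - the same dilution model as
#' [predict_read_proportions()]. Read 1 is the sample's barcode followed
#' by the fragment 5' end (so the enzyme overhang directly follows the
#' barcode); read 2 is the reverse complement of the fragment 3' end.
#' Substitution errors are added at `error_rate` per base.
#'
#' @param fragments Fragment tibble with `sequence` and `region_class`.
#' @param barcodes Barcode table (default [default_barcode_table()] with
#'   12 samples).
#' @param n_pairs_per_sample Read pairs per sample (default 1000).
#' @param read_length Read length in bp (default 150).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param rrna_copies_per_haploid,chloroplast_copies_per_cell,ploidy Copy
#'   numbers of the dilution model (defaults 700, 1200, 2).
#' @param output_dir If non-`NULL`, write `pool_R1.fastq` and
#'   `pool_R2.fastq` there.
#' @param seed Optional RNG seed.
#' @return List: `r1`, `r2` (character vectors of read sequences, in pool
#'   order), `ids`, `truth` (tibble `read_id`, `sample_id`, `fragment`,
#'   `class`), and `r1_path`/`r2_path` when files were written.
#' @export
simulate_read_pool <- function(fragments, barcodes = default_barcode_table(),
                               n_pairs_per_sample = 1000, read_length = 150,
                               error_rate = 0.001,
                               rrna_copies_per_haploid = 700,
                               chloroplast_copies_per_cell = 1200,
                               ploidy = 2, output_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(fragments) == 0L) abort("`fragments` is empty.")
  if (!"sequence" %in% names(fragments)) abort("`fragments` needs a `sequence` column.")
  w <- dplyr::case_when(
    fragments$region_class == "rRNA" ~ ploidy * rrna_copies_per_haploid,
    fragments$region_class == "chloroplast" ~ chloroplast_copies_per_cell,
    TRUE ~ as.numeric(ploidy)
  )
  n_samples <- nrow(barcodes)
  n_total <- n_samples * n_pairs_per_sample
  sample_of <- rep(seq_len(n_samples), each = n_pairs_per_sample)
  frag_of <- sample.int(nrow(fragments), n_total, replace = TRUE, prob = w)
  # shuffle into pool order
  ord <- sample.int(n_total)
  sample_of <- sample_of[ord]; frag_of <- frag_of[ord]

  fseq <- fragments$sequence[frag_of]
  flen <- nchar(fseq)
  bc <- barcodes$barcode[sample_of]
  ins1 <- read_length - nchar(bc)
  r1 <- paste0(bc, substr(fseq, 1L, pmin(ins1, flen)))
  r2 <- revcomp(substr(fseq, pmax(1L, flen - read_length + 1L), flen))
  r1 <- inject_errors(r1, error_rate)
  r2 <- inject_errors(r2, error_rate)
  ids <- sprintf("pair%07d", seq_len(n_total))
  truth <- tibble(
    read_id = ids,
    sample_id = barcodes$sample_id[sample_of],
    fragment = frag_of,
    class = fragments$region_class[frag_of]
  )
  out <- list(r1 = r1, r2 = r2, ids = ids, truth = truth)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    out$r1_path <- file.path(output_dir, "pool_R1.fastq")
    out$r2_path <- file.path(output_dir, "pool_R2.fastq")
    write_simple_fastq(ids, r1, out$r1_path)
    write_simple_fastq(ids, r2, out$r2_path)
  }
  out
}

write_simple_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
}

#' Simulate a segregating-population genotype matrix (and VCF)
#'
#' Draws per-offspring genotype classes from the expected class
#' frequencies of a population model (or explicit `truth_freqs`),
#' assigns concrete genotype calls with homozygous grandparental lines as
#' the two parent samples, and simulates per-call depth and genotype
#' quality such that a configurable fraction of calls fail the standard
#' filtering thresholds (DP >= 10, GQ >= 20).
#'
#' @param population,alpha Population model (see
#'   [expected_genotype_freqs()]).
#' @param n_markers,n_offspring Scan dimensions (defaults 1000 markers,
#'   10 offspring as in a 2-parents + 10-offspring pool).
#' @param truth_freqs Optional explicit class frequencies replacing the
#'   model's.
#' @param mean_depth,mean_gq Means of the simulated passing DP and GQ
#'   (defaults 30 and 45; passing calls are kept above the filter
#'   thresholds).
#' @param fail_fraction Fraction of calls rendered sub-threshold
#'   (default 0).
#' @param n_chromosomes,chromosome_length Marker coordinate space.
#' @param path If non-`NULL`, also write a VCFv4.2 file (gzipped when the
#'   path ends in `.gz`) via `vcfR`.
#' @param seed Optional RNG seed.
#' @return List: `genotypes` (long tibble as in
#'   [read_genotype_matrix()]), `truth` (tibble `seq_id`, `pos`,
#'   `sample_id`, `class`), `expected` (class frequencies used), `path`.
#' @export
simulate_population_vcf <- function(population = "diploid_F2", alpha = 0,
                                    n_markers = 1000, n_offspring = 10,
                                    truth_freqs = NULL,
                                    mean_depth = 30, mean_gq = 45,
                                    fail_fraction = 0,
                                    n_chromosomes = 5,
                                    chromosome_length = 1e6,
                                    path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- truth_freqs %||% expected_genotype_freqs(population, alpha)
  tetra <- grepl("^tetraploid", population)
  gt_of <- if (tetra) {
    c(homP1 = "0/0/0/0", het = "0/0/1/1", homP2 = "1/1/1/1")
  } else {
    c(homP1 = "0/0", het = "0/1", homP2 = "1/1")
  }
  parent_gt <- switch(population,
    diploid_F1_AAxAa = c("0/0", "0/1"),
    tetraploid_F1 = c("0/1/1/1", "1/1/1/1"),
    if (tetra) c("0/0/0/0", "1/1/1/1") else c("0/0", "1/1")
  )

  chrom <- sort(sample.int(n_chromosomes, n_markers, replace = TRUE))
  pos <- integer(n_markers)
  for (cc in unique(chrom)) {
    k <- sum(chrom == cc)
    pos[chrom == cc] <- sort(sample.int(chromosome_length - 1L, k))
  }
  seq_id <- sprintf("chr%d", chrom)

  classes <- matrix(
    sample(names(f), n_markers * n_offspring, replace = TRUE, prob = f),
    nrow = n_markers
  )
  offspring_ids <- sprintf("F2_%02d", seq_len(n_offspring))
  samples <- c("P1", "P2", offspring_ids)

  gm <- tidyr::expand_grid(marker = seq_len(n_markers), sample_id = samples)
  gm <- dplyr::mutate(
    gm,
    seq_id = seq_id[.data$marker],
    pos = pos[.data$marker],
    ref = "A", alt = "T",
    role = dplyr::case_when(sample_id == "P1" ~ "parent1",
                            sample_id == "P2" ~ "parent2",
                            TRUE ~ "offspring"),
    gt = dplyr::case_when(
      sample_id == "P1" ~ parent_gt[[1]],
      sample_id == "P2" ~ parent_gt[[2]],
      TRUE ~ unname(gt_of[classes[cbind(.data$marker,
                                        pmax(match(.data$sample_id, offspring_ids), 1L))]])
    )
  )
  n_calls <- nrow(gm)
  gm$dp <- 10L + rpois(n_calls, max(0, mean_depth - 10))
  gm$gq <- 20L + rpois(n_calls, max(0, mean_gq - 20))
  if (fail_fraction > 0) {
    fail <- runif(n_calls) < fail_fraction
    gm$dp[fail] <- sample(0:9, sum(fail), replace = TRUE)
  }
  gm <- dplyr::select(gm, "seq_id", "pos", "ref", "alt", "sample_id", "role",
                      "gt", "dp", "gq")

  truth <- tidyr::expand_grid(marker = seq_len(n_markers),
                              sample_id = offspring_ids)
  truth <- dplyr::mutate(truth,
                         seq_id = seq_id[.data$marker], pos = pos[.data$marker],
                         class = classes[cbind(.data$marker,
                                               match(.data$sample_id, offspring_ids))])
  truth <- dplyr::select(truth, "seq_id", "pos", "sample_id", "class")

  if (!is.null(path)) write_population_vcf(gm, samples, path)
  list(genotypes = gm, truth = truth, expected = f, path = path)
}

# Minimal VCFv4.2 writer over vcfR for the simulated population.
write_population_vcf <- function(gm, samples, path) {
  keys <- dplyr::distinct(gm, .data$seq_id, .data$pos, .data$ref, .data$alt)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  fix <- cbind(
    CHROM = keys$seq_id, POS = as.character(keys$pos), ID = ".",
    REF = keys$ref, ALT = keys$alt, QUAL = ".", FILTER = "PASS", INFO = "."
  )
  wide <- gm |>
    dplyr::mutate(call = sprintf("%s:%d:%d",
                                 dplyr::coalesce(.data$gt, "./."),
                                 .data$dp, .data$gq)) |>
    dplyr::select("seq_id", "pos", "sample_id", "call") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "call")
  gt <- cbind(FORMAT = "GT:DP:GQ",
              as.matrix(wide[match(paste(keys$seq_id, keys$pos),
                                   paste(wide$seq_id, wide$pos)), samples]))
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
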