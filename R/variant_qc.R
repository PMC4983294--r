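# Population variant QC: VCF import to a long genotype tibble and the
# five-criterion filtering used before segregation analysis.

#' Read a population VCF into a long genotype tibble
#'
#' Imports a VCFv4.2 file (plain or gzipped) holding two parental lines
#' and their segregating offspring. Genotype (`GT`), depth (`DP`) and
#' genotype quality (`GQ`) are taken from the per-sample FORMAT fields;
#' a missing genotype is `./.` (any ploidy) or an absent field.
#'
#' @param path VCF file path.
#' @param parents Character vector of the two parental sample names, in
#'   order (`parent1`, `parent2`).
#' @return Long tibble with one row per variant x sample: `seq_id`, `pos`
#'   (1-based), `ref`, `alt`, `sample_id`, `role` (`parent1`, `parent2`,
#'   `offspring`), `gt`, `dp`, `gq`.
#' @export
read_genotype_matrix <- function(path, parents) {
  if (length(parents) != 2L) abort("`parents` must name exactly 2 samples.")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  samples <- colnames(gt)
  if (!all(parents %in% samples)) {
    abort("Both parental sample names must be present in the VCF.")
  }
  long <- tidyr::expand_grid(
    variant = seq_len(nrow(fix)), sample_id = samples
  )
  long <- dplyr::mutate(
    long,
    seq_id = fix$CHROM[.data$variant],
    pos = as.integer(fix$POS[.data$variant]),
    ref = fix$REF[.data$variant],
    alt = fix$ALT[.data$variant],
    role = dplyr::case_when(
      sample_id == parents[[1]] ~ "parent1",
      sample_id == parents[[2]] ~ "parent2",
      TRUE ~ "offspring"
    ),
    gt = gt[cbind(.data$variant, match(.data$sample_id, samples))],
    dp = dp[cbind(.data$variant, match(.data$sample_id, samples))],
    gq = gq[cbind(.data$variant, match(.data$sample_id, samples))]
  )
  dplyr::select(long, "seq_id", "pos", "ref", "alt", "sample_id", "role",
                "gt", "dp", "gq")
}

# Allele index sets from GT strings ("0/1", "0|1", "0/0/1/1", "./."),
# NA/"."-only -> NULL (missing).
gt_alleles <- function(gt) {
  lapply(strsplit(ifelse(is.na(gt), ".", gt), "[/|]"), function(a) {
    a <- a[a != "."]
    if (length(a) == 0L) NULL else sort(unique(a))
  })
}

#' Filter candidate variants for a segregating population
#'
#' Applies the stringent site-level criteria used before genotype
#' validation. Calls failing the per-sample depth or genotype-quality
#' thresholds are first set to missing; each variant is then rejected by
#' the first failed criterion, in this fixed order: (3) a parental
#' genotype is missing, (4) fewer than `min_offspring_genotyped`
#' offspring genotyped, (5) an offspring carries an allele absent from
#' both parents, and finally more than two alleles at the site.
#'
#' @param genotypes Long genotype tibble (see [read_genotype_matrix()]).
#' @param min_depth Minimum per-sample mapping depth (default 10 reads).
#' @param min_genotype_quality Minimum per-sample Phred genotype quality
#'   (default 20).
#' @param require_both_parents Reject variants with a missing parental
#'   call (default `TRUE`).
#' @param min_offspring_genotyped Minimum offspring with a genotype
#'   (default 7).
#' @param require_allele_consistency Reject variants whose offspring
#'   alleles are not a subset of the parental alleles (default `TRUE`).
#' @param biallelic_only Reject variants with more than one ALT allele
#'   (default `TRUE`).
#' @return A `rad_filter` object: list with `passing` (the masked
#'   genotype tibble restricted to surviving variants), `tally` (tibble of
#'   first-failed-criterion rejection counts), `n_input`, `n_passing`.
#'   `tidy()` returns the tally.
#' @export
filter_variants <- function(genotypes, min_depth = 10,
                            min_genotype_quality = 20,
                            require_both_parents = TRUE,
                            min_offspring_genotyped = 7,
                            require_allele_consistency = TRUE,
                            biallelic_only = TRUE) {
  if (length(unique(genotypes$sample_id[genotypes$role == "parent1"])) != 1L ||
      length(unique(genotypes$sample_id[genotypes$role == "parent2"])) != 1L) {
    abort("`genotypes` must label exactly one parent1 and one parent2 sample.")
  }
  g <- dplyr::mutate(
    genotypes,
    gt_masked = dplyr::if_else(
      is.na(.data$gt) |
        dplyr::coalesce(.data$dp, 0) < min_depth |
        dplyr::coalesce(.data$gq, 0) < min_genotype_quality,
      NA_character_, .data$gt
    )
  )
  g$alleles <- gt_alleles(g$gt_masked)
  g$missing <- purrr::map_lgl(g$alleles, is.null)

  per_variant <- g |>
    dplyr::group_by(.data$seq_id, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      parents_ok = sum(!.data$missing[.data$role != "offspring"]) == 2L,
      n_offspring = sum(!.data$missing[.data$role == "offspring"]),
      consistent = {
        par_alleles <- unique(unlist(.data$alleles[.data$role != "offspring"]))
        off_alleles <- unique(unlist(.data$alleles[.data$role == "offspring"]))
        all(off_alleles %in% par_alleles)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      biallelic = !grepl(",", .data$alt, fixed = TRUE),
      first_fail = dplyr::case_when(
        require_both_parents & !.data$parents_ok ~ "parent_missing",
        .data$n_offspring < min_offspring_genotyped ~ "too_few_offspring",
        require_allele_consistency & !.data$consistent ~ "allele_inconsistency",
        biallelic_only & !.data$biallelic ~ "multiallelic",
        TRUE ~ NA_character_
      )
    )

  tally_levels <- c("parent_missing", "too_few_offspring",
                    "allele_inconsistency", "multiallelic")
  tally <- tibble(
    criterion = tally_levels,
    n_rejected = vapply(tally_levels,
                        function(l) sum(per_variant$first_fail %in% l),
                        integer(1), USE.NAMES = FALSE)
  )
  keys <- dplyr::filter(per_variant, is.na(.data$first_fail))
  passing <- dplyr::semi_join(
    dplyr::select(g, -"gt", -"missing") |> dplyr::rename(gt = "gt_masked"),
    keys, by = c("seq_id", "pos", "ref", "alt")
  )
  passing$alleles <- NULL
  structure(
    list(passing = passing, tally = tally,
         n_input = nrow(per_variant), n_passing = nrow(keys)),
    class = "rad_filter"
  )
}

#' @export
print.rad_filter <- function(x, ...) {
  cat(sprintf("Variant filtering: %d of %d sites pass\n",
              x$n_passing, x$n_input))
  print(x$tally, ...)
  invisible(x)
}

#' @rdname filter_variants
#' @param x A `rad_filter` object.
#' @param ... Unused.
#' @export
tidy.rad_filter <- function(x, ...) x$tally

#' @rdname filter_variants
#' @export
glance.rad_filter <- function(x, ...) {
  tibble(n_input = x$n_input, n_passing = x$n_passing,
         pass_fraction = x$n_passing / max(x$n_input, 1))
}

#' Tally offspring genotype classes per variant
#'
#' Reduces each offspring call to an allele-presence class relative to the
#' parental lines: `homP1` / `homP2` when only one parent's allele is
#' observed, `het` when both are. In tetraploids this is deliberately a
#' presence class, carrying no allele-dosage information.
#'
#' @param genotypes Long genotype tibble (typically the `passing` element
#'   of [filter_variants()]).
#' @return Tibble with one row per variant: `seq_id`, `pos`, `homP1`,
#'   `het`, `homP2`, `n` (genotyped offspring).
#' @export
genotype_class_counts <- function(genotypes) {
  g <- genotypes
  g$alleles <- gt_alleles(g$gt)
  per_variant <- g |>
    dplyr::group_by(.data$seq_id, .data$pos) |>
    dplyr::summarise(
      classes = {
        p1 <- unlist(.data$alleles[.data$role == "parent1"])
        p2 <- unlist(.data$alleles[.data$role == "parent2"])
        off <- .data$alleles[.data$role == "offspring"]
        list(vapply(off, classify_offspring, character(1), p1 = p1, p2 = p2))
      },
      .groups = "drop"
    )
  dplyr::mutate(
    per_variant,
    homP1 = purrr::map_int(.data$classes, ~ sum(.x == "homP1")),
    het = purrr::map_int(.data$classes, ~ sum(.x == "het")),
    homP2 = purrr::map_int(.data$classes, ~ sum(.x == "homP2")),
    n = .data$homP1 + .data$het + .data$homP2
  ) |>
    dplyr::select(-"classes")
}

classify_offspring <- function(alleles, p1, p2) {
  if (is.null(alleles)) return("missing")
  if (length(alleles) >= 2L) return("het")
  a <- alleles[[1]]
  if (identical(sort(p1), a)) return("homP1")
  if (identical(sort(p2), a)) return("homP2")
  if (a %in% p1) "homP1" else "homP2"
}
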