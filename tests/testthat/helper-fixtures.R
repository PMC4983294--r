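# Shared fixture helpers.

# Catalog rows by name, preserving the requested order.
catalog_subset_pub <- function(names) {
  cat <- default_enzyme_catalog()
  cat[match(names, cat$name), ]
}

# Hand-built genotype fixture: 5 sites engineered so that two survive the
# filters and the other three each trip a distinct criterion.
make_gm_fixture <- function() {
  samples <- c("P1", "P2", sprintf("F2_%02d", 1:10))
  site <- function(seq_id, pos, alt, gts, dps = NULL, gqs = NULL) {
    tibble::tibble(
      seq_id = seq_id, pos = pos, ref = "A", alt = alt,
      sample_id = samples,
      role = c("parent1", "parent2", rep("offspring", 10)),
      gt = gts,
      dp = if (is.null(dps)) rep(30L, 12) else dps,
      gq = if (is.null(gqs)) rep(45L, 12) else gqs
    )
  }
  off_ok <- c(rep("0/0", 3), rep("0/1", 4), rep("1/1", 3))
  dplyr::bind_rows(
    site("chr1", 100L, "T", c("0/0", "1/1", off_ok)),                 # passes
    site("chr1", 200L, "T", c("0/0", "1/1", off_ok)),                 # passes
    site("chr1", 300L, "T", c("0/0", NA, off_ok)),                    # parent missing
    site("chr1", 400L, "T", c("0/0", "1/1", off_ok),
         dps = c(30L, 30L, rep(5L, 4), rep(30L, 6))),                 # 6 of 10 genotyped
    site("chr1", 500L, "T,G", c("0/0", "1/1",
                                c(rep("0/1", 9), "2/2")))             # foreign allele
  )
}
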