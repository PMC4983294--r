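enz_pair <- function(names = c("EcoRI", "MspI")) {
  dplyr::filter(default_enzyme_catalog(), name %in% names)
}

test_that("digestion produces cut-to-cut fragments with labelled boundaries", {
  g <- tibble::tibble(seq_id = "chr", sequence = "GAATTCAAAACCGGT")
  frags <- digest(g, enz_pair())
  expect_equal(frags$start, c(0L, 1L, 11L))
  expect_equal(frags$end, c(1L, 11L, 15L))
  expect_equal(frags$left_cutter, c("SEQ_END", "EcoRI", "MspI"))
  expect_equal(frags$right_cutter, c("EcoRI", "MspI", "SEQ_END"))
  expect_equal(frags$region_class, rep("genomic", 3))
})

test_that("a site-free sequence yields one terminal-bounded fragment", {
  g <- tibble::tibble(seq_id = "chr", sequence = strrep("ACAC", 25))
  frags <- digest(g, enz_pair())
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$start, 0L)
  expect_equal(frags$end, 100L)
  expect_equal(frags$left_cutter, "SEQ_END")
  expect_equal(nrow(drop_terminal_fragments(frags)), 0L)
})

test_that("fragments tile the sequence and concatenate back to the input", {
  set.seed(42)
  cat <- default_enzyme_catalog()
  for (rep in 1:8) {
    s <- random_dna(sample(500:8000, 1))
    enz <- cat[sample(nrow(cat), 3), ]
    g <- tibble::tibble(seq_id = "x", sequence = s)
    frags <- digest(g, enz, with_sequence = TRUE)
    expect_equal(sum(frags$length), nchar(s))
    expect_equal(paste(frags$sequence, collapse = ""), s)
    expect_true(all(frags$start < frags$end))
    expect_equal(frags$start[-1], frags$end[-nrow(frags)])
  }
})

test_that("digestion equals the naive string-splitting oracle", {
  set.seed(99)
  cat <- default_enzyme_catalog()
  for (rep in 1:10) {
    s <- random_dna(sample(1000:5000, 1))
    enz <- cat[sample(nrow(cat), sample(2:4, 1)), ]
    frags <- digest(tibble::tibble(seq_id = "x", sequence = s), enz)
    want <- oracle_digest(s, setNames(enz$site, enz$name))
    expect_equal(frags$start, want$start)
    expect_equal(frags$end, want$end)
  }
})

test_that("adding an enzyme never merges fragments or lengthens any fragment", {
  set.seed(5)
  s <- random_dna(6000)
  g <- tibble::tibble(seq_id = "x", sequence = s)
  two <- digest(g, enz_pair(c("EcoRI", "MspI")))
  three <- digest(g, enz_pair(c("EcoRI", "MspI", "MseI")))
  expect_gte(nrow(three), nrow(two))
  expect_lte(max(three$length), max(two$length))
  # the original cut set is preserved
  expect_true(all(two$start %in% c(0L, three$start)))
})

test_that("re-digesting fragments with the same enzymes is idempotent", {
  set.seed(13)
  s <- random_dna(6000)
  enz <- enz_pair(c("EcoRI", "MspI", "Sse9I"))
  frags <- digest(tibble::tibble(seq_id = "x", sequence = s), enz,
                  with_sequence = TRUE)
  redo <- digest(tibble::tibble(seq_id = as.character(seq_len(nrow(frags))),
                                sequence = frags$sequence), enz)
  # every fragment is internally cut-free, so it survives unchanged
  expect_equal(nrow(redo), nrow(frags))
  expect_equal(sort(redo$length), sort(frags$length))
})

test_that("size selection is inclusive on both bounds and order-preserving", {
  frags <- tibble::tibble(
    seq_id = "x", start = 0L, end = c(100L, 224L, 300L, 424L, 425L),
    length = c(100L, 224L, 300L, 424L, 425L),
    left_cutter = "EcoRI", right_cutter = "MspI", region_class = "genomic"
  )
  kept <- size_select(frags, c(224, 424))
  expect_equal(kept$length, c(224L, 300L, 424L))
  expect_equal(nrow(size_select(frags[0, ], c(224, 424))), 0L)
  expect_equal(size_select(frags, c(1, Inf)), frags)
  expect_error(size_select(frags, c(424, 224)), "min <= max")
})

test_that("fragments are classified by region and any rRNA overlap", {
  regions <- tibble::tibble(
    seq_id = c("chr1", "cp"),
    sequence = c(strrep("A", 600), strrep("A", 300)),
    region_class = c("genomic", "chloroplast")
  )
  rrna <- tibble::tibble(seq_id = "chr1", start = 250L, end = 500L)
  frags <- tibble::tibble(
    seq_id = c("chr1", "chr1", "cp"),
    start = c(100L, 0L, 10L), end = c(300L, 100L, 200L),
    length = c(200L, 100L, 190L),
    left_cutter = "EcoRI", right_cutter = "MspI"
  )
  out <- classify_fragments(frags, regions, rrna)
  # [100,300) overlaps [250,500); [0,100) touches but does not overlap
  expect_equal(out$region_class, c("rRNA", "genomic", "chloroplast"))
  bad <- dplyr::mutate(frags, seq_id = "nope")
  expect_error(classify_fragments(bad, regions, rrna), "absent")
})

test_that("end-composition filtering models ddRAD adapter requirements", {
  frags <- tibble::tibble(
    seq_id = "x", start = 0L, end = 10L, length = 10L,
    left_cutter = c("EcoRI", "MspI", "SEQ_END", "HindIII"),
    right_cutter = c("MspI", "MspI", "EcoRI", "EcoRI"),
    region_class = "genomic"
  )
  bc <- c("EcoRI", "HindIII"); un <- "MspI"
  expect_equal(filter_by_end_composition(frags, bc, un, "all"), frags)
  kept <- filter_by_end_composition(frags, bc, un, "one_rare_end")
  expect_equal(kept$left_cutter, c("EcoRI", "SEQ_END", "HindIII"))
  mixed <- filter_by_end_composition(frags, bc, un, "mixed_ends")
  expect_equal(mixed$left_cutter, "EcoRI")   # (EcoRI,MspI) only
  expect_error(filter_by_end_composition(frags, bc, un, "nope"))
})
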