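# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   left_join bind_rows n desc across row_number distinct if_else pull rename
#' @importFrom purrr map map_int map_chr map_dbl map_lgl map2 pmap imap walk
#' @importFrom stats pchisq t.test cor.test rpois rnorm runif rbinom sd setNames
#' @importFrom utils combn head
NULL

# IUPAC nucleotide codes mapped to the set of concrete bases each matches.
# A genome 'N' is deliberately absent from every set: an ambiguous genome
# base never supports a cut site.
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.iupac_raw <- lapply(.iupac_sets, function(x) charToRaw(paste(x, collapse = "")))

.iupac_chars <- names(.iupac_sets)

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every symbol under the IUPAC code (R<->Y, K<->M, B<->V,
#' D<->H; S, W and N are self-complementary) and reverses the string.
#'
#' @param x Character vector of uppercase IUPAC strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("GAATTC")  # palindromic site
#' revcomp("GANTC")
revcomp <- function(x) {
  flipped <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Round half away from zero (0.05 -> 0.1), the convention used for all
# percentages printed in reports; base round() would round to even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 0-based start positions where `site` (IUPAC) matches `seq_raw`
# (raw bytes of an uppercase sequence). Vectorized over positions.
match_site_starts <- function(seq_raw, site) {
  m <- nchar(site)
  L <- length(seq_raw)
  if (L < m || m == 0L) return(integer(0))
  site_chars <- strsplit(site, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    allowed <- .iupac_raw[[site_chars[[j]]]]
    ok <- ok & (seq_raw[j:(L - m + j)] %in% allowed)
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

# Does `sequence` (uppercase character scalar) contain a match of any of the
# IUPAC patterns (either strand handled by the caller via revcomp)?
contains_any_site <- function(seq_raw, patterns) {
  for (p in patterns) {
    if (length(match_site_starts(seq_raw, p)) > 0L) return(TRUE)
  }
  FALSE
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}
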