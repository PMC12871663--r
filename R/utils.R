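# Internal helpers shared across modules: IUPAC sets, reverse complement,
# argument checks. Sequences are plain uppercase character scalars; coordinates
# are 0-based half-open throughout the package.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B"
)

is_iupac <- function(x) {
  all(strsplit(toupper(x), "", fixed = TRUE)[[1]] %in% names(IUPAC_SETS))
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' Reverse-complement a nucleotide string
#'
#' IUPAC-aware reverse complement of a single sequence.
#'
#' @param x a nucleotide string (ACGTN + IUPAC ambiguity codes).
#' @return the reverse-complemented string.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  ch <- rev(seq_chars(x))
  out <- COMPLEMENT[ch]
  if (anyNA(out)) abort("sequence contains non-IUPAC characters")
  paste(out, collapse = "")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in [0, 1]", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(x < min) || any(x != floor(x))) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(x)
}

# a seed below 2^31 derived from a base seed and a stream offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}
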