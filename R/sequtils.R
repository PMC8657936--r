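#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Random DNA sequence
#'
#' Samples a sequence with a mildly AT-rich base composition (62% AT),
#' typical of grass plastomes.
#'
#' @param n Length in bp.
#' @param at Total A+T fraction (default 0.62).
#' @return A single uppercase character string.
#' @keywords internal
random_seq <- function(n, at = 0.62) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

subseq_str <- function(x, start, end) {
  if (end < start) return("")
  substr(x, start, end)
}

#' All overlapping k-mers of a sequence
#' @keywords internal
kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

# Maximal homopolymer run covering position `pos` (1-based).
# Returns list(start, end, base, len).
run_at <- function(seq, pos) {
  ch <- seq_chars(seq)
  b <- ch[pos]
  s <- pos
  while (s > 1 && ch[s - 1] == b) s <- s - 1
  e <- pos
  while (e < length(ch) && ch[e + 1] == b) e <- e + 1
  list(start = s, end = e, base = b, len = e - s + 1)
}

# TRUE if `region` contains an inverted repeat with stem >= k: a k-mer at
# position i whose reverse complement occurs at position j >= i + k (so the
# two arms do not overlap and could pair as a hairpin stem).
has_inverted_repeat <- function(region, k = 8) {
  km <- kmers(region, k)
  if (!length(km)) return(FALSE)
  rk <- revcomp(km)
  last <- tapply(seq_along(km), km, max)
  jmax <- unname(last[rk])
  any(!is.na(jmax) & jmax - seq_along(km) >= k)
}
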