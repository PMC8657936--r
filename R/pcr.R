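#' Define a PCR primer pair
#'
#' @param forward,reverse Primer sequences, 5' to 3' (>= 15 bp). The
#'   reverse primer binds the template as its reverse complement.
#' @param max_mismatch Mismatches tolerated per primer site (3' clamp
#'   excluded).
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly.
#' @return Object of class `PrimerPair`.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 0L,
                        three_prime_exact = 3L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nchar(forward) >= 15L, nchar(reverse) >= 15L,
            !grepl("[^ACGT]", forward), !grepl("[^ACGT]", reverse))
  p <- list(forward = forward, reverse = reverse,
            max_mismatch = as.integer(max_mismatch),
            three_prime_exact = as.integer(three_prime_exact))
  class(p) <- "PrimerPair"
  p
}

#' Find primer binding sites on a template
#'
#' Scans both orientations: forward sites are positions where the primer
#' matches the template 5'->3'; reverse-orientation sites are where its
#' reverse complement matches (the primer's 3' end pointing upstream). A
#' site requires <= `max_mismatch` mismatches overall and an exact match
#' over the primer's `three_prime_exact` terminal bases.
#'
#' @param template Template string (A/C/G/T).
#' @param primer Primer string, 5' to 3'.
#' @param max_mismatch Allowed mismatches.
#' @param three_prime_exact 3'-clamp length.
#' @return Data frame with columns start, end, orientation
#'   ("forward"/"reverse"), mismatches.
#' @export
find_sites <- function(template, primer, max_mismatch = 0L,
                       three_prime_exact = 3L) {
  template <- toupper(template)
  primer <- toupper(primer)
  L <- nchar(primer)
  tch <- seq_chars(template)
  n <- length(tch)
  scan <- function(pat, clamp_at_end) {
    if (n < L) return(list(starts = integer(0), mism = integer(0)))
    pch <- seq_chars(pat)
    starts <- seq_len(n - L + 1L)
    mism <- integer(length(starts))
    for (k in seq_len(L)) {
      mism <- mism + (tch[starts + k - 1L] != pch[k])
    }
    clamp_idx <- if (clamp_at_end) (L - three_prime_exact + 1L):L
                 else seq_len(three_prime_exact)
    clamp_ok <- rep(TRUE, length(starts))
    for (k in clamp_idx) {
      clamp_ok <- clamp_ok & (tch[starts + k - 1L] == pch[k])
    }
    list(starts = starts[mism <= max_mismatch & clamp_ok],
         mism = mism[mism <= max_mismatch & clamp_ok])
  }
  fwd <- scan(primer, clamp_at_end = TRUE)
  # reverse orientation: the primer's RC lies on the template; the primer's
  # 3' end corresponds to the first base of the RC match
  rev <- scan(revcomp(primer), clamp_at_end = FALSE)
  out <- rbind(
    if (length(fwd$starts)) data.frame(start = fwd$starts,
                                       end = fwd$starts + L - 1L,
                                       orientation = "forward",
                                       mismatches = fwd$mism,
                                       stringsAsFactors = FALSE),
    if (length(rev$starts)) data.frame(start = rev$starts,
                                       end = rev$starts + L - 1L,
                                       orientation = "reverse",
                                       mismatches = rev$mism,
                                       stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      orientation = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$orientation), , drop = FALSE]
}

#' Predict PCR products for a primer pair on a template
#'
#' Every combination of a forward-primer site and a downstream
#' reverse-orientation site within `max_product_len` yields one product;
#' product lengths include both primer footprints.
#'
#' @param template Template string.
#' @param pair A [primer_pair()].
#' @param max_product_len Longest product considered (bp).
#' @param template_name Label stored on the result.
#' @return An `AmpliconSet`: list with `template` and `products`
#'   (data frame start, end, length).
#' @export
predict_amplicons <- function(template, pair, max_product_len = 3000L,
                              template_name = "template") {
  stopifnot(inherits(pair, "PrimerPair"))
  f <- find_sites(template, pair$forward, pair$max_mismatch,
                  pair$three_prime_exact)
  f <- f[f$orientation == "forward", , drop = FALSE]
  r <- find_sites(template, pair$reverse, pair$max_mismatch,
                  pair$three_prime_exact)
  r <- r[r$orientation == "reverse", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      if (r$start[j] <= f$start[i]) next
      len <- r$end[j] - f$start[i] + 1L
      if (len > max_product_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = f$start[i], end = r$end[j], length = len)
    }
  }
  products <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), length = integer())
  products <- products[order(products$start, products$length), ,
                       drop = FALSE]
  rownames(products) <- NULL
  out <- list(template = template_name, products = products)
  class(out) <- "AmpliconSet"
  out
}

#' Presence/absence band table across samples
#'
#' Rows are samples, columns are distinct product lengths in bp; product
#' lengths within `gel_resolution` bp of one another are merged into one
#' band, emulating agarose-gel resolution.
#'
#' @param samples Named list; each element is a character vector of
#'   template sequences (alleles) for one sample.
#' @param pair A [primer_pair()].
#' @param max_product_len Longest product considered.
#' @param gel_resolution Merge radius in bp (default 2).
#' @return Logical matrix, samples x band lengths (columns named by the
#'   smallest length in each merged band, increasing).
#' @export
band_table <- function(samples, pair, max_product_len = 3000L,
                       gel_resolution = 2L) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  hits <- lapply(samples, function(templates) {
    sort(unique(unlist(lapply(templates, function(tp) {
      predict_amplicons(tp, pair, max_product_len)$products$length
    }))))
  })
  all_len <- sort(unique(unlist(hits)))
  if (!length(all_len)) {
    return(matrix(logical(0), nrow = length(samples), ncol = 0L,
                  dimnames = list(names(samples), NULL)))
  }
  band <- cumsum(c(TRUE, diff(all_len) > gel_resolution))
  band_name <- vapply(split(all_len, band), min, numeric(1))
  tab <- matrix(FALSE, length(samples), length(band_name),
                dimnames = list(names(samples),
                                as.character(band_name)))
  for (s in names(samples)) {
    b <- unique(band[match(hits[[s]], all_len)])
    tab[s, b] <- TRUE
  }
  tab
}

#' Write a band table as TSV
#' @param tab Matrix from [band_table()].
#' @param path Output path.
#' @export
write_band_table <- function(tab, path) {
  df <- data.frame(sample = rownames(tab),
                   ifelse(tab, "+", ""), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
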