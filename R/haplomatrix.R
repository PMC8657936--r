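#' Variant matrix container
#'
#' Samples-by-sites allele table with per-site context labels, the
#' multi-sample join of per-sample variant calls on reference coordinates.
#'
#' @param sites Data frame with columns ref_pos, locus, aa_label,
#'   ref_allele, kind.
#' @param samples Character vector of sample names.
#' @param alleles Character matrix, sites x samples.
#' @return Object of class `VariantMatrix`.
#' @export
variant_matrix <- function(sites, samples, alleles) {
  stopifnot(nrow(sites) == nrow(alleles), length(samples) == ncol(alleles))
  colnames(alleles) <- samples
  m <- list(sites = sites, samples = samples, alleles = alleles)
  class(m) <- "VariantMatrix"
  m
}

#' @export
print.VariantMatrix <- function(x, ...) {
  cat(sprintf("VariantMatrix: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Join per-sample variant calls into a matrix
#'
#' Sites are the union of variant positions (keyed by position, kind and
#' alleles' reference side); samples lacking a variant at a site carry the
#' reference state. All variant sets must be called against the same
#' reference: conflicting reference alleles at one position are an error.
#'
#' @param variant_sets Named list of variant data frames (one per sample,
#'   as from [classify_all()]).
#' @return A [variant_matrix()].
#' @export
build_matrix <- function(variant_sets) {
  samples <- names(variant_sets)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("variant_sets must be a named list (one entry per sample)")
  }
  all <- do.call(rbind, lapply(samples, function(s) {
    v <- variant_sets[[s]]
    if (is.null(v) || nrow(v) == 0L) return(NULL)
    v$sample <- s
    v
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(variant_matrix(
      data.frame(ref_pos = integer(), locus = character(),
                 aa_label = character(), ref_allele = character(),
                 kind = character(), stringsAsFactors = FALSE),
      samples, matrix(character(0), 0L, length(samples))))
  }
  conflict <- tapply(all$ref_allele, all$ref_pos,
                     function(x) length(unique(x)) > 1L)
  if (any(conflict)) {
    stop("conflicting reference alleles at position(s): ",
         paste(names(conflict)[conflict], collapse = ", "))
  }
  key <- paste(all$ref_pos, all$kind, all$ref_allele, sep = "\r")
  ord <- order(all$ref_pos)
  ukey <- unique(key[ord])
  first <- all[match(ukey, key), , drop = FALSE]
  sites <- data.frame(ref_pos = first$ref_pos, locus = first$locus,
                      aa_label = first$aa_label,
                      ref_allele = first$ref_allele, kind = first$kind,
                      stringsAsFactors = FALSE)
  alleles <- matrix(rep(sites$ref_allele, length(samples)),
                    nrow = nrow(sites), ncol = length(samples))
  colnames(alleles) <- samples
  rownames(alleles) <- as.character(sites$ref_pos)
  for (i in seq_len(nrow(all))) {
    r <- match(key[i], ukey)
    alleles[r, all$sample[i]] <- all$alt_allele[i]
  }
  variant_matrix(sites, samples, alleles)
}

#' Tally matrix sites by locus context
#'
#' Counts are over sites, not sample occurrences; synonymous sites are a
#' subset of the genic count.
#'
#' @param matrix A `VariantMatrix`.
#' @return Named list: intergenic, intron, genic, synonymous.
#' @export
tally_by_context <- function(matrix) {
  s <- matrix$sites
  if (nrow(s) == 0L) {
    return(list(intergenic = 0L, intron = 0L, genic = 0L, synonymous = 0L))
  }
  if (any(is.na(s$locus) | !nzchar(s$locus))) {
    stop("site(s) with missing locus label at position(s): ",
         paste(s$ref_pos[is.na(s$locus) | !nzchar(s$locus)], collapse = ", "))
  }
  genic <- startsWith(s$locus, "Gene")
  intron <- startsWith(s$locus, "Intron")
  list(intergenic = sum(!genic & !intron),
       intron = sum(intron),
       genic = sum(genic),
       synonymous = sum(genic & s$aa_label == "Syn"))
}

#' Pairwise Hamming distances between samples
#'
#' d(i, j) = number of sites at which the two samples carry different
#' states.
#'
#' @param matrix A `VariantMatrix`.
#' @param snp_only Count only SNP sites (default TRUE; indel and inversion
#'   sites are included when FALSE).
#' @return Symmetric numeric matrix with sample dimnames.
#' @export
hamming_distances <- function(matrix, snp_only = TRUE) {
  a <- matrix$alleles
  if (snp_only && nrow(matrix$sites)) {
    a <- a[matrix$sites$kind == "snp", , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("no sites to compare")
  n <- length(matrix$samples)
  d <- base::matrix(0, n, n,
                    dimnames = list(matrix$samples, matrix$samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(a[, i] != a[, j])
    }
  }
  d
}

#' Partition samples into haplotype groups
#'
#' Complete-linkage hierarchical clustering on pairwise Hamming distances,
#' cut into `n_groups` groups. Groups are returned sorted by decreasing
#' size, ties broken by the lexicographically smallest member, and the
#' result is invariant (up to labels) under sample-order permutation.
#'
#' @param matrix A `VariantMatrix`.
#' @param n_groups Number of groups (<= sample count).
#' @param snp_only Passed to [hamming_distances()].
#' @return List of character vectors of sample names.
#' @export
partition_samples <- function(matrix, n_groups = 2L, snp_only = TRUE) {
  stopifnot(n_groups <= length(matrix$samples))
  # lexicographic sample order makes hclust tie-breaks order-independent
  ord <- order(matrix$samples)
  perm <- variant_matrix(matrix$sites, matrix$samples[ord],
                         matrix$alleles[, ord, drop = FALSE])
  d <- stats::as.dist(hamming_distances(perm, snp_only = snp_only))
  if (n_groups == 1L) {
    groups <- list(perm$samples)
  } else {
    hc <- stats::hclust(d, method = "complete")
    cl <- stats::cutree(hc, k = n_groups)
    groups <- split(names(cl), cl)
  }
  groups <- lapply(groups, sort)
  first <- vapply(groups, `[`, character(1), 1L)
  groups <- groups[order(-vapply(groups, length, integer(1)), first)]
  names(groups) <- NULL
  groups
}

#' Write a variant matrix as TSV (sites as rows, samples as columns)
#' @param matrix A `VariantMatrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- cbind(matrix$sites, as.data.frame(matrix$alleles,
                                          stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
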