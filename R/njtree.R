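#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with deterministic tie-breaking:
#' at each agglomeration the pair with the smallest Q value is joined,
#' ties resolved by the lexicographically smallest (sorted) name pair.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sibling branch, so path lengths within the joined cherry are
#' preserved.
#'
#' @param d Symmetric numeric distance matrix with sample dimnames
#'   (>= 3 samples; negative entries are an error).
#' @return An unrooted \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 samples")
  if (any(d < 0)) stop("negative distances are not allowed")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node is a newick fragment
  frag <- labels
  repeat {
    m <- nrow(d)
    if (m == 2L) break
    tot <- rowSums(d)
    q <- (m - 2) * d - outer(tot, tot, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      paste(sort(c(frag[ij[1]], frag[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- 0.5 * d[i, j] + (tot[i] - tot[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
    d <- d2
  }
  # join the last two nodes by a single edge
  nwk <- if (startsWith(frag[2L], "(")) {
    sub("\\)$", sprintf(",%s:%.15g)", frag[1L], max(d[1L, 2L], 0)),
        frag[2L])
  } else if (startsWith(frag[1L], "(")) {
    sub("\\)$", sprintf(",%s:%.15g)", frag[2L], max(d[1L, 2L], 0)),
        frag[1L])
  } else {
    sprintf("(%s:%.15g,%s:%.15g)", frag[1L], d[1L, 2L] / 2,
            frag[2L], d[1L, 2L] / 2)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering rendered as a rooted ultrametric
#' tree; provided for comparison with [neighbor_joining()].
#'
#' @param d Symmetric numeric distance matrix with dimnames.
#' @return An \pkg{ape} `phylo` tree.
#' @export
upgma_tree <- function(d) {
  hc <- stats::hclust(stats::as.dist(as.matrix(d)), method = "average")
  ape::as.phylo(hc)
}

#' Distance tree from a variant matrix
#'
#' @param matrix A `VariantMatrix`.
#' @param method "nj" (default) or "upgma".
#' @param snp_only Passed to [hamming_distances()].
#' @return An \pkg{ape} `phylo` tree.
#' @export
build_tree <- function(matrix, method = c("nj", "upgma"), snp_only = TRUE) {
  method <- match.arg(method)
  d <- hamming_distances(matrix, snp_only = snp_only)
  if (method == "nj") neighbor_joining(d) else upgma_tree(d)
}

#' Does an unrooted tree contain a given leaf bipartition?
#'
#' @param tree An \pkg{ape} `phylo` tree.
#' @param tips Character vector naming one side of the split.
#' @return TRUE if some edge of the tree separates `tips` from the rest.
#' @export
has_bipartition <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  other <- setdiff(tree$tip.label, tips)
  if (!length(other)) return(FALSE)
  parts <- ape::prop.part(tree)
  lab <- attr(parts, "labels")
  side <- sort(match(tips, lab))
  comp <- sort(match(other, lab))
  any(vapply(parts, function(p) {
    identical(sort(p), side) || identical(sort(p), comp)
  }, logical(1)))
}

#' Patristic (path-length) distances between the leaves of a tree
#'
#' @param tree An \pkg{ape} `phylo` tree.
#' @return Symmetric matrix of summed branch lengths, leaf dimnames.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
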