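# Independent oracles and small shared fixtures for the test suite.

# Comparable identity key for variant calls (kind + canonical coordinates
# and alleles).
variant_key <- function(v) {
  paste(v$kind, v$ref_pos, v$ref_allele, v$alt_allele)
}

# Brute-force hairpin decomposition: try every stem length directly.
oracle_hairpin <- function(window) {
  len <- nchar(window)
  best <- 0L
  for (s in seq_len(len %/% 2L)) {
    if (substr(window, 1L, s) ==
        revcomp(substr(window, len - s + 1L, len))) best <- s
  }
  list(stem_len = best, loop_len = len - 2L * best)
}

# Quadratic affine-gap DP written independently of the package: plain
# three-state recursion over full matrices, no traceback tricks.
oracle_affine_score <- function(r, q, match = 1, mismatch = -2,
                                gap_open = -4, gap_extend = -1) {
  n <- nchar(r); m <- nchar(q)
  rc <- strsplit(r, "")[[1]]; qc <- strsplit(q, "")[[1]]
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (rc[i] == qc[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Unique-k-mer anchor seeds by direct scan (no diagonal merging, no
# extension): returns (ref_pos, qry_pos) pairs of shared unique k-mers.
oracle_unique_seeds <- function(ref, qry, k) {
  rk <- substring(ref, 1:(nchar(ref) - k + 1), k:nchar(ref))
  qk <- substring(qry, 1:(nchar(qry) - k + 1), k:nchar(qry))
  out <- NULL
  for (i in seq_along(rk)) {
    if (sum(rk == rk[i]) != 1L) next
    hits <- which(qk == rk[i])
    if (length(hits) != 1L) next
    out <- rbind(out, c(i, hits))
  }
  out
}

# Exhaustive maximum-weight co-linear chain over <= 10 anchors.
oracle_best_chain <- function(anchors) {
  n <- nrow(anchors)
  best_w <- -1
  best_set <- integer(0)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1) {
      rs <- anchors$ref_start[sel]; qs <- anchors$qry_start[sel]
      o <- order(rs)
      if (any(diff(rs[o]) <= 0) || any(diff(qs[o]) <= 0)) next
    }
    w <- sum(anchors$length[sel])
    if (w > best_w) { best_w <- w; best_set <- sel }
  }
  list(weight = best_w, set = sort(best_set))
}

# Edit distance implied by an alignment map: substitutions plus inserted
# plus deleted bases, block-wise.
implied_edit_distance <- function(map) {
  b <- map$blocks[map$blocks$kind == "divergent", , drop = FALSE]
  if (nrow(b) == 0L) return(0L)
  sum(pmax(b$ref_end - b$ref_start + 1L, b$qry_end - b$qry_start + 1L))
}

# One cached 30 kb study-condition reference shared by slow tests.
shared_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference(30000, n_genes = 10, homopolymer_runs = 5,
                               palindromes = 3, seed = 401)
    }
    cache
  }
})
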