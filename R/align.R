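#' Alignment parameters
#'
#' Defaults suit near-identical plastomes: long unique anchors dominate and
#' exact scores only matter in the short interstices between them.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param k Anchor seed size in bp (>= 8).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param max_gap_len Maximum interstice length fed to the gap aligner.
#' @param circular Rotate the query to the reference linearization first.
#' @return List of parameters.
#' @export
align_params <- function(k = 21L, match = 1, mismatch = -2, gap_open = -4,
                         gap_extend = -1, max_gap_len = 20000L,
                         circular = FALSE) {
  stopifnot(k >= 8L)
  list(k = as.integer(k), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       max_gap_len = as.integer(max_gap_len), circular = circular)
}

#' Rotate a circular query onto the reference linearization
#'
#' Finds the first reference k-mer that occurs in the (circularized) query
#' and rotates the query so that the occurrence with the longest exact
#' extension against the reference lands at the corresponding position;
#' already co-linear inputs are returned unchanged.
#'
#' @param ref,qry Sequence strings (each >= 2k bp).
#' @param k Seed size.
#' @return The rotated query string.
#' @export
rotate_circular <- function(ref, qry, k = 21L) {
  n <- nchar(qry)
  stopifnot(nchar(ref) >= 2L * k, n >= 2L * k)
  dq <- paste0(qry, substr(qry, 1L, k - 1L))
  qk <- kmers(dq, k)                     # k-mers at circular positions 1..n
  rk <- kmers(ref, k)
  rpos <- which(!is.na(match(rk, qk)))[1L]
  if (is.na(rpos)) stop("sequences too divergent: no shared ", k, "-mer")
  hits <- which(qk == rk[rpos])
  ext <- vapply(hits, function(h) {
    rot <- rotate_string(qry, h - 1L)
    len <- 0L
    limit <- min(nchar(ref) - rpos + 1L, n)
    while (len < limit &&
           substr(rot, len + 1L, len + 1L) ==
           substr(ref, rpos + len, rpos + len)) len <- len + 1L
    len
  }, integer(1))
  best <- hits[which.max(ext)]
  # rotate so this occurrence sits at reference position rpos
  rotate_string(qry, (best - rpos) %% n)
}

rotate_string <- function(x, shift) {
  n <- nchar(x)
  shift <- shift %% n
  if (shift == 0L) return(x)
  paste0(substr(x, shift + 1L, n), substr(x, 1L, shift))
}

#' Find unique-seed exact-match anchors
#'
#' Maximal exact matches whose seed k-mer occurs exactly once in both
#' sequences, merged along diagonals and extended outward to mismatch.
#'
#' @param ref,qry Sequence strings.
#' @param k Seed size (>= 8).
#' @return Data frame with columns ref_start, qry_start, length, sorted by
#'   ref_start (possibly empty).
#' @export
find_anchors <- function(ref, qry, k = 21L) {
  stopifnot(k >= 8L)
  empty <- data.frame(ref_start = integer(), qry_start = integer(),
                      length = integer())
  rk <- kmers(ref, k)
  qk <- kmers(qry, k)
  if (!length(rk) || !length(qk)) return(empty)
  ru <- !(duplicated(rk) | duplicated(rk, fromLast = TRUE))
  qu <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))
  qpos <- match(rk, qk)
  valid <- which(ru & !is.na(qpos) & qu[ifelse(is.na(qpos), 1L, qpos)])
  if (!length(valid)) return(empty)
  rp <- valid
  qp <- qpos[valid]
  # merge consecutive seeds on one diagonal
  brk <- c(TRUE, diff(rp) != 1L | diff(qp) != 1L)
  grp <- cumsum(brk)
  rs <- tapply(rp, grp, min)
  qs <- tapply(qp, grp, min)
  len <- tapply(rp, grp, length) + k - 1L
  a <- data.frame(ref_start = as.integer(rs), qry_start = as.integer(qs),
                  length = as.integer(len))
  # maximal extension
  nr <- nchar(ref); nq <- nchar(qry)
  for (i in seq_len(nrow(a))) {
    while (a$ref_start[i] > 1L && a$qry_start[i] > 1L &&
           substr(ref, a$ref_start[i] - 1L, a$ref_start[i] - 1L) ==
           substr(qry, a$qry_start[i] - 1L, a$qry_start[i] - 1L)) {
      a$ref_start[i] <- a$ref_start[i] - 1L
      a$qry_start[i] <- a$qry_start[i] - 1L
      a$length[i] <- a$length[i] + 1L
    }
    while (a$ref_start[i] + a$length[i] <= nr &&
           a$qry_start[i] + a$length[i] <= nq &&
           substr(ref, a$ref_start[i] + a$length[i],
                  a$ref_start[i] + a$length[i]) ==
           substr(qry, a$qry_start[i] + a$length[i],
                  a$qry_start[i] + a$length[i])) {
      a$length[i] <- a$length[i] + 1L
    }
  }
  a <- unique(a)
  a <- a[order(a$ref_start, a$qry_start), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Select the maximum-weight co-linear anchor chain
#'
#' Weight is anchor length; the chain must be strictly increasing in both
#' reference and query start coordinates. Ties resolve to the earliest
#' ref_start.
#'
#' @param anchors Anchor data frame sorted by ref_start.
#' @return Subset of `anchors` forming the chain, in order.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(anchors)
  w <- as.numeric(anchors$length)
  best <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (anchors$ref_start[j] < anchors$ref_start[i] &&
          anchors$qry_start[j] < anchors$qry_start[i]) {
        cand <- best[j] + w[i]
        if (cand > best[i]) {
          best[i] <- cand
          prev[i] <- j
        }
      }
    }
  }
  end <- which.max(best)
  path <- integer(0)
  while (!is.na(end)) {
    path <- c(end, path)
    end <- prev[end]
  }
  out <- anchors[path, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global alignment of one interstice with affine gaps
#'
#' Needleman-Wunsch with affine gap penalties and deterministic
#' tie-breaking: a diagonal (match/mismatch) step is preferred over a gap,
#' and a gap in the query over a gap in the reference.
#'
#' @param ref_segment,qry_segment Segment strings (either may be empty).
#' @param params [align_params()].
#' @return List with `score` and `edits`, a character vector over
#'   M (match), X (mismatch), I (insertion: base only in query),
#'   D (deletion: base only in reference).
#' @export
align_gap <- function(ref_segment, qry_segment, params = align_params()) {
  n <- nchar(ref_segment)
  m <- nchar(qry_segment)
  if (n > params$max_gap_len || m > params$max_gap_len) {
    stop("interstice of ", max(n, m), " bp exceeds max_gap_len (",
         params$max_gap_len, "); increase k or max_gap_len")
  }
  if (n == 0L && m == 0L) return(list(score = 0, edits = character(0)))
  if (n == 0L) {
    return(list(score = params$gap_open + m * params$gap_extend,
                edits = rep("I", m)))
  }
  if (m == 0L) {
    return(list(score = params$gap_open + n * params$gap_extend,
                edits = rep("D", n)))
  }
  rs <- seq_chars(ref_segment)
  qs <- seq_chars(qry_segment)
  NEG <- -1e18
  go <- params$gap_open; ge <- params$gap_extend
  # state 1 = diagonal, 2 = gap in query (D), 3 = gap in ref (I)
  M <- matrix(NEG, n + 1L, m + 1L)
  GQ <- matrix(NEG, n + 1L, m + 1L)
  GR <- matrix(NEG, n + 1L, m + 1L)
  tM <- matrix(0L, n + 1L, m + 1L)
  tGQ <- matrix(0L, n + 1L, m + 1L)
  tGR <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) {
    GQ[i, 1L] <- go + (i - 1L) * ge
    tGQ[i, 1L] <- 2L
  }
  for (j in 2L:(m + 1L)) {
    GR[1L, j] <- go + (j - 1L) * ge
    tGR[1L, j] <- 3L
  }
  pick <- function(vals) {
    # preference on ties: diagonal, then gap-in-query, then gap-in-ref
    which.max(vals + c(2e-9, 1e-9, 0))
  }
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (rs[i - 1L] == qs[j - 1L]) params$match else params$mismatch
      v <- c(M[i - 1L, j - 1L], GQ[i - 1L, j - 1L], GR[i - 1L, j - 1L])
      b <- pick(v)
      M[i, j] <- v[b] + s
      tM[i, j] <- b
      v <- c(M[i - 1L, j] + go + ge, GQ[i - 1L, j] + ge,
             GR[i - 1L, j] + go + ge)
      b <- pick(v)
      GQ[i, j] <- v[b]
      tGQ[i, j] <- b
      v <- c(M[i, j - 1L] + go + ge, GQ[i, j - 1L] + go + ge,
             GR[i, j - 1L] + ge)
      b <- pick(v)
      GR[i, j] <- v[b]
      tGR[i, j] <- b
    }
  }
  fin <- c(M[n + 1L, m + 1L], GQ[n + 1L, m + 1L], GR[n + 1L, m + 1L])
  state <- pick(fin)
  score <- fin[state]
  i <- n + 1L; j <- m + 1L
  edits <- character(0)
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      op <- if (rs[i - 1L] == qs[j - 1L]) "M" else "X"
      nxt <- tM[i, j]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      op <- "D"
      nxt <- tGQ[i, j]
      i <- i - 1L
    } else {
      op <- "I"
      nxt <- tGR[i, j]
      j <- j - 1L
    }
    edits <- c(op, edits)
    state <- if (nxt == 0L) 1L else nxt
  }
  list(score = score, edits = edits)
}

#' Whole-genome alignment of two near-identical plastomes
#'
#' Anchors on unique k-mer seeds, chains them co-linearly, aligns the
#' interstices with affine gaps, and tiles both sequences into match and
#' divergent blocks. Divergent blocks are maximal runs of non-match
#' columns.
#'
#' @param ref,qry Sequence strings (or [annotated_genome()] for `ref`).
#' @param params [align_params()]; set `circular = TRUE` to rotate the
#'   query onto the reference linearization first.
#' @return An `AlignmentMap`: list with `blocks` (ref_start, ref_end,
#'   qry_start, qry_end, kind), `identity`, and `qry` (the possibly
#'   rotated query used).
#' @export
whole_genome_align <- function(ref, qry, params = align_params()) {
  if (inherits(ref, "AnnotatedGenome")) ref <- ref$seq
  stopifnot(nchar(ref) >= 2L * params$k, nchar(qry) >= 2L * params$k)
  if (params$circular) qry <- rotate_circular(ref, qry, params$k)
  anchors <- chain_anchors(find_anchors(ref, qry, params$k))
  if (nrow(anchors) == 0L) {
    stop("sequences too divergent: no unique shared ", params$k, "-mer")
  }
  anchors <- trim_anchor_overlaps(anchors)

  ops <- character(0)
  rpos <- 1L; qpos <- 1L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    g <- align_gap(subseq_str(ref, rpos, a$ref_start - 1L),
                   subseq_str(qry, qpos, a$qry_start - 1L), params)
    ops <- c(ops, g$edits, rep("M", a$length))
    rpos <- a$ref_start + a$length
    qpos <- a$qry_start + a$length
  }
  g <- align_gap(subseq_str(ref, rpos, nchar(ref)),
                 subseq_str(qry, qpos, nchar(qry)), params)
  ops <- c(ops, g$edits)

  blocks <- ops_to_blocks(ops)
  map <- list(blocks = blocks,
              identity = mean(ops == "M"),
              qry = qry)
  class(map) <- "AlignmentMap"
  map
}

# After chaining, maximal extension can make neighbouring anchors overlap;
# trim the head of the later anchor (exact matches stay exact under
# trimming).
trim_anchor_overlaps <- function(anchors) {
  keep <- logical(nrow(anchors))
  last <- NULL
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    if (!is.null(last)) {
      delta <- max(last$ref_start + last$length - a$ref_start,
                   last$qry_start + last$length - a$qry_start, 0L)
      a$ref_start <- a$ref_start + delta
      a$qry_start <- a$qry_start + delta
      a$length <- a$length - delta
      if (a$length <= 0L) next
    }
    anchors[i, ] <- a
    keep[i] <- TRUE
    last <- a
  }
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Collapse a column-level edit string into tiling match/divergent blocks.
ops_to_blocks <- function(ops) {
  if (!length(ops)) {
    return(data.frame(ref_start = integer(), ref_end = integer(),
                      qry_start = integer(), qry_end = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  is_match <- ops == "M"
  grp <- cumsum(c(TRUE, is_match[-1L] != is_match[-length(ops)]))
  rconsume <- ops %in% c("M", "X", "D")
  qconsume <- ops %in% c("M", "X", "I")
  rpos <- cumsum(rconsume)
  qpos <- cumsum(qconsume)
  idx <- split(seq_along(ops), grp)
  rows <- lapply(idx, function(ii) {
    first <- ii[1L]; lasti <- ii[length(ii)]
    rs <- if (first == 1L) 1L else rpos[first - 1L] + 1L
    qs <- if (first == 1L) 1L else qpos[first - 1L] + 1L
    data.frame(ref_start = rs, ref_end = rpos[lasti],
               qry_start = qs, qry_end = qpos[lasti],
               kind = if (is_match[first]) "match" else "divergent",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.AlignmentMap <- function(x, ...) {
  cat(sprintf("AlignmentMap: %d blocks (%d divergent), identity %.4f\n",
              nrow(x$blocks), sum(x$blocks$kind == "divergent"),
              x$identity))
  invisible(x)
}

#' Reconstruct the query from an alignment map
#'
#' @param map An `AlignmentMap`.
#' @return The query string implied by concatenating query spans.
#' @export
map_query <- function(map) {
  b <- map$blocks
  paste0(vapply(seq_len(nrow(b)), function(i) {
    subseq_str(map$qry, b$qry_start[i], b$qry_end[i])
  }, character(1)), collapse = "")
}

#' Write alignment blocks as TSV
#' @param map An `AlignmentMap`.
#' @param path Output path.
#' @export
write_alignment_blocks <- function(map, path) {
  utils::write.table(map$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
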