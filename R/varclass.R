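variant_record <- function(sample, kind, ref_pos, ref_allele, alt_allele,
                           locus = "", aa_label = "none",
                           stem_len = NA_integer_, loop_len = NA_integer_,
                           flag = "") {
  data.frame(sample = sample, kind = kind, ref_pos = as.integer(ref_pos),
             ref_allele = ref_allele, alt_allele = alt_allele,
             locus = locus, aa_label = aa_label,
             stem_len = as.integer(stem_len),
             loop_len = as.integer(loop_len), flag = flag,
             stringsAsFactors = FALSE)
}

#' Stem-loop decomposition of a sequence window
#'
#' The stem length is the largest `s` such that the window's first `s`
#' bases equal the reverse complement of its last `s` bases (with
#' `2s <= window length`); the loop is what remains, so
#' `2 * stem + loop = window length` always.
#'
#' @param window Non-empty A/C/G/T string.
#' @return List with `stem_len` and `loop_len` (bp).
#' @export
#' @examples
#' characterize_hairpin("ACGT")  # stem 2, loop 0
characterize_hairpin <- function(window) {
  stopifnot(is.character(window), length(window) == 1L, nchar(window) > 0L)
  ch <- seq_chars(window)
  len <- length(ch)
  half <- len %/% 2L
  if (half == 0L) return(list(stem_len = 0L, loop_len = len))
  ok <- ch[1:half] == chartr("ACGTN", "TGCAN", ch[len:(len - half + 1L)])
  stem <- if (all(ok)) half else which(!ok)[1L] - 1L
  list(stem_len = as.integer(stem), loop_len = as.integer(len - 2L * stem))
}

#' Left-normalize an insertion or deletion
#'
#' Shifts an indel to its leftmost equivalent placement so calls in
#' repetitive context (homopolymer runs, tandem motifs) are canonical.
#' Insertions are anchored to the reference base they follow.
#'
#' @param ref Reference string.
#' @param pos For `ins`: the base the insertion follows. For `del`: the
#'   first deleted base.
#' @param allele Inserted or deleted sequence.
#' @param direction `"ins"` or `"del"`.
#' @return List with normalized `pos` and `allele`.
#' @export
left_normalize_indel <- function(ref, pos, allele, direction = c("ins", "del")) {
  direction <- match.arg(direction)
  L <- nchar(allele)
  stopifnot(L > 0L)
  if (direction == "ins") {
    while (pos >= 1L && substr(ref, pos, pos) == substr(allele, L, L)) {
      allele <- paste0(substr(ref, pos, pos), substr(allele, 1L, L - 1L))
      pos <- pos - 1L
    }
  } else {
    if (substr(ref, pos, pos + L - 1L) != allele) {
      stop("deletion allele does not match reference at ", pos)
    }
    while (pos > 1L &&
           substr(ref, pos - 1L, pos - 1L) ==
           substr(ref, pos + L - 1L, pos + L - 1L)) {
      pos <- pos - 1L
    }
    allele <- substr(ref, pos, pos + L - 1L)
  }
  list(pos = as.integer(pos), allele = allele)
}

# Pull the inserted (ref span empty) or deleted (qry span empty) bases of a
# pure-indel divergent block. Returns NULL for other block shapes.
block_indel <- function(ref, qry, block) {
  rl <- block$ref_end - block$ref_start + 1L
  ql <- block$qry_end - block$qry_start + 1L
  if (rl == 0L && ql > 0L) {
    list(direction = "ins", anchor = block$ref_end,
         allele = substr(qry, block$qry_start, block$qry_end))
  } else if (ql == 0L && rl > 0L) {
    list(direction = "del", anchor = block$ref_start,
         allele = substr(ref, block$ref_start, block$ref_end))
  } else {
    NULL
  }
}

#' Call a homopolymer run-length change
#'
#' If a pure insertion or deletion consists of one repeated base and lies
#' wholly within a reference mononucleotide run of length >= `min_run`,
#' it is reported in run notation (e.g. "15T" -> "18T") at the run start.
#'
#' @param ref,qry Sequence strings.
#' @param block One divergent block row of an `AlignmentMap`.
#' @param min_run Minimum reference run length (default 5).
#' @param sample_name Sample label.
#' @return One-row variant data frame, or NULL if the rule does not apply.
#' @export
call_homopolymer <- function(ref, qry, block, min_run = 5L,
                             sample_name = "query") {
  ind <- block_indel(ref, qry, block)
  if (is.null(ind)) return(NULL)
  ch <- unique(seq_chars(ind$allele))
  if (length(ch) != 1L) return(NULL)
  nrm <- left_normalize_indel(ref, ind$anchor, ind$allele, ind$direction)
  L <- nchar(nrm$allele)
  if (ind$direction == "ins") {
    at <- nrm$pos + 1L
    if (at > nchar(ref) || substr(ref, at, at) != ch) return(NULL)
    r <- run_at(ref, at)
    if (r$len < min_run) return(NULL)
    variant_record(sample_name, "homopolymer", r$start,
                   paste0(r$len, r$base), paste0(r$len + L, r$base))
  } else {
    r <- run_at(ref, nrm$pos)
    if (r$base != ch || r$len < min_run) return(NULL)
    if (nrm$pos + L - 1L > r$end) return(NULL)
    variant_record(sample_name, "homopolymer", r$start,
                   paste0(r$len, r$base), paste0(r$len - L, r$base))
  }
}

#' Call a tandem duplication
#'
#' A pure insertion whose (left-normalized) payload equals the immediately
#' adjacent reference segment on either side is reported as a duplication.
#' Mononucleotide payloads are excluded: run-length changes belong to the
#' homopolymer caller and its run notation.
#'
#' @inheritParams call_homopolymer
#' @return One-row variant data frame, or NULL.
#' @export
call_duplication <- function(ref, qry, block, sample_name = "query") {
  ind <- block_indel(ref, qry, block)
  if (is.null(ind) || ind$direction != "ins") return(NULL)
  if (length(unique(seq_chars(ind$allele))) < 2L) return(NULL)
  nrm <- left_normalize_indel(ref, ind$anchor, ind$allele, "ins")
  p <- nrm$pos
  L <- nchar(nrm$allele)
  after <- subseq_str(ref, p + 1L, p + L)
  before <- if (p - L + 1L >= 1L) subseq_str(ref, p - L + 1L, p) else ""
  if (identical(nrm$allele, after) || identical(nrm$allele, before)) {
    variant_record(sample_name, "duplication", p, "-", nrm$allele)
  } else {
    NULL
  }
}

#' Detect a hairpin-mediated small inversion
#'
#' A flipped stem-loop differs from the reference only where the loop
#' differs from its own reverse complement, so the divergent block is
#' extended symmetrically to the maximal window `W` with
#' `query(W) = revcomp(reference(W))`. An inversion is reported only when
#' such a window of length <= `max_window` exists and covers at least two
#' mismatching columns (an isolated transversion SNP is a 1-bp
#' reverse-complement-consistent window and is excluded).
#'
#' @param ref,qry Sequence strings.
#' @param block One length-preserving divergent block.
#' @param max_window Largest window considered (bp).
#' @param bounds Optional c(lo, hi) reference interval the window must stay
#'   within (used to stop extension at neighbouring indels).
#' @param sample_name Sample label.
#' @return One-row variant data frame (with hairpin decomposition of the
#'   reference window), or NULL.
#' @export
detect_inversion <- function(ref, qry, block, max_window = 200L,
                             bounds = NULL, sample_name = "query") {
  s <- block$ref_start; e <- block$ref_end
  rl <- e - s + 1L
  ql <- block$qry_end - block$qry_start + 1L
  if (rl != ql || rl < 1L) return(NULL)
  d <- block$qry_start - block$ref_start
  n <- nchar(ref)
  lo <- max(1L, s - max_window, if (!is.null(bounds)) bounds[1L] else 1L)
  hi <- min(n, e + max_window, if (!is.null(bounds)) bounds[2L] else n)
  hi <- min(hi, nchar(qry) - d)
  lo <- max(lo, 1L - d)
  if (lo > s || hi < e) return(NULL)
  rch <- seq_chars(substr(ref, lo, hi))
  qch <- seq_chars(substr(qry, lo + d, hi + d))
  crch <- chartr("ACGTN", "TGCAN", rch)
  off <- lo - 1L
  pair_ok <- function(i, j) {           # local (region) indices
    qch[i] == crch[j] && qch[j] == crch[i]
  }
  sl <- s - off; el <- e - off          # block in local indices
  nloc <- length(rch)
  best <- NULL
  for (c2 in (2L * el - max_window + 1L):(2L * sl + max_window - 1L)) {
    if (c2 %% 2L == 0L) {
      i0 <- c2 %/% 2L
      if (i0 < 1L || i0 > nloc || !pair_ok(i0, i0)) next
      l <- i0 - 1L; r <- i0 + 1L
    } else {
      l <- (c2 - 1L) %/% 2L; r <- l + 1L
      if (l < 1L || r > nloc) next
    }
    while (l >= 1L && r <= nloc && r - l + 1L <= max_window &&
           pair_ok(l, r)) {
      l <- l - 1L; r <- r + 1L
    }
    a <- l + 1L; b <- r - 1L
    if (b < a || a > sl || b < el) next
    len <- b - a + 1L
    if (len > max_window) next
    if (is.null(best) || len > best$len ||
        (len == best$len && a < best$a)) {
      best <- list(a = a, b = b, len = len)
    }
  }
  if (is.null(best)) return(NULL)
  mism <- sum(qch[best$a:best$b] != rch[best$a:best$b])
  if (mism < 2L) return(NULL)
  a <- best$a + off; b <- best$b + off
  w <- substr(ref, a, b)
  alt <- substr(qry, a + d, b + d)
  stopifnot(identical(alt, revcomp(w)))
  hp <- characterize_hairpin(w)
  variant_record(sample_name, "inversion", a, w, alt,
                 stem_len = hp$stem_len, loop_len = hp$loop_len)
}

#' Annotate a variant with locus context and amino-acid label
#'
#' Locus is "Gene X" inside a CDS/exon, "Intron X" inside a gene but
#' between its CDS parts, and "Intergenic A-B" otherwise (A and B the
#' nearest flanking genes, wrapping around for circular genomes). Coding
#' SNPs are translated on the coding strand with the standard genetic
#' code: "Syn" when the amino acid is unchanged, otherwise "X-Y" in
#' one-letter codes.
#'
#' @param v One-row variant data frame.
#' @param genome An [annotated_genome()].
#' @return The variant with `locus` and `aa_label` filled in.
#' @export
annotate_variant <- function(v, genome) {
  f <- genome$features
  pos <- v$ref_pos
  genes <- f[f$ftype == "gene", , drop = FALSE]
  v$aa_label <- "none"
  if (nrow(genes) == 0L) {
    v$locus <- "Intergenic"
    return(v)
  }
  hit <- genes[genes$start <= pos & genes$end >= pos, , drop = FALSE]
  if (nrow(hit) >= 1L) {
    gid <- hit$id[1L]
    parts <- cds_parts(genome, gid)
    in_cds <- nrow(parts) > 0L &&
      any(parts$start <= pos & parts$end >= pos)
    if (in_cds) {
      v$locus <- paste("Gene", gid)
      if (v$kind == "snp") {
        v$aa_label <- snp_aa_label(genome, gid, pos, v$ref_allele,
                                   v$alt_allele)
      }
    } else {
      v$locus <- paste("Intron", gid)
    }
    return(v)
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  left <- genes$id[genes$end < pos]
  right <- genes$id[genes$start > pos]
  left_id <- if (length(left)) left[length(left)] else
    if (genome$circular) genes$id[nrow(genes)] else NA_character_
  right_id <- if (length(right)) right[1L] else
    if (genome$circular) genes$id[1L] else NA_character_
  v$locus <- paste0("Intergenic ",
                    paste(stats::na.omit(c(left_id, right_id)),
                          collapse = "-"))
  v
}

snp_aa_label <- function(genome, gene_id, pos, ref_base, alt_base) {
  parts <- cds_parts(genome, gene_id)
  strand <- parts$strand[1L]
  lens <- parts$end - parts$start + 1L
  total <- sum(lens)
  if (total %% 3L != 0L) {
    stop("cannot annotate SNP: CDS of ", gene_id,
         " has length ", total, ", not divisible by 3")
  }
  coding_plus <- paste0(vapply(seq_len(nrow(parts)), function(i) {
    substr(genome$seq, parts$start[i], parts$end[i])
  }, character(1)), collapse = "")
  k <- which(parts$start <= pos & parts$end >= pos)
  idx_plus <- sum(lens[seq_len(k - 1L)]) + (pos - parts$start[k] + 1L)
  if (strand == "+") {
    coding <- coding_plus
    cidx <- idx_plus
    cref <- ref_base; calt <- alt_base
  } else {
    coding <- revcomp(coding_plus)
    cidx <- total - idx_plus + 1L
    cref <- comp_base(ref_base); calt <- comp_base(alt_base)
  }
  if (substr(coding, cidx, cidx) != cref) {
    stop("reference allele does not match CDS of ", gene_id, " at ", pos)
  }
  c0 <- ((cidx - 1L) %/% 3L) * 3L + 1L
  codon_ref <- substr(coding, c0, c0 + 2L)
  codon_alt <- codon_ref
  substr(codon_alt, cidx - c0 + 1L, cidx - c0 + 1L) <- calt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  if (identical(aa_ref, aa_alt)) "Syn" else paste0(aa_ref, "-", aa_alt)
}

#' Classify every divergent block of an alignment map
#'
#' Classification precedence is inversion, duplication, homopolymer,
#' insertion/deletion, SNP. An inversion consumes all divergent blocks
#' inside its maximal window. A block that both substitutes and changes
#' length is decomposed into paired deletion + insertion records flagged
#' "complex". All calls are annotated against the reference gene model and
#' sorted by reference position.
#'
#' @param map An `AlignmentMap` from [whole_genome_align()].
#' @param ref_genome The reference [annotated_genome()].
#' @param sample_name Sample label recorded on each call.
#' @param max_window Largest inversion window considered (bp).
#' @param min_run Minimum reference run length for homopolymer notation.
#' @return Variant data frame (zero rows when the sequences are identical).
#' @export
classify_all <- function(map, ref_genome, sample_name = "query",
                         max_window = 200L, min_run = 5L) {
  ref <- ref_genome$seq
  qry <- map$qry
  blocks <- map$blocks
  div <- blocks[blocks$kind == "divergent", , drop = FALSE]
  rownames(div) <- NULL
  out <- list()
  if (nrow(div) == 0L) {
    return(empty_variant_frame())
  }
  rl <- div$ref_end - div$ref_start + 1L
  ql <- div$qry_end - div$qry_start + 1L
  lp <- rl == ql & rl >= 1L             # length-preserving blocks
  consumed <- rep(FALSE, nrow(div))

  # inversions first. A flipped stem-loop is length-preserving overall but
  # may align as several blocks - including cancelling insertion/deletion
  # pairs when the gapped path outscores a mismatch run - so candidate
  # windows span length-balanced clusters of nearby divergent blocks.
  # Window extension cannot cross an indel outside the cluster (the column
  # offset changes there), so the search is bounded accordingly.
  nd <- nrow(div)
  for (i in seq_len(nd)) {
    if (consumed[i]) next
    for (j in rev(seq.int(i, nd))) {
      if (any(consumed[i:j])) next
      span <- div$ref_end[j] - div$ref_start[i]
      if (span + 1L > max_window || span < 0L) next
      if (div$qry_end[j] - div$qry_start[i] != span) next   # unbalanced
      lo <- 1L
      hi <- nchar(ref)
      before <- which(!lp & seq_len(nd) < i)
      after <- which(!lp & seq_len(nd) > j)
      if (length(before)) lo <- max(div$ref_end[before]) + 1L
      if (length(after)) hi <- min(div$ref_start[after]) - 1L
      cluster <- data.frame(ref_start = div$ref_start[i],
                            ref_end = div$ref_end[j],
                            qry_start = div$qry_start[i],
                            qry_end = div$qry_end[j])
      inv <- detect_inversion(ref, qry, cluster, max_window = max_window,
                              bounds = c(lo, hi),
                              sample_name = sample_name)
      if (!is.null(inv)) {
        a <- inv$ref_pos
        b <- a + nchar(inv$ref_allele) - 1L
        consumed[div$ref_start >= a & div$ref_end <= b] <- TRUE
        out[[length(out) + 1L]] <- inv
        break
      }
    }
  }

  for (i in seq_len(nrow(div))) {
    if (consumed[i]) next
    b <- div[i, ]
    if (rl[i] == 1L && ql[i] == 1L) {
      out[[length(out) + 1L]] <- variant_record(
        sample_name, "snp", b$ref_start,
        substr(ref, b$ref_start, b$ref_end),
        substr(qry, b$qry_start, b$qry_end))
    } else if (rl[i] == 0L || ql[i] == 0L) {
      v <- call_duplication(ref, qry, b, sample_name = sample_name)
      if (is.null(v)) {
        v <- call_homopolymer(ref, qry, b, min_run = min_run,
                              sample_name = sample_name)
      }
      if (is.null(v)) {
        ind <- block_indel(ref, qry, b)
        nrm <- left_normalize_indel(ref, ind$anchor, ind$allele,
                                    ind$direction)
        v <- if (ind$direction == "ins") {
          variant_record(sample_name, "insertion", nrm$pos, "-", nrm$allele)
        } else {
          variant_record(sample_name, "deletion", nrm$pos, nrm$allele, "-")
        }
      }
      out[[length(out) + 1L]] <- v
    } else {
      # substitution plus length change: decompose, flag as complex
      out[[length(out) + 1L]] <- variant_record(
        sample_name, "deletion", b$ref_start,
        substr(ref, b$ref_start, b$ref_end), "-", flag = "complex")
      out[[length(out) + 1L]] <- variant_record(
        sample_name, "insertion", b$ref_start - 1L, "-",
        substr(qry, b$qry_start, b$qry_end), flag = "complex")
    }
  }

  vs <- do.call(rbind, out)
  vs <- do.call(rbind, lapply(seq_len(nrow(vs)), function(i) {
    annotate_variant(vs[i, ], ref_genome)
  }))
  vs <- vs[order(vs$ref_pos, vs$kind), , drop = FALSE]
  rownames(vs) <- NULL
  vs
}

empty_variant_frame <- function() {
  data.frame(sample = character(0), kind = character(0),
             ref_pos = integer(0), ref_allele = character(0),
             alt_allele = character(0), locus = character(0),
             aa_label = character(0), stem_len = integer(0),
             loop_len = integer(0), flag = character(0),
             stringsAsFactors = FALSE)
}

#' Per-sample variant summary
#'
#' Counts of calls by kind and by locus class (genic / intron /
#' intergenic).
#'
#' @param variants Variant data frame from [classify_all()].
#' @return List with `by_kind` and `by_locus_class` tables.
#' @export
summarize_variants <- function(variants) {
  locus_class <- ifelse(startsWith(variants$locus, "Gene"), "genic",
                 ifelse(startsWith(variants$locus, "Intron"), "intron",
                        "intergenic"))
  list(by_kind = table(variants$kind),
       by_locus_class = table(locus_class))
}
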