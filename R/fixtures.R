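#' Printed marker sequences for hexaploid wheat chloroplast analysis
#'
#' Nucleotide sequences of the diagnostic indel/inversion markers of the
#' hexaploid wheat plastome and the Wknox1 PCR primer pairs, as used by the
#' packaged fixtures. Inversion windows are named by their flanking loci and
#' window length; stem/loop structure is computed, not stored.
#'
#' @return Named list of character strings / primer pairs.
#' @export
wheat_markers <- function() {
  list(
    rpl22_insertion_35 =
      "GATGGATCTAAAGGTTATTTAGATTTCTTTACTAT",
    rpl32_trnL_inversion_58 =
      "ACTTTTCATAATTTTCATAATAGAATCCTCATATTTTATTATGAAAATTATGAAAAGT",
    ccsA_ndhD_inversion_25 =
      "AAAACCTTCATGAAATGAAGGTTTT",
    rps19_psbA_inversion_56 =
      "AAAGACAGAAATACCCAATATCTTGCTAGAACAAGATATTGGGTATTTCTGTCTTT",
    rbcL_psaI_inversion_38 =
      "TCGGCTCAATCTTTTTTTTCTAAAAAAGATTGAGCCGA",
    wknox1d_intron4_insertion_42 =
      "AGTTTGCACACCTGAACATTTTGCATTATGTTCGGGAGCCTA",
    wknox1d_primers = c(forward = "AAAAAAAAGGTTAAATGGAC",
                        reverse = "ACCTTATACATGATTGGGAA"),
    wknox1b_primers = c(forward = "GCTGAAGCACCATCTCCTGA",
                        reverse = "CATGTAGAAGGCGGCGTTAG")
  )
}

#' Construct a variant specification
#'
#' A `VariantSpec` describes one planned difference between a reference and
#' a query genome. Coordinates are 1-based on the reference. Insertions are
#' anchored to the reference base they follow (`ref_pos` = base before the
#' inserted material).
#'
#' @param kind One of snp, insertion, deletion, homopolymer, duplication,
#'   inversion.
#' @param ref_pos 1-based reference coordinate.
#' @param payload For snp: the alternate base. For insertion: the inserted
#'   sequence. For deletion: the deleted reference segment. For duplication:
#'   the duplicated reference segment starting at `ref_pos`. For
#'   homopolymer: a signed run-length delta such as "+3" or "-2".
#' @param window_len Window length in bp (inversion only).
#' @return One-row data frame with columns kind, ref_pos, payload,
#'   window_len.
#' @export
variant_spec <- function(kind, ref_pos, payload = "", window_len = NA_integer_) {
  kinds <- c("snp", "insertion", "deletion", "homopolymer", "duplication",
             "inversion")
  kind <- match.arg(kind, kinds)
  if (kind != "homopolymer" && grepl("[^ACGT]", payload) && payload != "") {
    stop("payload must be over A/C/G/T for kind '", kind, "'")
  }
  data.frame(kind = kind, ref_pos = as.integer(ref_pos),
             payload = payload, window_len = as.integer(window_len),
             stringsAsFactors = FALSE)
}

# Reference-coordinate footprint of one spec row, used for overlap checks.
spec_footprint <- function(genome, s) {
  p <- s$ref_pos
  as.integer(switch(s$kind,
    snp = c(p, p),
    insertion = c(p, p + 1L),
    deletion = c(p, p + nchar(s$payload) - 1L),
    homopolymer = {
      r <- run_at(genome$seq, p)
      c(r$start, r$end)
    },
    duplication = c(p, p + nchar(s$payload)),
    inversion = c(p, p + s$window_len - 1L)
  ))
}

#' Synthesize an annotated reference plastome
#'
#' Generates a deterministic random genome (AT-rich, as grass plastomes are)
#' carrying non-overlapping protein-coding genes on both strands (the first
#' gene is intron-bearing when genes are requested), mononucleotide runs of
#' length >= 8, and near-palindromic stem-loop windows (perfect stem 8-14
#' bp, loop 3-14 bp) whose flipped form is detectable: the loop differs
#' from its own reverse complement at >= 2 positions and the window cannot
#' be extended outward.
#'
#' @param length Genome length in bp (>= 1000).
#' @param n_genes Number of genes to embed.
#' @param homopolymer_runs Number of mononucleotide runs to embed.
#' @param palindromes Number of stem-loop windows to embed.
#' @param seed Integer seed; identical inputs give identical genomes.
#' @param name Sequence name.
#' @return An [annotated_genome()] with generator bookkeeping in elements
#'   `runs` (start, end, base, len) and `palindromes` (start, end, stem_len,
#'   loop_len).
#' @export
make_reference <- function(length, n_genes = 0L, homopolymer_runs = 0L,
                           palindromes = 0L, seed = 1L, name = "ref") {
  stopifnot(length >= 1000)
  withr::with_seed(seed, {
    seq <- random_seq(length)

    # element lengths, in placement order: genes, runs, palindromes
    gene_plan <- list()
    if (n_genes > 0L) {
      for (i in seq_len(n_genes)) {
        codons <- sample(60:120, 1L)
        intron <- if (i == 1L) sample(60:120, 1L) else 0L
        gene_plan[[i]] <- list(cds_len = 3L * codons, intron_len = intron,
                               strand = sample(c("+", "-"), 1L))
      }
    }
    run_lens <- if (homopolymer_runs > 0L)
      sample(8:15, homopolymer_runs, replace = TRUE) else integer(0)
    pal_plan <- list()
    if (palindromes > 0L) {
      for (i in seq_len(palindromes)) {
        pal_plan[[i]] <- list(stem = sample(8:14, 1L),
                              loop = sample(3:14, 1L))
      }
    }
    elem_lens <- c(
      vapply(gene_plan, function(g) g$cds_len + g$intron_len, integer(1)),
      run_lens,
      vapply(pal_plan, function(p) 2L * p$stem + p$loop, integer(1))
    )
    n_elem <- length(elem_lens)
    margin <- 60L
    end_margin <- 120L
    free <- length - 2L * end_margin - sum(elem_lens) -
      max(0L, n_elem - 1L) * margin
    if (n_elem > 0L && free < 0L) {
      stop(sprintf(paste0("cannot pack %d elements (%d bp + margins) into ",
                          "a %d bp genome"), n_elem, sum(elem_lens), length))
    }

    starts <- integer(0)
    if (n_elem > 0L) {
      cuts <- sort(sample.int(free + 1L, n_elem, replace = TRUE) - 1L)
      starts <- end_margin + 1L + cuts +
        cumsum(c(0L, elem_lens[-n_elem] + margin))
    }

    features <- empty_features()
    idx <- 0L
    for (i in seq_along(gene_plan)) {
      idx <- idx + 1L
      g <- gene_plan[[i]]
      built <- build_gene_segment(g$cds_len, g$intron_len)
      a <- starts[idx]
      elen <- nchar(built$segment)
      segment <- built$segment
      parts <- built$parts          # 1-based within plus-strand element
      if (g$strand == "-") {
        segment <- revcomp(segment)
        parts <- data.frame(start = elen - parts$end + 1L,
                            end = elen - parts$start + 1L)
        parts <- parts[order(parts$start), , drop = FALSE]
      }
      substr(seq, a, a + elen - 1L) <- segment
      gid <- sprintf("gene%02d", i)
      features <- rbind(features, data.frame(
        id = gid, ftype = "gene", start = a, end = a + elen - 1L,
        strand = g$strand, parent = NA_character_, stringsAsFactors = FALSE))
      for (j in seq_len(nrow(parts))) {
        features <- rbind(features, data.frame(
          id = sprintf("%s.cds%d", gid, j), ftype = "CDS",
          start = a + parts$start[j] - 1L, end = a + parts$end[j] - 1L,
          strand = g$strand, parent = gid, stringsAsFactors = FALSE))
      }
    }

    runs <- data.frame(start = integer(), end = integer(),
                       base = character(), len = integer(),
                       stringsAsFactors = FALSE)
    for (i in seq_along(run_lens)) {
      idx <- idx + 1L
      a <- starts[idx]
      len <- run_lens[i]
      base <- sample(c("A", "C", "G", "T"), 1L)
      substr(seq, a, a + len - 1L) <- strrep(base, len)
      # distinct flanking bases keep the run length unambiguous
      others <- setdiff(c("A", "C", "G", "T"), base)
      substr(seq, a - 1L, a - 1L) <- sample(others, 1L)
      substr(seq, a + len, a + len) <- sample(others, 1L)
      runs <- rbind(runs, data.frame(start = a, end = a + len - 1L,
                                     base = base, len = len,
                                     stringsAsFactors = FALSE))
    }

    pals <- data.frame(start = integer(), end = integer(),
                       stem_len = integer(), loop_len = integer(),
                       stringsAsFactors = FALSE)
    for (i in seq_along(pal_plan)) {
      idx <- idx + 1L
      a <- starts[idx]
      p <- pal_plan[[i]]
      win <- make_palindrome(p$stem, p$loop)
      wlen <- nchar(win)
      substr(seq, a, a + wlen - 1L) <- win
      # block outward extension of the reverse-complement window
      if (substr(seq, a - 1L, a - 1L) ==
          comp_base(substr(seq, a + wlen, a + wlen))) {
        bad <- substr(seq, a + wlen, a + wlen)
        repl <- sample(setdiff(c("A", "C", "G", "T"),
                               c(bad, comp_base(substr(seq, a - 1L, a - 1L)))), 1L)
        substr(seq, a + wlen, a + wlen) <- repl
      }
      pals <- rbind(pals, data.frame(start = a, end = a + wlen - 1L,
                                     stem_len = p$stem, loop_len = p$loop,
                                     stringsAsFactors = FALSE))
    }

    g <- annotated_genome(name, seq, features, circular = TRUE)
    g$runs <- runs
    g$palindromes <- pals
    g
  })
}

# Coding segment with optional single intron; returns the genomic (+) strand
# segment and CDS part coordinates (1-based within the segment).
build_gene_segment <- function(cds_len, intron_len) {
  stopifnot(cds_len %% 3L == 0L, cds_len >= 9L)
  n_codon <- cds_len %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, stops)
  cds <- paste0(c("ATG", sample(sense, n_codon - 2L, replace = TRUE),
                  sample(stops, 1L)), collapse = "")
  if (intron_len == 0L) {
    return(list(segment = cds,
                parts = data.frame(start = 1L, end = cds_len)))
  }
  cut <- sample(seq(10L, cds_len - 10L), 1L)
  intron <- random_seq(intron_len)
  segment <- paste0(substr(cds, 1L, cut), intron,
                    substr(cds, cut + 1L, cds_len))
  list(segment = segment,
       parts = data.frame(start = c(1L, cut + intron_len + 1L),
                          end = c(cut, cds_len + intron_len)))
}

# Stem-loop window: stem + loop + revcomp(stem), with the loop differing
# from its own reverse complement at >= 2 positions and not extending the
# stem inward, so the hairpin decomposition is exactly (stem, loop).
make_palindrome <- function(stem_len, loop_len) {
  repeat {
    stem <- random_seq(stem_len)
    loop <- random_seq(loop_len)
    if (substr(loop, 1L, 1L) ==
        comp_base(substr(loop, loop_len, loop_len))) next
    lc <- seq_chars(loop)
    mism <- sum(lc != seq_chars(revcomp(loop)))
    if (mism < 2L) next
    return(paste0(stem, loop, revcomp(stem)))
  }
}

#' Apply variant specifications to a reference
#'
#' Edits are applied right-to-left so reference coordinates never shift.
#' Specs must be sorted by `ref_pos` and non-overlapping on the reference.
#'
#' @param genome An [annotated_genome()].
#' @param specs Data frame of [variant_spec()] rows.
#' @return List with elements `query` (character string) and `truth`
#'   (class `truth_table`: the specs plus bookkeeping).
#' @export
apply_variants <- function(genome, specs) {
  seq <- genome$seq
  n <- nchar(seq)
  if (is.null(specs) || nrow(specs) == 0L) {
    truth <- structure(list(specs = specs), class = "truth_table")
    return(list(query = seq, truth = truth))
  }
  if (is.unsorted(specs$ref_pos)) {
    stop("specs must be sorted by ref_pos")
  }
  fp <- t(vapply(seq_len(nrow(specs)),
                 function(i) spec_footprint(genome, specs[i, ]),
                 integer(2)))
  bad_range <- which(fp[, 1] < 1L | fp[, 2] > n)
  if (length(bad_range)) {
    stop("spec(s) out of reference range at rows: ",
         paste(bad_range, collapse = ", "))
  }
  if (nrow(specs) > 1L) {
    ov <- which(fp[-1L, 1] <= fp[-nrow(specs), 2])
    if (length(ov)) {
      stop("overlapping spec(s) at rows: ",
           paste(sort(unique(c(ov, ov + 1L))), collapse = ", "))
    }
  }
  for (i in rev(seq_len(nrow(specs)))) {
    s <- specs[i, ]
    p <- s$ref_pos
    seq <- switch(s$kind,
      snp = {
        if (substr(seq, p, p) == s$payload) {
          stop("snp at ", p, " has alt equal to reference base")
        }
        paste0(substr(seq, 1L, p - 1L), s$payload,
               substr(seq, p + 1L, nchar(seq)))
      },
      insertion = paste0(substr(seq, 1L, p), s$payload,
                         substr(seq, p + 1L, nchar(seq))),
      deletion = {
        L <- nchar(s$payload)
        if (substr(seq, p, p + L - 1L) != s$payload) {
          stop("deletion payload does not match reference at ", p)
        }
        paste0(substr(seq, 1L, p - 1L), substr(seq, p + L, nchar(seq)))
      },
      homopolymer = {
        r <- run_at(genome$seq, p)
        delta <- as.integer(s$payload)
        if (r$len + delta < 1L) stop("homopolymer delta removes entire run")
        paste0(substr(seq, 1L, r$start - 1L), strrep(r$base, r$len + delta),
               substr(seq, r$end + 1L, nchar(seq)))
      },
      duplication = {
        L <- nchar(s$payload)
        if (substr(seq, p, p + L - 1L) != s$payload) {
          stop("duplication payload does not match reference at ", p)
        }
        paste0(substr(seq, 1L, p + L - 1L), s$payload,
               substr(seq, p + L, nchar(seq)))
      },
      inversion = {
        w <- s$window_len
        paste0(substr(seq, 1L, p - 1L),
               revcomp(substr(seq, p, p + w - 1L)),
               substr(seq, p + w, nchar(seq)))
      }
    )
  }
  truth <- structure(list(specs = specs), class = "truth_table")
  list(query = seq, truth = truth)
}

#' Write / read a truth table as TSV
#'
#' Columns: kind, ref_pos, payload, window_len.
#' @param truth A `truth_table` (or its specs data frame).
#' @param path Output path.
#' @export
write_truth_table <- function(truth, path) {
  specs <- if (inherits(truth, "truth_table")) truth$specs else truth
  utils::write.table(specs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(kind = "character", ref_pos = "integer",
                                   payload = "character",
                                   window_len = "integer"))
}

#' Sample a random, recoverable variant specification set
#'
#' Draws non-overlapping variants of each class on a reference built with
#' [make_reference()]. Placement is rejection-sampled so every planted
#' variant has an unambiguous canonical call: indels cannot shift under
#' left normalization, plain indels avoid mononucleotide contexts,
#' duplications are not confounded by pre-existing tandem copies,
#' homopolymer changes target the embedded runs, and inversions flip the
#' embedded stem-loop windows. All variants keep >= `margin` bp from one
#' another and from unused embedded elements.
#'
#' @param genome Reference from [make_reference()].
#' @param n_snp,n_insertion,n_deletion,n_homopolymer,n_duplication,n_inversion
#'   Counts per variant class.
#' @param seed Integer seed.
#' @param margin Minimum spacing in bp between variant footprints.
#' @return Spec data frame sorted by ref_pos.
#' @export
sample_variant_specs <- function(genome, n_snp = 20L, n_insertion = 2L,
                                 n_deletion = 1L, n_homopolymer = 2L,
                                 n_duplication = 1L, n_inversion = 2L,
                                 seed = 1L, margin = 50L) {
  if (n_inversion > nrow(genome$palindromes)) {
    stop("reference has only ", nrow(genome$palindromes),
         " embedded stem-loop windows; ", n_inversion, " inversions requested")
  }
  if (n_homopolymer > nrow(genome$runs)) {
    stop("reference has only ", nrow(genome$runs),
         " embedded homopolymer runs; ", n_homopolymer, " changes requested")
  }
  ref <- genome$seq
  n <- nchar(ref)
  withr::with_seed(seed, {
    occupied <- rbind(
      cbind(genome$runs$start, genome$runs$end),
      cbind(genome$palindromes$start, genome$palindromes$end)
    )
    occupied <- rbind(occupied, c(1L, 100L), c(n - 100L, n))
    free_ok <- function(a, b) {
      !any(occupied[, 1] <= b + margin & occupied[, 2] >= a - margin)
    }
    claim <- function(a, b) occupied <<- rbind(occupied, c(a, b))
    specs <- list()
    add <- function(s) specs[[length(specs) + 1L]] <<- s

    inv_idx <- sample(seq_len(nrow(genome$palindromes)), n_inversion)
    for (i in inv_idx) {
      p <- genome$palindromes[i, ]
      add(variant_spec("inversion", p$start,
                       window_len = p$end - p$start + 1L))
    }
    hp_idx <- sample(seq_len(nrow(genome$runs)), n_homopolymer)
    for (i in hp_idx) {
      r <- genome$runs[i, ]
      delta <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1L)
      add(variant_spec("homopolymer", r$start,
                       payload = sprintf("%+d", delta)))
    }

    draw <- function(gen, tries = 500L) {
      for (t in seq_len(tries)) {
        s <- gen()
        if (!is.null(s)) return(s)
      }
      stop("could not place a variant after ", tries,
           " attempts; relax counts or margin")
    }

    for (i in seq_len(n_snp)) {
      add(draw(function() {
        p <- sample.int(n, 1L)
        if (!free_ok(p, p)) return(NULL)
        b <- substr(ref, p, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        claim(p, p)
        variant_spec("snp", p, payload = alt)
      }))
    }
    for (i in seq_len(n_insertion)) {
      add(draw(function() {
        p <- sample.int(n, 1L)
        L <- sample(3:10, 1L)
        if (!free_ok(p, p + 1L)) return(NULL)
        payload <- random_seq(L)
        if (length(unique(seq_chars(payload))) < 2L) return(NULL)
        nrm <- left_normalize_indel(ref, p, payload, "ins")
        if (nrm$pos != p) return(NULL)
        if (identical(payload, subseq_str(ref, p - L + 1L, p)) ||
            identical(payload, subseq_str(ref, p + 1L, p + L))) return(NULL)
        claim(p, p + 1L)
        variant_spec("insertion", p, payload = payload)
      }))
    }
    for (i in seq_len(n_deletion)) {
      add(draw(function() {
        p <- sample.int(n, 1L)
        L <- sample(3:8, 1L)
        if (!free_ok(p, p + L - 1L)) return(NULL)
        segment <- substr(ref, p, p + L - 1L)
        if (length(unique(seq_chars(segment))) < 2L) return(NULL)
        nrm <- left_normalize_indel(ref, p, segment, "del")
        if (nrm$pos != p) return(NULL)
        if (substr(ref, p, p + L) == substr(ref, p + 1L, p + L + 1L))
          return(NULL)
        claim(p, p + L - 1L)
        variant_spec("deletion", p, payload = segment)
      }))
    }
    for (i in seq_len(n_duplication)) {
      add(draw(function() {
        p <- sample.int(n, 1L)
        L <- sample(4:10, 1L)
        if (!free_ok(p - 1L, p + 2L * L)) return(NULL)
        segment <- substr(ref, p, p + L - 1L)
        if (length(unique(seq_chars(segment))) < 2L) return(NULL)
        nrm <- left_normalize_indel(ref, p + L - 1L, segment, "ins")
        if (nrm$pos != p - 1L || nrm$allele != segment) return(NULL)
        claim(p - 1L, p + 2L * L)
        variant_spec("duplication", p, payload = segment)
      }))
    }
    out <- do.call(rbind, specs)
    out <- out[order(out$ref_pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Canonical variant calls implied by a truth table
#'
#' Converts planted [variant_spec()] rows into the left-normalized,
#' run-notated, hairpin-decomposed records the classifier is expected to
#' emit, for truth-recovery comparisons.
#'
#' @param genome The reference the specs were applied to.
#' @param specs Spec data frame (or `truth_table`).
#' @param sample_name Sample label for the records.
#' @return Variant data frame in [write_variant_table()] column layout
#'   (without locus/aa annotation).
#' @export
expected_variants <- function(genome, specs, sample_name = "query") {
  if (inherits(specs, "truth_table")) specs <- specs$specs
  ref <- genome$seq
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    p <- s$ref_pos
    switch(s$kind,
      snp = variant_record(sample_name, "snp", p,
                           substr(ref, p, p), s$payload),
      insertion = {
        nrm <- left_normalize_indel(ref, p, s$payload, "ins")
        variant_record(sample_name, "insertion", nrm$pos, "-", nrm$allele)
      },
      deletion = {
        nrm <- left_normalize_indel(ref, p, s$payload, "del")
        variant_record(sample_name, "deletion", nrm$pos, nrm$allele, "-")
      },
      homopolymer = {
        r <- run_at(ref, p)
        m <- r$len + as.integer(s$payload)
        variant_record(sample_name, "homopolymer", r$start,
                       paste0(r$len, r$base), paste0(m, r$base))
      },
      duplication = {
        L <- nchar(s$payload)
        nrm <- left_normalize_indel(ref, p + L - 1L, s$payload, "ins")
        variant_record(sample_name, "duplication", nrm$pos, "-", nrm$allele)
      },
      inversion = {
        w <- substr(ref, p, p + s$window_len - 1L)
        hp <- characterize_hairpin(w)
        variant_record(sample_name, "inversion", p, w, revcomp(w),
                       stem_len = hp$stem_len, loop_len = hp$loop_len)
      })
  })
  out <- do.call(rbind, rows)
  out[order(out$ref_pos), , drop = FALSE]
}

#' The 34-site x 20-sample hexaploid wheat SNP matrix
#'
#' Returns the packaged transcription of the published SNP table for 20
#' hexaploid wheat plastomes (grouped sample columns expanded to one column
#' per sample), with each site carrying its locus label, reference (Chinese
#' Spring) allele and amino-acid substitution label.
#'
#' @return A `VariantMatrix` (see [build_matrix()]).
#' @export
paper_table4_matrix <- function() {
  path <- system.file("extdata", "table4_snps.tsv", package = "plastovar",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  sample_names <- setdiff(names(tab), c("pos", "locus", "aa"))
  sites <- data.frame(ref_pos = as.integer(tab$pos), locus = tab$locus,
                      aa_label = ifelse(nzchar(tab$aa), tab$aa, "none"),
                      ref_allele = tab$CS, kind = "snp",
                      stringsAsFactors = FALSE)
  alleles <- as.matrix(tab[, sample_names])
  rownames(alleles) <- as.character(sites$ref_pos)
  variant_matrix(sites, sample_names, alleles)
}

#' Synthetic reference/query pair carrying the printed wheat markers
#'
#' Builds a reference that embeds, in random palindrome-free flanking
#' context, the three printed inversion windows (58, 25 and 56 bp), and a
#' query in which those windows are reverse-complemented and the printed
#' 35-bp and 42-bp segments are inserted. The truth table therefore holds
#' exactly five specs.
#'
#' @param seed Integer seed for the flanking context.
#' @return List with `reference` ([annotated_genome()]), `query` (string)
#'   and `truth` (`truth_table`).
#' @export
paper_table6_pair <- function(seed = 1L) {
  mk <- wheat_markers()
  withr::with_seed(seed, {
    flank <- function(len) {
      repeat {
        f <- random_seq(len)
        if (!has_inverted_repeat(f, 8L)) return(f)
      }
    }
    # layout: F1 [ins35] F2 inv58 F3 [ins42] F4 inv25 F5 inv56 F6
    repeat {
      f <- replicate(6L, flank(350L))
      parts <- c(f[1], f[2], mk$rpl32_trnL_inversion_58,
                 f[3], f[4], mk$ccsA_ndhD_inversion_25,
                 f[5], mk$rps19_psbA_inversion_56, f[6])
      ref <- paste0(parts, collapse = "")
      offs <- cumsum(c(0L, nchar(parts)))
      inv_starts <- offs[c(3L, 6L, 8L)] + 1L
      inv_lens <- nchar(c(mk$rpl32_trnL_inversion_58,
                          mk$ccsA_ndhD_inversion_25,
                          mk$rps19_psbA_inversion_56))
      ins_pos <- c(offs[2L] - 150L, offs[5L] - 150L)
      ins_payloads <- c(mk$rpl22_insertion_35, mk$wknox1d_intron4_insertion_42)

      ok <- TRUE
      for (j in seq_along(inv_starts)) {
        a <- inv_starts[j]; b <- a + inv_lens[j] - 1L
        if (substr(ref, a - 1L, a - 1L) ==
            comp_base(substr(ref, b + 1L, b + 1L))) ok <- FALSE
        ctx <- substr(ref, max(1L, a - 100L), min(nchar(ref), b + 100L))
        # allow only the embedded window's own inverted repeat in context
        ctx_masked <- paste0(substr(ref, max(1L, a - 100L), a - 1L),
                             strrep("N", inv_lens[j]),
                             substr(ref, b + 1L, min(nchar(ref), b + 100L)))
        if (has_inverted_repeat(gsub("N", "", ctx_masked), 8L)) ok <- FALSE
      }
      for (j in seq_along(ins_pos)) {
        nrm <- left_normalize_indel(ref, ins_pos[j], ins_payloads[j], "ins")
        if (nrm$pos != ins_pos[j]) ok <- FALSE
      }
      if (!ok) next

      specs <- rbind(
        variant_spec("insertion", ins_pos[1L], payload = ins_payloads[1L]),
        variant_spec("inversion", inv_starts[1L], window_len = inv_lens[1L]),
        variant_spec("insertion", ins_pos[2L], payload = ins_payloads[2L]),
        variant_spec("inversion", inv_starts[2L], window_len = inv_lens[2L]),
        variant_spec("inversion", inv_starts[3L], window_len = inv_lens[3L])
      )
      specs <- specs[order(specs$ref_pos), , drop = FALSE]
      rownames(specs) <- NULL
      genome <- annotated_genome("synthetic_cs", ref, circular = FALSE)
      res <- apply_variants(genome, specs)
      return(list(reference = genome, query = res$query,
                  truth = res$truth))
    }
  })
}
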