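#' Read a FASTA file
#'
#' Sequences are uppercased; record order is preserved. Characters outside
#' A/C/G/T/N raise a parse error that names the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named list of uppercase sequence strings, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines))) {
    stop("empty FASTA file: ", path)
  }
  body <- !startsWith(lines, ">") & nzchar(lines)
  bad <- which(body & grepl("[^ACGTNacgtn]", lines))
  if (length(bad)) {
    stop(sprintf("non-ACGTN character in %s at line %d", path, bad[1L]))
  }
  if (!startsWith(lines[nzchar(lines)][1L], ">")) {
    stop(sprintf("FASTA record without header in %s at line 1", path))
  }
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  as.list(out)
}

#' Write sequences to FASTA
#'
#' @param seqs Named list/vector of sequence strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) into the flat feature table
#' used by [annotated_genome()]. Coordinates are validated against the
#' genome length; introns are not required in the file, as they are derived
#' as gaps between the CDS/exon parts of one parent gene.
#'
#' @param path Path to a GFF3 file.
#' @param genome_length Length of the reference sequence in bp.
#' @return Feature data frame (columns id, ftype, start, end, strand, parent).
#' @export
read_gff3 <- function(path, genome_length) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(empty_features())
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    paste0("feat", seq_along(gr))
  parent <- rep(NA_character_, length(gr))
  if ("Parent" %in% names(md)) {
    pl <- md$Parent
    parent <- vapply(seq_along(gr), function(i) {
      p <- pl[[i]]
      if (length(p)) as.character(p)[1L] else NA_character_
    }, character(1))
  }
  f <- data.frame(
    id = ids,
    ftype = as.character(md$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    parent = parent,
    stringsAsFactors = FALSE
  )
  keep <- f$ftype %in% c("gene", "CDS", "exon", "intron")
  f <- f[keep, , drop = FALSE]
  f$strand[!f$strand %in% c("+", "-")] <- "+"
  rownames(f) <- NULL
  validate_features(f, genome_length)
  f
}

#' Write gene models to GFF3
#'
#' @param genome An [annotated_genome()].
#' @param path Output path (should end in `.gff3`).
#' @export
write_gff3 <- function(genome, path) {
  f <- genome$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$name,
                     nchar(genome$seq)), con)
  if (nrow(f)) {
    attrs <- ifelse(is.na(f$parent),
                    paste0("ID=", f$id),
                    paste0("ID=", f$id, ";Parent=", f$parent))
    writeLines(paste(genome$name, "plastovar", f$ftype, f$start, f$end,
                     ".", f$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

variant_table_cols <- c("sample", "kind", "ref_pos", "ref_allele",
                        "alt_allele", "locus", "aa_label", "stem_len",
                        "loop_len")

#' Write classified variants to TSV
#'
#' Columns: sample, kind, ref_pos, ref_allele, alt_allele, locus, aa_label,
#' stem_len, loop_len. Hairpin columns are NA except for inversions.
#'
#' @param variants Variant data frame as returned by [classify_all()].
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  v <- variants
  for (col in variant_table_cols) {
    if (!col %in% names(v)) v[[col]] <- NA
  }
  utils::write.table(v[variant_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a variant TSV written by [write_variant_table()]
#'
#' @param path Path to the TSV file.
#' @return Variant data frame.
#' @export
read_variant_table <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           sample = "character", kind = "character",
                           ref_pos = "integer", ref_allele = "character",
                           alt_allele = "character", locus = "character",
                           aa_label = "character", stem_len = "integer",
                           loop_len = "integer"))
  v
}

#' Write a tree to Newick
#'
#' @param tree An \pkg{ape} `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
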