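#' Annotated genome container
#'
#' Bundles a named nucleotide sequence with a feature table. Coordinates are
#' 1-based and inclusive throughout the package, matching the convention of
#' positions given "according to" a reference linearization.
#'
#' @param name Sequence name (seqid used in FASTA/GFF3 output).
#' @param seq Uppercase A/C/G/T character string.
#' @param features Data frame with columns `id`, `ftype` (gene, CDS, exon,
#'   intron), `start`, `end`, `strand` (`+`/`-`), `parent` (NA for top-level
#'   features).
#' @param circular Logical; plastomes are circular molecules.
#' @return An object of class `AnnotatedGenome`.
#' @export
annotated_genome <- function(name, seq, features = empty_features(),
                             circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("genome sequence contains characters outside A/C/G/T")
  }
  validate_features(features, nchar(seq))
  g <- list(name = name, seq = seq, features = features, circular = circular)
  class(g) <- "AnnotatedGenome"
  g
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome '%s': %d bp%s, %d features\n",
              x$name, nchar(x$seq), if (x$circular) " (circular)" else "",
              nrow(x$features)))
  invisible(x)
}

#' @rdname annotated_genome
#' @export
empty_features <- function() {
  data.frame(id = character(), ftype = character(), start = integer(),
             end = integer(), strand = character(), parent = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_length) {
  req <- c("id", "ftype", "start", "end", "strand", "parent")
  if (!all(req %in% names(features))) {
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(features) == 0L) return(invisible(TRUE))
  if (any(features$end < features$start)) {
    bad <- features$id[features$end < features$start]
    stop("feature end < start for: ", paste(bad, collapse = ", "))
  }
  if (any(features$start < 1L) || any(features$end > genome_length)) {
    bad <- features$id[features$start < 1L | features$end > genome_length]
    stop("feature coordinates out of range for: ", paste(bad, collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  invisible(TRUE)
}

# CDS parts of one gene, in genomic order.
cds_parts <- function(genome, gene_id) {
  f <- genome$features
  p <- f[f$ftype == "CDS" & !is.na(f$parent) & f$parent == gene_id, ,
         drop = FALSE]
  p[order(p$start), , drop = FALSE]
}

# Derive intron spans of a gene as gaps between its CDS/exon parts.
gene_introns <- function(genome, gene_id) {
  p <- cds_parts(genome, gene_id)
  if (nrow(p) < 2L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = p$end[-nrow(p)] + 1L, end = p$start[-1L] - 1L)
}
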