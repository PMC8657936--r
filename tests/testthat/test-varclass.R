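test_that("hairpin decomposition matches a brute-force oracle", {
  mk <- wheat_markers()
  windows <- c(mk$rpl32_trnL_inversion_58, mk$ccsA_ndhD_inversion_25,
               mk$rps19_psbA_inversion_56, mk$rbcL_psaI_inversion_38,
               "ACGT", "AAAA")
  for (w in windows) {
    got <- characterize_hairpin(w)
    exp <- oracle_hairpin(w)
    expect_equal(got$stem_len, exp$stem_len)
    expect_equal(got$loop_len, exp$loop_len)
    expect_equal(2L * got$stem_len + got$loop_len, nchar(w))
  }
  expect_equal(characterize_hairpin("ACGT"),
               list(stem_len = 2L, loop_len = 0L))
  expect_equal(characterize_hairpin("AAAA"),
               list(stem_len = 0L, loop_len = 4L))
  # randomized identity: stem*2 + loop always equals the window length
  withr::with_seed(51, {
    for (i in 1:50) {
      w <- plastovar:::random_seq(sample(1:40, 1))
      hp <- characterize_hairpin(w)
      expect_equal(2L * hp$stem_len + hp$loop_len, nchar(w))
    }
  })
})

test_that("indels left-normalize to their leftmost equivalent placement", {
  ref <- "AATTTTG"
  # inserting one T anywhere in the T-run lands before the run
  for (p in 2:6) {
    nrm <- left_normalize_indel(ref, p, "T", "ins")
    expect_equal(nrm$pos, 2L)
    expect_equal(nrm$allele, "T")
  }
  # dinucleotide motif: enumerate equivalent placements directly
  ref2 <- "CATATATG"
  nrm <- left_normalize_indel(ref2, 7, "AT", "ins")
  insert_at <- function(ref, p, a) {
    paste0(substr(ref, 1, p), a, substr(ref, p + 1, nchar(ref)))
  }
  target <- insert_at(ref2, 7, "AT")
  equivalents <- Filter(function(p) {
    any(vapply(c("AT", "TA"), function(a) {
      identical(insert_at(ref2, p, a), target)
    }, logical(1)))
  }, 0:7)
  expect_equal(nrm$pos, min(unlist(equivalents)))
  # non-repetitive context stays put
  nrm <- left_normalize_indel("ACGTACGG", 4, "CCA", "ins")
  expect_equal(nrm$pos, 4L)
  expect_equal(nrm$allele, "CCA")
  # deletions shift across flanking repeats
  nrm <- left_normalize_indel("CAAAT", 3, "AA", "del")
  expect_equal(nrm$pos, 2L)
  expect_equal(nrm$allele, "AA")
})

test_that("run-length changes are reported in homopolymer notation", {
  ref <- paste0("GATC", strrep("T", 15), "GACG")
  qry <- paste0("GATC", strrep("T", 18), "GACG")
  map <- whole_genome_align(ref, qry, align_params(k = 8, max_gap_len = 100))
  g <- annotated_genome("r", ref, circular = FALSE)
  calls <- classify_all(map, g)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "homopolymer")
  expect_equal(calls$ref_allele, "15T")
  expect_equal(calls$alt_allele, "18T")
  expect_equal(calls$ref_pos, 5L)
  # shrinking run: 10A -> 9A
  ref2 <- paste0("GCTC", strrep("A", 10), "CGCG")
  qry2 <- paste0("GCTC", strrep("A", 9), "CGCG")
  map2 <- whole_genome_align(ref2, qry2, align_params(k = 8, max_gap_len = 100))
  calls2 <- classify_all(map2, annotated_genome("r", ref2, circular = FALSE))
  expect_equal(calls2$kind, "homopolymer")
  expect_equal(calls2$ref_allele, "10A")
  expect_equal(calls2$alt_allele, "9A")
})

test_that("short indels in non-repetitive context stay plain indels", {
  withr::with_seed(52, {
    g <- make_reference(5000, 0, 0, 0, seed = 53)
    specs <- sample_variant_specs(g, n_snp = 0, n_insertion = 1,
                                  n_deletion = 0, n_homopolymer = 0,
                                  n_duplication = 0, n_inversion = 0,
                                  seed = 54)
  })
  qry <- apply_variants(g, specs)$query
  calls <- classify_all(whole_genome_align(g$seq, qry), g)
  expect_equal(calls$kind, "insertion")
})

test_that("insertions equal to an adjacent segment call as duplications", {
  # published pattern: inserted TATT immediately after reference ...TATT
  core <- "GACCGTATT"
  ref <- paste0("CCTGAACGGA", core, "CAAGGCCTTAG")
  qry <- paste0("CCTGAACGGA", core, "TATT", "CAAGGCCTTAG")
  block <- data.frame(ref_start = 20L, ref_end = 19L,
                      qry_start = 20L, qry_end = 23L)
  v <- call_duplication(ref, qry, block)
  expect_equal(v$kind, "duplication")
  expect_equal(v$alt_allele, "TATT")
  # published 12-bp duplication payload
  seg <- "CTGTCATATTTT"
  ref2 <- paste0("GGAACCAGGG", seg, "GGCACTTGCA")
  qry2 <- paste0("GGAACCAGGT", seg, seg, "GGCACTTGCA")
  block2 <- data.frame(ref_start = 23L, ref_end = 22L,
                       qry_start = 23L, qry_end = 34L)
  v2 <- call_duplication(ref2, qry2, block2)
  expect_equal(v2$kind, "duplication")
  expect_equal(nchar(v2$alt_allele), 12L)
  expect_equal(v2$alt_allele, seg)
  # an insertion matching neither neighbour is not a duplication
  block3 <- data.frame(ref_start = 20L, ref_end = 19L,
                       qry_start = 20L, qry_end = 23L)
  qry3 <- paste0("CCTGAACGGA", core, "GTCA", "CAAGGCCTTAG")
  expect_null(call_duplication(ref, qry3, block3))
})

test_that("flipped printed windows are detected at their full extent", {
  mk <- wheat_markers()
  for (w in list(c(mk$rps19_psbA_inversion_56, 56L, 6L),
                 c(mk$ccsA_ndhD_inversion_25, 25L, 3L),
                 c(mk$rbcL_psaI_inversion_38, 38L, 4L))) {
    win <- w[1]
    withr::with_seed(55, {
      repeat {
        left <- plastovar:::random_seq(150)
        right <- plastovar:::random_seq(150)
        ref <- paste0(left, win, right)
        if (!plastovar:::has_inverted_repeat(left, 8) &&
            !plastovar:::has_inverted_repeat(right, 8) &&
            substr(left, 150, 150) != plastovar:::comp_base(
              substr(right, 1, 1))) break
      }
    })
    qry <- paste0(left, revcomp(win), right)
    g <- annotated_genome("r", ref, circular = FALSE)
    calls <- classify_all(whole_genome_align(ref, qry, align_params(k = 15)), g)
    expect_equal(calls$kind, "inversion")
    expect_equal(nchar(calls$ref_allele), as.integer(w[2]))
    expect_equal(calls$loop_len, as.integer(w[3]))
    expect_equal(calls$alt_allele, revcomp(calls$ref_allele))
  }
})

test_that("an isolated SNP is never promoted to an inversion", {
  withr::with_seed(56, ref <- plastovar:::random_seq(400))
  qry <- ref
  # transversion: the 1-bp window is reverse-complement-consistent
  substr(qry, 200, 200) <- plastovar:::comp_base(substr(ref, 200, 200))
  block <- data.frame(ref_start = 200L, ref_end = 200L,
                      qry_start = 200L, qry_end = 200L)
  expect_null(detect_inversion(ref, qry, block))
  g <- annotated_genome("r", ref, circular = FALSE)
  calls <- classify_all(whole_genome_align(ref, qry, align_params(k = 15)), g)
  expect_equal(calls$kind, "snp")
})

test_that("coding SNPs are translated strand-aware", {
  # plus strand: third-position change in a glycine codon is synonymous
  coding <- paste0("ATG", "GGA", "CAA", "TAA")
  feats <- data.frame(id = c("g1", "g1.cds1"), ftype = c("gene", "CDS"),
                      start = c(11L, 11L), end = c(22L, 22L), strand = "+",
                      parent = c(NA, "g1"), stringsAsFactors = FALSE)
  g <- annotated_genome("t", paste0("CCTGAACGTA", coding, "CCGGATTGCA"),
                        feats, circular = FALSE)
  v <- plastovar:::variant_record("s", "snp", 16L, "A", "G")
  av <- annotate_variant(v, g)
  expect_equal(av$locus, "Gene g1")
  expect_equal(av$aa_label, "Syn")
  # minus strand: genomic G->T flips coding CAA (Q) to AAA (K)
  coding2 <- paste0("ATG", "CAA", "TAA")
  seg <- revcomp(coding2)
  feats2 <- data.frame(id = c("g1", "g1.cds1"), ftype = c("gene", "CDS"),
                       start = c(11L, 11L), end = c(19L, 19L), strand = "-",
                       parent = c(NA, "g1"), stringsAsFactors = FALSE)
  g2 <- annotated_genome("t", paste0("CCTGAACGTA", seg, "CCGGATTGCA"),
                         feats2, circular = FALSE)
  expect_identical(substr(g2$seq, 16L, 16L), "G")
  v2 <- plastovar:::variant_record("s", "snp", 16L, "G", "T")
  av2 <- annotate_variant(v2, g2)
  expect_equal(av2$aa_label, "Q-K")
  # intergenic SNP labelled by its flanking genes
  feats3 <- rbind(feats,
                  data.frame(id = c("g2", "g2.cds1"),
                             ftype = c("gene", "CDS"),
                             start = c(31L, 31L), end = c(39L, 39L),
                             strand = "+", parent = c(NA, "g2"),
                             stringsAsFactors = FALSE))
  g3 <- annotated_genome("t", paste0("CCTGAACGTA", coding, "CCGGATTG",
                                     "ATGTGGTAACA"), feats3,
                         circular = FALSE)
  v3 <- plastovar:::variant_record("s", "snp", 25L, substr(g3$seq, 25, 25),
                                   "A")
  expect_equal(annotate_variant(v3, g3)$locus, "Intergenic g1-g2")
  # intron position between two CDS parts
  feats4 <- data.frame(
    id = c("g1", "g1.cds1", "g1.cds2"), ftype = c("gene", "CDS", "CDS"),
    start = c(11L, 11L, 31L), end = c(40L, 16L, 40L), strand = "+",
    parent = c(NA, "g1", "g1"), stringsAsFactors = FALSE)
  g4 <- annotated_genome("t", strrep("ACGTG", 12), feats4, circular = FALSE)
  v4 <- plastovar:::variant_record("s", "snp", 20L, substr(g4$seq, 20, 20),
                                   "A")
  expect_equal(annotate_variant(v4, g4)$locus, "Intron g1")
})

test_that("a CDS not divisible by three is an annotation error", {
  feats <- data.frame(id = c("g1", "g1.cds1"), ftype = c("gene", "CDS"),
                      start = c(11L, 11L), end = c(20L, 20L), strand = "+",
                      parent = c(NA, "g1"), stringsAsFactors = FALSE)
  g <- annotated_genome("t", strrep("ACGTG", 8), feats, circular = FALSE)
  v <- plastovar:::variant_record("s", "snp", 12L, substr(g$seq, 12, 12),
                                  "A")
  expect_error(annotate_variant(v, g), "not divisible by 3")
})

test_that("locus labels ignore unrelated features elsewhere", {
  withr::with_seed(57, seq <- plastovar:::random_seq(1000))
  gene <- function(id, start, end) {
    data.frame(id = c(id, paste0(id, ".cds1")), ftype = c("gene", "CDS"),
               start = start, end = end, strand = "+",
               parent = c(NA, id), stringsAsFactors = FALSE)
  }
  feats <- rbind(gene("gA", 101L, 202L), gene("gB", 501L, 602L))
  g1 <- annotated_genome("t", seq, feats, circular = FALSE)
  v <- plastovar:::variant_record("s", "snp", 300L,
                                  substr(seq, 300, 300), "A")
  lab1 <- annotate_variant(v, g1)$locus
  expect_equal(lab1, "Intergenic gA-gB")
  # a third gene outside the flanking interval does not change the label
  g2 <- annotated_genome("t", seq, rbind(feats, gene("gC", 801L, 902L)),
                         circular = FALSE)
  expect_equal(annotate_variant(v, g2)$locus, lab1)
  expect_equal(annotate_variant(plastovar:::variant_record(
    "s", "snp", 150L, substr(seq, 150, 150), "A"), g2)$locus,
    annotate_variant(plastovar:::variant_record(
      "s", "snp", 150L, substr(seq, 150, 150), "A"), g1)$locus)
})

test_that("classification is a partition with total precedence", {
  pair <- paper_table6_pair(seed = 2)
  map <- whole_genome_align(pair$reference$seq, pair$query)
  calls <- classify_all(map, pair$reference)
  expect_equal(nrow(calls), 5L)
  expect_equal(sum(calls$kind == "inversion"), 3L)
  expect_equal(sum(calls$kind == "insertion"), 2L)
  expect_setequal(nchar(calls$alt_allele[calls$kind == "insertion"]),
                  c(35L, 42L))
  expect_equal(sort(nchar(calls$ref_allele[calls$kind == "inversion"])),
               c(25L, 56L, 58L))
  expect_false(is.unsorted(calls$ref_pos))
  # inversion soundness: alt is exactly the reverse complement
  inv <- calls[calls$kind == "inversion", ]
  expect_identical(inv$alt_allele, revcomp(inv$ref_allele))
  expect_equal(2L * inv$stem_len + inv$loop_len, nchar(inv$ref_allele))
  # identical sequences classify to nothing
  empty <- classify_all(whole_genome_align(pair$reference$seq,
                                           pair$reference$seq),
                        pair$reference)
  expect_equal(nrow(empty), 0L)
})

test_that("length-changing substitutions decompose into flagged records", {
  withr::with_seed(58, {
    repeat {
      ref <- plastovar:::random_seq(600)
      if (!plastovar:::has_inverted_repeat(ref, 8)) break
    }
  })
  # replace a 6 bp reference segment by an unrelated 9 bp segment
  mid <- "CCCGGGTTT"
  qry <- paste0(substr(ref, 1, 300), mid, substr(ref, 307, 600))
  g <- annotated_genome("r", ref, circular = FALSE)
  calls <- classify_all(whole_genome_align(ref, qry, align_params(k = 15)), g)
  complex <- calls[calls$flag == "complex", ]
  if (nrow(complex) > 0L) {
    # complex blocks decompose into deletion + insertion pairs
    expect_setequal(complex$kind, c("deletion", "insertion"))
    expect_equal(sum(complex$kind == "deletion"),
                 sum(complex$kind == "insertion"))
  } else {
    # the aligner may legitimately resolve the replacement into separate
    # simple blocks; then every call must still be simple and annotated
    expect_true(all(calls$kind %in%
                      c("snp", "insertion", "deletion")))
  }
  expect_true(all(nzchar(calls$locus)))
})
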