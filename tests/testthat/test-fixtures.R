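test_that("make_reference is deterministic and seed-sensitive", {
  g1 <- make_reference(30000, 10, 5, 3, seed = 1)
  g2 <- make_reference(30000, 10, 5, 3, seed = 1)
  g3 <- make_reference(30000, 10, 5, 3, seed = 2)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$features, g2$features)
  expect_false(identical(g1$seq, g3$seq))
  expect_equal(sum(g1$features$ftype == "gene"), 10L)
  # at least one intron-bearing gene: a gene with two CDS parts
  parts_per_gene <- table(g1$features$parent[g1$features$ftype == "CDS"])
  expect_true(any(parts_per_gene >= 2L))
  expect_equal(nrow(g1$runs), 5L)
  expect_true(all(g1$runs$len >= 8L))
  expect_equal(nrow(g1$palindromes), 3L)
})

test_that("a featureless request gives a plain random sequence", {
  g <- make_reference(1000, 0, 0, 0, seed = 7)
  expect_equal(nchar(g$seq), 1000L)
  expect_equal(nrow(g$features), 0L)
  expect_false(grepl("[^ACGT]", g$seq))
})

test_that("infeasible packing errors name the constraint", {
  expect_error(make_reference(1000, n_genes = 20, seed = 1),
               "cannot pack")
})

test_that("embedded palindromes decompose to their planted stem and loop", {
  g <- make_reference(20000, 0, 0, 6, seed = 11)
  for (i in seq_len(nrow(g$palindromes))) {
    p <- g$palindromes[i, ]
    w <- substr(g$seq, p$start, p$end)
    hp <- characterize_hairpin(w)
    expect_equal(hp$stem_len, p$stem_len)
    expect_equal(hp$loop_len, p$loop_len)
    expect_equal(2L * hp$stem_len + hp$loop_len, nchar(w))
  }
})

test_that("apply_variants edits each class as specified", {
  g <- make_reference(2000, 0, 1, 1, seed = 3)
  n <- nchar(g$seq)
  # inversion over the embedded window reads as the reverse complement
  p <- g$palindromes[1, ]
  w <- p$end - p$start + 1L
  res <- apply_variants(g, variant_spec("inversion", p$start, window_len = w))
  expect_identical(substr(res$query, p$start, p$end),
                   revcomp(substr(g$seq, p$start, p$end)))
  expect_identical(substr(res$query, 1, p$start - 1L),
                   substr(g$seq, 1, p$start - 1L))
  # empty spec list is the identity
  res0 <- apply_variants(g, g$runs[0, 0])
  expect_identical(res0$query, g$seq)
  # snp / insertion / deletion surgery
  base <- substr(g$seq, 500, 500)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  res1 <- apply_variants(g, variant_spec("snp", 500, alt))
  expect_identical(substr(res1$query, 500, 500), alt)
  expect_equal(nchar(res1$query), n)
  res2 <- apply_variants(g, variant_spec("insertion", 500, "ACGT"))
  expect_equal(nchar(res2$query), n + 4L)
  expect_identical(substr(res2$query, 501, 504), "ACGT")
  seg <- substr(g$seq, 500, 503)
  res3 <- apply_variants(g, variant_spec("deletion", 500, seg))
  expect_equal(nchar(res3$query), n - 4L)
  # homopolymer delta rewrites the run
  r <- g$runs[1, ]
  res4 <- apply_variants(g, variant_spec("homopolymer", r$start, "+3"))
  expect_equal(nchar(res4$query), n + 3L)
  expect_identical(substr(res4$query, r$start, r$end + 3L),
                   strrep(r$base, r$len + 3L))
  # duplication doubles the segment in place
  seg <- substr(g$seq, 1200, 1205)
  res5 <- apply_variants(g, variant_spec("duplication", 1200, seg))
  expect_identical(substr(res5$query, 1200, 1211), strrep(seg, 2L))
})

test_that("overlapping or out-of-range specs are rejected with row numbers", {
  g <- make_reference(2000, 0, 0, 0, seed = 4)
  s1 <- rbind(variant_spec("deletion", 100, substr(g$seq, 100, 109)),
              variant_spec("snp", 105, "A"))
  expect_error(apply_variants(g, s1), "overlapping.*rows: 1, 2")
  expect_error(apply_variants(g, variant_spec("snp", 99999, "A")),
               "out of reference range")
  expect_error(
    apply_variants(g, rbind(variant_spec("snp", 500, "A"),
                            variant_spec("snp", 100, "C"))),
    "sorted")
})

test_that("twenty random SNP specs give exactly twenty mismatched positions", {
  g <- make_reference(30000, 0, 0, 0, seed = 5)
  specs <- sample_variant_specs(g, n_snp = 20, n_insertion = 0,
                                n_deletion = 0, n_homopolymer = 0,
                                n_duplication = 0, n_inversion = 0,
                                seed = 6)
  res <- apply_variants(g, specs)
  rc <- strsplit(g$seq, "")[[1]]
  qc <- strsplit(res$query, "")[[1]]
  expect_equal(sum(rc != qc), 20L)
  expect_setequal(which(rc != qc), specs$ref_pos)
})

test_that("truth tables round-trip through apply_variants and TSV", {
  g <- make_reference(20000, 5, 3, 2, seed = 8)
  specs <- sample_variant_specs(g, n_snp = 5, n_insertion = 1,
                                n_deletion = 1, n_homopolymer = 1,
                                n_duplication = 1, n_inversion = 1,
                                seed = 9)
  res <- apply_variants(g, specs)
  replay <- apply_variants(g, res$truth$specs)
  expect_identical(replay$query, res$query)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(res$truth, path)
  back <- read_truth_table(path)
  expect_equal(back, res$truth$specs, ignore_attr = TRUE)
  replay2 <- apply_variants(g, back)
  expect_identical(replay2$query, res$query)
})

test_that("the printed-marker pair embeds all five variants cleanly", {
  pair <- paper_table6_pair(seed = 1)
  expect_equal(nrow(pair$truth$specs), 5L)
  expect_equal(sort(table(pair$truth$specs$kind), decreasing = TRUE),
               sort(c(inversion = 3L, insertion = 2L), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_false(identical(pair$reference$seq, pair$query))
  mk <- wheat_markers()
  # reference embeds the inversion windows; query carries the insertions
  expect_true(grepl(mk$ccsA_ndhD_inversion_25, pair$reference$seq,
                    fixed = TRUE))
  expect_true(grepl(mk$rpl22_insertion_35, pair$query, fixed = TRUE))
  expect_true(grepl(mk$wknox1d_intron4_insertion_42, pair$query,
                    fixed = TRUE))
  # flanks near each embedded window are free of stem >= 8 inverted repeats
  inv <- pair$truth$specs[pair$truth$specs$kind == "inversion", ]
  for (i in seq_len(nrow(inv))) {
    a <- inv$ref_pos[i]
    b <- a + inv$window_len[i] - 1L
    left <- substr(pair$reference$seq, max(1, a - 100), a - 1)
    right <- substr(pair$reference$seq, b + 1,
                    min(nchar(pair$reference$seq), b + 100))
    expect_false(plastovar:::has_inverted_repeat(left, 8))
    expect_false(plastovar:::has_inverted_repeat(right, 8))
  }
})

test_that("the packaged wheat SNP matrix matches its published shape", {
  m <- paper_table4_matrix()
  expect_equal(nrow(m$sites), 34L)
  expect_equal(length(m$samples), 20L)
  site <- m$sites[m$sites$ref_pos == 2903, ]
  expect_equal(site$locus, "Gene matK")
  expect_equal(site$ref_allele, "G")
  expect_identical(unname(m$alleles["2903", "CS"]), "G")
  expect_identical(unname(m$alleles["2903", "Com2"]), "C")
  # every site carries at least one non-reference sample
  has_alt <- vapply(seq_len(nrow(m$sites)), function(i) {
    any(m$alleles[i, ] != m$sites$ref_allele[i])
  }, logical(1))
  expect_true(all(has_alt))
})
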