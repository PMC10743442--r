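test_that("readFasta parses, uppercases and maps U to T, preserving order", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "acgu", ">y", "GGTT", "AACC"), f)
  recs <- readFasta(f)
  expect_length(recs, 2L)
  expect_identical(genomeId(recs[[1]]), "x")
  expect_identical(genomeSeq(recs[[1]]), "ACGT")
  expect_identical(genomeLength(recs[[1]]), 4L)
  expect_identical(genomeId(recs[[2]]), "y")
  expect_identical(genomeSeq(recs[[2]]), "GGTTAACC")
})

test_that("readFasta rejects invalid characters and empty sequences by name", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACJT"), f)
  expect_error(readFasta(f), "bad.*J|J.*bad")
  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">empty", "", ">ok", "ACGT"), f2)
  expect_error(readFasta(f2), "empty")
  expect_error(readFasta(tempfile()), "not found")
})

test_that("FASTA round trip reproduces sequences byte-identically", {
  set.seed(101)
  recs <- lapply(1:3, function(i) genomeRecord(paste0("g", i), randomDna(150)))
  f <- tempfile(fileext = ".fasta")
  writeFasta(recs, f)
  back <- readFasta(f)
  expect_identical(vapply(back, genomeSeq, ""), vapply(recs, genomeSeq, ""))
  expect_identical(vapply(back, genomeId, ""), vapply(recs, genomeId, ""))
})

test_that("GenomeRecord enforces its alphabet and topology", {
  expect_error(genomeRecord("x", "ACGTX"), "outside")
  expect_error(genomeRecord("x", "ACGT", topology = "weird"), "topology")
  g <- genomeRecord("x", "acgtn")
  expect_identical(genomeSeq(g), "ACGTN")
})

test_that("readGenBank parses plus, complement and two-segment join CDS", {
  gbk <- system.file("extdata", "synthetic_phage.gbk", package = "DGRtools")
  rec <- readGenBank(gbk)
  expect_identical(genomeLength(rec$genome), 360L)
  expect_identical(genomeId(rec$genome), "SYNPHAGE")
  orfs <- rec$orfs
  expect_length(orfs, 3L)
  expect_identical(GenomicRanges::start(orfs), c(4L, 101L, 200L))
  expect_identical(GenomicRanges::end(orfs), c(63L, 157L, 250L))
  expect_identical(as.character(GenomicRanges::strand(orfs)), c("+", "-", "+"))
  lb <- S4Vectors::mcols(orfs)$label
  expect_true(any(grepl("portal protein", lb)))
  expect_true(any(grepl("large terminase subunit", lb)))
  # CDS on the minus strand translates from the reverse complement
  p2 <- S4Vectors::mcols(orfs)$protein[2]
  cds2 <- revCompStr(substr(genomeSeq(rec$genome), 101, 157))
  expect_identical(p2, sub("\\*$", "", translateSeq(cds2)))
  expect_false(grepl("\\*", S4Vectors::mcols(orfs)$protein[3]))
})

test_that("readGenBank requires an ORIGIN block", {
  f <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X 10 bp DNA linear", "//"), f)
  expect_error(readGenBank(f), "ORIGIN")
})

test_that("translateSeq follows table 11 and rejects partial codons", {
  expect_identical(translateSeq("AAC"), "N")
  expect_identical(translateSeq("AATAAC"), "NN")
  expect_identical(translateSeq("TACTGC"), "YC")
  expect_identical(translateSeq("TAA"), "*")
  expect_identical(translateSeq("ATGANC"), "MX")
  expect_error(translateSeq("ACGT"), "multiple of 3")
})

test_that("findOrfs reports complete ORFs with strand symmetry", {
  orfs <- findOrfs(genomeRecord("g", "ATGAAATAA"), minAa = 2)
  expect_length(orfs, 1L)
  expect_identical(S4Vectors::mcols(orfs)$protein, "MK")
  expect_identical(GenomicRanges::start(orfs), 1L)
  expect_identical(GenomicRanges::end(orfs), 9L)
  rc <- findOrfs(genomeRecord("g", revCompStr("ATGAAATAA")), minAa = 2)
  expect_length(rc, 1L)
  expect_identical(as.character(GenomicRanges::strand(rc)), "-")
  expect_identical(S4Vectors::mcols(rc)$protein, "MK")
})

test_that("findOrfs matches a brute-force 6-frame scan on random genomes", {
  set.seed(202)
  for (i in 1:25) {
    s <- randomDna(1000)
    got <- findOrfs(s, minAa = 20)
    df <- data.frame(start = GenomicRanges::start(got),
                     end = GenomicRanges::end(got),
                     strand = as.character(GenomicRanges::strand(got)))
    df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
    ref <- bruteForceOrfs(s, minAa = 20)
    expect_equal(unname(as.matrix(df)), unname(as.matrix(ref)))
  }
})

test_that("ORF coordinates are consistent: slice, translate, compare", {
  sim <- simulateGenome(simulationParams(seed = 12))
  orfs <- sim$orfs
  for (i in seq_along(orfs)) {
    cds <- substr(genomeSeq(sim$genome), GenomicRanges::start(orfs)[i],
                  GenomicRanges::end(orfs)[i])
    if (as.character(GenomicRanges::strand(orfs))[i] == "-") cds <- revCompStr(cds)
    expect_identical(translateSeq(cds),
                     paste0(S4Vectors::mcols(orfs)$protein[i], "*"))
  }
})

test_that("pairwiseIdentity handles the trivial cases and is symmetric", {
  expect_equal(pairwiseIdentity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(pairwiseIdentity("AAAA", "TTTT"), 0.0)
  expect_equal(pairwiseIdentity("MKLV", "MKLV", mode = "protein"), 1.0)
  expect_error(pairwiseIdentity("", "ACGT"), "empty")
  set.seed(303)
  for (i in 1:20) {
    a <- randomDna(60); b <- randomDna(60)
    expect_identical(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  }
})

test_that("global alignment scores match the quadratic-space DP reference", {
  set.seed(404)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  sm <- mat[DNA4, DNA4]
  for (i in 1:20) {
    a <- randomDna(60); b <- randomDna(60)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(min(a, b)), Biostrings::DNAString(max(a, b)),
      type = "global", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), nwGlobalScoreRef(min(a, b), max(a, b),
                                                          sm, 10, 0.5))
  }
})
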