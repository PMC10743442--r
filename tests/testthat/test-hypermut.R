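test_that("equal-length TR/VR pairs are classified positionally", {
  aln <- alignTrVr("AACGGT", "TACGGT")
  expect_identical(columnClasses(aln),
                   c("A_sub", rep("match", 5)))
  aln2 <- alignTrVr("GGC", "GTC")
  expect_identical(columnClasses(aln2), c("match", "B_sub", "match"))
  alnN <- alignTrVr("AAC", "ANC")
  expect_identical(columnClasses(alnN), c("match", "ambiguous", "match"))
  expect_error(alignTrVr("AACAACAAC", "ACG"), "ratio")
})

test_that("shorter repeats align semi-globally inside the longer one", {
  aln <- alignTrVr("AACAAC", "AAC")
  expect_identical(nColumns(aln), 3L)
  prof <- substitutionProfile(aln)
  expect_identical(prof@nTrAdenines, 4L)
  expect_identical(prof@nTrAdeninesCovered, 2L)
})

test_that("semi-global alignment scores match the quadratic DP reference", {
  set.seed(505)
  sm <- trVrRefMatrix()
  for (i in 1:20) {
    tr <- randomDna(sample(90:150, 1))
    vr <- randomDna(sample(75:89, 1))
    aln <- alignTrVr(tr, vr)
    expect_equal(aln@score, semiGlobalScoreRef(vr, tr, sm), ignore_attr = TRUE)
  }
})

test_that("column class conservation holds on random alignments", {
  set.seed(606)
  for (i in 1:50) {
    aln <- alignTrVr(randomDna(90), randomDna(90))
    cls <- table(factor(columnClasses(aln),
                        levels = c("match", "A_sub", "B_sub", "ambiguous")))
    expect_identical(sum(cls), 90L)
    prof <- substitutionProfile(aln)
    expect_identical(prof@nASub + prof@nBSub +
                       as.integer(cls[["match"]]) + as.integer(cls[["ambiguous"]]),
                     90L)
  }
})

test_that("countTrAdenines counts mutable positions", {
  expect_identical(countTrAdenines("AACAAT"), 4L)
  expect_identical(countTrAdenines(""), 0L)
  expect_identical(countTrAdenines("ccggtt"), 0L)
})

test_that("substitutionProfile reports aa substitutions with categories", {
  prof <- substitutionProfile(alignTrVr("AAC", "TAC"))
  aa <- aaSubstitutions(prof)
  expect_identical(nrow(aa), 1L)
  expect_identical(aa$aa_tr, "N")
  expect_identical(aa$aa_vr, "Y")
  expect_identical(aa$codon_index, 1L)
  expect_true(aa$adenine_only)
  expect_identical(unname(prof@aaCategoryCounts[["aromatic"]]), 1L)
  # identity alignment gives the zero profile
  z <- substitutionProfile(alignTrVr("AACGGTTAC", "AACGGTTAC"))
  expect_identical(z@nASub, 0L)
  expect_identical(z@nBSub, 0L)
  expect_identical(nrow(aaSubstitutions(z)), 0L)
  expect_identical(sum(z@aaCategoryCounts), 0L)
})

test_that("profiles computed on simulated cassettes equal the truth record", {
  sim <- simulateGenome(simulationParams(seed = 7, pSub = 0.5))
  tt <- sim$truth
  s <- genomeSeq(sim$genome)
  for (tru in tt$targets) {
    trCov <- substr(tt$tr$seq, tru$tr_offset, nchar(tt$tr$seq))
    vr <- substr(s, tru$vr_start, tru$vr_end)
    prof <- substitutionProfile(alignTrVr(trCov, vr))
    expect_identical(prof@nASub, sum(tru$substitutions$type == "A"))
    expect_identical(prof@nBSub, sum(tru$substitutions$type == "background"))
    aa <- aaSubstitutions(prof)
    expect_identical(aa$codon_index, tru$aa_substitutions$codon_index)
    expect_identical(aa$aa_tr, tru$aa_substitutions$aa_tr)
    expect_identical(aa$aa_vr, tru$aa_substitutions$aa_vr)
    # per-position adenine fates match the recorded substitutions
    asubs <- tru$substitutions[tru$substitutions$type == "A", ]
    expect_identical(unname(prof@perPositionFate[as.character(asubs$pos)]),
                     asubs$vr_base)
  }
})

test_that("a frame offset leaving no full codon warns and yields empty aa fields", {
  expect_warning(prof <- substitutionProfile(alignTrVr("CC", "GC")),
                 "no complete codon")
  expect_identical(nrow(aaSubstitutions(prof)), 0L)
  expect_identical(prof@nBSub, 1L)
})

test_that("shifting the alignment by one codon shifts aa indices by one", {
  set.seed(707)
  sim <- simulateGenome(simulationParams(seed = 42, pSub = 0.8))
  tr <- sim$truth$tr$seq
  vr <- substr(genomeSeq(sim$genome), sim$truth$targets[[1]]$vr_start,
               sim$truth$targets[[1]]$vr_end)
  a1 <- aaSubstitutions(substitutionProfile(alignTrVr(tr, vr)))
  a2 <- aaSubstitutions(substitutionProfile(
    alignTrVr(substr(tr, 4, nchar(tr)), substr(vr, 4, nchar(vr)))))
  keep <- a1$codon_index > 1L
  expect_identical(a2$codon_index, a1$codon_index[keep] - 1L)
  expect_identical(a2$aa_vr, a1$aa_vr[keep])
})

test_that("achievableResidues matches the 15-residue Asn-codon repertoire", {
  r <- achievableResidues("AAC")
  expect_length(r, 15L)
  expect_identical(as.character(r),
                   sort(c("N", "T", "S", "I", "H", "P", "R", "L", "D", "A",
                          "G", "V", "Y", "C", "F")))
  expect_length(intersect(r, c("Q", "M", "K", "E", "W")), 0L)
  expect_false(attr(r, "stopReachable"))
  expect_identical(as.character(achievableResidues("AAT")), as.character(r))
  expect_identical(as.character(achievableResidues("GGG")), "G")
  expect_true(attr(achievableResidues("AAA"), "stopReachable"))
  expect_error(achievableResidues("AXC"), "3-mer")
})

test_that("achievableResidues equals brute-force enumeration for all codons", {
  for (codon in as.vector(outer(outer(DNA4, DNA4, paste0), DNA4, paste0))) {
    expect_identical(as.character(achievableResidues(codon)),
                     achievableOracle(codon), info = codon)
  }
})

test_that("codons without adenine have a single achievable residue", {
  noA <- grep("A", as.vector(outer(outer(DNA4, DNA4, paste0), DNA4, paste0)),
              invert = TRUE, value = TRUE, fixed = TRUE)
  for (codon in setdiff(noA, c("TGA"))) {
    expect_length(achievableResidues(codon), 1L)
  }
})

test_that("codonPositionBias counts position-specific A fates in AAC/AAT", {
  p <- substitutionProfile(alignTrVr("AAC", "CAC"))
  tb <- codonPositionBias(p)
  expect_identical(tb$pos1_C[tb$codon == "AAC"], 1L)
  expect_identical(tb$pos2_C[tb$codon == "AAC"], 0L)
  empty <- codonPositionBias(list())
  expect_true(all(empty[, c("pos1_C", "pos2_C")] == 0L))
  expect_true(all(is.na(empty$ratio_pos1_pos2_C)))
})

test_that("position-asymmetric substitution weights are recovered from sims", {
  # adenines may only mutate to C at codon position 1 and to G at position 2
  bw <- matrix(c(1, 0, 0,   0, 1, 0,   0, 0, 1), nrow = 3, byrow = FALSE,
               dimnames = list(NULL, c("C", "G", "T")))
  bw[1, ] <- c(1, 0, 0); bw[2, ] <- c(0, 1, 0); bw[3, ] <- c(0, 0, 1)
  sim <- simulateGenome(simulationParams(seed = 11, pSub = 0.9,
                                         baseWeights = bw,
                                         pairCodons = "AAC"))
  tr <- sim$truth$tr$seq
  vr <- substr(genomeSeq(sim$genome), sim$truth$targets[[1]]$vr_start,
               sim$truth$targets[[1]]$vr_end)
  tb <- codonPositionBias(substitutionProfile(alignTrVr(tr, vr)))
  aac <- tb[tb$codon == "AAC", ]
  expect_identical(aac$pos1_G + aac$pos1_T, 0L)
  expect_identical(aac$pos2_C + aac$pos2_T, 0L)
  subs <- sim$truth$targets[[1]]$substitutions
  expect_identical(aac$pos1_C + aac$pos2_G, sum(subs$type == "A"))
})

test_that("compareVrPair summarises shared mutations against one TR", {
  tr <- "AACGGTAACGGT"
  expect_identical(
    compareVrPair(alignTrVr(tr, tr), alignTrVr(tr, tr))$summary[["both_mutated"]],
    0L)
  vr1 <- "AACGTTAACGGT"  # no adenine change, one B sub
  cmp <- compareVrPair(alignTrVr(tr, vr1), alignTrVr(tr, tr))
  expect_identical(cmp$summary[["both_mutated"]], 0L)
  # both VRs carry A->T at the same position
  vrA <- "TACGGTAACGGT"; vrB <- "TACGGTAACGGT"
  cmp2 <- compareVrPair(alignTrVr(tr, vrA), alignTrVr(tr, vrB))
  expect_identical(cmp2$summary[["both_mutated"]], 1L)
  expect_identical(cmp2$summary[["both_same_base"]], 1L)
  expect_error(compareVrPair(alignTrVr("AAC", "AAC"), alignTrVr("AAG", "AAG")),
               "same template")
})

test_that("independent mutagenesis of two VRs matches direct enumeration", {
  sim <- simulateGenome(simulationParams(seed = 3, pSub = 0.5))
  tt <- sim$truth
  s <- genomeSeq(sim$genome)
  tr <- tt$tr$seq
  aln1 <- alignTrVr(tr, substr(s, tt$targets[[1]]$vr_start,
                               tt$targets[[1]]$vr_end))
  aln2 <- alignTrVr(tr, substr(s, tt$targets[[2]]$vr_start,
                               tt$targets[[2]]$vr_end))
  cmp <- compareVrPair(aln1, aln2)
  # enumerate directly from the truth records over the common covered span
  covered <- tt$targets[[2]]$tr_offset:nchar(tr)
  trA <- intersect(which(strsplit(tr, "")[[1]] == "A"), covered)
  s1 <- tt$targets[[1]]$substitutions
  s2 <- tt$targets[[2]]$substitutions
  m1 <- trA %in% s1$pos[s1$type == "A"]
  m2 <- trA %in% s2$tr_pos[s2$type == "A"]
  expect_identical(cmp$summary[["n_covered_both"]], length(trA))
  expect_identical(cmp$summary[["both_mutated"]], sum(m1 & m2))
  expect_identical(cmp$summary[["only_one_mutated"]], sum(xor(m1, m2)))
  b1 <- setNames(s1$vr_base[s1$type == "A"], s1$pos[s1$type == "A"])
  b2 <- setNames(s2$vr_base[s2$type == "A"], s2$tr_pos[s2$type == "A"])
  same <- sum(m1 & m2 &
                b1[as.character(trA)] == b2[as.character(trA)], na.rm = TRUE)
  expect_identical(cmp$summary[["both_same_base"]], same)
})

test_that("histidine is categorised as positive and stops are flagged", {
  expect_identical(aaCategoryOf("H"), "positive")
  expect_identical(aaCategoryOf("*"), "stop")
  expect_identical(aaCategoryOf(c("F", "D", "K", "C", "V", "S")),
                   c("aromatic", "negative", "positive", "cysteine",
                     "hydrophobic_nonaromatic", "hydrophilic_uncharged"))
  expect_setequal(unlist(aaCategories()), AA20)
})
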