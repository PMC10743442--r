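# a small genome with a planted exact repeat: copies are separated by random
# filler and flanked by adenine-free mismatching guards so the repeat
# boundary is unambiguous
plantedExactRepeatGenome <- function(seed = 1, repLen = 120L) {
  set.seed(seed)
  rep <- randomDna(repLen)
  genomeRecord("planted",
               paste0(randomDna(800), "GG", rep, "GG", randomDna(900),
                      "CC", rep, "CC", randomDna(800)))
}

test_that("an exact repeat copy is reported only when minASub allows it", {
  g <- plantedExactRepeatGenome(7)
  expect_identical(nrow(findRepeatPairs(g)), 0L)          # default minASub = 3
  pairs <- findRepeatPairs(g, minASub = 0)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$n_A_sub, 0L)
  expect_identical(pairs$n_B_sub, 0L)
  expect_identical(pairs$n_columns, 120L)
})

test_that("detection recovers simulated TR/VR intervals and counts exactly", {
  sim <- simulateGenome(simulationParams(seed = 7, pSub = 0.5))
  tt <- sim$truth
  pairs <- findRepeatPairs(sim$genome)
  expect_identical(nrow(pairs), 2L)
  expect_identical(pairs$tr_end, rep(tt$tr$end, 2L))
  expect_identical(pairs$vr_start,
                   vapply(tt$targets, function(t) t$vr_start, 1L))
  expect_identical(pairs$vr_end,
                   vapply(tt$targets, function(t) t$vr_end, 1L))
  expect_identical(pairs$n_A_sub,
                   vapply(tt$targets, function(t)
                     sum(t$substitutions$type == "A"), 1L))
  expect_true(all(pairs$n_B_sub == 0L))
})

test_that("the TR copy is designated correctly on clean simulations", {
  for (seed in 20:24) {
    sim <- simulateGenome(simulationParams(seed = seed, pSub = 0.5,
                                           qBackground = 0))
    pairs <- findRepeatPairs(sim$genome)
    expect_true(all(pairs$tr_start >= sim$truth$tr$start - 1L &
                    pairs$tr_end <= sim$truth$tr$end + 1L),
                info = paste("seed", seed))
  }
})

test_that("no reported pair exceeds the configured B-substitution fraction", {
  for (seed in 30:33) {
    sim <- simulateGenome(simulationParams(seed = seed, pSub = 0.4,
                                           qBackground = 0.02))
    pairs <- findRepeatPairs(sim$genome, maxBSubFrac = 0.1)
    if (nrow(pairs))
      expect_true(all(pairs$n_B_sub / pairs$n_columns <= 0.1))
  }
})

test_that("reverse-complementing the genome maps cassettes by x -> L - x + 1", {
  sim <- simulateGenome(simulationParams(seed = 3))
  g <- sim$genome
  L <- genomeLength(g)
  fwd <- findRepeatPairs(g)
  rev <- findRepeatPairs(genomeRecord("rc", revCompStr(genomeSeq(g))))
  expect_identical(nrow(fwd), nrow(rev))
  key <- function(df, s, e) paste(df[[s]], df[[e]])
  mapped <- paste(L - rev$tr_end + 1L, L - rev$tr_start + 1L)
  expect_setequal(mapped, key(fwd, "tr_start", "tr_end"))
  mappedVr <- paste(L - rev$vr_end + 1L, L - rev$vr_start + 1L)
  expect_setequal(mappedVr, key(fwd, "vr_start", "vr_end"))
  expect_identical(sort(fwd$n_A_sub), sort(rev$n_A_sub))
  expect_true(all(rev$tr_strand == "-"))
})

test_that("detection is invariant to rotation of a circular genome", {
  sim <- simulateGenome(simulationParams(seed = 5))
  s <- genomeSeq(sim$genome)
  rot <- paste0(substr(s, 1001, nchar(s)), substr(s, 1, 1000))
  fwd <- findRepeatPairs(sim$genome)
  shifted <- findRepeatPairs(genomeRecord("rot", rot, topology = "circular"))
  expect_identical(nrow(fwd), nrow(shifted))
  expect_setequal(paste(shifted$tr_start + 1000L, shifted$vr_start + 1000L),
                  paste(fwd$tr_start, fwd$vr_start))
})

test_that("inverted repeat pairs are found and oriented", {
  sim <- simulateGenome(simulationParams(seed = 9, dualTarget = FALSE))
  tt <- sim$truth
  s <- genomeSeq(sim$genome)
  # flip the VR1 locus in place: the pair becomes an inverted repeat
  t1 <- tt$targets[[1]]
  vr <- substr(s, t1$vr_start, t1$vr_end)
  flipped <- paste0(substr(s, 1, t1$vr_start - 1), revCompStr(vr),
                    substr(s, t1$vr_end + 1, nchar(s)))
  pairs <- findRepeatPairs(genomeRecord("inv", flipped))
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$orientation, "inverted")
  # the flip makes the flanking guards complementary, so the repeat is
  # genuinely a little longer than the planted VR; the detected intervals
  # must contain the true ones with only modest boundary extension
  expect_lte(pairs$tr_start, tt$tr$start)
  expect_gte(pairs$tr_end, tt$tr$end)
  expect_lte(pairs$vr_start, t1$vr_start)
  expect_gte(pairs$vr_end, t1$vr_end)
  expect_lte(pairs$n_columns, (tt$tr$end - tt$tr$start + 1L) + 30L)
  expect_true(pairs$tr_strand != pairs$vr_strand)
})

test_that("cassette assembly groups dual targets on one TR and assigns RT", {
  sim <- simulateGenome(simulationParams(seed = 1))
  pairs <- findRepeatPairs(sim$genome)
  cas <- assembleCassettes(sim$genome, pairs, sim$orfs)
  expect_length(cas, 1L)
  tg <- cassetteTargets(cas[[1]])
  expect_identical(nrow(tg), 2L)
  expect_setequal(tg$vr_position_class, c("five_prime", "three_prime"))
  expect_true(all(tg$frame_offset == 0L))
  expect_length(cassetteRT(cas[[1]]), 1L)
  expect_true(grepl("reverse transcriptase",
                    S4Vectors::mcols(cassetteRT(cas[[1]]))$label))
  # every VR lies fully within its target ORF
  expect_true(all(tg$vr_start >= tg$orf_start & tg$vr_end <= tg$orf_end))
})

test_that("disjoint TRs become separate cassettes and orphan VRs are flagged", {
  sim <- simulateGenome(simulationParams(seed = 2))
  orfs <- sim$orfs
  pairs <- data.frame(
    genome_id = genomeId(sim$genome),
    tr_start = c(100L, 5000L), tr_end = c(219L, 5119L),
    tr_strand = "+",
    vr_start = c(sim$truth$targets[[1]]$vr_start, 20000L),
    vr_end = c(sim$truth$targets[[1]]$vr_end, 20119L),
    vr_strand = "+", orientation = "direct",
    n_columns = 120L, n_match = 110L, n_A_sub = 10L, n_B_sub = 0L,
    n_ambiguous = 0L, score = 110, stringsAsFactors = FALSE)
  expect_warning(cas <- assembleCassettes(sim$genome, pairs, orfs),
                 "not contained in any annotated ORF")
  expect_length(cas, 2L)
  flags <- unlist(lapply(cas, function(c) cassetteTargets(c)$excluded))
  expect_identical(sum(flags), 1L)
  orphan <- cassetteTargets(cas[[2]])
  expect_identical(orphan$orf_label, "none")
})

test_that("contig screening requires all marker labels", {
  mk <- function(id, labels) {
    g <- genomeRecord(id, randomDna(300))
    orfs <- GenomicRanges::GRanges(
      seqnames = id,
      ranges = IRanges::IRanges(start = seq(1, by = 30, length.out = length(labels)),
                                width = 21),
      strand = "+", protein = "M", label = labels)
    list(g = g, orfs = orfs)
  }
  set.seed(77)
  a <- mk("a", c("portal protein", "large terminase subunit", "other"))
  b <- mk("b", c("portal protein"))
  c <- mk("c", c("Large Terminase Subunit precursor", "phage portal protein"))
  recs <- list(a$g, b$g, c$g)
  orfs <- list(a = a$orfs, b = b$orfs, c = c$orfs)
  expect_setequal(screenPhageContigs(recs, orfs), c("a", "c"))
  expect_identical(screenPhageContigs(recs, orfs,
                                      requiredLabels = "portal protein"),
                   c("a", "b", "c"))
})
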