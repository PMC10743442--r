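# Independent reference implementations ("oracles") used to cross-check the
# package: brute-force ORF scanning, quadratic-space alignment DP, and
# exhaustive codon enumeration. These deliberately share no code with R/.

DNA4 <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomDna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

revCompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# brute-force 6-frame ORF scan: walk each frame codon by codon, opening an
# ORF at the first start codon after the previous stop
bruteForceOrfs <- function(s, minAa, code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  stops <- names(gc)[gc == "*"]
  starts <- c("ATG", "GTG", "TTG")
  L <- nchar(s)
  res <- list()
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") s else revCompStr(s)
    for (f in 0:2) {
      p <- f + 1L
      curStart <- NA_integer_
      while (p + 2L <= L) {
        cod <- substr(sc, p, p + 2L)
        if (is.na(curStart) && cod %in% starts) curStart <- p
        if (cod %in% stops) {
          if (!is.na(curStart) && (p - curStart) / 3 >= minAa) {
            b1 <- curStart; b2 <- p + 2L
            if (strand == "+") {
              res[[length(res) + 1L]] <- c(b1, b2, strand)
            } else {
              res[[length(res) + 1L]] <- c(L - b2 + 1L, L - b1 + 1L, strand)
            }
          }
          curStart <- NA_integer_
        }
        p <- p + 3L
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  df <- data.frame(start = vapply(res, function(x) as.integer(x[1]), 1L),
                   end = vapply(res, function(x) as.integer(x[2]), 1L),
                   strand = vapply(res, function(x) x[3], ""))
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# quadratic-space global affine-gap DP (gap of length L costs open + L*ext)
nwGlobalScoreRef <- function(a, b, smat, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1L) X[i, 1] <- -(go + (i - 1) * ge)
  for (j in seq_len(m) + 1L) Y[1, j] <- -(go + (j - 1) * ge)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        smat[A[i - 1], B[j - 1]]
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge,
                     X[i, j - 1] - go - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# scoring matrix of the TR/VR model, rebuilt independently: smat[vrChar, trChar]
trVrRefMatrix <- function() {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  m[c("C", "G", "T"), "A"] <- 0   # mismatch at a template adenine is free
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# quadratic-space semi-global DP: pattern global, subject ends free,
# linear gap penalty
semiGlobalScoreRef <- function(pat, sub, smat, gap = 4) {
  P <- strsplit(pat, "")[[1]]; S <- strsplit(sub, "")[[1]]
  n <- length(P); m <- length(S)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- -gap * (0:n)
  H[1, ] <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      H[i, j] <- max(H[i - 1, j - 1] + smat[P[i - 1], S[j - 1]],
                     H[i - 1, j] - gap, H[i, j - 1] - gap)
    }
  }
  max(H[n + 1, ])
}

# exhaustive oracle: residues of all 64 codons compatible with the input at
# its non-adenine positions
achievableOracle <- function(codon, code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  ch <- strsplit(codon, "")[[1]]
  fixed <- which(ch != "A")
  all64 <- names(gc)
  compat <- vapply(all64, function(c2) {
    c2c <- strsplit(c2, "")[[1]]
    all(c2c[fixed] == ch[fixed])
  }, logical(1))
  aa <- unique(unname(gc[all64[compat]]))
  sort(setdiff(aa, "*"))
}

# convenience: exact-recovery check of one simulated genome against truth
recoverSimulation <- function(seed, pSub = 0.5, qBackground = 0) {
  sim <- simulateGenome(simulationParams(seed = seed, pSub = pSub,
                                         qBackground = qBackground))
  tt <- sim$truth
  pairs <- findRepeatPairs(sim$genome)
  cas <- assembleCassettes(sim$genome, pairs, sim$orfs)
  if (length(cas) != 1L) return(FALSE)
  c1 <- cas[[1]]
  tr <- cassetteTR(c1); tg <- cassetteTargets(c1)
  if (!(GenomicRanges::start(tr) == tt$tr$start &&
        GenomicRanges::end(tr) == tt$tr$end &&
        nrow(tg) == length(tt$targets))) return(FALSE)
  for (i in seq_len(nrow(tg))) {
    t <- tg[i, ]; tru <- tt$targets[[i]]
    if (!(t$vr_start == tru$vr_start && t$vr_end == tru$vr_end &&
          t$n_A_sub == sum(tru$substitutions$type == "A") &&
          t$n_B_sub == sum(tru$substitutions$type == "background")))
      return(FALSE)
    trSeq <- substr(genomeSeq(sim$genome), GenomicRanges::start(tr),
                    GenomicRanges::end(tr))
    vrSeq <- substr(genomeSeq(sim$genome), t$vr_start, t$vr_end)
    aln <- alignTrVr(trSeq, vrSeq, trFrameOffset = t$frame_offset)
    aa <- aaSubstitutions(substitutionProfile(aln))
    tru_aa <- tru$aa_substitutions
    if (!(nrow(aa) == nrow(tru_aa) &&
          all(aa$codon_index == tru_aa$codon_index) &&
          all(aa$aa_tr == tru_aa$aa_tr) &&
          all(aa$aa_vr == tru_aa$aa_vr))) return(FALSE)
  }
  TRUE
}
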