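# column classification shared by alignment, detection and class validity:
# A_sub  <=> TR has A, VR differs and is not N
# B_sub  <=> TR has C/G/T, VR differs and neither is N
# ambiguous <=> N or gap on either side
.classifyColumns <- function(trc, vrc) {
  ifelse(trc == "-" | vrc == "-" | trc == "N" | vrc == "N", "ambiguous",
    ifelse(trc == vrc, "match",
      ifelse(trc == "A", "A_sub", "B_sub")))
}

#' Align a template repeat to a variable repeat
#'
#' Equal-length repeats are paired positionally (the DGR machinery
#' substitutes bases without indels). Otherwise the shorter sequence is
#' aligned semi-globally inside the longer one (match +1, mismatch at a
#' template adenine 0, other mismatch -2, gap -4) and columns outside the
#' overlap are excluded. Per-column substitution classes follow
#' [RepeatAlignment-class].
#'
#' @param tr Template repeat sequence.
#' @param vr Variable repeat sequence; `0.5 <= nchar(vr)/nchar(tr) <= 2`.
#' @param trFrameOffset Phase (0/1/2) of the aligned span relative to the
#'   target ORF codon grid, inherited from the VR placement (see
#'   [assembleCassettes()]).
#' @return A [RepeatAlignment-class] object.
#' @examples
#' aln <- alignTrVr("AACGGT", "TACGGT")
#' columnClasses(aln)
#' @export
alignTrVr <- function(tr, vr, trFrameOffset = 0L) {
  tr <- toupper(as.character(tr)); vr <- toupper(as.character(vr))
  if (!nzchar(tr) || !nzchar(vr)) stop("empty sequence")
  ratio <- nchar(vr) / nchar(tr)
  if (ratio < 0.5 || ratio > 2)
    stop("length ratio nchar(vr)/nchar(tr) = ", signif(ratio, 3),
         " outside [0.5, 2]")
  trFrameOffset <- as.integer(trFrameOffset)

  if (nchar(tr) == nchar(vr)) {
    trc <- .s2c(tr); vrc <- .s2c(vr)
    cls <- .classifyColumns(trc, vrc)
    score <- sum(ifelse(cls == "match", 1, ifelse(cls == "B_sub", -2, 0)))
    return(new("RepeatAlignment", trAligned = tr, vrAligned = vr,
               columnClass = cls, trFrameOffset = trFrameOffset,
               trOffset = 1L, trFull = tr, score = score))
  }

  trShorter <- nchar(tr) < nchar(vr)
  pat <- if (trShorter) tr else vr
  sub <- if (trShorter) vr else tr
  mat <- .trVrScoringMatrix(trIsPattern = trShorter)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pat), Biostrings::DNAString(sub),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 4)
  pa <- .s2c(as.character(Biostrings::alignedPattern(aln)))
  sa <- .s2c(as.character(Biostrings::alignedSubject(aln)))
  if (trShorter) {
    trA <- pa; vrA <- sa; trOffset <- 1L
  } else {
    trA <- sa; vrA <- pa
    trOffset <- Biostrings::start(Biostrings::subject(aln))
  }
  cls <- .classifyColumns(trA, vrA)
  new("RepeatAlignment", trAligned = .c2s(trA), vrAligned = .c2s(vrA),
      columnClass = cls, trFrameOffset = trFrameOffset,
      trOffset = as.integer(trOffset), trFull = tr,
      score = Biostrings::score(aln))
}

# asymmetric scoring: a substitution at a template adenine is free.
# Rows index the pattern sequence, columns the subject.
.trVrScoringMatrix <- function(trIsPattern) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  if (trIsPattern) m["A", c("C", "G", "T")] <- 0
  else m[c("C", "G", "T"), "A"] <- 0
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' @describeIn RepeatAlignment-class compact display
#' @param object A `RepeatAlignment`.
#' @export
setMethod("show", "RepeatAlignment", function(object) {
  cls <- table(factor(object@columnClass,
                      levels = c("match", "A_sub", "B_sub", "ambiguous")))
  cat("RepeatAlignment: ", length(object@columnClass), " columns (",
      paste(names(cls), as.integer(cls), sep = "=", collapse = ", "),
      "), span starts at TR position ", object@trOffset,
      ", frame offset ", object@trFrameOffset, "\n", sep = "")
})

#' Count adenines in a template repeat
#'
#' The number of mutable positions of a TR: each adenine can be substituted
#' during error-prone reverse transcription.
#'
#' @param tr Nucleotide string (may be empty).
#' @return Integer count of `A` characters.
#' @examples
#' countTrAdenines("AACAAT")  # 4
#' @export
countTrAdenines <- function(tr) {
  if (!nzchar(tr)) return(0L)
  sum(.s2c(toupper(tr)) == "A")
}

#' Nucleotide, codon and amino-acid substitution profile of a TR/VR alignment
#'
#' Counts substitution columns by class, records the fate of every
#' substituted template adenine, translates template and variable repeat
#' over all codons fully contained in the aligned span (skipping codons with
#' ambiguous columns) and tabulates amino-acid substitutions with their
#' physicochemical categories, plus the A->C/G/T counts at positions 1 and 2
#' of in-frame template AAC/AAT codons.
#'
#' @param aln A [RepeatAlignment-class].
#' @param code Genetic code table id (default `"11"`).
#' @param codonOffset Added to reported codon indices (use to express
#'   indices relative to the target ORF; default 0 reports indices within
#'   the aligned span).
#' @return A [SubstitutionProfile-class]. If the frame offset leaves no
#'   complete codon, the amino-acid fields are empty and a warning is given.
#' @examples
#' p <- substitutionProfile(alignTrVr("AAC", "TAC"))
#' aaSubstitutions(p)
#' @export
substitutionProfile <- function(aln, code = "11", codonOffset = 0L) {
  stopifnot(is(aln, "RepeatAlignment"))
  trc <- .s2c(aln@trAligned)
  vrc <- .s2c(aln@vrAligned)
  cls <- aln@columnClass
  gc <- .geneticCode(code)

  nTrA <- countTrAdenines(aln@trFull)
  nCovA <- sum(trc == "A")
  nASub <- sum(cls == "A_sub")
  nBSub <- sum(cls == "B_sub")
  # full-TR position of each alignment column (NA at TR gap columns)
  trPos <- ifelse(trc == "-", NA_integer_, cumsum(trc != "-") + aln@trOffset - 1L)
  fateIdx <- which(cls == "A_sub")
  fate <- setNames(vrc[fateIdx], trPos[fateIdx])

  firstCodonCol <- ((3L - aln@trFrameOffset) %% 3L) + 1L
  ncol <- length(cls)
  aaRows <- list()
  bias <- matrix(0L, nrow = 2, ncol = 6,
                 dimnames = list(c("AAC", "AAT"),
                                 c("pos1_C", "pos1_G", "pos1_T",
                                   "pos2_C", "pos2_G", "pos2_T")))
  codIdx <- 0L
  anyCodon <- FALSE
  colStart <- firstCodonCol
  while (colStart + 2L <= ncol) {
    colsel <- colStart:(colStart + 2L)
    codIdx <- codIdx + 1L
    ccls <- cls[colsel]
    if (!any(ccls == "ambiguous")) {
      anyCodon <- TRUE
      trCod <- .c2s(trc[colsel])
      vrCod <- .c2s(vrc[colsel])
      if (trCod %in% rownames(bias)) {
        for (p in 1:2) {
          vb <- vrc[colsel][p]
          if (vb != "A") {
            cn <- paste0("pos", p, "_", vb)
            bias[trCod, cn] <- bias[trCod, cn] + 1L
          }
        }
      }
      aaT <- unname(gc[trCod]); aaV <- unname(gc[vrCod])
      if (!is.na(aaT) && !is.na(aaV) && aaT != aaV) {
        aaRows[[length(aaRows) + 1L]] <- data.frame(
          codon_index = codIdx + as.integer(codonOffset),
          tr_codon = trCod, vr_codon = vrCod, aa_tr = aaT, aa_vr = aaV,
          adenine_only = all(ccls[ccls != "match"] == "A_sub"),
          category_vr = aaCategoryOf(aaV), stringsAsFactors = FALSE)
      }
    }
    colStart <- colStart + 3L
  }
  if (!anyCodon)
    warning("frame offset leaves no complete codon in the aligned span; ",
            "amino-acid fields are empty")
  aaSub <- if (length(aaRows)) do.call(rbind, aaRows) else
    data.frame(codon_index = integer(0), tr_codon = character(0),
               vr_codon = character(0), aa_tr = character(0),
               aa_vr = character(0), adenine_only = logical(0),
               category_vr = character(0), stringsAsFactors = FALSE)
  catLevels <- c(names(aaCategories()), "stop")
  catCounts <- setNames(integer(length(catLevels)), catLevels)
  if (nrow(aaSub)) {
    tb <- table(factor(aaSub$category_vr, levels = catLevels))
    catCounts[names(tb)] <- as.integer(tb)
  }
  new("SubstitutionProfile",
      nTrAdenines = as.integer(nTrA), nTrAdeninesCovered = as.integer(nCovA),
      nASub = as.integer(nASub), nBSub = as.integer(nBSub),
      perPositionFate = fate, aaSubstitutions = aaSub,
      aaCategoryCounts = catCounts, codonBias = bias)
}

#' Amino acids reachable from a codon by adenine substitution
#'
#' Enumerates every codon obtained by independently replacing each adenine
#' with any of A/C/G/T (non-adenine positions fixed), translates under the
#' chosen genetic code and collects the distinct residues. Stops are
#' excluded from the returned set but flagged via the `stopReachable`
#' attribute. For the Asn codons AAC and AAT — the codons in which template
#' adenines are predominantly grouped — this yields 15 residues (all but
#' Gln, Met, Lys, Glu and Trp).
#'
#' @param codon A 3-mer over \{A, C, G, T\}.
#' @param code Genetic code table id (default `"11"`).
#' @return Sorted character vector of reachable residues, with logical
#'   attribute `stopReachable`.
#' @examples
#' length(achievableResidues("AAC"))  # 15
#' achievableResidues("GGG")          # "G": no adenine to mutate
#' @export
achievableResidues <- function(codon, code = "11") {
  codon <- toupper(as.character(codon))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be a 3-mer over {A,C,G,T}")
  gc <- .geneticCode(code)
  ch <- .s2c(codon)
  apos <- which(ch == "A")
  variants <- codon
  if (length(apos)) {
    opts <- rep(list(c("A", "C", "G", "T")), length(apos))
    grid <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
    variants <- apply(grid, 1L, function(repl) {
      v <- ch
      v[apos] <- as.character(repl)
      .c2s(v)
    })
  }
  aa <- unique(unname(gc[variants]))
  res <- sort(setdiff(aa, "*"))
  attr(res, "stopReachable") <- "*" %in% aa
  res
}

#' Codon-position bias of adenine substitutions in AAC/AAT codons
#'
#' Aggregates, over one or more substitution profiles, the counts of A->C,
#' A->G and A->T at codon positions 1 and 2 within in-frame template AAC and
#' AAT codons, and reports the ratio of position-1 to position-2 A->C counts
#' (the asymmetry by which the second adenine of AAC rarely changes to
#' cytosine).
#'
#' @param profiles A [SubstitutionProfile-class] or list of them (empty list
#'   allowed).
#' @return A `data.frame` with one row per codon (`AAC`, `AAT`): the six
#'   position/base counts plus `ratio_pos1_pos2_C` (`NA` when 0/0).
#' @export
codonPositionBias <- function(profiles) {
  if (is(profiles, "SubstitutionProfile")) profiles <- list(profiles)
  tot <- matrix(0L, nrow = 2, ncol = 6,
                dimnames = list(c("AAC", "AAT"),
                                c("pos1_C", "pos1_G", "pos1_T",
                                  "pos2_C", "pos2_G", "pos2_T")))
  for (p in profiles) {
    stopifnot(is(p, "SubstitutionProfile"))
    tot <- tot + p@codonBias
  }
  ratio <- ifelse(tot[, "pos1_C"] == 0 & tot[, "pos2_C"] == 0, NA_real_,
                  tot[, "pos1_C"] / tot[, "pos2_C"])
  out <- as.data.frame(tot)
  out$codon <- rownames(tot)
  out$ratio_pos1_pos2_C <- ratio
  rownames(out) <- NULL
  out[, c("codon", colnames(tot), "ratio_pos1_pos2_C")]
}

#' Compare the mutation patterns of two VRs of the same template
#'
#' For every template adenine covered by both variable repeats, reports the
#' base observed in each VR and summarises how often mutations coincide —
#' the question of whether two targets of one cassette sample hypermutation
#' independently.
#'
#' @param aln1,aln2 [RepeatAlignment-class] objects against the same TR
#'   (identical `trFull`; otherwise an error).
#' @return A list with `positions` (a `data.frame`: `tr_pos`, `vr1`, `vr2`)
#'   and `summary` (named integer vector: `n_covered_both`, `both_mutated`,
#'   `both_same_base`, `only_one_mutated`, `neither_mutated`). Positions
#'   with `N` in either VR are dropped from the summary classes.
#' @export
compareVrPair <- function(aln1, aln2) {
  stopifnot(is(aln1, "RepeatAlignment"), is(aln2, "RepeatAlignment"))
  if (!identical(aln1@trFull, aln2@trFull))
    stop("the two alignments are not against the same template repeat")
  baseMap <- function(a) {
    trc <- .s2c(a@trAligned); vrc <- .s2c(a@vrAligned)
    ok <- trc != "-" & vrc != "-"
    pos <- cumsum(trc != "-") + a@trOffset - 1L
    setNames(vrc[ok], pos[ok])
  }
  m1 <- baseMap(aln1); m2 <- baseMap(aln2)
  trA <- which(.s2c(aln1@trFull) == "A")
  common <- intersect(intersect(names(m1), names(m2)), as.character(trA))
  common <- common[order(as.integer(common))]
  df <- data.frame(tr_pos = as.integer(common),
                   vr1 = unname(m1[common]), vr2 = unname(m2[common]),
                   stringsAsFactors = FALSE)
  ok <- df$vr1 != "N" & df$vr2 != "N"
  mut1 <- df$vr1 != "A" & ok
  mut2 <- df$vr2 != "A" & ok
  summary <- c(
    n_covered_both = nrow(df),
    both_mutated = sum(mut1 & mut2),
    both_same_base = sum(mut1 & mut2 & df$vr1 == df$vr2),
    only_one_mutated = sum(xor(mut1, mut2)),
    neither_mutated = sum(ok & !mut1 & !mut2))
  list(positions = df, summary = summary)
}
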