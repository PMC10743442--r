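#' Find TR/VR repeat pairs under the adenine-asymmetric mismatch model
#'
#' Seed-and-extend scan for DGR-type repeat pairs. Seeds are exact k-mer
#' matches (default k = 12) taken from adenine-free windows of the putative
#' template copy (windows free of A, or free of T for minus-strand readings);
#' extension is ungapped and run once per reading strand, with score +1 for
#' a match, 0 for a mismatch that could sit at a template adenine of that
#' reading (a column involving A for the plus reading, T for the minus
#' reading) and -2 for any other mismatch.
#' An extended pair is reported when its length falls in
#' `[minLen, maxLen]`, its fraction of non-adenine ("B") substitutions is at
#' most `maxBSubFrac`, and it carries at least `minASub` adenine
#' substitutions. The copy designated TR is the one in which at least
#' `designationFrac` (default 80%) of mismatched columns carry an adenine,
#' evaluated over both reading strands; pairs fitting no reading are dropped.
#' Overlapping reports are merged keeping the highest-scoring extension.
#' Both direct and inverted (reverse-complement) repeat pairs are scanned.
#'
#' @param genome A [GenomeRecord-class] (or nucleotide string).
#' @param minLen,maxLen Accepted repeat length range in bp
#'   (50 <= minLen <= maxLen <= 300; defaults 100/150, the canonical TR size).
#' @param maxBSubFrac Maximum fraction of columns with non-adenine
#'   substitutions (default 0.1).
#' @param minASub Minimum number of adenine-substitution columns (default 3).
#' @param k Seed length (default 12).
#' @param xDrop Extension stops when the running score drops this far below
#'   its maximum (default 20).
#' @param designationFrac Minimum fraction of mismatch columns carrying A in
#'   the template copy for TR designation (default 0.8).
#' @param scanInverted Also scan for inverted repeat pairs (default TRUE).
#' @return A `data.frame` with one row per repeat pair: `genome_id`,
#'   `tr_start`, `tr_end`, `tr_strand`, `vr_start`, `vr_end`, `vr_strand`,
#'   `orientation` (`direct`/`inverted`), `n_columns`, `n_match`, `n_A_sub`,
#'   `n_B_sub`, `n_ambiguous`, `score` (1-based inclusive coordinates).
#'   Zero rows when nothing is found.
#' @seealso [assembleCassettes()], [simulateGenome()]
#' @export
findRepeatPairs <- function(genome, minLen = 100L, maxLen = 150L,
                            maxBSubFrac = 0.1, minASub = 3L, k = 12L,
                            xDrop = 20, designationFrac = 0.8,
                            scanInverted = TRUE) {
  if (is(genome, "GenomeRecord")) {
    s <- genomeSeq(genome); id <- genomeId(genome)
  } else {
    s <- toupper(as.character(genome)); id <- "seq"
  }
  minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
  if (minLen < 50L || minLen > maxLen || maxLen > 300L)
    stop("need 50 <= minLen <= maxLen <= 300")
  L <- nchar(s)
  empty <- data.frame(genome_id = character(0), tr_start = integer(0),
                      tr_end = integer(0), tr_strand = character(0),
                      vr_start = integer(0), vr_end = integer(0),
                      vr_strand = character(0), orientation = character(0),
                      n_columns = integer(0), n_match = integer(0),
                      n_A_sub = integer(0), n_B_sub = integer(0),
                      n_ambiguous = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (L < 2L * k) return(empty)

  c1 <- .s2c(s)
  rc <- .revComp(s)
  c2 <- .s2c(rc)

  seedTab <- function(str) {
    n <- nchar(str) - k + 1L
    km <- substring(str, seq_len(n), k:(k + n - 1L))
    keep <- !grepl("N", km, fixed = TRUE) &
      (!grepl("A", km, fixed = TRUE) | !grepl("T", km, fixed = TRUE))
    list(pos = which(keep), kmer = km[keep])
  }
  t1 <- seedTab(s)

  cands <- list()   # list(text2 = 1 or 2, i, j)
  seen <- new.env(hash = TRUE)
  addCand <- function(text2, i, j) {
    key <- paste0(text2, ":", j - i)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      cands[[length(cands) + 1L]] <<- c(text2, i, j)
    }
  }
  sp <- split(t1$pos, t1$kmer)
  sp <- sp[lengths(sp) >= 2L & lengths(sp) <= 25L]
  for (g in sp) {
    for (ii in seq_len(length(g) - 1L)) {
      for (jj in (ii + 1L):length(g)) addCand(1L, g[ii], g[jj])
    }
  }
  if (scanInverted) {
    t2 <- seedTab(rc)
    common <- intersect(unique(t1$kmer), unique(t2$kmer))
    if (length(common)) {
      sp2 <- split(t2$pos, t2$kmer)
      for (km in common) {
        g1 <- t1$pos[t1$kmer == km]; g2 <- sp2[[km]]
        if (length(g1) * length(g2) > 50L) next
        for (i in g1) for (j in g2) addCand(2L, i, j)
      }
    }
  }
  if (!length(cands)) return(empty)

  rows <- list()
  for (cd in cands) {
    text2 <- cd[1L]; i <- cd[2L]; j <- cd[3L]
    cb <- if (text2 == 1L) c1 else c2
    # extend under each strand-reading hypothesis: mismatches are free only
    # at the mutable base of that reading (A for plus, T for minus), which
    # keeps the expected extension score negative outside the repeat
    for (mode in c("A", "T")) {
      ext <- .extendSeed(c1, cb, i, j, k, xDrop, mode)
      va <- c1[ext$a1:ext$a2]
      vb <- cb[ext$b1:ext$b2]
      # genomic interval of copy B
      if (text2 == 1L) {
        gB <- c(ext$b1, ext$b2)
      } else {
        gB <- c(L - ext$b2 + 1L, L - ext$b1 + 1L)
      }
      gA <- c(ext$a1, ext$a2)
      if (gA[1] <= gB[2] && gB[1] <= gA[2]) next  # copies must not overlap
      des <- .designatePair(va, vb, designationFrac, mode)
      if (is.null(des)) next
      orientation <- if (text2 == 1L) "direct" else "inverted"
      tb <- if (text2 == 1L) "+" else "-"
      # strands of the TR and VR reading for each designation option
      strands <- switch(des$option,
        `1` = c("+", tb), `2` = c(tb, "+"),
        `3` = c("-", if (tb == "+") "-" else "+"),
        `4` = c(if (tb == "+") "-" else "+", "-"))
      trInt <- if (des$trIsA) gA else gB
      vrInt <- if (des$trIsA) gB else gA
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = id, tr_start = trInt[1], tr_end = trInt[2],
        tr_strand = strands[1], vr_start = vrInt[1], vr_end = vrInt[2],
        vr_strand = strands[2], orientation = orientation,
        n_columns = des$nCol, n_match = des$nMatch, n_A_sub = des$nASub,
        n_B_sub = des$nBSub, n_ambiguous = des$nAmb, score = ext$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)

  out <- out[out$n_columns >= minLen & out$n_columns <= maxLen &
             out$n_B_sub / out$n_columns <= maxBSubFrac &
             out$n_A_sub >= as.integer(minASub), , drop = FALSE]
  if (!nrow(out)) return(empty)

  # non-maximum suppression: keep highest-scoring pair per overlapping locus
  out <- out[order(-out$score, out$tr_start, out$vr_start), , drop = FALSE]
  keep <- logical(nrow(out))
  ivOverlap <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  for (r in seq_len(nrow(out))) {
    dup <- FALSE
    for (kk in which(keep)) {
      sameLocus <-
        (ivOverlap(out$tr_start[r], out$tr_end[r], out$tr_start[kk], out$tr_end[kk]) &&
         ivOverlap(out$vr_start[r], out$vr_end[r], out$vr_start[kk], out$vr_end[kk])) ||
        (ivOverlap(out$tr_start[r], out$tr_end[r], out$vr_start[kk], out$vr_end[kk]) &&
         ivOverlap(out$vr_start[r], out$vr_end[r], out$tr_start[kk], out$tr_end[kk]))
      if (sameLocus) { dup <- TRUE; break }
    }
    keep[r] <- !dup
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$tr_start, out$vr_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ungapped two-sided extension of an exact seed; a mismatch is free only
# when the mutable base of the assumed reading (`mode`: A = plus strand,
# T = minus strand) sits on either copy
.extendSeed <- function(ca, cb, i, j, k, xDrop, mode = "A") {
  col1 <- function(x, y) {
    if (x == y) 1 else if (x == mode || y == mode ||
                           x == "N" || y == "N") 0 else -2
  }
  La <- length(ca); Lb <- length(cb)
  # ties prefer the longer extension so boundary columns whose mismatch is
  # model-consistent (score 0) are kept inside the repeat
  bestSc <- 0; bestR <- 0L; sc <- 0; off <- 0L
  p <- i + k; q <- j + k
  while (p <= La && q <= Lb) {
    sc <- sc + col1(ca[p], cb[q]); off <- off + 1L
    if (sc >= bestSc) { bestSc <- sc; bestR <- off }
    if (sc < bestSc - xDrop) break
    p <- p + 1L; q <- q + 1L
  }
  scR <- bestSc
  bestSc <- 0; bestL <- 0L; sc <- 0; off <- 0L
  p <- i - 1L; q <- j - 1L
  while (p >= 1L && q >= 1L) {
    sc <- sc + col1(ca[p], cb[q]); off <- off + 1L
    if (sc >= bestSc) { bestSc <- sc; bestL <- off }
    if (sc < bestSc - xDrop) break
    p <- p - 1L; q <- q - 1L
  }
  list(a1 = i - bestL, a2 = i + k - 1L + bestR,
       b1 = j - bestL, b2 = j + k - 1L + bestR,
       score = k + scR + bestSc)
}

# choose TR copy and reading strand consistent with the extension mode:
# options 1/2 place the TR on copy A/B read as-is (plus reading), options
# 3/4 on the reverse-complement reading. Returns NULL when no allowed
# option reaches the designation threshold (non-DGR-like repeat).
.designatePair <- function(va, vb, designationFrac, mode = "A") {
  amb <- va == "N" | vb == "N"
  mism <- va != vb & !amb
  nm <- sum(mism)
  if (nm == 0L) {
    # identical copies: designation is arbitrary; keep copy A as TR, plus reading
    return(list(option = "1", trIsA = TRUE, nCol = length(va),
                nMatch = sum(!amb), nASub = 0L, nBSub = 0L, nAmb = sum(amb)))
  }
  frac <- c(`1` = mean(va[mism] == "A"), `2` = mean(vb[mism] == "A"),
            `3` = mean(va[mism] == "T"), `4` = mean(vb[mism] == "T"))
  frac <- frac[if (mode == "A") c("1", "2") else c("3", "4")]
  opt <- names(frac)[which.max(frac)]
  if (frac[[opt]] < designationFrac) return(NULL)
  trv <- switch(opt, `1` = va, `2` = vb, `3` = .rcChars(va), `4` = .rcChars(vb))
  vrv <- switch(opt, `1` = vb, `2` = va, `3` = .rcChars(vb), `4` = .rcChars(va))
  cls <- .classifyColumns(trv, vrv)
  list(option = opt, trIsA = opt %in% c("1", "3"), nCol = length(trv),
       nMatch = sum(cls == "match"), nASub = sum(cls == "A_sub"),
       nBSub = sum(cls == "B_sub"), nAmb = sum(cls == "ambiguous"))
}

#' Assemble repeat pairs and ORF annotations into DGR cassettes
#'
#' Pairs whose TR intervals reciprocally overlap by at least
#' `minTrOverlap` are grouped into one cassette with multiple targets (the
#' dual-target layout in which one target gene carries its VR near the 5'
#' end and the other near the 3' end). For each VR the target ORF is the
#' annotated ORF fully containing it (the longest when several qualify); the
#' reverse-transcriptase ORF is the ORF labelled "reverse transcriptase"
#' within `windowBp` of the TR, else unassigned, and an accessory (Avd-like)
#' ORF is matched the same way.
#'
#' @param genome A [GenomeRecord-class].
#' @param pairs Repeat pairs from [findRepeatPairs()] (same genome).
#' @param orfs A [GenomicRanges::GRanges] of ORFs with metadata columns
#'   `protein` and `label` (user annotation).
#' @param windowBp Maximum TR-to-RT distance in bp (default 5000).
#' @param minTrOverlap Reciprocal TR overlap required to merge pairs into
#'   one cassette (default 0.9).
#' @return A list of [DgrCassette-class] objects. A VR contained in no ORF
#'   is kept in the cassette with `excluded = TRUE` and a warning, and is
#'   skipped by downstream amino-acid analysis.
#' @export
assembleCassettes <- function(genome, pairs, orfs, windowBp = 5000L,
                              minTrOverlap = 0.9) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  if (length(unique(pairs$genome_id)) > 1L)
    stop("all pairs must come from the same genome")
  id <- genomeId(genome)

  n <- nrow(pairs)
  # single-linkage grouping by reciprocal TR overlap
  grp <- seq_len(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a >= b) next
      ov <- min(pairs$tr_end[a], pairs$tr_end[b]) -
        max(pairs$tr_start[a], pairs$tr_start[b]) + 1L
      if (ov <= 0) next
      wa <- pairs$tr_end[a] - pairs$tr_start[a] + 1L
      wb <- pairs$tr_end[b] - pairs$tr_start[b] + 1L
      if (ov / wa >= minTrOverlap && ov / wb >= minTrOverlap) {
        g <- min(grp[a], grp[b])
        grp[grp == grp[a] | grp == grp[b]] <- g
      }
    }
  }

  labGrep <- function(pattern) {
    lb <- as.character(S4Vectors::mcols(orfs)$label)
    which(!is.na(lb) & grepl(pattern, lb, ignore.case = TRUE))
  }
  rtIdx <- labGrep("reverse transcriptase")
  avdIdx <- labGrep("accessory|\\bavd\\b")

  out <- list()
  for (g in unique(grp)) {
    rowsIdx <- which(grp == g)
    rowsIdx <- rowsIdx[order(-pairs$score[rowsIdx])]
    best <- rowsIdx[1L]
    trGr <- GenomicRanges::GRanges(
      seqnames = id,
      ranges = IRanges::IRanges(pairs$tr_start[best], pairs$tr_end[best]),
      strand = pairs$tr_strand[best])

    tgRows <- list()
    seenVr <- character(0)
    for (r in rowsIdx) {
      keyv <- paste(pairs$vr_start[r], pairs$vr_end[r])
      if (keyv %in% seenVr) next
      seenVr <- c(seenVr, keyv)
      vs <- pairs$vr_start[r]; ve <- pairs$vr_end[r]
      contain <- which(GenomicRanges::start(orfs) <= vs &
                       GenomicRanges::end(orfs) >= ve &
                       as.character(GenomicRanges::seqnames(orfs)) == id)
      if (length(contain)) {
        widths <- GenomicRanges::width(orfs)[contain]
        oi <- contain[which.max(widths)]
        os <- GenomicRanges::start(orfs)[oi]; oe <- GenomicRanges::end(orfs)[oi]
        ostr <- as.character(GenomicRanges::strand(orfs))[oi]
        mid <- (vs + ve) / 2
        relMid <- if (ostr == "-") (oe - mid) / (oe - os) else (mid - os) / (oe - os)
        cls <- if (relMid <= 1 / 3) "five_prime"
               else if (relMid >= 2 / 3) "three_prime" else "internal"
        fo <- if (ostr == "-") (oe - ve) %% 3L else (vs - os) %% 3L
        tgRows[[length(tgRows) + 1L]] <- data.frame(
          vr_start = vs, vr_end = ve, vr_strand = pairs$vr_strand[r],
          orf_start = os, orf_end = oe, orf_strand = ostr,
          orf_label = as.character(S4Vectors::mcols(orfs)$label[oi]),
          vr_position_class = cls, frame_offset = as.integer(fo),
          n_columns = pairs$n_columns[r], n_A_sub = pairs$n_A_sub[r],
          n_B_sub = pairs$n_B_sub[r], excluded = FALSE,
          stringsAsFactors = FALSE)
      } else {
        warning("VR ", vs, "-", ve, " in '", id,
                "' is not contained in any annotated ORF; ",
                "excluded from amino-acid analysis")
        tgRows[[length(tgRows) + 1L]] <- data.frame(
          vr_start = vs, vr_end = ve, vr_strand = pairs$vr_strand[r],
          orf_start = NA_integer_, orf_end = NA_integer_,
          orf_strand = NA_character_, orf_label = "none",
          vr_position_class = "unassigned", frame_offset = 0L,
          n_columns = pairs$n_columns[r], n_A_sub = pairs$n_A_sub[r],
          n_B_sub = pairs$n_B_sub[r], excluded = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    targets <- do.call(rbind, tgRows)
    targets <- targets[order(targets$vr_start), , drop = FALSE]
    rownames(targets) <- NULL

    nearLabelled <- function(idx) {
      if (!length(idx)) return(GenomicRanges::GRanges())
      d <- suppressWarnings(GenomicRanges::distance(trGr, orfs[idx],
                                                    ignore.strand = TRUE))
      ok <- which(!is.na(d) & d <= windowBp)
      if (!length(ok)) return(GenomicRanges::GRanges())
      orfs[idx[ok[which.min(d[ok])]]]
    }
    out[[length(out) + 1L]] <- new("DgrCassette", genomeId = id, tr = trGr,
                                   rtOrf = nearLabelled(rtIdx),
                                   avdOrf = nearLabelled(avdIdx),
                                   targets = targets)
  }
  ord <- order(vapply(out, function(x) GenomicRanges::start(x@tr), numeric(1)))
  out[ord]
}

#' Screen contigs for essential phage marker genes
#'
#' Keeps the records whose user-supplied ORF annotation labels include all
#' required markers (case-insensitive substring match); the default markers
#' are the large terminase subunit and the portal protein, the usual
#' criterion for calling a contig a phage genome.
#'
#' @param records List of [GenomeRecord-class] objects.
#' @param orfsPerRecord Named list (by genome id) of annotated ORF
#'   [GenomicRanges::GRanges], or one combined `GRanges` with seqnames
#'   matching the record ids.
#' @param requiredLabels Character vector of required label substrings.
#' @return Character vector of retained genome ids.
#' @export
screenPhageContigs <- function(records, orfsPerRecord,
                               requiredLabels = c("large terminase subunit",
                                                  "portal protein")) {
  if (is(orfsPerRecord, "GRanges")) {
    all <- orfsPerRecord
    orfsPerRecord <- lapply(records, function(r)
      all[as.character(GenomicRanges::seqnames(all)) == genomeId(r)])
    names(orfsPerRecord) <- vapply(records, genomeId, character(1))
  }
  keep <- vapply(records, function(r) {
    orfs <- orfsPerRecord[[genomeId(r)]]
    if (is.null(orfs) || length(orfs) == 0L) return(FALSE)
    lb <- as.character(S4Vectors::mcols(orfs)$label)
    lb <- lb[!is.na(lb)]
    all(vapply(requiredLabels,
               function(q) any(grepl(q, lb, ignore.case = TRUE)), logical(1)))
  }, logical(1))
  vapply(records[keep], genomeId, character(1))
}

#' Extract TR and VR sequences for a repeat pair
#'
#' Slices the genome at the pair's intervals and reverse-complements each
#' copy when its reading strand is `-`, so both sequences are returned in
#' the TR reading orientation used for substitution classification.
#'
#' @param genome A [GenomeRecord-class].
#' @param pairRow One row of the `data.frame` returned by
#'   [findRepeatPairs()] (or a target row of [cassetteTargets()] combined
#'   with the cassette TR).
#' @return A list with elements `tr` and `vr` (character).
#' @export
pairSequences <- function(genome, pairRow) {
  s <- genomeSeq(genome)
  tr <- substr(s, pairRow$tr_start, pairRow$tr_end)
  vr <- substr(s, pairRow$vr_start, pairRow$vr_end)
  if (pairRow$tr_strand == "-") tr <- .revComp(tr)
  if (pairRow$vr_strand == "-") vr <- .revComp(vr)
  list(tr = tr, vr = vr)
}
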