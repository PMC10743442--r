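#' Parameters for the DGR retrohoming simulator
#'
#' Describes the synthetic cassette the forward simulator emits: a
#' non-coding TR whose adenines are grouped in AAC/AAT codon pairs on the
#' target reading frame, and one or two target ORFs whose VRs derive from
#' the TR by substituting adenines (each with probability `pSub`, replacement
#' base drawn from `baseWeights`) plus a low per-site background rate
#' `qBackground` of non-adenine substitutions.
#'
#' @slot trLengthBp TR length in bp (multiple of 3; canonical TRs are
#'   100–150 bp, default 120).
#' @slot nAdeninePairs Number of AAC/AAT codons in the TR (default 12, i.e.
#'   24 adenines).
#' @slot pairCodons Codons used for the adenine pairs (subset of
#'   `c("AAC","AAT")`).
#' @slot pSub Per-adenine substitution probability in a VR.
#' @slot baseWeights 3 x 3 numeric matrix: rows = codon positions 1–3,
#'   columns = replacement bases C/G/T; each row sums to 1.
#' @slot qBackground Per-site probability of a background (non-adenine)
#'   substitution.
#' @slot dualTarget Emit two target ORFs (VR near the 5' end of target1 and
#'   the 3' end of target2), the dual-target cassette layout.
#' @slot forbidStop Resample codons whose mutation would introduce an
#'   in-frame stop (functional target proteins survive selection).
#' @slot vr2TrimCodons Codons trimmed from the TR 5' end to form the shorter
#'   VR2 (default 3, emulating VR2 covering fewer template adenines).
#' @slot genomeLengthBp Approximate emitted genome size (20–50 kb).
#' @slot seed Integer seed; the emitted genome is byte-identical for equal
#'   seeds.
#' @seealso [simulationParams()], [simulateGenome()]
#' @export
setClass("SimulationParams",
  slots = c(trLengthBp = "integer", nAdeninePairs = "integer",
            pairCodons = "character", pSub = "numeric",
            baseWeights = "matrix", qBackground = "numeric",
            dualTarget = "logical", forbidStop = "logical",
            vr2TrimCodons = "integer", genomeLengthBp = "integer",
            seed = "integer")
)

setValidity("SimulationParams", function(object) {
  msg <- NULL
  if (object@trLengthBp %% 3L != 0L || object@trLengthBp < 30L)
    msg <- c(msg, "trLengthBp must be a multiple of 3 and >= 30")
  nCod <- object@trLengthBp %/% 3L
  if (object@nAdeninePairs < 1L || object@nAdeninePairs > nCod - 6L)
    msg <- c(msg, "nAdeninePairs must leave at least 6 adenine-free codons")
  if (!all(object@pairCodons %in% c("AAC", "AAT")) || !length(object@pairCodons))
    msg <- c(msg, "pairCodons must be a non-empty subset of c(\"AAC\",\"AAT\")")
  if (object@pSub < 0 || object@pSub > 1) msg <- c(msg, "pSub must be in [0,1]")
  if (object@qBackground < 0 || object@qBackground > 1)
    msg <- c(msg, "qBackground must be in [0,1]")
  bw <- object@baseWeights
  if (!all(dim(bw) == c(3L, 3L)) || !identical(colnames(bw), c("C", "G", "T")))
    msg <- c(msg, "baseWeights must be a 3 x 3 matrix with columns C, G, T")
  else if (any(bw < 0) || any(abs(rowSums(bw) - 1) > 1e-9))
    msg <- c(msg, "each baseWeights row must be a distribution over C, G, T")
  if (object@vr2TrimCodons < 0L || object@vr2TrimCodons > nCod %/% 3L)
    msg <- c(msg, "vr2TrimCodons out of range")
  if (object@genomeLengthBp < 20000L || object@genomeLengthBp > 50000L)
    msg <- c(msg, "genomeLengthBp must be within 20000-50000")
  if (is.null(msg)) TRUE else msg
})

#' Construct simulator parameters
#'
#' @param preset Optional preset: `"nd4like"` (AAC pairs only, 120 bp TR)
#'   or `"nd12like"` (mixed AAC/AAT pairs, 126 bp TR with 14 pairs).
#' @param trLengthBp,nAdeninePairs,pairCodons,pSub,baseWeights,qBackground,dualTarget,forbidStop,vr2TrimCodons,genomeLengthBp,seed
#'   See [SimulationParams-class]; `baseWeights` may also be a length-3
#'   vector over C/G/T applied to every codon position.
#' @return A validated [SimulationParams-class] object.
#' @examples
#' simulationParams(seed = 1, pSub = 0.5)
#' @export
simulationParams <- function(preset = NULL, trLengthBp = 120L,
                             nAdeninePairs = 12L,
                             pairCodons = c("AAC", "AAT"), pSub = 0.5,
                             baseWeights = NULL, qBackground = 0,
                             dualTarget = TRUE, forbidStop = TRUE,
                             vr2TrimCodons = 3L, genomeLengthBp = 30000L,
                             seed = 0L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("nd4like", "nd12like"))
    if (preset == "nd4like") {
      pairCodons <- "AAC"
    } else {
      trLengthBp <- 126L; nAdeninePairs <- 14L
      pairCodons <- c("AAC", "AAT")
    }
  }
  if (is.null(baseWeights)) {
    baseWeights <- matrix(1 / 3, 3, 3, dimnames = list(NULL, c("C", "G", "T")))
  } else if (is.vector(baseWeights)) {
    if (length(baseWeights) != 3L) stop("baseWeights vector must have length 3 (C, G, T)")
    baseWeights <- matrix(rep(as.numeric(baseWeights), each = 3), 3, 3,
                          dimnames = list(NULL, c("C", "G", "T")))
  }
  new("SimulationParams", trLengthBp = as.integer(trLengthBp),
      nAdeninePairs = as.integer(nAdeninePairs),
      pairCodons = pairCodons, pSub = pSub, baseWeights = baseWeights,
      qBackground = qBackground, dualTarget = dualTarget,
      forbidStop = forbidStop, vr2TrimCodons = as.integer(vr2TrimCodons),
      genomeLengthBp = as.integer(genomeLengthBp), seed = as.integer(seed))
}

#' @describeIn SimulationParams-class compact display
#' @param object A `SimulationParams`.
#' @export
setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams: TR ", object@trLengthBp, " bp with ",
      object@nAdeninePairs, " ", paste(object@pairCodons, collapse = "/"),
      " pairs; pSub=", object@pSub, ", q=", object@qBackground,
      ", dualTarget=", object@dualTarget, ", seed=", object@seed, "\n",
      sep = "")
})

.ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     paste0), c("A", "C", "G", "T"), paste0))

.nonStopCodons <- function(code = "11") setdiff(.ALL_CODONS, .stopCodons(code))

.aFreeCodons <- function(code = "11") {
  cods <- .ALL_CODONS[!grepl("A", .ALL_CODONS, fixed = TRUE)]
  setdiff(cods, .stopCodons(code))
}

.randDna <- function(n) .c2s(sample(c("A", "C", "G", "T"), n, replace = TRUE))

.randOrfSeq <- function(nCodons, code = "11") {
  paste0("ATG", .c2s(sample(.nonStopCodons(code), nCodons, replace = TRUE)), "TAA")
}

#' Mutate a template repeat into a variable repeat
#'
#' The stochastic core of the simulator: each adenine of the (in-frame)
#' template is substituted with probability `pSub` by a base drawn from the
#' codon-position-specific `baseWeights`; every non-adenine site mutates
#' with probability `qBackground` to a uniformly chosen different base. With
#' `forbidStop`, a codon whose mutation yields an in-frame stop is resampled
#' (up to 100 attempts, then reverted). Uses the current RNG stream.
#'
#' @param tr In-frame template sequence (length a multiple of 3).
#' @param pSub Per-adenine substitution probability.
#' @param baseWeights 3 x 3 matrix as in [SimulationParams-class] (default
#'   uniform).
#' @param qBackground Per-site background substitution probability.
#' @param forbidStop Avoid in-frame stop codons.
#' @param code Genetic code table id.
#' @return A list: `vr` (the mutated sequence) and `substitutions`, a
#'   `data.frame` with columns `pos` (1-based in `tr`), `tr_base`,
#'   `vr_base`, `type` (`"A"` or `"background"`).
#' @export
mutateRepeat <- function(tr, pSub = 0.5, baseWeights = NULL, qBackground = 0,
                         forbidStop = TRUE, code = "11") {
  tr <- toupper(as.character(tr))
  if (nchar(tr) %% 3L != 0L) stop("template length must be a multiple of 3")
  if (is.null(baseWeights))
    baseWeights <- matrix(1 / 3, 3, 3, dimnames = list(NULL, c("C", "G", "T")))
  trc <- .s2c(tr)
  stops <- .stopCodons(code)
  vrc <- trc
  rows <- list()
  for (ci in seq_len(nchar(tr) %/% 3L)) {
    idx <- (3L * ci - 2L):(3L * ci)
    orig <- trc[idx]
    out <- orig
    recs <- NULL
    for (attempt in seq_len(100L)) {
      out <- orig
      recs <- list()
      for (p in 1:3) {
        if (orig[p] == "A") {
          if (stats::runif(1) < pSub) {
            b <- sample(c("C", "G", "T"), 1L, prob = baseWeights[p, ])
            out[p] <- b
            recs[[length(recs) + 1L]] <- c(idx[p], "A", b, "A")
          }
        } else if (qBackground > 0 && orig[p] %in% c("C", "G", "T")) {
          if (stats::runif(1) < qBackground) {
            b <- sample(setdiff(c("A", "C", "G", "T"), orig[p]), 1L)
            out[p] <- b
            recs[[length(recs) + 1L]] <- c(idx[p], orig[p], b, "background")
          }
        }
      }
      if (!forbidStop || !(.c2s(out) %in% stops)) break
      if (attempt == 100L) { out <- orig; recs <- list() }  # revert
    }
    vrc[idx] <- out
    for (r in recs) rows[[length(rows) + 1L]] <- r
  }
  subs <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(pos = as.integer(m[, 1]), tr_base = m[, 2], vr_base = m[, 3],
               type = m[, 4], stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(0), tr_base = character(0),
               vr_base = character(0), type = character(0),
               stringsAsFactors = FALSE)
  }
  list(vr = .c2s(vrc), substitutions = subs)
}

#' Simulate a phage genome carrying a DGR cassette, with ground truth
#'
#' Emits a linear genome containing filler sequence, marker ORFs (large
#' terminase subunit, portal protein), a reverse-transcriptase ORF, an
#' accessory (Avd-like) ORF, a non-coding TR, a target1 ORF with its VR in
#' the 5' third and — for dual-target cassettes — a target2 ORF with a
#' shorter VR in its 3' third. VRs derive from the TR by the adenine model
#' of [mutateRepeat()]. Repeat boundaries are sharp by construction: the TR
#' is flanked by GGG-GGG and each VR by CCC-CCC (proline) codon pairs,
#' giving six adenine-free mismatch columns at every edge, and the
#' adenine-pair layout
#' always leaves one run of at least five adenine-free codons clear of the
#' VR2 trim so that every repeat contains an exact adenine-free seed.
#' Deterministic given `params@seed`; the caller's RNG state is restored.
#'
#' @param params A [SimulationParams-class].
#' @return A list: `genome` ([GenomeRecord-class]), `orfs`
#'   ([GenomicRanges::GRanges] with `protein` and `label`), and `truth`, a
#'   `SimulationTruth` list recording the TR interval/sequence and, per
#'   target, the VR interval, frame offset, TR offset of the covered span,
#'   nucleotide substitutions (`pos` within the covered span, `tr_pos` in
#'   the full TR, `genome_pos`, bases, type) and the codon-level amino-acid
#'   substitution table, plus all ORF coordinates.
#' @examples
#' sim <- simulateGenome(simulationParams(seed = 1))
#' genomeLength(sim$genome)
#' sim$truth$tr$start
#' @export
simulateGenome <- function(params = simulationParams()) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    oldSeed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", oldSeed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(params@seed)

  nCod <- params@trLengthBp %/% 3L
  trim <- if (params@dualTarget) params@vr2TrimCodons else 0L
  trimIdx <- if (trim > 0L) trim else 0L
  # the last (up to two) trimmed codons are fixed to GGG so the VR2/TR
  # overlap starts at a sharp, adenine-free boundary
  guardIdx <- if (trimIdx > 0L) max(1L, trimIdx - 1L):trimIdx else integer(0)
  candidates <- setdiff(seq_len(nCod), guardIdx)

  # layout rejection: require a run of >= 5 adenine-free codons after the trim
  pairPos <- NULL
  for (try in seq_len(10000L)) {
    pp <- sort(sample(candidates, params@nAdeninePairs))
    free <- setdiff((trimIdx + 1L):nCod, pp)
    runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
    if (any(lengths(runs) >= 5L)) { pairPos <- pp; break }
  }
  if (is.null(pairPos)) stop("could not place adenine pairs with a seedable run")

  codons <- character(nCod)
  codons[pairPos] <- sample(params@pairCodons, length(pairPos), replace = TRUE)
  rest <- setdiff(seq_len(nCod), pairPos)
  codons[rest] <- sample(.aFreeCodons(), length(rest), replace = TRUE)
  if (trimIdx > 0L) codons[guardIdx] <- "GGG"
  tr <- .c2s(codons)

  v1 <- mutateRepeat(tr, params@pSub, params@baseWeights,
                     params@qBackground, params@forbidStop)
  v2 <- if (params@dualTarget) {
    mutateRepeat(substr(tr, 3L * trim + 1L, nchar(tr)), params@pSub,
                 params@baseWeights, params@qBackground, params@forbidStop)
  } else NULL

  # --- assemble the genome left to right, tracking features -------------
  segs <- character(0)
  pos <- 0L
  feats <- list()
  add <- function(seq, feature = NULL) {
    segs[[length(segs) + 1L]] <<- seq
    start <- pos + 1L
    pos <<- pos + nchar(seq)
    if (!is.null(feature)) {
      feature$start <- start
      feature$end <- pos
      feats[[length(feats) + 1L]] <<- feature
    }
    invisible(start)
  }

  add(.randDna(sample(1500:2500, 1)))
  add(.randOrfSeq(140L), list(name = "terminase", label = "large terminase subunit"))
  add(.randDna(sample(100:300, 1)))
  add(.randOrfSeq(120L), list(name = "portal", label = "portal protein"))
  add(.randDna(sample(500:900, 1)))
  add(.randOrfSeq(250L), list(name = "rt", label = "reverse transcriptase"))
  add(.randDna(sample(100:250, 1)))
  add(.randOrfSeq(80L),
      list(name = "avd", label = "accessory variability determinant (Avd)"))
  add(.randDna(sample(100:250, 1)))
  trBlockStart <- add(paste0("GGGGGG", tr, "GGGGGG"),
                      list(name = "trblock", label = "TR"))
  trStart <- trBlockStart + 6L
  trEnd <- trStart + nchar(tr) - 1L
  add(.randDna(sample(200:400, 1)))

  t1seq <- paste0("ATG", .c2s(sample(.nonStopCodons(), 20L, replace = TRUE)),
                  "CCCCCC", v1$vr, "CCCCCC",
                  .c2s(sample(.nonStopCodons(), 250L, replace = TRUE)), "TAA")
  t1Start <- add(t1seq, list(name = "target1",
                             label = "tentaclin-like target protein 1"))
  vr1Start <- t1Start + 3L * 23L
  vr1End <- vr1Start + nchar(v1$vr) - 1L
  add(.randDna(sample(300:600, 1)))

  vr2Start <- NA_integer_; vr2End <- NA_integer_
  if (params@dualTarget) {
    t2seq <- paste0("ATG", .c2s(sample(.nonStopCodons(), 150L, replace = TRUE)),
                    "CCCCCC", v2$vr, "CCCCCC",
                    .c2s(sample(.nonStopCodons(), 5L, replace = TRUE)), "TAA")
    t2Start <- add(t2seq, list(name = "target2",
                               label = "target protein 2 (Mtd-like)"))
    vr2Start <- t2Start + 3L * 153L
    vr2End <- vr2Start + nchar(v2$vr) - 1L
    add(.randDna(sample(300:600, 1)))
  }
  remaining <- params@genomeLengthBp - pos
  add(.randDna(max(500L, remaining)))

  id <- sprintf("sim_seed%d", params@seed)
  genome <- genomeRecord(id, .c2s(segs), source = "DGRtools simulator")

  orfFeats <- Filter(function(f) f$name != "trblock", feats)
  orfs <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(
      start = vapply(orfFeats, function(f) f$start, integer(1)),
      end = vapply(orfFeats, function(f) f$end, integer(1))),
    strand = "+",
    protein = vapply(orfFeats, function(f) {
      s <- substr(genomeSeq(genome), f$start, f$end)
      sub("\\*$", "", translateSeq(s))
    }, character(1)),
    label = vapply(orfFeats, function(f) f$label, character(1)))

  aaTruth <- function(trPart, vrPart) {
    tc <- .splitCodons(trPart); vc <- .splitCodons(vrPart)
    gc <- .geneticCode("11")
    aaT <- unname(gc[tc]); aaV <- unname(gc[vc])
    d <- which(aaT != aaV)
    data.frame(codon_index = d, tr_codon = tc[d], vr_codon = vc[d],
               aa_tr = aaT[d], aa_vr = aaV[d], stringsAsFactors = FALSE)
  }
  featByName <- function(nm) Filter(function(f) f$name == nm, feats)[[1L]]
  targets <- list(list(
    name = "target1", vr_start = vr1Start, vr_end = vr1End,
    tr_offset = 1L, frame_offset = 0L,
    substitutions = within(v1$substitutions, {
      genome_pos <- vr1Start + pos - 1L
      tr_pos <- pos
    }),
    aa_substitutions = aaTruth(tr, v1$vr),
    orf_start = featByName("target1")$start,
    orf_end = featByName("target1")$end))
  if (params@dualTarget) {
    targets[[2L]] <- list(
      name = "target2", vr_start = vr2Start, vr_end = vr2End,
      tr_offset = 3L * trim + 1L, frame_offset = 0L,
      substitutions = within(v2$substitutions, {
        genome_pos <- vr2Start + pos - 1L
        tr_pos <- pos + 3L * trim
      }),
      aa_substitutions = aaTruth(substr(tr, 3L * trim + 1L, nchar(tr)), v2$vr),
      orf_start = featByName("target2")$start,
      orf_end = featByName("target2")$end)
  }
  truth <- structure(list(
    genome_id = id, seed = params@seed, params = params,
    tr = list(start = trStart, end = trEnd, seq = tr),
    targets = targets,
    orfs = lapply(setNames(nm = vapply(orfFeats, function(f) f$name, character(1))),
                  function(nm) {
                    f <- featByName(nm)
                    c(start = f$start, end = f$end)
                  })),
    class = "SimulationTruth")
  list(genome = genome, orfs = orfs, truth = truth)
}

#' Closed-form substitution expectations for simulated VRs
#'
#' The number of adenine substitutions in a VR is binomial with size equal
#' to the covered template adenines and probability `pSub`; background
#' substitutions are binomial over the covered non-adenine sites with
#' probability `qBackground`. For target2 the covered adenine count depends
#' on the random pair layout; its expectation under a uniform layout is
#' reported unless an exact count is supplied.
#'
#' @param params A [SimulationParams-class].
#' @param nCoveredAdenines Optional numeric vector (one value per target)
#'   overriding the expected covered adenine counts, e.g. counted from a
#'   realized TR.
#' @return A `data.frame` with one row per target: `target`, `n_adenines`,
#'   `mean_A_sub`, `var_A_sub`, `mean_B_sub`, `var_B_sub`.
#' @examples
#' expectedSpectrum(simulationParams(pSub = 0.5), nCoveredAdenines = c(25, 21))
#' @export
expectedSpectrum <- function(params, nCoveredAdenines = NULL) {
  stopifnot(is(params, "SimulationParams"))
  nCod <- params@trLengthBp %/% 3L
  trim <- if (params@dualTarget) params@vr2TrimCodons else 0L
  nA <- 2 * params@nAdeninePairs
  lens <- c(params@trLengthBp,
            if (params@dualTarget) params@trLengthBp - 3L * trim)
  if (is.null(nCoveredAdenines)) {
    # pairs are placed uniformly over the codons not reserved for the trim
    # boundary; expected pairs lost to the trim = nPairs * (trim-1)/(nCod-1)
    lostPairs <- if (trim > 0L) params@nAdeninePairs * (trim - 1) / (nCod - 1) else 0
    nCoveredAdenines <- c(nA, if (params@dualTarget) nA - 2 * lostPairs)
  }
  tg <- c("target1", if (params@dualTarget) "target2")
  p <- params@pSub; q <- params@qBackground
  nB <- lens - nCoveredAdenines
  data.frame(target = tg, n_adenines = nCoveredAdenines,
             mean_A_sub = nCoveredAdenines * p,
             var_A_sub = nCoveredAdenines * p * (1 - p),
             mean_B_sub = nB * q, var_B_sub = nB * q * (1 - q),
             stringsAsFactors = FALSE)
}
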