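#' GenomeRecord: a nucleotide sequence with identity and topology
#'
#' Container for one genome (or contig): an uppercase sequence over
#' \{A, C, G, T, N\}, an identifier, a topology flag and a free-text source.
#'
#' @slot id Single identifier string.
#' @slot seq Uppercase nucleotide sequence.
#' @slot topology `"linear"` or `"circular"`.
#' @slot source Free text (e.g. the file the record was read from).
#'
#' @seealso [genomeRecord()], [readFasta()], [readGenBank()]
#' @export
setClass("GenomeRecord",
  slots = c(id = "character", seq = "character",
            topology = "character", source = "character"),
  prototype = prototype(topology = "linear", source = "")
)

setValidity("GenomeRecord", function(object) {
  msg <- NULL
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) != 1L || is.na(object@seq)) {
    msg <- c(msg, "'seq' must be a single string")
  } else {
    if (!nzchar(object@seq)) msg <- c(msg, "sequence is empty")
    if (grepl("[^ACGTN]", object@seq))
      msg <- c(msg, "sequence contains characters outside {A,C,G,T,N} (must be uppercase)")
  }
  if (length(object@topology) != 1L || !object@topology %in% c("linear", "circular"))
    msg <- c(msg, "'topology' must be \"linear\" or \"circular\"")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeRecord
#'
#' The sequence is uppercased and RNA `U` is mapped to `T` before validation;
#' any character outside \{A, C, G, T, N\} is rejected.
#'
#' @param id Identifier string.
#' @param seq Nucleotide sequence.
#' @param topology `"linear"` (default) or `"circular"`.
#' @param source Optional free text recording provenance.
#' @return A [GenomeRecord-class] object.
#' @examples
#' g <- genomeRecord("x", "acgu")
#' genomeSeq(g)   # "ACGT"
#' @export
genomeRecord <- function(id, seq, topology = "linear", source = "") {
  new("GenomeRecord", id = as.character(id),
      seq = chartr("u", "T", toupper(as.character(seq))),
      topology = topology, source = source)
}

#' @describeIn GenomeRecord-class compact display
#' @param object A `GenomeRecord`.
#' @export
setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord '", object@id, "' (", object@topology, "), ",
      nchar(object@seq), " bp\n", sep = "")
  s <- object@seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
})

#' DgrCassette: an assembled DGR cassette
#'
#' A located template repeat (TR) together with its reverse-transcriptase and
#' accessory (Avd-like) ORFs, if identified, and one or more targets: each a
#' variable repeat (VR) embedded in a target ORF with a reading-frame phase
#' and a 5'/3' position class.
#'
#' @slot genomeId Genome the cassette was found in.
#' @slot tr `GRanges` of length 1: the TR interval (strand = reading strand).
#' @slot rtOrf `GRanges` of length 0 or 1: the reverse-transcriptase ORF
#'   (length 0 when unassigned).
#' @slot avdOrf `GRanges` of length 0 or 1: the accessory ORF.
#' @slot targets `data.frame`, one row per target, with columns `vr_start`,
#'   `vr_end`, `vr_strand`, `orf_start`, `orf_end`, `orf_strand`, `orf_label`,
#'   `vr_position_class` (`five_prime`/`three_prime`/`internal`/`unassigned`),
#'   `frame_offset` (0/1/2), `n_columns`, `n_A_sub`, `n_B_sub`, `excluded`
#'   (`TRUE` when no ORF fully contains the VR).
#' @export
setClass("DgrCassette",
  slots = c(genomeId = "character", tr = "GRanges",
            rtOrf = "GRanges", avdOrf = "GRanges", targets = "data.frame")
)

setValidity("DgrCassette", function(object) {
  msg <- NULL
  if (length(object@tr) != 1L) msg <- c(msg, "'tr' must contain exactly one range")
  if (length(object@rtOrf) > 1L) msg <- c(msg, "'rtOrf' must contain at most one range")
  if (nrow(object@targets) < 1L) msg <- c(msg, "a cassette needs at least one target")
  need <- c("vr_start", "vr_end", "vr_strand", "orf_start", "orf_end",
            "orf_strand", "orf_label", "vr_position_class", "frame_offset",
            "n_columns", "n_A_sub", "n_B_sub", "excluded")
  miss <- setdiff(need, colnames(object@targets))
  if (length(miss))
    msg <- c(msg, paste0("targets is missing column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    tg <- object@targets
    ok <- tg$excluded | (tg$vr_start >= tg$orf_start & tg$vr_end <= tg$orf_end)
    if (!all(ok)) msg <- c(msg, "each non-excluded VR must lie fully within its target ORF")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn DgrCassette-class compact display
#' @param object A `DgrCassette`.
#' @export
setMethod("show", "DgrCassette", function(object) {
  tr <- object@tr
  cat("DgrCassette in '", object@genomeId, "': TR ",
      GenomicRanges::start(tr), "-", GenomicRanges::end(tr),
      " (", as.character(GenomicRanges::strand(tr)), "), ",
      nrow(object@targets), " target(s); RT ",
      if (length(object@rtOrf)) "assigned" else "unassigned", "\n", sep = "")
  for (i in seq_len(nrow(object@targets))) {
    t <- object@targets[i, ]
    cat(sprintf("  target %d: VR %d-%d (%s), %s, frame %d, A-sub %d, B-sub %d\n",
                i, t$vr_start, t$vr_end, t$vr_strand, t$vr_position_class,
                t$frame_offset, t$n_A_sub, t$n_B_sub))
  }
})

#' RepeatAlignment: columnwise TR/VR correspondence
#'
#' An aligned TR/VR pair with per-column substitution classes. For
#' equal-length repeats the pairing is positional; otherwise the shorter
#' sequence is placed semi-globally inside the longer one and only overlap
#' columns are kept (gap columns are classed `"ambiguous"`).
#'
#' Column classes: `"match"`, `"A_sub"` (TR adenine substituted in the VR,
#' the DGR-driven class), `"B_sub"` (a non-adenine template base differs),
#' `"ambiguous"` (N or gap on either side).
#'
#' @slot trAligned,vrAligned Equal-length aligned strings (may contain `-`).
#' @slot columnClass Character vector of per-column classes.
#' @slot trFrameOffset Phase (0/1/2) of the aligned TR span relative to the
#'   target ORF codon grid, inherited from the VR placement.
#' @slot trOffset 1-based position in the full TR where the aligned span starts.
#' @slot trFull The complete TR sequence.
#' @slot score Alignment score (columns under the asymmetric model).
#' @seealso [alignTrVr()], [substitutionProfile()]
#' @export
setClass("RepeatAlignment",
  slots = c(trAligned = "character", vrAligned = "character",
            columnClass = "character", trFrameOffset = "integer",
            trOffset = "integer", trFull = "character", score = "numeric")
)

setValidity("RepeatAlignment", function(object) {
  msg <- NULL
  tc <- .s2c(object@trAligned)
  vc <- .s2c(object@vrAligned)
  if (length(tc) != length(vc) || length(tc) != length(object@columnClass))
    msg <- c(msg, "trAligned, vrAligned and columnClass must have equal length")
  if (!all(object@columnClass %in% c("match", "A_sub", "B_sub", "ambiguous")))
    msg <- c(msg, "invalid column class label")
  if (!object@trFrameOffset %in% 0:2) msg <- c(msg, "trFrameOffset must be 0, 1 or 2")
  if (is.null(msg)) {
    expect <- .classifyColumns(tc, vc)
    if (!identical(expect, object@columnClass))
      msg <- c(msg, "columnClass is inconsistent with the aligned sequences")
  }
  if (is.null(msg)) TRUE else msg
})

#' SubstitutionProfile: hypermutation counts for one TR/VR alignment
#'
#' Nucleotide- and amino-acid-level substitution counts computed from a
#' [RepeatAlignment-class]. Amino-acid analysis translates TR and VR over
#' codons fully contained in the aligned span (genetic code table
#' configurable, default 11); codons touching an ambiguous column are
#' skipped.
#'
#' @slot nTrAdenines Adenines in the full TR.
#' @slot nTrAdeninesCovered TR adenines inside the aligned span.
#' @slot nASub,nBSub Counts of `A_sub` / `B_sub` columns.
#' @slot perPositionFate Named character vector: full-TR adenine position ->
#'   base observed in the VR (substituted positions only).
#' @slot aaSubstitutions `data.frame` with columns `codon_index`, `tr_codon`,
#'   `vr_codon`, `aa_tr`, `aa_vr`, `adenine_only` (no B-substitution in the
#'   codon), `category_vr`.
#' @slot aaCategoryCounts Named integer vector over the categories of
#'   [aaCategories()] plus `"stop"`.
#' @slot codonBias Integer matrix (rows `AAC`, `AAT`) counting A->C/G/T at
#'   codon positions 1 and 2 within in-frame template AAC/AAT codons.
#' @export
setClass("SubstitutionProfile",
  slots = c(nTrAdenines = "integer", nTrAdeninesCovered = "integer",
            nASub = "integer", nBSub = "integer",
            perPositionFate = "character",
            aaSubstitutions = "data.frame",
            aaCategoryCounts = "integer",
            codonBias = "matrix")
)

setValidity("SubstitutionProfile", function(object) {
  msg <- NULL
  if (object@nASub > object@nTrAdeninesCovered ||
      object@nTrAdeninesCovered > object@nTrAdenines)
    msg <- c(msg, "need nASub <= nTrAdeninesCovered <= nTrAdenines")
  if (sum(object@aaCategoryCounts) != nrow(object@aaSubstitutions))
    msg <- c(msg, "category counts must sum to the number of aa substitutions")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SubstitutionProfile-class compact display
#' @param object A `SubstitutionProfile`.
#' @export
setMethod("show", "SubstitutionProfile", function(object) {
  cat("SubstitutionProfile: ", object@nASub, " A-substitutions (",
      object@nTrAdeninesCovered, "/", object@nTrAdenines,
      " TR adenines covered), ", object@nBSub, " B-substitutions, ",
      nrow(object@aaSubstitutions), " aa substitution(s)\n", sep = "")
  if (nrow(object@aaSubstitutions)) {
    cc <- object@aaCategoryCounts[object@aaCategoryCounts > 0]
    cat("  categories:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  }
})

#' ConservationProfile: per-column residue frequencies of an aligned set
#'
#' Columnwise relative frequencies over the 20-residue alphabet plus gap for
#' an aligned protein-domain set, with conserved-column calls at a
#' configurable threshold (1.0 = invariant columns).
#'
#' @slot freq Numeric matrix, 21 rows (residues + `-`) by alignment columns;
#'   each column sums to 1.
#' @slot nSequences Number of sequences the profile was built from.
#' @slot threshold Conservation threshold used for `conservedColumns`.
#' @slot conservedColumns `data.frame` with columns `column`, `residue`.
#' @seealso [buildProfile()], [scanProtein()]
#' @export
setClass("ConservationProfile",
  slots = c(freq = "matrix", nSequences = "integer",
            threshold = "numeric", conservedColumns = "data.frame")
)

setValidity("ConservationProfile", function(object) {
  msg <- NULL
  if (!all(abs(colSums(object@freq) - 1) < 1e-9))
    msg <- c(msg, "per-column frequencies must sum to 1")
  if (nrow(object@conservedColumns) &&
      any(object@conservedColumns$column > ncol(object@freq)))
    msg <- c(msg, "conserved column index out of range")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ConservationProfile-class compact display
#' @param object A `ConservationProfile`.
#' @export
setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile: ", ncol(object@freq), " columns from ",
      object@nSequences, " sequences; ", nrow(object@conservedColumns),
      " conserved column(s) at threshold ", object@threshold, "\n", sep = "")
  if (nrow(object@conservedColumns)) {
    cc <- object@conservedColumns
    cat("  ", paste0(cc$column, ":", cc$residue, collapse = " "), "\n", sep = "")
  }
})
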