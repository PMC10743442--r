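#' Accessors for DGRtools classes
#'
#' Small accessor generics so slot layout stays an implementation detail:
#' `genomeId`/`genomeSeq`/`genomeLength` for [GenomeRecord-class],
#' `cassetteTR`/`cassetteTargets`/`cassetteRT` for [DgrCassette-class],
#' `columnClasses`/`trSequence`/`vrSequence`/`nColumns` for
#' [RepeatAlignment-class], `aaSubstitutions` for
#' [SubstitutionProfile-class] and `conservedColumns`/`profileFreq` for
#' [ConservationProfile-class].
#'
#' @param x An object of the documented class.
#' @return The corresponding slot value (see each method).
#' @name accessors
#' @examples
#' g <- genomeRecord("x", "ACGT")
#' genomeLength(g)
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("cassetteTR", function(x) standardGeneric("cassetteTR"))
#' @rdname accessors
#' @export
setGeneric("cassetteTargets", function(x) standardGeneric("cassetteTargets"))
#' @rdname accessors
#' @export
setGeneric("cassetteRT", function(x) standardGeneric("cassetteRT"))
#' @rdname accessors
#' @export
setGeneric("columnClasses", function(x) standardGeneric("columnClasses"))
#' @rdname accessors
#' @export
setGeneric("trSequence", function(x) standardGeneric("trSequence"))
#' @rdname accessors
#' @export
setGeneric("vrSequence", function(x) standardGeneric("vrSequence"))
#' @rdname accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))
#' @rdname accessors
#' @export
setGeneric("aaSubstitutions", function(x) standardGeneric("aaSubstitutions"))
#' @rdname accessors
#' @export
setGeneric("conservedColumns", function(x) standardGeneric("conservedColumns"))
#' @rdname accessors
#' @export
setGeneric("profileFreq", function(x) standardGeneric("profileFreq"))

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)
#' @rdname accessors
#' @export
setMethod("genomeLength", "GenomeRecord", function(x) nchar(x@seq))
#' @rdname accessors
#' @export
setMethod("cassetteTR", "DgrCassette", function(x) x@tr)
#' @rdname accessors
#' @export
setMethod("cassetteTargets", "DgrCassette", function(x) x@targets)
#' @rdname accessors
#' @export
setMethod("cassetteRT", "DgrCassette", function(x) x@rtOrf)
#' @rdname accessors
#' @export
setMethod("columnClasses", "RepeatAlignment", function(x) x@columnClass)
#' @rdname accessors
#' @export
setMethod("trSequence", "RepeatAlignment", function(x) x@trAligned)
#' @rdname accessors
#' @export
setMethod("vrSequence", "RepeatAlignment", function(x) x@vrAligned)
#' @rdname accessors
#' @export
setMethod("nColumns", "RepeatAlignment", function(x) length(x@columnClass))
#' @rdname accessors
#' @export
setMethod("aaSubstitutions", "SubstitutionProfile", function(x) x@aaSubstitutions)
#' @rdname accessors
#' @export
setMethod("conservedColumns", "ConservationProfile", function(x) x@conservedColumns)
#' @rdname accessors
#' @export
setMethod("profileFreq", "ConservationProfile", function(x) x@freq)
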