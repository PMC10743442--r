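.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a per-column conservation profile from aligned protein sequences
#'
#' Columnwise relative residue frequencies over an aligned domain set, with
#' conserved-column calls: a column is conserved when a single residue
#' reaches the threshold (default 1.0, i.e. invariant columns — the rule
#' behind the consensus of the tentaclin C-terminal Ig anchor domain).
#'
#' @param alignedSeqs Character vector (>= 2) of equal-length aligned
#'   sequences over the 20-residue alphabet plus gap `-`.
#' @param threshold Conservation threshold in (0, 1].
#' @return A [ConservationProfile-class].
#' @examples
#' p <- buildProfile(c("ACD", "ACE"))
#' conservedColumns(p)   # columns 1 (A) and 2 (C)
#' @export
buildProfile <- function(alignedSeqs, threshold = 1.0) {
  alignedSeqs <- toupper(as.character(alignedSeqs))
  if (length(alignedSeqs) < 2L) stop("need at least 2 sequences")
  w <- nchar(alignedSeqs)
  if (length(unique(w)) != 1L) stop("ragged input: sequences differ in length")
  if (w[1] == 0L) stop("empty sequences")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  bad <- grepl(paste0("[^", .c2s(.AA20), "-]"), alignedSeqs)
  if (any(bad))
    stop("sequence ", which(bad)[1],
         " contains characters outside the 20-residue alphabet plus '-'")
  m <- do.call(rbind, strsplit(alignedSeqs, "", fixed = TRUE))
  alpha <- c(.AA20, "-")
  freq <- apply(m, 2L, function(col) {
    tab <- table(factor(col, levels = alpha))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- alpha
  consIdx <- which(apply(freq[.AA20, , drop = FALSE], 2L, max) >= threshold - 1e-12)
  cons <- data.frame(
    column = as.integer(consIdx),
    residue = vapply(consIdx, function(j) .AA20[which.max(freq[.AA20, j])],
                     character(1)),
    stringsAsFactors = FALSE)
  new("ConservationProfile", freq = freq,
      nSequences = length(alignedSeqs), threshold = threshold,
      conservedColumns = cons)
}

#' Scan a protein tail for a conservation-profile signature
#'
#' Slides the (ungapped) profile over the last `tailWindow` residues of the
#' protein. Each offset is scored by the mean per-column log-odds of the
#' observed residue against a background distribution (uniform 1/20 by
#' default; a small pseudocount keeps unseen residues finite). The protein
#' "carries the signature" iff some offset matches every conserved column of
#' the profile exactly — the rule by which all tentaclins show the anchor
#' consensus within their last 100 residues.
#'
#' @param protein Amino-acid string.
#' @param profile A [ConservationProfile-class].
#' @param tailWindow Number of C-terminal residues scanned (default 100).
#' @param background Named numeric background frequencies over the
#'   20-residue alphabet (default uniform).
#' @param pseudocount Additive pseudocount applied to profile frequencies
#'   before the log-odds (default 0.01).
#' @return A list: `carriesSignature` (logical), `bestOffset` and
#'   `bestScore` (highest-scoring placement, 1-based within the scanned
#'   tail), `signatureOffset` (best placement where all conserved columns
#'   match, or `NA`), `nOffsets`. A protein shorter than the profile yields
#'   a no-match report, not an error.
#' @export
scanProtein <- function(protein, profile, tailWindow = 100L,
                        background = NULL, pseudocount = 0.01) {
  stopifnot(is(profile, "ConservationProfile"))
  protein <- toupper(as.character(protein))
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), .AA20)
  W <- ncol(profile@freq)
  tail <- substr(protein, max(1L, nchar(protein) - as.integer(tailWindow) + 1L),
                 nchar(protein))
  n <- nchar(tail) - W + 1L
  noMatch <- list(carriesSignature = FALSE, bestOffset = NA_integer_,
                  bestScore = NA_real_, signatureOffset = NA_integer_,
                  nOffsets = 0L)
  if (W == 0L || n < 1L) return(noMatch)

  f <- profile@freq[.AA20, , drop = FALSE]
  f <- sweep(f + pseudocount, 2L, colSums(f) + 20 * pseudocount, "/")
  lod <- log(sweep(f, 1L, background[.AA20], "/"))
  tc <- .s2c(tail)
  cons <- profile@conservedColumns

  scores <- numeric(n)
  consOk <- logical(n)
  for (o in seq_len(n)) {
    win <- tc[o:(o + W - 1L)]
    known <- win %in% .AA20
    scores[o] <- if (any(known))
      mean(lod[cbind(match(win[known], .AA20), which(known))]) else -Inf
    consOk[o] <- nrow(cons) == 0L ||
      all(win[cons$column] == cons$residue)
  }
  best <- which.max(scores)
  sigOff <- if (any(consOk)) {
    cand <- which(consOk)
    cand[which.max(scores[cand])]
  } else NA_integer_
  list(carriesSignature = any(consOk),
       bestOffset = as.integer(best), bestScore = scores[best],
       signatureOffset = as.integer(sigOff), nOffsets = as.integer(n))
}

#' Export a conservation profile as a logo-style frequency matrix
#'
#' Writes the per-column residue frequencies as TSV (columns = alignment
#' positions, rows = residues), a format standard logo tools accept.
#'
#' @param profile A [ConservationProfile-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeProfileMatrix <- function(profile, path) {
  stopifnot(is(profile, "ConservationProfile"))
  m <- profile@freq
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("residue", paste0("col", seq_len(ncol(m))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# DGRtools conservation profile: ", profile@nSequences,
                    " sequences, threshold ", profile@threshold), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
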