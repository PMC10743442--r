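# internal string helpers; sequences are plain uppercase character scalars

.s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.c2s <- function(x) paste(x, collapse = "")

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# reverse-complement of a character vector of single bases (N-safe)
.rcChars <- function(ch) rev(chartr("ACGTN", "TGCAN", ch))

.geneticCode <- function(code = "11") Biostrings::getGeneticCode(code)

.stopCodons <- function(code = "11") {
  gc <- .geneticCode(code)
  names(gc)[gc == "*"]
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

#' Amino-acid physicochemical categories
#'
#' The six disjoint residue categories used for substitution spectra:
#' aromatic (F, W, Y), negatively charged (D, E), positively charged
#' (K, R, H), cysteine, hydrophobic non-aromatic (A, V, L, I, M, P, G) and
#' hydrophilic uncharged (S, T, N, Q). Histidine is treated as positively
#' charged rather than aromatic so that the categories partition the
#' 20-residue alphabet.
#'
#' @return A named list of character vectors of one-letter residue codes.
#' @examples
#' aaCategories()$aromatic
#' aaCategoryOf(c("Y", "D", "C"))
#' @export
aaCategories <- function() {
  list(
    aromatic = c("F", "W", "Y"),
    negative = c("D", "E"),
    positive = c("K", "R", "H"),
    cysteine = "C",
    hydrophobic_nonaromatic = c("A", "V", "L", "I", "M", "P", "G"),
    hydrophilic_uncharged = c("S", "T", "N", "Q")
  )
}

#' @rdname aaCategories
#' @param aa Character vector of one-letter amino-acid codes (`"*"` for stop).
#' @return For `aaCategoryOf`, the category name of each residue
#'   (`"stop"` for `"*"`, `NA` for unknown letters).
#' @export
aaCategoryOf <- function(aa) {
  cats <- aaCategories()
  lk <- rep(names(cats), lengths(cats))
  names(lk) <- unlist(cats, use.names = FALSE)
  out <- unname(lk[aa])
  out[aa == "*"] <- "stop"
  out
}
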