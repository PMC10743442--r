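#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; any other character
#' outside \{A, C, G, T, N\} raises a parse error naming the offending record.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A list of [GenomeRecord-class] objects, in file order (empty
#'   list for a zero-record file).
#' @seealso [writeFasta()]
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), f)
#' readFasta(f)[[1]]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) return(list())
  lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    id <- sub("\\s.*$", "", nm)
    if (is.na(id) || !nzchar(id))
      stop("FASTA parse error in '", path, "': record ", i, " has an empty header")
    s <- chartr("Uu", "TT", toupper(as.character(set[[i]])))
    if (!nzchar(s))
      stop("FASTA parse error in '", path, "': record '", id, "' has an empty sequence")
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    if (length(bad) && nzchar(bad))
      stop("FASTA parse error in '", path, "': record '", id,
           "' contains invalid character '", bad, "'")
    genomeRecord(id, s, source = path)
  })
}

#' Write GenomeRecords to FASTA
#'
#' Sequences are wrapped at `width` columns (default 60); a round trip through
#' [readFasta()] reproduces the sequences byte-identically.
#'
#' @param records A [GenomeRecord-class] or list of them.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 60L) {
  if (is(records, "GenomeRecord")) records <- list(records)
  x <- Biostrings::DNAStringSet(vapply(records, genomeSeq, character(1)))
  names(x) <- vapply(records, genomeId, character(1))
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal reader for GenBank flat files with an ORIGIN block: the sequence
#' becomes a [GenomeRecord-class] and each CDS feature an ORF range.
#' Locations of the forms `a..b`, `complement(a..b)` and simple two-segment
#' `join()`s (optionally complemented) are supported; any other location is
#' skipped with a warning. Coordinates are reported 1-based inclusive; for a
#' two-segment join the range is the envelope of both segments and the
#' protein is translated from the joined coding sequence.
#'
#' @param path Path to a GenBank flat file.
#' @param code Genetic code table used when no `/translation` is present
#'   (default `"11"`, bacterial/phage).
#' @return A list with elements `genome` ([GenomeRecord-class]) and `orfs`
#'   (a [GenomicRanges::GRanges] with metadata columns `protein` and `label`).
#' @examples
#' gbk <- system.file("extdata", "synthetic_phage.gbk", package = "DGRtools")
#' rec <- readGenBank(gbk)
#' genomeLength(rec$genome)
#' @export
readGenBank <- function(path, code = "11") {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("GenBank parse error in '", path, "': missing LOCUS line")
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1L]][1L]

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank parse error in '", path, "': missing ORIGIN block")
  oi <- oi[1L]
  endi <- grep("^//", lines)
  endi <- if (length(endi)) endi[endi > oi][1L] else length(lines) + 1L
  if (is.na(endi)) endi <- length(lines) + 1L
  seqtxt <- paste(lines[(oi + 1L):(endi - 1L)], collapse = "")
  seqtxt <- toupper(gsub("[0-9/ ]", "", seqtxt))
  if (!nzchar(seqtxt)) stop("GenBank parse error in '", path, "': empty ORIGIN block")
  genome <- genomeRecord(name, seqtxt, source = path)

  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    block <- lines[(fi[1L] + 1L):(oi - 1L)]
    i <- 1L
    while (i <= length(block)) {
      ln <- block[i]
      key <- trimws(substr(ln, 1, 20))
      if (identical(key, "CDS")) {
        loc <- trimws(substr(ln, 21, nchar(ln)))
        j <- i + 1L
        while (j <= length(block) && grepl("^\\s{21}", block[j]) &&
               !grepl("^\\s*/", block[j])) {
          loc <- paste0(loc, trimws(block[j]))
          j <- j + 1L
        }
        quals <- character(0)
        while (j <= length(block) && (grepl("^\\s*/", block[j]) ||
               (length(quals) && !nzchar(trimws(substr(block[j], 1, 20))) &&
                !grepl("^\\s*/", block[j])))) {
          if (grepl("^\\s*/", block[j])) quals <- c(quals, trimws(block[j]))
          else quals[length(quals)] <- paste(quals[length(quals)], trimws(block[j]))
          j <- j + 1L
        }
        feats[[length(feats) + 1L]] <- list(loc = loc, quals = quals)
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }

  rows <- list()
  for (ft in feats) {
    parsed <- .parseGbLocation(ft$loc)
    if (is.null(parsed)) {
      warning("skipping CDS with unsupported location: ", ft$loc)
      next
    }
    getQ <- function(name) {
      hit <- grep(paste0("^/", name, "="), ft$quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1L]))
    }
    label <- getQ("product")
    if (is.na(label)) label <- getQ("gene")
    if (is.na(label)) label <- getQ("note")
    tbl <- getQ("transl_table")
    tbl <- if (is.na(tbl)) code else tbl
    cds <- paste(vapply(seq_len(nrow(parsed$segs)), function(k) {
      substr(genomeSeq(genome), parsed$segs[k, 1], parsed$segs[k, 2])
    }, character(1)), collapse = "")
    if (parsed$complement) cds <- .revComp(cds)
    prot <- getQ("translation")
    if (is.na(prot)) {
      if (nchar(cds) %% 3 != 0) {
        warning("skipping CDS with non-codon length at ", ft$loc)
        next
      }
      prot <- sub("\\*$", "", translateSeq(cds, tbl))
    } else {
      prot <- gsub(" ", "", prot)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = min(parsed$segs[, 1]), end = max(parsed$segs[, 2]),
      strand = if (parsed$complement) "-" else "+",
      protein = prot, label = label, stringsAsFactors = FALSE)
  }
  orfs <- if (length(rows)) {
    df <- do.call(rbind, rows)
    GenomicRanges::GRanges(
      seqnames = name,
      ranges = IRanges::IRanges(start = df$start, end = df$end),
      strand = df$strand, protein = df$protein, label = df$label)
  } else {
    GenomicRanges::GRanges(protein = character(0), label = character(0))
  }
  list(genome = genome, orfs = orfs)
}

# parse "a..b", "complement(a..b)", "join(a..b,c..d)", "complement(join(...))"
# returns list(segs = 2-col matrix, complement = flag) or NULL if unsupported
.parseGbLocation <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
    if (length(parts) > 2L) return(NULL)
  } else {
    parts <- loc
  }
  if (!all(grepl("^[0-9]+\\.\\.[0-9]+$", parts))) return(NULL)
  segs <- t(vapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1L]]),
                   integer(2)))
  list(segs = segs, complement = complement)
}

#' Translate a nucleotide sequence
#'
#' Standard translation under a chosen genetic-code table (default table 11,
#' bacterial/archaeal/plant-plastid, the usual choice for gut phages); stop
#' codons are rendered `"*"` and codons containing `N` as `"X"`.
#'
#' @param seq Nucleotide string; its length must be a multiple of 3.
#' @param code Genetic code table id passed to
#'   [Biostrings::getGeneticCode()].
#' @return The amino-acid string.
#' @examples
#' translateSeq("AATAAC")  # "NN"
#' @export
translateSeq <- function(seq, code = "11") {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0)
    stop("sequence length (", nchar(seq), ") is not a multiple of 3")
  if (!nzchar(seq)) return("")
  gc <- .geneticCode(code)
  aa <- gc[.splitCodons(seq)]
  aa[is.na(aa)] <- "X"
  .c2s(aa)
}

#' Find open reading frames on both strands
#'
#' Scans all six frames for complete ORFs: a start codon (ATG, GTG or TTG),
#' no internal stop, and a terminating stop codon under the chosen genetic
#' code. Within each frame, the reported ORF for a given stop codon begins at
#' the first start codon after the previous stop (i.e. the longest complete
#' ORF per stop). Results are sorted by start coordinate.
#'
#' @param genome A [GenomeRecord-class] or nucleotide string.
#' @param minAa Minimum protein length in residues (stop excluded).
#' @param code Genetic code table id.
#' @return A [GenomicRanges::GRanges] (1-based inclusive coordinates, stop
#'   codon included in the range) with metadata columns `protein` and `label`
#'   (`NA`; fill from annotation).
#' @examples
#' findOrfs(genomeRecord("g", "ATGAAATAA"), minAa = 2)
#' @export
findOrfs <- function(genome, minAa = 50L, code = "11") {
  if (is(genome, "GenomeRecord")) {
    s <- genomeSeq(genome)
    id <- genomeId(genome)
  } else {
    s <- toupper(as.character(genome))
    id <- "seq"
  }
  minAa <- as.integer(minAa)
  if (minAa < 1L) stop("minAa must be >= 1")
  gc <- .geneticCode(code)
  stops <- names(gc)[gc == "*"]
  startsC <- c("ATG", "GTG", "TTG")
  L <- nchar(s)
  rows <- list()
  for (str in c("+", "-")) {
    sc <- if (str == "+") s else .revComp(s)
    for (f in 0:2) {
      n <- (L - f) %/% 3L
      if (n < minAa + 1L) next
      cod <- substring(sc, f + 3L * (seq_len(n) - 1L) + 1L, f + 3L * seq_len(n))
      stopIdx <- which(cod %in% stops)
      startMask <- cod %in% startsC
      prev <- 0L
      for (si in stopIdx) {
        if (si - 1L >= prev + 1L) {
          rel <- which(startMask[(prev + 1L):(si - 1L)])
          if (length(rel)) {
            st <- prev + rel[1L]
            if (si - st >= minAa) {
              b1 <- f + 3L * (st - 1L) + 1L
              b2 <- f + 3L * si
              aa <- gc[cod[st:(si - 1L)]]
              aa[is.na(aa)] <- "X"
              if (str == "+") {
                gs <- b1; ge <- b2
              } else {
                gs <- L - b2 + 1L; ge <- L - b1 + 1L
              }
              rows[[length(rows) + 1L]] <-
                list(start = gs, end = ge, strand = str, protein = .c2s(aa))
            }
          }
        }
        prev <- si
      }
    }
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges(protein = character(0), label = character(0)))
  }
  df <- do.call(rbind.data.frame, rows)
  df <- df[order(df$start, df$end), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, protein = df$protein, label = NA_character_)
}

#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment (nucleotide: match +1 / mismatch -1;
#' protein: BLOSUM62; gap opening 10, gap extension 0.5) with identity
#' defined as identical columns divided by the full alignment length, gap
#' columns included. Arguments are ordered canonically before alignment, so
#' the value is symmetric in its arguments.
#'
#' @param a,b Sequences to compare (non-empty).
#' @param mode `"nucleotide"` or `"protein"`.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("ACGT", "ACGT")            # 1
#' pairwiseIdentity("AAAA", "TTTT")            # 0
#' @export
pairwiseIdentity <- function(a, b, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  if (mode == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5)
  }
  p <- .s2c(as.character(Biostrings::alignedPattern(aln)))
  q <- .s2c(as.character(Biostrings::alignedSubject(aln)))
  sum(p == q & p != "-") / length(p)
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
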