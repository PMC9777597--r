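## Position-frequency-matrix scanning for allele-dependent transcription
## factor binding sites: JASPAR flat-file parsing, PFM -> log-odds PWM,
## min-max relative scores, and a two-allele difference scan.

#' Construct a Motif from a count matrix
#'
#' @param counts 4 x L non-negative matrix with rownames A, C, G, T.
#' @param name transcription-factor name.
#' @param id matrix identifier (optional).
#' @return a \linkS4class{Motif}.
#' @export
Motif <- function(counts, name, id = "") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) == 4)
    rownames(counts) <- c("A", "C", "G", "T")
  new("Motif", name = name, id = id, counts = counts)
}

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif %s (%s), length %d, consensus %s\n", object@name,
              if (nzchar(object@id)) object@id else "no id",
              ncol(object@counts), consensusSequence(object)))
})

#' @rdname Motif-class
#' @param motif a \linkS4class{Motif}.
#' @return the consensus sequence (highest-count base per column; ties go
#'   to the alphabetically first base).
#' @export
consensusSequence <- function(motif) {
  paste(rownames(motif@counts)[apply(motif@counts, 2, which.max)],
        collapse = "")
}

#' Read motifs from a JASPAR flat file
#'
#' Parses the JASPAR ".jaspar"/".pfm" format: a header line
#' \code{>ID NAME} followed by four rows \code{A [ counts ]} etc.  Files
#' may hold several motifs.
#'
#' @param path file path.
#' @return a single \linkS4class{Motif}, or a named list when the file
#'   contains more than one.
#' @export
readJaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("not a JASPAR file: no '>' header in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    at <- heads[h]
    if (at + 4 > length(lines)) stop("truncated motif at end of ", path)
    hdr <- strsplit(sub("^>\\s*", "", lines[at]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else hdr[1]
    rows <- lapply(lines[at + 1:4], function(l) {
      base <- sub("^([ACGT]).*", "\\1", l)
      nums <- sub("^[ACGT]\\s*\\[?", "", l)
      nums <- sub("\\]\\s*$", "", nums)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) stop("unparseable count row in ", path, ": ", l)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("motif ", id, " must have rows A, C, G, T")
    lens <- vapply(rows, function(r) length(r$vals), integer(1))
    if (length(unique(lens)) != 1)
      stop("motif ", id, " has count rows of unequal length")
    if (any(vapply(rows, function(r) any(r$vals < 0), logical(1))))
      stop("motif ", id, " has negative counts")
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    out[[name]] <- Motif(counts, name = name, id = id)
  }
  if (length(out) == 1) out[[1]] else out
}

#' @rdname readJaspar
#' @param motifs a \linkS4class{Motif} or list of them.
#' @export
writeJaspar <- function(motifs, path) {
  if (is(motifs, "Motif")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", if (nzchar(m@id)) m@id else m@name, " ", m@name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m@counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Column-wise: probability = (count + pseudocount * background) /
#' (columnTotal + pseudocount); weight = log2(probability / background).
#' The pseudocount is split across bases in proportion to the background.
#'
#' @param motif a \linkS4class{Motif}.
#' @param pseudocount total pseudocount per column (default 0.8, a common
#'   JASPAR-tooling convention).
#' @param background base frequencies (A, C, G, T), summing to 1; default
#'   uniform.
#' @return 4 x L numeric log2-odds matrix.
#' @export
pfmToPwm <- function(motif, pseudocount = 0.8, background = rep(0.25, 4)) {
  stopifnot(is(motif, "Motif"), pseudocount > 0,
            abs(sum(background) - 1) < 1e-6)
  cnt <- motif@counts
  N <- colSums(cnt)
  prob <- sweep(cnt + pseudocount * background,
                2, N + pseudocount, "/")
  log2(prob / background)
}

#' Min-max relative score of a window against a PWM
#'
#' The raw log-odds score is rescaled by the best and worst attainable
#' scores of the matrix:
#' (raw - min) / (max - min), so the consensus scores exactly 1 and the
#' anti-consensus exactly 0.  Windows containing an ambiguous base return
#' NA.
#'
#' @param pwm log-odds matrix from [pfmToPwm()].
#' @param window character string of length \code{ncol(pwm)} over A/C/G/T.
#' @return relative score in [0, 1], or NA for ambiguous windows.
#' @export
relativeScore <- function(pwm, window) {
  L <- ncol(pwm)
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != L)
    stop("window length ", length(chars), " != motif length ", L)
  rows <- match(chars, rownames(pwm))
  if (anyNA(rows)) return(NA_real_)
  raw <- sum(pwm[cbind(rows, seq_len(L))])
  lo <- sum(apply(pwm, 2, min))
  hi <- sum(apply(pwm, 2, max))
  (raw - lo) / (hi - lo)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## all windows of a given allele's sequence that overlap the SNP position,
## both strands, with their relative scores
.scanOne <- function(seq, snpPos, pwm, threshold) {
  L <- ncol(pwm)
  lo <- max(1, snpPos - L + 1)
  hi <- min(nchar(seq) - L + 1, snpPos)
  if (hi < lo) return(NULL)
  starts <- lo:hi
  rows <- list()
  for (s in starts) {
    win <- substr(seq, s, s + L - 1)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else .revcomp(win)
      sc <- relativeScore(pwm, w)
      if (!is.na(sc))
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, strand = strand, site = w, score = sc,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Scan two alleles of a SNP for gained or lost binding sites
#'
#' For each motif and each allele the flanking sequence is scanned over
#' every window overlapping the SNP position, on both strands; a site is
#' "present" when its min-max relative score reaches \code{threshold}
#' (default 0.90).  Sites present for exactly one allele are reported as
#' gained (alt only) or lost (ref only).
#'
#' @param flank flanking sequence (character or
#'   [Biostrings::DNAString]) carrying the reference allele at
#'   \code{snpPos}.
#' @param snpPos 1-based position of the SNP within \code{flank}.
#' @param ref,alt the two alleles (single bases).
#' @param motifs a \linkS4class{Motif} or list of motifs.
#' @param threshold relative-score call threshold (default 0.90).
#' @param pseudocount,background passed to [pfmToPwm()].
#' @return data.frame of allele-dependent sites: motif, allele, start,
#'   strand, site, score, status ("lost" = present for ref only, "gained"
#'   = present for alt only).  Attribute \code{"hits"} holds all
#'   above-threshold hits for both alleles.
#' @export
scanAlleles <- function(flank, snpPos, ref, alt, motifs, threshold = 0.90,
                        pseudocount = 0.8, background = rep(0.25, 4)) {
  flank <- toupper(as.character(flank))
  stopifnot(nchar(ref) == 1, nchar(alt) == 1,
            snpPos >= 1, snpPos <= nchar(flank))
  if (substr(flank, snpPos, snpPos) != toupper(ref))
    stop("flank does not carry the ref allele at snpPos")
  if (is(motifs, "Motif")) motifs <- list(motifs)
  seqs <- c(ref = flank,
            alt = paste0(substr(flank, 1, snpPos - 1), toupper(alt),
                         substr(flank, snpPos + 1, nchar(flank))))
  allHits <- list()
  diffs <- list()
  for (m in motifs) {
    L <- ncol(m@counts)
    if (snpPos < 1 || nchar(flank) < L) {
      warning("flank too short for motif ", m@name, "; skipped")
      next
    }
    pwm <- pfmToPwm(m, pseudocount, background)
    hits <- lapply(names(seqs), function(al) {
      h <- .scanOne(seqs[[al]], snpPos, pwm, threshold)
      if (is.null(h)) return(NULL)
      h <- h[h$score >= threshold, , drop = FALSE]
      if (!nrow(h)) return(NULL)
      data.frame(motif = m@name, allele = al, h, stringsAsFactors = FALSE)
    })
    names(hits) <- names(seqs)
    key <- function(h) if (is.null(h)) character(0) else
      paste(h$start, h$strand)
    refKeys <- key(hits$ref)
    altKeys <- key(hits$alt)
    lost <- hits$ref[!(refKeys %in% altKeys), , drop = FALSE]
    gained <- hits$alt[!(altKeys %in% refKeys), , drop = FALSE]
    if (!is.null(lost) && nrow(lost)) {
      lost$status <- "lost"
      diffs[[length(diffs) + 1L]] <- lost
    }
    if (!is.null(gained) && nrow(gained)) {
      gained$status <- "gained"
      diffs[[length(diffs) + 1L]] <- gained
    }
    allHits <- c(allHits, hits[!vapply(hits, is.null, logical(1))])
  }
  empty <- data.frame(motif = character(0), allele = character(0),
                      start = integer(0), strand = character(0),
                      site = character(0), score = numeric(0),
                      status = character(0), stringsAsFactors = FALSE)
  res <- if (length(diffs)) do.call(rbind, diffs) else empty
  ## ref and alt alleles report the allele actually carried at the SNP
  res$allele[res$allele == "ref"] <- toupper(ref)
  res$allele[res$allele == "alt"] <- toupper(alt)
  hitsAll <- if (length(allHits)) do.call(rbind, allHits) else empty[, 1:6]
  hitsAll$allele[hitsAll$allele == "ref"] <- toupper(ref)
  hitsAll$allele[hitsAll$allele == "alt"] <- toupper(alt)
  rownames(hitsAll) <- NULL
  rownames(res) <- NULL
  attr(res, "hits") <- hitsAll
  res
}
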