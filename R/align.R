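#' Alignment scoring scheme
#'
#' BLASTn-like scoring for nucleotide local alignment. A gap of length k
#' costs \code{gapOpen + k * gapExtend}.
#'
#' @param match match reward (> 0)
#' @param mismatch mismatch penalty (<= 0)
#' @param gapOpen gap opening penalty (<= 0)
#' @param gapExtend per-base gap extension penalty (<= 0)
#' @return a list with the four components
#' @export
scoringScheme <- function(match = 1, mismatch = -2, gapOpen = -5,
                          gapExtend = -2) {
  stopifnot(match > 0, mismatch <= 0, gapOpen <= 0, gapExtend <= 0)
  list(match = match, mismatch = mismatch, gapOpen = gapOpen,
       gapExtend = gapExtend)
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.emptyHsps <- function() {
  data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
             b_end = integer(), strand = character(), aln_len = integer(),
             matches = integer(), gap_opens = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

# one banded/exact DP call returning a one-row HSP data.frame (or NULL)
.swHsp <- function(a, b, s, bandLo, bandHi) {
  r <- .sw_band(a, b, s$match, s$mismatch, s$gapOpen, s$gapExtend,
                bandLo, bandHi)
  if (r$score <= 0) return(NULL)
  data.frame(a_start = r$a_start, a_end = r$a_end, b_start = r$b_start,
             b_end = r$b_end, strand = "+", aln_len = r$aln_len,
             matches = r$matches, gap_opens = r$gap_opens,
             score = r$score, stringsAsFactors = FALSE)
}

.maskRegion <- function(x, from0, to0) {
  # replace [from0, to0) with the sentinel '#'
  paste0(substr(x, 1L, from0), strrep("#", to0 - from0),
         substr(x, to0 + 1L, nchar(x)))
}

# exact path: iterated full Smith-Waterman with masking of reported HSPs
.alignExact <- function(a, b, s, maxHsps) {
  out <- list()
  for (k in seq_len(maxHsps)) {
    h <- .swHsp(a, b, s, -nchar(a), nchar(b))
    if (is.null(h)) break
    out[[k]] <- h
    a <- .maskRegion(a, h$a_start, h$a_end)
    b <- .maskRegion(b, h$b_start, h$b_end)
  }
  if (length(out)) do.call(rbind, out) else .emptyHsps()
}

# seed hits between a and b: 0-based start pairs of shared k-mers.
# Low-complexity k-mers (mitogenomes are AT-rich, so near-homopolymer
# words are everywhere) and k-mers occurring too often in either sequence
# are excluded, as a word-frequency/DUST-style filter.
.seedHits <- function(a, b, k, maxKmerHits = 4L, maxMonoFrac = 8L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(NULL)
  akm <- substring(a, 1:(na - k + 1L), k:na)
  bkm <- substring(b, 1:(nb - k + 1L), k:nb)
  complexEnough <- function(km) {
    mono <- pmax(nchar(gsub("[^A]", "", km)), nchar(gsub("[^C]", "", km)),
                 nchar(gsub("[^G]", "", km)), nchar(gsub("[^T]", "", km)))
    mono < maxMonoFrac & !grepl("[^ACGT]", km)
  }
  keep <- complexEnough(akm)
  idx <- split(which(keep), akm[keep])
  idx <- idx[lengths(idx) <= maxKmerHits]
  bcount <- stats::ave(seq_along(bkm), bkm, FUN = length)
  hit <- bcount <= maxKmerHits & bkm %in% names(idx)
  if (!any(hit)) return(NULL)
  bpos <- which(hit)
  apos <- idx[bkm[bpos]]
  reps <- lengths(apos)
  data.frame(a0 = unlist(apos, use.names = FALSE) - 1L,
             b0 = rep(bpos, reps) - 1L)
}

# group seeds into clusters by diagonal proximity and then by position
# along a, so unrelated homologous segments that happen to sit on nearby
# diagonals do not chain into one huge DP window; each cluster defines a
# window (sequence ranges around its seeds) plus a diagonal band inside
# it; a cluster must contain at least two seed hits (two-hit rule), and
# only the most seed-rich clusters are extended
.seedBands <- function(hits, diagGap = 60L, posGap = 800L, maxBand = 3000L,
                       minSeeds = 2L, maxClusters = 8L) {
  d <- hits$b0 - hits$a0
  o <- order(d)
  grp <- cumsum(c(TRUE, diff(d[o]) > diagGap))
  cl <- list()
  for (idx in split(o, grp)) {
    idx <- idx[order(hits$a0[idx])]
    run <- cumsum(c(TRUE, diff(hits$a0[idx]) > posGap))
    for (sub in split(idx, run)) {
      if (length(sub) < minSeeds) next
      dd <- sort(d[sub])
      # chance word matches scatter widely in diagonal even inside one
      # run, while a genuine alignment concentrates its seeds: centre the
      # band on the densest diagonal window, then take the quantile core
      # of the seeds inside it
      win <- 300L
      j <- 1L; best <- 0L; ctr <- dd[1L]
      for (i2 in seq_along(dd)) {
        while (dd[i2] - dd[j] > 2L * win) j <- j + 1L
        if (i2 - j + 1L > best) {
          best <- i2 - j + 1L
          ctr <- (dd[i2] + dd[j]) %/% 2L
        }
      }
      sel <- dd[dd >= ctr - win & dd <= ctr + win]
      lo <- floor(stats::quantile(sel, 0.02, names = FALSE)) - diagGap
      hi <- ceiling(stats::quantile(sel, 0.98, names = FALSE)) + diagGap
      if (hi - lo > maxBand) {
        mid <- stats::median(dd)
        lo <- mid - maxBand %/% 2L
        hi <- mid + maxBand %/% 2L
      }
      cl[[length(cl) + 1L]] <-
        list(dlo = lo, dhi = hi, alo = min(hits$a0[sub]),
             ahi = max(hits$a0[sub]), blo = min(hits$b0[sub]),
             bhi = max(hits$b0[sub]), n = length(sub))
    }
  }
  if (length(cl) > maxClusters)
    cl <- cl[order(-vapply(cl, `[[`, integer(1), "n"))][seq_len(maxClusters)]
  cl
}

# heuristic path: seed, then exact affine DP banded inside a window around
# each seed cluster, iterated with masking, then greedy selection of
# non-overlapping HSPs by score
.alignSeeded <- function(a, b, s, maxHsps, seedLength, margin = 600L,
                         cellBudget = 2e7) {
  hits <- .seedHits(a, b, seedLength)
  if (is.null(hits)) return(.emptyHsps())
  bands <- .seedBands(hits)
  if (!length(bands)) return(.emptyHsps())
  bands <- bands[order(-vapply(bands, `[[`, integer(1), "n"))]
  out <- list()
  spent <- 0
  for (band in bands) {
    cells <- (band$ahi - band$alo + 2 * margin) *
      (band$dhi - band$dlo + 1)
    if (spent + cells > cellBudget && length(out)) next
    spent <- spent + cells
    aw <- c(max(0L, band$alo - margin),
            min(nchar(a), band$ahi + seedLength + margin))
    bw <- c(max(0L, band$blo - margin),
            min(nchar(b), band$bhi + seedLength + margin))
    aa <- substr(a, aw[1L] + 1L, aw[2L])
    bb <- substr(b, bw[1L] + 1L, bw[2L])
    shift <- bw[1L] - aw[1L]
    for (k in seq_len(maxHsps)) {
      h <- .swHsp(aa, bb, s, band$dlo - shift, band$dhi - shift)
      if (is.null(h)) break
      aa <- .maskRegion(aa, h$a_start, h$a_end)
      bb <- .maskRegion(bb, h$b_start, h$b_end)
      h$a_start <- h$a_start + aw[1L]; h$a_end <- h$a_end + aw[1L]
      h$b_start <- h$b_start + bw[1L]; h$b_end <- h$b_end + bw[1L]
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(.emptyHsps())
  hsps <- do.call(rbind, out)
  hsps <- hsps[order(-hsps$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hsps))
  for (i in seq_len(nrow(hsps))[-1L]) {
    prior <- hsps[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], ,
                                                   drop = FALSE]
    if (any(hsps$a_start[i] < prior$a_end & prior$a_start < hsps$a_end[i] &
            hsps$b_start[i] < prior$b_end & prior$b_start < hsps$b_end[i]))
      keep[i] <- FALSE
  }
  hsps[keep, , drop = FALSE]
}

#' Local alignment of two DNA sequences into HSPs
#'
#' Produces high-scoring segment pairs (HSPs) between two sequences. When
#' both sequences are at most \code{exactLimit} bp the alignment is exact
#' iterated Smith-Waterman; longer pairs use a seeded heuristic (shared
#' 11-mers grouped into diagonal bands, exact affine DP inside each band).
#' Both strands of \code{b} are searched and minus-strand HSPs are reported
#' in original \code{b} coordinates with \code{strand = "-"}.
#'
#' Coordinates are 0-based half-open. HSPs are sorted by alignment length
#' descending (ties: more matches, then smaller a_start), so the first row
#' is the "longest continuous alignment" used by the similarity network.
#'
#' @param a,b DNA character strings (uppercase A/C/G/T/N)
#' @param scoring a \code{\link{scoringScheme}}
#' @param maxHsps maximum HSPs reported per strand
#' @param bothStrands also search the reverse complement of \code{b}
#' @param exactLimit size bound for the exact path
#' @param seedLength seed k-mer length of the heuristic path
#' @return data.frame of HSPs (possibly empty) with columns a_start, a_end,
#'   b_start, b_end, strand, aln_len, matches, gap_opens, score
#' @export
localAlign <- function(a, b, scoring = scoringScheme(), maxHsps = 10L,
                       bothStrands = TRUE, exactLimit = 2000L,
                       seedLength = 11L) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a); b <- toupper(b)
  engine <- if (nchar(a) <= exactLimit && nchar(b) <= exactLimit)
    function(x, y) .alignExact(x, y, scoring, maxHsps)
  else
    function(x, y) .alignSeeded(x, y, scoring, maxHsps, seedLength)
  hsps <- engine(a, b)
  if (bothStrands) {
    rc <- engine(a, .revcomp(b))
    if (nrow(rc)) {
      m <- nchar(b)
      bs <- m - rc$b_end
      rc$b_end <- m - rc$b_start
      rc$b_start <- bs
      rc$strand <- "-"
      hsps <- rbind(hsps, rc)
    }
  }
  if (!nrow(hsps)) return(hsps)
  hsps <- hsps[order(-hsps$aln_len, -hsps$matches, hsps$a_start), ,
               drop = FALSE]
  rownames(hsps) <- NULL
  hsps
}

#' Identity of one HSP
#'
#' The similarity index of a continuous alignment: identical columns over
#' alignment columns.
#'
#' @param hsp one-row HSP slice from \code{\link{localAlign}}
#' @return fraction in [0, 1]
#' @export
hspIdentity <- function(hsp) {
  if (any(hsp$aln_len <= 0)) stop("hspIdentity undefined for empty HSP")
  hsp$matches / hsp$aln_len
}

#' Identity between two sequences under the clustering convention
#'
#' Identical columns of the best (highest-scoring) local alignment divided
#' by the length of the shorter sequence, capped at 1 -- the global-identity
#' convention of greedy redundancy clustering, under which a perfect
#' substring scores 1 against its parent.
#'
#' @param a,b DNA character strings
#' @param scoring a \code{\link{scoringScheme}}
#' @param ... passed to \code{\link{localAlign}}
#' @return fraction in [0, 1]
#' @export
clusteringIdentity <- function(a, b, scoring = scoringScheme(), ...) {
  hsps <- localAlign(a, b, scoring = scoring, maxHsps = 1L, ...)
  if (!nrow(hsps)) return(0)
  best <- hsps[which.max(hsps$score), ]
  min(1, best$matches / min(nchar(a), nchar(b)))
}

#' Format HSPs as BLAST-style tabular output
#'
#' Columns modeled on BLAST outfmt 6 (1-based inclusive coordinates).
#'
#' @param hsps HSP data.frame from \code{\link{localAlign}}
#' @param qseqid,sseqid sequence ids for the first two columns
#' @return data.frame with columns qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, score
#' @export
hspTable <- function(hsps, qseqid = "query", sseqid = "subject") {
  if (!nrow(hsps))
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      score = numeric()))
  gapcols <- hsps$aln_len - (hsps$a_end - hsps$a_start) +
    hsps$aln_len - (hsps$b_end - hsps$b_start)
  data.frame(qseqid = qseqid, sseqid = sseqid,
             pident = round(100 * hsps$matches / hsps$aln_len, 3),
             length = hsps$aln_len,
             mismatch = hsps$aln_len - hsps$matches - gapcols,
             gapopen = hsps$gap_opens,
             qstart = hsps$a_start + 1L, qend = hsps$a_end,
             sstart = ifelse(hsps$strand == "+", hsps$b_start + 1L,
                             hsps$b_end),
             send = ifelse(hsps$strand == "+", hsps$b_end,
                           hsps$b_start + 1L),
             score = hsps$score, stringsAsFactors = FALSE)
}
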