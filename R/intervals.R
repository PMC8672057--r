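#' Canonicalize feature coordinates into an interval set
#'
#' Implements the overlap-removal step of genic length accounting: feature
#' coordinates are projected onto a single axis (strand is ignored),
#' origin-wrapping features on circular genomes are split into their two
#' arcs, and overlapping or adjacent segments are merged. The covered
#' length of the result is the "final genic length" of the feature set.
#'
#' @param features feature data.frame (columns start, end, wraps_origin),
#'   or a \linkS4class{MitoGenome} (then all its features are used)
#' @param genomeLength genome length in bp (ignored when a genome is given)
#' @param topology \code{"circular"} or \code{"linear"} (ignored when a
#'   genome is given)
#' @return an \linkS4class{IntervalSet}
#' @examples
#' f <- data.frame(name = c("a", "b"), start = c(1L, 51L),
#'                 end = c(100L, 150L), strand = "+", wraps_origin = FALSE)
#' coveredLength(featureIntervals(f, 1000L, "linear"))
#' @export
featureIntervals <- function(features, genomeLength, topology = "circular") {
  if (is(features, "MitoGenome")) {
    genomeLength <- length(features@seq)
    topology <- features@topology
    features <- features@features
  }
  genomeLength <- as.integer(genomeLength)
  if (!nrow(features))
    return(new("IntervalSet", genomeLength = genomeLength,
               topology = topology, start0 = integer(), end0 = integer()))
  if (any(features$wraps_origin) && topology != "circular")
    stop("wrapping features on a linear genome")
  w <- features$wraps_origin
  start0 <- c(features$start[!w] - 1L, features$start[w] - 1L,
              rep(0L, sum(w)))
  end0 <- c(features$end[!w], rep(genomeLength, sum(w)), features$end[w])
  ir <- IRanges::reduce(IRanges::IRanges(start = start0 + 1L, end = end0))
  new("IntervalSet", genomeLength = genomeLength, topology = topology,
      start0 = IRanges::start(ir) - 1L, end0 = IRanges::end(ir))
}

#' @describeIn featureIntervals total covered length in bp (the final genic
#'   length after overlap removal)
#' @param x an \linkS4class{IntervalSet}
#' @export
setMethod("coveredLength", "IntervalSet", function(x)
  sum(x@end0 - x@start0))

#' Total intergenic length of a genome
#'
#' Genome length minus the union coverage of all annotated features.
#'
#' @param genome a \linkS4class{MitoGenome}
#' @return integer bp, between 0 and the genome length
#' @export
intergenicLength <- function(genome) {
  genomeLength(genome) - coveredLength(featureIntervals(genome))
}

setMethod("show", "IntervalSet", function(object) {
  cat("IntervalSet on", object@genomeLength, "bp", object@topology,
      "genome:", length(object@start0), "segments,",
      coveredLength(object), "bp covered\n")
})

.asIRanges <- function(s) IRanges::IRanges(start = s@start0 + 1L, end = s@end0)

# 0-based half-open segments of one feature (wrap split into two arcs)
.featureSegments <- function(start, end, wraps, genomeLength) {
  if (wraps)
    IRanges::IRanges(start = c(start, 1L), end = c(genomeLength, end))
  else
    IRanges::IRanges(start = start, end = end)
}

#' Overlap statistics between two feature categories
#'
#' For each feature of set A, measures its overlap with the union of set B:
#' \code{overlapping} counts A features sharing at least one bp with
#' union(B); \code{within} counts A features fully contained in union(B).
#' Both statistics the comparative analysis reports ("within intronic
#' regions", "overlap with HEG coordinates") are computed; each A feature is
#' counted once regardless of how many B features it touches.
#'
#' @param A,B feature data.frames from the same genome (e.g. the HEGs and
#'   the introns)
#' @param genomeLength genome length in bp
#' @param topology genome topology
#' @return list with n_A, n_A_overlapping_B, n_A_within_B and the two
#'   fractions (NA when A is empty)
#' @export
overlapReport <- function(A, B, genomeLength, topology = "circular") {
  genomeLength <- as.integer(genomeLength)
  nA <- nrow(A)
  bU <- .asIRanges(featureIntervals(B, genomeLength, topology))
  overlapping <- 0L; within <- 0L
  if (nA) for (i in seq_len(nA)) {
    segs <- .featureSegments(A$start[i], A$end[i], A$wraps_origin[i],
                             genomeLength)
    inter <- sum(IRanges::width(IRanges::intersect(segs, bU)))
    flen <- sum(IRanges::width(segs))
    if (inter > 0L) overlapping <- overlapping + 1L
    if (inter == flen) within <- within + 1L
  }
  list(n_A = nA,
       n_A_overlapping_B = overlapping,
       n_A_within_B = within,
       fraction_overlapping = if (nA) overlapping / nA else NA_real_,
       fraction_within = if (nA) within / nA else NA_real_)
}

#' Pool per-genome overlap reports over a dataset
#'
#' Fractions are computed over the summed counts ("of all HEGs"), not as a
#' mean of per-genome fractions.
#'
#' @param reports list of \code{\link{overlapReport}} results
#' @return one pooled report of the same shape
#' @export
poolOverlapReports <- function(reports) {
  nA <- sum(vapply(reports, `[[`, numeric(1), "n_A"))
  ov <- sum(vapply(reports, `[[`, numeric(1), "n_A_overlapping_B"))
  wi <- sum(vapply(reports, `[[`, numeric(1), "n_A_within_B"))
  list(n_A = nA, n_A_overlapping_B = ov, n_A_within_B = wi,
       fraction_overlapping = if (nA) ov / nA else NA_real_,
       fraction_within = if (nA) wi / nA else NA_real_)
}
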