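#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings DNAString
#' @importFrom Biostrings uniqueLetters
#' @useDynLib mitoCensus, .registration = TRUE
NULL

#' Supported mitochondrial genetic codes
#'
#' The four NCBI translation tables observed across fungal mitogenomes:
#' 1 (standard), 3 (yeast mitochondrial), 4 (mold/protozoan/coelenterate
#' mitochondrial) and 16 (chlorophycean mitochondrial).
#'
#' @export
SUPPORTED_GENETIC_CODES <- c(1L, 3L, 4L, 16L)

.FEATURE_COLUMNS <- c("name", "category", "subtype", "start", "end",
                      "strand", "wraps_origin")

.emptyFeatures <- function() {
  data.frame(name = character(), category = character(),
             subtype = character(), start = integer(), end = integer(),
             strand = character(), wraps_origin = logical(),
             stringsAsFactors = FALSE)
}

#' An annotated mitochondrial genome
#'
#' Bundles one genome sequence with its feature annotation. Coordinates in
#' the \code{features} slot are 1-based inclusive, as in feature tables and
#' GenBank records; a feature with \code{wraps_origin = TRUE} (permitted only
#' on circular genomes) runs from \code{start} to the sequence end and
#' continues from position 1 to \code{end}.
#'
#' @slot id single character, accession-like identifier
#' @slot seq a \link[Biostrings]{DNAString} over A, C, G, T, N
#' @slot topology \code{"circular"} or \code{"linear"}
#' @slot geneticCode one of \code{\link{SUPPORTED_GENETIC_CODES}}
#' @slot phylum free-text taxon label (may be \code{NA})
#' @slot features data.frame with columns name, category, subtype, start,
#'   end, strand, wraps_origin
#'
#' @exportClass MitoGenome
setClass("MitoGenome",
  slots = c(id = "character", seq = "DNAString", topology = "character",
            geneticCode = "integer", phylum = "character",
            features = "data.frame"))

setValidity("MitoGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (!is(object@seq, "DNAString"))
    msg <- c(msg, "seq must be a DNAString")
  else {
    if (length(object@seq) < 1L) msg <- c(msg, "sequence must be non-empty")
    bad <- setdiff(uniqueLetters(object@seq), c("A", "C", "G", "T", "N"))
    if (length(bad))
      msg <- c(msg, paste0("sequence contains non-ACGTN letters: ",
                           paste(bad, collapse = ",")))
  }
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  if (!object@geneticCode %in% SUPPORTED_GENETIC_CODES)
    msg <- c(msg, "geneticCode must be one of 1, 3, 4, 16")
  f <- object@features
  if (!all(.FEATURE_COLUMNS %in% names(f)))
    msg <- c(msg, paste0("features must have columns ",
                         paste(.FEATURE_COLUMNS, collapse = ", ")))
  else if (nrow(f) && is(object@seq, "DNAString")) {
    L <- length(object@seq)
    if (any(f$start < 1L | f$start > L | f$end < 1L | f$end > L))
      msg <- c(msg, "feature coordinates out of genome bounds")
    if (any(f$wraps_origin) && object@topology != "circular")
      msg <- c(msg, "origin-wrapping features require a circular genome")
    if (any(!f$wraps_origin & f$start > f$end))
      msg <- c(msg, "start > end without wraps_origin")
    if (!all(f$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' A set of annotated mitochondrial genomes
#'
#' A list-like container of \linkS4class{MitoGenome} objects with unique ids.
#'
#' @slot genomes named list of \linkS4class{MitoGenome}
#' @exportClass MitoGenomeSet
setClass("MitoGenomeSet", slots = c(genomes = "list"))

setValidity("MitoGenomeSet", function(object) {
  g <- object@genomes
  if (!all(vapply(g, is, logical(1), "MitoGenome")))
    return("all elements must be MitoGenome objects")
  ids <- unname(vapply(g, function(x) x@id, character(1)))
  if (anyDuplicated(ids)) return("genome ids must be unique")
  if (length(g) && !identical(unname(names(g)), ids))
    return("list names must equal genome ids")
  TRUE
})

#' Canonicalized circular-aware interval set
#'
#' Zero-based half-open segments on a genome axis, sorted, disjoint and with
#' adjacent segments merged. Produced by \code{\link{featureIntervals}}; the
#' building block of the overlap-removal length accounting.
#'
#' @slot genomeLength genome length in bp
#' @slot topology \code{"circular"} or \code{"linear"}
#' @slot start0 integer, 0-based inclusive segment starts
#' @slot end0 integer, exclusive segment ends
#' @exportClass IntervalSet
setClass("IntervalSet",
  slots = c(genomeLength = "integer", topology = "character",
            start0 = "integer", end0 = "integer"))

setValidity("IntervalSet", function(object) {
  s <- object@start0; e <- object@end0
  L <- object@genomeLength
  msg <- character()
  if (length(s) != length(e)) msg <- c(msg, "start0/end0 length mismatch")
  if (length(s)) {
    if (any(s >= e)) msg <- c(msg, "empty or inverted segment")
    if (any(s < 0L) || any(e > L)) msg <- c(msg, "segment outside genome")
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "segments must be sorted, disjoint and non-adjacent")
  }
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' Records what \code{\link{generateDataset}} planted, so pipeline output can
#' be compared against truth exactly: the feature tables with true categories
#' and subtypes, the planted core-gene presence matrix, family (cluster)
#' memberships, and the emitted protein-domain hits.
#'
#' @slot features data.frame of planted features across genomes (column
#'   \code{genome} plus the standard feature columns)
#' @slot corePresence logical matrix, genomes x the 16 core gene names
#' @slot families data.frame with columns genome, family, target_identity
#' @slot domainHits data.frame with columns orf_id, genome, domain_name,
#'   superfamily, e_value
#' @slot genomeInfo data.frame of planted per-genome attributes (genome,
#'   phylum, topology, genetic_code, length, gc_target)
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(features = "data.frame", corePresence = "matrix",
            families = "data.frame", domainHits = "data.frame",
            genomeInfo = "data.frame"))
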