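#' Construct an annotated mitochondrial genome
#'
#' @param id single accession-like identifier
#' @param seq DNA sequence as a character string or
#'   \link[Biostrings]{DNAString}; lowercase is uppercased and U is mapped
#'   to T; IUPAC ambiguity letters other than N are collapsed to N
#' @param topology \code{"circular"} (default) or \code{"linear"}
#' @param geneticCode NCBI translation table, one of 1, 3, 4, 16
#' @param phylum optional taxon label
#' @param features optional feature data.frame as returned by
#'   \code{\link{readFeatureTable}}; missing annotation columns are added
#'
#' @return a \linkS4class{MitoGenome}
#' @examples
#' g <- MitoGenome("g1", "ACGTACGTACGT")
#' genomeLength(g)
#' @export
MitoGenome <- function(id, seq, topology = "circular", geneticCode = 1L,
                       phylum = NA_character_, features = NULL) {
  if (is.character(seq)) seq <- Biostrings::DNAString(.cleanDNA(seq, id))
  if (is.null(features)) features <- .emptyFeatures()
  features <- .completeFeatureColumns(features)
  new("MitoGenome", id = as.character(id), seq = seq,
      topology = topology, geneticCode = as.integer(geneticCode),
      phylum = as.character(phylum), features = features)
}

.completeFeatureColumns <- function(f) {
  n <- nrow(f)
  if (is.null(f$category)) f$category <- rep(NA_character_, n)
  if (is.null(f$subtype)) f$subtype <- rep(NA_character_, n)
  if (is.null(f$wraps_origin)) f$wraps_origin <- rep(FALSE, n)
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  rownames(f) <- NULL
  f[, .FEATURE_COLUMNS]
}

# uppercase, U->T, collapse non-N IUPAC ambiguity codes to N; error on
# anything outside the IUPAC alphabet, naming the record and position
.cleanDNA <- function(s, id = "?") {
  s <- toupper(s)
  s <- chartr("U", "T", s)
  ambi <- "RYSWKMBDHV"
  s <- chartr(ambi, strrep("N", nchar(ambi)), s)
  bad <- regexpr("[^ACGTN]", s)
  if (bad != -1L)
    stop("record '", id, "': non-IUPAC character '",
         substr(s, bad, bad), "' at position ", bad)
  s
}

#' Accessors for MitoGenome and MitoGenomeSet
#'
#' @param x a \linkS4class{MitoGenome} or \linkS4class{MitoGenomeSet}
#' @param value replacement feature data.frame
#' @return the corresponding slot value; for a set, a vector or list over
#'   its genomes
#' @name MitoGenome-accessors
NULL

#' @rdname MitoGenome-accessors
setMethod("genomeId", "MitoGenome", function(x) x@id)
#' @rdname MitoGenome-accessors
setMethod("genomeSeq", "MitoGenome", function(x) x@seq)
#' @rdname MitoGenome-accessors
setMethod("topology", "MitoGenome", function(x) x@topology)
#' @rdname MitoGenome-accessors
setMethod("geneticCode", "MitoGenome", function(x) x@geneticCode)
#' @rdname MitoGenome-accessors
setMethod("phylum", "MitoGenome", function(x) x@phylum)
#' @rdname MitoGenome-accessors
setMethod("features", "MitoGenome", function(x) x@features)
#' @rdname MitoGenome-accessors
setMethod("genomeLength", "MitoGenome", function(x) length(x@seq))

#' @rdname MitoGenome-accessors
setReplaceMethod("features", "MitoGenome", function(x, value) {
  x@features <- .completeFeatureColumns(value)
  validObject(x)
  x
})

setMethod("show", "MitoGenome", function(object) {
  cat("MitoGenome", object@id, "|", length(object@seq), "bp",
      object@topology, "| code", object@geneticCode, "|",
      nrow(object@features), "features\n")
})

#' Construct a set of annotated genomes
#'
#' @param ... \linkS4class{MitoGenome} objects, or a single list of them
#' @return a \linkS4class{MitoGenomeSet}
#' @export
MitoGenomeSet <- function(...) {
  g <- list(...)
  if (length(g) == 1L && is.list(g[[1L]]) && !is(g[[1L]], "MitoGenome"))
    g <- g[[1L]]
  names(g) <- vapply(g, function(x) x@id, character(1))
  new("MitoGenomeSet", genomes = g)
}

#' @rdname MitoGenome-accessors
#' @export
setMethod("length", "MitoGenomeSet", function(x) length(x@genomes))

#' @rdname MitoGenome-accessors
#' @export
setMethod("names", "MitoGenomeSet", function(x) names(x@genomes))

#' @param i index or genome id
#' @rdname MitoGenome-accessors
#' @export
setMethod("[[", "MitoGenomeSet", function(x, i) x@genomes[[i]])

#' @rdname MitoGenome-accessors
#' @export
setMethod("[", "MitoGenomeSet", function(x, i) {
  new("MitoGenomeSet", genomes = x@genomes[i])
})

#' @rdname MitoGenome-accessors
setMethod("genomeId", "MitoGenomeSet", function(x) names(x@genomes))

#' @rdname MitoGenome-accessors
setMethod("genomeLength", "MitoGenomeSet", function(x)
  vapply(x@genomes, genomeLength, integer(1)))

setMethod("show", "MitoGenomeSet", function(object) {
  n <- length(object@genomes)
  cat("MitoGenomeSet of", n, "genomes\n")
  if (n) {
    L <- genomeLength(object)
    cat("  length range:", min(L), "-", max(L), "bp\n")
  }
})

#' Iterate over the genomes of a set
#'
#' @param X a \linkS4class{MitoGenomeSet}
#' @param FUN function applied to each \linkS4class{MitoGenome}
#' @param ... passed to \code{FUN}
#' @return a list, as \code{lapply}
#' @export
setMethod("lapply", "MitoGenomeSet", function(X, FUN, ...) {
  lapply(X@genomes, FUN, ...)
})

#' Coerce a genome set to a plain named list
#'
#' @param x a \linkS4class{MitoGenomeSet}
#' @param ... ignored
#' @return named list of \linkS4class{MitoGenome}
#' @export
as.list.MitoGenomeSet <- function(x, ...) x@genomes

#' Extract the nucleotide sequence of one feature
#'
#' Handles origin-wrapping features (concatenating the two arcs) and minus
#' strand features (reverse complement).
#'
#' @param genome a \linkS4class{MitoGenome}
#' @param feature a one-row slice of \code{features(genome)}
#' @return character DNA sequence of the feature
#' @export
featureSequence <- function(genome, feature) {
  s <- genome@seq
  L <- length(s)
  if (isTRUE(feature$wraps_origin)) {
    part <- paste0(as.character(Biostrings::subseq(s, feature$start, L)),
                   as.character(Biostrings::subseq(s, 1L, feature$end)))
  } else {
    part <- as.character(Biostrings::subseq(s, feature$start, feature$end))
  }
  if (identical(feature$strand, "-"))
    part <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(part)))
  part
}

#' Length of a feature in bp, wrap-aware
#'
#' @param feature one-row feature slice
#' @param genomeLength genome length in bp (needed for wrapping features)
#' @return integer length
#' @export
featureLength <- function(feature, genomeLength) {
  ifelse(feature$wraps_origin,
         (genomeLength - feature$start + 1L) + feature$end,
         feature$end - feature$start + 1L)
}

#' Rotate the origin of a circular genome
#'
#' Shifts the sequence so that former position \code{offset + 1} becomes
#' position 1, remapping all feature coordinates (possibly introducing or
#' removing origin wraps). Used to check rotation invariance of the interval
#' accounting.
#'
#' @param genome a circular \linkS4class{MitoGenome}
#' @param offset rotation in bp, 0 to genome length - 1
#' @return the rotated \linkS4class{MitoGenome}
#' @export
rotateGenome <- function(genome, offset) {
  stopifnot(topology(genome) == "circular")
  L <- genomeLength(genome)
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(genome)
  s <- as.character(genome@seq)
  newseq <- paste0(substr(s, offset + 1L, L), substr(s, 1L, offset))
  f <- genome@features
  if (nrow(f)) {
    ns <- ((f$start - 1L - offset) %% L) + 1L
    ne <- ((f$end - 1L - offset) %% L) + 1L
    f$start <- ns
    f$end <- ne
    f$wraps_origin <- ns > ne
  }
  MitoGenome(genome@id, newseq, topology = genome@topology,
             geneticCode = genome@geneticCode, phylum = genome@phylum,
             features = f)
}
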