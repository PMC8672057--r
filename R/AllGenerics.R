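#' @rdname MitoGenome-accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("geneticCode", function(x) standardGeneric("geneticCode"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("phylum", function(x) standardGeneric("phylum"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("features<-", function(x, value) standardGeneric("features<-"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname featureIntervals
#' @export
setGeneric("coveredLength", function(x) standardGeneric("coveredLength"))
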