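#' Greedy redundancy clustering of genomes by identity
#'
#' The incremental-clustering stage of the redundancy filter: genomes are
#' sorted by length descending (ties by id ascending) and each genome joins
#' the first existing cluster whose representative reaches the identity
#' threshold, otherwise it founds a new cluster. Members are compared only
#' against representatives, as in greedy incremental clustering tools; the
#' representatives form the non-redundant output set.
#'
#' @param genomes a \linkS4class{MitoGenomeSet}
#' @param threshold clustering identity threshold in (0, 1]
#' @param ... passed to \code{\link{clusteringIdentity}}
#' @return list of clusters, each a list with \code{representative} (id) and
#'   \code{members} (data.frame id / identity_to_rep, excluding the
#'   representative)
#' @export
greedyCluster <- function(genomes, threshold = 0.90, ...) {
  stopifnot(length(genomes) >= 1L, threshold > 0, threshold <= 1)
  L <- genomeLength(genomes)
  ids <- genomeId(genomes)
  ord <- order(-L, ids)
  clusters <- list()
  seqs <- lapply(genomes, function(g) as.character(genomeSeq(g)))
  # shared 11-mer prefilter: a pair whose distinct shared-seed count is far
  # below what any above-threshold alignment of the shorter sequence would
  # leave cannot pass, so the alignment is skipped (long sequences only)
  k <- 11L
  kmersOf <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  }
  kmF <- lapply(seqs, kmersOf)
  kmR <- lapply(seqs, function(s) kmersOf(.revcomp(s)))
  names(kmF) <- names(kmR) <- ids
  for (i in ord) {
    placed <- FALSE
    for (kc in seq_along(clusters)) {
      rep_id <- clusters[[kc]]$representative
      minLen <- min(L[[rep_id]], L[[i]])
      if (minLen > 2000L) {
        shared <- max(sum(kmF[[i]] %in% kmF[[rep_id]]),
                      sum(kmF[[i]] %in% kmR[[rep_id]]))
        if (shared < max(15L, 0.02 * minLen)) next
      }
      ident <- clusteringIdentity(seqs[[rep_id]], seqs[[i]], ...)
      if (ident >= threshold) {
        clusters[[kc]]$members <- rbind(
          clusters[[kc]]$members,
          data.frame(id = ids[i], identity_to_rep = ident,
                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(
        representative = ids[i],
        members = data.frame(id = character(),
                             identity_to_rep = numeric(),
                             stringsAsFactors = FALSE))
  }
  clusters
}

#' Representative (non-redundant) genome ids of a clustering
#'
#' @param clusters result of \code{\link{greedyCluster}}
#' @return character vector of representative ids
#' @export
clusterRepresentatives <- function(clusters)
  vapply(clusters, `[[`, character(1), "representative")

#' Write clusters in the .clstr text layout
#'
#' @param clusters result of \code{\link{greedyCluster}}
#' @param genomes the clustered \linkS4class{MitoGenomeSet} (for lengths)
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeClusters <- function(clusters, genomes, path) {
  L <- genomeLength(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    writeLines(paste0(">Cluster ", k - 1L), con)
    writeLines(paste0("0\t", L[[cl$representative]], "nt, >",
                      cl$representative, "... *"), con)
    if (nrow(cl$members))
      writeLines(paste0(seq_len(nrow(cl$members)), "\t",
                        L[cl$members$id], "nt, >", cl$members$id,
                        "... at ",
                        sprintf("%.2f%%",
                                100 * cl$members$identity_to_rep)), con)
  }
  invisible(path)
}

#' All-vs-all similarity network under the longest-alignment rule
#'
#' For every unordered genome pair with at least one HSP passing the
#' filters, one undirected edge is created. When a pair aligns in more than
#' one segment only the longest continuous alignment counts: the edge
#' carries the identity of the length-maximal HSP (ties broken by more
#' matches, then smaller query start), not of the best-scoring one.
#'
#' @param genomes a \linkS4class{MitoGenomeSet} (at least 2 genomes)
#' @param minIdentity drop edges with identity below this value
#' @param minHspLen drop edges whose longest HSP is shorter than this
#' @param ... passed to \code{\link{localAlign}}
#' @return data.frame of edges with columns u, v (u < v), hsp_len, identity
#' @export
buildNetwork <- function(genomes, minIdentity = 0, minHspLen = 0L, ...) {
  stopifnot(length(genomes) >= 2L)
  ids <- genomeId(genomes)
  seqs <- lapply(genomes, function(g) as.character(genomeSeq(g)))
  edges <- list()
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    hsps <- localAlign(seqs[[i]], seqs[[j]], ...)
    if (!nrow(hsps)) next
    top <- hsps[1L, ] # localAlign sorts by aln_len desc with tie-breaks
    ident <- hspIdentity(top)
    if (top$aln_len < minHspLen || ident < minIdentity) next
    u <- min(ids[i], ids[j]); v <- max(ids[i], ids[j])
    edges[[length(edges) + 1L]] <- data.frame(
      u = u, v = v, hsp_len = top$aln_len, identity = ident,
      stringsAsFactors = FALSE)
  }
  if (!length(edges))
    return(data.frame(u = character(), v = character(),
                      hsp_len = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Connected components of a similarity network
#'
#' @param edges edge data.frame from \code{\link{buildNetwork}}
#' @param ids full vector of genome ids, so isolated genomes appear as
#'   singleton components
#' @return list of character vectors, one per component, each sorted;
#'   components ordered by their first id
#' @importFrom igraph graph_from_data_frame components V
#' @export
networkComponents <- function(edges, ids) {
  if (!length(ids)) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("u", "v"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, function(p) sort(unname(p)))
  names(parts) <- NULL
  parts[order(vapply(parts, `[`, character(1), 1L))]
}

#' Write the network edge list as TSV
#'
#' @param edges edge data.frame
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export the network as GraphML
#'
#' @param edges edge data.frame
#' @param ids full genome id vector (isolated nodes included)
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeGraphml <- function(edges, ids, path) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
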