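#' Per-genome summary table
#'
#' One row per genome with length, GC, topology, genetic code, core-gene
#' complement, per-category feature counts and overlap-removed lengths, and
#' the genic/intergenic split. Features must already be classified (see
#' \code{\link{classifyFeatures}}).
#'
#' @param genomes a \linkS4class{MitoGenomeSet}
#' @param references optional per-gene references for presence rescue
#' @return data.frame, one row per genome
#' @export
summarizeGenomes <- function(genomes, references = NULL) {
  rows <- lapply(genomes, function(g) {
    cen <- categoryCensus(g)
    pres <- corePresence(g, references = references)
    gl <- coveredLength(featureIntervals(g))
    data.frame(
      id = genomeId(g), phylum = phylum(g),
      length = genomeLength(g), gc = gcContent(genomeSeq(g)),
      topology = topology(g), genetic_code = geneticCode(g),
      n_core_present = sum(pres),
      n_introns = cen$counts[["intron"]],
      n_hegs = cen$counts[["HEG"]],
      n_heg_laglidadg = cen$hegFamilies[["LAGLIDADG"]],
      n_heg_giyyig = cen$hegFamilies[["GIY-YIG"]],
      n_heg_hnh = cen$hegFamilies[["H-N-H"]],
      n_uorfs = cen$counts[["uORF"]],
      n_trna = cen$counts[["tRNA"]],
      n_dpo = cen$counts[["dpo"]],
      n_rpo = cen$counts[["rpo"]],
      genic_length = gl,
      intergenic_length = genomeLength(g) - gl,
      len_core = cen$lengths[["core_gene"]] + cen$lengths[["rRNA"]],
      len_intron = cen$lengths[["intron"]],
      len_heg = cen$lengths[["HEG"]],
      len_uorf = cen$lengths[["uORF"]],
      len_trna = cen$lengths[["tRNA"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summaries in mean +/- SD form
#'
#' @param summary data.frame from \code{\link{summarizeGenomes}}
#' @param by grouping column, default phylum
#' @param vars numeric columns to summarize
#' @return data.frame with group, n and mean/sd per variable
#' @export
phylumSummary <- function(summary, by = "phylum",
                          vars = c("length", "gc", "n_introns", "n_hegs",
                                   "n_uorfs")) {
  groups <- split(summary, summary[[by]])
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    row <- data.frame(group = g, n = nrow(d), stringsAsFactors = FALSE)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]])
      row[[paste0(v, "_sd")]] <- stats::sd(d[[v]])
    }
    row
  })
  do.call(rbind, out)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; the two-sided p-value comes from the t
#' transform t = r * sqrt((n - 2) / (1 - r^2)) against Student's t with
#' n - 2 degrees of freedom. Optionally both vectors are log10-transformed
#' first (used for uORF-length correlations).
#'
#' @param x,y equal-length numeric vectors, n >= 3
#' @param log10 transform both vectors by log10 before correlating
#'   (non-positive values are dropped pairwise)
#' @return list(r, p, n)
#' @export
pearsonCorrelation <- function(x, y, log10 = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (log10) keep <- keep & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (log10) { x <- log10(x); y <- log10(y) }
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The p-value is exact by
#' enumeration when the combined sample size is at most \code{exactLimit}
#' and there are no ties, and otherwise uses the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric samples
#' @param exactLimit combined-size bound for the exact path
#' @return list(statistic (Mann-Whitney U of x), p, exact)
#' @export
wilcoxonRankSum <- function(x, y, exactLimit = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exactLimit && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = min(1, wt$p.value),
       exact = exact)
}

#' Patristic distance matrix from a newick tree
#'
#' Path-length (sum of branch lengths) distances between all pairs of
#' leaves.
#'
#' @param tree newick string, or a file path to one, or an
#'   \link[ape]{read.tree} "phylo" object
#' @return symmetric numeric matrix with leaf labels as dimnames
#' @export
patristicMatrix <- function(tree) {
  if (is.character(tree)) {
    phy <- if (file.exists(tree[1L]) && !grepl("\\(", tree[1L]))
      ape::read.tree(file = tree)
    else
      ape::read.tree(text = tree)
    if (is.null(phy)) stop("could not parse newick input")
  } else phy <- tree
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    stop("tree must have a branch length on every edge")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label, drop = FALSE]
}
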