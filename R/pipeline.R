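#' Pipeline configuration
#'
#' Thresholds and filters of the end-to-end comparative analysis. The
#' defaults follow the published workflow: redundancy clustering at 90%
#' identity before all statistics, exclusion of genomes under 2 kbp or with
#' more than 20% N bases, the strict >50% identity absence rule, the >80%
#' identity ORF triage and a 0.01 domain e-value cut-off.
#'
#' @param clusterThreshold redundancy-clustering identity threshold
#' @param absenceThreshold core-gene absence-rule identity threshold
#' @param triageThreshold ORF identity-triage threshold
#' @param eValueCutoff domain-hit e-value cut-off
#' @param minLength minimum genome length in bp
#' @param maxNFraction maximum tolerated fraction of N bases
#' @param networkMinIdentity,networkMinHspLen edge filters of the
#'   similarity network
#' @param seed seed echoed into the run manifest
#' @return config list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(clusterThreshold = 0.90,
                           absenceThreshold = 0.50,
                           triageThreshold = 0.80,
                           eValueCutoff = 0.01,
                           minLength = 2000L,
                           maxNFraction = 0.20,
                           networkMinIdentity = 0,
                           networkMinHspLen = 0L,
                           seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(clusterThreshold > 0, clusterThreshold <= 1,
            absenceThreshold > 0, absenceThreshold <= 1,
            triageThreshold > 0, triageThreshold <= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys match the arguments of \code{\link{pipelineConfig}};
#' unknown keys raise an error.
#'
#' @param path YAML file
#' @return a \code{"PipelineConfig"}
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Run the comparative pipeline end to end
#'
#' Stages, in the order of the published workflow: (1) quality filter
#' (length and N-content); (2) greedy redundancy clustering, keeping
#' representatives for all subsequent analyses; (3) feature classification
#' (names, domain hits, identity triage); (4) core-gene presence matrix;
#' (5) genic/intergenic interval accounting and category census; (6)
#' HEG-intron overlap reports; (7) length correlations; (8) similarity
#' network and its components. Output tables are written under
#' \code{outDir} together with a JSON run manifest carrying the parameter
#' echo and per-stage record counts.
#'
#' @param input a \linkS4class{MitoGenomeSet} with features attached, or a
#'   dataset directory in the \code{\link{writeDataset}} layout
#' @param cfg a \code{\link{pipelineConfig}}
#' @param outDir output directory, created if needed
#' @param domainHits optional domain-hit data.frame (orf_id, genome,
#'   domain_name, superfamily, e_value); read from the dataset directory
#'   when \code{input} is a path
#' @param referencePanels optional panels for identity triage and presence
#'   rescue, as from \code{\link{syntheticReferencePanel}}
#' @return the run manifest, invisibly also written as JSON
#' @export
runPipeline <- function(input, cfg = pipelineConfig(), outDir,
                        domainHits = NULL, referencePanels = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  if (is.character(input)) {
    ds <- readDataset(input)
    genomes <- ds$genomes
    if (is.null(domainHits)) domainHits <- ds$domainHits
  } else genomes <- input
  if (length(genomes) == 0L) stop("stage filter: no input genomes")

  manifest <- list(package = "mitoCensus",
                   version = as.character(utils::packageVersion("mitoCensus")),
                   seed = cfg$seed, parameters = unclass(cfg),
                   stages = list())

  # stage 1: quality filter
  nfrac <- vapply(genomes, function(g)
    1 - sum(Biostrings::letterFrequency(genomeSeq(g),
                                        c("A", "C", "G", "T"))) /
      genomeLength(g), numeric(1))
  keep <- genomeLength(genomes) >= cfg$minLength & nfrac <= cfg$maxNFraction
  excluded <- data.frame(
    id = genomeId(genomes)[!keep],
    reason = ifelse(genomeLength(genomes)[!keep] < cfg$minLength,
                    "below minimum length", "excess N content"),
    stringsAsFactors = FALSE)
  utils::write.table(excluded, file.path(outDir, "excluded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  genomes <- genomes[keep]
  if (length(genomes) == 0L) stop("stage filter: all genomes excluded")
  manifest$stages$filter <- list(input = length(keep),
                                 retained = length(genomes),
                                 excluded = sum(!keep))

  # stage 2: redundancy clustering; representatives carry on
  clusters <- greedyCluster(genomes, threshold = cfg$clusterThreshold)
  writeClusters(clusters, genomes, file.path(outDir, "clusters.clstr"))
  reps <- clusterRepresentatives(clusters)
  writeLines(reps, file.path(outDir, "nonredundant_ids.txt"))
  genomes <- genomes[reps]
  manifest$stages$cluster <- list(clusters = length(clusters),
                                  representatives = length(reps))

  # stage 3: classification
  genomes <- MitoGenomeSet(lapply(genomes, classifyFeatures,
                                  domainHits = domainHits,
                                  referencePanels = referencePanels[
                                    intersect(c("heg", "dpo", "rpo"),
                                              names(referencePanels))],
                                  identityThreshold = cfg$triageThreshold,
                                  eValueCutoff = cfg$eValueCutoff))
  manifest$stages$classify <- list(
    features = sum(vapply(genomes, function(g) nrow(features(g)),
                          integer(1))))

  # stage 4: presence matrix
  pm <- presenceMatrix(genomes, references = referencePanels$core,
                       identityThreshold = cfg$absenceThreshold)
  utils::write.table(data.frame(id = rownames(pm), pm, check.names = FALSE),
                     file.path(outDir, "presence_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$presence <- list(
    genomes = nrow(pm),
    fraction_missing_any = mean(rowSums(!pm) > 0))

  # stage 5: summary (census + interval accounting)
  summary <- summarizeGenomes(genomes)
  utils::write.table(summary, file.path(outDir, "genome_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$summary <- list(rows = nrow(summary))

  # stage 6: HEG/intron overlap, per genome and pooled
  reports <- lapply(genomes, function(g) {
    f <- features(g)
    list(heg_in_intron = overlapReport(
           f[f$category %in% "HEG", , drop = FALSE],
           f[f$category %in% "intron", , drop = FALSE],
           genomeLength(g), topology(g)),
         intron_with_heg = overlapReport(
           f[f$category %in% "intron", , drop = FALSE],
           f[f$category %in% "HEG", , drop = FALSE],
           genomeLength(g), topology(g)))
  })
  pooled <- list(
    heg_in_intron = poolOverlapReports(lapply(reports, `[[`,
                                              "heg_in_intron")),
    intron_with_heg = poolOverlapReports(lapply(reports, `[[`,
                                                "intron_with_heg")))
  ovtab <- do.call(rbind, lapply(names(pooled), function(m)
    data.frame(mode = m, as.data.frame(pooled[[m]]))))
  utils::write.table(ovtab, file.path(outDir, "overlap_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$overlap <- pooled

  # stage 7: correlations between genome length and accessory loads
  cors <- list()
  addCor <- function(name, x, y, log10 = FALSE) {
    r <- tryCatch(pearsonCorrelation(x, y, log10 = log10),
                  error = function(e) NULL)
    if (!is.null(r)) cors[[name]] <<- c(list(pair = name,
                                             transform = if (log10)
                                               "log10" else "none"), r)
  }
  addCor("length_vs_heg_length", summary$length, summary$len_heg)
  addCor("length_vs_intron_length", summary$length, summary$len_intron)
  addCor("intron_length_vs_heg_length", summary$len_intron, summary$len_heg)
  addCor("length_vs_uorf_length_log10", summary$length, summary$len_uorf,
         log10 = TRUE)
  if (length(cors)) {
    cortab <- do.call(rbind, lapply(cors, function(r)
      data.frame(pair = r$pair, r = r$r, p = r$p, n = r$n,
                 transform = r$transform)))
    utils::write.table(cortab, file.path(outDir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$correlations <- cors

  # stage 8: similarity network over the non-redundant set
  if (length(genomes) >= 2L) {
    edges <- buildNetwork(genomes, minIdentity = cfg$networkMinIdentity,
                          minHspLen = cfg$networkMinHspLen)
    writeEdgeList(edges, file.path(outDir, "network_edges.tsv"))
    comps <- networkComponents(edges, genomeId(genomes))
    manifest$stages$network <- list(edges = nrow(edges),
                                    components = length(comps))
  } else manifest$stages$network <- list(edges = 0L, components =
                                           length(genomes))

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
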