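#' Core mitochondrial gene names
#'
#' The 14 conserved protein-coding genes (atp6/8/9, cob, cox1-3, nad1-6 and
#' nad4L), the two ribosomal RNA genes rns and rnl, and the optional
#' ribosomal protein gene rps3.
#'
#' @param includeRps3 append rps3 to the vector
#' @return character vector of 16 (or 17) names, fixed column order of the
#'   presence matrix
#' @export
coreGeneNames <- function(includeRps3 = FALSE) {
  core <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
            "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
            "rns", "rnl")
  if (includeRps3) c(core, "rps3") else core
}

.GENE_SYNONYMS <- c(
  coxi = "cox1", coxii = "cox2", coxiii = "cox3", co1 = "cox1",
  co2 = "cox2", co3 = "cox3", cytb = "cob", cob1 = "cob",
  nadl4 = "nad4L", nad4l = "nad4L", ndh1 = "nad1",
  atpase6 = "atp6", atpase8 = "atp8", atpase9 = "atp9",
  rrns = "rns", rrnl = "rnl", rnspc = "rns", `16srrna` = "rnl",
  `12srrna` = "rns")

#' Normalize a gene name to its canonical core label
#'
#' Case-insensitive; separators are stripped and common synonyms (coxI,
#' cytb, nadL4, ...) are mapped. Names that do not resolve to a core, rRNA
#' or rps3 label are returned lowercased as-is.
#'
#' @param name character vector of feature names
#' @return character vector of normalized names
#' @export
normalizeGeneName <- function(name) {
  key <- gsub("[^a-z0-9]", "", tolower(name))
  canon <- tolower(coreGeneNames(includeRps3 = TRUE))
  out <- character(length(key))
  hit <- match(key, canon)
  syn <- match(key, names(.GENE_SYNONYMS))
  out <- ifelse(!is.na(hit), coreGeneNames(TRUE)[hit],
                ifelse(!is.na(syn), unname(.GENE_SYNONYMS[syn]),
                       tolower(name)))
  out
}

.INTRON_CLASSES <- c("IA", "IB", "IC1", "IC2", "ID", "II")
.HEG_FAMILIES <- c("LAGLIDADG", "GIY-YIG", "H-N-H")

.parseIntronClass <- function(name) {
  m <- regmatches(name, regexpr("(IC1|IC2|IA|IB|ID|II)", name,
                                ignore.case = TRUE))
  if (length(m)) toupper(m) else NA_character_
}

.hegFamilyFromDomain <- function(domain) {
  d <- toupper(gsub("[^A-Za-z]", "", domain))
  if (grepl("LAGLIDADG", d)) return("LAGLIDADG")
  if (grepl("GIYYIG", d)) return("GIY-YIG")
  if (grepl("^HNH|HNHENDONUCLEASE|HNHC", d) || d == "HNH") return("H-N-H")
  NA_character_
}

#' Classify one feature into the comparative-analysis categories
#'
#' Precedence: (1) a name matching a core gene, rRNA, rps3 or tRNA label
#' wins outright; (2) a name marking an intron gives category intron with
#' the class (IA/IB/IC1/IC2/ID/II) parsed from the name; (3) an identity
#' hit above the triage threshold against a reference panel (HEG, dpo, rpo)
#' assigns that class, the highest identity winning conflicts (an exact tie
#' between classes is demoted to "other" with a warning); (4) a protein
#' domain hit of a homing-endonuclease family gives HEG with that family;
#' (5) any other accepted domain hit gives domain_orf; (6) an ORF with no
#' evidence at all is a uORF.
#'
#' @param name feature name
#' @param hits data.frame of domain hits for this feature (columns
#'   domain_name, superfamily, e_value), or NULL
#' @param idHits data.frame of reference-panel identities for this feature
#'   (columns ref_class in heg/dpo/rpo, identity), or NULL
#' @param identityThreshold triage threshold, strict ("above 80%")
#' @param eValueCutoff maximum e-value for accepting a domain hit
#' @return list(category, subtype)
#' @export
classifyFeature <- function(name, hits = NULL, idHits = NULL,
                            identityThreshold = 0.80, eValueCutoff = 0.01) {
  norm <- normalizeGeneName(name)
  if (norm %in% coreGeneNames()) {
    if (norm %in% c("rns", "rnl"))
      return(list(category = "rRNA", subtype = NA_character_))
    return(list(category = "core_gene", subtype = norm))
  }
  if (norm == "rps3") return(list(category = "rps3", subtype = NA_character_))
  if (grepl("^trn|^trna", norm))
    return(list(category = "tRNA", subtype = NA_character_))
  if (grepl("intron", norm, ignore.case = TRUE)) {
    return(list(category = "intron", subtype = .parseIntronClass(name)))
  }
  if (!is.null(idHits) && nrow(idHits)) {
    ok <- idHits[idHits$identity > identityThreshold, , drop = FALSE]
    if (nrow(ok)) {
      best <- max(ok$identity)
      top <- unique(ok$ref_class[ok$identity == best])
      if (length(top) > 1L) {
        warning("feature '", name, "': identity tie between classes ",
                paste(top, collapse = "/"), "; classified as 'other'")
        return(list(category = "other", subtype = NA_character_))
      }
      if (top == "heg") {
        fam <- if (!is.null(hits) && nrow(hits))
          unname(stats::na.omit(vapply(hits$domain_name,
                                       .hegFamilyFromDomain,
                                       character(1)))[1])
        else NA_character_
        return(list(category = "HEG", subtype = fam))
      }
      return(list(category = top, subtype = NA_character_))
    }
  }
  if (!is.null(hits) && nrow(hits)) {
    acc <- hits[hits$e_value <= eValueCutoff, , drop = FALSE]
    if (nrow(acc)) {
      fams <- vapply(acc$domain_name, .hegFamilyFromDomain, character(1))
      if (any(!is.na(fams)))
        return(list(category = "HEG",
                    subtype = unname(fams[!is.na(fams)][1L])))
      return(list(category = "domain_orf", subtype = NA_character_))
    }
  }
  list(category = "uORF", subtype = NA_character_)
}

#' Classify all features of a genome
#'
#' Applies \code{\link{classifyFeature}} to every feature. Domain hits are
#' matched by feature name via the \code{orf_id} column. When reference
#' panels are supplied, every not-name-resolved feature is aligned against
#' each panel class and its best clustering identity per class feeds the
#' triage.
#'
#' @param genome a \linkS4class{MitoGenome}
#' @param domainHits data.frame (orf_id, domain_name, superfamily, e_value)
#'   or NULL
#' @param referencePanels named list of \link[Biostrings]{DNAStringSet},
#'   names among "heg", "dpo", "rpo"; or NULL to skip identity triage
#' @param identityThreshold,eValueCutoff see \code{\link{classifyFeature}}
#' @return the genome with categories and subtypes filled in
#' @export
classifyFeatures <- function(genome, domainHits = NULL,
                             referencePanels = NULL,
                             identityThreshold = 0.80,
                             eValueCutoff = 0.01) {
  f <- features(genome)
  if (!nrow(f)) return(genome)
  for (i in seq_len(nrow(f))) {
    hits <- NULL
    if (!is.null(domainHits)) {
      hits <- domainHits[domainHits$orf_id == f$name[i], , drop = FALSE]
      if ("genome" %in% names(hits) && nrow(hits))
        hits <- hits[hits$genome == genomeId(genome), , drop = FALSE]
    }
    idHits <- NULL
    norm <- normalizeGeneName(f$name[i])
    nameResolved <- norm %in% c(coreGeneNames(TRUE)) ||
      grepl("^trn|^trna", norm) || grepl("intron", norm, ignore.case = TRUE)
    if (!nameResolved && !is.null(referencePanels)) {
      fseq <- featureSequence(genome, f[i, ])
      idHits <- do.call(rbind, lapply(names(referencePanels), function(cl) {
        ids <- vapply(as.character(referencePanels[[cl]]), function(ref)
          clusteringIdentity(fseq, ref), numeric(1))
        data.frame(ref_class = cl, identity = max(ids),
                   stringsAsFactors = FALSE)
      }))
    }
    cl <- classifyFeature(f$name[i], hits = hits, idHits = idHits,
                          identityThreshold = identityThreshold,
                          eValueCutoff = eValueCutoff)
    f$category[i] <- cl$category
    f$subtype[i] <- cl$subtype
  }
  features(genome) <- f
  genome
}

#' Core-gene presence for one genome
#'
#' A gene is present when it is annotated under its (normalized) name, or
#' when similarity rescue is enabled and some local alignment of the genome
#' against the gene's reference set reaches identity above the absence
#' threshold while covering at least half of the reference length. The
#' coverage requirement keeps spurious short high-identity HSPs from
#' rescuing an absent gene.
#'
#' @param genome a \linkS4class{MitoGenome}
#' @param references named list (gene name -> \link[Biostrings]{DNAStringSet}
#'   of reference sequences), or NULL for name-only presence
#' @param identityThreshold absence rule threshold, strict ("above 50%")
#' @param minCoverage minimum fraction of the reference length the HSP must
#'   span
#' @param genes gene names to evaluate
#' @return named logical vector over \code{genes}
#' @export
corePresence <- function(genome, references = NULL,
                         identityThreshold = 0.50, minCoverage = 0.50,
                         genes = coreGeneNames()) {
  annotated <- normalizeGeneName(features(genome)$name)
  present <- genes %in% annotated
  names(present) <- genes
  if (is.null(references)) return(present)
  gseq <- as.character(genomeSeq(genome))
  for (g in genes[!present]) {
    refs <- references[[g]]
    if (is.null(refs) || length(refs) == 0L)
      stop("no reference sequences for gene ", g)
    for (ref in as.character(refs)) {
      hsps <- localAlign(gseq, ref)
      if (!nrow(hsps)) next
      cov <- (hsps$b_end - hsps$b_start) / nchar(ref)
      if (any(hspIdentity(hsps) > identityThreshold & cov >= minCoverage)) {
        present[g] <- TRUE
        break
      }
    }
  }
  present
}

#' Core-gene presence/absence matrix over a dataset
#'
#' @param genomes a \linkS4class{MitoGenomeSet}
#' @param references optional references for similarity rescue, see
#'   \code{\link{corePresence}}
#' @param ... passed to \code{\link{corePresence}}
#' @return logical matrix, one row per genome, the 16 core names as columns
#' @export
presenceMatrix <- function(genomes, references = NULL, ...) {
  stopifnot(length(genomes) >= 1L)
  rows <- lapply(genomes, corePresence, references = references, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- genomeId(genomes)
  m
}

#' Per-phylum core-gene frequencies and the missing-gene share
#'
#' @param pm presence matrix from \code{\link{presenceMatrix}}
#' @param phyla character vector of phylum labels, one per row of \code{pm}
#' @return list with \code{byPhylum} (matrix of column means within each
#'   phylum) and \code{fractionMissingAny} (share of genomes lacking at
#'   least one core gene)
#' @export
presenceSummary <- function(pm, phyla = NULL) {
  fracMissing <- mean(rowSums(!pm) > 0L)
  byPhylum <- NULL
  if (!is.null(phyla)) {
    byPhylum <- do.call(rbind, lapply(split(seq_len(nrow(pm)), phyla),
      function(i) colMeans(pm[i, , drop = FALSE])))
  }
  list(byPhylum = byPhylum, fractionMissingAny = fracMissing)
}

#' Feature counts and total lengths per category
#'
#' Counts features of each category (HEGs also split by family) and
#' computes the per-category total length through interval
#' canonicalization, so overlapping same-category features are not double
#' counted. A HEG nested in an intron contributes to both categories.
#'
#' @param genome a classified \linkS4class{MitoGenome}
#' @return list with \code{counts} (named integer vector), \code{hegFamilies}
#'   (counts per family) and \code{lengths} (named integer vector of
#'   overlap-removed total lengths per category)
#' @export
categoryCensus <- function(genome) {
  f <- features(genome)
  L <- genomeLength(genome)
  topo <- topology(genome)
  cats <- c("core_gene", "rRNA", "rps3", "tRNA", "intron", "HEG", "uORF",
            "dpo", "rpo", "domain_orf", "other")
  counts <- vapply(cats, function(cl) sum(f$category %in% cl), integer(1))
  lens <- vapply(cats, function(cl) {
    sub <- f[f$category %in% cl, , drop = FALSE]
    if (!nrow(sub)) 0L else coveredLength(featureIntervals(sub, L, topo))
  }, integer(1))
  fams <- vapply(.HEG_FAMILIES, function(fam)
    sum(f$category %in% "HEG" & f$subtype %in% fam), integer(1))
  list(counts = counts, hegFamilies = fams, lengths = lens)
}
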