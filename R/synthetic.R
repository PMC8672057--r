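#' Generator configuration for synthetic annotated mitogenomes
#'
#' Defaults emulate the regimes reported for curated fungal mitogenome
#' collections, scaled down 10x in genome length to keep exhaustive
#' alignment oracles fast: lognormal genome lengths, ~5% linear topologies,
#' the four mitochondrial genetic codes with code 4 dominant, mean GC near
#' 25%, about 8 introns, 8 HEGs and 8 uORFs per genome with LAGLIDADG the
#' dominant HEG family, and just under half of the HEGs nested inside
#' introns.
#'
#' @param nGenomes number of genomes
#' @param lengthMeanLog,lengthSdLog lognormal parameters of genome length
#' @param lengthRange truncation range in bp (scaled-down default
#'   2.4-27.2 kbp; the lower bound keeps room for a full core complement)
#' @param circularFraction fraction of circular genomes
#' @param geneticCodeMix named probabilities over codes 1, 3, 4, 16
#' @param phylumMix named probabilities over phylum labels
#' @param gcMean,gcSd,gcRange per-genome GC target distribution (clamped
#'   per genome to the range achievable around its conserved genes)
#' @param coreDropout per-gene probability that a core gene is absent
#' @param rps3Probability probability that rps3 is present
#' @param trnaRange min/max tRNA gene count
#' @param intronMean mean intron count per genome (Poisson)
#' @param intronClassMix named probabilities over IA, IB, IC1, IC2, ID, II
#' @param hegMean mean HEG count per genome (Poisson)
#' @param hegInIntronProbability probability a HEG is nested in an intron
#' @param hegFamilyMix named probabilities over the three HEG families
#' @param uorfMean mean uORF count per genome (Poisson)
#' @param dpoMean,rpoMean mean counts of plasmid-derived polymerase genes
#' @param accessoryLengthCoupling coefficient coupling accessory counts to
#'   genome length (0 = none; counts scale as
#'   exp(c * z - c^2/2) with z the standardized log-length)
#' @param familyStructure optional list of \code{list(size =, identity =)}
#'   family definitions for \code{\link{plantFamilies}}
#' @param seed integer seed fixing the full output
#' @return a validated config list of class \code{"GeneratorConfig"}
#' @export
generatorConfig <- function(
    nGenomes = 60L,
    lengthMeanLog = log(8000), lengthSdLog = 0.45,
    lengthRange = c(2400L, 27200L),
    circularFraction = 0.948,
    geneticCodeMix = c(`1` = 0.20, `3` = 0.10, `4` = 0.62, `16` = 0.08),
    phylumMix = c(Ascomycota = 0.55, Basidiomycota = 0.27,
                  Mucoromycota = 0.07, Chytridiomycota = 0.06,
                  Zoopagomycota = 0.02, Blastocladiomycota = 0.02,
                  Cryptomycota = 0.01),
    gcMean = 0.25, gcSd = 0.06, gcRange = c(0.15, 0.45),
    coreDropout = 0.05, rps3Probability = 0.8,
    trnaRange = c(5L, 10L),
    intronMean = 8, intronClassMix = c(IA = 0.10, IB = 0.40, IC1 = 0.04,
                                       IC2 = 0.08, ID = 0.10, II = 0.28),
    hegMean = 8, hegInIntronProbability = 0.45,
    hegFamilyMix = c(LAGLIDADG = 0.778, `GIY-YIG` = 0.219, `H-N-H` = 0.003),
    uorfMean = 8.2, dpoMean = 0.5, rpoMean = 0.11,
    accessoryLengthCoupling = 0.5,
    familyStructure = NULL,
    seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(circularFraction, coreDropout, rps3Probability,
             hegInIntronProbability, geneticCodeMix, phylumMix,
             intronClassMix, hegFamilyMix)
  stopifnot(all(probs >= 0 & probs <= 1), nGenomes >= 1,
            lengthSdLog > 0, intronMean >= 0, hegMean >= 0, uorfMean >= 0,
            gcSd >= 0, lengthRange[1] > 0,
            lengthRange[2] >= lengthRange[1])
  class(cfg) <- "GeneratorConfig"
  cfg
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.randDNA <- function(n, gc = 0.25) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.randORF <- function(n, gc = 0.25) {
  # ATG start, TAA stop (a stop codon in all four supported codes)
  paste0("ATG", .randDNA(max(0L, n - 6L), gc), "TAA")
}

.PANEL_GENE_LENGTHS <- c(
  atp6 = 80L, atp8 = 50L, atp9 = 50L, cob = 110L, cox1 = 140L,
  cox2 = 80L, cox3 = 80L, nad1 = 100L, nad2 = 110L, nad3 = 50L,
  nad4 = 110L, nad4L = 50L, nad5 = 140L, nad6 = 60L, rns = 90L,
  rnl = 200L, rps3 = 110L)

#' Synthetic reference panels
#'
#' Deterministic randomly generated reference sequences standing in for
#' database-derived panels: one sequence per core gene (for the
#' nucleotide-similarity absence rule), one per HEG family and one each for
#' the plasmid-derived polymerases dpo and rpo (for the >80% identity
#' triage). They are synthetic stand-ins, not biological sequences.
#'
#' @return list with elements \code{core} (named list of
#'   \link[Biostrings]{DNAStringSet}, one per core gene and rps3),
#'   \code{heg}, \code{dpo}, \code{rpo} (DNAStringSet each)
#' @export
syntheticReferencePanel <- function() {
  .withSeed(104729L, {
    core <- lapply(.PANEL_GENE_LENGTHS, function(n)
      Biostrings::DNAStringSet(.randORF(n)))
    heg <- Biostrings::DNAStringSet(vapply(c(150L, 150L, 150L), .randORF,
                                           character(1)))
    names(heg) <- c("LAGLIDADG", "GIY-YIG", "H-N-H")
    list(core = core,
         heg = heg,
         dpo = Biostrings::DNAStringSet(c(dpo = .randORF(260L))),
         rpo = Biostrings::DNAStringSet(c(rpo = .randORF(230L))))
  })
}

#' Mutate a sequence toward a target identity
#'
#' Applies point events at rate 1 - target: 90% substitutions (always to a
#' different base) and 10% small indels with geometric sizes (mean 3 bp).
#' For sequences of a few kbp and targets near 1 the realized clustering
#' identity to the parent tracks the target closely; for low targets the
#' best local alignment fragments and the realized identity is necessarily
#' below the nominal rate.
#'
#' For a \linkS4class{MitoGenome} input the feature coordinates are remapped
#' through the indel map, so the mutated copy stays consistently annotated.
#'
#' @param x character DNA string or \linkS4class{MitoGenome}
#' @param targetIdentity in (0, 1]
#' @param seed optional seed (otherwise the current RNG stream is used)
#' @param id id for the mutated genome copy
#' @return object of the same type as \code{x}
#' @export
mutateCopy <- function(x, targetIdentity, seed = NULL, id = NULL) {
  stopifnot(targetIdentity > 0, targetIdentity <= 1)
  if (!is.null(seed)) return(.withSeed(seed,
    mutateCopy(x, targetIdentity, seed = NULL, id = id)))
  if (is(x, "MitoGenome")) {
    if (any(features(x)$wraps_origin))
      stop("mutateCopy requires an unrotated genome (no wrapping features)")
    m <- .mutateSeq(as.character(genomeSeq(x)), targetIdentity)
    f <- features(x)
    if (nrow(f)) {
      f$start <- m$mapStart[f$start]
      f$end <- m$mapEnd[f$end]
      f <- f[f$end >= f$start, , drop = FALSE]
    }
    return(MitoGenome(if (is.null(id)) paste0(genomeId(x), "_m") else id,
                      m$seq, topology = topology(x),
                      geneticCode = geneticCode(x), phylum = phylum(x),
                      features = f))
  }
  .mutateSeq(x, targetIdentity)$seq
}

# substitution/indel engine; returns the mutated sequence and, for feature
# remapping, the new position of each old position (start-rounded up for
# deleted starts, down for deleted ends)
.mutateSeq <- function(seq, target) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  nEvents <- round((1 - target) * n)
  keep <- rep(TRUE, n)
  insBefore <- integer(n) # characters inserted immediately before old pos
  insSeq <- vector("list", n)
  if (nEvents > 0L) {
    pos <- sample.int(n, min(nEvents, n))
    type <- ifelse(stats::runif(length(pos)) < 0.9, "sub", "indel")
    for (k in seq_along(pos)) {
      p <- pos[k]
      if (type[k] == "sub") {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      } else {
        size <- stats::rgeom(1L, 1 / 3) + 1L
        if (stats::runif(1L) < 0.5) { # deletion
          keep[p:min(n, p + size - 1L)] <- FALSE
        } else { # insertion before p
          insBefore[p] <- insBefore[p] + size
          insSeq[[p]] <- c(insSeq[[p]], .randDNA(size))
        }
      }
    }
  }
  keepCum <- cumsum(keep)
  insCum <- cumsum(insBefore)
  # assemble: kept chars, then splice insertions right-to-left
  out <- chars[keep]
  for (p in rev(which(insBefore > 0L))) {
    at <- if (p > 1L) keepCum[p - 1L] else 0L
    out <- append(out, strsplit(paste(insSeq[[p]], collapse = ""),
                                "", fixed = TRUE)[[1L]], after = at)
  }
  newpos <- ifelse(keep, keepCum + insCum, NA_integer_)
  # map a start to the first surviving position at/after it, an end to the
  # last surviving position at/before it
  mapStart <- rev(cummin(rev(ifelse(is.na(newpos), .Machine$integer.max,
                                    newpos))))
  mapEnd <- cummax(ifelse(is.na(newpos), 0L, newpos))
  list(seq = paste(out, collapse = ""), mapStart = mapStart,
       mapEnd = mapEnd)
}

# truncate an unrotated genome to newLen, clipping or dropping features
.trimGenome <- function(g, newLen) {
  f <- features(g)
  f <- f[f$start <= newLen, , drop = FALSE]
  f$end <- pmin(f$end, newLen)
  MitoGenome(genomeId(g),
             substr(as.character(genomeSeq(g)), 1L, newLen),
             topology = topology(g), geneticCode = geneticCode(g),
             phylum = phylum(g), features = f)
}

# ---- block construction -----------------------------------------------

# a block is a self-contained annotated chunk laid onto the genome:
# list(seq = forward-orientation sequence, feats = data.frame with
# block-relative 1-based coords: name, category, subtype, rel_start,
# rel_end)

.blk <- function(seq, name, category, subtype = NA_character_) {
  list(seq = seq,
       feats = data.frame(name = name, category = category,
                          subtype = subtype, rel_start = 1L,
                          rel_end = nchar(seq), stringsAsFactors = FALSE))
}

# intron hosting zero or more HEG ORFs; returns seq + relative feats
.makeIntron <- function(class, hegSpecs, gc, name) {
  spacers <- vapply(rep(NA, length(hegSpecs) + 1L),
                    function(i) .randDNA(sample(15:60, 1L), gc),
                    character(1))
  if (!length(hegSpecs)) {
    body <- .randDNA(sample(100:350, 1L), gc)
    seq <- body
    feats <- data.frame(name = name, category = "intron", subtype = class,
                        rel_start = 1L, rel_end = nchar(seq),
                        stringsAsFactors = FALSE)
    return(list(seq = seq, feats = feats))
  }
  pieces <- character(0)
  feats <- list()
  off <- 0L
  for (k in seq_along(hegSpecs)) {
    pieces <- c(pieces, spacers[k])
    off <- off + nchar(spacers[k])
    hseq <- hegSpecs[[k]]$seq
    feats[[k]] <- data.frame(name = hegSpecs[[k]]$name, category = "HEG",
                             subtype = hegSpecs[[k]]$family,
                             rel_start = off + 1L,
                             rel_end = off + nchar(hseq),
                             stringsAsFactors = FALSE)
    pieces <- c(pieces, hseq)
    off <- off + nchar(hseq)
  }
  pieces <- c(pieces, spacers[length(spacers)])
  seq <- paste(pieces, collapse = "")
  feats <- do.call(rbind, feats)
  feats <- rbind(data.frame(name = name, category = "intron",
                            subtype = class, rel_start = 1L,
                            rel_end = nchar(seq), stringsAsFactors = FALSE),
                 feats)
  list(seq = seq, feats = feats)
}

# core gene block, optionally interrupted by introns (which may host HEGs)
.makeGeneBlock <- function(gene, geneSeq, introns) {
  len <- nchar(geneSeq)
  category <- if (gene %in% c("rns", "rnl")) "rRNA"
  else if (gene == "rps3") "rps3" else "core_gene"
  subtype <- if (category == "core_gene") gene else NA_character_
  nInt <- length(introns)
  if (nInt == 0L)
    return(.blk(geneSeq, gene, category, subtype))
  if (nInt > len - 21L)
    stop("planted introns do not fit inside gene ", gene,
         "; feature load too high for the genome size")
  cuts <- sort(sample.int(len - 20L, nInt) + 10L)
  exons <- substring(geneSeq, c(1L, cuts + 1L), c(cuts, len))
  pieces <- character(0)
  feats <- list()
  off <- 0L
  for (k in seq_len(nInt)) {
    pieces <- c(pieces, exons[k])
    off <- off + nchar(exons[k])
    intr <- introns[[k]]
    fi <- intr$feats
    fi$rel_start <- fi$rel_start + off
    fi$rel_end <- fi$rel_end + off
    feats[[k]] <- fi
    pieces <- c(pieces, intr$seq)
    off <- off + nchar(intr$seq)
  }
  pieces <- c(pieces, exons[nInt + 1L])
  seq <- paste(pieces, collapse = "")
  feats <- do.call(rbind, feats)
  feats <- rbind(data.frame(name = gene, category = category,
                            subtype = subtype, rel_start = 1L,
                            rel_end = nchar(seq), stringsAsFactors = FALSE),
                 feats)
  list(seq = seq, feats = feats)
}

.flipBlock <- function(block) {
  W <- nchar(block$seq)
  f <- block$feats
  rs <- W - f$rel_end + 1L
  f$rel_end <- W - f$rel_start + 1L
  f$rel_start <- rs
  block$feats <- f[order(f$rel_start, -f$rel_end), , drop = FALSE]
  block$seq <- .revcomp(block$seq)
  block$minus <- TRUE
  block
}

# ---- the generator ----------------------------------------------------

.generateGenome <- function(cfg, idx, panel, rotate = TRUE) {
  id <- sprintf("SG%04d", idx)
  Lraw <- exp(stats::rnorm(1L, cfg$lengthMeanLog, cfg$lengthSdLog))
  Lraw <- as.integer(min(max(Lraw, cfg$lengthRange[1L]), cfg$lengthRange[2L]))
  z <- (log(Lraw) - cfg$lengthMeanLog) / cfg$lengthSdLog
  cc <- cfg$accessoryLengthCoupling
  fac <- exp(cc * z - cc^2 / 2)
  gcDraw <- min(max(stats::rnorm(1L, cfg$gcMean, cfg$gcSd),
                    cfg$gcRange[1L]), cfg$gcRange[2L])
  topo <- if (stats::runif(1L) < cfg$circularFraction) "circular" else "linear"
  code <- as.integer(sample(names(cfg$geneticCodeMix), 1L,
                            prob = cfg$geneticCodeMix))
  phy <- sample(names(cfg$phylumMix), 1L, prob = cfg$phylumMix)

  corePresent <- stats::runif(16L) >= cfg$coreDropout
  names(corePresent) <- coreGeneNames()
  hasRps3 <- stats::runif(1L) < cfg$rps3Probability

  # each embedded HEG founds its own host intron (HEG-bearing introns are
  # mostly ORF in real mitogenomes), and HEG-free introns follow a Poisson
  # whose mean keeps the total intron mean at intronMean
  nHeg <- stats::rpois(1L, cfg$hegMean * fac)
  nEmb <- stats::rbinom(1L, nHeg, cfg$hegInIntronProbability)
  freeMean <- max(0, cfg$intronMean -
                    cfg$hegMean * cfg$hegInIntronProbability)
  nIntron <- nEmb + stats::rpois(1L, freeMean * fac)
  nUorf <- stats::rpois(1L, cfg$uorfMean * fac)
  nDpo <- stats::rpois(1L, cfg$dpoMean)
  nRpo <- stats::rpois(1L, cfg$rpoMean)
  nTrna <- if (cfg$trnaRange[1L] == cfg$trnaRange[2L]) cfg$trnaRange[1L]
  else sample(cfg$trnaRange[1L]:cfg$trnaRange[2L], 1L)

  orfN <- 0L
  nextOrf <- function() {
    orfN <<- orfN + 1L
    sprintf("orf%03d", orfN)
  }

  # HEG specs: family, name, sequence; first nEmb go into introns
  hegSpecs <- lapply(seq_len(nHeg), function(k) {
    fam <- sample(names(cfg$hegFamilyMix), 1L, prob = cfg$hegFamilyMix)
    list(name = nextOrf(), family = fam,
         seq = .randORF(sample(90:200, 1L), gcDraw))
  })
  embAssign <- seq_len(nEmb) # one host intron per embedded HEG

  intronClasses <- sample(names(cfg$intronClassMix), nIntron, replace = TRUE,
                          prob = cfg$intronClassMix)
  introns <- lapply(seq_len(nIntron), function(k)
    .makeIntron(intronClasses[k],
                hegSpecs[seq_len(nEmb)][embAssign == k],
                gcDraw, sprintf("intron_%s_%d", intronClasses[k], k)))

  # distribute introns over host genes; intronless genomes keep them free
  genesHere <- c(names(corePresent)[corePresent],
                 if (hasRps3) "rps3")
  hostOf <- if (nIntron > 0L && length(genesHere))
    sample(genesHere, nIntron, replace = TRUE) else rep(NA, nIntron)

  blocks <- list()
  for (g in genesHere) {
    geneSeq <- mutateCopy(as.character(panel$core[[g]][[1L]]),
                          stats::runif(1L, 0.85, 0.95))
    blocks[[length(blocks) + 1L]] <-
      .makeGeneBlock(g, geneSeq, introns[which(hostOf == g)])
  }
  for (k in which(is.na(hostOf)))  # hostless introns sit free-standing
    blocks[[length(blocks) + 1L]] <- introns[[k]]
  if (nHeg > nEmb) for (k in seq.int(nEmb + 1L, nHeg)) {
    hs <- hegSpecs[[k]]
    blocks[[length(blocks) + 1L]] <- .blk(hs$seq, hs$name, "HEG", hs$family)
  }
  for (k in seq_len(nTrna))
    blocks[[length(blocks) + 1L]] <-
      .blk(.randDNA(sample(25:40, 1L), gcDraw),
           paste0("trn", sample(LETTERS, 1L), "_", k), "tRNA")
  for (k in seq_len(nUorf))
    blocks[[length(blocks) + 1L]] <-
      .blk(.randORF(sample(60:120, 1L), gcDraw), nextOrf(), "uORF")
  for (k in seq_len(nDpo))
    blocks[[length(blocks) + 1L]] <-
      .blk(mutateCopy(as.character(panel$dpo[[1L]]), 0.90), nextOrf(), "dpo")
  for (k in seq_len(nRpo))
    blocks[[length(blocks) + 1L]] <-
      .blk(mutateCopy(as.character(panel$rpo[[1L]]), 0.90), nextOrf(), "rpo")

  # strand assignment (nested blocks flip as a unit)
  blocks <- lapply(blocks, function(b) {
    if (stats::runif(1L) < 0.3) .flipBlock(b) else b
  })
  blocks <- blocks[sample.int(length(blocks))]

  total <- sum(vapply(blocks, function(b) nchar(b$seq), integer(1)))
  if (ceiling(1.05 * total) > cfg$lengthRange[2L])
    stop("planted features (", total, " bp) do not fit a genome within ",
         "lengthRange; reduce feature loads or raise the range")
  L <- max(Lraw, as.integer(ceiling(1.2 * total)))

  # intergenic gaps with exact background composition hitting the feasible
  # GC target
  nB <- length(blocks)
  Lbg <- L - total
  gaps <- if (Lbg > 0L)
    as.vector(stats::rmultinom(1L, Lbg, rep(1, nB + 1L))) else
    rep(0L, nB + 1L)
  blockGC <- sum(vapply(blocks, function(b)
    sum(strsplit(b$seq, "", fixed = TRUE)[[1L]] %in% c("G", "C")),
    integer(1)))
  gcTarget <- min(max(gcDraw, blockGC / L), (blockGC + Lbg) / L)
  needGC <- round(gcTarget * L) - blockGC
  needGC <- min(max(needGC, 0L), Lbg)
  bgChars <- sample(c(rep(c("G", "C"), c(ceiling(needGC / 2),
                                         floor(needGC / 2))),
                      rep(c("A", "T"), c(ceiling((Lbg - needGC) / 2),
                                         floor((Lbg - needGC) / 2)))))
  bgSplit <- split(bgChars, rep(seq_len(nB + 1L), gaps))

  pieces <- character(0)
  feats <- list()
  off <- 0L
  for (k in seq_len(nB)) {
    gapSeq <- paste(bgSplit[[as.character(k)]], collapse = "")
    pieces <- c(pieces, gapSeq)
    off <- off + gaps[k]
    b <- blocks[[k]]
    f <- b$feats
    strand <- if (isTRUE(b$minus)) "-" else "+"
    feats[[k]] <- data.frame(name = f$name, category = f$category,
                             subtype = f$subtype,
                             start = off + f$rel_start,
                             end = off + f$rel_end, strand = strand,
                             wraps_origin = FALSE, stringsAsFactors = FALSE)
    pieces <- c(pieces, b$seq)
    off <- off + nchar(b$seq)
  }
  pieces <- c(pieces, paste(bgSplit[[as.character(nB + 1L)]], collapse = ""))
  seq <- paste(pieces, collapse = "")
  feats <- do.call(rbind, feats)

  genome <- MitoGenome(id, seq, topology = topo, geneticCode = code,
                       phylum = phy, features = feats)
  if (rotate && topo == "circular")
    genome <- rotateGenome(genome, sample.int(L, 1L) - 1L)

  hits <- feats[feats$category == "HEG", , drop = FALSE]
  domainHits <- if (nrow(hits)) data.frame(
    orf_id = hits$name, genome = id,
    domain_name = ifelse(hits$subtype == "LAGLIDADG",
                         "LAGLIDADG_2", ifelse(hits$subtype == "GIY-YIG",
                                               "GIY-YIG", "HNH")),
    superfamily = "Homing_endonucleases",
    e_value = 10^(-stats::runif(nrow(hits), 10, 30)),
    stringsAsFactors = FALSE)
  else data.frame(orf_id = character(), genome = character(),
                  domain_name = character(), superfamily = character(),
                  e_value = numeric(), stringsAsFactors = FALSE)

  info <- data.frame(genome = id, phylum = phy, topology = topo,
                     genetic_code = code, length = L, gc_target = gcTarget,
                     stringsAsFactors = FALSE)

  list(genome = genome, corePresent = corePresent, domainHits = domainHits,
       info = info)
}

#' Generate a synthetic annotated mitogenome dataset with ground truth
#'
#' Builds genomes as shuffled blocks of planted features (core genes with
#' nested introns and intron-hosted HEGs, free-standing HEGs, tRNAs, uORFs
#' and plasmid-derived dpo/rpo copies derived from the synthetic reference
#' panel) separated by random intergenic background whose composition is
#' chosen so the genome hits its GC target exactly. Circular genomes get a
#' random origin rotation, which makes some features wrap the origin.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @param rotate rotate circular genomes to a random origin (disable to
#'   keep coordinates unwrapped, e.g. before \code{\link{mutateCopy}})
#' @return list with \code{genomes} (a \linkS4class{MitoGenomeSet}),
#'   \code{truth} (a \linkS4class{SyntheticTruth}) and \code{panel} (the
#'   \code{\link{syntheticReferencePanel}} the planted copies derive from)
#' @export
generateDataset <- function(cfg = generatorConfig(), rotate = TRUE) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  panel <- syntheticReferencePanel()
  .withSeed(cfg$seed, {
    out <- lapply(seq_len(cfg$nGenomes), function(i)
      .generateGenome(cfg, i, panel, rotate = rotate))
    genomes <- MitoGenomeSet(lapply(out, `[[`, "genome"))
    pres <- do.call(rbind, lapply(out, `[[`, "corePresent"))
    rownames(pres) <- genomeId(genomes)
    truthFeats <- do.call(rbind, lapply(out, function(o)
      cbind(genome = genomeId(o$genome), features(o$genome),
            stringsAsFactors = FALSE)))
    rownames(truthFeats) <- NULL
    hits <- do.call(rbind, lapply(out, `[[`, "domainHits"))
    rownames(hits) <- NULL
    info <- do.call(rbind, lapply(out, `[[`, "info"))
    rownames(info) <- NULL
    truth <- new("SyntheticTruth", features = truthFeats,
                 corePresence = pres,
                 families = data.frame(genome = character(),
                                       family = character(),
                                       target_identity = numeric(),
                                       stringsAsFactors = FALSE),
                 domainHits = hits, genomeInfo = info)
    list(genomes = genomes, truth = truth, panel = panel)
  })
}

#' Plant genome families for clustering and network tests
#'
#' Each family is one ancestor genome plus mutated copies at the family's
#' target identity; truth records the family memberships and target
#' identities. Ancestors are generated without origin rotation so feature
#' coordinates remap cleanly through the mutation indel map.
#'
#' @param cfg a \code{\link{generatorConfig}} whose \code{familyStructure}
#'   lists one \code{list(size =, identity =)} per family
#' @return as \code{\link{generateDataset}}; genome ids are
#'   \code{<ancestor>_m<k>} for copies
#' @export
plantFamilies <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"),
            length(cfg$familyStructure) >= 1L)
  fam <- cfg$familyStructure
  stopifnot(all(vapply(fam, function(f) f$size >= 1L, logical(1))))
  base <- generatorConfig()
  base[names(cfg)] <- cfg
  base$nGenomes <- length(fam)
  class(base) <- "GeneratorConfig"
  anc <- generateDataset(base, rotate = FALSE)
  .withSeed(cfg$seed + 1L, {
    genomes <- list()
    famRows <- list()
    hits <- list()
    pres <- list()
    feats <- list()
    infos <- list()
    for (i in seq_along(fam)) {
      a <- anc$genomes[[i]]
      aid <- genomeId(a)
      members <- list(a)
      if (fam[[i]]$size > 1L) for (k in seq_len(fam[[i]]$size - 1L)) {
        m <- mutateCopy(a, fam[[i]]$identity, id = paste0(aid, "_m", k))
        # keep the copy strictly shorter than the ancestor, so the
        # ancestor is always the length-descending greedy representative
        # and within-family identity is identity-to-ancestor
        if (genomeLength(m) >= genomeLength(a))
          m <- .trimGenome(m, genomeLength(a) - 1L)
        members[[k + 1L]] <- m
      }
      for (m in members) {
        mid <- genomeId(m)
        genomes[[mid]] <- m
        famRows[[mid]] <- data.frame(genome = mid, family = aid,
                                     target_identity = fam[[i]]$identity,
                                     stringsAsFactors = FALSE)
        mOrfs <- features(m)$name
        h <- anc$truth@domainHits[anc$truth@domainHits$genome == aid &
                                    anc$truth@domainHits$orf_id %in% mOrfs, ,
                                  drop = FALSE]
        if (nrow(h)) { h$genome <- mid; hits[[mid]] <- h }
        pres[[mid]] <- stats::setNames(
          coreGeneNames() %in% normalizeGeneName(mOrfs), coreGeneNames())
        feats[[mid]] <- cbind(genome = mid, features(m),
                              stringsAsFactors = FALSE)
        inf <- anc$truth@genomeInfo[
          anc$truth@genomeInfo$genome == aid, , drop = FALSE]
        inf$genome <- mid
        inf$length <- genomeLength(m)
        infos[[mid]] <- inf
      }
    }
    truth <- new("SyntheticTruth",
                 features = {
                   tf <- do.call(rbind, feats); rownames(tf) <- NULL; tf
                 },
                 corePresence = {
                   p <- do.call(rbind, pres)
                   rownames(p) <- names(genomes); p
                 },
                 families = {
                   fr <- do.call(rbind, famRows); rownames(fr) <- NULL; fr
                 },
                 domainHits = if (length(hits)) {
                   hh <- do.call(rbind, hits); rownames(hh) <- NULL; hh
                 } else anc$truth@domainHits[0, ],
                 genomeInfo = {
                   ii <- do.call(rbind, infos); rownames(ii) <- NULL; ii
                 })
    list(genomes = MitoGenomeSet(genomes), truth = truth,
         panel = anc$panel)
  })
}

#' Write a generated dataset to disk in the pipeline's input layout
#'
#' Emits \code{genomes.fasta}, \code{metadata.tsv}, one feature table per
#' genome under \code{features/}, \code{domain_hits.tsv} and the ground
#' truth as \code{truth.json}.
#'
#' @param dataset result of \code{\link{generateDataset}} or
#'   \code{\link{plantFamilies}}
#' @param dir output directory (created if needed)
#' @return invisibly, \code{dir}
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  writeFasta(dataset$genomes, file.path(dir, "genomes.fasta"))
  writeMetadata(dataset$genomes, file.path(dir, "metadata.tsv"))
  for (g in dataset$genomes@genomes)
    writeFeatureTable(features(g),
                      file.path(dir, "features",
                                paste0(genomeId(g), ".tsv")),
                      genomeLength(g))
  utils::write.table(dataset$truth@domainHits,
                     file.path(dir, "domain_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(features = dataset$truth@features,
                corePresence = as.data.frame(dataset$truth@corePresence),
                families = dataset$truth@families)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset written by \code{\link{writeDataset}}
#'
#' @param dir dataset directory
#' @return list with \code{genomes} (\linkS4class{MitoGenomeSet}, features
#'   attached but unclassified) and \code{domainHits}
#' @export
readDataset <- function(dir) {
  md <- readMetadata(file.path(dir, "metadata.tsv"))
  genomes <- readFasta(file.path(dir, "genomes.fasta"), metadata = md)
  gl <- list()
  for (id in genomeId(genomes)) {
    g <- genomes[[id]]
    path <- file.path(dir, "features", paste0(id, ".tsv"))
    if (file.exists(path))
      features(g) <- readFeatureTable(path, genomeLength(g), topology(g))
    gl[[id]] <- g
  }
  hitsPath <- file.path(dir, "domain_hits.tsv")
  hits <- if (file.exists(hitsPath))
    utils::read.delim(hitsPath, stringsAsFactors = FALSE) else NULL
  list(genomes = MitoGenomeSet(gl), domainHits = hits)
}
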