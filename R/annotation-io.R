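#' Read mitogenome sequences from a FASTA file
#'
#' Sequences are uppercased, U is mapped to T and IUPAC ambiguity letters
#' other than N are collapsed to N; any letter outside the IUPAC DNA
#' alphabet raises an error naming the record and position. Topology,
#' genetic code and phylum are taken from the metadata table when given
#' (matched by id), and default to circular / code 1 otherwise.
#'
#' @param path FASTA file (multi-record allowed)
#' @param metadata optional data.frame from \code{\link{readMetadata}}
#' @return a \linkS4class{MitoGenomeSet} in file order, without features
#' @export
readFasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  genomes <- lapply(seq_along(raw), function(i) {
    id <- ids[i]
    topo <- "circular"; code <- 1L; phy <- NA_character_
    if (!is.null(metadata)) {
      row <- metadata[metadata$id == id, , drop = FALSE]
      if (nrow(row) == 1L) {
        topo <- row$topology
        code <- as.integer(row$genetic_code)
        if (!is.null(row$phylum)) phy <- row$phylum
      }
    }
    MitoGenome(id, as.character(raw[[i]]), topology = topo,
               geneticCode = code, phylum = phy)
  })
  MitoGenomeSet(genomes)
}

#' Write genome sequences to FASTA
#'
#' @param genomes a \linkS4class{MitoGenomeSet}
#' @param path output file
#' @param width line width
#' @return invisibly, \code{path}
#' @export
writeFasta <- function(genomes, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(unlist(lapply(genomes, function(g)
    as.character(genomeSeq(g)))))
  names(seqs) <- genomeId(genomes)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read the dataset metadata table
#'
#' Tab-separated with header columns id, topology, genetic_code and
#' optionally phylum.
#'
#' @param path TSV file
#' @return data.frame
#' @export
readMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "topology", "genetic_code")
  if (!all(need %in% names(md)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  md
}

#' Write the dataset metadata table
#'
#' @param genomes a \linkS4class{MitoGenomeSet}
#' @param path output TSV
#' @return invisibly, \code{path}
#' @export
writeMetadata <- function(genomes, path) {
  g <- as.list(genomes)
  md <- data.frame(
    id = genomeId(genomes),
    topology = vapply(g, topology, character(1)),
    genetic_code = vapply(g, geneticCode, integer(1)),
    phylum = vapply(g, phylum, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Auto-detects the dialect: GFF3 when the first line is the
#' \code{##gff-version} pragma, otherwise the five-column tab-separated
#' layout \code{name / start / end / size / strand} (header line required;
#' size may be \code{.}). Coordinates are 1-based inclusive. On a circular
#' genome a TSV row with start > end is read as an origin-wrapping feature;
#' in GFF3 the same feature is written with end beyond the genome length
#' (the convention for circular replicons) and folded back on reading.
#'
#' @param path annotation file
#' @param genomeLength genome length in bp, used for validation
#' @param topology \code{"circular"} or \code{"linear"}
#' @return feature data.frame with columns name, category, subtype, start,
#'   end, strand, wraps_origin (category/subtype are NA on input); GFF3
#'   attributes other than Name are preserved in an \code{attributes} column
#' @export
readFeatureTable <- function(path, genomeLength, topology = "circular") {
  first <- readLines(path, n = 1L)
  if (grepl("^##gff-version", first))
    f <- .readGff3(path, genomeLength, topology)
  else
    f <- .readTsvFeatures(path, genomeLength, topology)
  .validateFeatures(f, genomeLength, topology, path)
  f
}

.readTsvFeatures <- function(path, genomeLength, topology) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "size", "strand")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns ", paste(need, collapse = ", "))
  tab$size <- as.character(tab$size)
  wraps <- tab$start > tab$end
  if (any(wraps) && topology != "circular")
    stop("start > end on a linear genome (row ",
         which(wraps)[1L], " of ", path, ")")
  len <- ifelse(wraps, (genomeLength - tab$start + 1L) + tab$end,
                tab$end - tab$start + 1L)
  stated <- suppressWarnings(as.integer(tab$size))
  bad <- !is.na(stated) & stated != len
  if (any(bad))
    stop("size column inconsistent with coordinates at row ",
         which(bad)[1L], " of ", path, " (stated ", stated[which(bad)[1L]],
         ", computed ", len[which(bad)[1L]], ")")
  f <- data.frame(name = tab$name, category = NA_character_,
                  subtype = NA_character_, start = as.integer(tab$start),
                  end = as.integer(tab$end), strand = tab$strand,
                  wraps_origin = wraps, stringsAsFactors = FALSE)
  f
}

.readGff3 <- function(path, genomeLength, topology) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(.emptyFeatures())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) stop("malformed GFF3 line in ", path)
  m <- do.call(rbind, parts)
  start <- as.integer(m[, 4L]); end <- as.integer(m[, 5L])
  wraps <- end > genomeLength
  if (any(wraps)) {
    if (topology != "circular")
      stop("feature end beyond genome length on a linear genome in ", path)
    end[wraps] <- end[wraps] - genomeLength
  }
  attrs <- m[, 9L]
  name <- sub("^.*Name=([^;]*).*$", "\\1", attrs)
  noname <- !grepl("Name=", attrs)
  name[noname] <- m[noname, 3L]
  rest <- vapply(strsplit(attrs, ";", fixed = TRUE), function(a)
    paste(a[!grepl("^Name=", a)], collapse = ";"), character(1))
  f <- data.frame(name = name, category = NA_character_,
                  subtype = NA_character_, start = start, end = end,
                  strand = m[, 7L], wraps_origin = wraps,
                  stringsAsFactors = FALSE)
  f$attributes <- rest
  f$type <- m[, 3L]
  f
}

.validateFeatures <- function(f, genomeLength, topology, path = "?") {
  if (!nrow(f)) return(invisible(f))
  if (any(f$start < 1L | f$start > genomeLength |
          f$end < 1L | f$end > genomeLength))
    stop("feature coordinates out of range 1..", genomeLength, " in ", path)
  if (!all(f$strand %in% c("+", "-")))
    stop("strand must be + or - in ", path)
  invisible(f)
}

#' Write a feature annotation table
#'
#' @param features feature data.frame
#' @param path output file
#' @param genomeLength genome length in bp
#' @param dialect \code{"tsv"} (name/start/end/size/strand) or \code{"gff3"}
#' @param seqid sequence id for the GFF3 first column
#' @return invisibly, \code{path}
#' @export
writeFeatureTable <- function(features, path, genomeLength,
                              dialect = c("tsv", "gff3"), seqid = "seq") {
  dialect <- match.arg(dialect)
  f <- features
  if (dialect == "tsv") {
    out <- data.frame(name = f$name, start = f$start, end = f$end,
                      size = featureLength(f, genomeLength),
                      strand = f$strand, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    type <- if (!is.null(f$type)) f$type else rep("region", nrow(f))
    end <- ifelse(f$wraps_origin, f$end + genomeLength, f$end)
    attrs <- paste0("Name=", f$name)
    if (!is.null(f$attributes)) {
      extra <- nzchar(f$attributes)
      attrs[extra] <- paste0(attrs[extra], ";", f$attributes[extra])
    }
    lines <- c("##gff-version 3",
               if (nrow(f)) paste(seqid, "mitoCensus", type, f$start, end,
                                  ".", f$strand, ".", attrs, sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' GC content of a DNA sequence
#'
#' Fraction (G + C) over non-N bases; N bases are excluded from the
#' denominator so gap-rich genomes do not get their GC deflated.
#'
#' @param seq character DNA string or \link[Biostrings]{DNAString}
#' @return fraction in [0, 1]
#' @export
gcContent <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(.cleanDNA(seq))
  counts <- Biostrings::letterFrequency(seq, c("G", "C", "A", "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("GC content undefined: no non-N bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

# NCBI translation tables embedded verbatim: table 1 in full, the fungal
# mitochondrial variants as diffs (3: yeast mito; 4: mold/protozoan mito;
# 16: chlorophycean mito)
.CODE1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.CODE_DIFFS <- list(
  `3` = c(ATA = "M", CTT = "T", CTC = "T", CTA = "T", CTG = "T", TGA = "W"),
  `4` = c(TGA = "W"),
  `16` = c(TAG = "L"))

#' Codon table of a supported genetic code
#'
#' @param codeId 1, 3, 4 or 16
#' @return named character vector of 64 codons to amino acids (stop = "*")
#' @export
geneticCodeTable <- function(codeId) {
  codeId <- as.integer(codeId)
  if (!codeId %in% SUPPORTED_GENETIC_CODES)
    stop("unsupported genetic code: ", codeId)
  tab <- .CODE1
  if (codeId != 1L) {
    d <- .CODE_DIFFS[[as.character(codeId)]]
    tab[names(d)] <- d
  }
  tab
}

#' Translate DNA under a mitochondrial genetic code
#'
#' Codon-by-codon translation from \code{frameOffset}; a trailing partial
#' codon is dropped; internal stops are rendered as \code{"*"}; codons
#' containing N translate to \code{"X"}.
#'
#' @param seq character DNA string
#' @param codeId genetic code, one of 1, 3, 4, 16
#' @param frameOffset 0, 1 or 2
#' @return protein string
#' @export
translateDNA <- function(seq, codeId = 1L, frameOffset = 0L) {
  tab <- geneticCodeTable(codeId)
  seq <- .cleanDNA(seq)
  n <- nchar(seq) - frameOffset
  if (n < 3L) return("")
  starts <- seq.int(frameOffset + 1L, frameOffset + (n %/% 3L) * 3L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
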