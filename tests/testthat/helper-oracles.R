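# Shared brute-force oracles and fixture builders. All oracles work
# per-base on logical vectors, independently of the interval code they
# check.

randomDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# per-base coverage of a feature table on a genome of length L
oracleCoverage <- function(f, L) {
  v <- logical(L)
  for (i in seq_len(nrow(f))) {
    pos <- if (f$wraps_origin[i]) c(f$start[i]:L, 1:f$end[i])
    else f$start[i]:f$end[i]
    v[pos] <- TRUE
  }
  v
}

# per-base overlap/containment counts of A features against union(B)
oracleOverlap <- function(A, B, L) {
  vb <- oracleCoverage(B, L)
  ov <- wi <- 0L
  for (i in seq_len(nrow(A))) {
    pos <- if (A$wraps_origin[i]) c(A$start[i]:L, 1:A$end[i])
    else A$start[i]:A$end[i]
    if (any(vb[pos])) ov <- ov + 1L
    if (all(vb[pos])) wi <- wi + 1L
  }
  c(overlapping = ov, within = wi)
}

# random feature table; wrapped features only on circular genomes
randomFeatures <- function(L, topology, nmax = 20L) {
  n <- sample(0:nmax, 1L)
  f <- data.frame(name = character(n), start = integer(n),
                  end = integer(n), strand = character(n),
                  wraps_origin = logical(n), stringsAsFactors = FALSE)
  if (n == 0L) return(f)
  f$name <- paste0("f", seq_len(n))
  f$strand <- sample(c("+", "-"), n, replace = TRUE)
  f$start <- sample.int(L, n, replace = TRUE)
  f$end <- pmin(L, f$start + sample(0:300, n, replace = TRUE))
  if (topology == "circular") {
    w <- stats::runif(n) < 0.2 & f$start > 1L
    f$wraps_origin <- w
    if (any(w))
      f$end[w] <- vapply(f$start[w],
                         function(x) sample.int(x - 1L, 1L), integer(1))
  }
  f
}

# Smith-Waterman score oracle via Biostrings (same scoring scheme)
biostringsLocal <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                type = "local", substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2)
}

# best local score over both strands of b
biostringsBestScore <- function(a, b) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  max(Biostrings::score(biostringsLocal(a, b)),
      Biostrings::score(biostringsLocal(a, rc)))
}

# an HSP row must be internally consistent with the scoring scheme:
# score = matches - 2*mismatches - 5*gap_opens - 2*gap_columns
hspInternallyConsistent <- function(h, s = scoringScheme()) {
  paired <- (h$a_end - h$a_start) + (h$b_end - h$b_start) - h$aln_len
  gapcols <- h$aln_len - paired
  mism <- paired - h$matches
  ok <- mism >= 0 & gapcols >= 0 &
    abs(h$score - (h$matches * s$match + mism * s$mismatch +
                   h$gap_opens * s$gapOpen + gapcols * s$gapExtend)) < 1e-9
  all(ok)
}

# tiny annotated genome around an explicit feature table
tinyGenome <- function(seq, features = NULL, topology = "linear", id = "t1",
                       code = 1L) {
  MitoGenome(id, seq, topology = topology, geneticCode = code,
             features = features)
}

# small family-structured generator config used across clustering tests;
# accessory loads are kept light so the features always fit the smaller
# genomes
familyConfig <- function(nFam, size, identity, seed,
                         meanLog = log(4000), sdLog = 0.3,
                         range = c(2400, 9000)) {
  generatorConfig(nGenomes = nFam, seed = seed,
                  lengthMeanLog = meanLog, lengthSdLog = sdLog,
                  lengthRange = range,
                  intronMean = 3, hegMean = 3, uorfMean = 3,
                  accessoryLengthCoupling = 0.3,
                  familyStructure = rep(list(list(size = size,
                                                  identity = identity)),
                                        nFam))
}

# a small-genome, light-load config for pipeline-level tests
smallConfig <- function(n, seed, meanLog = log(4000), sdLog = 0.25,
                        range = c(2400, 9000)) {
  generatorConfig(nGenomes = n, seed = seed,
                  lengthMeanLog = meanLog, lengthSdLog = sdLog,
                  lengthRange = range,
                  intronMean = 4, hegMean = 4, uorfMean = 4,
                  accessoryLengthCoupling = 0.3)
}
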