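test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- generatorConfig(nGenomes = 3, seed = 71)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(lapply(d1$genomes, function(g)
    as.character(genomeSeq(g))),
    lapply(d2$genomes, function(g) as.character(genomeSeq(g))))
  expect_identical(d1$truth@features, d2$truth@features)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  writeDataset(d1, dir1); writeDataset(d2, dir2)
  for (f in list.files(dir1, recursive = TRUE))
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
})

test_that("forced regimes: no dropout and no introns", {
  cfg <- generatorConfig(nGenomes = 4, coreDropout = 0, intronMean = 0,
                         hegInIntronProbability = 0, seed = 72)
  ds <- generateDataset(cfg)
  expect_true(all(ds$truth@corePresence))
  expect_identical(sum(ds$truth@features$category == "intron"), 0L)
  pm <- presenceMatrix(ds$genomes)
  expect_true(all(pm))
})

test_that("full HEG embedding puts every HEG inside an intron", {
  cfg <- generatorConfig(nGenomes = 4, hegInIntronProbability = 1,
                         hegMean = 6, seed = 73)
  ds <- generateDataset(cfg)
  reports <- lapply(ds$genomes, function(g) {
    f <- features(g)
    overlapReport(f[f$category == "HEG", ], f[f$category == "intron", ],
                  genomeLength(g), topology(g))
  })
  pooled <- poolOverlapReports(reports)
  expect_gt(pooled$n_A, 0)
  expect_equal(pooled$fraction_within, 1.0)
  # and the opposite regime: no HEG touches an intron
  cfg0 <- generatorConfig(nGenomes = 4, hegInIntronProbability = 0,
                          hegMean = 6, seed = 74)
  ds0 <- generateDataset(cfg0)
  rep0 <- poolOverlapReports(lapply(ds0$genomes, function(g) {
    f <- features(g)
    overlapReport(f[f$category == "HEG", ], f[f$category == "intron", ],
                  genomeLength(g), topology(g))
  }))
  expect_equal(rep0$n_A_overlapping_B, 0)
})

test_that("genomes hit their planted GC targets within two points", {
  cfg <- generatorConfig(nGenomes = 6, seed = 75)
  ds <- generateDataset(cfg)
  gc <- vapply(ds$genomes, function(g) gcContent(genomeSeq(g)), numeric(1))
  expect_true(all(abs(gc - ds$truth@genomeInfo$gc_target) <= 0.02))
})

test_that("genome metadata matches planted truth and constraints", {
  cfg <- generatorConfig(nGenomes = 10, seed = 76)
  ds <- generateDataset(cfg)
  info <- ds$truth@genomeInfo
  expect_identical(unname(genomeLength(ds$genomes)), info$length)
  expect_identical(vapply(ds$genomes, topology, character(1),
                          USE.NAMES = FALSE), info$topology)
  expect_true(all(info$length >= 2400 & info$length <= 27200))
  expect_true(all(vapply(ds$genomes, geneticCode, integer(1)) %in%
                    c(1L, 3L, 4L, 16L)))
  # wrapping features only on circular genomes
  for (id in names(ds$genomes@genomes)) {
    g <- ds$genomes[[id]]
    if (topology(g) == "linear")
      expect_false(any(features(g)$wraps_origin))
  }
})

test_that("mutateCopy respects identity targets", {
  set.seed(77)
  s <- randomDNA(5000, gc = 0.25)
  expect_identical(mutateCopy(s, 1.0), s)
  ids <- vapply(1:8, function(k)
    clusteringIdentity(s, mutateCopy(s, 0.95), exactLimit = 6000L),
    numeric(1))
  expect_true(all(ids >= 0.92 & ids <= 0.98))
})

test_that("a half-identity copy separates from its parent at 0.9", {
  set.seed(78)
  s <- randomDNA(3000, gc = 0.3)
  gs <- MitoGenomeSet(tinyGenome(s, id = "p"),
                      tinyGenome(mutateCopy(s, 0.5), id = "c"))
  cl <- greedyCluster(gs, 0.90)
  expect_length(cl, 2L)
})

test_that("mutateCopy remaps feature coordinates consistently", {
  cfg <- generatorConfig(nGenomes = 1, seed = 79)
  ds <- generateDataset(cfg, rotate = FALSE)
  g <- ds$genomes[[1]]
  m <- mutateCopy(g, 0.9, seed = 80)
  f <- features(m)
  expect_true(all(f$start >= 1 & f$end <= genomeLength(m)))
  expect_true(all(f$end >= f$start))
  # nesting is preserved under the monotone coordinate map: every HEG that
  # was inside an intron stays inside one
  fh <- f[f$category == "HEG", ]
  fi <- f[f$category == "intron", ]
  f0 <- features(g)
  emb0 <- oracleOverlap(f0[f0$category == "HEG", ],
                        f0[f0$category == "intron", ], genomeLength(g))
  emb1 <- oracleOverlap(fh, fi, genomeLength(m))
  expect_identical(unname(emb1["within"]), unname(emb0["within"]))
})

test_that("planted families cluster to truth; passthrough for size one", {
  cfg <- familyConfig(2, 3, 0.95, seed = 81)
  fd <- plantFamilies(cfg)
  expect_length(fd$genomes, 6L)
  cl <- greedyCluster(fd$genomes, 0.90)
  expect_length(cl, 2L)
  mem <- lapply(cl, function(x) sort(c(x$representative, x$members$id)))
  fam <- lapply(split(fd$truth@families$genome, fd$truth@families$family),
                sort)
  expect_true(setequal(mem, unname(fam)))

  lone <- plantFamilies(familyConfig(1, 1, 0.9, seed = 82))
  expect_length(lone$genomes, 1L)
  expect_identical(lone$truth@families$family,
                   lone$truth@families$genome)
})

test_that("distant families at 0.80 identity all stay singletons at
           threshold 0.90", {
  fd <- plantFamilies(familyConfig(3, 2, 0.80, seed = 83))
  cl <- greedyCluster(fd$genomes, 0.90)
  expect_length(cl, 6L)
})

test_that("an over-stuffed configuration errors", {
  cfg <- generatorConfig(nGenomes = 1, lengthRange = c(2400L, 2600L),
                         intronMean = 40, hegMean = 40, seed = 84)
  expect_error(generateDataset(cfg), "fit")
})
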