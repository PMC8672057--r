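test_that("gene name normalization maps case and synonyms", {
  expect_identical(normalizeGeneName(c("COX1", "coxI", "cytb", "nadL4",
                                       "ATP-6", "rnl", "orf123")),
                   c("cox1", "cox1", "cob", "nad4L", "atp6", "rnl",
                     "orf123"))
})

test_that("classification precedence: names, introns, identity triage,
           domains, then uORF", {
  expect_identical(classifyFeature("cox1"),
                   list(category = "core_gene", subtype = "cox1"))
  expect_identical(classifyFeature("rnl"),
                   list(category = "rRNA", subtype = NA_character_))
  expect_identical(classifyFeature("trnK")$category, "tRNA")
  expect_identical(classifyFeature("rps3")$category, "rps3")

  expect_identical(classifyFeature("intron_IC1_2"),
                   list(category = "intron", subtype = "IC1"))
  for (cl in c("IA", "IB", "IC1", "IC2", "ID", "II"))
    expect_identical(classifyFeature(paste0("intron_", cl))$subtype, cl)

  hit <- data.frame(domain_name = "LAGLIDADG_2", superfamily = "HE",
                    e_value = 1e-12)
  expect_identical(classifyFeature("orf9", hits = hit),
                   list(category = "HEG", subtype = "LAGLIDADG"))
  expect_identical(
    classifyFeature("orf9", hits = data.frame(domain_name = "GIY-YIG",
                                              superfamily = "HE",
                                              e_value = 1e-5))$subtype,
    "GIY-YIG")

  idh <- data.frame(ref_class = "dpo", identity = 0.92)
  expect_identical(classifyFeature("orf3", idHits = idh)$category, "dpo")
  # identity triage outranks the domain route
  expect_identical(classifyFeature("orf3", hits = hit,
                                   idHits = idh)$category, "dpo")
  # strictly above the threshold
  expect_identical(classifyFeature("orf3",
                                   idHits = data.frame(ref_class = "dpo",
                                                       identity = 0.80)
                                   )$category, "uORF")

  expect_identical(classifyFeature("orf1")$category, "uORF")
  # non-HEG accepted domain
  other <- data.frame(domain_name = "HAD_like", superfamily = "HAD",
                      e_value = 1e-4)
  expect_identical(classifyFeature("orf2", hits = other)$category,
                   "domain_orf")
  # a hit above the e-value cut-off does not count
  weak <- data.frame(domain_name = "HAD_like", superfamily = "HAD",
                     e_value = 0.5)
  expect_identical(classifyFeature("orf2", hits = weak)$category, "uORF")
})

test_that("an exact identity tie between classes demotes to other", {
  tie <- data.frame(ref_class = c("dpo", "rpo"), identity = c(0.9, 0.9))
  expect_warning(r <- classifyFeature("orf7", idHits = tie), "tie")
  expect_identical(r$category, "other")
  # a higher-identity winner resolves the conflict
  res <- data.frame(ref_class = c("dpo", "rpo"), identity = c(0.95, 0.9))
  expect_identical(classifyFeature("orf7", idHits = res)$category, "dpo")
})

test_that("core presence rescues an unannotated exact gene copy", {
  panel <- syntheticReferencePanel()
  cox1 <- as.character(panel$core$cox1[[1]])
  set.seed(12)
  g <- tinyGenome(paste0(randomDNA(400, gc = 0.25), cox1,
                         randomDNA(400, gc = 0.25)), topology = "linear")
  pres <- corePresence(g, references = panel$core)
  expect_true(pres[["cox1"]])
  expect_identical(sum(pres), 1L)
  # name-only mode sees nothing
  expect_identical(sum(corePresence(g)), 0L)
  # an unreachable threshold degenerates to name-only annotation presence
  expect_identical(sum(corePresence(g, references = panel$core,
                                    identityThreshold = 1.01)), 0L)
  expect_error(corePresence(g, references = list(cox1 = panel$core$cox1)),
               "no reference")
})

test_that("presence matrix equals planted truth across dropout levels", {
  for (dropout in c(0, 0.3, 1)) {
    cfg <- generatorConfig(nGenomes = 4, coreDropout = dropout,
                           seed = 100 + round(100 * dropout))
    ds <- generateDataset(cfg)
    pm <- presenceMatrix(ds$genomes)
    expect_identical(unname(pm), unname(ds$truth@corePresence),
                     info = paste("dropout", dropout))
    if (dropout == 0) expect_true(all(pm))
    if (dropout == 1) expect_false(any(pm))
  }
})

test_that("presence summary reports per-phylum frequencies and the
           missing-gene share", {
  pm <- rbind(g1 = rep(TRUE, 16), g2 = c(FALSE, rep(TRUE, 15)),
              g3 = rep(TRUE, 16))
  colnames(pm) <- coreGeneNames()
  s <- presenceSummary(pm, phyla = c("A", "A", "B"))
  expect_equal(s$fractionMissingAny, 1 / 3)
  expect_equal(unname(s$byPhylum["A", 1]), 0.5)
  expect_equal(unname(s$byPhylum["B", 1]), 1.0)
})

test_that("category census counts nested HEGs in both categories", {
  f <- data.frame(
    name = c("cox1", "intron_IB_1", "orf001", "orf002", "trnA"),
    category = c("core_gene", "intron", "HEG", "uORF", "tRNA"),
    subtype = c("cox1", "IB", "LAGLIDADG", NA, NA),
    start = c(100L, 150L, 200L, 700L, 900L),
    end = c(600L, 450L, 340L, 760L, 930L),
    strand = "+", wraps_origin = FALSE, stringsAsFactors = FALSE)
  g <- tinyGenome(randomDNA(1000), f, topology = "linear")
  cen <- categoryCensus(g)
  expect_identical(unname(cen$counts[c("core_gene", "intron", "HEG",
                                       "uORF", "tRNA")]),
                   c(1L, 1L, 1L, 1L, 1L))
  expect_identical(unname(cen$hegFamilies["LAGLIDADG"]), 1L)
  # the HEG bases also count inside the intron total
  expect_identical(unname(cen$lengths[["intron"]]), 301L)
  expect_identical(unname(cen$lengths[["HEG"]]), 141L)
  # the gene total includes its intron (annotation convention)
  expect_identical(unname(cen$lengths[["core_gene"]]), 501L)
})

test_that("classification is order-independent over the feature list", {
  cfg <- generatorConfig(nGenomes = 1, seed = 55)
  ds <- generateDataset(cfg)
  g <- ds$genomes[[1]]
  panel <- ds$panel[c("heg", "dpo", "rpo")]
  c1 <- categoryCensus(classifyFeatures(g, ds$truth@domainHits, panel))
  set.seed(9)
  f <- features(g)
  g2 <- g
  features(g2) <- f[sample.int(nrow(f)), ]
  c2 <- categoryCensus(classifyFeatures(g2, ds$truth@domainHits, panel))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$hegFamilies, c2$hegFamilies)
  expect_identical(c1$lengths, c2$lengths)
})
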