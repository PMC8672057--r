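test_that("distinct random genomes each found their own cluster", {
  set.seed(21)
  gs <- MitoGenomeSet(lapply(1:5, function(i)
    tinyGenome(randomDNA(800), id = paste0("g", i))))
  cl <- greedyCluster(gs, 0.90)
  expect_length(cl, 5L)
  expect_true(all(vapply(cl, function(x) nrow(x$members) == 0L,
                         logical(1))))
})

test_that("an exact duplicate is absorbed even at threshold 1.0", {
  set.seed(22)
  s <- randomDNA(1200)
  gs <- MitoGenomeSet(
    tinyGenome(s, id = "a"),
    tinyGenome(s, id = "a_dup"),
    tinyGenome(randomDNA(900), id = "c"))
  cl <- greedyCluster(gs, 1.0)
  expect_length(cl, 2L)
  reps <- clusterRepresentatives(cl)
  expect_true("c" %in% reps)
  dup <- cl[[which(reps != "c")]]
  expect_identical(sort(c(dup$representative, dup$members$id)),
                   c("a", "a_dup"))
  expect_equal(dup$members$identity_to_rep, 1.0)
})

test_that("every genome lands in exactly one cluster and the longest
           member represents it", {
  set.seed(23)
  long <- randomDNA(1500)
  gs <- MitoGenomeSet(
    tinyGenome(substr(long, 100, 900), id = "short"),
    tinyGenome(long, id = "long"),
    tinyGenome(randomDNA(700), id = "other"))
  cl <- greedyCluster(gs, 0.90)
  all_ids <- unlist(lapply(cl, function(x) c(x$representative,
                                             x$members$id)))
  expect_identical(sort(all_ids), sort(names(gs)))
  expect_identical(anyDuplicated(all_ids), 0L)
  joint <- cl[[which(vapply(cl, function(x) nrow(x$members) > 0,
                            logical(1)))]]
  expect_identical(joint$representative, "long")
  expect_equal(joint$members$identity_to_rep, 1.0) # substring convention
})

test_that("the network edge carries the longest HSP's identity, not the
           best-scoring one", {
  set.seed(24)
  common_long <- randomDNA(400) # will be degraded in b
  common_short <- randomDNA(120) # stays exact in b
  a <- tinyGenome(paste0(common_long, randomDNA(150), common_short),
                  id = "a")
  b <- tinyGenome(paste0(randomDNA(100), mutateCopy(common_long, 0.85),
                         randomDNA(150), common_short), id = "b")
  edges <- buildNetwork(MitoGenomeSet(a, b))
  expect_identical(nrow(edges), 1L)
  expect_gt(edges$hsp_len, 300L)
  expect_lt(edges$identity, 0.95) # the long degraded HSP, not the 1.0 one
  hs <- localAlign(as.character(genomeSeq(a)), as.character(genomeSeq(b)))
  expect_gte(sum(hspIdentity(hs) == 1 & hs$aln_len >= 120), 1)
})

test_that("pairs without shared seeds yield no edge", {
  # one sequence is pure homopolymer-ish repeat, filtered by the seeder
  a <- tinyGenome(strrep("AT", 1500), id = "a")
  set.seed(25)
  b <- tinyGenome(randomDNA(2500, gc = 0.8), id = "b")
  edges <- buildNetwork(MitoGenomeSet(a, b))
  expect_identical(nrow(edges), 0L)
})

test_that("edge list is undirected, deduplicated and self-edge free", {
  set.seed(26)
  base <- randomDNA(1000)
  gs <- MitoGenomeSet(
    tinyGenome(base, id = "b"),
    tinyGenome(mutateCopy(base, 0.9), id = "a"),
    tinyGenome(mutateCopy(base, 0.9), id = "c"))
  edges <- buildNetwork(gs)
  expect_true(all(edges$u < edges$v))
  expect_identical(anyDuplicated(edges[, c("u", "v")]), 0L)
})

test_that("edge identity is invariant under reverse-complementing a
           genome", {
  set.seed(27)
  base <- randomDNA(900)
  a <- tinyGenome(base, id = "a")
  b <- tinyGenome(mutateCopy(base, 0.9), id = "b")
  e1 <- buildNetwork(MitoGenomeSet(a, b))
  rc <- as.character(Biostrings::reverseComplement(genomeSeq(b)))
  e2 <- buildNetwork(MitoGenomeSet(a, tinyGenome(rc, id = "b")))
  expect_equal(e1$identity, e2$identity)
  expect_equal(e1$hsp_len, e2$hsp_len)
})

test_that("connected components include singletons and match a closure
           oracle", {
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"),
                      stringsAsFactors = FALSE)
  comps <- networkComponents(edges, c("a", "b", "c", "d"))
  expect_identical(comps, list(c("a", "b", "c"), "d"))

  expect_identical(networkComponents(edges[0, ], c("x", "y")),
                   list("x", "y"))

  # brute-force transitive closure on random graphs
  closure <- function(edges, ids) {
    part <- as.list(ids)
    for (i in seq_len(nrow(edges))) {
      ui <- which(vapply(part, function(p) edges$u[i] %in% p, logical(1)))
      vi <- which(vapply(part, function(p) edges$v[i] %in% p, logical(1)))
      if (ui != vi) {
        part[[ui]] <- c(part[[ui]], part[[vi]])
        part[[vi]] <- NULL
      }
    }
    unname(lapply(part, sort))
  }
  set.seed(28)
  for (k in 1:30) {
    n <- sample(2:50, 1)
    ids <- paste0("n", seq_len(n))
    m <- sample(0:min(60, n * 2), 1)
    e <- data.frame(u = sample(ids, m, replace = TRUE),
                    v = sample(ids, m, replace = TRUE),
                    stringsAsFactors = FALSE)
    e <- e[e$u != e$v, , drop = FALSE]
    got <- networkComponents(e, ids)
    want <- closure(e, ids)
    expect_identical(got[order(vapply(got, `[`, character(1), 1))],
                     want[order(vapply(want, `[`, character(1), 1))])
  }
})

test_that("cluster file output follows the .clstr layout", {
  set.seed(29)
  s <- randomDNA(600)
  gs <- MitoGenomeSet(tinyGenome(s, id = "g1"),
                      tinyGenome(s, id = "g2"))
  cl <- greedyCluster(gs, 0.9)
  p <- withr::local_tempfile(fileext = ".clstr")
  writeClusters(cl, gs, p)
  lines <- readLines(p)
  expect_identical(lines[1], ">Cluster 0")
  expect_match(lines[2], "600nt, >g1\\.\\.\\. \\*")
  expect_match(lines[3], "at 100.00%")
})
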