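test_that("FASTA reading cleans sequences and preserves record order", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "acgt", ">g2 some description",
               paste(rep("acgtu", 4), collapse = "")), p)
  gs <- readFasta(p)
  expect_s4_class(gs, "MitoGenomeSet")
  expect_identical(names(gs), c("g1", "g2"))
  expect_identical(as.character(genomeSeq(gs[["g1"]])), "ACGT")
  expect_identical(genomeLength(gs[["g1"]]), 4L)
  # U mapped to T
  expect_identical(as.character(genomeSeq(gs[["g2"]])),
                   strrep("ACGTT", 4))
  # defaults without metadata
  expect_identical(topology(gs[["g1"]]), "circular")
  expect_identical(geneticCode(gs[["g1"]]), 1L)
})

test_that("FASTA errors name the offending record; empty file errors", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACXGT"), p)
  expect_error(readFasta(p), "g1")
  writeLines(character(0), p)
  expect_error(readFasta(p))
})

test_that("metadata assigns topology, code and phylum by id", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">g1", "ACGTACGT"), fa)
  writeLines(c("id\ttopology\tgenetic_code\tphylum",
               "g1\tlinear\t4\tAscomycota"), md)
  g <- readFasta(fa, metadata = readMetadata(md))[["g1"]]
  expect_identical(topology(g), "linear")
  expect_identical(geneticCode(g), 4L)
  expect_identical(phylum(g), "Ascomycota")
})

test_that("feature table parsing validates size and handles origin wrap", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend\tsize\tstrand",
               "cox1\t10\t1200\t1191\t+",
               "rnl\t49900\t300\t.\t+"), p)
  f <- readFeatureTable(p, 50000L, "circular")
  expect_identical(f$start, c(10L, 49900L))
  expect_false(f$wraps_origin[1])
  expect_true(f$wraps_origin[2])
  # wrapped length by direct count: 49900..50000 plus 1..300
  expect_identical(featureLength(f[2, ], 50000L),
                   length(49900:50000) + length(1:300))
  expect_identical(featureLength(f[2, ], 50000L), 401L)

  writeLines(c("name\tstart\tend\tsize\tstrand",
               "cox1\t10\t1200\t1000\t+"), p)
  expect_error(readFeatureTable(p, 50000L, "circular"), "size")

  writeLines(c("name\tstart\tend\tsize\tstrand",
               "nad1\t500\t100\t.\t+"), p)
  expect_error(readFeatureTable(p, 50000L, "linear"), "linear")
})

test_that("TSV and GFF3 dialects round-trip names, coordinates, strands", {
  f <- data.frame(name = c("cox1", "rnl", "orf001"),
                  category = NA_character_, subtype = NA_character_,
                  start = c(10L, 900L, 40L), end = c(500L, 120L, 70L),
                  strand = c("+", "+", "-"),
                  wraps_origin = c(FALSE, TRUE, FALSE),
                  stringsAsFactors = FALSE)
  for (dialect in c("tsv", "gff3")) {
    p <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeFeatureTable(f, p, 1000L, dialect = dialect)
    g <- readFeatureTable(p, 1000L, "circular")
    expect_identical(g$name, f$name, info = dialect)
    expect_identical(g$start, f$start, info = dialect)
    expect_identical(g$end, f$end, info = dialect)
    expect_identical(g$strand, f$strand, info = dialect)
    expect_identical(g$wraps_origin, f$wraps_origin, info = dialect)
  }
})

test_that("GFF3 coordinates agree with an independent GFF3 parser", {
  skip_if_not_installed("rtracklayer")
  f <- data.frame(name = c("cox1", "trnA"), category = NA_character_,
                  subtype = NA_character_, start = c(3L, 200L),
                  end = c(120L, 260L), strand = c("+", "-"),
                  wraps_origin = FALSE, stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".gff3")
  writeFeatureTable(f, p, 500L, dialect = "gff3")
  gr <- rtracklayer::import(p)
  expect_identical(BiocGenerics::start(gr), f$start)
  expect_identical(BiocGenerics::end(gr), f$end)
  expect_identical(as.character(BiocGenerics::strand(gr)), f$strand)
  expect_identical(gr$Name, f$name)
})

test_that("GC content counts G+C over non-N bases only", {
  expect_equal(gcContent("GGCC"), 1.0)
  expect_equal(gcContent("ATAT"), 0.0)
  expect_equal(gcContent("ATGCN"), 0.5)
  expect_error(gcContent("NNNN"), "undefined")
})

test_that("GC content is invariant under reversal and complementation", {
  set.seed(41)
  for (k in 1:20) {
    s <- randomDNA(sample(10:500, 1), gc = runif(1, 0.1, 0.9))
    d <- Biostrings::DNAString(s)
    expect_equal(gcContent(s), gcContent(as.character(Biostrings::reverse(d))))
    expect_equal(gcContent(s),
                 gcContent(as.character(Biostrings::complement(d))))
  }
})

test_that("translation honors the four mitochondrial code variants", {
  expect_identical(translateDNA("TGA", 4L), "W")
  expect_identical(translateDNA("TAG", 16L), "L")
  expect_identical(translateDNA("TGA", 1L), "*")
  for (code in c(1L, 3L, 4L, 16L))
    expect_identical(translateDNA("ATGATG", code), "MM")
  # yeast mitochondrial reassignments
  expect_identical(translateDNA("CTACTG", 3L), "TT")
  expect_identical(translateDNA("ATA", 3L), "M")
  expect_error(translateDNA("ATG", 2L), "unsupported")
})

test_that("translation drops trailing partial codons and marks stops", {
  expect_identical(translateDNA("ATGTA", 1L), "M")
  expect_identical(translateDNA("ATGTAAATG", 1L), "M*M")
  expect_identical(translateDNA("AATGTAA", 1L, frameOffset = 1L), "M*")
  expect_identical(translateDNA("ATGNNA", 1L), "MX")
})

test_that("all four embedded code tables match the reference tables on a
           64-codon sweep", {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  for (code in c(1L, 3L, 4L, 16L)) {
    tab <- geneticCodeTable(code)
    ref <- Biostrings::getGeneticCode(as.character(code))
    expect_identical(unname(tab[codons]), unname(ref[codons]),
                     info = paste("code", code))
    # the sweep through the translator itself
    expect_identical(translateDNA(paste(codons, collapse = ""), code),
                     paste(ref[codons], collapse = ""))
  }
  # code 4 differs from code 1 only at TGA
  d <- names(geneticCodeTable(1L))[geneticCodeTable(1L) !=
                                   geneticCodeTable(4L)]
  expect_identical(d, "TGA")
})
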