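test_that("candidate alleles need more than one observation on each strand", {
  sc <- scDT(allele = c("A", "C", "C", "G", "T", "T"),
             strand = c("+", "+", "-", "+", "+", "-"),
             q = 30L, n = c(50L, 2L, 2L, 5L, 1L, 1L))
  cand <- candidateAlleles(sc, "A")
  expect_true("C" %in% cand)        # 2 fwd + 2 rev: retained
  expect_false("G" %in% cand)       # 5 fwd + 0 rev: not retained
  expect_false("T" %in% cand)       # 1 + 1: not retained
  expect_equal(cand[1], "A")        # reference always retained
})

test_that("strand-bias, base-quality and threshold filters flag correctly", {
  th <- callerThresholds()
  ## minor allele 20 fwd / 0 rev against a balanced major: strand biased.
  ## Independent check of the Fisher p-value via the hypergeometric tail.
  pOracle <- 2 * phyper(0, 20, 200, 120)            # both tails, smaller side
  expect_lt(pOracle, th$pStrand)
  sc <- scDT(allele = c("A", "A", "C"), strand = c("+", "-", "+"),
             q = 30L, n = c(100L, 100L, 20L))
  fl <- MitoLongCall:::.filterFlags(sc, "C", "A", f = 0.1, qual = 60, th)
  expect_match(fl, "strand_bias")
  ## equal qualities: no base-quality bias
  sc2 <- scDT(allele = c("A", "A", "C", "C"), strand = c("+", "-", "+", "-"),
              q = 30L, n = c(100L, 100L, 10L, 10L))
  fl2 <- MitoLongCall:::.filterFlags(sc2, "C", "A", f = 0.1, qual = 60, th)
  expect_equal(fl2, "PASS")
  ## minor allele systematically low quality: flagged
  sc3 <- scDT(allele = c("A", "A", "C", "C"),
              strand = c("+", "-", "+", "-"),
              q = c(30L, 30L, 7L, 7L), n = c(100L, 100L, 15L, 15L))
  fl3 <- MitoLongCall:::.filterFlags(sc3, "C", "A", f = 0.1, qual = 60, th)
  expect_match(fl3, "base_qual_bias")
  ## low frequency and low quality flags
  fl4 <- MitoLongCall:::.filterFlags(sc2, "C", "A", f = 0.002, qual = 60, th)
  expect_match(fl4, "low_freq")
  fl5 <- MitoLongCall:::.filterFlags(sc2, "C", "A", f = 0.1, qual = 10, th)
  expect_match(fl5, "low_qual")
})

test_that("an error-free single population yields no non-reference PASS calls", {
  td <- tempfile()
  cfg <- simConfig(l = 1000L,
                   cutSites = data.frame(name = "c1", sample = "s1",
                                         position = 101L),
                   readsPerSample = 10L, qualityLevels = 90L,
                   qualityProbs = 1, seed = 61L)
  sim <- simulateSample(cfg, td)
  pile <- buildPileup(readAlignments(sim$files[["sam_s1_c1"]]),
                      d = 5L, l = 1000L)
  calls <- callVariants(pile, sim$genome, sample = "s1")
  expect_equal(nrow(variantCalls(calls)), 0L)
  expect_equal(nrow(deletionAlleles(calls)), 0L)
})

test_that("a simulated heteroplasmic SNV is recovered within three SEs", {
  td <- tempfile()
  g <- toyGenome(2000L, seed = 62L)
  ref <- substr(genomeSeq(g), 900, 900)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  cfg <- simConfig(genome = g,
    populations = list(list(frac = 0.75, snvs = NULL, dels = NULL),
                       list(frac = 0.25,
                            snvs = data.frame(pos = 900L, alt = alt),
                            dels = NULL)),
    cutSites = data.frame(name = "c1", sample = "s1", position = 101L),
    readsPerSample = 400L, qualityLevels = 20L, qualityProbs = 1,
    seed = 63L)
  sim <- simulateSample(cfg, td)
  pile <- buildPileup(readAlignments(sim$files[["sam_s1_c1"]]),
                      d = 5L, l = 2000L)
  calls <- callVariants(pile, g, sample = "s1")
  vc <- variantCalls(calls)
  hit <- vc[vc$pos == 900L & vc$alt == alt, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$filter, "PASS")
  expect_lt(abs(hit$f - 0.25), 3 * hit$se)
  expect_lt(abs(hit$hf - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
})

test_that("long deletions are detected, clustered and quantified", {
  td <- tempfile()
  cfg <- simConfig(l = 2000L,
    populations = list(
      list(frac = 0.7, snvs = NULL, dels = NULL),
      list(frac = 0.3, snvs = NULL,
           dels = data.frame(start = 500L, end = 700L))),
    cutSites = data.frame(name = "c1", sample = "s1", position = 101L),
    readsPerSample = 80L, delJitter = 2L, seed = 64L)
  sim <- simulateSample(cfg, td)
  pile <- buildPileup(readAlignments(sim$files[["sam_s1_c1"]]),
                      d = 5L, l = 2000L)
  ld <- detectLongDeletions(pile)
  expect_equal(nrow(ld$dels), 1L)
  expect_lte(abs(ld$dels$start - 500L), 10L)
  expect_lte(abs(ld$dels$end - 700L), 10L)
  expect_lt(abs(ld$dels$f - 0.3), 3 * max(ld$dels$se, sqrt(0.3 * 0.7 / 80)))
  ## and the no-deletion case is empty
  expect_equal(nrow(detectLongDeletions(
    buildPileup(readAlignments(sim$files[["sam_s1_c1"]]), d = 5L,
                l = 2000L, qualityModel = QualityModel()))$dels), 1L)
  cfg0 <- simConfig(l = 1000L, readsPerSample = 10L,
                    cutSites = data.frame(name = "c1", sample = "s1",
                                          position = 101L), seed = 65L)
  sim0 <- simulateSample(cfg0, tempfile())
  pile0 <- buildPileup(readAlignments(sim0$files[["sam_s1_c1"]]),
                       d = 5L, l = 1000L)
  expect_equal(nrow(detectLongDeletions(pile0)$dels), 0L)
})

test_that("short-deletion haplotypes merge into window calls", {
  fx <- pileupFixture()
  nRef <- 12L; nDel <- 8L
  seqdel <- paste0(substr(fx$rot, 1, 19), substr(fx$rot, 21, 50))
  recs <- data.frame(
    qname = sprintf("r%02d", 1:(nRef + nDel)),
    flag = rep(c(0L, 16L), length.out = nRef + nDel),
    pos = fx$pos1,
    cigar = c(rep("50M", nRef), rep("19M1D30M", nDel)),
    seq = c(rep(fx$rot, nRef), rep(seqdel, nDel)),
    qual = c(rep(qstr(30L, 50L), nRef), rep(qstr(30L, 49L), nDel)))
  sam <- writeSamFixture(tempfile(fileext = ".sam"), fx$cr@name, 104L, recs)
  pile <- buildPileup(readAlignments(sam), d = fx$d, l = fx$l)
  refChars <- strsplit(genomeSeq(fx$g), "")[[1]]
  mc <- mergeIndelHaplotypes(pile, refChars)
  expect_equal(nrow(mc), 1L)
  ## window = anchor + deleted site; alt carries '-' at the deleted base
  expect_equal(nchar(mc$ref), 2L)
  expect_match(mc$alt, "-")
  e <- 1e-3                                         # q30
  expect_lt(abs(mc$f - (nDel / 20 - e) / (1 - 2 * e)), 0.02)
  expect_equal(mc$depth, 20L)
  ## the same event surfaces as a merged record in callVariants
  calls <- callVariants(pile, fx$g, sample = "s1")
  vc <- variantCalls(calls)
  expect_true(any(vc$type == "merged"))
  expect_false(any(vc$type == "del"))               # folded into the window
})

test_that("a 30% two-base deletion merges to a haplotype within three SEs", {
  fx <- pileupFixture()
  n <- 60L; nDel <- 18L
  seqdel <- paste0(substr(fx$rot, 1, 19), substr(fx$rot, 22, 50))
  recs <- data.frame(
    qname = sprintf("r%02d", 1:n),
    flag = rep(c(0L, 16L), length.out = n),
    pos = fx$pos1,
    cigar = c(rep("50M", n - nDel), rep("19M2D29M", nDel)),
    seq = c(rep(fx$rot, n - nDel), rep(seqdel, nDel)),
    qual = c(rep(qstr(30L, 50L), n - nDel), rep(qstr(30L, 48L), nDel)))
  sam <- writeSamFixture(tempfile(fileext = ".sam"), fx$cr@name, 104L, recs)
  pile <- buildPileup(readAlignments(sam), d = fx$d, l = fx$l)
  mc <- mergeIndelHaplotypes(pile, strsplit(genomeSeq(fx$g), "")[[1]])
  expect_equal(nrow(mc), 1L)
  expect_equal(nchar(mc$ref), 3L)                   # anchor + 2 deleted sites
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mc$f - 0.3), 3 * se)
})

test_that("VCF output is well-formed and read back by an independent parser", {
  skip_if_not_installed("VariantAnnotation")
  g <- toyGenome(200L, seed = 71L)
  refChars <- strsplit(genomeSeq(g), "")[[1]]
  ## header-only VCF
  empty <- new("MitoCalls",
               calls = data.frame(pos = integer(), ref = character(),
                                  alt = character(), type = character(),
                                  f = numeric(), se = numeric(),
                                  lr = numeric(), qual = numeric(),
                                  depth = integer(), adf = integer(),
                                  adr = integer(), hf = numeric(),
                                  filter = character()),
               dels = data.frame(start = integer(), end = integer(),
                                 length = integer(), support = integer(),
                                 f = numeric(), se = numeric(),
                                 qual = numeric(), filter = character()),
               sample = "s1", genome = "chrM", l = 200L)
  p0 <- tempfile(fileext = ".vcf")
  writeMitoVcf(empty, g, p0)
  v0 <- VariantAnnotation::readVcf(p0)
  expect_equal(length(v0), 0L)

  alt <- setdiff(c("A", "C", "G", "T"), refChars[42])[1]
  one <- empty
  one@calls <- data.frame(pos = 42L, ref = refChars[42], alt = alt,
                          type = "snv", f = 0.25, se = 0.02, lr = 80,
                          qual = 60, depth = 100L, adf = 12L, adr = 13L,
                          hf = 0.25, filter = "PASS")
  one@dels <- data.frame(start = 60L, end = 150L, length = 91L,
                         support = 30L, f = 0.3, se = 0.04, qual = 50,
                         filter = "PASS")
  p1 <- tempfile(fileext = ".vcf")
  writeMitoVcf(one, g, p1)
  v1 <- VariantAnnotation::readVcf(p1)
  expect_equal(length(v1), 2L)
  info <- VariantAnnotation::info(v1)
  expect_equal(unlist(info$AF), c(0.25, 0.3), tolerance = 1e-6)
  expect_equal(info$END[2], 150L)
  expect_equal(info$SVLEN[2], -91L)
  expect_equal(as.character(VariantAnnotation::fixed(v1)$FILTER),
               c("PASS", "PASS"))
  ## unsorted input is a contract error
  two <- one
  two@calls <- rbind(one@calls,
                     transform(one@calls, pos = 10L, alt = "A",
                               ref = refChars[10]))
  expect_error(writeMitoVcf(two, g, tempfile()), "sorted")
})

test_that("per-base coverage export matches read spans", {
  fx <- pileupFixture()
  sam <- writeSamFixture(tempfile(fileext = ".sam"), fx$cr@name, 104L,
    data.frame(qname = c("a", "b"), flag = 0L, pos = fx$pos1,
               cigar = c("50M", "20M"),
               seq = c(fx$rot, substr(fx$rot, 1, 20)),
               qual = c(qstr(30L, 50L), qstr(30L, 20L))))
  pile <- buildPileup(readAlignments(sam), d = fx$d, l = fx$l)
  p <- tempfile()
  writeCoverage(pile, p)
  cov <- read.table(p, sep = "\t")
  expect_equal(nrow(cov), 50L)
  expect_equal(sum(cov$V2), 70L)
  expect_equal(sort(unique(cov$V2)), c(1L, 2L))
})
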