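pafLine <- function(id, qlen, qs, qe, strand, t, tlen, ts, te, mapq = 60,
                    tag = "tp:A:P") {
  paste(id, qlen, qs, qe, strand, t, tlen, ts, te, qe - qs, qe - qs, mapq,
        tag, sep = "\t")
}

test_that("PAF parsing groups segments per read and flags secondaries", {
  p <- tempfile()
  writeLines(c(
    pafLine("r1", 16569, 0, 13442, "+", "chrM", 16569, 3127, 16569),
    pafLine("r1", 16569, 13442, 16569, "+", "chrM", 16569, 0, 3127),
    pafLine("r2", 500, 0, 500, "-", "chrM", 16569, 100, 600),
    pafLine("r2", 500, 0, 450, "-", "chr1", 248956422, 5e6, 5e6 + 450,
            mapq = 0, tag = "tp:A:S")), p)
  seg <- parsePaf(p)
  expect_equal(nrow(seg), 4L)
  expect_equal(sum(seg$read_id == "r1"), 2L)        # origin-split read
  expect_equal(seg$secondary, c(FALSE, FALSE, FALSE, TRUE))
  ## empty input
  p2 <- tempfile(); writeLines(character(0), p2)
  expect_equal(nrow(parsePaf(p2)), 0L)
  ## malformed line
  p3 <- tempfile(); writeLines("r1\t100\t0", p3)
  expect_error(parsePaf(p3), "malformed PAF line 1")
})

test_that("read validation applies the strand/order/span/coverage filters", {
  l <- 16569L
  seg <- function(...) {
    df <- data.frame(...)
    data.table::as.data.table(df)
  }
  ## origin-wrapping full-length read passes
  ok <- seg(read_id = "r", read_len = 16569L,
            read_start = c(0L, 13442L), read_end = c(13442L, 16569L),
            strand = "+", target = "chrM",
            target_start = c(3127L, 0L), target_end = c(16569L, 3127L),
            mapq = 60L, secondary = FALSE)
  expect_equal(validateRead(ok, "chrM", l), "pass")
  ## a segment on another contig
  nm <- ok; nm$target[2] <- "chr1"
  expect_equal(validateRead(nm, "chrM", l), "non_mito")
  ## opposite strands
  si <- ok; si$strand <- c("+", "-")
  expect_equal(validateRead(si, "chrM", l), "strand_inconsistent")
  ## mapq 0 everywhere = non-unique
  mq <- ok; mq$mapq <- 0L
  expect_equal(validateRead(mq, "chrM", l), "non_mito")
  ## second segment re-covers genome already passed (backwards overlap)
  oi <- ok
  oi$target_start <- c(6000L, 8000L); oi$target_end <- c(10000L, 12000L)
  oi$read_start <- c(0L, 4000L); oi$read_end <- c(4000L, 8000L)
  oi$read_len <- 8000L
  expect_equal(validateRead(oi, "chrM", l), "order_inconsistent")
  ## poorly mapped read
  lm <- ok; lm$read_end <- c(8000L, 16569L); lm$read_start <- c(0L, 15000L)
  expect_equal(validateRead(lm, "chrM", l), "low_mapped_fraction")
  ## span longer than the genome (wraps past its own start)
  ov <- seg(read_id = "r", read_len = 20142L,
            read_start = c(0L, 13442L), read_end = c(13442L, 20142L),
            strand = "+", target = "chrM",
            target_start = c(3127L, 0L), target_end = c(16569L, 6700L),
            mapq = 60L, secondary = FALSE)
  expect_equal(validateRead(ov, "chrM", l), "overlong_span")
})

test_that("read spans are strand-aware, including circular wrap", {
  l <- 16569L
  wrap <- data.table::data.table(
    read_id = "r", read_len = 16569L,
    read_start = c(0L, 13442L), read_end = c(13442L, 16569L),
    strand = "+", target = "chrM",
    target_start = c(3127L, 0L), target_end = c(16569L, 3127L),
    mapq = 60L, secondary = FALSE)
  sp <- readSpan(wrap, l)
  expect_equal(sp$start5, 3127L)
  expect_equal(sp$end3, 3126L)
  plus <- wrap[1]; plus$target_start <- 100L; plus$target_end <- 500L
  plus$read_start <- 0L; plus$read_end <- 400L; plus$read_len <- 400L
  expect_equal(readSpan(plus, l)[c("start5", "end3")],
               list(start5 = 100L, end3 = 499L))
  minus <- plus; minus$strand <- "-"
  expect_equal(readSpan(minus, l)[c("start5", "end3")],
               list(start5 = 499L, end3 = 100L))
})

test_that("cut-site matching uses an inclusive tolerance window", {
  cfg <- CutSiteConfig("chrM", data.frame(name = "mt3", sample = "s",
                                          position = 3127L))
  l <- 16569L
  m <- matchCutSite(list(start5 = 3126L, end3 = 3125L, strand = "+"), cfg, l)
  expect_equal(m$start, "mt3")                      # exactly at the cut
  expect_equal(m$end, "mt3")
  ## 100 bp after: still a match; 101: not
  expect_equal(matchCutSite(list(start5 = 3226L, end3 = 500L,
                                 strand = "+"), cfg, l)$start, "mt3")
  expect_equal(length(matchCutSite(list(start5 = 3227L, end3 = 500L,
                                        strand = "+"), cfg, l)$start), 0L)
  ## minus strand mirrors the window
  mm <- matchCutSite(list(start5 = 3125L, end3 = 3126L, strand = "-"),
                     cfg, l)
  expect_equal(mm$start, "mt3")
  expect_equal(mm$end, "mt3")
})

test_that("selection strategies behave per definition, with ambiguity rejection", {
  fl <- list(start = "mt3", end = "mt3")            # full-length read
  expect_equal(selectRead(fl, "both")$cut_site, "mt3")
  expect_equal(selectRead(fl, "start")$cut_site, "mt3")
  expect_equal(selectRead(fl, "either")$cut_site, "mt3")
  expect_equal(selectRead(fl, "xor")$status, "no_cutsite_match")
  so <- list(start = "mt3", end = character(0))     # start-anchored fragment
  expect_equal(selectRead(so, "both")$status, "no_cutsite_match")
  expect_equal(selectRead(so, "start")$cut_site, "mt3")
  expect_equal(selectRead(so, "either")$cut_site, "mt3")
  expect_equal(selectRead(so, "xor")$cut_site, "mt3")
  conflict <- list(start = "mt3", end = "mt5")
  for (st in c("both", "start", "either", "xor"))
    expect_equal(selectRead(conflict, st)$status, "ambiguous")
  expect_error(selectRead(fl, "nope"), "unknown strategy")
})

test_that("simulated multiplexed runs demultiplex perfectly under 'both'", {
  td <- tempfile()
  cfg <- simConfig(l = 2000L,
    cutSites = data.frame(name = c("c1", "c2", "c3", "c4"),
                          sample = c("s1", "s1", "s2", "s2"),
                          position = c(201L, 701L, 1201L, 1701L)),
    readsPerSample = 50L, seed = 21L)
  sim <- simulateSample(cfg, td)
  dm <- demultiplex(sim$files["fastq"], sim$files["paf"], sim$config,
                    file.path(td, "out"), l = 2000L)
  expect_equal(sum(dm$report$count), 100L)          # counts reconcile
  asg <- merge(dm$assignments, sim$truth$reads, by = "read_id")
  expect_true(all(asg$status == "assigned"))
  expect_equal(asg$cut_site.x, asg$cut_site.y)      # zero mis-assignments
  ## each read lands in exactly one file
  written <- unlist(lapply(dm$files, function(f)
    sub("^@", "", readLines(f)[c(TRUE, FALSE, FALSE, FALSE)])))
  expect_equal(sort(unname(written)), sort(asg$read_id))
  ## determinism: byte-identical on rerun
  dm2 <- demultiplex(sim$files["fastq"], sim$files["paf"], sim$config,
                     file.path(td, "out2"), l = 2000L)
  for (cs in names(dm$files))
    expect_identical(readLines(dm$files[cs]), readLines(dm2$files[cs]))
})

test_that("strategy sets satisfy Both within Start within Either; XOR is the difference", {
  for (seed in c(31L, 32L)) {
    td <- tempfile()
    cfg <- simConfig(l = 2000L,
      cutSites = data.frame(name = c("c1", "c2"), sample = c("s1", "s2"),
                            position = c(301L, 1301L)),
      readsPerSample = 60L, fullLengthFraction = 0.5, seed = seed)
    sim <- simulateSample(cfg, td)
    paf <- parsePaf(sim$files["paf"])
    sets <- lapply(c("both", "start", "either", "xor"), function(st) {
      a <- assignReads(paf, sim$config, 2000L, strategy = st)
      a$read_id[a$status == "assigned"]
    })
    names(sets) <- c("both", "start", "either", "xor")
    expect_true(all(sets$both %in% sets$start))
    expect_true(all(sets$start %in% sets$either))
    expect_setequal(sets$xor, setdiff(sets$either, sets$both))
  }
})

test_that("an empty PAF leaves every read unassigned with consistent totals", {
  td <- tempfile()
  cfg <- simConfig(l = 1000L, readsPerSample = 10L,
                   cutSites = data.frame(name = "c1", sample = "s1",
                                         position = 101L), seed = 41L)
  sim <- simulateSample(cfg, td)
  empty <- tempfile(); writeLines(character(0), empty)
  dm <- demultiplex(sim$files["fastq"], empty, sim$config,
                    file.path(td, "out"), l = 1000L)
  expect_equal(sum(dm$report$count), 10L)
  expect_equal(dm$report$status, "unaligned")
  expect_equal(sum(dm$assignments$status == "assigned"), 0L)
})
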