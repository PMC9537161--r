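## Synthetic data generator.
##
## Emulates the statistical structure the pipeline assumes: a circular
## genome cut at Cas9 cut-sites, full-length (and optionally fragmented)
## reads starting/ending at the cut, a mixture of molecule populations
## carrying haplotype SNVs and long deletions, per-base qualities drawn
## from a discrete level mix with substitution errors at the Phred rate,
## and ideal PAF (vs the linear mitochondrial contig) and SAM (vs each
## doubled custom reference) alignments emitted by construction, so no
## external aligner is needed.  A molecule whose deletion removes a
## cut-site cannot be cleaved there, so populations are re-weighted per
## cut-site accordingly (a cut-site all of whose populations are deleted is
## a configuration error).

#' Random circular genome
#'
#' @param l genome length in bp
#' @param name contig name
#' @return a [MitoGenome]; draws from the current RNG stream
#' @export
randomMitoGenome <- function(l, name = "chrM") {
  MitoGenome(name, paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                         collapse = ""))
}

#' Simulation configuration
#'
#' @param genome a [MitoGenome], or NULL to draw a random genome of length `l`
#' @param l genome length used when `genome` is NULL
#' @param populations list of populations, each a list with `frac` (mixture
#'   fraction; fractions sum to 1), `snvs` (data.frame `pos` 1-based, `alt`)
#'   and `dels` (data.frame `start`, `end`, 1-based closed)
#' @param cutSites data.frame `name`, `sample`, `position` (1-based)
#' @param readsPerSample reads simulated per sample
#' @param fullLengthFraction fraction of full-length reads (rest are
#'   cut-anchored fragments)
#' @param fragLenRange integer range for fragment lengths (degraded mode)
#' @param qualityLevels,qualityProbs discrete base-quality mix
#' @param indelRate per-base single-base deletion error rate
#' @param startOffsetMax full-length reads start at the cut plus a uniform
#'   offset in `[0, startOffsetMax]` (0 = exact cut-site ends)
#' @param delJitter per-read uniform jitter (+/- bp) on deletion breakpoints
#' @param tolerance,strategy,d,qMin demultiplexing parameters passed into
#'   the emitted [CutSiteConfig]
#' @param seed RNG seed used by [simulateSample]
#' @return a list of class `simConfig`
#' @export
simConfig <- function(genome = NULL, l = 2000L,
                      populations = list(list(frac = 1, snvs = NULL,
                                              dels = NULL)),
                      cutSites = data.frame(name = "cs1", sample = "s1",
                                            position = 101L),
                      readsPerSample = 100L, fullLengthFraction = 1,
                      fragLenRange = NULL,
                      qualityLevels = c(10L, 15L, 20L, 25L, 30L),
                      qualityProbs = c(0.1, 0.2, 0.3, 0.25, 0.15),
                      indelRate = 0, startOffsetMax = 0L, delJitter = 0L,
                      tolerance = 100L, strategy = "both", d = 5L,
                      qMin = 5L, seed = 1L) {
  fr <- vapply(populations, `[[`, 0, "frac")
  if (abs(sum(fr) - 1) > 1e-9) stop("population fractions must sum to 1")
  if (is.null(fragLenRange)) {
    ll <- if (is.null(genome)) l else genomeLength(genome)
    fragLenRange <- c(max(50L, ll %/% 10L), ll %/% 2L)
  }
  structure(list(genome = genome, l = as.integer(l),
                 populations = populations, cutSites = cutSites,
                 readsPerSample = as.integer(readsPerSample),
                 fullLengthFraction = fullLengthFraction,
                 fragLenRange = as.integer(fragLenRange),
                 qualityLevels = as.integer(qualityLevels),
                 qualityProbs = qualityProbs, indelRate = indelRate,
                 startOffsetMax = as.integer(startOffsetMax),
                 delJitter = as.integer(delJitter),
                 tolerance = as.integer(tolerance), strategy = strategy,
                 d = as.integer(d), qMin = as.integer(qMin),
                 seed = as.integer(seed)),
            class = "simConfig")
}

.revcomp <- function(s) as.character(reverseComplement(DNAString(s)))

## rotated 0-based deletion intervals of a population w.r.t. cut x0
.rotDels <- function(pop, x0, l, jitter = 0L) {
  d <- pop$dels
  if (is.null(d) || !nrow(d)) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(d))) {
    s <- d$start[i]; e <- d$end[i]
    if (jitter > 0L) {
      s <- s + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      e <- e + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
    }
    rs <- (s - 1L - x0) %% l; re <- (e - 1L - x0) %% l
    if (rs > re) stop("deletion m.", d$start[i], "_", d$end[i],
                      " covers the cut-site at m.", x0 + 1L)
    out <- rbind(out, data.frame(rs = rs, re = re))
  }
  out <- out[order(out$rs), , drop = FALSE]
  if (nrow(out) > 1L && any(out$rs[-1] <= out$re[-nrow(out)]))
    stop("overlapping deletions within one population are not supported")
  out
}

## molecule blocks (rotated genome intervals retained) and SNV-edited
## rotated genome characters for one (population, cut) pair
.moleculeModel <- function(pop, x0, l, rotCharsBase, jitter = 0L) {
  rot <- rotCharsBase
  if (!is.null(pop$snvs) && nrow(pop$snvs)) {
    idx <- ((pop$snvs$pos - 1L - x0) %% l) + 1L
    rot[idx] <- pop$snvs$alt
  }
  dels <- .rotDels(pop, x0, l, jitter)
  if (is.null(dels)) {
    blocks <- data.frame(g0 = 0L, len = l)
  } else {
    keepS <- c(0L, dels$re + 1L)
    keepE <- c(dels$rs - 1L, l - 1L)
    ok <- keepS <= keepE
    blocks <- data.frame(g0 = keepS[ok], len = keepE[ok] - keepS[ok] + 1L)
  }
  blocks$m0 <- cumsum(c(0L, blocks$len))[seq_len(nrow(blocks))]
  keepIdx <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    blocks$g0[i] + seq_len(blocks$len[i]) - 1L))
  list(blocks = blocks, chars = rot[keepIdx + 1L], offsets = keepIdx)
}

#' Simulate a multiplexed sequencing run
#'
#' Generates reads for every sample/cut-site, the truth tables, and ideal
#' alignments; writes FASTQ, PAF, per-cut-site SAM, genome and custom
#' reference FASTAs, the cut-site config and truth TSVs under `outDir`.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [simConfig]
#' @param outDir output directory (created)
#' @return list: `files` (named paths), `truth` (list of data.frames
#'   `reads`, `sites`, `dels`), `genome`, `refs`, `config`
#' @export
simulateSample <- function(cfg, outDir) {
  set.seed(cfg$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- if (is.null(cfg$genome)) randomMitoGenome(cfg$l) else cfg$genome
  l <- genomeLength(genome)
  chars <- strsplit(genomeSeq(genome), "")[[1]]
  config <- CutSiteConfig(genomeName(genome), cfg$cutSites,
                          tolerance = cfg$tolerance,
                          strategy = cfg$strategy, d = cfg$d,
                          qMin = cfg$qMin, l = l)
  refs <- buildCustomReferences(genome, config)
  sites <- cutSites(config)
  fr <- vapply(cfg$populations, `[[`, 0, "frac")

  ## per cut-site: admissible populations (deletion must not remove the cut)
  admis <- lapply(seq_len(nrow(sites)), function(i) {
    x1 <- sites$position[i]
    ok <- vapply(cfg$populations, function(p) {
      if (is.null(p$dels) || !nrow(p$dels)) return(TRUE)
      !any(((x1 - 1L) - (p$dels$start - 1L)) %% l <=
             (p$dels$end - p$dels$start) %% l)
    }, NA)
    if (!any(ok & fr > 0))
      stop("impossible config: every population's deletion removes cut-site ",
           sites$name[i], " (no molecule can be cleaved there)")
    w <- fr * ok
    w / sum(w)
  })

  ## molecule model cache keyed by (pop, cut); rebuilt per read when jitter>0
  rotCache <- lapply(seq_len(nrow(sites)), function(i) {
    x0 <- sites$position[i] - 1L
    c(chars[(x0 + 1L):l], if (x0 > 0L) chars[seq_len(x0)])
  })
  molCache <- list()
  molKey <- function(p, c) paste(p, c, sep = "_")
  getModel <- function(p, ci) {
    if (cfg$delJitter > 0L)
      return(.moleculeModel(cfg$populations[[p]], sites$position[ci] - 1L,
                            l, rotCache[[ci]], cfg$delJitter))
    k <- molKey(p, ci)
    if (is.null(molCache[[k]])) {
      molCache[[k]] <<- .moleculeModel(cfg$populations[[p]],
                                       sites$position[ci] - 1L, l,
                                       rotCache[[ci]])
    }
    molCache[[k]]
  }

  fastq <- character(0); paf <- character(0)
  samLines <- setNames(vector("list", nrow(sites)), sites$name)
  for (i in seq_len(nrow(sites)))
    samLines[[i]] <- c("@HD\tVN:1.6\tSO:unknown",
                       paste0("@SQ\tSN:", refs[[sites$name[i]]]@name,
                              "\tLN:", 2L * (l + cfg$d)))
  truthReads <- NULL
  rid <- 0L
  for (s in unique(sites$sample)) {
    sIdx <- which(sites$sample == s)
    for (r in seq_len(cfg$readsPerSample)) {
      rid <- rid + 1L
      ci <- sIdx[sample.int(length(sIdx), 1L)]
      x0 <- sites$position[ci] - 1L
      p <- sample.int(length(fr), 1L, prob = admis[[ci]])
      mm <- getModel(p, ci)
      molLen <- length(mm$chars)
      strand <- if (runif(1) < 0.5) "+" else "-"
      full <- runif(1) < cfg$fullLengthFraction
      if (full) {
        a <- if (cfg$startOffsetMax > 0L)
               sample.int(cfg$startOffsetMax + 1L, 1L) - 1L else 0L
        b <- molLen
        type <- "full"
      } else {
        fl <- min(molLen,
                  sample(cfg$fragLenRange[1]:cfg$fragLenRange[2], 1L))
        if (runif(1) < 0.5) { a <- 0L; b <- fl; type <- "frag_start" }
        else { a <- molLen - fl; b <- molLen; type <- "frag_end" }
      }
      idx <- (a + 1L):b
      bases <- mm$chars[idx]
      offs <- mm$offsets[idx]            # rotated genome offsets
      nb <- length(bases)
      q <- cfg$qualityLevels[sample.int(length(cfg$qualityLevels), nb,
                                        replace = TRUE,
                                        prob = cfg$qualityProbs)]
      e <- 10^(-q / 10)
      err <- runif(nb) < e
      if (any(err)) {
        alt <- vapply(bases[err], function(bb)
          sample(setdiff(c("A", "C", "G", "T"), bb), 1L), "")
        bases[err] <- alt
      }
      keep <- if (cfg$indelRate > 0) runif(nb) >= cfg$indelRate
              else rep(TRUE, nb)
      if (!any(keep)) keep[1] <- TRUE
      rb <- bases[keep]; rq <- q[keep]; ro <- offs[keep]
      readSeq <- paste(rb, collapse = "")
      readQual <- intToUtf8(rq + 33L, multiple = FALSE)
      name <- sprintf("r%06d", rid)

      ## FASTQ (as sequenced: minus-strand reads are reverse-complemented)
      if (strand == "+") {
        fastq <- c(fastq, paste0("@", name), readSeq, "+", readQual)
      } else {
        fastq <- c(fastq, paste0("@", name), .revcomp(readSeq), "+",
                   paste(rev(strsplit(readQual, "")[[1]]), collapse = ""))
      }

      ## ideal SAM vs the cut-site custom reference (M/D CIGAR)
      refLo <- ro[1]; refHi <- ro[length(ro)]
      isM <- logical(refHi - refLo + 1L)
      isM[ro - refLo + 1L] <- TRUE
      rl <- rle(isM)
      cigar <- paste0(rl$lengths, ifelse(rl$values, "M", "D"),
                      collapse = "")
      flag <- if (strand == "+") 0L else 16L
      samLines[[sites$name[ci]]] <- c(samLines[[sites$name[ci]]],
        paste(name, flag, refs[[sites$name[ci]]]@name,
              x0 + cfg$d + refLo + 1L, 60L, cigar, "*", 0L, 0L,
              readSeq, readQual, sep = "\t"))

      ## ideal PAF vs the linear mitochondrial contig: one segment per
      ## contiguous genome block, split where a block spans the origin
      blocks <- mm$blocks
      segs <- NULL
      nkeepBefore <- cumsum(c(0L, as.integer(keep)))
      for (bi in seq_len(nrow(blocks))) {
        ba <- max(blocks$m0[bi], a); bb <- min(blocks$m0[bi] + blocks$len[bi], b)
        if (ba >= bb) next
        g0 <- blocks$g0[bi] + (ba - blocks$m0[bi])
        len <- bb - ba
        rs <- nkeepBefore[ba - a + 1L]           # kept bases before block
        re <- nkeepBefore[bb - a + 1L]
        if (re <= rs) next
        gstart <- (x0 + g0) %% l
        parts <- if (gstart + len <= l) list(c(gstart, len, rs, re))
                 else list(c(gstart, l - gstart, rs,
                             rs + (l - gstart)),
                           c(0L, len - (l - gstart), rs + (l - gstart), re))
        for (pp in parts)
          segs <- rbind(segs, data.frame(ts = pp[1], len = pp[2],
                                         rs = pp[3], re = pp[4]))
      }
      L <- length(rb)
      for (si in seq_len(nrow(segs))) {
        sg <- segs[si, ]
        if (strand == "+") { qs <- sg$rs; qe <- sg$re }
        else { qs <- L - sg$re; qe <- L - sg$rs }
        paf <- c(paf, paste(name, L, qs, qe, strand, genomeName(genome), l,
                            sg$ts, sg$ts + sg$len, qe - qs, qe - qs, 60L,
                            "tp:A:P", sep = "\t"))
      }
      truthReads <- rbind(truthReads, data.frame(
        read_id = name, sample = s, cut_site = sites$name[ci],
        population = p, strand = strand, type = type,
        n_bases = L, n_errors = sum(err & keep)))
    }
  }

  ## per-site truth VAFs: among molecules spanning the position
  siteRows <- NULL
  for (p in seq_along(cfg$populations)) {
    sn <- cfg$populations[[p]]$snvs
    if (is.null(sn) || !nrow(sn)) next
    for (i in seq_len(nrow(sn))) {
      span <- vapply(seq_along(cfg$populations), function(pp) {
        dd <- cfg$populations[[pp]]$dels
        if (is.null(dd) || !nrow(dd)) return(TRUE)
        !any(sn$pos[i] >= dd$start & sn$pos[i] <= dd$end)
      }, NA)
      carrier <- vapply(seq_along(cfg$populations), function(pp) {
        s2 <- cfg$populations[[pp]]$snvs
        !is.null(s2) && any(s2$pos == sn$pos[i] & s2$alt == sn$alt[i])
      }, NA)
      siteRows <- rbind(siteRows, data.frame(
        pos = sn$pos[i], alt = sn$alt[i],
        vaf = sum(fr[carrier & span]) / sum(fr[span])))
    }
  }
  truthSites <- unique(siteRows)
  delRows <- NULL
  for (p in seq_along(cfg$populations)) {
    dd <- cfg$populations[[p]]$dels
    if (is.null(dd) || !nrow(dd)) next
    delRows <- rbind(delRows, data.frame(population = p, start = dd$start,
                                         end = dd$end, frac = fr[p]))
  }

  files <- c(fastq = file.path(outDir, "reads.fastq"),
             paf = file.path(outDir, "reads.paf"),
             genome = file.path(outDir, "genome.fa"),
             config = file.path(outDir, "cutsites.cfg"),
             refmeta = file.path(outDir, "ref_meta.tsv"),
             truth_reads = file.path(outDir, "truth_reads.tsv"))
  writeLines(fastq, files["fastq"])
  writeLines(paf, files["paf"])
  writeXStringSet(setNames(DNAStringSet(genomeSeq(genome)),
                           genomeName(genome)), files["genome"], width = 60L)
  writeCutSiteConfig(config, files["config"])
  writeReferenceMeta(refs, files["refmeta"])
  write.table(truthReads, files["truth_reads"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (i in seq_len(nrow(sites))) {
    fp <- file.path(outDir, paste0("sam_", sites$sample[i], "_",
                                   sites$name[i], ".sam"))
    writeLines(samLines[[sites$name[i]]], fp)
    files[paste0("sam_", sites$sample[i], "_", sites$name[i])] <- fp
    fr2 <- file.path(outDir, paste0("ref_", sites$name[i], ".fa"))
    writeReference(refs[[sites$name[i]]], fr2)
    files[paste0("ref_", sites$name[i])] <- fr2
  }
  if (!is.null(truthSites)) {
    files["truth_sites"] <- file.path(outDir, "truth_sites.tsv")
    write.table(truthSites, files["truth_sites"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(delRows)) {
    files["truth_dels"] <- file.path(outDir, "truth_dels.tsv")
    write.table(delRows, files["truth_dels"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(files = files, truth = list(reads = truthReads, sites = truthSites,
                                   dels = delRows),
       genome = genome, refs = refs, config = config)
}

#' Simulate stratified site counts directly
#'
#' Each observation draws its true allele from `f`, a quality level from the
#' mix, a strand fairly, and is flipped to a uniformly chosen other modeled
#' allele with probability `e(q)`.  For two-allele sites this reproduces the
#' caller's one-vs-rest error model exactly.
#'
#' @param f named (or unnamed) true allele frequencies summing to 1; the
#'   first entry is the reference allele
#' @param n number of observations
#' @param qualityLevels,qualityProbs discrete quality mix
#' @param model a [QualityModel] (for the error cap)
#' @param seed optional RNG seed
#' @return data.table with columns `allele`, `strand`, `q`, `n` (site-count
#'   form accepted by [candidateAlleles] and the caller internals)
#' @export
simulatePileupCounts <- function(f, n, qualityLevels = c(10L, 20L, 30L),
                                 qualityProbs = rep(1 / 3, 3),
                                 model = QualityModel(), seed = NULL) {
  stopifnot(abs(sum(f) - 1) < 1e-9, n > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- length(f)
  alleles <- if (!is.null(names(f))) names(f) else
    c("REF", paste0("ALT", seq_len(m - 1L)))
  true <- sample.int(m, n, replace = TRUE, prob = f)
  q <- qualityLevels[sample.int(length(qualityLevels), n, replace = TRUE,
                                prob = qualityProbs)]
  e <- phredError(q, model)
  flip <- runif(n) < e
  obsA <- true
  if (any(flip) && m > 1L) {
    obsA[flip] <- vapply(true[flip], function(t) {
      s <- setdiff(seq_len(m), t)
      s[sample.int(length(s), 1L)]
    }, 0L)
  }
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  dt <- data.table(allele = alleles[obsA], strand = strand, q = q)
  dt[, list(n = .N), by = c("allele", "strand", "q")]
}
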