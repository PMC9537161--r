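## The statistical calling engine: candidate alleles, per-site ML estimation,
## long-deletion disentangling, local indel-haplotype merging and call
## filtering.

#' Caller thresholds
#'
#' Conservative defaults chosen to resolve heteroplasmy below 1% while
#' flagging calls under 0.5% as low frequency; all configurable.
#'
#' @param pStrand Fisher strand-bias p-value threshold
#' @param pQual Mann-Whitney base-quality p-value threshold
#' @param qualMin minimum phred-scaled LRT quality for a confident call
#' @param lowFreq VAF below which a call is flagged low frequency
#' @param longDelMin minimum consecutive deleted sites for a long deletion (bp)
#' @param mergeTol clustering tolerance for deletion start/length (bp)
#' @param delErr misassignment probability for reads voting on long-deletion
#'   clusters (cluster membership is a whole-read decision, not a
#'   base-quality one)
#' @param maxWindow maximum indel-haplotype merge window (bp)
#' @param tol relative log-likelihood convergence tolerance
#' @param maxIter maximum Fisher-scoring iterations
#' @return a named list of thresholds
#' @export
callerThresholds <- function(pStrand = 1e-3, pQual = 1e-3, qualMin = 30,
                             lowFreq = 0.005, longDelMin = 64L,
                             mergeTol = 10L, delErr = 1e-3,
                             maxWindow = 50L, tol = 1e-8, maxIter = 100L) {
  list(pStrand = pStrand, pQual = pQual, qualMin = qualMin,
       lowFreq = lowFreq, longDelMin = as.integer(longDelMin),
       mergeTol = as.integer(mergeTol), delErr = delErr,
       maxWindow = as.integer(maxWindow),
       tol = tol, maxIter = as.integer(maxIter))
}

#' Candidate alleles at a site
#'
#' An allele is retained as a candidate iff it has more than one observation
#' on each strand (>= 2 forward and >= 2 reverse); the reference allele is
#' always retained as the baseline.
#'
#' @param sc site counts (data.table: allele, strand, q, n) from [siteCounts]
#' @param refAllele the reference base at the site
#' @return character vector of candidate alleles, reference first
#' @export
candidateAlleles <- function(sc, refAllele) {
  if (!nrow(sc)) return(refAllele)
  tab <- sc[, list(nf = sum(n[strand == "+"]), nr = sum(n[strand == "-"])),
            by = "allele"]
  cand <- tab$allele[tab$nf >= 2L & tab$nr >= 2L]
  union(refAllele, cand)
}

## Build the allele x quality count matrix at a site and fit it.
## Non-candidate alleles are kept as fixed-zero rows: their observations are
## treated as errors but still contribute to the totals.
.fitSite <- function(sc, refAllele, model, th) {
  alleles <- union(union(refAllele, candidateAlleles(sc, refAllele)),
                   unique(sc$allele))
  cand <- candidateAlleles(sc, refAllele)
  qlev <- sort(unique(sc$q))
  cmat <- matrix(0, nrow = length(alleles), ncol = length(qlev),
                 dimnames = list(alleles, qlev))
  agg <- sc[, list(n = sum(n)), by = c("allele", "q")]
  cmat[cbind(match(agg$allele, alleles), match(agg$q, qlev))] <- agg$n
  fixedZero <- which(!alleles %in% cand)
  fixedZero <- fixedZero[fixedZero != 1L]
  fit <- vafFit(cmat, phredError(qlev, model), tol = th$tol,
                maxIter = th$maxIter, fixedZero = fixedZero)
  strandTab <- sc[, list(nf = sum(n[strand == "+"]),
                         nr = sum(n[strand == "-"])), by = "allele"]
  list(alleles = alleles, fit = fit, cand = cand,
       strand = strandTab, qlev = qlev)
}

#' Estimate allele frequencies at one site
#'
#' Builds the allele-by-quality count matrix from stratified site counts,
#' fits it by Fisher scoring (non-candidate alleles constrained to zero but
#' contributing their observations) and applies the call filters to every
#' retained non-reference candidate.
#'
#' @param sc site counts (data.table: `allele`, `strand`, `q`, `n`), e.g.
#'   from [siteCounts] or [simulatePileupCounts]
#' @param refAllele the reference (baseline) allele
#' @param model a [QualityModel]
#' @param th thresholds from [callerThresholds]
#' @return data.frame, one row per allele: `allele`, `candidate`, `f`,
#'   `se`, `lr`, `qual`, `filter` (`NA` filter for the reference and for
#'   non-retained alleles)
#' @export
estimateSite <- function(sc, refAllele, model = QualityModel(),
                         th = callerThresholds()) {
  fs <- .fitSite(sc, refAllele, model, th)
  out <- data.frame(allele = fs$alleles,
                    candidate = fs$alleles %in% fs$cand,
                    f = fs$fit$f, se = fs$fit$se, lr = fs$fit$lr,
                    qual = fs$fit$qual, filter = NA_character_)
  for (i in seq_along(fs$alleles)[-1]) {
    if (out$candidate[i] && out$f[i] > 0)
      out$filter[i] <- .filterFlags(sc, fs$alleles[i], refAllele, out$f[i],
                                    ifelse(is.na(out$qual[i]), 0,
                                           out$qual[i]), th)
  }
  out
}

#' Detect, cluster and quantify long deletions
#'
#' Maximal runs of at least `longDelMin` consecutive positions carrying a
#' candidate deletion allele define regions; the per-read CIGAR deletion
#' intervals inside a region are clustered (start and length each within
#' `mergeTol` of the cluster medians), and each cluster becomes a deletion
#' allele whose frequency is estimated by the same ML machinery against the
#' reads spanning the region.
#'
#' @param pileup a [MitoPileup]
#' @param model a [QualityModel]
#' @param th thresholds from [callerThresholds]
#' @return list: `dels` (data.frame: start/end 1-based closed, length,
#'   support, f, se, qual), `regions` (data.frame start0/end0, 0-based),
#'   `delReads` (integer read indices carrying a long deletion)
#' @export
detectLongDeletions <- function(pileup, model = QualityModel(),
                                th = callerThresholds()) {
  empty <- list(dels = data.frame(start = integer(), end = integer(),
                                  length = integer(), support = integer(),
                                  f = numeric(), se = numeric(),
                                  qual = numeric()),
                regions = data.frame(start0 = integer(), end0 = integer()),
                delReads = integer(0))
  counts <- pileup@counts
  if (!nrow(counts) || !nrow(pileup@readDels)) return(empty)
  delTab <- counts[counts$allele == "-",
                   list(nf = sum(n[strand == "+"]),
                        nr = sum(n[strand == "-"])), by = "pos"]
  delPos <- sort(delTab$pos[delTab$nf >= 2L & delTab$nr >= 2L])
  if (!length(delPos)) return(empty)
  runId <- cumsum(c(1L, diff(delPos) > 1L))
  runs <- do.call(rbind, lapply(split(delPos, runId), function(p)
    data.frame(start0 = p[1], end0 = p[length(p)])))
  ## circular wrap: join a run ending at l-1 with one starting at 0
  if (nrow(runs) > 1L && runs$start0[1] == 0L &&
      runs$end0[nrow(runs)] == pileup@l - 1L) {
    runs$start0[1] <- runs$start0[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  runLen <- ifelse(runs$end0 >= runs$start0, runs$end0 - runs$start0 + 1L,
                   pileup@l - runs$start0 + runs$end0 + 1L)
  regions <- runs[runLen >= th$longDelMin, , drop = FALSE]
  if (!nrow(regions)) return(empty)

  rd <- pileup@readDels
  rd <- rd[rd$length >= th$longDelMin, , drop = FALSE]
  obs <- pileup@obs
  spans <- obs[, list(lo = min(pos), hi = max(pos)), by = "read"]
  delsOut <- NULL; delReads <- integer(0)
  for (g in seq_len(nrow(regions))) {
    rs <- regions$start0[g]; re <- regions$end0[g]
    ints <- rd[rd$start >= rs - th$mergeTol & rd$start <= re, , drop = FALSE]
    if (!nrow(ints)) next
    ints <- ints[order(ints$start, ints$length), , drop = FALSE]
    cl <- integer(nrow(ints)); medS <- numeric(0); medL <- numeric(0)
    members <- list()
    for (i in seq_len(nrow(ints))) {
      hit <- which(abs(medS - ints$start[i]) <= th$mergeTol &
                   abs(medL - ints$length[i]) <= th$mergeTol)
      if (length(hit)) {
        k <- hit[1]
        members[[k]] <- c(members[[k]], i)
        medS[k] <- median(ints$start[members[[k]]])
        medL[k] <- median(ints$length[members[[k]]])
      } else {
        members[[length(members) + 1L]] <- i
        medS <- c(medS, ints$start[i]); medL <- c(medL, ints$length[i])
      }
      cl[i] <- length(medS)
    }
    ## reads spanning the region can vote: intact baseline vs each cluster
    spanning <- spans$read[spans$lo <= rs & spans$hi >= re]
    clReads <- lapply(members, function(ix) unique(ints$read[ix]))
    inCluster <- unlist(clReads)
    intact <- setdiff(spanning, unique(rd$read[rd$start <= re &
                                                 rd$start + rd$length > rs]))
    ## a read's membership in a multi-kb deletion cluster is decided by its
    ## whole CIGAR, not a single base, so the error channel for these class
    ## counts is a small fixed misassignment probability rather than the
    ## base-quality model
    classes <- c(list(intact), clReads)
    cmat <- matrix(vapply(classes, length, 0L), ncol = 1L)
    fit <- vafFit(cmat, th$delErr, tol = th$tol, maxIter = th$maxIter)
    for (k in seq_along(clReads)) {
      s1 <- as.integer(round(medS[k])) + 1L           # 1-based start
      ln <- as.integer(round(medL[k]))
      delsOut <- rbind(delsOut, data.frame(
        start = s1, end = (s1 - 1L + ln - 1L) %% pileup@l + 1L,
        length = ln, support = length(clReads[[k]]),
        f = fit$f[k + 1L], se = fit$se[k + 1L],
        qual = if (!is.na(fit$qual[k + 1L])) fit$qual[k + 1L] else 0))
    }
    delReads <- union(delReads, inCluster)
  }
  if (is.null(delsOut)) return(empty)
  list(dels = delsOut, regions = regions[, c("start0", "end0")],
       delReads = as.integer(delReads))
}

#' Merge short indel haplotypes over local windows
#'
#' Windows start at a site without a candidate deletion allele (the anchor)
#' followed by one or more sites that carry one.  Merged alleles are built
#' incrementally from the product of the per-site retained alleles, counted
#' from reads spanning the window (the multibase quality is the lowest
#' component base quality), refitted at each extension and pruned at zero
#' frequency.
#'
#' @param pileup a [MitoPileup]
#' @param refChars character vector of reference bases (length l)
#' @param model a [QualityModel]
#' @param th thresholds from [callerThresholds]
#' @param skipPos 0-based positions to skip (e.g. long-deletion regions)
#' @param excludeReads read indices to ignore (long-deletion carriers)
#' @return data.frame of merged calls: `pos` (1-based window start), `ref`,
#'   `alt` (with `-` marking deleted bases), `f`, `se`, `qual`, `depth`
#' @export
mergeIndelHaplotypes <- function(pileup, refChars, model = QualityModel(),
                                 th = callerThresholds(),
                                 skipPos = integer(0),
                                 excludeReads = integer(0)) {
  counts <- pileup@counts
  emptyOut <- data.frame(pos = integer(), ref = character(),
                         alt = character(), f = numeric(), se = numeric(),
                         qual = numeric(), depth = integer())
  if (!nrow(counts)) return(emptyOut)
  obs <- pileup@obs
  if (length(excludeReads)) obs <- obs[!obs$read %in% excludeReads, ]
  delTab <- counts[counts$allele == "-",
                   list(nf = sum(n[strand == "+"]),
                        nr = sum(n[strand == "-"])), by = "pos"]
  delPos <- sort(setdiff(delTab$pos[delTab$nf >= 2L & delTab$nr >= 2L],
                         skipPos))
  if (!length(delPos)) return(emptyOut)
  runId <- cumsum(c(1L, diff(delPos) > 1L))
  out <- NULL
  for (p in split(delPos, runId)) {
    anchor <- p[1] - 1L
    if (anchor < 0L || anchor %in% delPos) next
    run <- p[seq_len(min(length(p), th$maxWindow - 1L))]
    if (length(p) > length(run))
      warning("merge window truncated at ", th$maxWindow, " bp")
    win <- c(anchor, run)
    wobs <- obs[obs$pos %in% win & !startsWith(obs$allele, "+"), ]
    cov <- wobs[, list(k = length(unique(pos)), qmin = min(q),
                       strand = strand[1]), by = "read"]
    full <- cov$read[cov$k == length(win)]
    if (length(full) < 4L) next
    wobs <- wobs[wobs$read %in% full, ]
    ## per-read haplotype string over the window
    setorder(wobs, read, pos)
    hap <- wobs[, list(h = paste(allele, collapse = "")), by = "read"]
    hap$qmin <- cov$qmin[match(hap$read, cov$read)]
    hap$strand <- cov$strand[match(hap$read, cov$read)]
    ## product of per-site retained alleles
    perSite <- lapply(win, function(pp)
      candidateAlleles(siteCounts(pileup, pp), refChars[pp + 1L]))
    prod <- Reduce(function(a, b) as.vector(outer(a, b, paste0)),
                   perSite)
    refHap <- paste(refChars[win + 1L], collapse = "")
    prod <- union(refHap, prod)
    alleles <- union(prod, unique(hap$h))
    qlev <- sort(unique(hap$qmin))
    cmat <- matrix(0, length(alleles), length(qlev),
                   dimnames = list(alleles, qlev))
    agg <- hap[, list(n = .N), by = c("h", "qmin")]
    cmat[cbind(match(agg$h, alleles), match(agg$qmin, qlev))] <- agg$n
    ## candidate merged alleles need >=2 observations on each strand
    str2 <- hap[, list(nf = sum(strand == "+"), nr = sum(strand == "-")),
                by = "h"]
    keep <- str2$h[str2$nf >= 2L & str2$nr >= 2L]
    fixedZero <- which(!(alleles %in% intersect(prod, keep)))
    fixedZero <- fixedZero[fixedZero != 1L]
    fit <- vafFit(cmat, phredError(qlev, model), tol = th$tol,
                  maxIter = th$maxIter, fixedZero = fixedZero)
    for (i in seq_along(alleles)[-1]) {
      if (fit$f[i] > 0 && alleles[i] != refHap)
        out <- rbind(out, data.frame(
          pos = anchor + 1L, ref = refHap, alt = alleles[i],
          f = fit$f[i], se = fit$se[i],
          qual = if (!is.na(fit$qual[i])) fit$qual[i] else 0,
          depth = length(full)))
    }
  }
  if (is.null(out)) emptyOut else out
}

## Fisher strand-bias and Mann-Whitney base-quality filters for one allele
## against the site's dominant other allele.
.filterFlags <- function(sc, allele, refAllele, f, qual, th) {
  flags <- character(0)
  other <- sc[sc$allele != allele,
              list(n = sum(n)), by = "allele"]
  comp <- if (nrow(other)) other$allele[which.max(other$n)] else refAllele
  aF <- sum(sc$n[sc$allele == allele & sc$strand == "+"])
  aR <- sum(sc$n[sc$allele == allele & sc$strand == "-"])
  cF <- sum(sc$n[sc$allele == comp & sc$strand == "+"])
  cR <- sum(sc$n[sc$allele == comp & sc$strand == "-"])
  if (aF + aR > 0 && cF + cR > 0) {
    p <- fisher.test(matrix(c(cF, cR, aF, aR), 2L))$p.value
    if (p < th$pStrand) flags <- c(flags, "strand_bias")
    if (aF + aR <= cF + cR) {         # called allele is the minor one
      qa <- rep(sc$q[sc$allele == allele], sc$n[sc$allele == allele])
      qc <- rep(sc$q[sc$allele == comp], sc$n[sc$allele == comp])
      pw <- suppressWarnings(
        wilcox.test(qa, qc, alternative = "less", exact = FALSE)$p.value)
      if (!is.na(pw) && pw < th$pQual) flags <- c(flags, "base_qual_bias")
    }
  }
  if (qual < th$qualMin) flags <- c(flags, "low_qual")
  if (f < th$lowFreq) flags <- c(flags, "low_freq")
  if (!length(flags)) "PASS" else paste(flags, collapse = ";")
}

#' Call variants from a pileup
#'
#' The full calling strategy: candidate alleles per site, ML frequency
#' estimation with LRT qualities, long-deletion detection/merging with
#' re-estimation of the affected sites excluding deletion carriers, local
#' indel-haplotype merging, and the three call filters (strand bias, minor
#' base quality, call quality) plus the low-frequency flag.
#'
#' @param pileup a [MitoPileup]
#' @param genome a [MitoGenome]
#' @param sample sample identifier carried into the output
#' @param model a [QualityModel]
#' @param th thresholds from [callerThresholds]
#' @param mergeHaplotypes run the indel-haplotype merge step (default TRUE)
#' @return a [MitoCalls]
#' @export
callVariants <- function(pileup, genome, sample = "sample",
                         model = QualityModel(), th = callerThresholds(),
                         mergeHaplotypes = TRUE) {
  l <- pileup@l
  stopifnot(genomeLength(genome) == l)
  refChars <- strsplit(genomeSeq(genome), "")[[1]]
  counts <- pileup@counts

  ld <- detectLongDeletions(pileup, model, th)
  regionPos <- integer(0)
  if (nrow(ld$regions))
    regionPos <- unlist(lapply(seq_len(nrow(ld$regions)), function(g) {
      s <- ld$regions$start0[g]; e <- ld$regions$end0[g]
      if (e >= s) s:e else c(s:(l - 1L), 0L:e)
    }))

  ## re-estimate sites inside deletion regions without the carrier reads
  if (length(ld$delReads) && length(regionPos)) {
    obs2 <- pileup@obs[!(pileup@obs$read %in% ld$delReads) &
                         pileup@obs$pos %in% regionPos, ]
    counts2 <- obs2[, list(n = .N), by = c("pos", "allele", "strand", "q")]
    counts <- rbind(counts[!counts$pos %in% regionPos, ], counts2)
  }

  ## sites worth fitting: any non-reference candidate allele
  tab <- counts[, list(nf = sum(n[strand == "+"]),
                       nr = sum(n[strand == "-"])),
                by = c("pos", "allele")]
  tab <- tab[tab$nf >= 2L & tab$nr >= 2L, ]
  tab <- tab[tab$allele != refChars[tab$pos + 1L], ]
  fitPos <- sort(unique(tab$pos))

  mergedWindows <- integer(0)
  mergedCalls <- NULL
  if (mergeHaplotypes) {
    mergedCalls <- mergeIndelHaplotypes(pileup, refChars, model, th,
                                        skipPos = regionPos,
                                        excludeReads = ld$delReads)
    if (nrow(mergedCalls))
      mergedWindows <- unlist(lapply(seq_len(nrow(mergedCalls)), function(i)
        (mergedCalls$pos[i] - 1L) + seq_len(nchar(mergedCalls$ref[i])) - 1L))
  }

  rows <- vector("list", length(fitPos))
  for (k in seq_along(fitPos)) {
    p <- fitPos[k]
    sc <- counts[counts$pos == p, ]
    refA <- refChars[p + 1L]
    fs <- .fitSite(sc, refA, model, th)
    depth <- sum(sc$n[!startsWith(sc$allele, "+")])
    siteRows <- NULL
    for (i in seq_along(fs$alleles)[-1]) {
      a <- fs$alleles[i]
      if (!(a %in% fs$cand) || fs$fit$f[i] <= 0) next
      if (a == "-" && (p %in% mergedWindows)) next  # folded into merged call
      qual <- if (!is.na(fs$fit$qual[i])) fs$fit$qual[i] else 0
      adf <- sum(sc$n[sc$allele == a & sc$strand == "+"])
      adr <- sum(sc$n[sc$allele == a & sc$strand == "-"])
      type <- if (a == "-") "del" else if (startsWith(a, "+")) "ins" else "snv"
      siteRows <- rbind(siteRows, data.frame(
        pos = p + 1L, ref = refA, alt = a, type = type,
        f = fs$fit$f[i], se = fs$fit$se[i], lr = fs$fit$lr[i], qual = qual,
        depth = depth, adf = adf, adr = adr,
        hf = (adf + adr) / depth,
        filter = .filterFlags(sc, a, refA, fs$fit$f[i], qual, th)))
    }
    rows[[k]] <- siteRows
  }
  calls <- do.call(rbind, rows)
  if (!is.null(mergedCalls) && nrow(mergedCalls)) {
    mc <- data.frame(pos = mergedCalls$pos, ref = mergedCalls$ref,
                     alt = mergedCalls$alt, type = "merged",
                     f = mergedCalls$f, se = mergedCalls$se, lr = NA_real_,
                     qual = mergedCalls$qual, depth = mergedCalls$depth,
                     adf = NA_integer_, adr = NA_integer_,
                     hf = NA_real_,
                     filter = ifelse(mergedCalls$qual < th$qualMin,
                                     "low_qual",
                              ifelse(mergedCalls$f < th$lowFreq,
                                     "low_freq", "PASS")))
    calls <- rbind(calls, mc)
  }
  if (is.null(calls))
    calls <- data.frame(pos = integer(), ref = character(),
                        alt = character(), type = character(), f = numeric(),
                        se = numeric(), lr = numeric(), qual = numeric(),
                        depth = integer(), adf = integer(), adr = integer(),
                        hf = numeric(), filter = character())
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  dels <- ld$dels
  dels$filter <- if (nrow(dels))
    ifelse(dels$qual < th$qualMin, "low_qual", "PASS") else character(0)
  new("MitoCalls", calls = calls, dels = dels, sample = sample,
      genome = genomeName(genome), l = as.integer(l))
}

#' Export per-base coverage
#'
#' Tab-separated `position<TAB>depth` (1-based), depth counting aligned
#' bases and deletions (insertions anchor without adding depth).
#'
#' @param pileup a [MitoPileup]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeCoverage <- function(pileup, path) {
  obs <- pileup@obs[!startsWith(pileup@obs$allele, "+"), ]
  depth <- integer(pileup@l)
  if (nrow(obs)) {
    tab <- obs[, list(n = .N), by = "pos"]
    depth[tab$pos + 1L] <- tab$n
  }
  write.table(data.frame(pos = seq_len(pileup@l), depth = depth), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
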