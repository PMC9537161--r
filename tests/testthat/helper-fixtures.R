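## Shared fixtures and independent oracles for the test suite.

## --- independent grid-search oracle for the VAF likelihood ----------------
## Maximises the same log-likelihood by coarse-to-fine grid search on the
## simplex (valid because the log-likelihood is concave in f), down to a
## stated resolution; shares no code with the Fisher-scoring path.

oracleLoglik <- function(f, counts, e) {
  P <- sweep(outer(f, 1 - 2 * e), 2, e, "+")
  sum(counts * log(P))
}

## dense 1-D grid for two-allele sites
gridMLE2 <- function(counts, e, step = 1e-5) {
  f <- seq(0, 1, by = step)
  ll <- numeric(length(f))
  for (j in seq_along(e)) {
    p1 <- e[j] + f * (1 - 2 * e[j])
    p0 <- e[j] + (1 - f) * (1 - 2 * e[j])
    ll <- ll + counts[2, j] * log(p1) + counts[1, j] * log(p0)
  }
  fb <- f[which.max(ll)]
  c(1 - fb, fb)
}

## coarse-to-fine 2-D grid for three-allele sites
gridMLE3 <- function(counts, e, step = 1e-5) {
  lo <- c(0, 0); hi <- c(1, 1); r <- 0.01
  best <- c(0, 0)
  repeat {
    f1 <- seq(max(0, lo[1]), min(1, hi[1]), by = r)
    f2 <- seq(max(0, lo[2]), min(1, hi[2]), by = r)
    g <- expand.grid(f1 = f1, f2 = f2)
    g <- g[g$f1 + g$f2 <= 1, ]
    ll <- numeric(nrow(g))
    for (j in seq_along(e)) {
      w <- 1 - 2 * e[j]
      ll <- ll + counts[2, j] * log(e[j] + g$f1 * w) +
        counts[3, j] * log(e[j] + g$f2 * w) +
        counts[1, j] * log(e[j] + (1 - g$f1 - g$f2) * w)
    }
    k <- which.max(ll)
    best <- c(g$f1[k], g$f2[k])
    if (r <= step) break
    lo <- best - 2 * r; hi <- best + 2 * r; r <- r / 10
  }
  c(1 - sum(best), best)
}

gridMLE <- function(counts, e, step = 1e-5) {
  if (nrow(counts) == 2L) gridMLE2(counts, e, step)
  else if (nrow(counts) == 3L) gridMLE3(counts, e, step)
  else stop("oracle supports 2 or 3 alleles")
}

## random site-count matrix: <= 3 alleles, <= maxObs observations,
## qualities in {10, 20, 30}
randomCountMatrix <- function(maxObs = 200L) {
  m <- sample(2:3, 1L)
  f <- c(1, runif(m - 1L, 0, 0.6))
  f <- f / sum(f)
  n <- sample(20:maxObs, 1L)
  qlev <- c(10L, 20L, 30L)
  true <- sample.int(m, n, replace = TRUE, prob = f)
  q <- sample(qlev, n, replace = TRUE)
  e <- 10^(-q / 10)
  flip <- runif(n) < e
  obsA <- true
  obsA[flip] <- vapply(true[flip], function(t) {
    s <- setdiff(seq_len(m), t)
    s[sample.int(length(s), 1L)]
  }, 0L)
  cm <- matrix(0, m, 3)
  for (j in 1:3) for (i in 1:m) cm[i, j] <- sum(obsA == i & q == qlev[j])
  list(counts = cm, e = 10^(-qlev / 10))
}

## --- site-count data.table builder (the caller's pileup slice shape) -----
scDT <- function(allele, strand, q, n) {
  data.table::data.table(allele = allele, strand = strand,
                         q = as.integer(q), n = as.integer(n))
}

## --- minimal SAM writer for hand-built alignment fixtures -----------------
## recs: data.frame with qname, flag, pos (1-based), cigar, seq, qual
writeSamFixture <- function(path, refName, refLen, recs) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", refName, "\tLN:", refLen))
  for (i in seq_len(nrow(recs)))
    lines <- c(lines, paste(recs$qname[i], recs$flag[i], refName,
                            recs$pos[i], 60L, recs$cigar[i], "*", 0L, 0L,
                            recs$seq[i], recs$qual[i], sep = "\t"))
  writeLines(lines, path)
  path
}

## fixed small toy genome used across tests
toyGenome <- function(l = 2000L, seed = 7L) {
  set.seed(seed)
  randomMitoGenome(l)
}

## quality string helper
qstr <- function(q, n = NULL) {
  if (!is.null(n)) q <- rep(q, n)
  intToUtf8(q + 33L, multiple = FALSE)
}

## shared alignment fixture: 50 bp toy genome, cut at m.10, d = 2
pileupFixture <- function() {
  g <- toyGenome(50L, seed = 99L)
  cr <- buildCustomReference(g, "c1", "s1", position = 10L, d = 2L)
  rot <- paste0(substr(genomeSeq(g), 10, 50), substr(genomeSeq(g), 1, 9))
  list(g = g, cr = cr, rot = rot, x0 = 9L, d = 2L, l = 50L,
       pos1 = 9L + 2L + 1L)                        # POS of a cut-start read
}
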