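## Maximum-likelihood estimation of variant allele fractions by Fisher
## scoring, under the quality-stratified one-vs-rest error model
## p(f, e) = f(1 - e) + (1 - f)e.
##
## Input is a count matrix c[i, j] of observations of allele i at quality
## level j (row 1 is the baseline/reference allele carrying f0 = 1 - sum f_i)
## and the per-level error probabilities e_j.  With m alleles there are m - 1
## free parameters; the score and expected-information elements are
##   S_i    = sum_j (1-2e_j) (c_ij / p(f_i,e_j) - c_0j / p(f_0,e_j))
##   I_ii   = sum_j (1-2e_j)^2 c_j (1/p(f_i,e_j) + 1/p(f_0,e_j))
##   I_ik   = sum_j (1-2e_j)^2 c_j / p(f_0,e_j)          (i != k)
## with c_j = sum_i c_ij, and updates f' = f + a I^-1 S with a in (0, 1]
## backtracked so the likelihood does not decrease and all frequencies
## stay >= 0.  A frequency driven to the zero boundary whose score is
## negative is fixed at zero and its allele removed from the maximisation.

.vafLoglik <- function(f, counts, e) {
  P <- sweep(outer(f, 1 - 2 * e), 2, e, "+")
  sum(counts * log(P))
}

#' Maximum-likelihood allele frequencies by Fisher scoring
#'
#' @param counts integer matrix, alleles x quality levels; row 1 is the
#'   baseline (reference) allele
#' @param e numeric vector of per-quality-level error probabilities, each in
#'   `(0, 0.5)`
#' @param tol relative log-likelihood convergence tolerance
#' @param maxIter maximum scoring iterations
#' @param fixedZero indices (> 1) of alleles whose frequency is constrained
#'   to zero (their observations still enter the likelihood and the totals)
#' @return list with elements `f` (frequencies, sum to 1), `se` (asymptotic
#'   standard errors from the inverse information; `NA` for constrained
#'   alleles), `loglik`, `converged`, `iter`, `free` (indices still free at
#'   the optimum)
#' @export
vafMLE <- function(counts, e, tol = 1e-8, maxIter = 100L,
                   fixedZero = integer(0)) {
  counts <- as.matrix(counts)
  m <- nrow(counts); J <- ncol(counts)
  stopifnot(m >= 1L, length(e) == J, all(e > 0), all(e < 0.5))
  if (any(fixedZero == 1L)) stop("baseline allele cannot be fixed to zero")
  w <- 1 - 2 * e
  cj <- colSums(counts)

  ## init from raw allele proportions, constrained alleles at 0
  f <- rowSums(counts) / max(1, sum(counts))
  f[fixedZero] <- 0
  if (sum(f) <= 0) f[1] <- 1 else f <- f / sum(f)
  free <- setdiff(seq_len(m)[-1], fixedZero)
  free <- free[f[free] > 0 | rowSums(counts)[free] > 0]

  L <- .vafLoglik(f, counts, e)
  iter <- 0L; converged <- FALSE
  while (iter < maxIter && length(free)) {
    iter <- iter + 1L
    P <- sweep(outer(f, w), 2, e, "+")
    invP0 <- 1 / P[1, ]
    S <- vapply(free, function(i)
      sum(w * (counts[i, ] / P[i, ] - counts[1, ] * invP0)), 0)
    A <- w^2 * cj
    off <- sum(A * invP0)
    Imat <- matrix(off, length(free), length(free))
    diag(Imat) <- vapply(free, function(i)
      sum(A * (1 / P[i, ] + invP0)), 0)
    delta <- tryCatch(solve(Imat, S),
                      error = function(err)
                        solve(Imat + diag(1e-8 * (1 + diag(Imat))), S))
    df <- numeric(m)
    df[free] <- delta
    df[1] <- -sum(delta)

    ## largest admissible step keeping all frequencies >= 0
    neg <- which(df < 0 & f + df < 0)
    amax <- if (length(neg)) min(1, min(-f[neg] / df[neg])) else 1
    if (!is.finite(amax) || amax <= 0) { converged <- TRUE; break }

    a <- amax; L2 <- -Inf; f2 <- f
    for (bt in 1:50) {
      f2 <- f + a * df
      f2[f2 < 0] <- 0                      # numeric dust from amax step
      f2[1] <- max(0, 1 - sum(f2[-1]))
      L2 <- .vafLoglik(f2, counts, e)
      if (L2 >= L - 1e-12) break
      a <- a / 2
    }
    if (L2 < L - 1e-12) { converged <- TRUE; break }  # no a > 0 improves L
    step <- max(abs(a * df))
    relD <- abs(L2 - L) / (abs(L) + 1)
    f <- f2; L <- L2

    ## zero-boundary handling: re-evaluate score at the boundary
    hit <- free[f[free] <= 1e-12]
    if (length(hit)) {
      f[hit] <- 0
      P <- sweep(outer(f, w), 2, e, "+")
      invP0 <- 1 / P[1, ]
      drop <- hit[vapply(hit, function(i)
        sum(w * (counts[i, ] / P[i, ] - counts[1, ] * invP0)) < 0, NA)]
      if (length(drop)) free <- setdiff(free, drop)
    }
    if (relD < tol && step < 1e-7) { converged <- TRUE; break }
  }
  if (!length(free)) converged <- TRUE

  se <- rep(NA_real_, m)
  if (length(free)) {
    P <- sweep(outer(f, w), 2, e, "+")
    invP0 <- 1 / P[1, ]
    A <- w^2 * cj
    Imat <- matrix(sum(A * invP0), length(free), length(free))
    diag(Imat) <- vapply(free, function(i) sum(A * (1 / P[i, ] + invP0)), 0)
    V <- tryCatch(solve(Imat), error = function(err) NULL)
    if (!is.null(V)) {
      se[free] <- sqrt(pmax(0, diag(V)))
      se[1] <- sqrt(max(0, sum(V)))       # var(f0) = 1' V 1
    }
  }
  list(f = f, se = se, loglik = L, converged = converged, iter = iter,
       free = free)
}

#' Full per-site fit: frequencies, standard errors and per-allele LRT
#'
#' Fits all alleles jointly, then tests each retained non-reference allele by
#' refitting with that allele's frequency fixed at zero (its observations
#' stay in the likelihood).  Qualities are the phred-scaled chi-square (1 df)
#' tail probabilities of the likelihood-ratio statistics.
#'
#' @inheritParams vafMLE
#' @param fixedZero alleles constrained to zero in the full fit (e.g.
#'   non-candidate alleles whose observations are treated as errors)
#' @return list: `f`, `se`, `loglik`, `converged`, plus `lr` and `qual`
#'   vectors (NA for the baseline and for constrained alleles)
#' @export
vafFit <- function(counts, e, tol = 1e-8, maxIter = 100L,
                   fixedZero = integer(0)) {
  full <- vafMLE(counts, e, tol, maxIter, fixedZero)
  m <- nrow(as.matrix(counts))
  lr <- rep(NA_real_, m); qual <- rep(NA_real_, m)
  for (i in setdiff(seq_len(m)[-1], fixedZero)) {
    if (full$f[i] <= 0) next                      # not retained
    null <- vafMLE(counts, e, tol, maxIter, fixedZero = c(fixedZero, i))
    lr[i] <- max(0, 2 * (full$loglik - null$loglik))
    logp <- pchisq(lr[i], df = 1, lower.tail = FALSE, log.p = TRUE)
    qual[i] <- min(-10 * logp / log(10), 9999)
  }
  c(full, list(lr = lr, qual = qual))
}
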