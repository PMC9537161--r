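## Pileup construction from alignments against doubled custom references.
##
## Every aligned base, deletion and insertion becomes an observation at its
## collapsed genome coordinate x' = (x - d) mod l.  Deletions take the
## quality of the preceding read base; insertions take the lowest quality of
## their component bases and are anchored at the preceding reference
## position without adding depth.  CIGAR D runs are additionally recorded as
## per-read deletion intervals for the long-deletion stage.

.CIGAR_RE <- "\\d+[MIDNSHP=X]"

.parseCigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr(.CIGAR_RE, cigar))[[1]]
  if (!length(m) || sum(nchar(m)) != nchar(cigar))
    stop("unparsable CIGAR: ", cigar)
  list(op = substr(m, nchar(m), nchar(m)),
       len = as.integer(substr(m, 1L, nchar(m) - 1L)))
}

#' Read SAM/BAM alignments in file order
#'
#' SAM text is converted on the fly with Rsamtools; records are returned in
#' file (read) order, unmapped records dropped.  Multiple files (one per
#' cut-site of a sample) may be given; they are concatenated in order, which
#' matches the merged, read-ordered inputs the caller expects.
#'
#' @param paths SAM or BAM file path(s)
#' @return data.frame: `qname`, `flag`, `pos` (1-based), `cigar`, `seq`,
#'   `qual` (ASCII Phred+33 string)
#' @export
readAlignments <- function(paths) {
  recs <- lapply(paths, function(path) {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    r <- Rsamtools::scanBam(Rsamtools::BamFile(bam),
      param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "pos", "cigar", "seq", "qual")))[[1]]
    keep <- !bitwAnd(r$flag, 4L)
    data.frame(qname = r$qname[keep], flag = r$flag[keep],
               pos = r$pos[keep], cigar = r$cigar[keep],
               seq = as.character(r$seq)[keep],
               qual = as.character(r$qual)[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

## Expand one alignment record into observation rows (0-based custom coords).
.expandRecord <- function(pos1, cigar, seqc, qualc, d, l, readIdx, strand) {
  cg <- .parseCigar(cigar)
  if (any(cg$op == "H")) stop("hard-clipped alignments are not supported")
  nOps <- length(cg$op)
  refc <- cg$op %in% c("M", "=", "X", "D", "N")
  readc <- cg$op %in% c("M", "=", "X", "I", "S")
  refStart <- pos1 - 1L + c(0L, cumsum(cg$len * refc))[seq_len(nOps)]
  readStart <- c(0L, cumsum(cg$len * readc))[seq_len(nOps)]
  bases <- strsplit(seqc, "")[[1]]
  quals <- utf8ToInt(qualc) - 33L

  outPos <- vector("list", nOps); outAll <- vector("list", nOps)
  outQ <- vector("list", nOps)
  dels <- NULL
  for (k in seq_len(nOps)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      idx <- readStart[k] + seq_len(len)
      outPos[[k]] <- refStart[k] + seq_len(len) - 1L
      outAll[[k]] <- bases[idx]
      outQ[[k]] <- quals[idx]
    } else if (op == "D") {
      qprev <- if (readStart[k] >= 1L) quals[readStart[k]] else quals[1L]
      outPos[[k]] <- refStart[k] + seq_len(len) - 1L
      outAll[[k]] <- rep("-", len)
      outQ[[k]] <- rep(qprev, len)
      dels <- rbind(dels, data.frame(read = readIdx,
                                     start = (refStart[k] - d) %% l,
                                     length = len, strand = strand))
    } else if (op == "I") {
      if (refStart[k] >= 1L) {     # anchored at the preceding reference base
        idx <- readStart[k] + seq_len(len)
        outPos[[k]] <- refStart[k] - 1L
        outAll[[k]] <- paste0("+", paste(bases[idx], collapse = ""))
        outQ[[k]] <- min(quals[idx])
      }
    }
    ## S consumes read only; N consumes reference as a skip: no observation
  }
  pos <- unlist(outPos)
  if (is.null(pos))
    return(list(obs = NULL, dels = dels))
  if (any(pos < 0L | pos >= 2L * (l + d)))
    stop("alignment outside the custom reference [0, 2(l+d))")
  list(obs = data.table(read = readIdx, pos = (pos - d) %% l,
                        allele = unlist(outAll), strand = strand,
                        q = unlist(outQ)),
       dels = dels)
}

#' Build a collapsed pileup from custom-reference alignments
#'
#' @param aln data.frame from [readAlignments] (possibly merged across
#'   cut-sites of one sample; coordinates collapse identically because all
#'   custom references share the doubled layout)
#' @param d padding used to build the custom references
#' @param l genome length
#' @param qualityModel a [QualityModel]; observations below `qMin` and `N`
#'   bases are discarded
#' @return a [MitoPileup]
#' @export
buildPileup <- function(aln, d, l, qualityModel = QualityModel()) {
  if (is.null(aln) || !nrow(aln))
    return(new("MitoPileup",
               counts = data.table(pos = integer(), allele = character(),
                                   strand = character(), q = integer(),
                                   n = integer()),
               obs = data.table(read = integer(), pos = integer(),
                                allele = character(), strand = character(),
                                q = integer()),
               readDels = data.frame(read = integer(), start = integer(),
                                     length = integer(),
                                     strand = character()),
               readIds = character(), l = as.integer(l)))
  ## a missing QUAL field ('*') surfaces as 0xff bytes / blank strings
  if (any(is.na(aln$qual)) || any(grepl("^[* ]*$", aln$qual)))
    stop("alignments must carry base qualities")
  readIds <- aln$qname
  obsList <- vector("list", nrow(aln))
  delList <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    strand <- if (bitwAnd(aln$flag[i], 16L)) "-" else "+"
    ex <- .expandRecord(aln$pos[i], aln$cigar[i], aln$seq[i], aln$qual[i],
                        d, l, i, strand)
    obsList[[i]] <- ex$obs
    delList[[i]] <- ex$dels
  }
  obs <- rbindlist(obsList)
  obs <- obs[obs$q >= qualityModel@qMin & obs$allele != "N", ]
  counts <- obs[, list(n = .N), by = c("pos", "allele", "strand", "q")]
  setorder(counts, pos, allele, strand, q)
  dels <- rbindlist(delList)
  dels <- if (nrow(dels)) as.data.frame(dels)
          else data.frame(read = integer(), start = integer(),
                          length = integer(), strand = character())
  new("MitoPileup", counts = counts, obs = obs, readDels = dels,
      readIds = readIds, l = as.integer(l))
}

#' Strand- and quality-stratified counts at one site
#'
#' @param pileup a [MitoPileup]
#' @param pos 0-based genome position
#' @return data.table of `allele`, `strand`, `q`, `n` at the site
#' @export
siteCounts <- function(pileup, pos) {
  pileup@counts[pileup@counts$pos == pos, ]
}

#' Per-read by per-position view matrix
#'
#' One row per read, exactly `l` columns: aligned base, `-` for deletion,
#' `.` for skip; an insertion is tagged by lower-casing its anchor base.
#'
#' @param pileup a [MitoPileup]
#' @return a [MitoViewMatrix]
#' @export
buildViewMatrix <- function(pileup) {
  l <- pileup@l
  nreads <- length(pileup@readIds)
  rows <- character(nreads)
  obs <- pileup@obs
  byRead <- split(seq_len(nrow(obs)), obs$read)
  template <- rep(".", l)
  for (r in seq_len(nreads)) {
    chars <- template
    idx <- byRead[[as.character(r)]]
    if (!is.null(idx)) {
      a <- obs$allele[idx]; p <- obs$pos[idx] + 1L
      ins <- startsWith(a, "+")
      base <- !ins
      chars[p[base]] <- a[base]
      if (any(ins)) {                     # lower-case the anchor base
        ap <- p[ins]
        chars[ap] <- tolower(chars[ap])
      }
    }
    rows[r] <- paste(chars, collapse = "")
  }
  new("MitoViewMatrix", rows = rows, readIds = pileup@readIds,
      l = as.integer(l))
}

#' Write a view matrix as fixed-width text
#'
#' @param vm a [MitoViewMatrix]
#' @param path output path
#' @param header if TRUE, prefix a line with each column's 1-based position
#'   modulo 10 (a light position ruler)
#' @return `path`, invisibly
#' @export
writeViewMatrix <- function(vm, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header)
    writeLines(paste(seq_len(vm@l) %% 10, collapse = ""), con)
  writeLines(vm@rows, con)
  invisible(path)
}

#' Haplotype counts and frequencies over a set of positions
#'
#' Reads with a skip at any selected position are excluded; frequencies are
#' over the remaining (covering) reads and sum to 1.
#'
#' @param vm a [MitoViewMatrix]
#' @param positions 1-based genome positions (non-empty)
#' @return data.frame: `haplotype` (concatenated per-position characters),
#'   `count`, `frequency`
#' @export
phaseFrequencies <- function(vm, positions) {
  if (!length(positions)) stop("empty position set")
  if (any(positions < 1L | positions > vm@l))
    stop("positions must lie in [1, l]")
  chars <- vapply(positions, function(p) substr(vm@rows, p, p),
                  character(length(vm@rows)))
  if (length(vm@rows) == 1L) chars <- matrix(chars, nrow = 1L)
  covered <- rowSums(chars == ".") == 0L
  chars <- chars[covered, , drop = FALSE]
  if (!nrow(chars))
    return(data.frame(haplotype = character(), count = integer(),
                      frequency = numeric()))
  hap <- apply(chars, 1L, paste, collapse = "")
  tab <- sort(table(hap), decreasing = TRUE)
  data.frame(haplotype = names(tab), count = as.integer(tab),
             frequency = as.integer(tab) / sum(tab), row.names = NULL)
}
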