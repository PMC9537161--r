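#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement BStringSet
#' @importFrom data.table data.table as.data.table setkey setorder rbindlist := .N
#' @importFrom stats runif rbinom pchisq fisher.test wilcox.test setNames median
#' @importFrom utils write.table read.table
NULL

## data.table NSE variables
utils::globalVariables(c(
  ".", "..keep", "allele", "n", "pos", "q", "read", "strand", "read_id",
  "start", "length", "N", "qname", "cluster"
))

#' Mitochondrial reference genome
#'
#' A single circular contig: name plus upper-case DNA sequence.  The length
#' slot `l` is the genome length in bp (16,569 for the human rCRS; arbitrary
#' for toy genomes used in tests and simulations).
#'
#' @slot name contig identifier (e.g. "chrM")
#' @slot seq a [Biostrings::DNAString] of the genome
#' @exportClass MitoGenome
setClass("MitoGenome", representation(name = "character", seq = "DNAString"))

setValidity("MitoGenome", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "genome sequence must be non-empty")
  bad <- setdiff(unique(strsplit(as.character(object@seq), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("alphabet restricted to A,C,G,T,N; found: ",
                         paste(bad, collapse = ",")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a MitoGenome
#'
#' @param name contig identifier
#' @param seq DNA sequence (character or DNAString); coerced to upper case
#' @return a `MitoGenome`
#' @export
#' @examples
#' g <- MitoGenome("toy", "ACGTACGTAC")
#' genomeLength(g)
MitoGenome <- function(name, seq) {
  if (is.character(seq)) {
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq))
      stop("alphabet restricted to A,C,G,T,N")
    seq <- DNAString(seq)
  }
  new("MitoGenome", name = name, seq = seq)
}

#' Read a single-contig mitochondrial genome from FASTA
#'
#' @param path FASTA file with exactly one contig
#' @return a `MitoGenome`
#' @export
readMitoGenome <- function(path) {
  ss <- readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-contig FASTA, found ", length(ss), " contigs")
  MitoGenome(sub("\\s.*$", "", names(ss)[1]), ss[[1]])
}

#' @describeIn MitoGenome-class contig name
#' @param x a MitoGenome
#' @export
genomeName <- function(x) x@name

#' @describeIn MitoGenome-class genome length in bp
#' @export
genomeLength <- function(x) length(x@seq)

#' @describeIn MitoGenome-class genome sequence as a character string
#' @export
genomeSeq <- function(x) as.character(x@seq)

setMethod("show", "MitoGenome", function(object) {
  cat("MitoGenome '", object@name, "': ", length(object@seq),
      " bp circular\n", sep = "")
})

#' Cut-site configuration
#'
#' Maps samples to named Cas9 cut-sites (1-based mitochondrial coordinates)
#' and carries the demultiplexing parameters: matching tolerance, selection
#' strategy and the padding `d` used when building custom references.
#'
#' @slot genome contig name of the mitochondrial reference
#' @slot l genome length (bp); 0 when unknown until a genome is attached
#' @slot sites data.frame with columns `name`, `sample`, `position` (1-based)
#' @slot tolerance matching tolerance in bp (default 100)
#' @slot strategy one of "both", "start", "either", "xor"
#' @slot d padding in bp for custom references (default 5)
#' @slot qMin minimum accepted base quality (default 5)
#' @exportClass CutSiteConfig
setClass("CutSiteConfig", representation(
  genome = "character", l = "integer", sites = "data.frame",
  tolerance = "integer", strategy = "character", d = "integer",
  qMin = "integer"))

setValidity("CutSiteConfig", function(object) {
  msg <- NULL
  s <- object@sites
  if (!all(c("name", "sample", "position") %in% names(s)))
    msg <- c(msg, "sites needs columns name, sample, position")
  else {
    if (anyDuplicated(s$name))
      msg <- c(msg, "cut-site names must be unique")
    if (nrow(s) && any(s$position < 1L))
      msg <- c(msg, "cut-site positions are 1-based (>= 1)")
    if (object@l > 0L && nrow(s) && any(s$position > object@l))
      msg <- c(msg, "cut-site position beyond genome length")
  }
  if (object@tolerance < 0L) msg <- c(msg, "tolerance must be >= 0")
  if (object@d < 1L) msg <- c(msg, "padding d must be >= 1")
  if (!object@strategy %in% c("both", "start", "either", "xor"))
    msg <- c(msg, "strategy must be one of both/start/either/xor")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CutSiteConfig
#'
#' @param genome contig name
#' @param sites data.frame with columns name, sample, position (1-based)
#' @param tolerance cut-site matching tolerance in bp
#' @param strategy read selection strategy: "both", "start", "either" or "xor"
#' @param d padding in bp for doubled custom references
#' @param qMin minimum accepted base quality
#' @param l genome length if known (enables position validation)
#' @return a `CutSiteConfig`
#' @export
CutSiteConfig <- function(genome, sites, tolerance = 100L, strategy = "both",
                          d = 5L, qMin = 5L, l = 0L) {
  sites <- as.data.frame(sites)
  sites$position <- as.integer(sites$position)
  cfg <- new("CutSiteConfig", genome = genome, l = as.integer(l),
             sites = sites, tolerance = as.integer(tolerance),
             strategy = tolower(strategy), d = as.integer(d),
             qMin = as.integer(qMin))
  ## cut-sites closer than 2*tolerance risk ambiguous assignment
  if (nrow(sites) > 1L && l > 0L) {
    p <- sort(sites$position)
    gaps <- c(diff(p), p[1] + l - p[length(p)])
    if (any(gaps < 2L * cfg@tolerance))
      warning("cut-sites closer than 2*tolerance: ambiguous assignments likely")
  }
  cfg
}

#' @describeIn CutSiteConfig-class the cut-site table
#' @param x a CutSiteConfig
#' @export
cutSites <- function(x) x@sites

setMethod("show", "CutSiteConfig", function(object) {
  cat("CutSiteConfig: ", nrow(object@sites), " cut-site(s), ",
      length(unique(object@sites$sample)), " sample(s); strategy=",
      object@strategy, " tolerance=", object@tolerance,
      "bp d=", object@d, "\n", sep = "")
})

#' Base quality / error model
#'
#' Converts Phred base qualities to error probabilities, discarding bases
#' below `qMin` and capping the error probability at `eCap` so that the
#' per-observation likelihood stays strictly increasing in the allele
#' frequency (requires e < 0.5).
#'
#' @slot qMin minimum accepted base quality
#' @slot eCap maximum error probability (< 0.5)
#' @exportClass QualityModel
setClass("QualityModel", representation(qMin = "integer", eCap = "numeric"))

setValidity("QualityModel", function(object) {
  msg <- NULL
  if (object@qMin < 0L) msg <- c(msg, "qMin must be >= 0")
  if (object@eCap <= 0 || object@eCap >= 0.5)
    msg <- c(msg, "eCap must be in (0, 0.5)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a QualityModel
#' @param qMin minimum accepted base quality (default 5)
#' @param eCap error-probability cap (default 0.45)
#' @return a `QualityModel`
#' @export
QualityModel <- function(qMin = 5L, eCap = 0.45) {
  new("QualityModel", qMin = as.integer(qMin), eCap = eCap)
}

setMethod("show", "QualityModel", function(object) {
  cat("QualityModel: qMin=", object@qMin, " eCap=", object@eCap, "\n", sep = "")
})

#' Doubled, masked custom reference for one cut-site
#'
#' The sequence is lastd(R) + R + R + firstd(R) of total length 2(l+d); all
#' bases outside the window [cut-site copy 1 - d, cut-site copy 2 + d]
#' (inclusive, 0-based custom coordinates) are masked to N, so every read
#' assigned to the cut-site maps exactly once whatever its length.
#'
#' @slot name contig name written to FASTA
#' @slot sample sample identifier
#' @slot cutName cut-site label
#' @slot cutPos 1-based cut position on the original genome
#' @slot d padding in bp
#' @slot l original genome length
#' @slot seq masked custom sequence (DNAString), length 2(l+d)
#' @slot unmasked integer c(lo, hi), 0-based inclusive unmasked interval
#' @exportClass CustomReference
setClass("CustomReference", representation(
  name = "character", sample = "character", cutName = "character",
  cutPos = "integer", d = "integer", l = "integer", seq = "DNAString",
  unmasked = "integer"))

setValidity("CustomReference", function(object) {
  msg <- NULL
  if (length(object@seq) != 2L * (object@l + object@d))
    msg <- c(msg, "custom sequence length must be 2(l+d)")
  if (diff(object@unmasked) + 1L != object@l + 2L * object@d + 1L)
    msg <- c(msg, "unmasked length must be l + 2d + 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CustomReference", function(object) {
  cat("CustomReference '", object@name, "': cut ", object@cutName,
      " @ m.", object@cutPos, ", 2(l+d) = ", length(object@seq),
      " bp, unmasked [", object@unmasked[1], ",", object@unmasked[2],
      "]\n", sep = "")
})

#' Per-sample pileup over the collapsed circular genome
#'
#' Holds quality- and strand-stratified allele counts per genome position
#' (the caller's input), the long per-read observation table (used for
#' haplotype merging and the view matrix) and the per-read long-deletion
#' intervals extracted from CIGAR D runs.
#'
#' @slot counts data.table: pos (0-based), allele, strand, q, n
#' @slot obs data.table: read (index), pos, allele, strand, q
#' @slot readDels data.frame: read (index), start (0-based), length, strand
#' @slot readIds character vector of read names (row index space)
#' @slot l genome length
#' @exportClass MitoPileup
setClass("MitoPileup", representation(
  counts = "data.table", obs = "data.table", readDels = "data.frame",
  readIds = "character", l = "integer"))

setMethod("show", "MitoPileup", function(object) {
  cat("MitoPileup: ", length(object@readIds), " read(s), l=", object@l,
      ", ", nrow(object@counts), " count cells, ",
      nrow(object@readDels), " long per-read deletion interval(s)\n", sep = "")
})

#' @describeIn MitoPileup-class number of reads in the pileup
#' @param x a MitoPileup
#' @export
pileupReads <- function(x) x@readIds

#' @describeIn MitoPileup-class genome length
#' @export
pileupGenomeLength <- function(x) x@l

#' Per-read by per-position view matrix
#'
#' One row per read and exactly `l` columns (16,569 for an rCRS-length
#' genome).  Cells hold the aligned base, '-' for a deletion, '.' for a skip
#' (position not covered) and a lower-case base to tag an insertion anchor.
#'
#' @slot rows character vector, one string of `l` characters per read
#' @slot readIds read names, parallel to `rows`
#' @slot l number of columns (genome length)
#' @exportClass MitoViewMatrix
setClass("MitoViewMatrix", representation(
  rows = "character", readIds = "character", l = "integer"))

setValidity("MitoViewMatrix", function(object) {
  if (length(object@rows) &&
      !all(nchar(object@rows) == object@l))
    "every row must have exactly l characters"
  else if (length(object@rows) != length(object@readIds))
    "rows and readIds must be parallel"
  else TRUE
})

setMethod("show", "MitoViewMatrix", function(object) {
  cat("MitoViewMatrix: ", length(object@rows), " read row(s) x ",
      object@l, " columns\n", sep = "")
})

#' @describeIn MitoViewMatrix-class number of columns (= genome length)
#' @param x a MitoViewMatrix
#' @export
viewColumns <- function(x) x@l

#' @describeIn MitoViewMatrix-class row strings
#' @export
viewRows <- function(x) x@rows

#' Variant call set for one sample
#'
#' SNV/indel calls with ML allele-frequency estimates, standard errors,
#' phred-scaled LRT qualities, per-strand depths and filter flags, plus long
#' deletion alleles with breakpoints, supporting read counts and frequencies.
#'
#' @slot calls data.frame of site-level calls (1-based positions)
#' @slot dels data.frame of long deletion alleles (1-based closed intervals)
#' @slot sample sample identifier
#' @slot genome contig name
#' @slot l genome length
#' @exportClass MitoCalls
setClass("MitoCalls", representation(
  calls = "data.frame", dels = "data.frame", sample = "character",
  genome = "character", l = "integer"))

setMethod("show", "MitoCalls", function(object) {
  npass <- if (nrow(object@calls)) sum(object@calls$filter == "PASS") else 0L
  cat("MitoCalls for sample '", object@sample, "': ", nrow(object@calls),
      " site call(s) (", npass, " PASS), ", nrow(object@dels),
      " long deletion allele(s)\n", sep = "")
})

#' @describeIn MitoCalls-class site-level call table
#' @param x a MitoCalls
#' @export
variantCalls <- function(x) x@calls

#' @describeIn MitoCalls-class long deletion allele table
#' @export
deletionAlleles <- function(x) x@dels
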