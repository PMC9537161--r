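## VCF 4.2 output.  Site calls carry the ML allele frequency (AF), its
## asymptotic standard error (SE) and the phred-scaled LRT quality; the
## per-sample FORMAT fields give total depth, per-strand allele depths and
## the read-count heteroplasmy fraction HF (alt-supporting reads over reads
## spanning the position).  Long deletions are emitted as symbolic <DEL>
## records with explicit END and SVLEN; a deletion spanning the reference
## origin becomes two records sharing an EVENT id.

.vcfHeader <- function(genome, l, sample) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", genome, ",length=", l, ">"),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Maximum-likelihood variant allele fraction\">",
    "##INFO=<ID=SE,Number=A,Type=Float,Description=\"Asymptotic standard error of AF\">",
    "##INFO=<ID=LRT,Number=A,Type=Float,Description=\"Likelihood-ratio statistic vs AF=0\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of a deletion (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length (negative)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Reads supporting the deletion allele\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"Shared id for records of one origin-spanning deletion\">",
    "##FILTER=<ID=strand_bias,Description=\"Fisher exact test of allelic strand bias\">",
    "##FILTER=<ID=base_qual_bias,Description=\"Mann-Whitney test of low minor-allele base quality\">",
    "##FILTER=<ID=low_qual,Description=\"Phred-scaled LRT quality below threshold\">",
    "##FILTER=<ID=low_freq,Description=\"Allele fraction below the low-frequency threshold\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the site\">",
    "##FORMAT=<ID=ADF,Number=1,Type=Integer,Description=\"Alt allele depth, forward strand\">",
    "##FORMAT=<ID=ADR,Number=1,Type=Integer,Description=\"Alt allele depth, reverse strand\">",
    "##FORMAT=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmy fraction: alt reads / spanning reads\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

.fmtNum <- function(x, digits = 6) {
  ifelse(is.na(x), ".", trimws(formatC(x, digits = digits, format = "g")))
}

## Translate one site call row into VCF REF/ALT/POS.
.vcfAlleles <- function(row, refChars, l) {
  pos <- row$pos; ref <- row$ref; alt <- row$alt
  if (row$type == "snv") return(list(pos = pos, ref = ref, alt = alt))
  if (row$type == "ins") {
    return(list(pos = pos, ref = ref, alt = paste0(ref, sub("^\\+", "", alt))))
  }
  if (row$type == "del") {                 # single deleted base, left-anchored
    apos <- if (pos > 1L) pos - 1L else l
    anchor <- refChars[apos]
    return(list(pos = apos, ref = paste0(anchor, ref), alt = anchor))
  }
  ## merged haplotype: strip '-' (deleted bases) from the alt string
  list(pos = pos, ref = ref, alt = gsub("-", "", row$alt, fixed = TRUE))
}

#' Write calls to a VCF 4.2 file
#'
#' @param calls a [MitoCalls] (calls must be position-sorted)
#' @param genome the [MitoGenome] the calls refer to
#' @param path output VCF path
#' @return `path`, invisibly
#' @export
writeMitoVcf <- function(calls, genome, path) {
  df <- calls@calls
  if (nrow(df) && is.unsorted(df$pos))
    stop("calls must be sorted by position")
  refChars <- strsplit(genomeSeq(genome), "")[[1]]
  l <- calls@l
  lines <- .vcfHeader(calls@genome, l, calls@sample)
  recs <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    al <- .vcfAlleles(row, refChars, l)
    if (al$alt == al$ref) next
    info <- paste0("AF=", .fmtNum(row$f), ";SE=", .fmtNum(row$se),
                   ";LRT=", .fmtNum(row$lr))
    fmt <- paste(ifelse(is.na(row$depth), ".", row$depth),
                 ifelse(is.na(row$adf), ".", row$adf),
                 ifelse(is.na(row$adr), ".", row$adr),
                 .fmtNum(row$hf, 4), sep = ":")
    recs <- c(recs, paste(calls@genome, al$pos, ".", al$ref, al$alt,
                          .fmtNum(row$qual, 4), row$filter, info,
                          "DP:ADF:ADR:HF", fmt, sep = "\t"))
  }
  dl <- calls@dels
  for (i in seq_len(nrow(dl))) {
    d <- dl[i, ]
    pieces <- if (d$end >= d$start) {
      list(c(d$start, d$end))
    } else {                               # origin-spanning: two records
      list(c(d$start, l), c(1L, d$end))
    }
    ev <- if (length(pieces) > 1L) paste0(";EVENT=DEL", i) else ""
    for (pc in pieces) {
      apos <- if (pc[1] > 1L) pc[1] - 1L else l
      info <- paste0("SVTYPE=DEL;END=", pc[2],
                     ";SVLEN=", -(pc[2] - pc[1] + 1L),
                     ";SUPPORT=", d$support,
                     ";AF=", .fmtNum(d$f), ";SE=", .fmtNum(d$se), ev)
      recs <- c(recs, paste(calls@genome, apos, ".", refChars[apos], "<DEL>",
                            .fmtNum(d$qual, 4), d$filter, info,
                            "DP:ADF:ADR:HF", ".:.:.:.", sep = "\t"))
    }
  }
  if (length(recs)) {
    ord <- order(as.integer(vapply(strsplit(recs, "\t"), `[`, "", 2L)))
    recs <- recs[ord]
  }
  writeLines(c(lines, recs), path)
  invisible(path)
}
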