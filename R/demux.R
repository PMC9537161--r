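## Cut-site demultiplexing from PAF alignments.
##
## Reads aligned to a whole-genome reference are assigned to the Cas9
## cut-site (and hence the sample) they were cleaved at.  A read passes the
## consistency filters only if (a) all its segments align to the same strand
## of the mitochondrial contig and nowhere else, (b) the segment order along
## the read and along the chromosome is consistent allowing for circularity,
## and (c) almost all of the read is mapped, with a circular genomic span of
## at most one genome length.  Its 5'/3' genome end points are then matched
## against the configured cut-sites: the start matches a cut-site if it lies
## at most `tolerance` bp after it in the direction of synthesis, the end if
## it lies at most `tolerance` bp before it.

#' Parse a PAF alignment file
#'
#' Mandatory 12 columns are kept; of the optional tags only `tp:A` is used,
#' to drop secondary alignments (primary and supplementary records are both
#' treated as segments of the read).
#'
#' @param path PAF file (minimap2 dialect, tab-separated, >= 12 columns)
#' @return data.table of alignment segments: `read_id`, `read_len`,
#'   `read_start`/`read_end` (0-based half-open, read space), `strand`,
#'   `target`, `target_start`/`target_end`, `mapq`, `secondary`
#' @export
parsePaf <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.table(read_id = character(), read_len = integer(),
                      read_start = integer(), read_end = integer(),
                      strand = character(), target = character(),
                      target_start = integer(), target_end = integer(),
                      mapq = integer(), secondary = logical()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed PAF line ", which(nf < 12L)[1], ": fewer than 12 columns")
  sec <- vapply(fields, function(fl)
    any(fl[-(1:12)] == "tp:A:S"), NA)
  dt <- data.table(
    read_id      = vapply(fields, `[`, "", 1L),
    read_len     = as.integer(vapply(fields, `[`, "", 2L)),
    read_start   = as.integer(vapply(fields, `[`, "", 3L)),
    read_end     = as.integer(vapply(fields, `[`, "", 4L)),
    strand       = vapply(fields, `[`, "", 5L),
    target       = vapply(fields, `[`, "", 6L),
    target_start = as.integer(vapply(fields, `[`, "", 8L)),
    target_end   = as.integer(vapply(fields, `[`, "", 9L)),
    mapq         = as.integer(vapply(fields, `[`, "", 12L)),
    secondary    = sec)
  bad <- which(is.na(dt$read_len) | is.na(dt$read_start) |
                 is.na(dt$target_start) | !dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed PAF line ", bad[1], ": unparsable coordinates/strand")
  dt
}

#' Validate one read's alignment segments
#'
#' @param seg data.table of non-secondary segments for one read (as from
#'   [parsePaf])
#' @param mitoName mitochondrial contig name
#' @param l genome length
#' @param minMappedFrac minimum fraction of read bases covered by segments
#' @return `"pass"` or a failure status: `non_mito`, `strand_inconsistent`,
#'   `order_inconsistent`, `low_mapped_fraction`, `overlong_span`
#' @export
validateRead <- function(seg, mitoName, l, minMappedFrac = 0.9) {
  if (!nrow(seg)) return("non_mito")
  if (any(seg$target != mitoName)) return("non_mito")
  if (all(seg$mapq == 0L)) return("non_mito")        # non-unique alignment
  if (length(unique(seg$strand)) != 1L) return("strand_inconsistent")
  seg <- seg[order(seg$read_start), ]
  ts <- seg$target_start; te <- seg$target_end
  if (seg$strand[1] == "-") {                        # mirror to + logic
    tmp <- l - te; te <- l - ts; ts <- tmp
  }
  off <- (ts - ts[1]) %% l
  ends <- off + (te - ts)
  if (nrow(seg) > 1L && any(diff(off) < 0)) return("order_inconsistent")
  if (nrow(seg) > 1L && any(off[-1] < ends[-nrow(seg)] - 0L))
    return("order_inconsistent")
  if (max(ends) > l) return("overlong_span")
  if (sum(seg$read_end - seg$read_start) < minMappedFrac * seg$read_len[1])
    return("low_mapped_fraction")
  "pass"
}

#' Genomic span of a validated read
#'
#' Returns the genome positions of the first (5') and last (3') sequenced
#' base; for minus-strand reads the 5' end is the highest genomic coordinate
#' of its first read-space segment.
#'
#' @inheritParams validateRead
#' @return list with `start5`, `end3` (0-based genome positions), `strand`
#' @export
readSpan <- function(seg, l) {
  stopifnot(nrow(seg) >= 1L)
  seg <- seg[order(seg$read_start), ]
  n <- nrow(seg)
  if (seg$strand[1] == "+")
    list(start5 = seg$target_start[1], end3 = seg$target_end[n] - 1L,
         strand = "+")
  else
    list(start5 = seg$target_end[1] - 1L, end3 = seg$target_start[n],
         strand = "-")
}

#' Match a read span against the configured cut-sites
#'
#' @param span result of [readSpan]
#' @param config a [CutSiteConfig]
#' @param l genome length
#' @return list with character vectors `start` and `end` of matching
#'   cut-site names
#' @export
matchCutSite <- function(span, config, l) {
  s <- cutSites(config); tol <- config@tolerance
  c0 <- s$position - 1L
  if (span$strand == "+") {
    sm <- ((span$start5 - c0) %% l) <= tol
    em <- ((c0 - 1L - span$end3) %% l) <= tol
  } else {
    sm <- ((c0 - 1L - span$start5) %% l) <= tol
    em <- ((span$end3 - c0) %% l) <= tol
  }
  list(start = s$name[sm], end = s$name[em])
}

#' Select a cut-site for a read from its start/end matches
#'
#' Strategies: `both` requires start and end to match the same cut-site
#' (full-length reads only); `start` requires a start match; `either`
#' selects on a start or end match; `xor` selects reads matching at exactly
#' one end (never full-length reads).  A read whose candidate set holds more
#' than one cut-site, or whose start and end match different cut-sites, is
#' rejected as `ambiguous`.
#'
#' @param matches result of [matchCutSite]
#' @param strategy one of "both", "start", "either", "xor"
#' @return list with `status`, `cut_site` (`NA` unless assigned) and
#'   `matched` ends ("start", "end", "both" or `NA`)
#' @export
selectRead <- function(matches, strategy) {
  st <- matches$start; en <- matches$end
  res <- function(status, cut = NA_character_, matched = NA_character_)
    list(status = status, cut_site = cut, matched = matched)
  ## conflicting evidence is rejected under every strategy: a read whose
  ## start and end match only different cut-sites cannot be assigned safely
  if (length(st) && length(en) && !length(intersect(st, en)))
    return(res("ambiguous"))
  switch(strategy,
    both = {
      if (!length(st) || !length(en)) return(res("no_cutsite_match"))
      both <- intersect(st, en)
      if (length(both) == 1L) res("assigned", both, "both")
      else res("ambiguous")
    },
    start = {
      if (!length(st)) return(res("no_cutsite_match"))
      if (length(st) == 1L)
        res("assigned", st, if (st %in% en) "both" else "start")
      else res("ambiguous")
    },
    either = {
      u <- union(st, en)
      if (!length(u)) return(res("no_cutsite_match"))
      if (length(u) > 1L) return(res("ambiguous"))
      res("assigned", u,
          if (length(st) && length(en)) "both"
          else if (length(st)) "start" else "end")
    },
    xor = {
      if (length(st) && length(en)) {
        ## full-length (or doubly matching) reads are excluded by design
        return(res("no_cutsite_match"))
      }
      u <- union(st, en)
      if (!length(u)) return(res("no_cutsite_match"))
      if (length(u) > 1L) return(res("ambiguous"))
      res("assigned", u, if (length(st)) "start" else "end")
    },
    stop("unknown strategy '", strategy, "'")
  )
}

#' Assign every read in a PAF file to a cut-site
#'
#' @param paf data.table from [parsePaf]
#' @param config a [CutSiteConfig]
#' @param l genome length
#' @param minMappedFrac minimum mapped fraction of read length
#' @param strategy selection strategy (defaults to the config's)
#' @return data.table: `read_id`, `status`, `cut_site`, `matched`
#' @export
assignReads <- function(paf, config, l, minMappedFrac = 0.9,
                        strategy = config@strategy) {
  paf <- paf[!paf$secondary, ]
  ids <- unique(paf$read_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    seg <- paf[paf$read_id == ids[k], ]
    v <- validateRead(seg, config@genome, l, minMappedFrac)
    if (v != "pass") {
      out[[k]] <- list(status = v, cut_site = NA_character_,
                       matched = NA_character_)
      next
    }
    out[[k]] <- selectRead(matchCutSite(readSpan(seg, l), config, l),
                           strategy)
  }
  data.table(read_id = ids,
             status = vapply(out, `[[`, "", "status"),
             cut_site = vapply(out, `[[`, "", "cut_site"),
             matched = vapply(out, `[[`, "", "matched"))
}

#' Demultiplex a FASTQ by cut-site
#'
#' Applies the consistency filters and the selection strategy to the PAF
#' alignments, then writes each assigned read to exactly one per-cut-site
#' FASTQ named `<sample>_<cutsite>.fastq`.  The report counts every status;
#' the status counts sum to the FASTQ read count.
#'
#' @param fastq input FASTQ path
#' @param paf PAF path (alignments of the same reads)
#' @param config a [CutSiteConfig]
#' @param outDir output directory (created if needed)
#' @param l genome length (required: the PAF does not carry it for circular
#'   span checks)
#' @param minMappedFrac minimum mapped fraction
#' @param strategy selection strategy (defaults to the config's)
#' @return list with `assignments` (data.table), `report` (data.frame of
#'   status counts), `perCutSite` (data.frame), `files` (written FASTQs)
#' @export
demultiplex <- function(fastq, paf, config, outDir, l,
                        minMappedFrac = 0.9, strategy = config@strategy) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reads <- readDNAStringSet(fastq, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(reads))
  if (anyDuplicated(ids)) stop("duplicate read ids in FASTQ")
  pafdt <- parsePaf(paf)
  asg <- assignReads(pafdt, config, l, minMappedFrac, strategy)

  missing_fastq <- setdiff(asg$read_id, ids)
  if (length(missing_fastq))
    warning(length(missing_fastq), " read(s) in PAF absent from FASTQ")
  asg <- asg[asg$read_id %in% ids, ]
  unaligned <- setdiff(ids, asg$read_id)
  if (length(unaligned))
    asg <- rbind(asg, data.table(read_id = unaligned, status = "unaligned",
                                 cut_site = NA_character_,
                                 matched = NA_character_))

  sites <- cutSites(config)
  files <- character(0)
  for (i in seq_len(nrow(sites))) {
    cs <- sites$name[i]
    sel <- asg$read_id[asg$status == "assigned" & asg$cut_site == cs]
    path <- file.path(outDir, paste0(sites$sample[i], "_", cs, ".fastq"))
    idx <- match(sel, ids)
    writeXStringSet(reads[idx], path, format = "fastq",
                    qualities = S4Vectors::mcols(reads)$qualities[idx])
    files[cs] <- path
  }
  statusCounts <- as.data.frame(table(status = asg$status),
                                stringsAsFactors = FALSE)
  names(statusCounts) <- c("status", "count")
  tab <- table(factor(asg$cut_site[asg$status == "assigned"],
                      levels = sites$name))
  per <- data.frame(cut_site = names(tab), count = as.integer(tab))
  stopifnot(sum(statusCounts$count) == length(ids))
  list(assignments = asg, report = statusCounts, perCutSite = per,
       files = files, missingFromFastq = missing_fastq)
}

#' Write a demultiplexing report as tab-separated text
#'
#' @param demux result of [demultiplex]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeDemuxReport <- function(demux, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# status\tcount", con)
  write.table(demux$report, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines("# cut_site\tcount", con)
  write.table(demux$perCutSite, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
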