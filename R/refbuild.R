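## Doubled, masked per-cut-site custom references.
##
## For a circular genome R of length l and padding d, the custom sequence is
## lastd(R) + R + R + firstd(R), total 2(l+d) bp, so every genome position
## appears in two copies at custom offsets +d and +l+d.  For a cut at
## 0-based genome position x, everything outside the window
## [x, x + l + 2d] (0-based inclusive custom coordinates, i.e. from d bases
## before the first cut copy to d bases after the second) is masked to N:
## a read assigned to the cut-site then maps exactly once whether it is
## full or partial length, and all cut-sites share one coordinate system.

#' Build the doubled, masked custom reference for one cut-site
#'
#' @param genome a [MitoGenome]
#' @param cutName cut-site label (e.g. "mt3")
#' @param sample sample identifier
#' @param position 1-based cut position on the genome
#' @param d padding in bp (>= 1); the cut must not lie within the first or
#'   last `d` bases of the genome
#' @return a [CustomReference]
#' @export
#' @examples
#' g <- MitoGenome("toy", "ACGTACGTAC")
#' buildCustomReference(g, "c1", "s1", position = 4, d = 2)
buildCustomReference <- function(genome, cutName, sample, position, d = 5L) {
  l <- genomeLength(genome); d <- as.integer(d)
  stopifnot(d >= 1L, position >= 1L, position <= l)
  x <- as.integer(position) - 1L               # 0-based cut position
  if (x < d || x >= l - d)
    stop("unsupported cut-site: cut at m.", position,
         " lies within ", d, " bp of the reference origin")
  s <- genomeSeq(genome)
  doubled <- paste0(substr(s, l - d + 1L, l), s, s, substr(s, 1L, d))
  lo <- x                                      # first cut copy at x+d, minus d
  hi <- x + l + 2L * d                         # second copy at x+l+d, plus d
  n <- 2L * (l + d)
  masked <- paste0(strrep("N", lo), substr(doubled, lo + 1L, hi + 1L),
                   strrep("N", n - hi - 1L))
  new("CustomReference",
      name = sprintf("%s_%s_cut%d_d%d", sample, cutName, position, d),
      sample = sample, cutName = cutName, cutPos = as.integer(position),
      d = d, l = l, seq = DNAString(masked),
      unmasked = c(lo, hi))
}

#' Build custom references for every cut-site in a configuration
#'
#' @param genome a [MitoGenome]
#' @param config a [CutSiteConfig]
#' @return named list of [CustomReference], one per cut-site
#' @export
buildCustomReferences <- function(genome, config) {
  s <- cutSites(config)
  refs <- lapply(seq_len(nrow(s)), function(i)
    buildCustomReference(genome, s$name[i], s$sample[i], s$position[i],
                         d = config@d))
  names(refs) <- s$name
  refs
}

#' Write a custom reference to FASTA
#'
#' Single contig, 60-column wrapping; the contig name encodes sample,
#' cut-site and padding.
#'
#' @param cr a [CustomReference]
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
writeReference <- function(cr, path) {
  ss <- DNAStringSet(cr@seq)
  names(ss) <- cr@name
  writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write / read custom-reference metadata
#'
#' A small TSV carrying, per custom reference, the fields the pileup stage
#' needs to collapse coordinates: contig name, sample, cut-site name,
#' 1-based cut position, padding `d` and genome length `l`.
#'
#' @param refs list of [CustomReference]
#' @param path TSV path
#' @return `path` (write) / data.frame (read)
#' @export
writeReferenceMeta <- function(refs, path) {
  df <- do.call(rbind, lapply(refs, function(r)
    data.frame(name = r@name, sample = r@sample, cut = r@cutName,
               position = r@cutPos, d = r@d, l = r@l)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceMeta
#' @export
readReferenceMeta <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
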