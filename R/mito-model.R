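## Circular-coordinate arithmetic and the quality/error model.
## All internal coordinates are 0-based half-open; user-facing coordinates
## (config files, VCF, reports) are 1-based, converted only at I/O.

#' Collapse a custom-reference coordinate back onto the circular genome
#'
#' Custom references carry two tandem genome copies with `d` bp of padding at
#' each end; a base at custom position `x` (0-based) originates from genome
#' position `(x - d) mod l`.
#'
#' @param x 0-based position(s) on the custom reference, in `[0, 2(l+d))`
#' @param d padding in bp
#' @param l genome length in bp
#' @return 0-based position(s) on the original genome, in `[0, l)`
#' @export
#' @examples
#' circularRemap(5, 5, 16569)      # 0
#' circularRemap(16574, 5, 16569)  # 0: one genome length downstream
circularRemap <- function(x, d, l) {
  stopifnot(l > 0, d >= 0)
  if (any(x < 0 | x >= 2 * (l + d)))
    stop("custom-reference coordinate out of range [0, 2(l+d))")
  (x - d) %% l
}

#' Phred quality to error probability
#'
#' `e = 10^(-q/10)`, capped at the model's `eCap` so the likelihood factor
#' `(1 - 2e)` stays positive.  Bases below `qMin` are excluded upstream
#' (in the pileup), not here.
#'
#' @param q integer base quality value(s), >= 0
#' @param model a [QualityModel]
#' @return error probabilities in `(0, eCap]`
#' @export
phredError <- function(q, model = QualityModel()) {
  if (any(q < 0)) stop("base quality must be non-negative")
  pmin(10^(-q / 10), model@eCap)
}

#' Per-observation likelihood of seeing an allele
#'
#' For an allele at frequency `f` observed through an error channel with
#' error probability `e`, the probability of the observation is the mixture
#' `p(f, e) = f (1 - e) + (1 - f) e`, affine and strictly increasing in `f`
#' whenever `e < 1/2`.
#'
#' @param f allele frequency in `[0, 1]`
#' @param e error probability in `(0, 0.5)`
#' @return observation probability in `(0, 1)`
#' @export
obsLikelihood <- function(f, e) {
  stopifnot(all(f >= 0 & f <= 1), all(e > 0 & e < 0.5))
  f * (1 - e) + (1 - f) * e
}

## internal, unchecked version used in the scoring loops
.pfe <- function(f, e) e + f * (1 - 2 * e)

#' Read a cut-site configuration file
#'
#' Plain-text key/value format.  Global keys (`genome`, `tolerance_bp`,
#' `strategy`, `d`, `q_min`) come first; each `[sample]` section lists
#' `cutsite_name = 1-based_position` pairs.  Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path configuration file
#' @return a [CutSiteConfig]
#' @export
readCutSiteConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  globals <- list(genome = "chrM", tolerance_bp = 100L, strategy = "both",
                  d = 5L, q_min = 5L)
  sites <- list(); sample <- NA_character_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.+\\]$", ln)) {
      sample <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("config parse error at line ", i, ": '", ln, "'")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (is.na(sample)) {
      if (!key %in% names(globals))
        stop("unknown global config key '", key, "'")
      globals[[key]] <- if (key %in% c("genome", "strategy")) val
                        else as.integer(val)
    } else {
      sites[[length(sites) + 1L]] <-
        data.frame(name = key, sample = sample, position = as.integer(val))
    }
  }
  if (!length(sites)) stop("config defines no cut-sites")
  CutSiteConfig(genome = globals$genome, sites = do.call(rbind, sites),
                tolerance = globals$tolerance_bp, strategy = globals$strategy,
                d = globals$d, qMin = globals$q_min)
}

#' Write a cut-site configuration file
#'
#' @param config a [CutSiteConfig]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCutSiteConfig <- function(config, path) {
  out <- c(paste0("genome = ", config@genome),
           paste0("tolerance_bp = ", config@tolerance),
           paste0("strategy = ", config@strategy),
           paste0("d = ", config@d),
           paste0("q_min = ", config@qMin), "")
  for (s in unique(config@sites$sample)) {
    sub <- config@sites[config@sites$sample == s, ]
    out <- c(out, paste0("[", s, "]"),
             paste0(sub$name, " = ", sub$position), "")
  }
  writeLines(out, path)
  invisible(path)
}
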