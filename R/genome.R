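# Genome geometry: chromosome lengths and centromere intervals.
# Telomeric-allelic-imbalance and large-state-transition scoring need to know
# where chromosome ends and arm boundaries are; builds are plain tables so
# tests and simulations never download anything.

#' Validate a genome build table
#'
#' A build is a data frame with columns `chrom`, `length`, `cen_start`,
#' `cen_end` (1-based bp; the centromere interval is excluded from both arms).
#'
#' @param build data frame.
#' @return `build`, invisibly; errors if malformed.
#' @export
validate_build <- function(build) {
  need <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(need, names(build))
  if (length(miss)) stop("genome build missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(build$chrom)) stop("duplicate chromosome names in build")
  bad <- build$cen_start <= 0 | build$cen_end >= build$length |
    build$cen_start >= build$cen_end
  if (any(bad))
    stop("invalid centromere interval for: ",
         paste(build$chrom[bad], collapse = ", "))
  invisible(build)
}

#' Read / write a genome build TSV
#'
#' @param path TSV with columns `chrom`, `length`, `cen_start`, `cen_end`.
#' @export
read_build_tsv <- function(path) {
  b <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_build(b)
  b
}

#' @rdname read_build_tsv
#' @param build validated build data frame.
#' @export
write_build_tsv <- function(build, path) {
  validate_build(build)
  utils::write.table(build, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' GRCh37 genome build
#'
#' Chromosome lengths and centromere intervals for GRCh37/hg19 (UCSC gap
#' track centromere coordinates), shipped as package data. Sex chromosomes
#' are included but excluded from scar scoring by default.
#'
#' @return Build data frame.
#' @export
grch37_build <- function() {
  read_build_tsv(system.file("extdata", "grch37_build.tsv",
                             package = "hrdscars", mustWork = TRUE))
}

#' Parameterized toy genome build
#'
#' A compact multi-chromosome build used by the synthetic cohort generator
#' and the test suite: `n_chrom` autosome-like chromosomes of `chrom_mb`
#' megabases with a centromere at `cen_start_mb`..`cen_end_mb`.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_mb chromosome length, Mb.
#' @param cen_start_mb,cen_end_mb centromere interval, Mb.
#' @return Build data frame.
#' @export
toy_genome_build <- function(n_chrom = 8L, chrom_mb = 130,
                             cen_start_mb = 60, cen_end_mb = 65) {
  mb <- 1e6
  b <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                  length = as.integer(chrom_mb * mb),
                  cen_start = as.integer(cen_start_mb * mb),
                  cen_end = as.integer(cen_end_mb * mb),
                  stringsAsFactors = FALSE)
  validate_build(b)
  b
}

#' Chromosome arms of a build
#'
#' @param build validated build.
#' @return Data frame with one row per arm: `chrom`, `arm` ("p"/"q"),
#'   `start`, `end` (1-based inclusive, centromere excluded).
#' @export
chrom_arms <- function(build) {
  validate_build(build)
  p <- data.frame(chrom = build$chrom, arm = "p", start = 1L,
                  end = build$cen_start - 1L, stringsAsFactors = FALSE)
  q <- data.frame(chrom = build$chrom, arm = "q", start = build$cen_end + 1L,
                  end = build$length, stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out[order(match(out$chrom, build$chrom), out$arm), , drop = FALSE]
}
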