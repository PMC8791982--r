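# 96-channel single-base-substitution catalog machinery.
#
# Channels follow the canonical COSMIC ordering: the six pyrimidine-strand
# substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each crossed with the 16
# flanking-base contexts in lexicographic (5', 3') order over A, C, G, T.

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
SBS_BASES <- c("A", "C", "G", "T")

.make_channel_labels <- function() {
  labs <- character(96)
  i <- 0L
  for (cls in SBS_CLASSES) {
    ref <- substr(cls, 1, 1)
    for (b5 in SBS_BASES) {
      for (b3 in SBS_BASES) {
        i <- i + 1L
        labs[i] <- paste0(b5, "[", cls, "]", b3)
      }
    }
  }
  labs
}

#' Canonical 96-channel labels
#'
#' Returns the 96 substitution-channel labels (e.g. `"A[C>T]G"`) in the fixed
#' COSMIC order used throughout the package: substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G, each with 16 flanking contexts ordered
#' lexicographically by 5' then 3' base.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() .SBS_CHANNELS

.SBS_CHANNELS <- .make_channel_labels()

#' Reverse complement of a DNA string
#'
#' @param x character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    bad <- !b %in% names(comp)
    if (any(bad)) stop("non-ACGT base in '", paste(b, collapse = ""), "'")
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

.check_base <- function(b, what) {
  if (length(b) != 1L || !toupper(b) %in% SBS_BASES)
    stop("invalid ", what, " base: '", b, "' (must be one of A, C, G, T)")
  toupper(b)
}

#' Map a substitution to its 96-channel index
#'
#' Substitutions with a purine reference (A or G) are reverse-complemented to
#' the pyrimidine-strand representation before indexing, so every substitution
#' maps to exactly one of the 96 canonical channels.
#'
#' @param ref,alt single reference/alternate bases (A/C/G/T), `ref != alt`.
#' @param context reference-strand trinucleotide centered on the variant; its
#'   middle base must equal `ref`.
#' @return Integer channel index in `1:96` (named with the channel label).
#' @export
#' @examples
#' channel_index("C", "T", "ACA")  # A[C>T]A
#' channel_index("G", "A", "AGG")  # reverse-complemented to C[C>T]T
channel_index <- function(ref, alt, context) {
  ref <- .check_base(ref, "reference")
  alt <- .check_base(alt, "alternate")
  if (ref == alt) stop("ref equals alt ('", ref, "'): not a substitution")
  context <- toupper(context)
  if (nchar(context) != 3L)
    stop("context must be a trinucleotide, got '", context, "'")
  if (!all(strsplit(context, "")[[1]] %in% SBS_BASES))
    stop("non-ACGT base in context '", context, "'")
  if (substr(context, 2, 2) != ref)
    stop("context '", context, "' middle base does not match ref '", ref, "'")
  if (ref %in% c("A", "G")) {
    context <- revcomp(context)
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  }
  cls <- match(paste0(ref, ">", alt), SBS_CLASSES)
  b5 <- match(substr(context, 1, 1), SBS_BASES)
  b3 <- match(substr(context, 3, 3), SBS_BASES)
  idx <- (cls - 1L) * 16L + (b5 - 1L) * 4L + b3
  names(idx) <- .SBS_CHANNELS[idx]
  idx
}

#' Flag clustered substitutions (kataegis)
#'
#' Marks runs of `min_run` or more same-sample variants whose consecutive
#' inter-mutation distances are all at most `max_dist` bp, the usual operating
#' definition of a kataegis focus. Used as an optional pre-filter before
#' catalog construction; off by default because published thresholds vary.
#'
#' @param variants data frame with at least `chrom` and `pos` columns
#'   (one sample).
#' @param max_dist maximum inter-mutation distance within a run, bp.
#' @param min_run minimum run length to flag.
#' @return Logical vector, `TRUE` for variants inside a flagged run.
#' @export
kataegis_flags <- function(variants, max_dist = 1000, min_run = 6L) {
  n <- nrow(variants)
  flag <- logical(n)
  if (n == 0L) return(flag)
  ord <- order(variants$chrom, variants$pos)
  chrom <- variants$chrom[ord]
  pos <- variants$pos[ord]
  run_start <- 1L
  close_run <- function(s, e) {
    if (e - s + 1L >= min_run) flag[ord[s:e]] <<- TRUE
  }
  for (i in seq_len(n)[-1]) {
    if (chrom[i] != chrom[i - 1L] || pos[i] - pos[i - 1L] > max_dist) {
      close_run(run_start, i - 1L)
      run_start <- i
    }
  }
  close_run(run_start, n)
  flag
}
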