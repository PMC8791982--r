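# Genomic scar scores from allele-specific copy number.
#
# Three scar scores summarize the copy-number fingerprint of homologous
# recombination deficiency:
#   LOH  - count of sizeable loss-of-heterozygosity regions (minor allele
#          lost) not spanning a whole chromosome;
#   ntAI - count of allelic-imbalance regions reaching a chromosome end
#          without crossing the centromere;
#   LST  - count of breakpoints between long adjacent segments in different
#          allele-specific states, per chromosome arm.
# The combined score is the unweighted sum LOH + TAI + LST; a sample is
# called HR-deficient when the combined score reaches the threshold (42).

MB <- 1e6
SEX_CHROMS <- c("chrX", "chrY", "X", "Y")

#' Validate an allele-specific segment table
#'
#' Segments carry `sample`, `chrom`, `start`, `end` (1-based inclusive bp),
#' `total_cn` and `minor_cn`. The minor allele is the smaller
#' (`minor_cn <= total_cn - minor_cn`) and segments of one sample/chromosome
#' must not overlap.
#'
#' @param segments data frame.
#' @return `segments`, invisibly.
#' @export
validate_segments <- function(segments) {
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(segments) == 0L) return(invisible(segments))
  if (any(segments$start > segments$end)) stop("segment with start > end")
  if (any(segments$total_cn < 0 | segments$minor_cn < 0))
    stop("negative copy number")
  if (any(segments$minor_cn > segments$total_cn - segments$minor_cn))
    stop("minor_cn exceeds the major allele copy number")
  for (key in split(segments, list(segments$sample, segments$chrom), drop = TRUE)) {
    o <- key[order(key$start), , drop = FALSE]
    if (nrow(o) > 1L && any(o$start[-1] <= o$end[-nrow(o)]))
      stop("overlapping segments for sample ", o$sample[1],
           " on ", o$chrom[1])
  }
  invisible(segments)
}

#' Read / write SEG-like segment tables
#'
#' Tab-delimited with columns `sample`, `chrom`, `start`, `end`, `total_cn`,
#' `minor_cn` (1-based inclusive coordinates).
#'
#' @param path file path.
#' @export
read_segments_tsv <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_segments(s)
  s
}

#' @rdname read_segments_tsv
#' @param segments validated segment table.
#' @export
write_segments_tsv <- function(segments, path) {
  validate_segments(segments)
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.state_dist <- function(a, b) {
  abs(a$total_cn - b$total_cn) + abs(a$minor_cn - b$minor_cn)
}

.coalesce_one <- function(seg) {
  # merge abutting segments with identical allele-specific state
  if (nrow(seg) < 2L) return(seg)
  keep <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    last <- nrow(keep)
    if (seg$start[i] == keep$end[last] + 1L &&
        seg$total_cn[i] == keep$total_cn[last] &&
        seg$minor_cn[i] == keep$minor_cn[last]) {
      keep$end[last] <- seg$end[i]
    } else {
      keep <- rbind(keep, seg[i, , drop = FALSE])
    }
  }
  keep
}

#' Smooth a segment profile
#'
#' Segments shorter than `min_len_mb` are absorbed into the neighboring
#' segment whose allele-specific state is closer (Manhattan distance on
#' (total, minor); ties go to the left neighbor), then abutting segments with
#' identical states are coalesced. The operation is idempotent and is the
#' standard pre-processing step before large-state-transition counting.
#'
#' @param segments validated segment table.
#' @param min_len_mb minimum retained segment length, Mb.
#' @return Smoothed segment table.
#' @export
smooth_segments <- function(segments, min_len_mb = 3) {
  validate_segments(segments)
  if (nrow(segments) == 0L) return(segments)
  min_len <- min_len_mb * MB
  pieces <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
  out <- lapply(pieces, function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    repeat {
      len <- seg$end - seg$start + 1
      short <- which(len < min_len)
      if (length(short) == 0L || nrow(seg) == 1L) break
      i <- short[which.min(len[short])]
      left <- if (i > 1L) i - 1L else NA_integer_
      right <- if (i < nrow(seg)) i + 1L else NA_integer_
      tgt <- if (is.na(left)) right
             else if (is.na(right)) left
             else if (.state_dist(seg[i, ], seg[left, ]) <=
                      .state_dist(seg[i, ], seg[right, ])) left else right
      if (tgt < i) seg$end[tgt] <- seg$end[i] else seg$start[tgt] <- seg$start[i]
      seg <- seg[-i, , drop = FALSE]
    }
    .coalesce_one(seg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.drop_sex <- function(segments, include_sex) {
  if (include_sex) segments else
    segments[!segments$chrom %in% SEX_CHROMS, , drop = FALSE]
}

.build_lookup <- function(segments, build) {
  unknown <- setdiff(unique(segments$chrom), build$chrom)
  if (length(unknown))
    stop("chromosome(s) not in genome build: ", paste(unknown, collapse = ", "))
  build[match(segments$chrom, build$chrom), , drop = FALSE]
}

#' HRD-LOH score
#'
#' Counts loss-of-heterozygosity segments (`minor_cn == 0`, `total_cn >= 1`)
#' of at least `min_mb` megabases that do not span an entire chromosome.
#' Input should be smoothed ([smooth_segments()]). One sample.
#'
#' @param segments smoothed segment table for one sample.
#' @param build genome build (see [toy_genome_build()], [grch37_build()]).
#' @param min_mb minimum LOH segment length, Mb (15 by convention).
#' @param include_sex include chrX/chrY (off: allele-specific states are
#'   ill-defined for XY genomes).
#' @return Integer count.
#' @export
score_loh <- function(segments, build, min_mb = 15, include_sex = FALSE) {
  validate_segments(segments)
  segments <- .drop_sex(segments, include_sex)
  if (nrow(segments) == 0L) return(0L)
  b <- .build_lookup(segments, build)
  len <- segments$end - segments$start + 1
  is_loh <- segments$minor_cn == 0 & segments$total_cn >= 1
  whole <- segments$start == 1 & segments$end == b$length
  sum(is_loh & len >= min_mb * MB & !whole)
}

#' Telomeric allelic imbalance score (ntAI)
#'
#' Counts allelic-imbalance segments (`minor_cn != total_cn - minor_cn`)
#' of at least `min_mb` megabases that touch a chromosome end
#' (`start == 1` or `end == ` chromosome length) and do not cross the
#' centromere (do not span the full centromere interval).
#'
#' @inheritParams score_loh
#' @param min_mb minimum segment length, Mb.
#' @return Integer count.
#' @export
score_ntai <- function(segments, build, min_mb = 1, include_sex = FALSE) {
  validate_segments(segments)
  segments <- .drop_sex(segments, include_sex)
  if (nrow(segments) == 0L) return(0L)
  b <- .build_lookup(segments, build)
  len <- segments$end - segments$start + 1
  ai <- segments$minor_cn != segments$total_cn - segments$minor_cn
  telo <- segments$start == 1 | segments$end == b$length
  crosses <- segments$start <= b$cen_start & segments$end >= b$cen_end
  sum(ai & telo & !crosses & len >= min_mb * MB)
}

#' Large state transition score (LST)
#'
#' Per chromosome arm (segments clipped at the centromere), counts
#' breakpoints between consecutive segments in different allele-specific
#' states where both flanking segments are at least `min_seg_mb` megabases
#' (after clipping) and the gap between them is under `max_gap_mb` megabases.
#' Input should be smoothed at 3 Mb first.
#'
#' @inheritParams score_loh
#' @param min_seg_mb minimum flanking-segment length, Mb.
#' @param max_gap_mb maximum inter-segment gap, Mb (strict).
#' @return Integer count.
#' @export
score_lst <- function(segments, build, min_seg_mb = 10, max_gap_mb = 3,
                      include_sex = FALSE) {
  validate_segments(segments)
  segments <- .drop_sex(segments, include_sex)
  if (nrow(segments) == 0L) return(0L)
  .build_lookup(segments, build)  # chromosome check
  arms <- chrom_arms(build)
  total <- 0L
  for (a in seq_len(nrow(arms))) {
    seg <- segments[segments$chrom == arms$chrom[a] &
                    segments$end >= arms$start[a] &
                    segments$start <= arms$end[a], , drop = FALSE]
    if (nrow(seg) < 2L) next
    seg$start <- pmax(seg$start, arms$start[a])
    seg$end <- pmin(seg$end, arms$end[a])
    seg <- seg[order(seg$start), , drop = FALSE]
    len <- seg$end - seg$start + 1
    for (i in seq_len(nrow(seg) - 1L)) {
      gap <- seg$start[i + 1L] - seg$end[i] - 1
      state_change <- seg$total_cn[i] != seg$total_cn[i + 1L] ||
        seg$minor_cn[i] != seg$minor_cn[i + 1L]
      if (state_change && len[i] >= min_seg_mb * MB &&
          len[i + 1L] >= min_seg_mb * MB && gap < max_gap_mb * MB)
        total <- total + 1L
    }
  }
  total
}

#' Combined genomic scar score and HR-deficiency call
#'
#' The combined score is the unweighted sum `LOH + TAI + LST`; a sample is
#' HR-deficient when the combined score reaches `cutoff` (42).
#'
#' @param loh,tai,lst non-negative integer component scores.
#' @return `combined_score()`: integer sum.
#' @export
combined_score <- function(loh, tai, lst) {
  if (any(c(loh, tai, lst) < 0)) stop("scar scores must be non-negative")
  as.integer(loh + tai + lst)
}

#' @rdname combined_score
#' @param combined combined score.
#' @param cutoff deficiency threshold; scores `>= cutoff` are deficient.
#' @return `classify_hrd()`: logical.
#' @export
classify_hrd <- function(combined, cutoff = 42) {
  if (any(combined < 0)) stop("combined score must be non-negative")
  combined >= cutoff
}

#' Score all scars for a multi-sample segment table
#'
#' Smooths each sample's profile and computes LOH, ntAI, LST, the combined
#' score and the deficiency call.
#'
#' @param segments segment table (any number of samples).
#' @param build genome build.
#' @param min_len_mb smoothing length, Mb.
#' @param loh_min_mb,ntai_min_mb,lst_min_seg_mb,lst_max_gap_mb scorer
#'   thresholds, Mb.
#' @param hrd_cutoff deficiency threshold on the combined score.
#' @param include_sex include sex chromosomes.
#' @return Object of class `scar_scores`: data frame with one row per sample
#'   (`sample`, `loh`, `tai`, `lst`, `combined`, `deficient`).
#' @export
score_scars <- function(segments, build, min_len_mb = 3, loh_min_mb = 15,
                        ntai_min_mb = 1, lst_min_seg_mb = 10,
                        lst_max_gap_mb = 3, hrd_cutoff = 42,
                        include_sex = FALSE) {
  validate_segments(segments)
  samples <- unique(segments$sample)
  rows <- lapply(samples, function(s) {
    seg <- smooth_segments(segments[segments$sample == s, , drop = FALSE],
                           min_len_mb = min_len_mb)
    loh <- score_loh(seg, build, min_mb = loh_min_mb, include_sex = include_sex)
    tai <- score_ntai(seg, build, min_mb = ntai_min_mb, include_sex = include_sex)
    lst <- score_lst(seg, build, min_seg_mb = lst_min_seg_mb,
                     max_gap_mb = lst_max_gap_mb, include_sex = include_sex)
    comb <- combined_score(loh, tai, lst)
    data.frame(sample = s, loh = loh, tai = tai, lst = lst, combined = comb,
               deficient = classify_hrd(comb, cutoff = hrd_cutoff),
               row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("scar_scores", "data.frame"))
}

#' @export
print.scar_scores <- function(x, ...) {
  cat("Genomic scar scores (combined = LOH + TAI + LST):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Paired scar-score comparison
#'
#' One-sided Wilcoxon signed-rank test that metastasis scar scores exceed
#' their patient-matched primaries (exact for small samples without ties or
#' zeros; normal approximation otherwise). When every within-pair difference
#' is zero the test is degenerate and returns p = 1 with a warning.
#'
#' @param primary_scores,met_scores equal-length paired numeric vectors.
#' @param alternative `"greater"` (metastasis > primary, default), `"less"`
#'   or `"two.sided"`.
#' @return The p-value, with the signed-rank statistic as attribute
#'   `statistic`.
#' @export
paired_scar_test <- function(primary_scores, met_scores,
                             alternative = "greater") {
  if (length(primary_scores) != length(met_scores))
    stop("paired vectors differ in length")
  if (length(primary_scores) < 2L) stop("need at least 2 pairs")
  d <- met_scores - primary_scores
  if (all(d == 0)) {
    warning("all paired differences are zero; signed-rank test degenerate")
    return(structure(1, statistic = 0))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(met_scores, primary_scores, paired = TRUE,
                       alternative = alternative))
  structure(unname(ht$p.value), statistic = unname(ht$statistic))
}
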