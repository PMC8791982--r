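# Single-sample gene-set enrichment of DNA-repair pathways.
#
# Two rank-based per-sample scorers:
#  - ssgsea_scores(): rank-weighted running-sum statistic (weights rank^tau),
#    the single-sample GSEA score; depends only on within-sample ranks.
#  - gsva_scores(): cross-sample kernel-CDF transform per gene, symmetric
#    rank weighting and a KS-like random walk; signed scores in [-1, 1]
#    expressing enrichment relative to the rest of the cohort.
# Cohort-level comparisons use exact Wilcoxon tests with Benjamini-Hochberg
# adjustment across gene sets within one test family.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are dropped.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  sets <- list()
  for (l in ln) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", f[1])
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  ln <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(ln, path)
}

# Match set members to matrix genes (case-folded exact string match); sets
# with fewer than 2 matched genes are dropped with a warning.
.match_sets <- function(sets, genes) {
  up <- toupper(genes)
  matched <- lapply(sets, function(s) genes[up %in% toupper(s)])
  keep <- vapply(matched, length, 0L) >= 2L
  if (!any(keep))
    stop("no gene set has at least 2 members present in the matrix")
  if (any(!keep))
    warning("dropping gene set(s) with < 2 matched genes: ",
            paste(names(sets)[!keep], collapse = ", "))
  matched[keep]
}

#' ssGSEA per-sample enrichment scores
#'
#' For each sample, genes are ordered by decreasing expression and assigned
#' weights `rank^tau` (rank N for the most expressed gene). The score of a
#' set is the sum over the ordered list of the difference between the
#' weighted cumulative fraction of in-set genes and the unweighted cumulative
#' fraction of out-of-set genes. With `tau = 0` this is the classical
#' Kolmogorov-Smirnov running-sum statistic. Scores depend only on ranks, so
#' any strictly increasing per-sample transform leaves them unchanged.
#'
#' @param mat genes x samples numeric matrix with row and column names
#'   (log-scale expression).
#' @param sets named list of gene-identifier vectors.
#' @param tau rank-weighting exponent (0.25, the original method's default).
#' @param normalize divide the full score matrix by its global
#'   `max - min` range.
#' @return sets x samples numeric matrix.
#' @export
ssgsea_scores <- function(mat, sets, tau = 0.25, normalize = TRUE) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene row names and sample column names")
  matched <- .match_sets(sets, rownames(mat))
  N <- nrow(mat)
  scores <- matrix(0, length(matched), ncol(mat),
                   dimnames = list(names(matched), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    ord <- order(mat[, j], decreasing = TRUE)
    w <- (N - seq_len(N) + 1) ^ tau  # weight by descending rank position
    for (k in seq_along(matched)) {
      inset <- rownames(mat)[ord] %in% matched[[k]]
      n_in <- sum(inset)
      cdf_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
      cdf_out <- cumsum(!inset) / (N - n_in)
      scores[k, j] <- sum(cdf_in - cdf_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' GSVA-style per-sample enrichment scores
#'
#' Each gene's expression is first transformed to a cross-sample relative
#' statistic by Gaussian-kernel CDF estimation (bandwidth = per-gene sample
#' SD / 4). Per sample, genes are ranked by that statistic and given
#' symmetric rank weights `|N/2 - position + 1/2|` so both tails of the
#' ranking carry weight. A Kolmogorov-Smirnov-like random walk steps up by
#' normalized weight at in-set genes and down by `1/(N - |set|)` otherwise;
#' the score is the maximum positive deviation plus the minimum negative
#' deviation of the walk, which lies in `[-1, 1]`.
#'
#' Needs at least 4 samples (the kernel CDF is estimated across samples);
#' for smaller cohorts use [ssgsea_scores()].
#'
#' @inheritParams ssgsea_scores
#' @param bw_factor divisor applied to the per-gene SD to get the kernel
#'   bandwidth.
#' @return sets x samples numeric matrix with values in `[-1, 1]`.
#' @export
gsva_scores <- function(mat, sets, bw_factor = 4) {
  if (ncol(mat) < 4L)
    stop("gsva_scores needs at least 4 samples; use ssgsea_scores for ",
         ncol(mat), " sample(s)")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene row names and sample column names")
  matched <- .match_sets(sets, rownames(mat))
  N <- nrow(mat); S <- ncol(mat)
  # kernel CDF transform, per gene across samples
  z <- matrix(0, N, S, dimnames = dimnames(mat))
  for (g in seq_len(N)) {
    x <- mat[g, ]
    h <- stats::sd(x) / bw_factor
    if (!is.finite(h) || h <= 0) h <- 1e-8
    z[g, ] <- vapply(x, function(v) mean(stats::pnorm((v - x) / h)), 0)
  }
  scores <- matrix(0, length(matched), S,
                   dimnames = list(names(matched), colnames(mat)))
  for (j in seq_len(S)) {
    ord <- order(z[, j], decreasing = TRUE)
    pos <- seq_len(N)
    w <- abs(N / 2 - pos + 0.5)
    genes_ord <- rownames(mat)[ord]
    for (k in seq_along(matched)) {
      inset <- genes_ord %in% matched[[k]]
      n_in <- sum(inset)
      step <- ifelse(inset, w / sum(w[inset]), -1 / (N - n_in))
      walk <- cumsum(step)
      scores[k, j] <- max(c(walk, 0)) + min(c(walk, 0))
    }
  }
  scores
}

.check_pairing <- function(samples, pairing) {
  need <- c("sample", "patient", "disease_status")
  miss <- setdiff(need, names(pairing))
  if (length(miss)) stop("pairing table missing column(s): ",
                         paste(miss, collapse = ", "))
  p <- pairing[pairing$sample %in% samples, , drop = FALSE]
  pat <- unique(p$patient)
  bad <- character(0)
  for (id in pat) {
    st <- p$disease_status[p$patient == id]
    if (sum(st == "primary") != 1L || sum(st == "metastasis") != 1L)
      bad <- c(bad, id)
  }
  if (length(bad))
    stop("incomplete primary/metastasis pairing for patient(s): ",
         paste(bad, collapse = ", "))
  p
}

.exact_two_sided_signed_rank <- function(a, b) {
  d <- b - a
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  unname(suppressWarnings(
    stats::wilcox.test(b, a, paired = TRUE,
                       alternative = "two.sided")$p.value))
}

#' Paired primary-vs-metastasis pathway test
#'
#' Two-sided Wilcoxon signed-rank test per gene set comparing metastasis and
#' patient-matched primary scores, with Benjamini-Hochberg adjustment across
#' the sets of this family.
#'
#' @param scores sets x samples matrix ([ssgsea_scores()] / [gsva_scores()]).
#' @param pairing data frame with columns `sample`, `patient`,
#'   `disease_status` (`"primary"`/`"metastasis"`); every patient must have
#'   exactly one sample of each status among the score columns.
#' @return Data frame: `set`, `n_pairs`, `median_diff`
#'   (metastasis - primary), `p`, `q`.
#' @export
paired_pathway_test <- function(scores, pairing) {
  p <- .check_pairing(colnames(scores), pairing)
  pats <- unique(p$patient)
  prim <- vapply(pats, function(id)
    p$sample[p$patient == id & p$disease_status == "primary"], "")
  met <- vapply(pats, function(id)
    p$sample[p$patient == id & p$disease_status == "metastasis"], "")
  res <- data.frame(set = rownames(scores), n_pairs = length(pats),
                    median_diff = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(scores))) {
    a <- scores[k, prim]; b <- scores[k, met]
    res$median_diff[k] <- stats::median(b - a)
    res$p[k] <- .exact_two_sided_signed_rank(a, b)
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Site-enrichment test (one site versus all others)
#'
#' Two-sided Mann-Whitney rank-sum test per gene set comparing scores of the
#' target-site samples against all other samples, BH-adjusted across sets.
#'
#' @param scores sets x samples matrix.
#' @param site_labels character vector of site labels, one per score column.
#' @param target site label defining the first group (e.g. `"brain"`).
#' @return Data frame: `set`, `n_target`, `n_other`, `p`, `q`.
#' @export
site_enrichment_test <- function(scores, site_labels, target = "brain") {
  if (length(site_labels) != ncol(scores))
    stop("site_labels length does not match score columns")
  grp <- site_labels == target
  if (!any(grp) || all(grp))
    stop("both groups must be non-empty (target '", target, "')")
  res <- data.frame(set = rownames(scores), n_target = sum(grp),
                    n_other = sum(!grp), p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(scores))) {
    res$p[k] <- unname(suppressWarnings(
      stats::wilcox.test(scores[k, grp], scores[k, !grp],
                         alternative = "two.sided")$p.value))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Read / write expression matrices
#'
#' Tab-delimited genes x samples table: first column `gene`, remaining
#' columns one per sample.
#'
#' @param path file path.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in expression matrix ", path)
  m
}

#' @rdname read_expression_tsv
#' @param mat genes x samples matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
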