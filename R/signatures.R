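# Mutational-signature refitting with bootstrap exposure thresholding.
#
# A tumor catalog is modeled as a non-negative mixture of fixed reference
# signatures (96-channel probability vectors). Exposures are estimated by
# non-negative least squares; stability of each exposure is assessed by
# bootstrapping the mutation catalog, and unstable signatures are zeroed.

#' Read a reference signature matrix
#'
#' Expects a tab-delimited table with a `channel` column of the 96 canonical
#' labels and one column per signature. Columns are renormalized checked, not
#' silently: each signature must already sum to 1 within `tol`.
#'
#' @param path TSV path.
#' @param tol column-sum tolerance.
#' @return 96 x K numeric matrix (rows in canonical channel order, columns
#'   named by signature), validated by [validate_signatures()].
#' @export
read_signatures_tsv <- function(path, tol = 1e-8) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  if (!setequal(rownames(m), .SBS_CHANNELS))
    stop("signature table ", path, " does not cover the 96 canonical channels")
  m <- m[.SBS_CHANNELS, , drop = FALSE]
  validate_signatures(m, tol = tol)
  m
}

#' Validate a reference signature matrix
#'
#' @param refs 96 x K numeric matrix, rows in canonical channel order.
#' @param tol tolerance on column sums.
#' @return `refs`, invisibly; errors if invalid.
#' @export
validate_signatures <- function(refs, tol = 1e-8) {
  if (!is.matrix(refs) || nrow(refs) != 96L)
    stop("reference signatures must be a 96-row matrix")
  if (is.null(rownames(refs)) || !identical(rownames(refs), .SBS_CHANNELS))
    stop("signature rows must be the 96 canonical channels in canonical order")
  if (any(refs < 0)) stop("negative entries in signature matrix")
  cs <- colSums(refs)
  off <- abs(cs - 1) > tol
  if (any(off))
    stop("signature column(s) not summing to 1: ",
         paste(colnames(refs)[off], collapse = ", "))
  invisible(refs)
}

.check_catalog_alignment <- function(catalog, refs) {
  cn <- names(catalog)
  if (is.null(cn) || !identical(cn, rownames(refs)))
    stop("catalog channel order does not match reference signature rows")
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves `min ||counts - refs %*% e||_2` subject to `e >= 0`
#' (Lawson-Hanson NNLS). Exposures are in mutation-count units since the
#' reference columns sum to 1.
#'
#' @param catalog length-96 named count vector ([build_catalog()] output) in
#'   canonical channel order; total must be positive.
#' @param refs validated 96 x K reference matrix.
#' @return List with `exposures` (named length-K vector) and `residual`
#'   (Euclidean norm of the fit residual).
#' @export
fit_exposures <- function(catalog, refs) {
  validate_signatures(refs)
  counts <- as.numeric(catalog)
  names(counts) <- names(catalog)
  if (sum(counts) <= 0) stop("empty catalog: no mutations to fit")
  .check_catalog_alignment(catalog, refs)
  fit <- pracma::lsqnonneg(refs, counts)
  list(exposures = stats::setNames(fit$x, colnames(refs)),
       residual = sqrt(fit$resid.norm))
}

#' Deterministic child seed for a sample
#'
#' Derives a per-sample seed from a top-level seed and the sample identifier
#' so cohort results do not depend on sample processing order. The derived
#' seed stays below 2^31 - 1.
#'
#' @param seed integer top-level seed.
#' @param id character identifier.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435761 + h) %% 2147483647)
}

#' Bootstrap signature refitting with exposure thresholding
#'
#' Resamples the catalog `n_boot` times (multinomial over the 96 channels at
#' the observed total N, equivalent to resampling individual mutations with
#' replacement), refits each resample, and summarizes per signature:
#' the point estimate is the median exposure over bootstraps, and the
#' retention probability is the fraction of bootstraps in which the exposure
#' reaches `threshold_fraction * N` mutations. Signatures whose retention
#' probability falls below `retention_p` have their point estimate set to 0;
#' relative contributions are the surviving exposures renormalized to sum 1.
#'
#' @param catalog length-96 count vector, total > 0.
#' @param refs validated 96 x K reference matrix.
#' @param n_boot number of bootstrap iterations (>= 1); 100 by default.
#' @param threshold_fraction exposure threshold as a fraction of the sample's
#'   total mutation count (default 0.05, i.e. 5% of mutations).
#' @param retention_p minimum retention probability for a signature to
#'   survive thresholding (default 0.95).
#' @param seed integer seed for the bootstrap stream.
#' @return Object of class `signature_exposure`: list with `sample`,
#'   `exposures` (thresholded point estimates, counts),
#'   `relative_contribution` (sums to 1 when any exposure is nonzero),
#'   `retention_prob`, `raw_median`, `n_boot`, `threshold_fraction`,
#'   `retention_p`, `residual`.
#' @export
bootstrap_fit <- function(catalog, refs, n_boot = 100L,
                          threshold_fraction = 0.05, retention_p = 0.95,
                          seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be at least 1")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  point_fit <- fit_exposures(catalog, refs)  # validates catalog and alignment
  counts <- as.numeric(catalog)
  N <- sum(counts)
  K <- ncol(refs)
  boot <- matrix(0, n_boot, K, dimnames = list(NULL, colnames(refs)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p <- counts / N
  for (b in seq_len(n_boot)) {
    res <- as.numeric(stats::rmultinom(1L, size = N, prob = p))
    names(res) <- names(catalog)
    boot[b, ] <- fit_exposures(res, refs)$exposures
  }
  med <- apply(boot, 2, stats::median)
  retain_prob <- colMeans(boot >= threshold_fraction * N)
  exposures <- ifelse(retain_prob >= retention_p, med, 0)
  names(exposures) <- colnames(refs)
  rel <- if (sum(exposures) > 0) exposures / sum(exposures) else exposures
  structure(list(sample = attr(catalog, "sample"),
                 exposures = exposures,
                 relative_contribution = rel,
                 retention_prob = stats::setNames(retain_prob, colnames(refs)),
                 raw_median = stats::setNames(med, colnames(refs)),
                 n_boot = as.integer(n_boot),
                 threshold_fraction = threshold_fraction,
                 retention_p = retention_p,
                 residual = point_fit$residual),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat("Bootstrap signature exposure (", x$n_boot, " iterations, threshold ",
      format(100 * x$threshold_fraction), "% of mutations)\n", sep = "")
  if (!is.null(x$sample) && !is.na(x$sample)) cat("sample:", x$sample, "\n")
  kept <- x$exposures > 0
  if (!any(kept)) {
    cat("no signature retained\n")
  } else {
    df <- data.frame(exposure = round(x$exposures[kept], 1),
                     rel_contribution = round(x$relative_contribution[kept], 3),
                     retention_prob = round(x$retention_prob[kept], 3))
    print(df)
  }
  invisible(x)
}

#' @export
summary.signature_exposure <- function(object, ...) {
  data.frame(signature = names(object$exposures),
             exposure = unname(object$exposures),
             rel_contribution = unname(object$relative_contribution),
             retention_prob = unname(object$retention_prob),
             retained = unname(object$exposures > 0),
             row.names = NULL)
}

#' Call signature-positive status
#'
#' A sample is positive for a signature when that signature's relative
#' contribution strictly exceeds `cutoff` (0.9 by default, the benchmarked
#' cut-off for calling the HRD-associated breast signature).
#'
#' @param estimate `signature_exposure` object.
#' @param signature signature label present in the estimate.
#' @param cutoff strict lower bound on relative contribution.
#' @return Logical.
#' @export
call_signature_status <- function(estimate, signature, cutoff = 0.9) {
  rc <- estimate$relative_contribution
  if (!signature %in% names(rc))
    stop("unknown signature '", signature, "'")
  unname(rc[signature] > cutoff)
}

#' Signature gained in the metastasis
#'
#' Flags patients whose metastasis is signature-positive while the matched
#' primary is not.
#'
#' @param primary,met `signature_exposure` objects fitted against the same
#'   reference set.
#' @param signature signature label.
#' @param cutoff passed to [call_signature_status()].
#' @return Logical.
#' @export
gained_in_met <- function(primary, met, signature, cutoff = 0.9) {
  if (!identical(names(primary$relative_contribution),
                 names(met$relative_contribution)))
    stop("primary and metastasis estimates use different reference sets")
  call_signature_status(met, signature, cutoff) &&
    !call_signature_status(primary, signature, cutoff)
}

#' Write exposures as a long-format table
#'
#' @param estimates list of `signature_exposure` objects.
#' @param path output TSV.
#' @export
write_exposures_tsv <- function(estimates, path) {
  rows <- lapply(estimates, function(e) {
    data.frame(sample = e$sample, signature = names(e$exposures),
               exposure = unname(e$exposures),
               rel_contribution = unname(e$relative_contribution),
               retained = unname(e$exposures > 0), row.names = NULL)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# RNG bookkeeping: functions that seed internally must not disturb the
# caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
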