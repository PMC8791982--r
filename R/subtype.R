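# Nearest-centroid intrinsic subtype assignment.
#
# Each tumor is assigned to the intrinsic molecular subtype (LumA / LumB /
# Her2 / Basal / Normal in the standard predictor) whose reference expression
# centroid it correlates with most strongly by Spearman correlation over the
# genes shared between sample and centroid matrix. Spearman makes the call
# invariant to any strictly monotone per-sample transform of expression.

#' Read a centroid matrix
#'
#' Tab-delimited genes x subtypes table: first column `gene`, one column per
#' subtype.
#'
#' @param path file path.
#' @return Numeric matrix, genes x subtypes.
#' @export
read_centroids_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("duplicate subtype labels")
  m
}

#' @rdname read_centroids_tsv
#' @param centroids genes x subtypes matrix.
#' @export
write_centroids_tsv <- function(centroids, path) {
  df <- data.frame(gene = rownames(centroids), centroids, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Nearest-centroid subtype calls
#'
#' Per sample, computes Spearman correlation against every centroid over the
#' genes shared between the expression matrix and the centroid matrix (at
#' least 3 required) and assigns the subtype with maximal correlation. Ties
#' are broken deterministically by centroid column order. Calls may be
#' overridden per sample via `override` (e.g. a manual reassignment after
#' inspection of a borderline probability); overridden rows are flagged,
#' never silently replaced.
#'
#' @param mat genes x samples expression matrix (log scale).
#' @param centroids genes x subtypes centroid matrix.
#' @param override optional named character vector `sample -> subtype label`
#'   of manual call overrides.
#' @return Data frame with one row per sample: `sample`, `subtype`,
#'   `override` flag, and one `rho_<subtype>` column per centroid.
#' @export
call_subtypes <- function(mat, centroids, override = NULL) {
  shared <- intersect(rownames(mat), rownames(centroids))
  labels <- colnames(centroids)
  rows <- lapply(colnames(mat), function(s) {
    x <- mat[shared, s]
    usable <- shared[!is.na(x)]
    if (length(usable) < 3L)
      stop("fewer than 3 genes shared with centroids for sample ", s)
    rho <- vapply(labels, function(l)
      stats::cor(mat[usable, s], centroids[usable, l], method = "spearman"), 0)
    call <- labels[which.max(rho)]  # which.max: first maximum = declared order
    ovr <- !is.null(override) && s %in% names(override)
    if (ovr) {
      if (!override[[s]] %in% labels)
        stop("override for sample ", s, " names unknown subtype '",
             override[[s]], "'")
      call <- override[[s]]
    }
    out <- data.frame(sample = s, subtype = call, override = ovr,
                      stringsAsFactors = FALSE)
    for (l in labels) out[[paste0("rho_", l)]] <- unname(rho[l])
    out
  })
  do.call(rbind, rows)
}

#' Subtype-switching summary for a paired cohort
#'
#' Compares per-patient primary and metastasis subtype calls and summarizes
#' how many patients switched subtype, plus the full subtype-to-subtype
#' transition table (rows: primary call, columns: metastasis call).
#'
#' @param primary_calls,met_calls data frames from [call_subtypes()] (or any
#'   frames with `sample` and `subtype` columns).
#' @param pairing data frame with `patient`, `primary_sample`, `met_sample`.
#' @return List with `n_switched`, `n_total`, `fraction`, `switched`
#'   (named logical per patient) and `transitions` (contingency table).
#' @export
switching_summary <- function(primary_calls, met_calls, pairing) {
  need <- c("patient", "primary_sample", "met_sample")
  miss <- setdiff(need, names(pairing))
  if (length(miss)) stop("pairing missing column(s): ",
                         paste(miss, collapse = ", "))
  get_call <- function(calls, s, what) {
    i <- match(s, calls$sample)
    if (is.na(i)) stop("no subtype call for ", what, " sample ", s)
    calls$subtype[i]
  }
  prim <- vapply(pairing$primary_sample, get_call, "", calls = primary_calls,
                 what = "primary")
  met <- vapply(pairing$met_sample, get_call, "", calls = met_calls,
                what = "metastasis")
  switched <- stats::setNames(prim != met, pairing$patient)
  levels_all <- sort(unique(c(prim, met)))
  transitions <- table(factor(prim, levels = levels_all),
                       factor(met, levels = levels_all),
                       dnn = c("primary", "metastasis"))
  list(n_switched = sum(switched), n_total = length(switched),
       fraction = sum(switched) / length(switched),
       switched = switched, transitions = transitions)
}
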