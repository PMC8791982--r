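# Somatic variant parsing and 96-channel catalog construction.

#' Read somatic SNVs from a 5-column variant table
#'
#' Reads the package's tab-delimited variant dialect: columns `sample`,
#' `chrom`, `pos`, `sub` (as `"REF>ALT"`), `context`. An optional `coding`
#' column (0/1 or TRUE/FALSE) marks variants that count toward tumor
#' mutational burden; absent, all variants are treated as coding.
#'
#' @param path file path.
#' @return Data frame with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `context`, `coding`.
#' @export
read_variants_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "chrom", "pos", "sub", "context")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("variant table ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  sub <- strsplit(x$sub, ">", fixed = TRUE)
  bad <- vapply(sub, length, 0L) != 2L
  if (any(bad)) stop("malformed substitution field at row(s) ",
                     paste(which(bad), collapse = ", "))
  data.frame(
    sample = x$sample, chrom = x$chrom, pos = as.integer(x$pos),
    ref = toupper(vapply(sub, `[`, "", 1L)),
    alt = toupper(vapply(sub, `[`, "", 2L)),
    context = toupper(x$context),
    coding = if ("coding" %in% names(x)) as.logical(as.integer(x$coding)) else TRUE,
    stringsAsFactors = FALSE)
}

#' Read SNVs from a minimal VCF
#'
#' Parses CHROM, POS, REF, ALT and FILTER from an uncompressed VCF. Indels and
#' multi-allelic records are dropped (counted in the `skipped` attribute);
#' `pass_only = TRUE` additionally drops records whose FILTER is neither
#' `PASS` nor `.`.
#'
#' @param path VCF path.
#' @param sample sample identifier attached to every record.
#' @param pass_only drop non-PASS records.
#' @return Data frame as [read_variants_tsv()] but with `context = NA`
#'   (supply a FASTA to [build_catalog()] for lookup); attribute `skipped`
#'   holds counts of dropped records by reason.
#' @export
read_variants_vcf <- function(path, sample, pass_only = TRUE) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  skipped <- c(indel = 0L, multiallelic = 0L, non_pass = 0L)
  out <- list()
  for (l in ln) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) next
    ref <- toupper(f[4]); alt <- toupper(f[5])
    filt <- if (length(f) >= 7L) f[7] else "."
    if (grepl(",", alt, fixed = TRUE)) { skipped["multiallelic"] <- skipped["multiallelic"] + 1L; next }
    if (nchar(ref) != 1L || nchar(alt) != 1L) { skipped["indel"] <- skipped["indel"] + 1L; next }
    if (pass_only && !filt %in% c("PASS", ".")) { skipped["non_pass"] <- skipped["non_pass"] + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      sample = sample, chrom = f[1], pos = as.integer(f[2]),
      ref = ref, alt = alt, context = NA_character_, coding = TRUE,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), context = character(),
               coding = logical(), stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}

.context_from_fasta <- function(variants, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA context lookup")
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ctx <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    chr <- variants$chrom[i]
    if (!chr %in% names(genome))
      stop("chromosome '", chr, "' not present in FASTA ", fasta)
    p <- variants$pos[i]
    if (p < 2L || p > length(genome[[chr]]) - 1L)
      stop("variant at ", chr, ":", p, " too close to contig edge for context")
    ctx[i] <- toupper(as.character(Biostrings::subseq(genome[[chr]], p - 1L, p + 1L)))
  }
  ctx
}

#' Build a 96-channel mutation catalog for one sample
#'
#' Normalizes each admitted single-nucleotide substitution to the
#' pyrimidine strand and bins it into the canonical 96-channel catalog.
#' Records failing the SNV contract (indels, ref = alt, non-ACGT) are
#' rejected at parse time upstream; here missing contexts are looked up in
#' `fasta` when provided, and a context whose middle base contradicts the
#' recorded reference allele is an error.
#'
#' @param variants data frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `context` (NA allowed when `fasta` given). One sample only.
#' @param fasta optional FASTA path for trinucleotide context lookup.
#' @param filter_kataegis drop variants inside clustered-substitution runs
#'   (see [kataegis_flags()]) before binning.
#' @param max_dist,min_run kataegis run parameters, used only when filtering.
#' @return Object of class `mutation_catalog`: a named integer vector of
#'   length 96 with attributes `sample` and `n_filtered`.
#' @export
#' @examples
#' v <- data.frame(sample = "s1", chrom = "chr1", pos = c(100, 200, 300),
#'                 ref = "C", alt = "T", context = "ACA")
#' build_catalog(v)
build_catalog <- function(variants, fasta = NULL, filter_kataegis = FALSE,
                          max_dist = 1000, min_run = 6L) {
  counts <- stats::setNames(integer(96), .SBS_CHANNELS)
  n_filtered <- 0L
  if (nrow(variants) == 0L) {
    return(structure(counts, sample = NA_character_, n_filtered = 0L,
                     class = "mutation_catalog"))
  }
  if (length(unique(variants$sample)) > 1L)
    stop("build_catalog expects one sample per call; got ",
         paste(unique(variants$sample), collapse = ", "))
  if (filter_kataegis) {
    drop <- kataegis_flags(variants, max_dist = max_dist, min_run = min_run)
    n_filtered <- sum(drop)
    variants <- variants[!drop, , drop = FALSE]
  }
  missing_ctx <- is.na(variants$context) | variants$context == ""
  if (any(missing_ctx)) {
    if (is.null(fasta))
      stop("missing trinucleotide context for record(s) ",
           paste(which(missing_ctx), collapse = ", "),
           " and no reference FASTA supplied")
    variants$context[missing_ctx] <-
      .context_from_fasta(variants[missing_ctx, , drop = FALSE], fasta)
  }
  for (i in seq_len(nrow(variants))) {
    idx <- tryCatch(
      channel_index(variants$ref[i], variants$alt[i], variants$context[i]),
      error = function(e) stop("record ", i, " (", variants$chrom[i], ":",
                               variants$pos[i], "): ", conditionMessage(e),
                               call. = FALSE))
    counts[idx] <- counts[idx] + 1L
  }
  structure(counts, sample = variants$sample[1], n_filtered = n_filtered,
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("96-channel mutation catalog, sample:", attr(x, "sample"),
      "\n  total mutations:", sum(x),
      "\n  nonzero channels:", sum(x > 0), "\n")
  invisible(x)
}

#' Tumor mutational burden
#'
#' TMB is the number of coding somatic variants divided by the length of the
#' exome capture in megabases (50 Mb for a standard whole-exome capture).
#'
#' @param n_coding_variants non-negative count of coding variants.
#' @param capture_mb capture size in megabases; must be positive.
#' @return Mutations per megabase.
#' @export
#' @examples
#' compute_tmb(100, 50)  # 2 mutations/Mb
compute_tmb <- function(n_coding_variants, capture_mb = 50) {
  if (!is.numeric(capture_mb) || capture_mb <= 0)
    stop("capture_mb must be positive, got ", capture_mb)
  if (n_coding_variants < 0) stop("negative variant count")
  n_coding_variants / capture_mb
}

#' Write / read multi-sample catalog tables
#'
#' Catalogs are stored as a 96 x S tab-delimited table with channel labels as
#' row names and sample identifiers as column names.
#'
#' @param catalogs named list of `mutation_catalog` objects (or a 96 x S
#'   matrix with channel row names).
#' @param path output file.
#' @export
write_catalog_tsv <- function(catalogs, path) {
  m <- if (is.matrix(catalogs)) catalogs else
    do.call(cbind, lapply(catalogs, as.integer))
  if (!is.matrix(catalogs)) {
    rownames(m) <- .SBS_CHANNELS
    colnames(m) <- if (!is.null(names(catalogs))) names(catalogs) else
      vapply(catalogs, function(x) attr(x, "sample"), "")
  }
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_catalog_tsv
#' @return `read_catalog_tsv()`: a 96 x S integer matrix with channel row
#'   names, rows reordered to the canonical channel order.
#' @export
read_catalog_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  if (!setequal(rownames(m), .SBS_CHANNELS))
    stop("catalog table ", path, " does not contain the 96 canonical channels")
  m[.SBS_CHANNELS, , drop = FALSE]
}
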