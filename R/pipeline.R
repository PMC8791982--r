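# End-to-end cohort pipeline: catalogs -> signature refitting, scar scores,
# pathway scores and subtype calls, joined into one per-patient report.

.default_config <- function() {
  list(
    seed = 1L,
    capture_mb = 50,
    n_boot = 100L,
    threshold_fraction = 0.05,
    retention_p = 0.95,
    signature_cutoff = 0.9,
    hrd_cutoff = 42,
    smooth_mb = 3,
    loh_min_mb = 15,
    ntai_min_mb = 1,
    lst_min_seg_mb = 10,
    lst_max_gap_mb = 3,
    tau = 0.25,
    stages = c("signatures", "scars", "pathways", "subtypes"))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, .default_config()$stages)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  cfg
}

.read_manifest <- function(cohort_dir) {
  mf <- file.path(cohort_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", cohort_dir)
  jsonlite::read_json(mf, simplifyVector = TRUE)
}

#' Validate a cohort directory
#'
#' Checks the manifest, per-file schemas, primary/metastasis pairing
#' completeness and channel/gene-identifier consistency. Findings are
#' returned as a data frame with a `severity` column distinguishing
#' warnings from fatal problems.
#'
#' @param cohort_dir cohort directory (as written by [simulate_cohort()]).
#' @return Data frame with columns `severity` (`"fatal"`/`"warning"`),
#'   `stage`, `message`; zero rows means a clean cohort.
#' @export
validate_inputs <- function(cohort_dir) {
  findings <- data.frame(severity = character(), stage = character(),
                         message = character(), stringsAsFactors = FALSE)
  add <- function(severity, stage, message) {
    findings <<- rbind(findings, data.frame(
      severity = severity, stage = stage, message = message,
      stringsAsFactors = FALSE))
  }
  if (!dir.exists(cohort_dir)) stop("directory does not exist: ", cohort_dir)
  man <- tryCatch(.read_manifest(cohort_dir), error = function(e) {
    add("fatal", "manifest", conditionMessage(e)); NULL
  })
  if (is.null(man)) return(findings)
  paths <- file.path(cohort_dir, unlist(man$files))
  missing <- !file.exists(paths)
  for (p in paths[missing]) add("fatal", "manifest", paste("missing file:", p))
  if (any(missing)) return(findings)

  try_read <- function(stage, fn, path) {
    tryCatch(fn(path), error = function(e) {
      add("fatal", stage, paste0(basename(path), ": ", conditionMessage(e)))
      NULL
    })
  }
  f <- function(key) file.path(cohort_dir, man$files[[key]])
  refs <- try_read("signatures", read_signatures_tsv, f("signatures"))
  build <- try_read("build", read_build_tsv, f("build"))
  variants <- try_read("variants", read_variants_tsv, f("variants"))
  segments <- try_read("scars", read_segments_tsv, f("segments"))
  expr <- try_read("pathways", read_expression_tsv, f("expression"))
  meta <- try_read("pairing", function(p)
    utils::read.table(p, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE), f("samples"))
  sets <- try_read("pathways", read_gmt, f("sets"))
  cents <- try_read("subtypes", read_centroids_tsv, f("centroids"))

  if (!is.null(segments) && !is.null(build)) {
    unknown <- setdiff(unique(segments$chrom), build$chrom)
    if (length(unknown))
      add("fatal", "scars",
          paste("segment chromosome(s) not in build:",
                paste(unknown, collapse = ", ")))
  }
  if (!is.null(meta)) {
    pats <- unique(meta$patient)
    for (id in pats) {
      st <- meta$disease_status[meta$patient == id]
      if (sum(st == "primary") != 1L || sum(st == "metastasis") != 1L)
        add("fatal", "pairing",
            paste("patient", id, "lacks a complete primary/metastasis pair"))
    }
    if (!is.null(expr)) {
      lost <- setdiff(meta$sample, colnames(expr))
      for (s in lost)
        add("fatal", "pairing",
            paste("sample", s, "missing from the expression matrix"))
    }
  }
  if (!is.null(sets) && !is.null(expr)) {
    matched <- vapply(sets, function(s)
      sum(toupper(rownames(expr)) %in% toupper(s)), 0L)
    for (nm in names(matched)[matched < 2])
      add("warning", "pathways",
          paste("gene set", nm, "has fewer than 2 genes in the matrix"))
  }
  if (!is.null(cents) && !is.null(expr) &&
      length(intersect(rownames(cents), rownames(expr))) < 3L)
    add("fatal", "subtypes", "fewer than 3 centroid genes in the matrix")
  findings
}

#' Run the full HRD pipeline over a cohort directory
#'
#' Executes, in dependency order, catalog construction and tumor mutational
#' burden, bootstrap signature refitting with HRD-signature status calls,
#' genomic scar scoring with the paired scar test, pathway enrichment
#' scoring with the paired and site tests, and nearest-centroid subtype
#' calls with the switching summary. Stage outputs are written as TSV tables
#' plus a single `report.json`; the run is deterministic given
#' (inputs, config, seed), so a rerun writes byte-identical outputs.
#'
#' @param cohort_dir input directory (see [simulate_cohort()] for layout).
#' @param out_dir output directory, created if needed.
#' @param config list (or YAML file path) overriding the defaults:
#'   `seed`, `capture_mb` (50), `n_boot` (100), `threshold_fraction` (0.05),
#'   `retention_p` (0.95), `signature_cutoff` (0.9), `hrd_cutoff` (42),
#'   smoothing and scar thresholds, `tau` (0.25), and `stages`, a character
#'   subset of signatures/scars/pathways/subtypes.
#' @return Object of class `cohort_report` (invisibly): the per-patient and
#'   cohort-level result lists that were written to disk.
#' @export
run_pipeline <- function(cohort_dir, out_dir, config = list()) {
  cfg <- .load_config(config)
  findings <- validate_inputs(cohort_dir)
  fatal <- findings[findings$severity == "fatal", , drop = FALSE]
  if (nrow(fatal))
    stop("cohort validation failed:\n  ",
         paste(fatal$stage, fatal$message, sep = ": ", collapse = "\n  "))
  man <- .read_manifest(cohort_dir)
  f <- function(key) file.path(cohort_dir, man$files[[key]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  meta <- utils::read.table(f("samples"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  patients <- unique(meta$patient)
  sample_of <- function(id, status)
    meta$sample[meta$patient == id & meta$disease_status == status]
  log_counts <- list()
  report <- list(config = cfg[order(names(cfg))],
                 n_patients = length(patients))

  # --- catalogs + TMB (needed by the signatures stage) -------------------
  exposures <- NULL; tmb <- NULL; sig_status <- NULL
  if ("signatures" %in% cfg$stages) {
    refs <- read_signatures_tsv(f("signatures"))
    variants <- read_variants_tsv(f("variants"))
    hrd_sig <- man$hrd_signature
    if (is.null(hrd_sig)) hrd_sig <- colnames(refs)[ncol(refs)]
    catalogs <- lapply(split(variants, variants$sample), build_catalog)
    log_counts$variants_in <- nrow(variants)
    tmb <- vapply(split(variants, variants$sample), function(v)
      compute_tmb(sum(v$coding), cfg$capture_mb), 0)
    est <- lapply(names(catalogs), function(sid)
      bootstrap_fit(catalogs[[sid]], refs, n_boot = cfg$n_boot,
                    threshold_fraction = cfg$threshold_fraction,
                    retention_p = cfg$retention_p,
                    seed = derive_seed(cfg$seed, sid)))
    names(est) <- names(catalogs)
    exposures <- est
    sig_status <- lapply(patients, function(id) {
      ep <- est[[sample_of(id, "primary")]]
      em <- est[[sample_of(id, "metastasis")]]
      list(patient = id,
           primary = call_signature_status(ep, hrd_sig, cfg$signature_cutoff),
           metastasis = call_signature_status(em, hrd_sig,
                                              cfg$signature_cutoff),
           gained = gained_in_met(ep, em, hrd_sig, cfg$signature_cutoff))
    })
    names(sig_status) <- patients
    write_exposures_tsv(est, file.path(out_dir, "exposures.tsv"))
    report$hrd_signature <- hrd_sig
    report$tmb <- as.list(round(tmb, 6))
    report$signature_status <- sig_status
  }

  # --- genomic scars ------------------------------------------------------
  scars <- NULL
  if ("scars" %in% cfg$stages) {
    build <- read_build_tsv(f("build"))
    segments <- read_segments_tsv(f("segments"))
    log_counts$segments_in <- nrow(segments)
    scars <- score_scars(segments, build, min_len_mb = cfg$smooth_mb,
                         loh_min_mb = cfg$loh_min_mb,
                         ntai_min_mb = cfg$ntai_min_mb,
                         lst_min_seg_mb = cfg$lst_min_seg_mb,
                         lst_max_gap_mb = cfg$lst_max_gap_mb,
                         hrd_cutoff = cfg$hrd_cutoff)
    utils::write.table(scars, file.path(out_dir, "scars.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prim <- scars$combined[match(vapply(patients, sample_of, "",
                                        status = "primary"), scars$sample)]
    met <- scars$combined[match(vapply(patients, sample_of, "",
                                       status = "metastasis"), scars$sample)]
    p_scar <- paired_scar_test(prim, met, alternative = "greater")
    report$scars <- lapply(seq_len(nrow(scars)), function(i) as.list(scars[i, ]))
    report$scar_paired_test <- list(p = as.numeric(p_scar),
                                    statistic = attr(p_scar, "statistic"),
                                    alternative = "metastasis > primary")
  }

  # --- pathway scores -----------------------------------------------------
  pathway <- NULL
  if ("pathways" %in% cfg$stages) {
    expr <- read_expression_tsv(f("expression"))
    sets <- read_gmt(f("sets"))
    log_counts$genes_in <- nrow(expr)
    ss <- ssgsea_scores(expr, sets, tau = cfg$tau)
    gs <- gsva_scores(expr, sets)
    paired <- paired_pathway_test(gs, meta)
    site <- site_enrichment_test(ss, meta$site[match(colnames(ss),
                                                     meta$sample)],
                                 target = "brain")
    utils::write.table(data.frame(set = rownames(ss), ss, check.names = FALSE),
                       file.path(out_dir, "ssgsea_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(set = rownames(gs), gs, check.names = FALSE),
                       file.path(out_dir, "gsva_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(paired, file.path(out_dir, "pathway_paired_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(site, file.path(out_dir, "site_enrichment_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pathway <- list(paired = paired, site = site)
    report$pathway_paired_test <- lapply(seq_len(nrow(paired)), function(i)
      as.list(paired[i, ]))
    report$site_enrichment_test <- lapply(seq_len(nrow(site)), function(i)
      as.list(site[i, ]))
  }

  # --- subtypes -----------------------------------------------------------
  subtypes <- NULL
  if ("subtypes" %in% cfg$stages) {
    expr <- read_expression_tsv(f("expression"))
    cents <- read_centroids_tsv(f("centroids"))
    calls <- call_subtypes(expr, cents)
    utils::write.table(calls, file.path(out_dir, "subtype_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pairing <- data.frame(
      patient = patients,
      primary_sample = vapply(patients, sample_of, "", status = "primary"),
      met_sample = vapply(patients, sample_of, "", status = "metastasis"),
      stringsAsFactors = FALSE)
    sw <- switching_summary(calls, calls, pairing)
    subtypes <- list(calls = calls, switching = sw)
    report$subtype_calls <- as.list(stats::setNames(calls$subtype,
                                                    calls$sample))
    report$switching <- list(n_switched = sw$n_switched,
                             n_total = sw$n_total,
                             fraction = sw$fraction)
  }

  report$stage_counts <- log_counts
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- structure(list(report = report, exposures = exposures, tmb = tmb,
                        scars = scars, pathway = pathway,
                        subtypes = subtypes, out_dir = out_dir),
                   class = "cohort_report")
  invisible(out)
}

#' @export
print.cohort_report <- function(x, ...) {
  r <- x$report
  cat("Cohort HRD report:", r$n_patients, "patients\n")
  if (!is.null(r$signature_status)) {
    gained <- sum(vapply(r$signature_status, `[[`, TRUE, "gained"))
    pos <- sum(vapply(r$signature_status, `[[`, TRUE, "metastasis"))
    cat("  HRD signature (", r$hrd_signature, "): ", pos,
        " metastases positive, ", gained, " gained over primary\n", sep = "")
  }
  if (!is.null(x$scars)) {
    cat("  HR-deficient by scar score:", sum(x$scars$deficient), "of",
        nrow(x$scars), "samples; paired test p =",
        signif(r$scar_paired_test$p, 3), "\n")
  }
  if (!is.null(x$pathway))
    cat("  pathway sets tested:", nrow(x$pathway$paired), "\n")
  if (!is.null(r$switching))
    cat("  subtype switching:", r$switching$n_switched, "/",
        r$switching$n_total, "patients\n")
  invisible(x)
}
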