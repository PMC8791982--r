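# Synthetic paired-cohort generator with planted ground truth.
#
# Stands in for restricted patient data: every pipeline stage can be
# exercised against known truth. Mutation catalogs are drawn from known
# signature mixtures; copy-number profiles are laid out constructively so
# the scar scorers recover exactly the planted (LOH, TAI, LST) counts;
# expression matrices carry a planted additive shift on a named gene set in
# the metastasis arm plus centroid-consistent subtype profiles.

#' Synthetic reference signatures
#'
#' Builds a 96 x K column-stochastic signature matrix with sparse,
#' near-orthogonal columns: each signature concentrates 90% of its mass on
#' its own block of 16 channels (Dirichlet-like weights) over a 10% uniform
#' background, keeping pairwise cosine similarity low (< 0.3) so recovery
#' experiments are well conditioned. Published signature files in the same
#' TSV layout load through [read_signatures_tsv()] instead.
#'
#' @param n_sig number of signatures (2..6).
#' @param seed integer seed.
#' @return Validated 96 x K matrix, columns `BreastA`, `BreastB`, ...
#' @export
synthetic_signatures <- function(n_sig = 6L, seed = 20260901L) {
  if (n_sig < 2L || n_sig > 6L) stop("n_sig must be between 2 and 6")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m <- matrix(0.1 / 96, 96, n_sig,
              dimnames = list(.SBS_CHANNELS,
                              paste0("Breast", LETTERS[seq_len(n_sig)])))
  for (k in seq_len(n_sig)) {
    block <- (k - 1L) * 16L + 1:16
    w <- stats::rgamma(16, shape = 0.7)
    m[block, k] <- m[block, k] + 0.9 * w / sum(w)
  }
  m <- sweep(m, 2, colSums(m), "/")
  validate_signatures(m)
  m
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws `n_mutations` channel assignments from the mixture distribution
#' `refs %*% mixture` (multinomial).
#'
#' @param mixture named non-negative fractions summing to 1; names must be
#'   reference signature names.
#' @param n_mutations total mutation count.
#' @param refs validated reference matrix.
#' @param seed integer seed.
#' @param sample_id identifier attached to the catalog.
#' @return `mutation_catalog` object with total `n_mutations`.
#' @export
simulate_catalog <- function(mixture, n_mutations, refs, seed,
                             sample_id = "synthetic") {
  unknown <- setdiff(names(mixture), colnames(refs))
  if (length(unknown))
    stop("unknown signature(s) in mixture: ", paste(unknown, collapse = ", "))
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-9)
    stop("mixture fractions must be non-negative and sum to 1")
  p <- as.numeric(refs[, names(mixture), drop = FALSE] %*% mixture)
  counts <- stats::setNames(integer(96), .SBS_CHANNELS)
  if (n_mutations > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    counts[] <- as.integer(stats::rmultinom(1L, n_mutations, p))
  }
  structure(counts, sample = sample_id, n_filtered = 0L,
            class = "mutation_catalog")
}

#' Expand a catalog into a synthetic variant table
#'
#' Emits one variant row per counted mutation, with the channel's reference
#' allele, alternate allele and pyrimidine-strand context, at synthetic
#' positions spaced widely apart on one chromosome. Round-tripping through
#' [build_catalog()] reproduces the catalog exactly.
#'
#' @param catalog `mutation_catalog`.
#' @param chrom chromosome name used for all synthetic positions.
#' @return Variant data frame in the [read_variants_tsv()] layout.
#' @export
catalog_to_variants <- function(catalog, chrom = "chr1") {
  n <- sum(catalog)
  if (n == 0L)
    return(data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      context = character(), coding = logical(),
                      stringsAsFactors = FALSE))
  idx <- rep(seq_len(96), as.integer(catalog))
  lab <- .SBS_CHANNELS[idx]
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  data.frame(sample = attr(catalog, "sample"), chrom = chrom,
             pos = 10000L + 10000L * seq_len(n), ref = ref, alt = alt,
             context = ctx, coding = TRUE, stringsAsFactors = FALSE)
}

# Event space requirements (Mb) used by the constructive layout.
.EVT <- list(loh_len = 20, tai_len = 20, lst_len = 12, gap = 5)

#' Constructively simulate a segment profile with planted scar counts
#'
#' Lays out exactly `planted["loh"]` LOH events (interior 20-Mb copy-neutral
#' LOH blocks), `planted["tai"]` telomeric allelic-imbalance events (20-Mb
#' imbalanced blocks abutting a telomere) and `planted["lst"]` large state
#' transitions (abutting 12-Mb balanced segments in different states), each
#' engineered to satisfy exactly one scorer predicate and violate the
#' others; all events are isolated by >3-Mb gaps so no incidental breakpoint
#' is counted, and the remaining genome is emitted as balanced diploid
#' filler. Scoring the result recovers the planted counts exactly.
#'
#' @param build genome build with enough arm capacity; infeasible counts are
#'   an error stating the capacity.
#' @param planted named integer vector `c(loh=, tai=, lst=)`.
#' @param seed integer seed (shuffles arm assignment only; counts are exact).
#' @param sample_id sample identifier.
#' @return Segment data frame ([validate_segments()] layout).
#' @export
simulate_segments <- function(build, planted, seed = 1L,
                              sample_id = "synthetic") {
  validate_build(build)
  planted <- planted[c("loh", "tai", "lst")]
  if (anyNA(planted) || any(planted < 0))
    stop("planted must be a named non-negative vector c(loh=, tai=, lst=)")
  arms <- chrom_arms(build)
  arms <- arms[!arms$chrom %in% SEX_CHROMS, , drop = FALSE]
  mb <- MB
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  arm_order <- sample(nrow(arms))
  if (planted["tai"] > nrow(arms))
    stop("infeasible planted counts: ", planted["tai"],
         " TAI events but only ", nrow(arms), " telomeric arm ends")
  tai_arms <- arm_order[seq_len(planted["tai"])]
  # free interior interval per arm, after telomere margins / TAI blocks
  lo <- numeric(nrow(arms)); hi <- numeric(nrow(arms))
  segs <- list()
  emit <- function(start, end, total, minor) {
    segs[[length(segs) + 1L]] <<- data.frame(
      sample = sample_id, chrom = NA_character_, start = start, end = end,
      total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)
    length(segs)
  }
  for (i in seq_len(nrow(arms))) {
    is_p <- arms$arm[i] == "p"
    lo[i] <- arms$start[i]; hi[i] <- arms$end[i]
    has_tai <- i %in% tai_arms
    if (has_tai) {
      if (is_p) {
        j <- emit(arms$start[i], arms$start[i] + .EVT$tai_len * mb - 1, 3L, 1L)
        segs[[j]]$chrom <- arms$chrom[i]
        lo[i] <- arms$start[i] + (.EVT$tai_len + .EVT$gap) * mb
      } else {
        j <- emit(arms$end[i] - .EVT$tai_len * mb + 1, arms$end[i], 3L, 1L)
        segs[[j]]$chrom <- arms$chrom[i]
        hi[i] <- arms$end[i] - (.EVT$tai_len + .EVT$gap) * mb
      }
    } else {
      # keep interior events off the telomere
      if (is_p) lo[i] <- arms$start[i] + .EVT$gap * mb
      else hi[i] <- arms$end[i] - .EVT$gap * mb
    }
  }
  place <- function(kind, arm_i) {
    need <- switch(kind, loh = .EVT$loh_len, lst = 2 * .EVT$lst_len) * mb
    if (hi[arm_i] - lo[arm_i] + 1 < need) return(FALSE)
    s <- lo[arm_i]
    if (kind == "loh") {
      j <- emit(s, s + .EVT$loh_len * mb - 1, 2L, 0L)
      segs[[j]]$chrom <<- arms$chrom[arm_i]
    } else {
      j <- emit(s, s + .EVT$lst_len * mb - 1, 2L, 1L)
      segs[[j]]$chrom <<- arms$chrom[arm_i]
      j <- emit(s + .EVT$lst_len * mb, s + 2 * .EVT$lst_len * mb - 1, 4L, 2L)
      segs[[j]]$chrom <<- arms$chrom[arm_i]
    }
    lo[arm_i] <<- s + need + .EVT$gap * mb
    TRUE
  }
  queue <- c(rep("loh", planted["loh"]), rep("lst", planted["lst"]))
  cursor <- 1L
  for (kind in queue) {
    placed <- FALSE
    for (tries in seq_len(nrow(arms))) {
      arm_i <- arm_order[(cursor - 1L) %% nrow(arms) + 1L]
      cursor <- cursor + 1L
      if (place(kind, arm_i)) { placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible planted counts: no arm has ",
           switch(kind, loh = .EVT$loh_len, lst = 2 * .EVT$lst_len),
           " Mb of free interior left for a ", toupper(kind), " event")
  }
  # balanced diploid filler in the remaining interior of every arm
  for (i in seq_len(nrow(arms))) {
    if (hi[i] - lo[i] + 1 >= 5 * mb) {
      j <- emit(lo[i], hi[i], 2L, 1L)
      segs[[j]]$chrom <- arms$chrom[i]
    }
  }
  out <- do.call(rbind, segs)
  out <- out[order(match(out$chrom, build$chrom), out$start), , drop = FALSE]
  out$start <- as.numeric(out$start); out$end <- as.numeric(out$end)
  rownames(out) <- NULL
  validate_segments(out)
  out
}

#' Simulate a paired expression cohort with a planted pathway shift
#'
#' Expression for gene g, patient i, arm a (0 = primary, 1 = metastasis) is
#' `mu_g + b_i + a * delta * 1[g in target_set] + N(0, sigma_g)` with
#' per-gene baselines `mu_g ~ N(baseline_mean, baseline_sd)` and patient
#' random effects `b_i ~ N(0, patient_sd)` shared by both arms. Values are
#' on the log2 scale.
#'
#' @param n_patients number of primary/metastasis pairs.
#' @param genes character vector of gene identifiers.
#' @param target_set character vector (subset of `genes`) receiving the
#'   metastasis-arm shift.
#' @param delta additive shift in units of `sigma_g` SDs (log2 scale).
#' @param sigma_g residual SD per observation.
#' @param patient_sd SD of the shared patient effect.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param seed integer seed.
#' @return List with `mat` (genes x 2*n_patients matrix) and `meta`
#'   (data frame `sample`, `patient`, `disease_status`, `site`).
#' @export
simulate_expression_cohort <- function(n_patients, genes, target_set,
                                       delta = 1, sigma_g = 1,
                                       patient_sd = 0.5, baseline_mean = 6,
                                       baseline_sd = 2, seed = 1L) {
  if (!all(target_set %in% genes))
    stop("target_set contains genes absent from `genes`")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  G <- length(genes)
  mu <- stats::rnorm(G, baseline_mean, baseline_sd)
  b <- stats::rnorm(n_patients, 0, patient_sd)
  pat <- sprintf("P%02d", seq_len(n_patients))
  samples <- c(paste0(pat, "_prim"), paste0(pat, "_met"))
  mat <- matrix(0, G, 2L * n_patients, dimnames = list(genes, samples))
  shift <- as.numeric(genes %in% target_set) * delta * sigma_g
  for (i in seq_len(n_patients)) {
    mat[, i] <- mu + b[i] + stats::rnorm(G, 0, sigma_g)
    mat[, n_patients + i] <- mu + b[i] + shift + stats::rnorm(G, 0, sigma_g)
  }
  meta <- data.frame(
    sample = samples,
    patient = c(pat, pat),
    disease_status = rep(c("primary", "metastasis"), each = n_patients),
    site = rep(c("breast", "brain"), each = n_patients),
    stringsAsFactors = FALSE)
  list(mat = mat, meta = meta)
}

#' Synthetic subtype centroids
#'
#' Random genes x subtypes centroid matrix for the nearest-centroid
#' classifier; a stand-in for published centroid files (which load through
#' [read_centroids_tsv()]).
#'
#' @param n_genes number of centroid genes.
#' @param subtypes subtype labels.
#' @param seed integer seed.
#' @return genes x subtypes matrix, genes named `ctg001`, ...
#' @export
synthetic_centroids <- function(n_genes = 40L,
                                subtypes = c("LumA", "LumB", "Her2",
                                             "Basal", "Normal"),
                                seed = 20260902L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * length(subtypes)), n_genes,
              dimnames = list(sprintf("ctg%03d", seq_len(n_genes)), subtypes))
  m
}

#' Centroid-consistent expression profiles
#'
#' Emits, for each requested subtype label, a noisy copy of that subtype's
#' centroid column (additive Gaussian noise), the generative model under
#' which nearest-centroid Spearman assignment should recover the label.
#'
#' @param centroids genes x subtypes matrix.
#' @param labels character vector of true subtype labels, one per sample.
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @param sample_names optional column names (default `S001`, ...).
#' @return genes x samples matrix.
#' @export
centroid_profiles <- function(centroids, labels, noise_sd = 0.3, seed = 1L,
                              sample_names = NULL) {
  if (!all(labels %in% colnames(centroids)))
    stop("labels contain unknown subtypes")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(labels)
  if (is.null(sample_names)) sample_names <- sprintf("S%03d", seq_len(n))
  m <- matrix(0, nrow(centroids), n,
              dimnames = list(rownames(centroids), sample_names))
  for (i in seq_len(n))
    m[, i] <- centroids[, labels[i]] + stats::rnorm(nrow(centroids), 0, noise_sd)
  m
}

#' Generate and write a complete synthetic cohort
#'
#' Emits every input the pipeline reads into `dir`: reference signatures,
#' per-sample variant tables expanded from simulated catalogs, planted
#' segment profiles, a paired expression matrix (DNA-repair shift plus
#' centroid-consistent subtype rows), gene sets, centroids, the genome
#' build, sample metadata, a `manifest.json` and a `truth.json` recording
#' all planted ground truth (the pipeline never reads the truth file).
#'
#' Defaults emulate the statistical structure of a paired breast
#' primary / brain-metastasis cohort: roughly half the patients acquire a
#' dominant (95%) HRD signature and an HR-deficient scar profile
#' (20, 12, 11; combined 43) in the metastasis while primaries stay scar-low
#' (5, 3, 2; combined 10); metastases carry a +1 SD shift on the HR gene
#' set; about a quarter of patients switch intrinsic subtype.
#'
#' @param dir output directory (created if missing).
#' @param n_patients number of pairs.
#' @param seed top-level seed; all per-sample streams derive from it.
#' @param n_mutations_mean,n_mutations_size negative-binomial mutation-count
#'   distribution per sample.
#' @param hrd_fraction fraction of patients whose metastasis is HRD.
#' @param prof_scars,def_scars planted (loh, tai, lst) for HR-proficient and
#'   HR-deficient profiles.
#' @param scar_jitter apply Poisson jitter around the planted counts.
#' @param delta metastasis-arm shift on the HR set, in residual SDs.
#' @param n_genes number of background/pathway genes.
#' @param switch_fraction fraction of patients switching subtype.
#' @return Invisibly, the parsed manifest list.
#' @export
simulate_cohort <- function(dir, n_patients = 10L, seed = 1L,
                            n_mutations_mean = 500, n_mutations_size = 5,
                            hrd_fraction = 0.5,
                            prof_scars = c(loh = 5, tai = 3, lst = 2),
                            def_scars = c(loh = 20, tai = 12, lst = 11),
                            scar_jitter = FALSE,
                            delta = 1, n_genes = 300,
                            switch_fraction = 0.27) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- synthetic_signatures(n_sig = 6L)
  hrd_sig <- colnames(refs)[ncol(refs)]
  build <- toy_genome_build(n_chrom = 22L, chrom_mb = 150,
                            cen_start_mb = 70, cen_end_mb = 75)
  pat <- sprintf("P%02d", seq_len(n_patients))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(derive_seed(seed, "cohort-design"))
  n_hrd <- round(hrd_fraction * n_patients)
  hrd_pos <- pat %in% sample(pat, n_hrd)
  base_mix <- stats::setNames(c(0.6, 0.4, 0, 0, 0, 0), colnames(refs))
  hrd_mix <- stats::setNames(c(0.03, 0.02, 0, 0, 0, 0.95), colnames(refs))

  variants <- list(); segments <- list()
  truth_samples <- list()
  for (i in seq_len(n_patients)) {
    for (arm in c("prim", "met")) {
      sid <- paste0(pat[i], "_", arm)
      s_seed <- derive_seed(seed, sid)
      mix <- if (arm == "met" && hrd_pos[i]) hrd_mix else base_mix
      set.seed(derive_seed(seed, paste0(sid, "-n")))
      n_mut <- stats::rnbinom(1, size = n_mutations_size,
                              mu = n_mutations_mean) + 50L
      cat96 <- simulate_catalog(mix, n_mut, refs, seed = s_seed,
                                sample_id = sid)
      variants[[sid]] <- catalog_to_variants(cat96)
      planted <- if (arm == "met" && hrd_pos[i]) def_scars else prof_scars
      if (scar_jitter) {
        set.seed(derive_seed(seed, paste0(sid, "-jitter")))
        planted <- stats::setNames(stats::rpois(3, planted), names(planted))
      }
      segments[[sid]] <- simulate_segments(build, planted, seed = s_seed,
                                           sample_id = sid)
      truth_samples[[sid]] <- list(
        patient = pat[i], arm = arm,
        mixture = as.list(mix[mix > 0]),
        hrd_signature_positive = (arm == "met" && hrd_pos[i]),
        n_mutations = n_mut,
        planted_scars = as.list(planted),
        combined = unname(sum(planted)))
    }
  }

  genes <- sprintf("gene%04d", seq_len(n_genes))
  sets <- list(HR = genes[1:25], MMR = genes[26:45], BER = genes[46:65],
               NHEJ = genes[66:80])
  expr <- simulate_expression_cohort(
    n_patients, genes, target_set = sets$HR, delta = delta,
    seed = derive_seed(seed, "expression"))
  # centroid-consistent subtype rows appended to the expression matrix
  centroids <- synthetic_centroids()
  subtypes <- colnames(centroids)
  set.seed(derive_seed(seed, "subtypes"))
  prim_label <- sample(subtypes, n_patients, replace = TRUE)
  met_label <- prim_label
  n_switch <- round(switch_fraction * n_patients)
  if (n_switch > 0) {
    sw <- sample(seq_len(n_patients), n_switch)
    for (i in sw)
      met_label[i] <- sample(setdiff(subtypes, prim_label[i]), 1)
  }
  labels <- c(prim_label, met_label)  # matches expr column order
  sub_rows <- centroid_profiles(centroids, labels,
                                seed = derive_seed(seed, "centroid-noise"),
                                sample_names = colnames(expr$mat))
  mat <- rbind(expr$mat, sub_rows)

  # write everything
  write_signatures <- function(m, path) {
    df <- data.frame(channel = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_signatures(refs, file.path(dir, "signatures.tsv"))
  write_build_tsv(build, file.path(dir, "build.tsv"))
  all_var <- do.call(rbind, variants)
  utils::write.table(
    data.frame(sample = all_var$sample, chrom = all_var$chrom,
               pos = all_var$pos, sub = paste0(all_var$ref, ">", all_var$alt),
               context = all_var$context, coding = as.integer(all_var$coding)),
    file.path(dir, "variants.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_segments_tsv(do.call(rbind, segments), file.path(dir, "segments.tsv"))
  write_expression_tsv(mat, file.path(dir, "expression.tsv"))
  utils::write.table(expr$meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(sets, file.path(dir, "sets.gmt"))
  write_centroids_tsv(centroids, file.path(dir, "centroids.tsv"))

  manifest <- list(
    n_patients = n_patients, seed = seed, hrd_signature = hrd_sig,
    target_set = "HR",
    files = list(signatures = "signatures.tsv", build = "build.tsv",
                 variants = "variants.tsv", segments = "segments.tsv",
                 expression = "expression.tsv", samples = "samples.tsv",
                 sets = "sets.gmt", centroids = "centroids.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  truth <- list(samples = truth_samples, delta = delta,
                hrd_signature = hrd_sig,
                primary_subtype = as.list(stats::setNames(prim_label, pat)),
                metastasis_subtype = as.list(stats::setNames(met_label, pat)),
                n_switched = sum(prim_label != met_label))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
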