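# Independent oracle implementations, coded directly from the written
# definitions of each statistic. They deliberately use naive loops and never
# share code with the package internals.

# ---- genomic scar predicates, evaluated segment by segment ----------------

oracle_loh <- function(seg, build, min_mb = 15) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$chrom[i] %in% c("chrX", "chrY", "X", "Y")) next
    row <- build[build$chrom == seg$chrom[i], ]
    is_loh <- seg$minor_cn[i] == 0 && seg$total_cn[i] >= 1
    long_enough <- (seg$end[i] - seg$start[i] + 1) >= min_mb * 1e6
    whole_chrom <- seg$start[i] == 1 && seg$end[i] == row$length
    if (is_loh && long_enough && !whole_chrom) n <- n + 1L
  }
  n
}

oracle_ntai <- function(seg, build, min_mb = 1) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$chrom[i] %in% c("chrX", "chrY", "X", "Y")) next
    row <- build[build$chrom == seg$chrom[i], ]
    ai <- seg$minor_cn[i] != seg$total_cn[i] - seg$minor_cn[i]
    telomeric <- seg$start[i] == 1 || seg$end[i] == row$length
    crosses_cen <- seg$start[i] <= row$cen_start && seg$end[i] >= row$cen_end
    long_enough <- (seg$end[i] - seg$start[i] + 1) >= min_mb * 1e6
    if (ai && telomeric && !crosses_cen && long_enough) n <- n + 1L
  }
  n
}

oracle_lst <- function(seg, build, min_seg_mb = 10, max_gap_mb = 3) {
  seg <- seg[!seg$chrom %in% c("chrX", "chrY", "X", "Y"), , drop = FALSE]
  n <- 0L
  for (ci in seq_len(nrow(build))) {
    row <- build[ci, ]
    for (arm in list(c(1, row$cen_start - 1), c(row$cen_end + 1, row$length))) {
      keep <- seg$chrom == row$chrom & seg$start <= arm[2] & seg$end >= arm[1]
      s <- seg[keep, , drop = FALSE]
      if (nrow(s) < 2L) next
      s$start <- pmax(s$start, arm[1]); s$end <- pmin(s$end, arm[2])
      s <- s[order(s$start), ]
      for (i in 1:(nrow(s) - 1L)) {
        len_a <- s$end[i] - s$start[i] + 1
        len_b <- s$end[i + 1] - s$start[i + 1] + 1
        gap <- s$start[i + 1] - s$end[i] - 1
        differ <- s$total_cn[i] != s$total_cn[i + 1] ||
          s$minor_cn[i] != s$minor_cn[i + 1]
        if (differ && len_a >= min_seg_mb * 1e6 && len_b >= min_seg_mb * 1e6 &&
            gap < max_gap_mb * 1e6) n <- n + 1L
      }
    }
  }
  n
}

# random segment profile on a build: random tiling with occasional gaps and
# random allele-specific states (for oracle-equivalence sweeps)
random_genome <- function(build, seed, sample_id = "rg") {
  set.seed(seed)
  out <- list()
  for (ci in seq_len(nrow(build))) {
    len <- build$length[ci]
    pos <- 1
    while (pos < len) {
      seglen <- sample(c(2e6, 5e6, 9e6, 12e6, 18e6, 25e6, 40e6), 1)
      end <- min(pos + seglen - 1, len)
      total <- sample(0:4, 1)
      minor <- if (total == 0) 0L else sample(0:(total %/% 2), 1)
      out[[length(out) + 1L]] <- data.frame(
        sample = sample_id, chrom = build$chrom[ci], start = pos, end = end,
        total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)
      gap <- sample(c(0, 0, 0, 1e6, 4e6), 1)
      pos <- end + 1 + gap
    }
  }
  do.call(rbind, out)
}

# ---- exact nonparametric tests by full enumeration ------------------------

# Wilcoxon signed-rank: enumerate all 2^n sign assignments of |d| ranks.
oracle_signed_rank <- function(a, b, alternative = "two.sided") {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  ge <- mean(w_all >= w_obs)
  le <- mean(w_all <= w_obs)
  switch(alternative,
         greater = ge, less = le,
         two.sided = min(2 * min(ge, le), 1))
}

# Mann-Whitney rank-sum: enumerate all group labelings.
oracle_rank_sum <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(id) sum(r[id]))
  ge <- mean(w_all >= w_obs)
  le <- mean(w_all <= w_obs)
  switch(alternative,
         greater = ge, less = le,
         two.sided = min(2 * min(ge, le), 1))
}

# ---- enrichment scores, step-by-step from the definitions -----------------

oracle_ssgsea_one <- function(x, set_genes, tau = 0.25) {
  # x: named expression vector for one sample
  N <- length(x)
  ord <- names(x)[order(x, decreasing = TRUE)]
  w <- (N:1) ^ tau
  inset <- ord %in% set_genes
  score <- 0
  cum_in <- 0; cum_out <- 0
  sum_w_in <- sum(w[inset]); n_out <- sum(!inset)
  for (i in seq_len(N)) {
    if (inset[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    score <- score + (cum_in / sum_w_in - cum_out / n_out)
  }
  score
}

oracle_gsva <- function(mat, set_genes, bw_factor = 4) {
  N <- nrow(mat); S <- ncol(mat)
  z <- mat * 0
  for (g in seq_len(N)) {
    h <- sd(mat[g, ]) / bw_factor
    if (!is.finite(h) || h <= 0) h <- 1e-8
    for (j in seq_len(S)) {
      acc <- 0
      for (k in seq_len(S)) acc <- acc + pnorm((mat[g, j] - mat[g, k]) / h)
      z[g, j] <- acc / S
    }
  }
  out <- numeric(S)
  for (j in seq_len(S)) {
    ord <- order(z[, j], decreasing = TRUE)
    w <- abs(N / 2 - seq_len(N) + 0.5)
    inset <- rownames(mat)[ord] %in% set_genes
    up <- w / sum(w[inset]); down <- 1 / (N - sum(inset))
    v <- 0; vmax <- 0; vmin <- 0
    for (i in seq_len(N)) {
      v <- v + if (inset[i]) up[i] else -down
      vmax <- max(vmax, v); vmin <- min(vmin, v)
    }
    out[j] <- vmax + vmin
  }
  names(out) <- colnames(mat)
  out
}

# ---- NNLS objective on a dense 2-signature grid ---------------------------

oracle_nnls_grid <- function(counts, m2, e_max, step) {
  best <- c(NA, NA); best_val <- Inf
  for (e1 in seq(0, e_max, by = step)) {
    for (e2 in seq(0, e_max, by = step)) {
      r <- counts - m2 %*% c(e1, e2)
      v <- sum(r^2)
      if (v < best_val) { best_val <- v; best <- c(e1, e2) }
    }
  }
  list(exposures = best, objective = best_val)
}

# convenience: pyrimidine-context variant for a given channel label
variant_for_channel <- function(label, strand = c("pyr", "pur"), sample = "s") {
  strand <- match.arg(strand)
  ref <- substr(label, 3, 3); alt <- substr(label, 5, 5)
  ctx <- paste0(substr(label, 1, 1), ref, substr(label, 7, 7))
  if (strand == "pur") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ctx <- paste(rev(comp[strsplit(ctx, "")[[1]]]), collapse = "")
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  data.frame(sample = sample, chrom = "chr1", pos = 1000L, ref = ref,
             alt = alt, context = ctx, coding = TRUE, stringsAsFactors = FALSE)
}
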