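make_mat <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc, 6, 2), nr, nc,
         dimnames = list(sprintf("g%02d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

test_that("GMT files round-trip", {
  sets <- list(HR = c("BRCA1", "BRCA2", "RAD51"), MMR = c("MLH1", "MSH2"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})

test_that("ssGSEA matches the step-by-step running-sum oracle", {
  m <- make_mat(5, 3, seed = 2)
  sets <- list(top2 = names(sort(m[, 1], decreasing = TRUE))[1:2],
               mix = c("g01", "g04"))
  sc <- ssgsea_scores(m, sets, tau = 0.25, normalize = FALSE)
  for (j in 1:3) {
    for (k in names(sets)) {
      expect_equal(sc[k, j], oracle_ssgsea_one(m[, j], sets[[k]], tau = 0.25),
                   tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA with tau = 0 reduces to the classical KS running sum", {
  m <- make_mat(8, 2, seed = 3)
  set_genes <- c("g02", "g05", "g07")
  sc <- ssgsea_scores(m, list(s = set_genes), tau = 0, normalize = FALSE)
  for (j in 1:2) {
    ord <- names(sort(m[, j], decreasing = TRUE))
    inset <- ord %in% set_genes
    ks_sum <- sum(cumsum(inset) / sum(inset) - cumsum(!inset) / sum(!inset))
    expect_equal(sc["s", j], ks_sum, tolerance = 1e-12)
  }
})

test_that("ssGSEA is rank-based: monotone transforms and identical columns", {
  m <- make_mat(20, 4, seed = 4)
  m[, 2] <- m[, 1]  # duplicate sample
  sets <- list(a = c("g01", "g03", "g09"), b = c("g10", "g12"))
  sc <- ssgsea_scores(m, sets, normalize = FALSE)
  expect_equal(sc[, 1], sc[, 2], ignore_attr = TRUE)
  m2 <- m
  m2[, 3] <- exp(m2[, 3] / 2) + 5   # strictly increasing transform
  sc2 <- ssgsea_scores(m2, sets, normalize = FALSE)
  expect_equal(sc[, 3], sc2[, 3], ignore_attr = TRUE)
})

test_that("ssGSEA is invariant to gene-row and sample-column order", {
  m <- make_mat(15, 3, seed = 5)
  sets <- list(a = c("g02", "g07", "g11"))
  sc <- ssgsea_scores(m, sets)
  set.seed(6)
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  sc_perm <- ssgsea_scores(perm, sets)
  expect_equal(sc_perm[, colnames(sc)], sc, ignore_attr = TRUE)
})

test_that("gene sets with fewer than 2 matched genes are dropped, not scored", {
  m <- make_mat(10, 3)
  expect_warning(sc <- ssgsea_scores(m, list(ok = c("g01", "g02"),
                                             tiny = "g03",
                                             alien = c("x", "y"))),
                 "dropping gene set")
  expect_equal(rownames(sc), "ok")
  expect_error(ssgsea_scores(m, list(alien = c("x", "y"))), "no gene set")
})

test_that("GSVA matches the kernel + random-walk oracle and stays in [-1, 1]", {
  m <- make_mat(6, 4, seed = 7)
  set_genes <- c("g01", "g02", "g04")
  sc <- gsva_scores(m, list(s = set_genes))
  oracle <- oracle_gsva(m, set_genes)
  expect_equal(sc["s", ], oracle, tolerance = 1e-9)
  big <- make_mat(40, 8, seed = 8)
  sc2 <- gsva_scores(big, list(a = sprintf("g%02d", 1:6),
                               b = sprintf("g%02d", 30:40)))
  expect_true(all(sc2 >= -1 & sc2 <= 1))
})

test_that("GSVA signs follow within-sample relative enrichment", {
  # scores are relative to the cohort: set genes spiking in sample 1 rank at
  # the top of its transformed statistic (positive score there) and at the
  # bottom elsewhere (negative scores); a uniform offset shared by all
  # samples changes nothing
  m <- make_mat(30, 5, seed = 9)
  m[1:5, 1] <- m[1:5, 1] + 50
  sc <- gsva_scores(m, list(top = sprintf("g%02d", 1:5)))
  expect_gt(sc[1, 1], 0)
  expect_true(all(sc[1, -1] < 0))
  shifted <- m
  shifted[1:5, ] <- shifted[1:5, ] + 50  # cohort-wide offset cancels out
  expect_equal(gsva_scores(shifted, list(top = sprintf("g%02d", 1:5))),
               sc, tolerance = 1e-9)
})

test_that("GSVA refuses tiny cohorts, pointing at ssGSEA", {
  m <- make_mat(10, 3)
  expect_error(gsva_scores(m, list(a = c("g01", "g02"))), "ssgsea")
})

test_that("paired pathway test: exact two-sided p-values and BH adjustment", {
  # n = 8 pairs, metastasis always higher: two-sided exact p = 2/256
  scores <- matrix(0, 2, 16, dimnames = list(
    c("HR", "flat"), c(paste0("P", 1:8, "_p"), paste0("P", 1:8, "_m"))))
  set.seed(10)
  base <- rnorm(8)
  scores["HR", ] <- c(base, base + runif(8, 0.1, 0.5))
  scores["flat", ] <- c(base, base)
  pairing <- data.frame(sample = colnames(scores),
                        patient = rep(paste0("P", 1:8), 2),
                        disease_status = rep(c("primary", "metastasis"),
                                             each = 8))
  expect_warning(res <- paired_pathway_test(scores, pairing), "zero")
  expect_equal(res$p[res$set == "HR"], 2 / 256)
  expect_equal(res$p[res$set == "flat"], 1)
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("incomplete pairing is rejected with the offending patients named", {
  scores <- matrix(rnorm(6), 1, 6,
                   dimnames = list("s", paste0("x", 1:6)))
  pairing <- data.frame(sample = paste0("x", 1:6),
                        patient = c("A", "A", "B", "B", "C", "C"),
                        disease_status = c("primary", "metastasis",
                                           "primary", "primary",
                                           "metastasis", "metastasis"))
  expect_error(paired_pathway_test(scores, pairing), "B, C")
})

test_that("Benjamini-Hochberg follows the hand computation", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.8), "BH"),
               c(0.04, 0.04, 0.04, 0.8))
})

test_that("site enrichment: exact rank-sum p-values match enumeration", {
  scores <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                   dimnames = list("s", paste0("x", 1:6)))
  labs <- c("brain", "brain", "brain", "bone", "lung", "liver")
  res <- site_enrichment_test(scores, labs, target = "brain")
  expect_equal(res$p, 0.1)  # U = 0, 2 * (1 / C(6,3))
  # random fixtures vs enumeration oracle, both group sizes <= 4
  for (s in 1:8) {
    set.seed(1300 + s)
    x <- rnorm(4); y <- rnorm(4)
    m <- matrix(c(x, y), 1, dimnames = list("s", paste0("v", 1:8)))
    res2 <- site_enrichment_test(m, rep(c("brain", "other"), each = 4))
    expect_equal(res2$p, oracle_rank_sum(x, y), info = s)
  }
  expect_error(site_enrichment_test(scores, rep("brain", 6)), "non-empty")
})

test_that("expression matrices round-trip through the TSV reader/writer", {
  m <- make_mat(6, 4, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(m, path)
  expect_equal(read_expression_tsv(path), m, tolerance = 1e-12)
})
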