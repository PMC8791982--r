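refs <- synthetic_signatures()

test_that("a pure reference column is recovered exactly", {
  catal <- structure(stats::setNames(round(1000 * refs[, "BreastC"]),
                                     rownames(refs)),
                     sample = "pure", class = "mutation_catalog")
  fit <- fit_exposures(catal, refs)
  expect_equal(unname(fit$exposures["BreastC"]), sum(catal), tolerance = 0.02)
  expect_lt(max(fit$exposures[names(fit$exposures) != "BreastC"]), 5)
})

test_that("two-signature mixtures match a dense grid-search oracle", {
  m2 <- refs[, c("BreastA", "BreastE")]
  counts <- round(600 * m2[, 1] + 400 * m2[, 2])
  fit <- fit_exposures(stats::setNames(counts, rownames(refs)), refs[, c(1, 5)])
  grid <- oracle_nnls_grid(counts, m2, e_max = 800, step = 5)
  expect_equal(unname(fit$exposures), grid$exposures, tolerance = 0.02)
  # fitted residual can never exceed the best grid point's
  expect_lte(fit$residual^2, grid$objective + 1e-6)
  expect_equal(unname(fit$exposures), c(600, 400), tolerance = 0.02)
})

test_that("uniform-noise catalogs keep total exposure near the catalog total", {
  # holds when the reference set spans flat spectra (an ageing-like
  # signature); checked against the grid-search oracle on the same objective
  flat_refs <- cbind(Flat = rep(1 / 96, 96), Spiky = refs[, "BreastB"])
  rownames(flat_refs) <- rownames(refs)
  set.seed(11)
  counts <- stats::setNames(rpois(96, 10), rownames(refs))
  fit <- fit_exposures(counts, flat_refs)
  expect_equal(sum(fit$exposures), sum(counts), tolerance = 0.1)
  grid <- oracle_nnls_grid(counts, flat_refs, e_max = 1200, step = 10)
  expect_lte(fit$residual^2, grid$objective + 1e-6)
})

test_that("fitting is scale-equivariant and rejects degenerate input", {
  catal <- stats::setNames(round(500 * (0.7 * refs[, 1] + 0.3 * refs[, 2])),
                           rownames(refs))
  e1 <- fit_exposures(catal, refs)$exposures
  e3 <- fit_exposures(catal * 3L, refs)$exposures
  expect_equal(unname(e3), unname(3 * e1), tolerance = 1e-6)
  expect_error(fit_exposures(stats::setNames(integer(96), rownames(refs)),
                             refs), "empty catalog")
  bad <- stats::setNames(rep(1L, 96), rev(rownames(refs)))
  expect_error(fit_exposures(bad, refs), "channel order")
})

test_that("bootstrap retains a pure signal with full contribution", {
  catal <- simulate_catalog(c(BreastB = 1), 1000, refs, seed = 5)
  est <- bootstrap_fit(catal, refs, seed = 9)
  expect_s3_class(est, "signature_exposure")
  expect_equal(unname(est$relative_contribution["BreastB"]), 1.0)
  expect_equal(sum(est$exposures > 0), 1L)
  expect_equal(unname(est$retention_prob["BreastB"]), 1.0)
})

test_that("a 3% contaminant is zeroed by the 5% exposure threshold", {
  zeroed <- vapply(1:20, function(s) {
    catal <- simulate_catalog(c(BreastA = 0.97, BreastF = 0.03), 1000, refs,
                              seed = 100 + s)
    est <- bootstrap_fit(catal, refs, seed = 200 + s)
    est$exposures["BreastF"] == 0
  }, TRUE)
  expect_gte(sum(zeroed), 18L)
})

test_that("relative contributions renormalize to one after zeroing", {
  catal <- simulate_catalog(c(BreastA = 0.55, BreastD = 0.42, BreastF = 0.03),
                            2000, refs, seed = 17)
  est <- bootstrap_fit(catal, refs, seed = 18)
  expect_equal(sum(est$relative_contribution), 1, tolerance = 1e-12)
  expect_true(all(est$relative_contribution[est$exposures == 0] == 0))
  expect_true(all(est$relative_contribution >= 0 &
                  est$relative_contribution <= 1))
})

test_that("raising the exposure threshold never un-zeroes a signature", {
  catal <- simulate_catalog(c(BreastA = 0.6, BreastD = 0.3, BreastF = 0.1),
                            1500, refs, seed = 31)
  zeroed_at <- function(thr) {
    est <- bootstrap_fit(catal, refs, threshold_fraction = thr, seed = 32)
    names(est$exposures)[est$exposures == 0]
  }
  z1 <- zeroed_at(0.02); z2 <- zeroed_at(0.05); z3 <- zeroed_at(0.15)
  expect_true(all(z1 %in% z2))
  expect_true(all(z2 %in% z3))
})

test_that("n_boot = 1 reduces to a single resample fit; n_boot < 1 errors", {
  catal <- simulate_catalog(c(BreastA = 1), 500, refs, seed = 3)
  est <- bootstrap_fit(catal, refs, n_boot = 1, seed = 40)
  set.seed(40)
  res <- stats::setNames(as.numeric(
    stats::rmultinom(1, sum(catal), as.numeric(catal) / sum(catal))),
    names(catal))
  single <- fit_exposures(res, refs)$exposures
  expect_equal(unname(est$raw_median), unname(single))
  expect_error(bootstrap_fit(catal, refs, n_boot = 0), "n_boot")
})

test_that("signature status uses a strict cutoff on relative contribution", {
  fake <- function(rc) {
    structure(list(relative_contribution = rc), class = "signature_exposure")
  }
  rc <- stats::setNames(c(0.95, 0.05), c("BreastF", "BreastA"))
  expect_true(call_signature_status(fake(rc), "BreastF", 0.9))
  expect_false(call_signature_status(fake(rc), "BreastA", 0.9))
  rc_edge <- stats::setNames(c(0.9, 0.1), c("BreastF", "BreastA"))
  expect_false(call_signature_status(fake(rc_edge), "BreastF", 0.9))
  expect_error(call_signature_status(fake(rc), "nope"), "unknown signature")
})

test_that("gained_in_met requires positive metastasis and negative primary", {
  fake <- function(v) structure(
    list(relative_contribution = stats::setNames(c(v, 1 - v),
                                                 c("BreastF", "BreastA"))),
    class = "signature_exposure")
  expect_true(gained_in_met(fake(0.2), fake(0.95), "BreastF"))
  expect_false(gained_in_met(fake(0.95), fake(0.95), "BreastF"))
  expect_false(gained_in_met(fake(0.95), fake(0.2), "BreastF"))
  other <- structure(list(relative_contribution = c(X = 1)),
                     class = "signature_exposure")
  expect_error(gained_in_met(fake(0.2), other, "BreastF"),
               "different reference sets")
})

test_that("bootstrap results are seed-deterministic and order-independent", {
  catal <- simulate_catalog(c(BreastA = 0.5, BreastB = 0.5), 800, refs,
                            seed = 77)
  e1 <- bootstrap_fit(catal, refs, seed = derive_seed(1, "sampleX"))
  e2 <- bootstrap_fit(catal, refs, seed = derive_seed(1, "sampleX"))
  expect_identical(e1$exposures, e2$exposures)
  expect_false(derive_seed(1, "sampleX") == derive_seed(1, "sampleY"))
  expect_lt(derive_seed(1, "sampleX"), 2^31)
})
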