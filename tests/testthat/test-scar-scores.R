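build <- toy_genome_build()  # 8 chromosomes x 130 Mb, centromere 60-65 Mb

seg_row <- function(chrom, start, end, total, minor, sample = "s") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             total_cn = total, minor_cn = minor, stringsAsFactors = FALSE)
}

test_that("segment validation enforces the allele-specific contract", {
  expect_error(validate_segments(seg_row("chr1", 10, 5, 2, 1)), "start > end")
  expect_error(validate_segments(seg_row("chr1", 1, 10, 2, 2)),
               "minor_cn exceeds")
  two <- rbind(seg_row("chr1", 1, 10e6, 2, 1), seg_row("chr1", 5e6, 15e6, 3, 1))
  expect_error(validate_segments(two), "overlapping")
})

test_that("smoothing coalesces identical neighbors and absorbs short segments", {
  # two abutting identical segments -> one
  two <- rbind(seg_row("chr1", 1, 10e6, 2, 1), seg_row("chr1", 10e6 + 1, 30e6, 2, 1))
  sm <- smooth_segments(two)
  expect_equal(nrow(sm), 1L)
  expect_equal(c(sm$start, sm$end), c(1, 30e6))
  # 1-Mb blip between two 20-Mb segments of equal state -> single 41-Mb segment
  blip <- rbind(seg_row("chr1", 1, 20e6, 2, 1),
                seg_row("chr1", 20e6 + 1, 21e6, 4, 0),
                seg_row("chr1", 21e6 + 1, 41e6, 2, 1))
  sm2 <- smooth_segments(blip)
  expect_equal(nrow(sm2), 1L)
  expect_equal(c(sm2$total_cn, sm2$minor_cn), c(2, 1))
  expect_equal(sm2$end - sm2$start + 1, 41e6)
  # idempotence
  expect_identical(smooth_segments(sm2), sm2)
})

test_that("short segments merge into the closer-state neighbor, ties left", {
  x <- rbind(seg_row("chr1", 1, 20e6, 4, 2),
             seg_row("chr1", 20e6 + 1, 22e6, 3, 1),
             seg_row("chr1", 22e6 + 1, 42e6, 2, 1))
  sm <- smooth_segments(x)
  # (3,1) is distance 2 from (4,2) and 1 from (2,1): merges right
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$start[2], 20e6 + 1)
})

test_that("LOH scoring counts sizeable non-whole-chromosome LOH", {
  one <- seg_row("chr1", 30e6, 49999999, 2, 0)  # 20 Mb copy-neutral LOH
  expect_equal(score_loh(one, build), 1L)
  diploid <- seg_row("chr1", 1, 130e6, 2, 1)
  expect_equal(score_loh(diploid, build), 0L)
  whole <- seg_row("chr1", 1, 130e6, 1, 0)  # whole-chromosome LOH excluded
  expect_equal(score_loh(whole, build), 0L)
  short <- seg_row("chr1", 30e6, 39999999, 2, 0)  # 10 Mb < 15 Mb
  expect_equal(score_loh(short, build), 0L)
  expect_error(score_loh(seg_row("chrZ", 1, 2e6, 2, 0), build),
               "not in genome build")
})

test_that("ntAI counts telomere-touching, centromere-respecting imbalance", {
  telo <- seg_row("chr1", 1, 20e6, 3, 1)  # AI at p-telomere, cen at 60 Mb
  expect_equal(score_ntai(telo, build), 1L)
  spanning <- seg_row("chr1", 1, 70e6, 3, 1)  # crosses the 60-65 Mb centromere
  expect_equal(score_ntai(spanning, build), 0L)
  balanced <- seg_row("chr1", 1, 130e6, 2, 1)
  expect_equal(score_ntai(balanced, build), 0L)
  interior <- seg_row("chr1", 30e6, 50e6, 3, 1)  # AI but not telomeric
  expect_equal(score_ntai(interior, build), 0L)
  q_telo <- seg_row("chr1", 110e6, 130e6, 3, 1)
  expect_equal(score_ntai(q_telo, build), 1L)
})

test_that("LST counts state-changing breakpoints between long arm segments", {
  pair <- rbind(seg_row("chr1", 1e6, 13e6, 2, 1),
                seg_row("chr1", 13e6 + 1, 25e6, 3, 1))
  expect_equal(score_lst(pair, build), 1L)
  single <- seg_row("chr1", 1, 130e6, 2, 1)
  expect_equal(score_lst(single, build), 0L)
  short_flank <- rbind(seg_row("chr1", 1e6, 13e6, 2, 1),
                       seg_row("chr1", 13e6 + 1, 21e6, 3, 1))  # 8 Mb < 10 Mb
  expect_equal(score_lst(short_flank, build), 0L)
  wide_gap <- rbind(seg_row("chr1", 1e6, 13e6, 2, 1),
                    seg_row("chr1", 17e6 + 1, 30e6, 3, 1))  # 4 Mb gap >= 3 Mb
  expect_equal(score_lst(wide_gap, build), 0L)
  across_cen <- rbind(seg_row("chr1", 45e6, 59999999, 2, 1),
                      seg_row("chr1", 65e6 + 1, 80e6, 3, 1))  # different arms
  expect_equal(score_lst(across_cen, build), 0L)
})

test_that("combined score sums components; deficiency boundary at 42", {
  expect_equal(combined_score(10, 15, 18), 43L)
  expect_true(classify_hrd(43))
  expect_true(classify_hrd(42))
  expect_false(classify_hrd(41))
  expect_equal(combined_score(0, 0, 0), 0L)
  expect_false(classify_hrd(0))
  expect_error(combined_score(-1, 0, 0), "non-negative")
})

test_that("scorers match the brute-force predicate oracle on random genomes", {
  for (s in 1:25) {
    g <- smooth_segments(random_genome(build, seed = 900 + s))
    expect_equal(score_loh(g, build), oracle_loh(g, build), info = s)
    expect_equal(score_ntai(g, build), oracle_ntai(g, build), info = s)
    expect_equal(score_lst(g, build), oracle_lst(g, build), info = s)
  }
})

test_that("scores are invariant to splitting a segment into equal-state halves", {
  for (s in 1:5) {
    g <- smooth_segments(random_genome(build, seed = 950 + s))
    i <- which.max(g$end - g$start)  # split the longest segment
    mid <- floor((g$start[i] + g$end[i]) / 2)
    split_g <- rbind(g[-i, ],
                     transform(g[i, ], end = mid),
                     transform(g[i, ], start = mid + 1))
    split_g <- smooth_segments(split_g[order(split_g$chrom, split_g$start), ])
    expect_equal(score_loh(split_g, build), score_loh(g, build))
    expect_equal(score_ntai(split_g, build), score_ntai(g, build))
    expect_equal(score_lst(split_g, build), score_lst(g, build))
  }
})

test_that("genome scores are additive across chromosomes", {
  g <- smooth_segments(random_genome(build, seed = 999))
  per_chrom <- vapply(build$chrom, function(ch) {
    s <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) return(0L)
    score_loh(s, build) + score_ntai(s, build) + score_lst(s, build)
  }, 0L)
  total <- score_loh(g, build) + score_ntai(g, build) + score_lst(g, build)
  expect_equal(sum(per_chrom), total)
})

test_that("sex chromosomes are excluded unless requested", {
  b <- grch37_build()
  x_loh <- seg_row("chrX", 30e6, 50e6, 2, 0)
  expect_equal(score_loh(x_loh, b), 0L)
  expect_equal(score_loh(x_loh, b, include_sex = TRUE), 1L)
})

test_that("score_scars joins smoothing, scoring and the deficiency call", {
  seg <- rbind(simulate_segments(build, c(loh = 3, tai = 2, lst = 1),
                                 seed = 1, sample_id = "a"),
               simulate_segments(build, c(loh = 0, tai = 0, lst = 0),
                                 seed = 2, sample_id = "b"))
  sc <- score_scars(seg, build)
  expect_s3_class(sc, "scar_scores")
  a <- sc[sc$sample == "a", ]
  expect_equal(c(a$loh, a$tai, a$lst, a$combined), c(3, 2, 1, 6))
  expect_false(a$deficient)
  b_row <- sc[sc$sample == "b", ]
  expect_equal(b_row$combined, 0L)
})

test_that("paired scar test: exact one-sided p-values and degenerate case", {
  # n = 6, metastasis always higher, no ties: p = 1/64
  prim <- c(10, 12, 15, 20, 8, 30)
  met <- prim + c(5, 3, 9, 2, 7, 4)
  p <- paired_scar_test(prim, met)
  expect_equal(as.numeric(p), 1 / 64)
  expect_warning(pd <- paired_scar_test(c(5, 5, 5), c(5, 5, 5)), "degenerate")
  expect_equal(as.numeric(pd), 1)
  expect_error(paired_scar_test(1:3, 1:4), "length")
  # random fixtures against the enumeration oracle
  for (s in 1:10) {
    set.seed(1200 + s)
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(as.numeric(paired_scar_test(a, b)),
                 oracle_signed_rank(a, b, "greater"), info = s)
  }
})

test_that("segment tables round-trip through the SEG reader/writer", {
  seg <- simulate_segments(build, c(loh = 2, tai = 1, lst = 1), seed = 5)
  path <- tempfile(fileext = ".seg")
  write_segments_tsv(seg, path)
  back <- read_segments_tsv(path)
  expect_equal(back, seg, ignore_attr = TRUE)
})
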