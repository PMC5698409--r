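cpg_calls <- function(pos, level, cov = 10, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.double(pos), strand = "+",
                 context = "CpG", meth = as.integer(round(level * cov)),
                 total = as.integer(cov))
}

test_that("strand combining sums the two cytosines of a CpG", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(100, 101, 300, 500),
    strand = c("+", "-", "+", "+"),
    context = c("CpG", "CpG", "CpG", "CHH"),
    meth = c(3L, 2L, 1L, 4L), total = c(5L, 5L, 8L, 9L))
  out <- combine_cpg_strands(calls)
  cpg <- out[out$context == "CpG", ]
  expect_equal(cpg$pos, c(100, 300))
  expect_equal(cpg$meth, c(5L, 1L))
  expect_equal(cpg$total, c(10L, 8L))
  # CHH passes through unchanged
  expect_equal(out[out$context == "CHH", ]$total, 9L)
  # conservation of counts
  expect_equal(sum(out$meth), sum(calls$meth))
  expect_equal(sum(out$total), sum(calls$total))
  dup <- rbind(calls, calls[1, ])
  expect_error(combine_cpg_strands(dup), "duplicate")
})

test_that("uniformly high methylation yields a single FMR", {
  calls <- cpg_calls(seq(0, by = 100, length.out = 200), 0.95, cov = 20)
  segs <- segment_methylome(calls)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$class, "FMR")
  expect_equal(segs$n_cpg, 200L)
  expect_gte(segs$mean_meth, 0.85)
})

test_that("a planted PMD is recovered and short PMDs are excluded", {
  set.seed(21)
  mk <- function(pmd_len) {
    left <- cpg_calls(seq(0, by = 100, length.out = 500), 0.95)
    pmd_pos <- seq(50200, by = 100, length.out = pmd_len / 100)
    pmd <- tibble::tibble(chrom = "chr1", pos = pmd_pos, strand = "+",
                          context = "CpG",
                          meth = rbinom(length(pmd_pos), 10,
                                        runif(length(pmd_pos), 0.3, 0.7)),
                          total = 10L)
    right_start <- max(pmd_pos) + 100
    right <- cpg_calls(seq(right_start, by = 100, length.out = 500), 0.95)
    dplyr::arrange(dplyr::bind_rows(left, pmd, right), pos)
  }
  segs <- segment_methylome(mk(150000))
  pmd <- segs[segs$class == "PMD", ]
  expect_equal(nrow(pmd), 1)
  truthy <- tibble::tibble(chrom = "chr1", start = 50200, end = 200200)
  expect_gte(interval_jaccard(pmd[, c("chrom", "start", "end")], truthy),
             0.8)

  segs80 <- segment_methylome(mk(80000))
  expect_equal(nrow(segs80[segs80$class == "PMD", ]), 0)
  expect_gt(nrow(attr(segs80, "short_pmds")), 0)
})

test_that("raising the PMD length floor never increases the PMD count", {
  set.seed(22)
  pos <- sort(sample(1:6e5, 4000))
  lev <- ifelse(pos > 2e5 & pos < 4e5, runif(4000, 0.3, 0.7), 0.95)
  calls <- tibble::tibble(chrom = "chr1", pos = as.double(pos),
                          strand = "+", context = "CpG",
                          meth = rbinom(4000, 12, lev), total = 12L)
  counts <- vapply(c(5e4, 1e5, 1.5e5, 2.5e5), function(minlen) {
    s <- segment_methylome(calls, pmd_min_length = minlen)
    sum(s$class == "PMD")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is a partition: classes never overlap", {
  truth <- fix_truth()
  segs <- fix_segments()
  by_chrom <- split(segs, segs$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  calls <- fix_methylome()
  n_qual <- sum(calls$context == "CpG" & calls$total >= 4)
  expect_lte(sum(segs$n_cpg), n_qual)
})

test_that("CHH pooling uses summed counts, not mean of ratios", {
  g <- cm_genome("chr1", 3000)
  calls <- tibble::tibble(chrom = "chr1", pos = c(100, 900, 2500),
                          strand = "+", context = "CHH",
                          meth = c(1L, 3L, 2L), total = c(10L, 10L, 4L))
  tr <- bin_chh(calls, g)
  expect_equal(tr$value[1], 4 / 20)
  expect_true(is.na(tr$value[2]))
  expect_equal(tr$value[3], 0.5)
  expect_equal(tr$end - tr$start, rep(1000, 3))
  # CpG records are ignored
  tr2 <- bin_chh(cpg_calls(1:10 * 50, 0.5), g)
  expect_true(all(is.na(tr2$value)))
})

test_that("mean methylation in regions is coverage weighted and filtered", {
  reg <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  one <- cpg_calls(500, 0.8, cov = 10)
  expect_equal(mean_methylation_in(one, reg), 0.8)
  low <- cpg_calls(500, 0.8, cov = 3)
  expect_true(is.na(mean_methylation_in(low, reg)))
  two <- dplyr::bind_rows(cpg_calls(100, 0, cov = 10),
                          cpg_calls(200, 1, cov = 10))
  expect_equal(mean_methylation_in(two, reg), 0.5)
})
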