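test_that("bins tile each chromosome exactly, terminal bins flagged", {
  g <- cm_genome(c("chr1", "chr2"), c(100190, 2.5e5))
  bins <- cm_bins(g, 4e4)
  widths <- bins |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(total = sum(end - start),
                     gaps = sum(start[-1] != end[-dplyr::n()]))
  expect_equal(widths$total, g$length)
  expect_true(all(widths$gaps == 0))
  expect_equal(sum(bins$short), 2)  # 100190 %% 4e4 and 2.5e5 %% 4e4
  expect_equal(nrow(bins), length(unique(bins$bin)))
  # bin <-> coordinate bijection
  idx <- pos_to_bin(bins, bins$chrom, bins$start)
  expect_equal(idx, bins$bin)
})

test_that("genome constructor rejects duplicates and bad lengths", {
  expect_error(cm_genome(c("chr1", "chr1"), c(10, 20)), "duplicated")
  expect_error(cm_genome("chr1", 0), "length")
})

test_that("BED reading handles records, empty files and malformed input", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t40000\tA", p)
  b <- read_bed(p)
  expect_equal(b$chrom, "chr1")
  expect_equal(b$start, 0)
  expect_equal(b$end, 40000)
  expect_equal(b$name, "A")

  writeLines(character(), p)
  expect_equal(nrow(read_bed(p)), 0)

  writeLines("chr1\t500\t100", p)
  expect_error(read_bed(p), "start < end")

  writeLines("chrUn\t0\t100", p)
  g <- cm_genome("chr1", 1000)
  expect_error(read_bed(p, genome = g), "chrUn")
  expect_warning(out <- read_bed(p, genome = g, unknown_chrom = "skip"),
                 "skipping")
  expect_equal(nrow(out), 0)
})

test_that("bedGraph maps to bins with weighted means and explicit mask", {
  g <- cm_genome(c("chr1", "chr2"), c(400, 400))
  bins <- cm_bins(g, 100)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("track type=bedGraph", "chr1\t0\t100\t1.5"), p)
  tr <- read_bedgraph(p, bins)
  expect_equal(tr$value[1], 1.5)
  expect_true(all(is.na(tr$value[-1])))

  writeLines(c("chr1\t0\t50\t1.0", "chr1\t50\t100\t3.0"), p)
  expect_equal(read_bedgraph(p, bins)$value[1], 2.0)

  writeLines("chr1\t0\t60\t1", p)
  expect_equal(read_bedgraph(p, bins)$value[1], 1)

  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), p)
  expect_error(read_bedgraph(p, bins), "overlapping")
})

test_that("bedGraph round trip is the identity on unmasked values", {
  g <- cm_genome(c("chr1", "chr2"), c(1000, 700))
  bins <- cm_bins(g, 100)
  set.seed(42)
  v <- rnorm(nrow(bins))
  v[c(3, 9)] <- NA
  v[5] <- 0  # zero is a value, not missing
  tr <- bin_track(bins, v)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p, bins)
  expect_equal(back$value, tr$value, tolerance = 5e-6)
  expect_equal(back$value[5], 0)
  expect_true(all(is.na(back$value[c(3, 9)])))

  write_bedgraph(bin_track(bins, rep(NA_real_, nrow(bins))), p)
  expect_equal(sum(!is.na(read_bedgraph(p, bins)$value)), 0)
})

test_that("overlap_fraction follows interval algebra", {
  q <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  t1 <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  expect_equal(overlap_fraction(q, t1), 0.5)
  expect_equal(overlap_fraction(q, t1[0, ]), 0)
  tiling <- tibble::tibble(chrom = "chr1", start = c(0, 40), end = c(40, 100))
  expect_equal(overlap_fraction(q, tiling), 1)
  # invariant under permutation and splitting of targets
  set.seed(7)
  for (i in 1:20) {
    st <- sort(sample(0:400, 6))
    tg <- tibble::tibble(chrom = "chr1",
                         start = st[c(1, 3, 5)], end = st[c(2, 4, 6)])
    tg <- tg[tg$end > tg$start, ]
    if (nrow(tg) == 0) next
    qq <- tibble::tibble(chrom = "chr1", start = 100, end = 300)
    base <- overlap_fraction(qq, tg)
    expect_equal(overlap_fraction(qq, tg[sample(nrow(tg)), ]), base)
    sp <- tg[1, ]
    mid <- floor((sp$start + sp$end) / 2)
    if (mid > sp$start && mid < sp$end) {
      split <- rbind(
        tibble::tibble(chrom = "chr1", start = sp$start, end = mid),
        tibble::tibble(chrom = "chr1", start = mid, end = sp$end),
        tg[-1, ]
      )
      expect_equal(overlap_fraction(qq, split), base)
    }
  }
})

test_that("methylation call files round trip", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(10, 11, 55),
                          strand = c("+", "-", "+"),
                          context = c("CpG", "CpG", "CHH"),
                          meth = c(3L, 2L, 1L), total = c(5L, 5L, 9L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_methylation(calls, p)
  expect_equal(as.data.frame(read_methylation(p)), as.data.frame(calls))
  writeLines("chr1\t10\t+\tCpG\t7\t5", p)
  expect_error(read_methylation(p), "counts")
})
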