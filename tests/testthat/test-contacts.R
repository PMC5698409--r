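make_contacts <- function(m, bin_size = 100) {
  g <- cm_genome("chr1", nrow(m) * bin_size)
  bins <- cm_bins(g, bin_size)
  mats <- list(chr1 = m)
  compartmeth:::new_contacts(bins, mats)
}

test_that("sparse triplets load symmetrized with diagonal preserved", {
  g <- cm_genome("chr1", 300)
  bins <- cm_bins(g, 100)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# bin_size=100", "chr1\t0\tchrX\t1\t5",
               "chr1\t0\tchr1\t0\t10"), p)
  # inter-chromosomal records are dropped with a message
  expect_message(x0 <- load_matrix(p, bins), "inter-chromosomal")
  expect_equal(x0$mats$chr1[1, 2], 0)
  expect_equal(x0$mats$chr1[1, 1], 10)
  writeLines(c("# bin_size=100", "chr1\t0\tchr1\t1\t5",
               "chr1\t0\tchr1\t0\t10"), p)
  x <- load_matrix(p, bins)
  expect_equal(x$mats$chr1[1, 2], 5)
  expect_equal(x$mats$chr1[2, 1], 5)
  expect_equal(x$mats$chr1[1, 1], 10)

  writeLines(character(), p)
  expect_true(all(load_matrix(p, bins)$mats$chr1 == 0))

  writeLines("chr1\t0\tchr1\t9\t5", p)
  expect_error(load_matrix(p, bins), "out of range")
  writeLines("chr1\t0\tchr1\t1\t-2", p)
  expect_error(load_matrix(p, bins), "negative")
})

test_that("matrix writer round trips through the loader", {
  set.seed(1)
  m <- matrix(rpois(64, 5), 8, 8)
  m <- m + t(m)
  x <- make_contacts(m)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(x, p)
  y <- load_matrix(p, x$bins)
  expect_equal(y$mats$chr1, m)
})

test_that("ICE leaves a balanced matrix unchanged and equalizes row sums", {
  ones <- matrix(1, 3, 3)
  b <- ice_balance(make_contacts(ones), low_coverage_quantile = 0)
  rs <- rowSums(b$mats$chr1)
  expect_equal(max(abs(rs / mean(rs) - 1)), 0)
  expect_equal(b$mats$chr1 / mean(b$mats$chr1), ones / mean(ones))

  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(225, 0.1, 3), 15, 15)
    m <- m + t(m)
    b <- ice_balance(make_contacts(m), tol = 1e-8,
                     low_coverage_quantile = 0)
    rs <- rowSums(b$mats$chr1)
    expect_lt(max(abs(rs / mean(rs) - 1)), 1e-8)
    # symmetry and zero pattern preserved, weights positive
    expect_equal(b$mats$chr1, t(b$mats$chr1))
    expect_true(all(b$weights$chr1 > 0))
  }
})

test_that("ICE masks empty and low-coverage bins", {
  m <- matrix(runif(36, 1, 2), 6, 6)
  m <- m + t(m)
  m[3, ] <- 0; m[, 3] <- 0
  b <- ice_balance(make_contacts(m), low_coverage_quantile = 0)
  expect_false(b$mask$chr1[3])
  expect_true(all(is.na(b$mats$chr1[3, ])))
  rs <- rowSums(b$mats$chr1[-3, -3])
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-5)
  expect_error(ice_balance(make_contacts(matrix(0, 4, 4))), "no usable")
})

test_that("ICE matches the alternating-normalization oracle", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    m <- matrix(runif(n * n, 0.2, 4), n, n)
    m <- m + t(m)
    b <- ice_balance(make_contacts(m), tol = 1e-12, max_iter = 10000,
                     low_coverage_quantile = 0)
    o <- oracle_ice(m)
    expect_equal(b$mats$chr1 / mean(b$mats$chr1), o / mean(o),
                 tolerance = 1e-6)
  }
})

test_that("expected-by-distance has the documented closed forms", {
  n <- 6
  m <- matrix(0, n, n)
  for (i in 1:(n - 1)) m[i, i + 1] <- 4
  m <- m + t(m) + diag(8, n)
  x <- make_contacts(m)
  x$balanced <- TRUE
  x$mask <- list(chr1 = rep(TRUE, n))
  e <- expected_by_distance(x)
  expect_equal(e$chr1[2], 4)
  expect_equal(e$chr1[1], 8)
  expect_equal(e$chr1[4], 0)

  one <- make_contacts(matrix(5, 1, 1))
  one$balanced <- TRUE
  one$mask <- list(chr1 = TRUE)
  expect_equal(length(expected_by_distance(one)$chr1), 1)
})

test_that("O/E correlation recovers planted checkerboard structure", {
  # two-block plaid on a decaying background
  n <- 40
  lab <- rep(c(1, -1), each = n / 2)
  d <- abs(outer(1:n, 1:n, "-"))
  m <- (1 + d)^-1 * ifelse(outer(lab, lab) > 0, 1.5, 0.5) * 1000
  x <- make_contacts(m)
  b <- ice_balance(x, low_coverage_quantile = 0)
  cc <- oe_correlation(b)$chr1
  expect_true(all(cc[is.finite(cc)] >= -1 - 1e-12 &
                    cc[is.finite(cc)] <= 1 + 1e-12))
  expect_equal(unname(diag(cc)), rep(1, n))
  same <- outer(lab, lab) > 0
  expect_gt(mean(cc[same & upper.tri(cc)]), 0)
  expect_lt(mean(cc[!same & upper.tri(cc)]), 0)
})

test_that("tidy and glance summarize a contact object", {
  m <- matrix(c(0, 2, 2, 4), 2, 2)
  x <- make_contacts(m)
  td <- tidy(x)
  expect_equal(nrow(td), 2)  # (0,1) and (1,1)
  gl <- glance(x)
  expect_equal(gl$total_contacts, 6)
  expect_false(gl$balanced)
})
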