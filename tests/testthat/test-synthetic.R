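test_that("truth model satisfies its structural invariants", {
  truth <- fix_truth()
  # labels cover all bins at every stage
  for (st in c(truth$stages, truth$ko_sample)) {
    expect_false(anyNA(truth_labels(truth, st)$label))
  }
  # knockout shares the adult compartment truth exactly
  expect_equal(truth_labels(truth, truth$ko_sample)$label,
               truth_labels(truth, "adult")$label)
  # switch blocks change label exactly once along the stage axis
  labs <- vapply(truth$stages, function(st) truth_labels(truth, st)$label,
                 character(nrow(truth$bins)))
  changes <- apply(labs, 1, function(r) sum(r[-1] != r[-length(r)]))
  expect_true(all(changes <= 1))
  sw <- truth$blocks[!is.na(truth$blocks$switch_idx), ]
  expect_equal(nrow(sw), 4)
  # planted PMDs are >= 100 kb and confined to B (lagged label)
  pmd <- truth_features(truth, "PMD", "adult")
  expect_true(all(pmd$end - pmd$start >= 1e5))
  # planted DMRs carry >= 5 CpGs with gaps <= 1 kb (fixed grid)
  dmr <- truth_features(truth, "DMR")
  expect_true(all(dmr$end - dmr$start >= 5 * 120))
})

test_that("contact generation is deterministic and conserves read totals", {
  truth <- fix_truth()
  hp <- hic_params(n_reads = 2e5, seed = 77)
  m1 <- generate_contacts(truth, hp, "fetal")
  m2 <- generate_contacts(truth, hp, "fetal")
  expect_identical(m1$mats, m2$mats)
  m3 <- generate_contacts(truth, hic_params(n_reads = 2e5, seed = 78),
                          "fetal")
  expect_false(identical(m1$mats, m3$mats))
  for (ch in truth$genome$chrom) {
    m <- m1$mats[[ch]]
    expect_equal(sum(m[upper.tri(m, diag = TRUE)]), 2e5)
    expect_equal(m, t(m))
  }
})

test_that("plaid-off contacts depend only on distance", {
  truth <- cohort_truth(genome = cm_genome("chr1", 8e6))
  hp <- hic_params(epsilon = 0, tau = 0, n_reads = 2e6, seed = 5)
  m <- generate_contacts(truth, hp, "adult")$mats$chr1
  lab <- truth_labels(truth, "adult")$label
  same <- outer(lab, lab, "==")
  for (d in c(1, 3, 10)) {
    v <- m[row(m) == col(m) - d]
    s <- same[row(same) == col(same) - d]
    # same- and cross-label means agree when the plaid is off
    expect_equal(mean(v[s]), mean(v[!s]), tolerance = 0.1)
  }
})

test_that("same-vs-cross O/E contrast grows with plaid strength", {
  truth <- cohort_truth(genome = cm_genome("chr1", 1.2e7))
  lab <- truth_labels(truth, "adult")$label
  gap <- vapply(c(0.1, 0.3, 0.5), function(eps) {
    hp <- hic_params(epsilon = eps, tau = 0, n_reads = 1e6, seed = 9)
    m <- generate_contacts(truth, hp, "adult")$mats$chr1
    n <- nrow(m)
    d <- abs(outer(1:n, 1:n, "-"))
    e <- vapply(0:(n - 1), function(k) mean(m[d == k]), numeric(1))
    oe <- m / matrix(e[d + 1], n, n)
    same <- outer(lab, lab, "==") & upper.tri(m) & d >= 2
    cross <- !outer(lab, lab, "==") & upper.tri(m) & d >= 2
    mean(oe[same], na.rm = TRUE) - mean(oe[cross], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("methylome generation is deterministic with shared CpG frame", {
  truth <- fix_truth()
  mp <- methyl_params(seed = 55)
  a1 <- generate_methylome(truth, mp, "newborn")
  a2 <- generate_methylome(truth, mp, "newborn")
  expect_identical(a1, a2)
  es <- generate_methylome(truth, mp, "ES")
  # CpG positions shared across stages (up to rare zero-coverage dropouts)
  pes <- unique(combine_cpg_strands(es)$pos)
  pa1 <- unique(combine_cpg_strands(a1)$pos)
  expect_gte(mean(pes %in% pa1), 0.999)
  expect_gte(mean(pa1 %in% pes), 0.999)
  # zero coverage: empty call set
  empty <- generate_methylome(truth, methyl_params(coverage = 0, seed = 1),
                              "ES")
  expect_equal(nrow(empty[empty$context == "CpG", ]), 0)
})

test_that("planted FMR levels are realized to within two percent", {
  truth <- fix_truth()
  mp <- methyl_params(seed = 55)
  calls <- combine_cpg_strands(generate_methylome(truth, mp, "ES"))
  # an A-block region without planted features: CpGs follow the A-level Beta
  blocks <- truth$blocks
  a_static <- blocks[blocks$base_label == "A" & is.na(blocks$switch_idx), ][1, ]
  probe <- tibble::tibble(chrom = a_static$chrom,
                          start = a_static$start, end = a_static$start + 1e5)
  cpg <- calls[calls$context == "CpG" & calls$chrom == probe$chrom &
                 calls$pos >= probe$start & calls$pos < probe$end, ]
  expect_gt(nrow(cpg), 500)
  expect_equal(sum(cpg$meth) / sum(cpg$total), mp$fmr_mean_a,
               tolerance = 0.02 / mp$fmr_mean_a)
})

test_that("knockout methylome has zero methylated CHH and planted deltas", {
  truth <- fix_truth()
  adult <- fix_methylome("adult")
  ko <- fix_methylome("adult_KO")
  expect_true(all(ko$meth[ko$context == "CHH"] == 0))
  expect_gt(sum(adult$meth[adult$context == "CHH"]), 0)
  # planted DMR contract: mean delta >= 0.4, per-CpG delta >= 0.1
  dmr <- truth_features(truth, "DMR")
  for (i in sample(nrow(dmr), 5)) {
    sel <- function(x) x[x$context == "CpG" & x$chrom == dmr$chrom[i] &
                           x$pos >= dmr$start[i] & x$pos < dmr$end[i], ]
    a <- sel(adult); k <- sel(ko)
    expect_equal(a$pos, k$pos)
    delta <- a$meth / a$total - k$meth / k$total
    expect_true(all(delta >= 0.1))
    expect_gte(mean(delta), 0.4)
    expect_true(all(a$total >= 4) && all(k$total >= 4))
  }
  # outside planted DMRs the knockout carries the adult counts
  out_a <- adult[adult$context == "CpG", ]
  out_k <- ko[ko$context == "CpG", ]
  inr <- compartmeth:::in_regions(out_a$chrom, out_a$pos, dmr)
  expect_equal(out_a$meth[!inr], out_k$meth[!inr])
})

test_that("truth report round trips through the BED reader", {
  truth <- fix_truth()
  dir <- withr::local_tempdir()
  files <- truth_report(truth, dir)
  pmd <- read_bed(file.path(dir, "pmd_adult.bed"))
  want <- truth_features(truth, "PMD", "adult")
  expect_equal(pmd[, c("chrom", "start", "end")], want)
  # no PMDs before the onset stage
  expect_equal(nrow(read_bed(file.path(dir, "pmd_ES.bed"))), 0)
  # switch files: empty at ES, populated later
  expect_equal(nrow(read_bed(file.path(dir, "switches_ES.bed"))), 0)
  expect_equal(nrow(read_bed(file.path(dir, "switches_adult.bed"))), 4)
  g <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(as.data.frame(g), as.data.frame(truth$genome))
})
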