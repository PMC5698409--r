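test_that("feature fractions follow the majority-overlap rule", {
  bins <- tiny_bins(10, bin_size = 1000)
  track <- pc1_track(bins, c(rep(1, 5), rep(-1, 5)))
  inside_a <- tibble::tibble(chrom = "chr1",
                             start = c(100, 1200, 3300),
                             end = c(600, 1900, 3900))
  fr <- feature_compartment_fractions(inside_a, track, n_perm = 50,
                                      seed = 2)
  expect_equal(fr$frac_a, 1)
  expect_equal(fr$genome_frac_a, 0.5)
  expect_equal(fr$fold, 2)
  # a feature split exactly 50/50 stays unassigned
  tied <- tibble::tibble(chrom = "chr1", start = 4500, end = 5500)
  fr2 <- feature_compartment_fractions(rbind(inside_a, tied), track,
                                       n_perm = 50, seed = 2)
  expect_equal(fr2$n_unassigned, 1)
  expect_equal(fr2$n_assigned, 3)
  expect_error(feature_compartment_fractions(inside_a[0, ], track),
               "empty")
})

test_that("scattered features show no compartment preference", {
  set.seed(33)
  g <- cm_genome("chr1", 4e7)
  bins <- cm_bins(g, 4e4)
  lab <- rep(rep(c(1, -1), each = 30), length.out = nrow(bins))
  track <- pc1_track(bins, lab)
  feats <- tibble::tibble(chrom = "chr1",
                          start = sort(sample(0:(4e7 - 2000), 150)))
  feats$end <- feats$start + 1500
  fr <- feature_compartment_fractions(feats, track, n_perm = 400, seed = 5)
  expect_lt(abs(fr$fold - 1), 0.15)
  expect_gt(fr$p_value, 0.05)
})

test_that("signal enrichment fold is scale-invariant with exact limits", {
  g <- cm_genome("chr1", 1e6)
  bins <- cm_bins(g, 1000)
  comp_bins <- cm_bins(g, 4e4)
  comp <- pc1_track(comp_bins, rep(c(1, -1), length.out = nrow(comp_bins)))
  const <- bin_track(bins, rep(3, nrow(bins)))
  e <- signal_compartment_enrichment(const, compartments = comp,
                                     n_perm = 50, seed = 1)
  expect_equal(e$fold, 1)
  set.seed(3)
  sig <- bin_track(bins, runif(nrow(bins)))
  e1 <- signal_compartment_enrichment(sig, compartments = comp,
                                      n_perm = 99, seed = 4)
  sig10 <- bin_track(bins, sig$value * 10)
  e2 <- signal_compartment_enrichment(sig10, compartments = comp,
                                      n_perm = 99, seed = 4)
  expect_equal(e1$fold, e2$fold)
  expect_equal(e1$p_value, e2$p_value)
  # zero signal reports "no signal" rather than a fold
  zero <- bin_track(bins, rep(0, nrow(bins)))
  ez <- signal_compartment_enrichment(zero, compartments = comp,
                                      n_perm = 50, seed = 1)
  expect_equal(ez$note, "no signal")
  expect_true(is.na(ez$fold))
})

test_that("common-compartment methylation table needs >= 2 stages", {
  bins <- tiny_bins(4, bin_size = 1000)
  common <- bins
  common$status <- c("common-A", "common-A", "common-B", "dynamic")
  calls <- tibble::tibble(chrom = "chr1", pos = c(500, 2500),
                          strand = "+", context = "CpG",
                          meth = c(9L, 1L), total = c(10L, 10L))
  out <- compartment_mean_methylation_by_stage(
    list(s1 = calls, s2 = calls), common)
  expect_equal(out$mean_a, c(0.9, 0.9))
  expect_equal(out$mean_b, c(0.1, 0.1))
  expect_equal(out$diff, c(0.8, 0.8))
  expect_error(compartment_mean_methylation_by_stage(list(s1 = calls),
                                                     common), ">= 2")
  common$status <- "dynamic"
  expect_error(compartment_mean_methylation_by_stage(
    list(s1 = calls, s2 = calls), common), "no common")
})

test_that("stage profiles track the planted methylation chronology", {
  truth <- fix_truth()
  stages <- truth$stages
  segs <- lapply(setNames(stages, stages), function(s) fix_segments(s))
  meth <- lapply(setNames(stages, stages), function(s) fix_methylome(s))
  act <- lapply(setNames(stages, stages), function(s) {
    generate_activity(truth, s, seed = 101)
  })
  sw <- truth_features(truth, "switch", "adult")
  a2b <- sw[grepl("^A->B", sw$name), c("chrom", "start", "end")]
  prof <- stage_profiles(a2b, segs, act, meth)
  # A->B switches at progenitor/fetal, methylation lags one stage:
  # no PMD bases before fetal, PMDs from the lagged stage onward
  expect_equal(prof$pmd_bases[1:2], c(0, 0))
  expect_gt(prof$pmd_bases[4], 0)
  expect_gt(prof$pmd_bases[5], 0)
  # expression collapses after the switch manifests
  expect_gt(prof$mean_expression[1], prof$mean_expression[5])
  b2a <- sw[grepl("^B->A", sw$name), c("chrom", "start", "end")]
  prof2 <- stage_profiles(b2a, segs, act, meth)
  # LMRs appear only after the B->A switch
  expect_equal(prof2$lmr_count[1], 0)
  expect_gt(prof2$lmr_count[5], 0)
  expect_error(stage_profiles(a2b[0, ], segs, act, meth), "empty")
})

test_that("sample PCA embeds degenerate inputs predictably", {
  m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 3, byrow = TRUE)
  rownames(m) <- c("a", "b", "c")
  same <- sample_pca(rbind(m[1, , drop = FALSE], m[1, , drop = FALSE],
                           m[1, , drop = FALSE]))
  expect_true(all(abs(c(same$PC1, same$PC2)) < 1e-12))
  emb <- sample_pca(m)
  expect_gte(emb$PC1[1], 0)
  dup <- sample_pca(rbind(m, m[2, , drop = FALSE]))
  expect_equal(dup$PC1[4], dup$PC1[2])
  expect_equal(dup$PC2[4], dup$PC2[2])
  # invariant under adding a constant to every column
  shifted <- sample_pca(m + 100)
  expect_equal(shifted$PC1, emb$PC1)
  expect_error(sample_pca(m[1:2, ]), ">= 3")
  m_na <- m; m_na[1, 1:2] <- NA
  expect_error(sample_pca(m_na[, 1:4]), "unmasked|jointly|columns")
})
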