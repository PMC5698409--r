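# Shared fixtures, built lazily once per test run.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fix)) assign(name, builder(), envir = .fix)
  get(name, envir = .fix)
}

fix_truth <- function() fixture("truth", function() cohort_truth())

fix_balanced <- function(stage = "adult", seed = 101) {
  fixture(paste0("bal_", stage, "_", seed), function() {
    ice_balance(generate_contacts(fix_truth(), hic_params(seed = seed),
                                  stage))
  })
}

fix_compartments <- function(stage = "adult", seed = 101) {
  fixture(paste0("comp_", stage, "_", seed), function() {
    call_compartments(fix_balanced(stage, seed),
                      generate_activity(fix_truth(), stage, seed = seed))
  })
}

fix_methylome <- function(stage = "adult", seed = 101) {
  fixture(paste0("meth_", stage, "_", seed), function() {
    combine_cpg_strands(generate_methylome(fix_truth(),
                                           methyl_params(seed = seed),
                                           stage))
  })
}

fix_segments <- function(stage = "adult", seed = 101) {
  fixture(paste0("seg_", stage, "_", seed), function() {
    segment_methylome(fix_methylome(stage, seed))
  })
}

# small ad-hoc bin frame for rule-level tests
tiny_bins <- function(n = 10, bin_size = 100, chrom = "chr1") {
  cm_bins(cm_genome(chrom, n * bin_size), bin_size)
}

# compartment-track tibble from a plain numeric vector
pc1_track <- function(bins, pc1) {
  out <- bin_track(bins, pc1)
  names(out)[names(out) == "value"] <- "pc1"
  out$label <- dplyr::case_when(out$pc1 > 0 ~ "A", out$pc1 < 0 ~ "B",
                                TRUE ~ NA_character_)
  out
}

# random CpG call set on one chromosome (sorted, unique positions)
random_callset <- function(n, chrom = "chr1", max_pos = 20000,
                           max_cov = 10) {
  pos <- sort(sample.int(max_pos, n))
  total <- sample.int(max_cov, n, replace = TRUE)
  meth <- rbinom(n, total, runif(n))
  tibble::tibble(chrom = chrom, pos = as.double(pos), strand = "+",
                 context = "CpG", meth = meth, total = total)
}
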