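#' Truth model for the synthetic multi-stage cohort
#'
#' Builds the planted ground truth the generators draw from: a small
#' multi-chromosome genome partitioned into compartment-sized blocks with
#' per-stage A/B labels (including blocks that switch at a named stage),
#' TAD boundaries, and planted methylome features — LMRs and UMRs inside A
#' compartments, large PMDs inside B compartments, DMR regions (adult vs
#' adult-KO) inside stable A compartments, and CHH-positive regions (the A
#' compartment of the adult stage).
#'
#' Methylation features follow compartment switches with a configurable
#' lag of `meth_lag` stages, and PMDs additionally appear only from the
#' `pmd_onset` stage onward (so undifferentiated stages carry
#' hypermethylated B compartments while differentiated ones lose
#' methylation in B).
#'
#' @param genome A [cm_genome()]; default two chromosomes of 20 Mb.
#' @param bin_size Bin size in bp (default 4e4).
#' @param stages Ordered developmental stages.
#' @param ko_sample Name of the knockout sample; it shares the adult
#'   compartment truth exactly.
#' @param block_bins Compartment block size in bins (default 30, i.e.
#'   1.2 Mb); kept a multiple of `tad_bins` so compartment transitions
#'   coincide with TAD boundaries, as they do in mammalian genomes.
#' @param tad_bins TAD size in bins (default 15, i.e. 600 kb).
#' @param switches_per_chrom Number of switching blocks per chromosome
#'   (default 2: one A->B and one B->A).
#' @param meth_lag Stages by which methylation features trail a
#'   compartment switch (default 1).
#' @param pmd_onset Stage (name) from which PMDs exist (default
#'   `"fetal"`).
#' @return A `cm_truth` object.
#' @export
cohort_truth <- function(genome = cm_genome(c("chr1", "chr2"), c(2e7, 2e7)),
                         bin_size = 4e4,
                         stages = c("ES", "progenitor", "fetal", "newborn",
                                    "adult"),
                         ko_sample = "adult_KO",
                         block_bins = 30,
                         tad_bins = 15,
                         switches_per_chrom = 2,
                         meth_lag = 1,
                         pmd_onset = "fetal") {
  bins <- cm_bins(genome, bin_size)
  pmd_onset_idx <- match(pmd_onset, stages)
  stopifnot(!is.na(pmd_onset_idx), switches_per_chrom %in% 0:2)
  blocks <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    nb <- sum(bins$chrom == ch & !bins$short)
    n_blocks <- nb %/% block_bins
    first_label <- if (ci %% 2 == 1) "A" else "B"
    lab <- rep(c(first_label, setdiff(c("A", "B"), first_label)),
               length.out = n_blocks)
    bstart <- (seq_len(n_blocks) - 1) * block_bins * bin_size
    bend <- bstart + block_bins * bin_size
    # extend the final block to cover any trailing bins
    bend[n_blocks] <- genome$length[ci]
    sw_idx <- rep(NA_integer_, n_blocks)
    if (switches_per_chrom >= 1) {
      # one B->A switch: progenitor on odd chromosomes, fetal on even
      st <- if (ci %% 2 == 1) 2L else 3L
      cand <- which(lab == "B")
      sw_idx[cand[ceiling(length(cand) / 3)]] <- st
    }
    if (switches_per_chrom >= 2) {
      st <- if (ci %% 2 == 1) 2L else 3L
      cand <- which(lab == "A")
      sw_idx[cand[ceiling(2 * length(cand) / 3)]] <- st
    }
    blocks[[ch]] <- tibble(chrom = ch, start = bstart, end = bend,
                           base_label = lab, switch_idx = sw_idx)
  }
  blocks <- bind_rows(blocks)
  tadb <- purrr::map_dfr(seq_len(nrow(genome)), function(ci) {
    ch <- genome$chrom[ci]
    nb <- floor(genome$length[ci] / bin_size)
    pos <- seq(tad_bins, nb - 1, by = tad_bins) * bin_size
    tibble(chrom = ch, pos = pos)
  })
  truth <- structure(list(genome = genome, bin_size = bin_size, bins = bins,
                          stages = stages, ko_sample = ko_sample,
                          blocks = blocks, tad_boundaries = tadb,
                          meth_lag = meth_lag,
                          pmd_onset_idx = pmd_onset_idx),
                     class = "cm_truth")
  truth$features <- plant_features(truth)
  truth
}

# Fixed fractional offsets inside a block for each feature class; DMRs are
# kept clear of LMR/UMR positions so planted classes never overlap.
plant_features <- function(truth) {
  out <- list()
  for (r in seq_len(nrow(truth$blocks))) {
    b <- truth$blocks[r, ]
    len <- b$end - b$start
    ever_a <- b$base_label == "A" || !is.na(b$switch_idx)
    ever_b <- b$base_label == "B" || !is.na(b$switch_idx)
    add <- function(class, f0, width) {
      tibble(class = class, chrom = b$chrom,
             start = round(b$start + f0 * len),
             end = round(b$start + f0 * len) + width,
             block = r)
    }
    if (ever_a) {
      out[[length(out) + 1]] <- bind_rows(
        add("LMR", 0.15, 1500), add("LMR", 0.45, 1500),
        add("LMR", 0.75, 1500), add("UMR", 0.30, 4000)
      )
    }
    if (ever_b) {
      out[[length(out) + 1]] <-
        tibble(class = "PMD", chrom = b$chrom,
               start = round(b$start + 0.15 * len),
               end = round(b$start + 0.85 * len), block = r)
    }
    if (b$base_label == "A" && is.na(b$switch_idx)) {
      out[[length(out) + 1]] <- bind_rows(add("DMR", 0.55, 1320),
                                          add("DMR", 0.90, 1320))
    }
  }
  arrange(bind_rows(out), class, chrom, start)
}

#' @export
print.cm_truth <- function(x, ...) {
  cat(sprintf(
    "<cm_truth> %d chromosome(s), %d bins of %g bp, stages: %s (+ %s)\n",
    nrow(x$genome), nrow(x$bins), x$bin_size,
    paste(x$stages, collapse = " > "), x$ko_sample))
  invisible(x)
}

stage_index <- function(truth, stage) {
  if (stage == truth$ko_sample) return(length(truth$stages))
  i <- match(stage, truth$stages)
  if (is.na(i)) stopf("unknown stage: %s", stage)
  i
}

block_labels_at <- function(truth, stage_idx) {
  b <- truth$blocks
  flip <- !is.na(b$switch_idx) & stage_idx >= b$switch_idx
  ifelse(flip, ifelse(b$base_label == "A", "B", "A"), b$base_label)
}

# compartment label per block with the methylation lag applied
meth_block_labels_at <- function(truth, stage_idx) {
  block_labels_at(truth, max(1L, stage_idx - truth$meth_lag))
}

#' Planted compartment labels per bin at a stage
#'
#' @param truth A [cohort_truth()].
#' @param stage Stage name (or the knockout sample, which shares the adult
#'   truth).
#' @return Bin table with a `label` column.
#' @export
truth_labels <- function(truth, stage) {
  idx <- stage_index(truth, stage)
  lab <- block_labels_at(truth, idx)
  bin_lab <- rep(NA_character_, nrow(truth$bins))
  for (r in seq_len(nrow(truth$blocks))) {
    sel <- truth$bins$chrom == truth$blocks$chrom[r] &
      truth$bins$start >= truth$blocks$start[r] &
      truth$bins$start < truth$blocks$end[r]
    bin_lab[sel] <- lab[r]
  }
  out <- as_tibble(truth$bins)
  out$label <- bin_lab
  out
}

#' Planted feature intervals present at a stage
#'
#' LMRs/UMRs exist where the lagged compartment label is A, PMDs where it
#' is B (and the stage has reached the PMD onset), DMRs and CHH-positive
#' regions are stage-independent interval sets (DMRs are defined for the
#' adult-vs-knockout contrast; CHH-positive regions are the adult A
#' compartment).
#'
#' @param truth A [cohort_truth()].
#' @param class One of `"LMR"`, `"UMR"`, `"PMD"`, `"DMR"`,
#'   `"CHH_positive"`, `"switch"`.
#' @param stage Stage name; ignored for `"DMR"` and `"CHH_positive"`.
#' @return Tibble of intervals.
#' @export
truth_features <- function(truth, class, stage = "adult") {
  idx <- stage_index(truth, stage)
  if (class == "CHH_positive") {
    lab <- block_labels_at(truth, length(truth$stages))
    b <- truth$blocks[lab == "A", c("chrom", "start", "end")]
    return(b)
  }
  if (class == "switch") {
    keep <- !is.na(truth$blocks$switch_idx) &
      truth$blocks$switch_idx <= idx
    b <- truth$blocks[keep, , drop = FALSE]
    lab <- block_labels_at(truth, idx)[keep]
    out <- b[, c("chrom", "start", "end")]
    out$name <- paste0(ifelse(lab == "A", "B->A", "A->B"), "@",
                       truth$stages[b$switch_idx])
    return(out)
  }
  if (class == "DMR") {
    return(truth$features[truth$features$class == "DMR",
                          c("chrom", "start", "end")])
  }
  mlab <- meth_block_labels_at(truth, idx)
  f <- truth$features[truth$features$class == class, , drop = FALSE]
  present <- switch(class,
    LMR = mlab[f$block] == "A",
    UMR = mlab[f$block] == "A",
    PMD = mlab[f$block] == "B" & idx >= truth$pmd_onset_idx,
    stopf("unknown feature class: %s", class)
  )
  f[present, c("chrom", "start", "end")]
}

#' Hi-C generator parameters
#'
#' Contacts follow a multiplicative plaid model: the expected count at bin
#' distance `d` decays as `(1 + d)^-alpha`, is multiplied by `1 + epsilon`
#' for same-compartment pairs and `1 - epsilon * kappa` for
#' cross-compartment pairs, and by `1 + tau` for pairs inside the same
#' TAD; `n_reads` read pairs per chromosome are then drawn multinomially.
#'
#' @param alpha Distance-decay exponent (> 0, default 1).
#' @param epsilon Plaid (checkerboard) strength (default 0.4).
#' @param kappa Cross-compartment attenuation factor; `epsilon * kappa`
#'   must stay below 1 (default 1).
#' @param tau Within-TAD contact boost (default 1).
#' @param n_reads Total sampled contacts per chromosome (default 1e6).
#' @param seed Generator seed.
#' @return Parameter list.
#' @export
hic_params <- function(alpha = 1, epsilon = 0.4, kappa = 1, tau = 1,
                       n_reads = 1e6, seed = 1L) {
  stopifnot(alpha > 0, epsilon >= 0, tau >= 0, n_reads >= 0,
            epsilon * kappa < 1)
  list(alpha = alpha, epsilon = epsilon, kappa = kappa, tau = tau,
       n_reads = n_reads, seed = as.integer(seed))
}

#' Methylome generator parameters
#'
#' @param coverage Mean per-CpG coverage (Poisson; default 12).
#' @param cpg_spacing Mean CpG spacing in bp (geometric; default 100).
#' @param fmr_mean_a,fmr_mean_b Mean fully-methylated-region level in
#'   A and B compartments (Beta with concentration `fmr_conc`; defaults
#'   0.88 and 0.95 — inactive chromatin of undifferentiated cells is the
#'   more methylated).
#' @param fmr_conc Beta concentration of FMR levels (default 50).
#' @param lmr_mean,umr_mean Mean levels of LMRs and UMRs (defaults 0.12,
#'   0.04).
#' @param pmd_range Range of the per-CpG uniform PMD levels (default
#'   `c(0.3, 0.7)`, a disordered intermediate methylation).
#' @param dmr_level,dmr_ko_level Planted DMR levels in the adult and
#'   knockout samples (defaults 0.92, 0.18; the knockout delta of 0.74 is
#'   well above the 0.5 floor the truth model requires).
#' @param chh_spacing CHH site spacing in bp (default 150).
#' @param chh_coverage Mean per-CHH coverage (Poisson; default 8).
#' @param chh_rate,chh_background CHH methylation rate inside CHH-positive
#'   regions (adult only) and elsewhere (defaults 0.12, 0.004).
#' @param seed Generator seed.
#' @return Parameter list.
#' @export
methyl_params <- function(coverage = 12, cpg_spacing = 100,
                          fmr_mean_a = 0.88, fmr_mean_b = 0.95,
                          fmr_conc = 50, lmr_mean = 0.12, umr_mean = 0.04,
                          pmd_range = c(0.3, 0.7), dmr_level = 0.92,
                          dmr_ko_level = 0.18, chh_spacing = 150,
                          chh_coverage = 8, chh_rate = 0.12,
                          chh_background = 0.004, seed = 1L) {
  stopifnot(coverage >= 0, cpg_spacing >= 1,
            all(c(fmr_mean_a, fmr_mean_b, lmr_mean, umr_mean, dmr_level,
                  dmr_ko_level, chh_rate, chh_background) >= 0),
            all(c(fmr_mean_a, fmr_mean_b, lmr_mean, umr_mean, dmr_level,
                  dmr_ko_level, chh_rate, chh_background) <= 1),
            length(pmd_range) == 2, pmd_range[1] >= 0, pmd_range[2] <= 1,
            dmr_level - dmr_ko_level >= 0.5)
  list(coverage = coverage, cpg_spacing = cpg_spacing,
       fmr_mean_a = fmr_mean_a, fmr_mean_b = fmr_mean_b,
       fmr_conc = fmr_conc, lmr_mean = lmr_mean, umr_mean = umr_mean,
       pmd_range = pmd_range, dmr_level = dmr_level,
       dmr_ko_level = dmr_ko_level, chh_spacing = chh_spacing,
       chh_coverage = chh_coverage, chh_rate = chh_rate,
       chh_background = chh_background, seed = as.integer(seed))
}

#' Generate a synthetic Hi-C contact matrix for one stage
#'
#' @param truth A [cohort_truth()].
#' @param params A [hic_params()] list.
#' @param stage Stage name (the knockout sample shares the adult labels).
#' @return A raw `cm_contacts` object; deterministic for a fixed seed.
#' @export
generate_contacts <- function(truth, params = hic_params(), stage = "adult") {
  labels <- truth_labels(truth, stage)
  g <- truth$genome
  mats <- list()
  for (ch in g$chrom) {
    rows <- labels$chrom == ch
    lab <- labels$label[rows]
    n <- sum(rows)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- (1 + d)^(-params$alpha)
    same <- outer(lab, lab, "==")
    same[is.na(same)] <- TRUE
    w <- w * ifelse(same, 1 + params$epsilon,
                    1 - params$epsilon * params$kappa)
    # TAD membership: index of the domain a bin falls in
    tb <- truth$tad_boundaries$pos[truth$tad_boundaries$chrom == ch]
    dom <- findInterval(labels$start[rows], c(0, tb))
    w <- w * ifelse(outer(dom, dom, "=="), 1 + params$tau, 1)
    up <- which(upper.tri(w, diag = TRUE))
    p <- w[up] / sum(w[up])
    cnt <- with_seed(derive_seed(params$seed, "hic", stage, ch), {
      as.vector(rmultinom(1, params$n_reads, p))
    })
    m <- matrix(0, n, n)
    m[up] <- cnt
    m <- m + t(m) - diag(diag(m))
    if (any(rowSums(m) == 0)) {
      warnf("all-zero row(s) in generated matrix for %s (n_reads too small?)",
            ch)
    }
    mats[[ch]] <- m
  }
  new_contacts(truth$bins, mats)
}

# CpG layout (positions + static per-CpG randomness), shared by all stages
# and genotypes.  Inside planted DMR intervals the geometric spacing is
# replaced by a fixed 120-bp grid so every planted DMR carries 11 CpGs with
# small gaps by construction.
cpg_layout <- function(truth, params, ch) {
  len <- genome_length(truth$genome, ch)
  dmr <- truth$features[truth$features$class == "DMR" &
                          truth$features$chrom == ch, , drop = FALSE]
  with_seed(derive_seed(params$seed, "cpg-layout", ch), {
    n_guess <- ceiling(len / params$cpg_spacing * 1.3) + 100
    gaps <- rgeom(n_guess, 1 / params$cpg_spacing) + 1
    pos <- cumsum(gaps)
    while (pos[length(pos)] < len) {
      gaps <- rgeom(n_guess, 1 / params$cpg_spacing) + 1
      pos <- c(pos, pos[length(pos)] + cumsum(gaps))
    }
    pos <- pos[pos < len - 1]
    if (nrow(dmr) > 0) {
      indmr <- in_regions(rep(ch, length(pos)), pos, dmr)
      pos <- pos[!indmr]
      grid <- unlist(lapply(seq_len(nrow(dmr)), function(i) {
        seq(dmr$start[i] + 60, dmr$end[i] - 60, by = 120)
      }))
      pos <- sort(c(pos, grid))
    }
    n <- length(pos)
    tibble(pos = pos,
           u = runif(n),        # quantile draw for FMR/PMD levels
           in_dmr = if (nrow(dmr) > 0)
             in_regions(rep(ch, n), pos, dmr) else rep(FALSE, n))
  })
}

# Per-CpG methylation levels for one chromosome at one stage/genotype.
stage_levels <- function(truth, params, ch, stage, layout) {
  idx <- stage_index(truth, stage)
  labels <- truth_labels(truth, stage)
  mlab <- meth_block_labels_at(truth, idx)
  bl <- truth$blocks[truth$blocks$chrom == ch, , drop = FALSE]
  bl_rows <- which(truth$blocks$chrom == ch)
  pos <- layout$pos
  # base: FMR Beta level via shared uniform quantile, A vs B by lagged label
  blk <- findInterval(pos, bl$start)
  blk[blk < 1] <- 1
  lab <- mlab[bl_rows][blk]
  shape_a <- c(params$fmr_mean_a, 1 - params$fmr_mean_a) * params$fmr_conc
  shape_b <- c(params$fmr_mean_b, 1 - params$fmr_mean_b) * params$fmr_conc
  lev <- ifelse(lab == "A",
                stats::qbeta(layout$u, shape_a[1], shape_a[2]),
                stats::qbeta(layout$u, shape_b[1], shape_b[2]))
  # PMDs: disordered uniform per-CpG levels
  pmd <- truth_features(truth, "PMD", stage)
  pmd <- pmd[pmd$chrom == ch, , drop = FALSE]
  if (nrow(pmd) > 0) {
    sel <- in_regions(rep(ch, length(pos)), pos, pmd)
    lev[sel] <- params$pmd_range[1] +
      diff(params$pmd_range) * layout$u[sel]
  }
  # LMRs / UMRs: per-region low levels (deterministic per region)
  for (class in c("LMR", "UMR")) {
    f <- truth_features(truth, class, stage)
    f <- f[f$chrom == ch, , drop = FALSE]
    mean_lev <- if (class == "LMR") params$lmr_mean else params$umr_mean
    if (nrow(f) > 0) {
      sel <- in_regions(rep(ch, length(pos)), pos, f)
      lev[sel] <- mean_lev
    }
  }
  # planted DMR levels (adult high, knockout low)
  if (any(layout$in_dmr)) {
    lev[layout$in_dmr] <- if (stage == truth$ko_sample)
      params$dmr_ko_level else params$dmr_level
  }
  pmin(pmax(lev, 0), 1)
}

# Binomial counts with a bounded-deviation emission inside planted DMRs:
# within a DMR, draws whose realized level strays more than 0.15 from the
# planted level are redrawn, so the planted adult-vs-knockout contrast is
# realized at every CpG (mean delta >= 0.4, per-CpG delta >= 0.1).
draw_counts <- function(cov, lev, bounded) {
  meth <- rbinom(length(cov), cov, lev)
  if (any(bounded)) {
    for (t in 1:50) {
      off <- bounded & cov > 0 & abs(meth / pmax(cov, 1) - lev) > 0.15
      if (!any(off)) break
      meth[off] <- rbinom(sum(off), cov[off], lev[off])
    }
    off <- bounded & cov > 0 & abs(meth / pmax(cov, 1) - lev) > 0.15
    meth[off] <- round(cov[off] * lev[off])
  }
  meth
}

chrom_cpg_counts <- function(truth, params, ch, stage, layout) {
  lev <- stage_levels(truth, params, ch, stage, layout)
  with_seed(derive_seed(params$seed, "cpg-counts", stage, ch), {
    n <- length(lev)
    cov <- rpois(n, params$coverage)
    if (any(layout$in_dmr)) {
      # guarantee DMR CpGs pass the coverage filter in every sample
      cov[layout$in_dmr] <- 4 + rpois(sum(layout$in_dmr),
                                      max(params$coverage - 4, 0))
    }
    meth <- draw_counts(cov, lev, layout$in_dmr)
    list(cov = cov, meth = meth)
  })
}

#' Generate a synthetic methylome for one stage
#'
#' CpG positions are laid down once per genome and shared across all
#' stages and genotypes, so per-CpG differences are always well defined.
#' Counts are binomial draws from the planted per-CpG level at the stage;
#' each CpG is emitted as a forward- and a reverse-strand record (the
#' reverse cytosine at position + 1) so strand combining is exercised.
#' The knockout sample carries exactly the adult counts outside planted
#' DMR regions and independently drawn hypomethylated counts inside them,
#' isolating the planted differential signal; its CHH records have zero
#' methylated counts. CHH records exist only for the adult and knockout
#' samples; methylated CHH is confined to the CHH-positive regions of the
#' truth (adult A compartments) above a small genome-wide background.
#'
#' @param truth A [cohort_truth()].
#' @param params A [methyl_params()] list.
#' @param stage Stage name or the knockout sample name.
#' @return Methylation call tibble (`chrom`, `pos`, `strand`, `context`,
#'   `meth`, `total`), zero-coverage records dropped.
#' @export
generate_methylome <- function(truth, params = methyl_params(),
                               stage = "adult") {
  stage_index(truth, stage)  # validates
  is_ko <- stage == truth$ko_sample
  out <- list()
  for (ch in truth$genome$chrom) {
    layout <- cpg_layout(truth, params, ch)
    if (params$coverage == 0) next
    cc <- chrom_cpg_counts(truth, params, ch, stage, layout)
    if (is_ko) {
      # splice: adult counts outside DMRs, knockout draws inside
      adult <- chrom_cpg_counts(truth, params, ch, "adult", layout)
      keep <- !layout$in_dmr
      cc$cov[keep] <- adult$cov[keep]
      cc$meth[keep] <- adult$meth[keep]
    }
    strands <- with_seed(derive_seed(params$seed, "strand", stage, ch), {
      cov_f <- rbinom(length(cc$cov), cc$cov, 0.5)
      meth_f <- stats::rhyper(length(cc$cov), cc$meth, cc$cov - cc$meth,
                              cov_f)
      list(cov_f = cov_f, meth_f = meth_f)
    })
    cpg <- bind_rows(
      tibble(chrom = ch, pos = layout$pos, strand = "+", context = "CpG",
             meth = strands$meth_f, total = strands$cov_f),
      tibble(chrom = ch, pos = layout$pos + 1, strand = "-",
             context = "CpG", meth = cc$meth - strands$meth_f,
             total = cc$cov - strands$cov_f)
    )
    out[[length(out) + 1]] <- cpg[cpg$total > 0, , drop = FALSE]
    if (stage %in% c("adult", truth$ko_sample)) {
      chh_pos <- seq(10, genome_length(truth$genome, ch) - 2,
                     by = params$chh_spacing)
      pos_reg <- truth_features(truth, "CHH_positive")
      pos_reg <- pos_reg[pos_reg$chrom == ch, , drop = FALSE]
      rate <- ifelse(in_regions(rep(ch, length(chh_pos)), chh_pos, pos_reg),
                     params$chh_rate, params$chh_background)
      chh <- with_seed(derive_seed(params$seed, "chh", stage, ch), {
        cov <- rpois(length(chh_pos), params$chh_coverage)
        meth <- if (is_ko) rep(0L, length(chh_pos)) else
          rbinom(length(chh_pos), cov, rate)
        tibble(chrom = ch, pos = chh_pos, strand = "+", context = "CHH",
               meth = meth, total = cov)
      })
      out[[length(out) + 1]] <- chh[chh$total > 0, , drop = FALSE]
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), pos = double(), strand = character(),
                  context = character(), meth = integer(),
                  total = integer()))
  }
  arrange(bind_rows(out), chrom, pos)
}

#' Generate a per-bin activity (expression proxy) track for one stage
#'
#' Log-normal per-bin values, higher in active (A) chromatin; like the
#' planted methylome features, expression follows compartment switches
#' with the truth model's lag.
#'
#' @param truth A [cohort_truth()].
#' @param stage Stage name.
#' @param seed Seed for the log-normal noise.
#' @return A [bin_track()].
#' @export
generate_activity <- function(truth, stage = "adult", seed = 1L) {
  idx <- stage_index(truth, stage)
  mlab <- meth_block_labels_at(truth, idx)
  blocks <- truth$blocks
  lab <- rep(NA_character_, nrow(truth$bins))
  for (r in seq_len(nrow(blocks))) {
    sel <- truth$bins$chrom == blocks$chrom[r] &
      truth$bins$start >= blocks$start[r] &
      truth$bins$start < blocks$end[r]
    lab[sel] <- mlab[r]
  }
  v <- with_seed(derive_seed(seed, "activity", stage), {
    stats::rlnorm(nrow(truth$bins),
                  meanlog = ifelse(lab == "A", 0.7, -1.6), sdlog = 0.5)
  })
  v[is.na(lab)] <- NA_real_
  bin_track(truth$bins, v)
}

#' Write the planted ground truth as BED files
#'
#' One BED per feature class and stage (compartment labels, switch blocks,
#' LMR/UMR/PMD), plus stage-independent DMR, CHH-positive and TAD-boundary
#' files and a chromosome-sizes file.
#'
#' @param truth A [cohort_truth()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
truth_report <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    write_bed(x, p)
    files <<- c(files, p)
  }
  for (st in truth$stages) {
    lb <- truth_labels(truth, st)
    wr(tibble(chrom = lb$chrom, start = lb$start, end = lb$end,
              name = lb$label), sprintf("compartments_%s.bed", st))
    wr(truth_features(truth, "switch", st), sprintf("switches_%s.bed", st))
    for (cl in c("LMR", "UMR", "PMD")) {
      wr(truth_features(truth, cl, st),
         sprintf("%s_%s.bed", tolower(cl), st))
    }
  }
  wr(truth_features(truth, "DMR"), "dmr.bed")
  wr(truth_features(truth, "CHH_positive"), "chh_positive.bed")
  wr(tibble(chrom = truth$tad_boundaries$chrom,
            start = truth$tad_boundaries$pos,
            end = truth$tad_boundaries$pos + 1), "tad_boundaries.bed")
  write_chrom_sizes(truth$genome, file.path(dir, "chrom.sizes"))
  files <- c(files, file.path(dir, "chrom.sizes"))
  invisible(files)
}

#' Jaccard index of two interval sets
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return Intersection bases over union bases (0 when both empty).
#' @export
interval_jaccard <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  inter <- sum(overlap_bases(a$chrom, a$start, a$end, b))
  total_a <- sum(a$end - a$start)
  total_b <- sum(b$end - b$start)
  inter / (total_a + total_b - inter)
}
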