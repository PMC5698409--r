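new_enrichment <- function(df) {
  structure(df, class = c("cm_enrichment", class(df)))
}

#' @export
tidy.cm_enrichment <- function(x, ...) {
  as_tibble(unclass(x))
}

# Per-chromosome prefix sums of A-labelled and assigned bases on the bin
# grid; gives O(log n) per-interval base counts in each label.
label_prefix <- function(track) {
  lapply(setNames(unique(track$chrom), unique(track$chrom)), function(ch) {
    d <- track[track$chrom == ch, , drop = FALSE]
    w <- d$end - d$start
    list(start = d$start, end = d$end,
         cum_a = cumsum(ifelse(!is.na(d$label) & d$label == "A", w, 0)),
         cum_b = cumsum(ifelse(!is.na(d$label) & d$label == "B", w, 0)))
  })
}

# bases of [start, end) falling in A- and B-labelled bins
interval_label_bases <- function(pref, chrom, start, end) {
  out_a <- numeric(length(chrom)); out_b <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    p <- pref[[ch]]
    if (is.null(p)) next
    sel <- which(chrom == ch)
    upto <- function(cum, pos) {
      # covered bases in labelled bins up to position pos
      i <- findInterval(pos, p$start)
      full <- ifelse(i >= 2, cum[pmax(i - 1, 1)], 0)
      part <- ifelse(i >= 1,
                     (cum[pmax(i, 1)] - ifelse(i >= 2, cum[pmax(i - 1, 1)], 0)) /
                       (p$end[pmax(i, 1)] - p$start[pmax(i, 1)]) *
                       pmax(0, pmin(pos, p$end[pmax(i, 1)]) - p$start[pmax(i, 1)]),
                     0)
      full + part
    }
    out_a[sel] <- upto(p$cum_a, end[sel]) - upto(p$cum_a, start[sel])
    out_b[sel] <- upto(p$cum_b, end[sel]) - upto(p$cum_b, start[sel])
  }
  list(a = out_a, b = out_b)
}

frac_a_of_features <- function(pref, chrom, start, end) {
  lb <- interval_label_bases(pref, chrom, start, end)
  width <- end - start
  assign <- ifelse(lb$a / width > 0.5, "A",
                   ifelse(lb$b / width > 0.5, "B", NA_character_))
  n_a <- sum(assign == "A", na.rm = TRUE)
  n_b <- sum(assign == "B", na.rm = TRUE)
  list(frac_a = if (n_a + n_b > 0) n_a / (n_a + n_b) else NA_real_,
       n_assigned = n_a + n_b, n_unassigned = sum(is.na(assign)))
}

#' Compartment localization of a feature set
#'
#' Each feature is assigned to A or B by majority base overlap (> 50% of
#' its bases; exact ties stay unassigned), the fraction of assigned
#' features in A is compared with the genomic A fraction, and an empirical
#' p-value is computed by circularly shifting the whole feature set along
#' each chromosome (a permutation null that preserves the feature spacing
#' and the compartment autocorrelation).
#'
#' @param features Interval tibble.
#' @param track A `cm_compartments` track (or any bin table with a `label`
#'   column).
#' @param n_perm Number of circular shifts (default 1000).
#' @param seed Permutation seed.
#' @return A one-row `cm_enrichment` tibble: `n_features`, `n_assigned`,
#'   `frac_a`, `genome_frac_a`, `fold` and `p_value` (one-sided, for
#'   enrichment in A).
#' @export
feature_compartment_fractions <- function(features, track, n_perm = 1000,
                                          seed = 1L) {
  if (nrow(features) == 0) stopf("empty feature set")
  pref <- label_prefix(track)
  g <- bins_genome(track)
  obs <- frac_a_of_features(pref, features$chrom, features$start,
                            features$end)
  w <- track$end - track$start
  assigned <- !is.na(track$label)
  genome_frac_a <- sum(w[assigned & track$label == "A"]) / sum(w[assigned])
  perm <- with_seed(derive_seed(seed, "featperm"), {
    vapply(seq_len(n_perm), function(i) {
      sh_chrom <- features$chrom
      off <- setNames(
        floor(runif(nrow(g)) * g$length), g$chrom)
      len <- genome_length(g, sh_chrom)
      s2 <- (features$start + off[sh_chrom]) %% len
      e2 <- s2 + (features$end - features$start)
      # features wrapping past the end are wrapped to the origin
      wrap <- e2 > len
      s2[wrap] <- 0
      e2[wrap] <- features$end[wrap] - features$start[wrap]
      frac_a_of_features(pref, sh_chrom, s2, e2)$frac_a
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  p <- (1 + sum(perm >= obs$frac_a)) / (length(perm) + 1)
  new_enrichment(tibble(
    n_features = nrow(features),
    n_assigned = obs$n_assigned,
    n_unassigned = obs$n_unassigned,
    frac_a = obs$frac_a,
    genome_frac_a = genome_frac_a,
    fold = obs$frac_a / genome_frac_a,
    p_value = p,
    n_perm = length(perm)
  ))
}

#' Enrichment of a signal track in A compartments or in a region set
#'
#' Computes the ratio of the mean signal inside a selection (A-labelled
#' compartment bins, or bins overlapping `regions`) to the genome-wide
#' mean, with an empirical p-value from circular shifts of the signal
#' values along each chromosome. Signal bins of any size are mapped to
#' the compartment bin containing their start. With `context` intervals
#' the comparison is restricted to signal bins inside the context first
#' (e.g. CHH enrichment in A within fully methylated regions).
#'
#' @param track A [bin_track()] (e.g. a [bin_chh()] result).
#' @param compartments Optional `cm_compartments` track; selection = bins
#'   labelled A.
#' @param regions Optional interval tibble; selection = signal bins whose
#'   start lies in a region (used when `compartments` is `NULL`).
#' @param context Optional interval tibble restricting the universe.
#' @param n_perm Number of circular shifts (default 1000).
#' @param seed Permutation seed.
#' @return A one-row `cm_enrichment` tibble with `mean_selected`,
#'   `mean_overall`, `fold`, `p_value`; `note` is `"no signal"` when the
#'   overall mean is zero (fold undefined).
#' @export
signal_compartment_enrichment <- function(track, compartments = NULL,
                                          regions = NULL, context = NULL,
                                          n_perm = 1000, seed = 1L) {
  scope <- !is.na(track$value)
  if (!is.null(context)) {
    scope <- scope & in_regions(track$chrom, track$start, context)
  }
  if (!any(scope)) stopf("no unmasked signal bins in scope")
  if (!is.null(compartments)) {
    cidx <- pos_to_bin(compartments, track$chrom, track$start)
    sel <- !is.na(cidx) & !is.na(compartments$label[cidx]) &
      compartments$label[cidx] == "A"
  } else if (!is.null(regions)) {
    sel <- in_regions(track$chrom, track$start, regions)
  } else {
    stopf("give either `compartments` or `regions`")
  }
  sel <- sel & scope
  if (!any(sel)) stopf("no unmasked signal bins selected")
  mean_overall <- mean(track$value[scope])
  mean_sel <- mean(track$value[sel])
  if (mean_overall == 0) {
    return(new_enrichment(tibble(
      n_selected = sum(sel), n_total = sum(scope),
      mean_selected = mean_sel, mean_overall = mean_overall,
      fold = NA_real_, p_value = NA_real_, n_perm = 0L,
      note = "no signal")))
  }
  # circular shifts of the signal vector within each chromosome
  chroms <- unique(track$chrom)
  idx_by_chrom <- lapply(setNames(chroms, chroms),
                         function(ch) which(track$chrom == ch))
  perm <- with_seed(derive_seed(seed, "sigperm"), {
    vapply(seq_len(n_perm), function(i) {
      shifted <- track$value
      for (ch in chroms) {
        ix <- idx_by_chrom[[ch]]
        k <- 1L + floor(runif(1) * (length(ix) - 1L))
        shifted[ix] <- track$value[ix][c((k + 1):length(ix), 1:k)]
      }
      m_all <- mean(shifted[scope], na.rm = TRUE)
      if (!is.finite(m_all) || m_all == 0) return(NA_real_)
      mean(shifted[sel], na.rm = TRUE) / m_all
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  fold <- mean_sel / mean_overall
  p <- (1 + sum(perm >= fold)) / (length(perm) + 1)
  new_enrichment(tibble(
    n_selected = sum(sel), n_total = sum(scope),
    mean_selected = mean_sel, mean_overall = mean_overall,
    fold = fold, p_value = p, n_perm = length(perm),
    note = NA_character_))
}

#' Mean CpG methylation in common compartments, per stage
#'
#' Averages CpG methylation over the bins whose compartment label is A
#' (resp. B) in every stage of a cohort, for each stage's methylome.
#'
#' @param calls_by_stage Named, ordered list of strand-combined CpG call
#'   sets (>= 2 stages).
#' @param common A [common_compartments()] table.
#' @param min_coverage Per-CpG coverage filter (default 4).
#' @return Tibble with one row per stage: `stage`, `mean_a`, `mean_b`,
#'   `diff` (A minus B).
#' @export
compartment_mean_methylation_by_stage <- function(calls_by_stage, common,
                                                  min_coverage = 4) {
  if (length(calls_by_stage) < 2) stopf("need >= 2 stages")
  reg_a <- common[common$status == "common-A", c("chrom", "start", "end")]
  reg_b <- common[common$status == "common-B", c("chrom", "start", "end")]
  if (nrow(reg_a) == 0 || nrow(reg_b) == 0) stopf("no common bins")
  purrr::imap_dfr(calls_by_stage, function(calls, st) {
    ma <- mean_methylation_in(calls, reg_a, min_coverage)
    mb <- mean_methylation_in(calls, reg_b, min_coverage)
    tibble(stage = st, mean_a = ma, mean_b = mb, diff = ma - mb)
  })
}

#' Methylome and expression profile of selected regions across stages
#'
#' For a fixed region selection (typically compartment-switch blocks from
#' [differential_compartments()]), tabulates per stage the LMR count, PMD
#' base coverage, mean expression and mean CpG methylation inside the
#' regions.
#'
#' @param regions Interval tibble (non-empty).
#' @param segments_by_stage Named, ordered list of [segment_methylome()]
#'   outputs.
#' @param expression_by_stage Named list of [bin_track()]s (same names).
#' @param calls_by_stage Named list of strand-combined CpG call sets.
#' @param min_coverage Per-CpG coverage filter (default 4).
#' @return Tibble with one row per stage: `stage`, `lmr_count`,
#'   `pmd_bases`, `mean_expression`, `mean_methylation`.
#' @export
stage_profiles <- function(regions, segments_by_stage, expression_by_stage,
                           calls_by_stage, min_coverage = 4) {
  if (nrow(regions) == 0) stopf("empty region selection")
  regions <- merge_intervals(regions)
  purrr::imap_dfr(segments_by_stage, function(segs, st) {
    lmr <- segs[segs$class == "LMR", , drop = FALSE]
    mid_in <- if (nrow(lmr) > 0) {
      in_regions(lmr$chrom, (lmr$start + lmr$end) %/% 2, regions)
    } else logical(0)
    pmd <- segs[segs$class == "PMD", , drop = FALSE]
    pmd_bases <- if (nrow(pmd) > 0) {
      sum(overlap_bases(pmd$chrom, pmd$start, pmd$end, regions))
    } else 0
    expr <- expression_by_stage[[st]]
    in_reg <- in_regions(expr$chrom, expr$start, regions)
    mean_expr <- mean(expr$value[in_reg], na.rm = TRUE)
    tibble(stage = st,
           lmr_count = sum(mid_in),
           pmd_bases = pmd_bases,
           mean_expression = mean_expr,
           mean_methylation = mean_methylation_in(calls_by_stage[[st]],
                                                  regions, min_coverage))
  })
}

#' PCA embedding of samples from per-bin (or per-CpG) profiles
#'
#' Columns with a missing value in any sample are dropped, the rest are
#' mean-centered, and the samples are embedded on the top two principal
#' components. Axis signs are fixed so the first sample has non-negative
#' coordinates.
#'
#' @param profiles A samples x variables numeric matrix with rownames, or
#'   a named list of [bin_track()]s (their `value` columns become rows).
#' @return A `cm_embedding` tibble: `sample`, `PC1`, `PC2`; attribute
#'   `var_explained` has the variance fractions of the two axes.
#' @export
sample_pca <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    m <- do.call(rbind, lapply(profiles, function(t) t$value))
    rownames(m) <- names(profiles)
  } else {
    m <- profiles
  }
  if (nrow(m) < 3) stopf("need >= 3 samples")
  ok <- colSums(!is.finite(m)) == 0
  if (sum(ok) < 3) stopf("fewer than 3 jointly unmasked columns")
  x <- scale(m[, ok, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(x)
  d2 <- sv$d^2
  k <- min(2, length(sv$d))
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k, k)
  if (k < 2) scores <- cbind(scores, 0)
  for (ax in 1:2) {
    if (isTRUE(scores[1, ax] < 0)) scores[, ax] <- -scores[, ax]
  }
  ve <- if (sum(d2) > 0) d2[1:2] / sum(d2) else c(0, 0)
  out <- tibble(sample = rownames(m) %||% paste0("s", seq_len(nrow(m))),
                PC1 = scores[, 1], PC2 = scores[, 2])
  attr(out, "var_explained") <- ve
  class(out) <- c("cm_embedding", class(out))
  out
}

#' @export
glance.cm_embedding <- function(x, ...) {
  ve <- attr(x, "var_explained")
  tibble(n_samples = nrow(x), var_pc1 = ve[1], var_pc2 = ve[2])
}

#' @export
tidy.cm_embedding <- function(x, ...) as_tibble(unclass(x))
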