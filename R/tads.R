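#' Multi-scale TAD separation (insulation) score
#'
#' For each window depth between `min_depth` and `max_depth` (step
#' `step`), the diamond mean at bin `i` is the mean balanced contact
#' between the `w` bins upstream and the `w` bins downstream of the
#' inter-bin junction at `i` (`w = depth / bin size`, rounded to the
#' nearest whole bin count). Each per-scale profile is z-transformed per
#' chromosome, and the final score is the mean across scales. Bins within
#' `w` of a chromosome end are masked at that scale; TAD boundaries appear
#' as local minima of the score.
#'
#' @param x A balanced `cm_contacts`.
#' @param min_depth,max_depth,step Window depths in bp (defaults 3e5, 3e6,
#'   3e5).
#' @return A [bin_track()] with the score in `value`; attribute `scales`
#'   lists the window sizes used (in bins).
#' @export
tad_score <- function(x, min_depth = 3e5, max_depth = 3e6, step = 3e5) {
  if (max_depth < min_depth) stopf("max_depth < min_depth")
  if (!x$balanced) stopf("tad_score() needs a balanced matrix")
  s <- bins_size(x$bins)
  scales <- unique(pmax(1L, as.integer(round(seq(min_depth, max_depth,
                                                 by = step) / s))))
  g <- bins_genome(x$bins)
  score <- rep(NA_real_, nrow(x$bins))
  for (ch in g$chrom) {
    rows <- which(x$bins$chrom == ch)
    m <- x$mats[[ch]]
    n <- nrow(m)
    per_scale <- matrix(NA_real_, n, length(scales))
    for (si in seq_along(scales)) {
      w <- scales[si]
      if (2 * w > n) next
      v <- rep(NA_real_, n)
      for (i in (w + 1):(n - w + 1)) {
        d <- m[(i - w):(i - 1), i:(i + w - 1), drop = FALSE]
        if (any(is.finite(d))) v[i] <- mean(d, na.rm = TRUE)
      }
      mu <- mean(v, na.rm = TRUE)
      sg <- sd(v[is.finite(v)])
      if (is.finite(sg) && sg > 0) {
        per_scale[, si] <- (v - mu) / sg
      } else {
        per_scale[, si] <- v * 0
      }
    }
    score[rows] <- rowMeans(per_scale, na.rm = TRUE)
  }
  score[is.nan(score)] <- NA_real_
  out <- bin_track(x$bins, score)
  attr(out, "scales") <- scales
  out
}

# Prominence of a local minimum: the smaller of the highest levels reached
# on each side before a strictly lower value occurs (chromosome ends count
# as walls).
min_prominence_at <- function(v, i) {
  val <- v[i]
  side <- function(idx_seq) {
    peak <- -Inf
    for (j in idx_seq) {
      if (!is.finite(v[j])) next
      if (v[j] < val) break
      peak <- max(peak, v[j])
    }
    peak
  }
  left <- side(rev(seq_len(i - 1)))
  right <- side(seq((i + 1), length(v))[seq((i + 1), length(v)) <= length(v)])
  lo <- min(left, right)
  if (!is.finite(lo)) lo <- max(left, right)
  if (!is.finite(lo)) return(0)
  lo - val
}

#' Call TAD boundaries from an insulation track
#'
#' Local minima of the score with prominence at least `min_prominence` are
#' boundary candidates; candidates are accepted greedily in order of
#' ascending score, enforcing a pairwise distance of at least
#' `min_boundary_distance`.
#'
#' @param track A [tad_score()] track.
#' @param min_boundary_distance Minimum distance between reported
#'   boundaries in bp (default 4e5).
#' @param min_prominence Minimum prominence in z-units (default 0.5).
#' @return Tibble of boundaries: `chrom`, `pos` (the junction coordinate,
#'   i.e. the start of the boundary bin), `bin`, `score`, `prominence`.
#' @export
find_boundaries <- function(track, min_boundary_distance = 4e5,
                            min_prominence = 0.5) {
  out <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch)
    v <- track$value[rows]
    n <- length(v)
    if (n < 3) next
    cand <- integer()
    for (i in 2:(n - 1)) {
      if (!is.finite(v[i])) next
      lv <- v[i - 1]; rv <- v[i + 1]
      # a boundary needs flanking context: masked neighbours disqualify
      if (is.finite(lv) && is.finite(rv) && v[i] < lv && v[i] <= rv) {
        cand <- c(cand, i)
      }
    }
    if (length(cand) == 0) next
    prom <- vapply(cand, function(i) min_prominence_at(v, i), numeric(1))
    keep <- prom >= min_prominence
    cand <- cand[keep]; prom <- prom[keep]
    if (length(cand) == 0) next
    o <- order(v[cand])
    acc <- integer(); accp <- numeric()
    pos <- track$start[rows]
    for (k in o) {
      i <- cand[k]
      if (all(abs(pos[i] - pos[acc]) >= min_boundary_distance)) {
        acc <- c(acc, i); accp <- c(accp, prom[k])
      }
    }
    ord <- order(acc)
    out[[ch]] <- tibble(chrom = ch, pos = pos[acc][ord],
                        bin = track$bin[rows][acc][ord],
                        score = v[acc][ord], prominence = accp[ord])
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), pos = double(), bin = integer(),
                  score = double(), prominence = double()))
  }
  bind_rows(out)
}

#' TAD domains between consecutive boundaries
#'
#' @param boundaries A [find_boundaries()] table.
#' @param genome A [cm_genome()].
#' @return Tibble of intervals tiling each chromosome between boundaries.
#' @export
tad_domains <- function(boundaries, genome) {
  purrr::map_dfr(genome$chrom, function(ch) {
    p <- sort(boundaries$pos[boundaries$chrom == ch])
    edges <- unique(c(0, p, genome_length(genome, ch)))
    tibble(chrom = ch, start = head(edges, -1), end = tail(edges, -1))
  })
}

#' Correlation of two insulation tracks
#'
#' @param a,b [tad_score()] tracks on the same bins.
#' @return One-row tibble with `r`, `r_squared`, `n_bins`.
#' @export
tadscore_correlation <- function(a, b) {
  if (!same_bins(a, b)) stopf("tracks are on different bin tables")
  ok <- is.finite(a$value) & is.finite(b$value)
  if (sum(ok) < 3) stopf("fewer than 3 jointly unmasked bins")
  r <- cor(a$value[ok], b$value[ok])
  tibble(r = r, r_squared = r^2, n_bins = sum(ok))
}
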