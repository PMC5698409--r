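#' Define a genome as an ordered set of chromosomes
#'
#' The genome is the coordinate frame every track in the package shares.
#' Chromosome order is meaningful: it fixes the concatenation order of
#' genome-wide vectors (for example in sample PCA or genome-wide
#' correlations).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in base pairs
#'   (all >= 1).
#' @return A tibble with columns `chrom` and `length`, class `cm_genome`.
#' @examples
#' cm_genome(c("chr1", "chr2"), c(2e7, 2e7))
#' @export
cm_genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.double(length)
  if (anyDuplicated(chrom)) {
    stopf("duplicated chromosome names: %s",
          paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(!is.finite(length)) || any(length < 1)) {
    stopf("chromosome lengths must be finite and >= 1")
  }
  out <- tibble(chrom = chrom, length = length)
  class(out) <- c("cm_genome", class(out))
  out
}

genome_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stopf("unknown chromosome: %s",
          paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  genome$length[i]
}

#' Tile a genome into fixed-width bins
#'
#' Bins are half-open `[k*s, min((k+1)*s, L))` intervals tiling each
#' chromosome without gaps or overlaps; the terminal bin of a chromosome may
#' be shorter than `bin_size` and is flagged `short` (such bins are kept so
#' the bin index <-> coordinate mapping stays a bijection, but compartment
#' PCA masks them).
#'
#' @param genome A [cm_genome()].
#' @param bin_size Bin width in base pairs.
#' @return A tibble with columns `bin` (1-based genome-wide index), `chrom`,
#'   `start`, `end` (0-based half-open) and `short`; attributes `bin_size`
#'   and `genome`. Class `cm_bins`.
#' @examples
#' g <- cm_genome("chr1", 1e5)
#' cm_bins(g, 4e4)
#' @export
cm_bins <- function(genome, bin_size) {
  stopifnot(bin_size >= 1)
  bin_size <- as.double(bin_size)
  per_chrom <- purrr::map2(genome$chrom, genome$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + bin_size, len))
  })
  out <- bind_rows(per_chrom)
  out <- tibble(bin = seq_len(nrow(out)), out,
                short = (out$end - out$start) < bin_size)
  attr(out, "bin_size") <- bin_size
  attr(out, "genome") <- genome
  class(out) <- c("cm_bins", class(out))
  out
}

bins_genome <- function(bins) {
  g <- attr(bins, "genome")
  if (!is.null(g)) return(g)
  gg <- bins |>
    group_by(chrom) |>
    summarise(length = max(end), .groups = "drop")
  # preserve first-appearance order
  gg <- gg[match(unique(bins$chrom), gg$chrom), ]
  cm_genome(gg$chrom, gg$length)
}

bins_size <- function(bins) {
  s <- attr(bins, "bin_size")
  if (!is.null(s)) return(s)
  max(bins$end - bins$start)
}

# Map positions to the 1-based genome-wide bin index of their containing bin.
# Positions are 0-based; out-of-range positions yield NA.
pos_to_bin <- function(bins, chrom, pos) {
  s <- bins_size(bins)
  g <- bins_genome(bins)
  offs <- c(0, cumsum(ceiling(g$length / s)))
  ci <- match(chrom, g$chrom)
  ok <- !is.na(ci) & pos >= 0 & pos < g$length[ci]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- as.integer(offs[ci[ok]] + floor(pos[ok] / s) + 1)
  out
}

same_bins <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$chrom, b$chrom) &&
    isTRUE(all(a$start == b$start)) &&
    isTRUE(all(a$end == b$end))
}

#' Attach a value vector to a bin table
#'
#' A bin track is the package's per-bin signal container (PC1, insulation
#' score, mCHH level, expression, ...). Missing data is an explicit `NA`
#' mask, never a sentinel: 0 is a legal value.
#'
#' @param bins A [cm_bins()] table.
#' @param value Numeric vector, one value per bin; `NA` marks masked bins.
#' @return The bin table with a `value` column.
#' @export
bin_track <- function(bins, value) {
  if (length(value) != nrow(bins)) {
    stopf("value length (%d) does not match bin count (%d)",
          length(value), nrow(bins))
  }
  out <- mutate(as_tibble(bins), value = as.double(value))
  attr(out, "bin_size") <- attr(bins, "bin_size")
  attr(out, "genome") <- attr(bins, "genome")
  out
}

#' Merge intervals into a disjoint union
#'
#' @param x Tibble of intervals with `chrom`, `start`, `end`.
#' @return Sorted, merged (non-overlapping, non-touching-merged) intervals.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = double(), end = double()))
  x <- arrange(x, chrom, start, end)
  out <- x |>
    group_by(chrom) |>
    dplyr::group_modify(function(d, key) {
      st <- d$start; en <- d$end
      keep_st <- st[1]; keep_en <- en[1]
      res_st <- double(); res_en <- double()
      if (nrow(d) > 1) {
        for (i in 2:nrow(d)) {
          if (st[i] <= keep_en) {
            keep_en <- max(keep_en, en[i])
          } else {
            res_st <- c(res_st, keep_st); res_en <- c(res_en, keep_en)
            keep_st <- st[i]; keep_en <- en[i]
          }
        }
      }
      tibble(start = c(res_st, keep_st), end = c(res_en, keep_en))
    }) |>
    ungroup()
  out
}

#' Fraction of a query interval covered by a set of target intervals
#'
#' @param query A one-row tibble (or list) with `chrom`, `start`, `end`.
#' @param targets Tibble of non-overlapping (pre-merged) intervals.
#' @return A number in \[0, 1\]: fraction of query bases covered by the
#'   union of targets.
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' t <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_fraction(q, t)  # 0.5
#' @export
overlap_fraction <- function(query, targets) {
  stopifnot(query$end > query$start)
  if (nrow(targets) == 0) return(0)
  t <- targets[targets$chrom == query$chrom, , drop = FALSE]
  if (nrow(t) == 0) return(0)
  ov <- pmax(0, pmin(t$end, query$end) - pmax(t$start, query$start))
  sum(ov) / (query$end - query$start)
}

# Total overlap (bases) of each of a vector of intervals with a merged
# interval set, computed per chromosome with prefix sums over breakpoints.
overlap_bases <- function(chrom, start, end, targets) {
  out <- numeric(length(chrom))
  if (nrow(targets) == 0) return(out)
  for (ch in unique(chrom)) {
    t <- targets[targets$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(t) == 0) next
    t <- t[order(t$start), , drop = FALSE]
    # coverage prefix: cum covered bases up to position p
    cumcov <- function(p) {
      ov <- pmin(p, t$end) - t$start
      sum(pmax(0, pmin(ov, t$end - t$start)))
    }
    out[idx] <- vapply(idx, function(i) cumcov(end[i]) - cumcov(start[i]),
                       numeric(1))
  }
  out
}
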