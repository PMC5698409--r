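#' Contact matrix container
#'
#' A `cm_contacts` object holds one symmetric intra-chromosomal contact
#' matrix per chromosome on a shared [cm_bins()] frame, together with the
#' per-bin usability mask, ICE balancing weights and convergence
#' diagnostics. Only intra-chromosomal analysis is supported; inter-
#' chromosomal records are dropped at load time with a message.
#'
#' @param bins A [cm_bins()] table.
#' @param mats Named list (by chromosome) of symmetric numeric matrices.
#' @return A `cm_contacts` object.
#' @keywords internal
new_contacts <- function(bins, mats, balanced = FALSE, weights = NULL,
                         mask = NULL, diagnostics = NULL) {
  g <- bins_genome(bins)
  stopifnot(identical(sort(names(mats)), sort(g$chrom)))
  mats <- mats[g$chrom]
  for (ch in g$chrom) {
    m <- mats[[ch]]
    nb <- sum(bins$chrom == ch)
    if (!is.matrix(m) || nrow(m) != nb || ncol(m) != nb) {
      stopf("matrix for %s has wrong dimensions", ch)
    }
  }
  structure(list(bins = bins, mats = mats, balanced = balanced,
                 weights = weights, mask = mask, diagnostics = diagnostics),
            class = "cm_contacts")
}

#' @export
print.cm_contacts <- function(x, ...) {
  g <- bins_genome(x$bins)
  cat(sprintf("<cm_contacts> %d chromosome(s), %d bins, %s\n",
              nrow(g), nrow(x$bins),
              if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' Load a binned contact matrix from sparse triplet text
#'
#' Expected format: tab-separated `chrom_i`, `bin_i`, `chrom_j`, `bin_j`,
#' `count` with 0-based per-chromosome bin indices; `#` header lines are
#' ignored. If only one triangle is present the matrix is symmetrized.
#' Inter-chromosomal records are dropped (their number is messaged).
#'
#' @param path File path.
#' @param bins A [cm_bins()] table.
#' @return A raw `cm_contacts` object.
#' @export
load_matrix <- function(path, bins) {
  d <- readr::read_tsv(path,
                       col_names = c("chrom_i", "bin_i", "chrom_j", "bin_j",
                                     "count"),
                       col_types = "cicid", comment = "#", progress = FALSE)
  if (nrow(d) > 0 && any(d$count < 0)) stopf("negative count in %s", path)
  inter <- d$chrom_i != d$chrom_j
  if (any(inter)) {
    inform(sprintf("dropping %d inter-chromosomal record(s)", sum(inter)))
    d <- d[!inter, , drop = FALSE]
  }
  g <- bins_genome(bins)
  mats <- lapply(setNames(g$chrom, g$chrom), function(ch) {
    nb <- sum(bins$chrom == ch)
    m <- matrix(0, nb, nb)
    dd <- d[d$chrom_i == ch, , drop = FALSE]
    if (nrow(dd) > 0) {
      if (any(dd$bin_i < 0 | dd$bin_i >= nb | dd$bin_j < 0 | dd$bin_j >= nb)) {
        stopf("bin index out of range for %s in %s", ch, path)
      }
      dd <- dd |>
        group_by(bin_i, bin_j) |>
        summarise(count = sum(count), .groups = "drop")
      m[cbind(dd$bin_i + 1L, dd$bin_j + 1L)] <- dd$count
      # symmetrize: entries may come as one triangle or both; mirror each
      # pair and, where both triangles carry the entry, they must agree
      up <- m; up[lower.tri(up)] <- 0
      lo <- t(m); lo[lower.tri(lo)] <- 0
      both <- up > 0 & lo > 0 & upper.tri(up)
      if (any(up[both] != lo[both])) {
        stopf("inconsistent duplicate entries for %s in %s", ch, path)
      }
      up <- pmax(up, lo)
      m <- up + t(up) - diag(diag(up))
    }
    m
  })
  new_contacts(bins, mats)
}

#' Write a contact matrix as sparse triplet text
#'
#' Upper triangle (including the diagonal) only; round-trips through
#' [load_matrix()].
#'
#' @param x A `cm_contacts` object.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  g <- bins_genome(x$bins)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# bin_size=%d", as.integer(bins_size(x$bins))), con)
  for (ch in g$chrom) {
    m <- x$mats[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    o <- order(idx[, 1], idx[, 2])
    idx <- idx[o, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%d\t%s", ch, idx[, 1] - 1L, ch,
                       idx[, 2] - 1L,
                       formatC(m[idx], format = "g", digits = 10)), con)
  }
  invisible(path)
}

#' Balance a contact matrix by iterative correction (ICE)
#'
#' Per chromosome: bins whose raw coverage (row sum) is zero or falls below
#' the `low_coverage_quantile` of the nonzero row sums are masked, then
#' iterative proportional fitting equalizes the remaining row sums. The
#' stored weights satisfy `balanced[i,j] = raw[i,j] / (w[i] * w[j])`.
#'
#' @param x A raw `cm_contacts`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance: maximum relative deviation of any
#'   unmasked row sum from the mean row sum (default 1e-5).
#' @param low_coverage_quantile Fraction of lowest-coverage nonzero bins to
#'   mask (default 0.02).
#' @return A balanced `cm_contacts` with `weights`, `mask` and per-
#'   chromosome convergence diagnostics.
#' @export
ice_balance <- function(x, max_iter = 200, tol = 1e-5,
                        low_coverage_quantile = 0.02) {
  g <- bins_genome(x$bins)
  weights <- list(); mask <- list(); diags <- list()
  mats <- list()
  for (ch in g$chrom) {
    m <- x$mats[[ch]]
    rs <- rowSums(m)
    usable <- rs > 0
    if (any(usable) && low_coverage_quantile > 0) {
      thr <- quantile(rs[usable], low_coverage_quantile, names = FALSE)
      usable <- usable & rs >= thr
      if (!any(usable)) usable <- rs >= max(rs)  # keep at least the densest bin
    }
    if (!any(usable)) stopf("no usable bins on %s", ch)
    sub <- m[usable, usable, drop = FALSE]
    w <- rep(1, nrow(sub))
    dev <- Inf; it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      s <- rowSums(sub)
      ms <- mean(s)
      if (ms == 0) stopf("no usable bins on %s", ch)
      s <- s / ms
      dev <- max(abs(s - 1))
      if (dev <= tol) break
      w <- w * s
      sub <- sub / outer(s, s)
    }
    if (dev > tol) {
      warnf("ICE did not converge on %s (deviation %.3g after %d iterations)",
            ch, dev, it)
    }
    out <- matrix(NA_real_, nrow(m), ncol(m))
    out[usable, usable] <- sub
    wfull <- rep(NA_real_, nrow(m))
    wfull[usable] <- w
    mats[[ch]] <- out
    weights[[ch]] <- wfull
    mask[[ch]] <- usable
    diags[[ch]] <- tibble(chrom = ch, iterations = it, deviation = dev,
                          n_masked = sum(!usable))
  }
  new_contacts(x$bins, mats, balanced = TRUE, weights = weights, mask = mask,
               diagnostics = bind_rows(diags))
}

#' Expected contact frequency by genomic distance
#'
#' The distance-decay background: for each bin distance `d`, the mean
#' balanced contact over all unmasked pairs at that distance.
#'
#' @param x A balanced `cm_contacts`.
#' @return Named list (per chromosome) of numeric vectors `e` with
#'   `e[d + 1]` the expectation at bin distance `d`; `NA` where no unmasked
#'   pair exists.
#' @export
expected_by_distance <- function(x) {
  if (!x$balanced) stopf("expected_by_distance() needs a balanced matrix")
  g <- bins_genome(x$bins)
  lapply(setNames(g$chrom, g$chrom), function(ch) {
    m <- x$mats[[ch]]
    n <- nrow(m)
    vapply(0:(n - 1), function(d) {
      v <- m[cbind(1:(n - d), (1 + d):n)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  })
}

#' Observed/expected correlation matrices
#'
#' Divides the balanced matrix by the distance expectation and returns, per
#' chromosome, the Pearson correlation matrix of the O/E rows over unmasked
#' columns. The diagonal of the O/E matrix is excluded from the correlation
#' computation (self-contacts dominate the variance); the diagonal of the
#' returned matrix is 1 on unmasked bins.
#'
#' @param x A balanced `cm_contacts`.
#' @param expected Optional precomputed [expected_by_distance()] result.
#' @return Named list of symmetric correlation matrices (NA on masked bins).
#' @export
oe_correlation <- function(x, expected = NULL) {
  if (!x$balanced) stopf("oe_correlation() needs a balanced matrix")
  expected <- expected %||% expected_by_distance(x)
  g <- bins_genome(x$bins)
  lapply(setNames(g$chrom, g$chrom), function(ch) {
    m <- x$mats[[ch]]
    n <- nrow(m)
    e <- expected[[ch]]
    out <- matrix(NA_real_, n, n)
    ok <- x$mask[[ch]] %||% apply(m, 1, function(r) any(!is.na(r)))
    if (sum(ok) < 3) {
      warnf("fewer than 3 unmasked bins on %s; correlation masked", ch)
      return(out)
    }
    dmat <- abs(outer(1:n, 1:n, "-"))
    emat <- matrix(e[dmat + 1], n, n)
    oe <- m / emat
    oe[!is.finite(oe)] <- NA
    diag(oe) <- NA
    sub <- oe[ok, ok, drop = FALSE]
    cc <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
    diag(cc) <- 1
    out[ok, ok] <- cc
    out
  })
}

#' @export
tidy.cm_contacts <- function(x, ...) {
  g <- bins_genome(x$bins)
  purrr::map_dfr(g$chrom, function(ch) {
    m <- x$mats[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & !is.na(m) & m != 0,
                 arr.ind = TRUE)
    tibble(chrom = ch, bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
           count = m[idx])
  })
}

#' @export
glance.cm_contacts <- function(x, ...) {
  g <- bins_genome(x$bins)
  total <- sum(vapply(x$mats, function(m) {
    sum(m[upper.tri(m, diag = TRUE)], na.rm = TRUE)
  }, numeric(1)))
  d <- x$diagnostics
  tibble(
    n_chrom = nrow(g),
    n_bins = nrow(x$bins),
    n_masked = if (is.null(x$mask)) NA_integer_ else
      sum(!unlist(x$mask)),
    balanced = x$balanced,
    total_contacts = total,
    max_rowsum_deviation = if (is.null(d)) NA_real_ else max(d$deviation),
    max_iterations = if (is.null(d)) NA_integer_ else max(d$iterations)
  )
}
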