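# Independent brute-force re-implementations used as oracles; deliberately
# share no code with the package internals.

# Differential compartments by a plain per-bin scan.
oracle_differential <- function(a, b, delta = 1, min_bins = 2) {
  res <- list()
  for (ch in unique(a$chrom)) {
    ia <- a[a$chrom == ch, ]
    ib <- b[b$chrom == ch, ]
    n <- nrow(ia)
    cur <- NULL
    flush <- function(cur) {
      if (!is.null(cur) && length(cur$rows) >= min_bins) {
        res[[length(res) + 1]] <<- tibble::tibble(
          chrom = ch,
          start = ia$start[cur$rows[1]],
          end = ia$end[cur$rows[length(cur$rows)]],
          direction = cur$dir,
          n_bins = length(cur$rows))
      }
    }
    for (i in seq_len(n)) {
      pa <- ia$pc1[i]; pb <- ib$pc1[i]
      ok <- !is.na(pa) && !is.na(pb) && pa != 0 && pb != 0 &&
        ((pa > 0) != (pb > 0)) && abs(pa - pb) >= delta
      dir <- if (isTRUE(pa > 0)) "A->B" else "B->A"
      if (ok) {
        if (is.null(cur)) {
          cur <- list(rows = i, dir = dir)
        } else if (cur$dir == dir) {
          cur$rows <- c(cur$rows, i)
        } else {
          flush(cur)
          cur <- list(rows = i, dir = dir)
        }
      } else {
        flush(cur)
        cur <- NULL
      }
    }
    flush(cur)
  }
  if (length(res) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), direction = character(),
                          n_bins = integer()))
  }
  out <- dplyr::bind_rows(res)
  out[order(out$chrom, out$start), ]
}

# ICE by naive alternating row/column normalization to a fixed point.
oracle_ice <- function(m, iters = 5000) {
  for (i in seq_len(iters)) {
    rs <- rowSums(m)
    rs <- rs / mean(rs)
    m <- m / rs
    cs <- colSums(m)
    cs <- cs / mean(cs)
    m <- sweep(m, 2, cs, "/")
    if (max(abs(rowSums(m) / mean(rowSums(m)) - 1)) < 1e-12 &&
        max(abs(colSums(m) / mean(colSums(m)) - 1)) < 1e-12) break
  }
  m
}
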