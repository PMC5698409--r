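#' Parameters of the threshold-based DMR caller
#'
#' @param delta Minimum mean absolute methylation difference over a window
#'   (default 0.40).
#' @param k Window size in CpGs (default 5).
#' @param min_coverage Minimum coverage per CpG in both samples (default 4).
#' @param min_cpg_delta Minimum absolute per-CpG difference (default 0.10).
#' @param max_gap Maximum genomic distance between adjacent CpGs of a
#'   region, in bp (default 1000).
#' @return A validated parameter list.
#' @export
dmr_params <- function(delta = 0.40, k = 5, min_coverage = 4,
                       min_cpg_delta = 0.10, max_gap = 1000) {
  if (!(min_cpg_delta > 0 && min_cpg_delta <= delta && delta <= 1)) {
    stopf("need 0 < min_cpg_delta <= delta <= 1")
  }
  if (k < 2) stopf("window size k must be >= 2")
  if (min_coverage < 1) stopf("min_coverage must be >= 1")
  if (max_gap <= 0) stopf("max_gap must be > 0")
  list(delta = delta, k = k, min_coverage = min_coverage,
       min_cpg_delta = min_cpg_delta, max_gap = max_gap)
}

check_callset <- function(x, who) {
  cpg <- x[x$context == "CpG", , drop = FALSE]
  for (ch in unique(cpg$chrom)) {
    p <- cpg$pos[cpg$chrom == ch]
    if (is.unsorted(p)) stopf("%s call set is unsorted on %s", who, ch)
    if (anyDuplicated(p)) stopf("%s call set has duplicate positions on %s",
                                who, ch)
  }
  cpg
}

# Eligible CpGs shared by both samples: coverage >= c in both and per-CpG
# |delta| >= min_cpg_delta.  delta = level_a - level_b.
dmr_eligible <- function(a, b, params) {
  ca <- check_callset(a, "first")
  cb <- check_callset(b, "second")
  j <- inner_join(
    ca |> select(chrom, pos, meth_a = meth, total_a = total),
    cb |> select(chrom, pos, meth_b = meth, total_b = total),
    by = c("chrom", "pos")
  )
  j <- j |>
    filter(total_a >= params$min_coverage, total_b >= params$min_coverage) |>
    mutate(delta = meth_a / total_a - meth_b / total_b) |>
    filter(abs(delta) >= params$min_cpg_delta) |>
    arrange(chrom, pos)
  j
}

#' Call differentially methylated regions (DMRs)
#'
#' Implements a purely threshold-based sliding-window rule: eligible CpGs
#' are those covered at least `min_coverage`-fold in both samples whose
#' methylation levels differ by at least `min_cpg_delta`; a window of `k`
#' consecutive eligible CpGs (uniform difference sign, adjacent genomic
#' gaps at most `max_gap`) qualifies when its mean absolute difference
#' reaches `delta`; overlapping qualifying windows of the same sign merge
#' into one region spanning the first to the last CpG.
#'
#' @param a,b Strand-combined CpG call sets on a shared coordinate frame.
#' @param params A [dmr_params()] list.
#' @return Tibble of DMRs sorted by coordinate: `chrom`, `start`, `end`
#'   (half-open; end = last CpG + 1), `direction` (`"hyper"` when `a` is
#'   more methylated than `b`, else `"hypo"`), `n_cpg`, `mean_delta`
#'   (signed, a minus b) and list-column `deltas`.
#' @export
call_dmrs <- function(a, b, params = dmr_params()) {
  e <- dmr_eligible(a, b, params)
  out <- list()
  k <- params$k
  for (ch in unique(e$chrom)) {
    d <- e[e$chrom == ch, , drop = FALSE]
    n <- nrow(d)
    if (n < k) next
    # blocks: break at sign change or gap > max_gap
    brk <- c(TRUE, sign(d$delta[-1]) != sign(d$delta[-n]) |
               diff(d$pos) > params$max_gap)
    block <- cumsum(brk)
    for (bl in unique(block)) {
      idx <- which(block == bl)
      m <- length(idx)
      if (m < k) next
      dd <- abs(d$delta[idx])
      win_ok <- vapply(seq_len(m - k + 1),
                       function(i) mean(dd[i:(i + k - 1)]) >= params$delta,
                       logical(1))
      if (!any(win_ok)) next
      starts <- which(win_ok)
      # merge windows whose CpG ranges overlap (start difference <= k - 1)
      grp <- cumsum(c(TRUE, diff(starts) > k - 1))
      for (gname in unique(grp)) {
        ws <- starts[grp == gname]
        i0 <- idx[min(ws)]; i1 <- idx[max(ws) + k - 1]
        rows <- i0:i1
        out[[length(out) + 1]] <- tibble(
          chrom = ch,
          start = d$pos[i0],
          end = d$pos[i1] + 1,
          direction = if (d$delta[i0] > 0) "hyper" else "hypo",
          n_cpg = length(rows),
          mean_delta = mean(d$delta[rows]),
          deltas = list(d$delta[rows])
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  direction = character(), n_cpg = integer(),
                  mean_delta = double(), deltas = list()))
  }
  arrange(bind_rows(out), chrom, start)
}

#' Brute-force DMR oracle
#'
#' An independent re-derivation of [call_dmrs()] for testing on small
#' inputs: every window of `k` consecutive eligible CpGs is enumerated
#' explicitly and each rule is checked one by one; qualifying windows that
#' share a CpG are merged iteratively. No code is shared with
#' [call_dmrs()].
#'
#' @inheritParams call_dmrs
#' @return Same shape as [call_dmrs()] (without the `deltas` column).
#' @export
dmr_oracle <- function(a, b, params = dmr_params()) {
  ca <- a[a$context == "CpG", , drop = FALSE]
  cb <- b[b$context == "CpG", , drop = FALSE]
  ca <- ca[order(ca$chrom, ca$pos), , drop = FALSE]
  cb <- cb[order(cb$chrom, cb$pos), , drop = FALSE]
  for (s in list(ca, cb)) {
    key <- paste(s$chrom, s$pos)
    if (anyDuplicated(key)) stopf("duplicate positions in call set")
  }
  # verify the caller-supplied order was already sorted
  for (s in list(a[a$context == "CpG", ], b[b$context == "CpG", ])) {
    for (ch in unique(s$chrom)) {
      if (is.unsorted(s$pos[s$chrom == ch])) stopf("call set is unsorted")
    }
  }
  keyb <- paste(cb$chrom, cb$pos)
  rows <- list()
  for (i in seq_len(nrow(ca))) {
    j <- match(paste(ca$chrom[i], ca$pos[i]), keyb)
    if (is.na(j)) next
    if (ca$total[i] < params$min_coverage) next
    if (cb$total[j] < params$min_coverage) next
    dl <- ca$meth[i] / ca$total[i] - cb$meth[j] / cb$total[j]
    if (abs(dl) < params$min_cpg_delta) next
    rows[[length(rows) + 1]] <- list(chrom = ca$chrom[i], pos = ca$pos[i],
                                     delta = dl)
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  direction = character(), n_cpg = integer(),
                  mean_delta = double()))
  }
  el <- bind_rows(lapply(rows, as_tibble))
  el <- el[order(el$chrom, el$pos), , drop = FALSE]
  k <- params$k
  windows <- list()
  for (i in seq_len(nrow(el) - k + 1)) {
    w <- el[i:(i + k - 1), ]
    if (length(unique(w$chrom)) != 1) next
    if (any(diff(w$pos) > params$max_gap)) next
    if (length(unique(sign(w$delta))) != 1) next
    if (mean(abs(w$delta)) < params$delta) next
    windows[[length(windows) + 1]] <- i:(i + k - 1)
  }
  if (length(windows) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  direction = character(), n_cpg = integer(),
                  mean_delta = double()))
  }
  # iteratively merge windows sharing any CpG index
  merged <- list(windows[[1]])
  for (w in windows[-1]) {
    placed <- FALSE
    for (m in seq_along(merged)) {
      if (length(intersect(merged[[m]], w)) > 0) {
        merged[[m]] <- sort(unique(c(merged[[m]], w)))
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1]] <- w
  }
  regs <- lapply(merged, function(ix) {
    ix <- min(ix):max(ix)
    tibble(chrom = el$chrom[ix[1]],
           start = el$pos[ix[1]],
           end = el$pos[ix[length(ix)]] + 1,
           direction = if (el$delta[ix[1]] > 0) "hyper" else "hypo",
           n_cpg = length(ix),
           mean_delta = mean(el$delta[ix]))
  })
  out <- bind_rows(regs)
  out[order(out$chrom, out$start), , drop = FALSE]
}
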