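#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length in base pairs.
#'
#' @param path File path.
#' @return A [cm_genome()].
#' @export
read_chrom_sizes <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", comment = "#", progress = FALSE)
  cm_genome(d$chrom, d$length)
}

#' @rdname read_chrom_sizes
#' @param genome A [cm_genome()] to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  readr::write_tsv(as_tibble(genome), path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

strip_headers <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lines[!grepl("^(track|browser|#)", lines)]
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3+ column BED (tab-separated, 0-based half-open). Columns beyond
#' the third are kept as `name`, `score`, `strand` where present.
#'
#' @param path File path.
#' @param genome Optional [cm_genome()]; when given, records on chromosomes
#'   not listed raise an error naming them (set `unknown_chrom = "skip"` to
#'   drop them with a warning instead).
#' @param unknown_chrom `"error"` or `"skip"`.
#' @return Tibble of intervals in file order (`chrom`, `start`, `end`, and
#'   any of `name`, `score`, `strand`).
#' @export
read_bed <- function(path, genome = NULL,
                     unknown_chrom = c("error", "skip")) {
  unknown_chrom <- match.arg(unknown_chrom)
  lines <- strip_headers(readr::read_lines(path, progress = FALSE))
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3)
  if (length(bad)) stopf("malformed BED line %d in %s", bad[1], path)
  start <- suppressWarnings(as.double(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.double(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stopf("malformed BED line %d in %s (need 0 <= start < end)", bad[1], path)
  }
  out <- tibble(chrom = vapply(parts, `[[`, "", 1), start = start, end = end)
  getcol <- function(j) {
    vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_, "")
  }
  if (any(nf >= 4)) out$name <- getcol(4)
  if (any(nf >= 5)) out$score <- suppressWarnings(as.double(getcol(5)))
  if (any(nf >= 6)) out$strand <- getcol(6)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(out$chrom), genome$chrom)
    if (length(unknown)) {
      if (unknown_chrom == "error") {
        stopf("unknown chromosome(s) in %s: %s", path,
              paste(unknown, collapse = ", "))
      }
      warnf("skipping %d record(s) on unlisted chromosome(s): %s",
            sum(out$chrom %in% unknown), paste(unknown, collapse = ", "))
      out <- out[!out$chrom %in% unknown, , drop = FALSE]
    }
    too_far <- out$end > genome_length(genome, out$chrom)
    if (any(too_far)) stopf("interval beyond chromosome end in %s", path)
  }
  out
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED is positional: can only carry name/score/strand as a prefix chain
  keep <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% cols) keep <- c(keep, extra) else break
  }
  d <- as_tibble(x)[, keep, drop = FALSE]
  d$start <- format(d$start, scientific = FALSE, trim = TRUE)
  d$end <- format(d$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(d, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a bin table
#'
#' Records that align to bin boundaries map directly; others are aggregated
#' into bins by coverage-weighted mean. Bins with no record are masked
#' (`NA`). Records overlapping each other is an error.
#'
#' @param path File path.
#' @param bins A [cm_bins()] table.
#' @return A [bin_track()].
#' @export
read_bedgraph <- function(path, bins) {
  genome <- bins_genome(bins)
  lines <- strip_headers(readr::read_lines(path, progress = FALSE))
  value <- rep(NA_real_, nrow(bins))
  if (length(lines) == 0) return(bin_track(bins, value))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) stopf("malformed bedGraph line %d in %s", which(nf < 4)[1], path)
  d <- tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.double(vapply(parts, `[[`, "", 2)),
    end = as.double(vapply(parts, `[[`, "", 3)),
    val = as.double(vapply(parts, `[[`, "", 4))
  )
  if (anyNA(d$start) || anyNA(d$end) || anyNA(d$val)) {
    stopf("unparseable numeric field in %s", path)
  }
  unknown <- setdiff(unique(d$chrom), genome$chrom)
  if (length(unknown)) {
    warnf("skipping %d bedGraph record(s) on unlisted chromosome(s): %s",
          sum(d$chrom %in% unknown), paste(unknown, collapse = ", "))
    d <- d[!d$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(d) == 0) return(bin_track(bins, value))
  d <- arrange(d, chrom, start)
  ovl <- d |>
    group_by(chrom) |>
    summarise(bad = any(start < dplyr::lag(end, default = -Inf)),
              .groups = "drop")
  if (any(ovl$bad)) stopf("overlapping bedGraph records in %s", path)
  s <- bins_size(bins)
  # split every record at bin boundaries, then weighted-mean per bin
  pieces <- purrr::pmap(d, function(chrom, start, end, val) {
    b0 <- floor(start / s); b1 <- floor((end - 1) / s)
    bs <- (b0:b1) * s
    tibble(chrom = chrom,
           bstart = bs,
           w = pmin(end, bs + s) - pmax(start, bs),
           val = val)
  })
  agg <- bind_rows(pieces) |>
    group_by(chrom, bstart) |>
    summarise(val = sum(val * w) / sum(w), .groups = "drop")
  idx <- pos_to_bin(bins, agg$chrom, agg$bstart)
  if (anyNA(idx)) stopf("bedGraph record beyond chromosome end in %s", path)
  value[idx] <- agg$val
  bin_track(bins, value)
}

#' Write a bin track as bedGraph
#'
#' One record per unmasked bin (zero is a value, not missing); masked bins
#' are omitted. Values are written with 6 significant digits, so a
#' write/read round trip is the identity to that precision.
#'
#' @param track A [bin_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  d <- track[!is.na(track$value), c("chrom", "start", "end", "value")]
  lines <- sprintf("%s\t%s\t%s\t%s", d$chrom,
                   format(d$start, scientific = FALSE, trim = TRUE),
                   format(d$end, scientific = FALSE, trim = TRUE),
                   formatC(d$value, format = "g", digits = 6))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write per-cytosine methylation calls
#'
#' Tab-separated text with columns `chrom`, `pos` (0-based), `strand`,
#' `context` (`CpG`/`CHH`), `meth`, `total` — a superset of bedGraph-style
#' bisulfite caller output.
#'
#' @param path File path.
#' @return Tibble of calls.
#' @export
read_methylation <- function(path) {
  d <- readr::read_tsv(path,
                       col_names = c("chrom", "pos", "strand", "context",
                                     "meth", "total"),
                       col_types = "cdccii", comment = "#", progress = FALSE)
  if (any(d$meth > d$total) || any(d$meth < 0)) {
    stopf("invalid methylation counts in %s (need 0 <= meth <= total)", path)
  }
  d
}

#' @rdname read_methylation
#' @param calls Tibble of methylation calls.
#' @export
write_methylation <- function(calls, path) {
  d <- as_tibble(calls)[, c("chrom", "pos", "strand", "context", "meth", "total")]
  d$pos <- format(d$pos, scientific = FALSE, trim = TRUE)
  readr::write_tsv(d, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
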