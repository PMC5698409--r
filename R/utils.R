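#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n row_number lag lead across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor prcomp quantile rbinom rgeom rmultinom rnorm rpois
#'   runif rbeta sd setNames var
#' @importFrom utils head tail
NULL

# Deterministic sub-seed derivation: one global seed fans out to per-module,
# per-stage, per-chromosome streams so adding a consumer never perturbs the
# others.  Result always fits a 32-bit signed integer.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tags)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) rlang::warn(sprintf(fmt, ...))

# Pearson correlation over jointly non-missing entries; NA if < 3 pairs or a
# degenerate (zero-variance) vector.
cor_pairwise <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

# Identify maximal runs of TRUE in a logical vector; returns tibble(start, end)
# of 1-based index ranges (end inclusive).  NA counts as FALSE.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}
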