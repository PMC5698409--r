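config_spec <- function() {
  tibble::tribble(
    ~key, ~default, ~min, ~max,
    "seed",                    1,      0,    2^31 - 1,
    "bin_size",                4e4,    1e3,  1e7,
    "n_contacts",              1e6,    1e3,  1e9,
    "hic_alpha",               1,      1e-3, 10,
    "hic_epsilon",             0.4,    0,    0.99,
    "hic_tau",                 1,      0,    10,
    "coverage",                12,     0,    1000,
    "ice_tol",                 1e-5,   0,    1,
    "ice_max_iter",            200,    1,    1e5,
    "tad_min_depth",           3e5,    4e4,  1e8,
    "tad_max_depth",           3e6,    4e4,  1e8,
    "tad_step",                3e5,    4e4,  1e8,
    "tad_min_boundary_distance", 4e5,  0,    1e8,
    "tad_min_prominence",      0.5,    0,    100,
    "dmr_delta",               0.4,    0,    1,
    "dmr_k",                   5,      2,    100,
    "dmr_min_coverage",        4,      1,    1000,
    "dmr_min_cpg_delta",       0.1,    0,    1,
    "dmr_max_gap",             1000,   1,    1e7,
    "diff_delta",              1,      0,    100,
    "diff_min_bins",           2,      1,    1000,
    "n_perm",                  1000,   10,   1e6,
    "meth_lag",                1,      0,    4
  )
}

#' Validate a pipeline configuration
#'
#' The configuration is a flat `key = value` text file (or a named list);
#' `#` comment lines are ignored. Unknown keys are rejected and every
#' violation is reported at once.
#'
#' @param config Path to a config file, or a named list; an empty/missing
#'   argument yields all defaults.
#' @return A validated named list of parameters with defaults filled in.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    lines <- readr::read_lines(config, progress = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) stopf("config file %s is empty", config)
    kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", lines))
    bad <- which(lengths(kv) != 3)
    if (length(bad)) stopf("unparseable config line %d", bad[1])
    config <- setNames(
      lapply(kv, function(m) {
        v <- suppressWarnings(as.numeric(m[3]))
        if (is.na(v)) m[3] else v
      }),
      vapply(kv, `[[`, "", 2)
    )
  }
  spec <- config_spec()
  errs <- character()
  unknown <- setdiff(names(config), spec$key)
  if (length(unknown)) {
    errs <- c(errs, sprintf("unknown key: %s", unknown))
  }
  out <- setNames(as.list(spec$default), spec$key)
  for (k in intersect(names(config), spec$key)) {
    v <- config[[k]]
    row <- spec[spec$key == k, ]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      errs <- c(errs, sprintf("%s: not a number", k))
    } else if (v < row$min || v > row$max) {
      errs <- c(errs, sprintf("%s: %g outside [%g, %g]", k, v, row$min,
                              row$max))
    } else {
      out[[k]] <- v
    }
  }
  if (length(errs)) {
    rlang::abort(c("invalid configuration", setNames(errs, rep("x", length(errs)))))
  }
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the synthetic multi-stage cohort, then runs every analysis
#' stage: ICE balancing, compartment calling per stage, differential and
#' common compartments, TAD insulation and boundaries, methylome
#' combining and segmentation, adult-vs-knockout DMR calling, and the
#' compartment-methylation integration statistics. All outputs are plain
#' text (BED/bedGraph/TSV) plus a JSON run log with parameters, seeds,
#' per-chromosome component selections and convergence diagnostics; runs
#' with identical configuration and seed are byte-identical.
#'
#' @param config A [validate_config()] result, config file path, or list
#'   of overrides.
#' @param outdir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (!is.list(config) && !is.character(config)) {
    stopf("config must be a path or a named list")
  }
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outdir, ".incomplete")
  writeLines("run in progress", marker)
  log <- list(parameters = cfg, steps = list())
  note <- function(step, ...) {
    log$steps[[length(log$steps) + 1]] <<- c(list(step = step), list(...))
  }

  truth <- cohort_truth(bin_size = cfg$bin_size, meth_lag = cfg$meth_lag)
  hp <- hic_params(alpha = cfg$hic_alpha, epsilon = cfg$hic_epsilon,
                   tau = cfg$hic_tau, n_reads = cfg$n_contacts,
                   seed = derive_seed(cfg$seed, "hic"))
  mp <- methyl_params(coverage = cfg$coverage,
                      seed = derive_seed(cfg$seed, "meth"))
  samples <- c(truth$stages, truth$ko_sample)
  truth_report(truth, file.path(outdir, "truth"))
  note("truth", n_bins = nrow(truth$bins))

  comps <- list(); tads <- list(); methylomes <- list()
  segments <- list(); activity <- list()
  for (st in samples) {
    raw <- generate_contacts(truth, hp, st)
    bal <- ice_balance(raw, max_iter = cfg$ice_max_iter, tol = cfg$ice_tol)
    act <- generate_activity(truth, st, seed = derive_seed(cfg$seed, "act"))
    comp <- call_compartments(bal, act)
    ins <- tad_score(bal, cfg$tad_min_depth, cfg$tad_max_depth,
                     cfg$tad_step)
    bd <- find_boundaries(ins, cfg$tad_min_boundary_distance,
                          cfg$tad_min_prominence)
    calls <- combine_cpg_strands(generate_methylome(truth, mp, st))
    segs <- segment_methylome(calls, min_coverage = cfg$dmr_min_coverage)
    comps[[st]] <- comp; tads[[st]] <- ins
    methylomes[[st]] <- calls; segments[[st]] <- segs
    activity[[st]] <- act
    write_bedgraph(bin_track(truth$bins, comp$pc1),
                   file.path(outdir, sprintf("pc1_%s.bedgraph", st)))
    write_bedgraph(ins, file.path(outdir, sprintf("tadscore_%s.bedgraph", st)))
    write_bed(tibble(chrom = bd$chrom, start = bd$pos, end = bd$pos + 1),
              file.path(outdir, sprintf("tad_boundaries_%s.bed", st)))
    write_bed(segs |> mutate(name = class),
              file.path(outdir, sprintf("segments_%s.bed", st)))
    sel <- attr(comp, "pc_selection")
    note("sample", sample = st,
         pc = as.list(setNames(sel$component, sel$chrom)),
         ice_deviation = max(bal$diagnostics$deviation))
  }

  wt_stages <- truth$stages
  diffs <- differential_compartments(comps[[wt_stages[1]]],
                                     comps[[wt_stages[length(wt_stages)]]],
                                     delta = cfg$diff_delta,
                                     min_bins = cfg$diff_min_bins)
  write_bed(diffs |> mutate(name = direction),
            file.path(outdir, "differential_compartments.bed"))
  common <- common_compartments(comps[wt_stages])
  write_bed(common |> mutate(name = status) |>
              select(chrom, start, end, name),
            file.path(outdir, "common_compartments.bed"))

  dp <- dmr_params(delta = cfg$dmr_delta, k = cfg$dmr_k,
                   min_coverage = cfg$dmr_min_coverage,
                   min_cpg_delta = cfg$dmr_min_cpg_delta,
                   max_gap = cfg$dmr_max_gap)
  dmrs <- call_dmrs(methylomes[["adult"]], methylomes[[truth$ko_sample]], dp)
  write_bed(dmrs |>
              mutate(name = direction,
                     score = round(100 * abs(mean_delta))) |>
              select(chrom, start, end, name, score),
            file.path(outdir, "dmrs_adult_vs_ko.bed"))
  note("dmr", n = nrow(dmrs))

  mtab <- compartment_mean_methylation_by_stage(methylomes[wt_stages],
                                                common,
                                                cfg$dmr_min_coverage)
  readr::write_tsv(mtab, file.path(outdir, "common_compartment_methylation.tsv"),
                   progress = FALSE)

  dmr_loc <- feature_compartment_fractions(
    dmrs[, c("chrom", "start", "end")], comps[["adult"]],
    n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, "perm1"))
  chh <- bin_chh(methylomes[["adult"]], truth$genome)
  chh_a <- signal_compartment_enrichment(
    chh, compartments = comps[["adult"]], n_perm = cfg$n_perm,
    seed = derive_seed(cfg$seed, "perm2"))
  adult_fmr <- segments[["adult"]]
  adult_fmr <- adult_fmr[adult_fmr$class == "FMR", c("chrom", "start", "end")]
  chh_fmr <- signal_compartment_enrichment(
    chh, regions = adult_fmr, n_perm = cfg$n_perm,
    seed = derive_seed(cfg$seed, "perm3"))
  enrich <- bind_rows(
    tidy(dmr_loc) |> mutate(what = "dmr_in_A", .before = 1),
    tidy(chh_a) |> mutate(what = "chh_in_A", .before = 1),
    tidy(chh_fmr) |> mutate(what = "chh_in_FMR", .before = 1)
  )
  readr::write_tsv(enrich, file.path(outdir, "enrichment.tsv"),
                   progress = FALSE)

  emb <- sample_pca(lapply(comps[wt_stages], function(c) {
    t <- c; names(t)[names(t) == "pc1"] <- "value"; t
  }))
  readr::write_tsv(tidy(emb), file.path(outdir, "compartment_pca.tsv"),
                   progress = FALSE)

  switch_regions <- truth_features(truth, "switch", "adult")
  prof <- stage_profiles(switch_regions[, c("chrom", "start", "end")],
                         segments[wt_stages], activity[wt_stages],
                         methylomes[wt_stages], cfg$dmr_min_coverage)
  readr::write_tsv(prof, file.path(outdir, "stage_profiles.tsv"),
                   progress = FALSE)

  note("integration", dmr_frac_a = dmr_loc$frac_a, chh_fold_a = chh_a$fold)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(marker)
  invisible(list(truth = truth, compartments = comps, insulation = tads,
                 methylomes = methylomes, segments = segments,
                 differential = diffs, common = common, dmrs = dmrs,
                 methylation_by_stage = mtab, enrichment = enrich,
                 embedding = emb, profiles = prof, config = cfg))
}
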