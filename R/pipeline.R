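#' Structured run configuration
#'
#' Collects every tunable of the pipeline with the protocol defaults:
#' QC thresholds (see [qc_thresholds()]), the FDR ladder, the dispersal
#' configuration (see [dispersal_config()]) and the master RNG seed.
#'
#' @param qc A [qc_thresholds()].
#' @param outlier_fdr_ladder FDR levels reported by the outlier scan.
#' @param outlier_split_level FDR at which the neutral/adaptive split is
#'   made.
#' @param outlier_working_level FDR for adaptive classification.
#' @param dispersal A [dispersal_config()].
#' @param rng_seed Master seed; stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(qc = qc_thresholds(),
                       outlier_fdr_ladder = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2),
                       outlier_split_level = 0.01,
                       outlier_working_level = 0.05,
                       dispersal = dispersal_config(),
                       rng_seed = 1L) {
  stopifnot(all(outlier_fdr_ladder > 0 & outlier_fdr_ladder < 1))
  structure(list(qc = qc, outlier_fdr_ladder = outlier_fdr_ladder,
                 outlier_split_level = outlier_split_level,
                 outlier_working_level = outlier_working_level,
                 dispersal = dispersal, rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read / write a run configuration
#'
#' Configurations are stored as a flat structured text file (YAML:
#' key/value with nested sections); every field defaults to the protocol
#' value and any subset may be overridden in the file.
#'
#' @param path File path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  if (!is.null(raw$qc)) cfg$qc <- do.call(qc_thresholds, merge_in(unclass(qc_thresholds()), raw$qc))
  if (!is.null(raw$dispersal)) {
    cfg$dispersal <- do.call(dispersal_config,
                             merge_in(unclass(dispersal_config()), raw$dispersal))
  }
  for (nm in c("outlier_fdr_ladder", "outlier_split_level",
               "outlier_working_level", "rng_seed")) {
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg
}

#' @rdname read_run_config
#' @param cfg A [run_config()].
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains quality control, diversity statistics, structure inference and
#' the outlier scan (plus dispersal when a current field and seed
#' polygons are supplied), writing JSON/CSV reports when `out_dir` is
#' given. Identical seeds reproduce every number exactly; the report
#' echoes the thresholds and seed for provenance.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param config A [run_config()].
#' @param replicate_pairs Optional replicate pairing for repeatability.
#' @param currents Optional [current_field()].
#' @param seed_polygons Optional named polygon list for dispersal.
#' @param out_dir Optional output directory.
#' @param n_perm Permutations for pairwise FST / AMOVA / Mantel.
#' @param n_sim_loci Null-cloud size for the outlier scan.
#' @return A named list of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(G, map, config = run_config(),
                         replicate_pairs = NULL, currents = NULL,
                         seed_polygons = NULL, out_dir = NULL,
                         n_perm = 199, n_sim_loci = 20000) {
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res$qc <- stage("qc", filter_cascade(G, config$qc, replicate_pairs, map,
                                       seed = config$rng_seed))
  Gf <- res$qc$genotypes
  res$outliers <- stage("outliers",
    outlier_scan(Gf, map, n_sim_loci = n_sim_loci,
                 ladder = config$outlier_fdr_ladder,
                 working_level = config$outlier_split_level,
                 seed = config$rng_seed + 1L))
  res$split <- stage("split", split_datasets(Gf, res$outliers,
                                             unclassified = "neutral"))
  Gn <- res$split$neutral
  res$stats <- stage("stats", list(
    heterozygosities = heterozygosities(Gn, map),
    fis = fis_wc(Gn, map),
    alleles = allele_summaries(Gn, map),
    individual = individual_heterozygosity(Gn, map),
    ne = ne_ld(Gn, map)))
  res$structure <- stage("structure", {
    fst <- pairwise_fst(Gn, map, n_perm = n_perm, seed = config$rng_seed + 2L)
    ds <- nei_ds(Gn, map)
    out <- list(pairwise_fst = fst, nei_ds = ds)
    if (length(unique(map$region)) > 1) {
      out$amova <- hierarchical_amova(Gn, map, n_perm = min(n_perm, 99),
                                      seed = config$rng_seed + 3L)
    }
    if (!is.null(pop_coords(map)) && length(unique(map$population)) >= 4) {
      gd <- geo_dist_matrix(map)[rownames(fst$values), rownames(fst$values)]
      out$mantel <- mantel_test(fst$values, gd, n_perm = max(n_perm, 999),
                                seed = config$rng_seed + 4L)
    }
    out$migration <- directional_migration(Gn, map, n_boot = 0)
    out
  })
  if (!is.null(currents) && !is.null(seed_polygons)) {
    res$dispersal <- stage("dispersal", {
      run <- run_dispersal(currents, config$dispersal, seed_polygons)
      list(run = run,
           connectivity = connectivity_matrix(run$particles, seed_polygons))
    })
  } else {
    res$dispersal_skipped <- "no current field supplied; dispersal stage skipped"
  }
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

write_pipeline_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$qc$ledger, file.path(out_dir, "filter_ledger.csv"))
  readr::write_csv(tibble::as_tibble(res$outliers),
                   file.path(out_dir, "outlier_report.csv"))
  report <- list(
    seed = res$config$rng_seed,
    thresholds = unclass(res$config$qc),
    ledger = res$qc$ledger,
    outlier_counts = attr(res$outliers, "counts"),
    heterozygosities = res$stats$heterozygosities,
    fis = res$stats$fis,
    ne = res$stats$ne,
    pairwise_fst = res$structure$pairwise_fst$values,
    nei_ds = res$structure$nei_ds$values,
    amova = if (!is.null(res$structure$amova)) res$structure$amova$table,
    mantel = res$structure$mantel,
    dispersal = if (!is.null(res[["dispersal"]]))
      res[["dispersal"]]$connectivity else res$dispersal_skipped)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
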