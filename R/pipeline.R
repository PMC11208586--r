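# Pipeline orchestration: run every stage from one config, write
# deterministic per-stage CSV outputs plus a machine-readable manifest,
# and skip stages whose inputs have not changed.

stage_files <- list(
  synth = c("genes.csv", "regions.csv", "loops_baseline.bedpe",
            "loops_treatment.bedpe", "expression.csv", "m6a_peaks.csv",
            "m6a_expression.csv", "isotopologues.csv", "ct.csv",
            "truth.json"),
  loops = c("distance_distribution.csv", "ep_counts.csv"),
  integration = c("resample_groups.csv", "candidates.csv",
                  "integration_stats.csv"),
  m6a = c("m6a_calls.csv", "m6a_down.csv"),
  tracing = c("corrected_mids.csv", "labeled_fractions.csv", "screen.csv")
)

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config)[order(names(unclass(config)))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — synthetic-data generation,
#' loop analytics (filtering, distance classes, EP counting),
#' transcription integration (grouped resampling + candidate funnel),
#' m6A polymethylation, and isotope tracing — writing per-stage CSV
#' outputs and a `manifest.json` into `out_dir`. On a rerun with an
#' unchanged config, stages whose recorded outputs still match their
#' checksums are skipped.
#'
#' Identical configs produce byte-identical outputs.
#'
#' @param config a [generator_config()], or a path to a YAML file of
#'   `generator_config()` arguments.
#' @param out_dir output directory (created if needed).
#' @param force rerun all stages even when up to date.
#' @return Invisibly, a list with `out_dir`, `stages` (named
#'   `"run"`/`"skipped"`), and the `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir, force = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- config_fingerprint(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  stage_ok <- function(stage) {
    if (force || is.null(old) || !identical(old$config_fingerprint, fp)) {
      return(FALSE)
    }
    rec <- old$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    paths <- file.path(out_dir, stage_files[[stage]])
    all(file.exists(paths)) &&
      identical(unname(tools::md5sum(paths)), unname(unlist(rec$md5)))
  }
  status <- c(synth = "skipped", loops = "skipped", integration = "skipped",
              m6a = "skipped", tracing = "skipped")

  # --- synth ---------------------------------------------------------
  if (!stage_ok("synth")) {
    status["synth"] <- "run"
    catalog <- generate_genome(config)
    lp <- generate_loops(config, catalog)
    ex <- generate_expression(config, lp$truth)
    m6 <- generate_m6a(config, catalog)
    iso <- generate_isotopologues(config)
    ctt <- generate_ct(config)
    write_table(catalog$genes, file.path(out_dir, "genes.csv"))
    write_table(catalog$regions, file.path(out_dir, "regions.csv"))
    conds <- config$conditions
    for (role in c("baseline", "treatment")) {
      sub <- lp$loops[lp$loops$condition == unname(conds[[role]]), , drop = FALSE]
      write_loops(sub, file.path(out_dir, sprintf("loops_%s.bedpe", role)))
    }
    write_table(ex$expression, file.path(out_dir, "expression.csv"))
    write_table(m6$peaks, file.path(out_dir, "m6a_peaks.csv"))
    write_table(m6$expression, file.path(out_dir, "m6a_expression.csv"))
    write_table(iso$intensities, file.path(out_dir, "isotopologues.csv"))
    write_table(ctt$ct, file.path(out_dir, "ct.csv"))
    jsonlite::write_json(
      list(ep = lp$truth, mtc_genes = ex$truth$mtc_genes,
           poly = m6$truth$poly, poly_down = m6$truth$poly_down,
           metabolite_panel = iso$truth, ct_folds = as.list(ctt$truth)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- loops ---------------------------------------------------------
  run_loops <- !stage_ok("loops") || status["synth"] == "run"
  catalog <- read_catalog_csv(out_dir)
  conds <- config$conditions
  if (run_loops) {
    status["loops"] <- "run"
    loops <- rbind(
      read_loops(file.path(out_dir, "loops_baseline.bedpe"),
                 assay = config$assay, condition = unname(conds[["baseline"]])),
      read_loops(file.path(out_dir, "loops_treatment.bedpe"),
                 assay = config$assay, condition = unname(conds[["treatment"]])))
    sig <- filter_significant_loops(loops, config$assay)
    write_table(distance_distribution(sig),
                file.path(out_dir, "distance_distribution.csv"))
    promoters <- define_promoters(catalog, config$promoter_flank)
    ep <- assign_ep(sig, promoters)
    counts <- count_ep_per_gene(ep, catalog$genes$gene_id,
                                baseline = unname(conds[["baseline"]]),
                                treatment = unname(conds[["treatment"]]))
    write_table(counts, file.path(out_dir, "ep_counts.csv"))
  }

  # --- integration ---------------------------------------------------
  if (!stage_ok("integration") || status["loops"] == "run") {
    status["integration"] <- "run"
    counts <- read_table(file.path(out_dir, "ep_counts.csv"),
                         c(gene_id = "character", ep_baseline = "integer",
                           ep_treatment = "integer", delta_ep = "integer"))
    expr <- read_table(file.path(out_dir, "expression.csv"), schema_expression)
    sen <- expr[expr$contrast == "sen_vs_growing", , drop = FALSE]
    rs <- group_resample_logfc(counts, sen, seed = config$seed + 10L)
    write_table(rs$groups, file.path(out_dir, "resample_groups.csv"))
    funnel <- select_mtc_dependent_genes(expr)
    funnel <- intersect_enhanced_contacts(funnel, counts)
    write_table(funnel$pairs, file.path(out_dir, "candidates.csv"))
    cand_cor <- if (nrow(funnel$pairs) >= 3L &&
                    stats::sd(funnel$pairs$delta_ep) > 0 &&
                    stats::sd(funnel$pairs$log_fc) > 0) {
      correlate_candidates(funnel$pairs$delta_ep, funnel$pairs$log_fc)
    } else list(pearson_r = NA_real_, p_value = NA_real_, n = nrow(funnel$pairs))
    write_table(data.frame(
      resample_pearson_r = rs$pearson_r, resample_p = rs$p_value,
      candidate_pearson_r = cand_cor$pearson_r,
      candidate_p = cand_cor$p_value,
      n_up = length(funnel$up), n_down_kd1 = length(funnel$down_kd1),
      n_down_kd2 = length(funnel$down_kd2),
      n_candidates = length(funnel$candidates),
      n_contact_enhanced = length(funnel$contact_enhanced)),
      file.path(out_dir, "integration_stats.csv"))
  }

  # --- m6a -----------------------------------------------------------
  if (!stage_ok("m6a") || status["synth"] == "run") {
    status["m6a"] <- "run"
    peaks <- read_table(file.path(out_dir, "m6a_peaks.csv"), schema_m6a_peaks)
    m6_expr <- read_table(file.path(out_dir, "m6a_expression.csv"),
                          schema_expression)
    sites <- count_unique_sites(peaks, catalog)
    calls <- classify_polymethylated(sites,
                                     all_transcripts = catalog$genes$gene_id)
    write_table(calls, file.path(out_dir, "m6a_calls.csv"))
    down <- intersect_downregulated(calls, m6_expr)
    write_table(data.frame(transcript_id = down),
                file.path(out_dir, "m6a_down.csv"))
  }

  # --- tracing -------------------------------------------------------
  if (!stage_ok("tracing") || status["synth"] == "run") {
    status["tracing"] <- "run"
    iso <- read_table(file.path(out_dir, "isotopologues.csv"),
                      c(metabolite = "character", n_carbons = "integer",
                        m_label = "integer", group = "character",
                        replicate = "integer", mz = "integer",
                        intensity = "numeric"))
    corr <- correct_isotopologue_table(iso, config$p13c)
    write_table(corr$mids, file.path(out_dir, "corrected_mids.csv"))
    write_table(corr$fractions, file.path(out_dir, "labeled_fractions.csv"))
    write_table(screen_metabolites(corr$fractions),
                file.path(out_dir, "screen.csv"))
  }

  manifest <- list(
    package = "loopmet",
    version = as.character(utils::packageVersion("loopmet")),
    config_fingerprint = fp,
    config = unclass(config),
    stages = lapply(stats::setNames(names(stage_files), names(stage_files)),
                    function(st) {
      paths <- file.path(out_dir, stage_files[[st]])
      list(files = stage_files[[st]],
           md5 = as.list(setNames(unname(tools::md5sum(paths)),
                                  stage_files[[st]])),
           rows = as.list(setNames(
             lapply(paths, count_data_rows), stage_files[[st]])))
    }))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, stages = status, manifest = manifest))
}

count_data_rows <- function(path) {
  if (!file.exists(path)) return(NA_integer_)
  n <- length(readLines(path, warn = FALSE))
  if (grepl("\\.csv$", path)) max(0L, n - 1L) else n
}

read_catalog_csv <- function(out_dir) {
  genes <- read_table(file.path(out_dir, "genes.csv"),
                      c(gene_id = "character", chrom = "character",
                        strand = "character", start = "numeric",
                        end = "numeric", tss = "numeric"))
  regions <- read_table(file.path(out_dir, "regions.csv"),
                        c(gene_id = "character", chrom = "character",
                          region = "character", start = "numeric",
                          end = "numeric"))
  new_gene_catalog(genes, regions)
}

#' Load a pipeline config from YAML
#'
#' The file holds `generator_config()` arguments; unknown keys are an
#' error, a missing `seed` is an error (every run must be seeded).
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  args <- yaml::read_yaml(path)
  if (is.null(args$seed)) stopf("config validation: field 'seed' is required")
  unknown <- setdiff(names(args), names(formals(generator_config)))
  if (length(unknown) > 0L) {
    stopf("config validation: unknown field(s): %s",
          paste(unknown, collapse = ", "))
  }
  if (!is.null(args$conditions)) args$conditions <- unlist(args$conditions)
  do.call(generator_config, args)
}

#' Summarize pipeline outputs
#'
#' Collects the distance distribution, resampling curve, candidate
#' funnel counts and metabolite screen from a pipeline output directory
#' into one report, written as `report.json` (deterministic;
#' regeneration is byte-identical). Missing stage outputs produce a
#' partial report with a warning.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param write write `report.json` into `out_dir` (default `TRUE`).
#' @return The report, a named list of data frames / lists.
#' @export
make_report <- function(out_dir, write = TRUE) {
  sections <- list(
    distance_distribution = "distance_distribution.csv",
    resampling = "resample_groups.csv",
    integration = "integration_stats.csv",
    funnel = "candidates.csv",
    m6a_calls = "m6a_calls.csv",
    screen = "screen.csv")
  report <- list()
  for (nm in names(sections)) {
    path <- file.path(out_dir, sections[[nm]])
    if (!file.exists(path)) {
      warnf("report section '%s' missing (no %s); partial report", nm,
            sections[[nm]])
      next
    }
    report[[nm]] <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(report$m6a_calls)) {
    report$m6a_summary <- list(
      n_transcripts = nrow(report$m6a_calls),
      n_polymethylated = sum(report$m6a_calls$is_polymethylated))
    report$m6a_calls <- NULL
  }
  if (write) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
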