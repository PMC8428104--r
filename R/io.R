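# Readers, writers, validation and the pipeline driver.
#
# All tables are plain UTF-8 text with a header row; counts and event
# tables are tab-separated, sample sheets and cardiac traces
# comma-separated. Lines starting with '#' are metadata comments written
# by this package and skipped on read.

#' Read a gene-level count matrix (TSV)
#'
#' First column: gene id; remaining columns: one integer count column
#' per sample. Duplicate gene or sample ids, negative and non-integer
#' counts are rejected with the offending row named.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  assert_that(file.exists(path), "counts file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "%s: need a gene-id column plus sample columns", path)
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  assert_that(length(dup) == 0, "%s: duplicate gene id(s): %s",
              path, paste(unique(dup), collapse = ", "))
  dup_s <- names(df)[-1][duplicated(names(df)[-1])]
  assert_that(length(dup_s) == 0, "%s: duplicate sample id(s): %s",
              path, paste(unique(dup_s), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  assert_that(is.numeric(mat), "%s: non-numeric counts", path)
  bad <- which(rowSums(mat < 0) > 0)
  assert_that(length(bad) == 0, "%s: negative count at data row %s",
              path, paste(bad, collapse = ", "))
  off <- which(rowSums(mat != floor(mat)) > 0)
  assert_that(length(off) == 0, "%s: non-integer count at data row %s",
              path, paste(off, collapse = ", "))
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  mat
}

#' Read a sample sheet (CSV)
#'
#' Required columns: `sample`, `population` (`P1`/`P2`/`F1`),
#' `condition` (`control`/`heat`), `replicate`.
#'
#' @param path Path to a comma-separated file.
#' @return Validated `data.frame`.
#' @export
read_samples <- function(path) {
  assert_that(file.exists(path), "sample sheet not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_samples(df)
}

# Shared sample-sheet validation; optionally cross-checks against the
# count matrix's column names.
validate_samples <- function(samples, count_cols = NULL) {
  need <- c("sample", "population", "condition", "replicate")
  missing_col <- setdiff(need, names(samples))
  assert_that(length(missing_col) == 0, "sample sheet lacks column(s): %s",
              paste(missing_col, collapse = ", "))
  dup <- samples$sample[duplicated(samples$sample)]
  assert_that(length(dup) == 0, "duplicate sample id(s): %s",
              paste(unique(dup), collapse = ", "))
  bad_pop <- setdiff(unique(samples$population), c("P1", "P2", "F1"))
  assert_that(length(bad_pop) == 0, "unknown population code(s): %s (use P1/P2/F1)",
              paste(bad_pop, collapse = ", "))
  bad_cond <- setdiff(unique(samples$condition), c("control", "heat"))
  assert_that(length(bad_cond) == 0, "unknown condition(s): %s (use control/heat)",
              paste(bad_cond, collapse = ", "))
  if (!is.null(count_cols)) {
    unmatched <- setdiff(samples$sample, count_cols)
    assert_that(length(unmatched) == 0,
                "sample id(s) missing from the count matrix: %s",
                paste(unmatched, collapse = ", "))
  }
  samples
}

#' Read a splice-event table (TSV, wide layout)
#'
#' Columns: `event_id, gene_id, type`, per-replicate junction counts
#' `I_ctrl_1..., S_ctrl_1..., I_heat_1..., S_heat_1...`, and effective
#' lengths `len_inclusion, len_skipping`.
#'
#' @param path Path to a tab-separated file.
#' @return Validated `data.frame`.
#' @export
read_events <- function(path) {
  assert_that(file.exists(path), "event table not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (need in c("event_id", "gene_id", "type", "len_inclusion", "len_skipping")) {
    assert_that(need %in% names(df), "%s: missing column '%s'", path, need)
  }
  dup <- df$event_id[duplicated(df$event_id)]
  assert_that(length(dup) == 0, "%s: duplicate event id(s): %s",
              path, paste(unique(dup), collapse = ", "))
  bad_type <- setdiff(unique(df$type), SPLICE_TYPES)
  assert_that(length(bad_type) == 0, "%s: unknown event type(s): %s",
              path, paste(bad_type, collapse = ", "))
  cnt_cols <- grep("^[IS]_(ctrl|heat)_\\d+$", names(df), value = TRUE)
  assert_that(length(cnt_cols) >= 4, "%s: no replicate junction-count columns", path)
  cnt <- as.matrix(df[cnt_cols])
  bad <- which(rowSums(cnt < 0) > 0)
  assert_that(length(bad) == 0, "%s: negative junction count at data row %s",
              path, paste(bad, collapse = ", "))
  df
}

#' Read a cardiac heart-rate trace (CSV)
#'
#' Columns: `temp_c` (strictly increasing) and `bpm` (positive).
#'
#' @param path Path to a comma-separated file.
#' @return `data.frame` with `temp_c` and `bpm`.
#' @export
read_trace <- function(path) {
  assert_that(file.exists(path), "trace file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  assert_that(all(c("temp_c", "bpm") %in% names(df)),
              "%s: needs columns temp_c and bpm", path)
  assert_that(all(diff(df$temp_c) > 0),
              "%s: temperatures must be strictly increasing", path)
  bad <- which(!(is.finite(df$bpm) & df$bpm > 0))
  assert_that(length(bad) == 0, "%s: non-positive heart rate at data row %s",
              path, paste(bad, collapse = ", "))
  df[c("temp_c", "bpm")]
}

#' Write a simulated triad to disk
#'
#' Writes the counts TSV, sample-sheet CSV and truth TSV of a
#' [simulate_triad_counts()] result, each stamped with a metadata
#' header.
#'
#' @param sim Result of [simulate_triad_counts()].
#' @param dir Output directory (created if absent).
#' @param seed Seed recorded in the file headers.
#' @return Named vector of the written paths.
#' @export
write_triad <- function(sim, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_df <- data.frame(gene = rownames(sim$counts), sim$counts,
                          check.names = FALSE, row.names = NULL)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "triad_truth.tsv"))
  write_tsv_stamped(counts_df, paths[["counts"]], seed = seed)
  con <- file(paths[["samples"]], "wt", encoding = "UTF-8")
  writeLines(output_header(seed = seed), con)
  utils::write.csv(sim$samples, con, quote = FALSE, row.names = FALSE)
  close(con)
  write_tsv_stamped(sim$truth, paths[["truth"]], seed = seed)
  paths
}

#' Pipeline configuration
#'
#' Bundles input paths, stage parameters and the run seed for
#' [run_pipeline()].
#'
#' @param counts,samples Paths to the count matrix (TSV) and sample
#'   sheet (CSV); required.
#' @param events Optional path to a splice-event table (TSV); the splice
#'   and integration stages run only when present.
#' @param traces Optional named character vector of cardiac trace CSV
#'   paths (one per individual); the ABT stage runs only when present.
#' @param pathway_map Optional path to a gene-to-pathway TSV
#'   (columns `gene`, `pathway`) enabling over-representation testing.
#' @param out_dir Output directory.
#' @param seed Run seed; all stage randomness derives from it.
#' @param fdr_cut,lfc_cut DE thresholds.
#' @param dpsi_cut,min_mean_reads,splice_fdr_cut Splice-filter
#'   thresholds.
#' @param convention,normalization,epsilon Mode-classification options
#'   (see [classify_matrix()]).
#' @param min_segment ABT fitting option (see [fit_breakpoint()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, events = NULL, traces = NULL,
                            pathway_map = NULL, out_dir = "heterosis_out",
                            seed = 1,
                            fdr_cut = 0.05, lfc_cut = 1.0,
                            dpsi_cut = 0.1, min_mean_reads = 5,
                            splice_fdr_cut = 0.05,
                            convention = "full_gap",
                            normalization = "tmm_linear",
                            epsilon = 1e-8, min_segment = 3) {
  assert_that(is.character(counts) && length(counts) == 1, "counts path required")
  assert_that(is.character(samples) && length(samples) == 1, "samples path required")
  cfg <- list(counts = counts, samples = samples, events = events,
              traces = traces, pathway_map = pathway_map, out_dir = out_dir,
              seed = as.integer(seed), fdr_cut = fdr_cut, lfc_cut = lfc_cut,
              dpsi_cut = dpsi_cut, min_mean_reads = min_mean_reads,
              splice_fdr_cut = splice_fdr_cut, convention = convention,
              normalization = normalization, epsilon = epsilon,
              min_segment = min_segment)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full heterosis pipeline
#'
#' Stages, in order: read and validate inputs; TMM normalization;
#' control-vs-heat DE per population; dominance-mode classification per
#' condition; splice divergence test and filter (when an event table is
#' configured); ABT fits (when traces are configured); gene-set
#' integration. Every output table carries a metadata header (package
#' version, seed, parameter hash) and a JSON manifest records inputs
#' (with MD5 checksums), parameters and outputs. Reruns with the same
#' config and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  for (p in c(config$counts, config$samples, config$events,
              config$pathway_map, unname(config$traces))) {
    assert_that(is.null(p) || file.exists(p), "input path does not exist: %s", p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  # analysis parameters only: paths and output location must not change
  # the stamped hash, or reruns in a different directory would not be
  # byte-identical
  analysis_params <- unclass(config)[setdiff(names(unclass(config)),
                                             c("counts", "samples", "events",
                                               "traces", "pathway_map", "out_dir"))]
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_stamped(df, path, seed = seed, params = analysis_params)
    outputs <<- c(outputs, path)
    path
  }

  counts <- stage("read", read_counts(config$counts))
  samples <- stage("read", validate_samples(read_samples(config$samples),
                                            colnames(counts)))

  norm <- stage("normalize", tmm_normalize(counts))
  emit(data.frame(sample = names(norm$factors), factor = norm$factors,
                  lib_size = norm$lib_size, row.names = NULL),
       "tmm_factors.tsv")

  deg_sets <- list()
  for (pop in c("P1", "P2", "F1")) {
    degs <- stage("de", call_degs(norm, samples, pop,
                                  fdr_cut = config$fdr_cut,
                                  lfc_cut = config$lfc_cut))
    emit(degs, sprintf("degs_%s.tsv", pop))
    deg_sets[[paste0(pop, "_CvsH")]] <- degs$gene[degs$significant]
  }

  mode_calls <- list()
  for (cond in c("control", "heat")) {
    calls <- stage("modes", classify_matrix(counts, samples, condition = cond,
                                            convention = config$convention,
                                            normalization = config$normalization,
                                            epsilon = config$epsilon))
    emit(calls, sprintf("modes_%s.tsv", cond))
    s <- summarize_modes(calls)
    emit(data.frame(class = names(s$counts), n = s$counts,
                    pct = s$class_pct, row.names = NULL),
         sprintf("mode_summary_%s.tsv", cond))
    mode_calls[[cond]] <- calls
  }

  splice_genes <- character(0)
  if (!is.null(config$events)) {
    events <- stage("splice", read_events(config$events))
    tested <- stage("splice", test_events(events, method = "welch"))
    kept <- stage("splice", filter_events(tested,
                                          min_mean_reads = config$min_mean_reads,
                                          dpsi_cut = config$dpsi_cut,
                                          fdr_cut = config$splice_fdr_cut))
    emit(tested[c("event_id", "gene_id", "type", "psi_ctrl", "psi_heat",
                  "delta_psi", "mean_reads", "p", "fdr")], "splice_tested.tsv")
    emit(kept[c("event_id", "gene_id", "type", "delta_psi", "mean_reads", "fdr")],
         "splice_significant.tsv")
    splice_genes <- unique(kept$gene_id)
  }

  if (!is.null(config$traces)) {
    fits <- stage("abt", lapply(config$traces, function(p) {
      fit_breakpoint(arrhenius_transform(read_trace(p)),
                     min_segment = config$min_segment)
    }))
    ids <- if (!is.null(names(config$traces))) names(config$traces)
           else basename(unlist(config$traces))
    emit(data.frame(individual = ids,
                    abt_celsius = vapply(fits, `[[`, numeric(1), "abt_celsius"),
                    rss = vapply(fits, `[[`, numeric(1), "rss"),
                    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
                    row.names = NULL),
         "abt_fits.tsv")
  }

  integ <- stage("integration",
                 integrate_heterosis(deg_sets, mode_calls[["heat"]], splice_genes))
  emit(data.frame(set = names(integ$sizes), size = integ$sizes, row.names = NULL),
       "integration_sizes.tsv")
  emit(integ$venn$regions, "integration_venn.tsv")
  if (length(integ$final)) {
    emit(data.frame(gene = integ$final), "integration_final_genes.tsv")
  }
  if (!is.null(config$pathway_map) && length(integ$common_deg_odo)) {
    map <- utils::read.delim(config$pathway_map, comment.char = "#",
                             stringsAsFactors = FALSE)
    enr <- stage("integration",
                 enrich(integ$common_deg_odo, rownames(counts), map))
    emit(enr, "enrichment.tsv")
  }

  inputs <- c(counts = config$counts, samples = config$samples,
              events = config$events, pathway_map = config$pathway_map,
              unname(config$traces))
  manifest <- list(
    tool = "heterosiskit",
    version = pkg_version(),
    seed = seed,
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("counts", "samples", "events",
                                           "traces", "pathway_map", "out_dir"))],
    inputs = lapply(inputs[!vapply(inputs, is.null, logical(1))], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(outputs)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
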