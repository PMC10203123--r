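#' Assemble the per-species analysis table
#'
#' Convenience wrapper chaining [vet_species()], [relative_abundance()] and
#' [abundance_summary()] into the analysis-ready species table: one row per
#' species-level taxon with vetting status, range, longevity and abundance
#' summaries.
#'
#' @inheritParams vet_species
#' @return A tibble; see [abundance_summary()] for columns.
#' @export
species_table <- function(table, exclusions = NULL, edge_samples = 2L,
                          min_error_samples = 1L,
                          gap_method = c("runs", "samples"), quiet = FALSE) {
  if (!is.null(exclusions)) {
    table <- apply_exclusions(table, exclusions, quiet = quiet)
  }
  ranges <- vet_species(table, exclusions = NULL,
                        edge_samples = edge_samples,
                        min_error_samples = min_error_samples,
                        gap_method = gap_method, quiet = quiet)
  ab <- relative_abundance(table)
  abundance_summary(ab, ranges, table)
}

#' Run the full abundance-longevity analysis on one dataset
#'
#' End-to-end orchestration for a single regional dataset (regions are
#' always analyzed separately, never pooled): flagged-occurrence exclusion,
#' range vetting, abundance summaries, the four OLS regressions of
#' longevity on ln mean / ln max / ln SD relative abundance, one-way ANOVAs
#' by taxonomic order and by biogeographic category, the mixed-effects
#' model combining abundance and biogeography with its AICc comparison
#' against the abundance-only regression, and per-sample richness and
#' coverage.
#'
#' ANOVAs and the mixed model are attempted and reported as `NULL` with a
#' note when their preconditions fail (e.g. a group with fewer than two
#' included species), so a run on a sparse dataset still completes.
#'
#' @param table an [occurrence_table()] (or `NULL` if the three `*_path`
#'   arguments are given).
#' @param exclusions optional flagged-occurrence data frame.
#' @param label dataset label carried into every output (`"SO"`, `"EEP"`,
#'   or any custom string).
#' @param edge_samples,min_error_samples,gap_method vetting knobs, see
#'   [vet_species()].
#' @param alpha significance level used in the textual summary (tests are
#'   two-sided).
#' @param counts_path,ages_path,meta_path optional file paths, passed to
#'   [read_occurrences()] when `table` is `NULL`.
#' @param quiet suppress progress messages.
#' @return An object of class `range_run`: a list with elements `label`,
#'   `species` (the species table), `vetting_counts`, `ols` (list of
#'   `range_ols` for mean/max/sd predictors), `diagnostics`, `anova_order`,
#'   `anova_biogeo`, `mixed`, `aicc_comparison`, `richness`, `coverage`,
#'   `notes` and `summary` (a flat named list of headline numbers, the
#'   machine-readable results bundle).
#' @export
run_pipeline <- function(table = NULL, exclusions = NULL, label = "custom",
                         edge_samples = 2L, min_error_samples = 1L,
                         gap_method = c("runs", "samples"), alpha = 0.05,
                         counts_path = NULL, ages_path = NULL,
                         meta_path = NULL, quiet = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(table)) {
    table <- read_occurrences(counts_path, ages_path, meta_path, quiet = quiet)
  }
  stopifnot(inherits(table, "occurrence_table"))
  notes <- character(0)

  species <- species_table(table, exclusions = exclusions,
                           edge_samples = edge_samples,
                           min_error_samples = min_error_samples,
                           gap_method = gap_method, quiet = quiet)
  vetting_counts <- species |>
    dplyr::count(.data$status, name = "n_species")
  included <- dplyr::filter(species, .data$status == "included")
  if (nrow(included) < 3) {
    abort(sprintf("stage vet_species [%s]: only %d species survive vetting",
                  label, nrow(included)))
  }

  ols <- list(
    mean = fit_longevity_ols(included, ln_mean_ra,
                             label = paste0(label, ": longevity ~ ln mean RA")),
    max = fit_longevity_ols(included, ln_max_ra,
                            label = paste0(label, ": longevity ~ ln max RA")),
    sd = tryCatch(
      fit_longevity_ols(included, ln_sd_ra,
                        label = paste0(label, ": longevity ~ ln SD RA")),
      error = function(e) NULL
    )
  )
  if (is.null(ols$sd)) notes <- c(notes, "SD regression not fit")
  diagnostics <- purrr::map_dfr(
    purrr::compact(ols),
    function(m) dplyr::bind_cols(tibble::tibble(label = m$label),
                                 residual_diagnostics(m))
  )

  try_stage <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, paste0(what, " skipped: ", conditionMessage(e)))
      NULL
    })
  }
  anova_order <- try_stage(longevity_anova(included, order_code),
                           "order ANOVA")
  anova_biogeo <- try_stage(longevity_anova(included, biogeo_code),
                            "biogeography ANOVA")
  mixed <- try_stage(
    withCallingHandlers(
      fit_longevity_mixed(included, ln_mean_ra, biogeo_code),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    "mixed model"
  )
  aicc_comparison <- if (!is.null(mixed)) compare_aicc(ols$mean, mixed) else NULL

  richness <- sample_richness(table)
  coverage <- sample_coverage(table)

  g_mean <- glance(ols$mean)
  g_max <- glance(ols$max)
  summary <- list(
    label = label,
    n_samples = nrow(table$counts),
    n_species_level_taxa = sum(table$meta$species_level),
    n_included = nrow(included),
    median_longevity = median(included$longevity),
    mean_longevity = mean(included$longevity),
    median_mean_ra = median(included$mean_ra),
    median_max_ra = median(included$max_ra),
    ols_mean_slope = g_mean$slope, ols_mean_r2 = g_mean$r_squared,
    ols_mean_p = g_mean$p_value,
    ols_max_slope = g_max$slope, ols_max_r2 = g_max$r_squared,
    ols_max_p = g_max$p_value,
    ols_sd_r2 = if (!is.null(ols$sd)) glance(ols$sd)$r_squared else NA_real_,
    anova_order_f = if (!is.null(anova_order)) glance(anova_order)$f_stat else NA_real_,
    anova_order_p = if (!is.null(anova_order)) glance(anova_order)$p_value else NA_real_,
    anova_biogeo_f = if (!is.null(anova_biogeo)) glance(anova_biogeo)$f_stat else NA_real_,
    anova_biogeo_p = if (!is.null(anova_biogeo)) glance(anova_biogeo)$p_value else NA_real_,
    delta_aicc = if (!is.null(aicc_comparison)) aicc_comparison$delta_aicc else NA_real_,
    median_coverage = median(coverage$coverage),
    alpha = alpha
  )

  structure(
    list(label = label, species = species, vetting_counts = vetting_counts,
         ols = ols, diagnostics = diagnostics, anova_order = anova_order,
         anova_biogeo = anova_biogeo, mixed = mixed,
         aicc_comparison = aicc_comparison, richness = richness,
         coverage = coverage, notes = notes, summary = summary),
    class = "range_run"
  )
}

#' @export
print.range_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<range_run> %s: %d included species of %d species-level taxa\n",
              s$label, s$n_included, s$n_species_level_taxa))
  cat(sprintf("  median longevity %.2f my; ln mean RA regression R^2 = %.3f (p = %.3g)\n",
              s$median_longevity, s$ols_mean_r2, s$ols_mean_p))
  if (!is.na(s$delta_aicc)) {
    cat(sprintf("  mixed vs abundance-only model: delta AICc = %.2f\n",
                s$delta_aicc))
  }
  invisible(x)
}

#' Write a run's results bundle to disk
#'
#' Writes the species table, vetting counts, per-model summaries,
#' residuals, richness/coverage tables (CSV) and the flat headline summary
#' (JSON) into `dir`. The JSON is deterministic given the same inputs and
#' seed: no timestamps.
#'
#' @param run a `range_run` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "range_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_species_table(run$species, p("species_table.csv"))
  readr::write_csv(run$vetting_counts, p("vetting_counts.csv"), progress = FALSE)
  models <- purrr::map_dfr(purrr::compact(run$ols), glance)
  readr::write_csv(models, p("regressions.csv"), progress = FALSE)
  readr::write_csv(run$diagnostics, p("diagnostics.csv"), progress = FALSE)
  resids <- purrr::map_dfr(
    purrr::compact(run$ols),
    function(m) dplyr::bind_cols(tibble::tibble(label = m$label), augment(m))
  )
  readr::write_csv(resids, p("residuals.csv"), progress = FALSE)
  readr::write_csv(
    dplyr::left_join(run$richness, run$coverage, by = c("sample_id", "age")),
    p("samples.csv"), progress = FALSE
  )
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a pipeline run configuration from YAML
#'
#' Expected fields: `counts`, `ages`, `meta` (paths), optional
#' `exclusions` (path to a CSV of `taxon_id,sample_id`), `label`,
#' `edge_samples`, `min_error_samples`, `alpha`, `out_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(label = "custom", edge_samples = 2L,
                   min_error_samples = 1L, alpha = 0.05,
                   out_dir = "paleorange_out", seed = 1L,
                   exclusions = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("counts", "ages", "meta")) {
    if (is.null(cfg[[f]])) abort(paste0("config missing field: ", f))
  }
  cfg
}

#' Execute a YAML-configured run end to end
#'
#' @param config path to a YAML config ([read_run_config()]) or the
#'   already-parsed list.
#' @return The `range_run`, invisibly, after writing results to
#'   `cfg$out_dir`.
#' @export
run_from_config <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  set.seed(as.integer(cfg$seed))
  excl <- if (!is.null(cfg$exclusions)) read_delim_auto(cfg$exclusions) else NULL
  run <- run_pipeline(counts_path = cfg$counts, ages_path = cfg$ages,
                      meta_path = cfg$meta, exclusions = excl,
                      label = cfg$label, edge_samples = cfg$edge_samples,
                      min_error_samples = cfg$min_error_samples,
                      alpha = cfg$alpha)
  write_results(run, cfg$out_dir)
  invisible(run)
}
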