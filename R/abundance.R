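#' Per-sample relative abundance of species-level taxa
#'
#' Standardizes raw specimen counts to percent relative abundance within
#' each sample, `p_ij = 100 * n_ij / N_j`, where `N_j` is the total number
#' of species-level specimens in sample `j`. Genus- and higher-level
#' columns are excluded from both numerator and denominator, so percentages
#' are shares of the species-level assemblage and sum to 100 within every
#' sample.
#'
#' @param table an [occurrence_table()].
#' @return A long tibble: `sample_id`, `age`, `taxon_id`, `count`,
#'   `sample_total` (`N_j`), `rel_abund` (percent).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  sp <- table$meta$taxon_id[table$meta$species_level]
  if (length(sp) == 0) abort("no species-level taxa in table")
  counts <- table$counts[, sp, drop = FALSE]
  totals <- unname(rowSums(counts))
  if (any(totals == 0)) {
    abort(paste0("sample(s) with zero species-level specimens: ",
                 paste(head(rownames(counts)[totals == 0], 5), collapse = ", ")))
  }
  tibble::as_tibble(counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon_id",
                        values_to = "count") |>
    dplyr::left_join(
      tibble::tibble(sample_id = rownames(counts), age = table$samples$age,
                     sample_total = totals),
      by = "sample_id"
    ) |>
    dplyr::mutate(rel_abund = 100 * .data$count / .data$sample_total) |>
    dplyr::select("sample_id", "age", "taxon_id", "count", "sample_total",
                  "rel_abund")
}

#' Per-species abundance summaries over each species' range
#'
#' For every vetted species, computes the mean, maximum and standard
#' deviation of its percent relative abundance across **all** samples lying
#' between its first and last occurrence, counting samples where it was not
#' observed as zeros. Zero-inclusive averaging is what lets the mean drop
#' below the smallest possible nonzero single-sample share, as observed in
#' real assemblage data. The standard deviation uses the n-1 denominator.
#' Natural-log transforms of the percent values (`ln_mean_ra` etc.) are
#' attached for regression use; `ln_sd_ra` is `NA` where the SD is zero
#' (flat single- or constant-abundance records), and such species are
#' dropped from SD-based regressions only.
#'
#' @param abund long abundance tibble from [relative_abundance()].
#' @param ranges vetting tibble from [vet_species()]; species with no
#'   occurrences are skipped.
#' @param table the [occurrence_table()] the other two came from (supplies
#'   the sample ordering).
#' @return `ranges` with columns `mean_ra`, `max_ra`, `sd_ra`, `ln_mean_ra`,
#'   `ln_max_ra`, `ln_sd_ra` appended.
#' @export
abundance_summary <- function(abund, ranges, table) {
  stopifnot(inherits(table, "occurrence_table"))
  sample_order <- table$samples$sample_id
  ra_mat <- abund |>
    dplyr::select("sample_id", "taxon_id", "rel_abund") |>
    tidyr::pivot_wider(names_from = "taxon_id", values_from = "rel_abund")
  ra_mat <- ra_mat[match(sample_order, ra_mat$sample_id), , drop = FALSE]

  stats <- purrr::pmap_dfr(
    dplyr::select(ranges, "taxon_id", "fo_index", "lo_index"),
    function(taxon_id, fo_index, lo_index) {
      if (is.na(fo_index) || !taxon_id %in% names(ra_mat)) {
        return(tibble::tibble(taxon_id = taxon_id, mean_ra = NA_real_,
                              max_ra = NA_real_, sd_ra = NA_real_))
      }
      p <- ra_mat[[taxon_id]][fo_index:lo_index]
      tibble::tibble(
        taxon_id = taxon_id,
        mean_ra = mean(p),
        max_ra = max(p),
        sd_ra = if (length(p) > 1) sd(p) else 0
      )
    }
  )
  ranges |>
    dplyr::left_join(stats, by = "taxon_id") |>
    dplyr::mutate(
      ln_mean_ra = ifelse(.data$mean_ra > 0, log(.data$mean_ra), NA_real_),
      ln_max_ra = ifelse(.data$max_ra > 0, log(.data$max_ra), NA_real_),
      ln_sd_ra = ifelse(.data$sd_ra > 0, log(.data$sd_ra), NA_real_)
    )
}

#' Per-sample raw species richness
#'
#' @param table an [occurrence_table()].
#' @return Tibble `sample_id`, `age`, `richness` — the number of
#'   species-level taxa with a positive count in each sample.
#' @export
sample_richness <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  sp <- table$meta$taxon_id[table$meta$species_level]
  tibble::tibble(
    sample_id = rownames(table$counts),
    age = table$samples$age,
    richness = unname(rowSums(table$counts[, sp, drop = FALSE] > 0))
  )
}

#' Good-Turing/Chao sample coverage
#'
#' Estimates the fraction of an assemblage's individuals belonging to
#' species already seen in the sample — the standard check that counting a
#' sample was carried far enough. With `n` specimens, `f1` singleton
#' species and `f2` doubletons:
#' \deqn{C = 1 - \frac{f_1}{n}\,\frac{(n-1)f_1}{(n-1)f_1 + 2f_2}.}
#' When no species is a singleton, coverage is exactly 1.
#'
#' @param x specimen counts for the species-level taxa of one sample
#'   (zeros allowed and ignored).
#' @return Tibble with one row: `n`, `f1`, `f2`, `coverage` in \[0, 1\].
#' @examples
#' coverage_estimate(c(90, 5, rep(1, 5))) # n = 100 with 5 singletons
#' @export
coverage_estimate <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  stopifnot(n >= 1)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  C <- if (f1 == 0) {
    1
  } else if (n == 1) {
    0  # a single singleton specimen: no evidence of coverage
  } else {
    1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  }
  tibble::tibble(n = n, f1 = f1, f2 = f2, coverage = C)
}

#' Coverage for every sample of a table
#'
#' @param table an [occurrence_table()].
#' @return Tibble `sample_id`, `age`, `n`, `f1`, `f2`, `coverage`.
#' @export
sample_coverage <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  sp <- table$meta$taxon_id[table$meta$species_level]
  purrr::map_dfr(seq_len(nrow(table$counts)), function(j) {
    dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(table$counts)[j],
                     age = table$samples$age[j]),
      coverage_estimate(table$counts[j, sp])
    )
  })
}
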