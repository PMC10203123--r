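#' Build an occurrence table from its components
#'
#' An `occurrence_table` holds an age-dated microfossil count matrix: one row
#' per dated sediment sample, one column per taxon, with specimen counts
#' `n_ij`. Samples are stored oldest-first (decreasing age in Ma); ties in
#' age are broken by `site_id` then `sample_id` so that composite multi-site
#' sections sort deterministically. Taxon metadata records the taxonomic
#' order (`C` = Collodaria, `N` = Nassellaria, `S` = Spumellaria), the
#' biogeographic category (`E` = endemic, `C` = cosmopolitan) and whether the
#' column is a species-level taxon. Genus- and higher-level columns are kept
#' in the object but excluded from every downstream computation.
#'
#' @param counts integer matrix of specimen counts, samples in rows and taxa
#'   in columns, with dimnames `sample_id` x `taxon_id` (any row order; the
#'   constructor sorts by age).
#' @param samples tibble/data frame with columns `sample_id`, `site_id`,
#'   `age` (Ma, non-negative), one row per row of `counts`.
#' @param meta tibble/data frame with columns `taxon_id`, `order_code`
#'   (`"C"`, `"N"` or `"S"`), `biogeo_code` (`"E"` or `"C"`) and
#'   `species_level` (logical), one row per column of `counts`.
#' @return An object of class `occurrence_table`.
#' @examples
#' counts <- matrix(c(0, 3, 1, 2, 0, 4), nrow = 3,
#'                  dimnames = list(c("s1", "s2", "s3"), c("t1", "t2")))
#' samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
#'                           site_id = "siteA", age = c(10, 5, 1))
#' meta <- tibble::tibble(taxon_id = c("t1", "t2"), order_code = "N",
#'                        biogeo_code = "E", species_level = TRUE)
#' occurrence_table(counts, samples, meta)
#' @export
occurrence_table <- function(counts, samples, meta) {
  samples <- tibble::as_tibble(samples)
  meta <- tibble::as_tibble(meta)
  stopifnot(is.matrix(counts))
  need_s <- c("sample_id", "site_id", "age")
  need_m <- c("taxon_id", "order_code", "biogeo_code", "species_level")
  if (!all(need_s %in% names(samples))) {
    abort(paste0("`samples` must have columns: ", paste(need_s, collapse = ", ")))
  }
  if (!all(need_m %in% names(meta))) {
    abort(paste0("`meta` must have columns: ", paste(need_m, collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$site_id <- as.character(samples$site_id)
  meta$taxon_id <- as.character(meta$taxon_id)
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in `samples`")
  if (anyDuplicated(meta$taxon_id)) abort("duplicate taxon_id in `meta`")
  if (any(samples$age < 0)) abort("sample ages must be >= 0 Ma")
  if (!all(meta$order_code %in% c("C", "N", "S"))) {
    abort("order_code must be one of \"C\", \"N\", \"S\"")
  }
  if (!all(meta$biogeo_code %in% c("E", "C"))) {
    abort("biogeo_code must be \"E\" or \"C\"")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry sample_id rownames and taxon_id colnames")
  }
  if (!setequal(rownames(counts), samples$sample_id) ||
      nrow(counts) != nrow(samples)) {
    abort("rownames(counts) must match samples$sample_id")
  }
  if (!setequal(colnames(counts), meta$taxon_id) ||
      ncol(counts) != nrow(meta)) {
    abort("colnames(counts) must match meta$taxon_id")
  }
  validate_counts(counts)

  # oldest first; age ties broken by (site_id, sample_id) so composite
  # sections from several drill sites merge into one deterministic sequence
  ord <- order(-samples$age, samples$site_id, samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  counts <- counts[samples$sample_id, meta$taxon_id, drop = FALSE]
  storage.mode(counts) <- "integer"

  structure(
    list(counts = counts, samples = samples, meta = meta),
    class = "occurrence_table"
  )
}

validate_counts <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "invalid count %s at taxon \"%s\", sample \"%s\": counts must be non-negative integers",
      format(counts[bad[1, , drop = FALSE]]),
      colnames(counts)[bad[1, 2]], rownames(counts)[bad[1, 1]]
    ))
  }
  invisible(counts)
}

#' @export
print.occurrence_table <- function(x, ...) {
  sp <- sum(x$meta$species_level)
  cat(sprintf(
    "<occurrence_table> %d samples (%.2f-%.2f Ma), %d taxa (%d species-level), %s specimens\n",
    nrow(x$counts), max(x$samples$age), min(x$samples$age),
    ncol(x$counts), sp, format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.occurrence_table <- function(x) dim(x$counts)

#' Pivot an occurrence table to a long tibble
#'
#' @param x an [occurrence_table()].
#' @param ... unused.
#' @return A tibble with one row per (sample, taxon) cell: `sample_id`,
#'   `site_id`, `age`, `taxon_id`, `order_code`, `biogeo_code`,
#'   `species_level`, `count`.
#' @importFrom tibble as_tibble
#' @method as_tibble occurrence_table
#' @export
as_tibble.occurrence_table <- function(x, ...) {
  long <- tibble::as_tibble(x$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon_id",
                        values_to = "count")
  long |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::left_join(x$meta, by = "taxon_id") |>
    dplyr::select("sample_id", "site_id", "age", "taxon_id", "order_code",
                  "biogeo_code", "species_level", "count")
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read an occurrence dataset from its three files
#'
#' Reads the wide counts file (first column `sample_id`, remaining columns
#' one per taxon), the sample age file (`sample_id`, `site_id`, `age` in Ma)
#' and the taxon metadata file (`taxon_id`, `order_code`, `biogeo_code`,
#' `species_level`), validates them and returns an age-sorted
#' [occurrence_table()]. Comma vs tab delimiters are auto-detected from the
#' file extension (`.tsv`/`.tab` means tab). Missing count cells are read as
#' zero. A taxon present in the counts but absent from the metadata file is
#' kept with a warning and `species_level = FALSE`, which excludes it from
#' every analysis; a sample missing from the age file is a hard error.
#'
#' @param counts_path,ages_path,meta_path file paths (CSV or TSV).
#' @param quiet suppress the validation summary message.
#' @return An [occurrence_table()].
#' @export
read_occurrences <- function(counts_path, ages_path, meta_path, quiet = FALSE) {
  for (p in c(counts_path, ages_path, meta_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  raw <- read_delim_auto(counts_path)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  counts[is.na(counts)] <- 0
  rownames(counts) <- raw$sample_id

  ages <- read_delim_auto(ages_path)
  if (!all(c("sample_id", "site_id", "age") %in% names(ages))) {
    abort("ages file must have columns sample_id, site_id, age")
  }
  ages$sample_id <- as.character(ages$sample_id)
  missing_s <- setdiff(rownames(counts), ages$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("samples in counts file absent from ages file: ",
                 paste(head(missing_s, 5), collapse = ", ")))
  }
  samples <- dplyr::semi_join(ages, tibble::tibble(sample_id = rownames(counts)),
                              by = "sample_id")

  meta <- read_delim_auto(meta_path)
  if (!all(c("taxon_id", "order_code", "biogeo_code", "species_level")
           %in% names(meta))) {
    abort("meta file must have columns taxon_id, order_code, biogeo_code, species_level")
  }
  meta$taxon_id <- as.character(meta$taxon_id)
  meta$species_level <- as.logical(meta$species_level)
  missing_t <- setdiff(colnames(counts), meta$taxon_id)
  if (length(missing_t) > 0) {
    warn(paste0(length(missing_t),
                " taxa absent from meta file; kept with species_level = FALSE: ",
                paste(head(missing_t, 5), collapse = ", ")))
    meta <- dplyr::bind_rows(meta, tibble::tibble(
      taxon_id = missing_t, order_code = "N", biogeo_code = "C",
      species_level = FALSE
    ))
  }
  meta <- meta[match(colnames(counts), meta$taxon_id), , drop = FALSE]

  tbl <- occurrence_table(counts, samples, meta)
  if (!quiet) {
    inform(sprintf(
      "read %d samples x %d taxa (%d species-level), %s specimens, %.2f-%.2f Ma",
      nrow(tbl$counts), ncol(tbl$counts), sum(tbl$meta$species_level),
      format(sum(tbl$counts), big.mark = ","),
      max(tbl$samples$age), min(tbl$samples$age)
    ))
  }
  tbl
}

#' Write an occurrence table back to the three-file layout
#'
#' Inverse of [read_occurrences()]: writes `<stem>_counts.csv`,
#' `<stem>_ages.csv` and `<stem>_meta.csv`. The round trip is lossless for
#' integer counts and preserves ages to full double precision.
#'
#' @param table an [occurrence_table()].
#' @param stem path stem, e.g. `"out/so"`.
#' @return Invisibly, the three paths written.
#' @export
write_occurrences <- function(table, stem) {
  stopifnot(inherits(table, "occurrence_table"))
  paths <- paste0(stem, c("_counts.csv", "_ages.csv", "_meta.csv"))
  wide <- tibble::as_tibble(table$counts, rownames = "sample_id")
  readr::write_csv(wide, paths[1], progress = FALSE)
  readr::write_csv(table$samples, paths[2], progress = FALSE)
  readr::write_csv(table$meta, paths[3], progress = FALSE)
  invisible(paths)
}

#' Zero out occurrences flagged as reworked or misidentified
#'
#' Sets the listed (taxon, sample) cells to zero, the standard treatment for
#' occurrences judged to be reworked specimens or misidentifications (e.g.
#' biostratigraphic marker taxa found far outside their established ranges).
#' All other cells are unchanged.
#'
#' @param table an [occurrence_table()].
#' @param exclusions data frame with columns `taxon_id`, `sample_id`; `NULL`
#'   or zero rows leaves the table untouched.
#' @param quiet suppress the message reporting how many cells were zeroed.
#' @return The modified [occurrence_table()].
#' @export
apply_exclusions <- function(table, exclusions, quiet = FALSE) {
  stopifnot(inherits(table, "occurrence_table"))
  if (is.null(exclusions) || nrow(exclusions) == 0) return(table)
  exclusions <- tibble::as_tibble(exclusions)
  stopifnot(all(c("taxon_id", "sample_id") %in% names(exclusions)))
  bad_t <- setdiff(exclusions$taxon_id, colnames(table$counts))
  bad_s <- setdiff(exclusions$sample_id, rownames(table$counts))
  if (length(bad_t) > 0 || length(bad_s) > 0) {
    abort(paste0("exclusion list references unknown ids: ",
                 paste(c(bad_t, bad_s), collapse = ", ")))
  }
  idx <- cbind(match(exclusions$sample_id, rownames(table$counts)),
               match(exclusions$taxon_id, colnames(table$counts)))
  removed <- sum(table$counts[idx])
  table$counts[idx] <- 0L
  if (!quiet) {
    inform(sprintf("excluded %d flagged occurrences (%d specimens zeroed)",
                   nrow(idx), removed))
  }
  table
}

#' Write the per-species results table
#'
#' One row per species-level taxon with its vetting status, first/last
#' occurrence ages, error-bar size, longevity and abundance summaries —
#' the analysis-ready species table. A zero-row input yields a header-only
#' file. Values survive a write/read round trip to at least 12 significant
#' digits.
#'
#' @param rows tibble of per-species records (see [species_table()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_species_table <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path, progress = FALSE)
  invisible(path)
}
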