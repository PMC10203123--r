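#' First and last occurrence of a counts-by-sample vector
#'
#' @param x non-negative counts for one taxon across the age-ordered sample
#'   sequence (oldest first).
#' @return Integer vector `c(fo = , lo = )` of the oldest and youngest
#'   sample positions with a positive count, or `c(NA, NA)` when the taxon
#'   never occurs.
#' @examples
#' observed_range(c(0, 3, 0, 2, 0)) # fo = 2, lo = 4
#' @export
observed_range <- function(x) {
  hit <- unname(which(x > 0))
  if (length(hit) == 0) return(c(fo = NA_integer_, lo = NA_integer_))
  c(fo = hit[1], lo = hit[length(hit)])
}

#' Mean gap size between occurrences
#'
#' The error bar on a species' first and last occurrence is derived from how
#' gappy its record is: `mean_gap()` measures, in samples, the average
#' length of the maximal runs of zero-count samples strictly between the
#' first and last occurrence. A species seen in every sample of its range
#' (including a single-sample range) has gap 0.
#'
#' The default averages over zero-*runs*. `method = "samples"` instead
#' divides the total number of interior zero samples by the number of
#' consecutive occurrence pairs — an alternative reading of "average gap
#' size" kept for sensitivity analysis.
#'
#' @param x counts (or presence) across the age-ordered sample sequence.
#' @param method `"runs"` (default) or `"samples"`.
#' @return Mean gap size in samples (>= 0); `NA` for a taxon with no
#'   occurrences.
#' @examples
#' mean_gap(c(1, 0, 0, 1, 0, 1)) # runs of length 2 and 1 -> 1.5
#' mean_gap(c(1, 1, 1))          # 0
#' @export
mean_gap <- function(x, method = c("runs", "samples")) {
  method <- match.arg(method)
  r <- observed_range(x)
  if (is.na(r[1])) return(NA_real_)
  inner <- x[r[1]:r[2]] > 0
  occ <- which(inner)
  gaps <- diff(occ) - 1L          # zero samples between consecutive occurrences
  gaps <- gaps[gaps > 0]
  if (length(gaps) == 0) return(0)
  if (method == "runs") mean(gaps) else sum(gaps) / (length(occ) - 1L)
}

#' Error-bar size in samples from the mean gap
#'
#' The mean gap is rounded up to the next whole number of samples; gap-free
#' species receive the minimum error bar, 1 sample by default.
#'
#' @param g mean gap size in samples (from [mean_gap()]).
#' @param min_error minimum error bar in samples.
#' @return Integer number of samples, `>= min_error`.
#' @examples
#' error_samples(1.5) # 2
#' error_samples(0)   # 1
#' @export
error_samples <- function(g, min_error = 1L) {
  stopifnot(all(g >= 0, na.rm = TRUE))
  pmax(as.integer(min_error), as.integer(ceiling(g)))
}

#' Longevity from the two error intervals
#'
#' A species' longevity is the midpoint of its first-occurrence error
#' interval minus the midpoint of its last-occurrence error interval, in
#' millions of years. Degenerate intervals (equal endpoints) are allowed.
#'
#' @param fo_interval,lo_interval length-2 numeric vectors of interval
#'   endpoint ages in Ma (order irrelevant).
#' @return Longevity in my.
#' @examples
#' longevity_estimate(c(8, 6), c(4, 2)) # 7 - 3 = 4 my
#' @export
longevity_estimate <- function(fo_interval, lo_interval) {
  mean(fo_interval) - mean(lo_interval)
}

# Error intervals on FO and LO, one-sided outward: the FO interval extends
# e samples toward the old end (uncertainty on true origination), the LO
# interval e samples toward the young end (true extinction). Positions
# falling off the sequence mark the interval as overflowing.
error_interval_ages <- function(ages, fo, lo, e) {
  n <- length(ages)
  fo_old_idx <- fo - e
  lo_yng_idx <- lo + e
  list(
    fo_overflow = fo_old_idx < 1L,
    lo_overflow = lo_yng_idx > n,
    fo_interval = c(old = if (fo_old_idx >= 1L) ages[fo_old_idx] else NA_real_,
                    young = ages[fo]),
    lo_interval = c(old = ages[lo],
                    young = if (lo_yng_idx <= n) ages[lo_yng_idx] else NA_real_)
  )
}

#' Vet species stratigraphic ranges and compute longevities
#'
#' Implements the full vetting cascade for an age-dated occurrence matrix,
#' retaining only species whose entire stratigraphic range is credibly
#' contained in the study interval:
#'
#' 1. optional exclusion of flagged reworked/misidentified occurrences
#'    ([apply_exclusions()]);
#' 2. **edge filter** — any species with any occurrence in the
#'    `edge_samples` oldest or youngest samples of the composite sequence is
#'    removed (it may range beyond the study interval);
#' 3. **error bars** — the mean gap between occurrences ([mean_gap()]),
#'    rounded up ([error_samples()]), sets a one-sided error interval of
#'    `e` samples beyond the first occurrence (older) and last occurrence
#'    (younger);
#' 4. **overflow filter** — species whose error interval runs off either end
#'    of the sample sequence are removed (possibly extant, or originating
#'    before the record starts);
#' 5. **doubling filter** — species whose outer error-bar span is more than
#'    double their raw observed range are removed as too poorly
#'    constrained (single-sample ranges necessarily fail);
#' 6. **longevity** — for survivors, the midpoint of the first-occurrence
#'    error interval minus the midpoint of the last-occurrence interval,
#'    in millions of years.
#'
#' Only species-level taxa are vetted; genus- and higher-level columns are
#' ignored throughout. Results are identical whether the input rows arrive
#' oldest-first or youngest-first.
#'
#' @param table an [occurrence_table()].
#' @param exclusions optional data frame of flagged `(taxon_id, sample_id)`
#'   occurrences, passed to [apply_exclusions()].
#' @param edge_samples number of samples at each end of the sequence in
#'   which any occurrence disqualifies a species (default 2).
#' @param min_error_samples minimum error bar in samples (default 1).
#' @param gap_method see [mean_gap()].
#' @param quiet suppress the per-status count message.
#' @return A tibble with one row per species-level taxon: `taxon_id`,
#'   `order_code`, `biogeo_code`, `n_occurrences`, `total_count`,
#'   `fo_index`, `lo_index`, `fo_age`, `lo_age` (Ma), `gap_mean`,
#'   `err_samples`, `fo_int_old`, `lo_int_young` (outer error-bar ages, Ma),
#'   `raw_range`, `ext_range` (my), `longevity` (my, `NA` unless included)
#'   and `status` (one of `included`, `excluded_edge`, `excluded_overflow`,
#'   `excluded_doubling`, `excluded_no_occurrence`).
#' @export
vet_species <- function(table, exclusions = NULL, edge_samples = 2L,
                        min_error_samples = 1L,
                        gap_method = c("runs", "samples"), quiet = FALSE) {
  stopifnot(inherits(table, "occurrence_table"), edge_samples >= 0)
  gap_method <- match.arg(gap_method)
  if (!is.null(exclusions)) {
    table <- apply_exclusions(table, exclusions, quiet = quiet)
  }
  ages <- table$samples$age
  n <- length(ages)
  edge_idx <- if (edge_samples > 0) {
    unique(c(seq_len(min(edge_samples, n)),
             seq.int(max(1L, n - edge_samples + 1L), n)))
  } else integer(0)
  sp <- table$meta$taxon_id[table$meta$species_level]

  res <- purrr::map_dfr(sp, function(tid) {
    x <- table$counts[, tid]
    r <- observed_range(x)
    out <- tibble::tibble(
      taxon_id = tid,
      n_occurrences = sum(x > 0), total_count = sum(x),
      fo_index = r[["fo"]], lo_index = r[["lo"]],
      fo_age = NA_real_, lo_age = NA_real_,
      gap_mean = NA_real_, err_samples = NA_integer_,
      fo_int_old = NA_real_, lo_int_young = NA_real_,
      raw_range = NA_real_, ext_range = NA_real_,
      longevity = NA_real_, status = NA_character_
    )
    if (is.na(r[["fo"]])) {
      out$status <- "excluded_no_occurrence"
      return(out)
    }
    out$fo_age <- ages[r[["fo"]]]
    out$lo_age <- ages[r[["lo"]]]
    out$raw_range <- out$fo_age - out$lo_age
    out$gap_mean <- mean_gap(x, method = gap_method)
    out$err_samples <- error_samples(out$gap_mean, min_error_samples)
    iv <- error_interval_ages(ages, r[["fo"]], r[["lo"]], out$err_samples)
    out$fo_int_old <- iv$fo_interval[["old"]]
    out$lo_int_young <- iv$lo_interval[["young"]]
    if (!iv$fo_overflow && !iv$lo_overflow) {
      out$ext_range <- out$fo_int_old - out$lo_int_young
    }
    if (length(edge_idx) > 0 && any(x[edge_idx] > 0)) {
      out$status <- "excluded_edge"
    } else if (iv$fo_overflow || iv$lo_overflow) {
      out$status <- "excluded_overflow"
    } else if (out$ext_range > 2 * out$raw_range) {
      out$status <- "excluded_doubling"
    } else {
      out$status <- "included"
      L <- longevity_estimate(c(out$fo_int_old, out$fo_age),
                              c(out$lo_age, out$lo_int_young))
      if (L <= 0) {
        abort(sprintf("non-positive longevity for taxon \"%s\": age ordering is corrupt", tid))
      }
      out$longevity <- L
    }
    out
  })

  res <- dplyr::left_join(
    res,
    dplyr::select(table$meta, "taxon_id", "order_code", "biogeo_code"),
    by = "taxon_id"
  ) |>
    dplyr::relocate("order_code", "biogeo_code", .after = "taxon_id")

  if (!quiet) {
    tab <- table(res$status)
    inform(paste0("vetting: ",
                  paste(names(tab), tab, sep = " = ", collapse = ", ")))
  }
  res
}
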