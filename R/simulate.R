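#' Bundle synthetic-generator parameters
#'
#' Light validated container for the knobs shared by the generators; mostly
#' useful when driving [simulate_neutral_community()] or
#' [simulate_niche_community()] from a YAML config.
#'
#' @param J community size (individuals), >= 10.
#' @param nu per-birth speciation probability in \[0, 1\].
#' @param n_steps number of Moran birth-death events.
#' @param sample_ages strictly decreasing ages (Ma) at which fossil samples
#'   are taken.
#' @param specimens_per_sample expected species-level specimens per sample.
#' @param abundance_sigma lognormal shape (sd of ln abundance) of the
#'   species abundance distribution.
#' @param coupling_beta true longevity change (my) per ln-unit of mean
#'   abundance in the niche generator.
#' @param noise_sd residual longevity noise (my).
#' @param seed integer seed; equal seeds give bit-identical outputs.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(J = 100, nu = 0.01, n_steps = 5e5,
                       sample_ages = NULL, specimens_per_sample = 1000,
                       abundance_sigma = 2, coupling_beta = 0,
                       noise_sd = 2, seed = 1) {
  stopifnot(J >= 10, nu >= 0, nu <= 1, n_steps >= 1,
            is.null(sample_ages) || all(diff(sample_ages) < 0))
  structure(
    list(J = J, nu = nu, n_steps = n_steps, sample_ages = sample_ages,
         specimens_per_sample = specimens_per_sample,
         abundance_sigma = abundance_sigma, coupling_beta = coupling_beta,
         noise_sd = noise_sd, seed = seed),
    class = "sim_config"
  )
}

# One Moran generation maps to this many millions of years. Calibrated once
# so that the median completed species lifetime at the default J = 100,
# nu = 0.01 lands near 8 my, echoing high-latitude radiolarian medians.
MY_PER_STEP_DEFAULT <- 0.08

#' Zero-sum Moran neutral-drift community simulator
#'
#' The canonical neutral null model: a community of exactly `J` individuals
#' in which, at every step, one uniformly chosen individual dies and is
#' replaced either by the offspring of a uniformly chosen survivor or, with
#' probability `nu`, by the founder of a new species. Total abundance is
#' conserved exactly, so species abundances random-walk and rare species
#' drift to extinction faster than common ones — the mechanism behind the
#' neutral expectation that abundance and longevity are positively
#' correlated. Species lifetimes (birth step to extinction step) and
#' time-averaged abundances are tracked exactly for every species born
#' during the run; the founding community is censored and excluded from
#' lifetime statistics.
#'
#' @param J community size (individuals).
#' @param nu per-birth speciation probability.
#' @param n_steps number of birth-death events.
#' @param my_per_step millions of years per event, used to scale lifetimes
#'   and sample ages.
#' @param sample_ages optional strictly decreasing ages (Ma) at which to
#'   draw fossil samples (multinomial draws of `specimens_per_sample`
#'   specimens from the instantaneous community); ages must lie within the
#'   simulated span `n_steps * my_per_step`.
#' @param specimens_per_sample specimens per fossil sample.
#' @param seed integer seed.
#' @return A list with `species` (tibble of completed lifetimes: `species`,
#'   `birth_step`, `death_step`, `lifetime_steps`, `longevity_my`,
#'   `mean_abundance`), `n_species_born`, `my_per_step`,
#'   `final_community` (per-species abundances at the last step; always
#'   sums to `J`), and — when `sample_ages` is given — `table`, an
#'   [occurrence_table()] of the fossilized record.
#' @export
simulate_neutral_community <- function(J = 100, nu = 0.01, n_steps = 5e5,
                                       my_per_step = MY_PER_STEP_DEFAULT,
                                       sample_ages = NULL,
                                       specimens_per_sample = 1000,
                                       seed = 1) {
  stopifnot(J >= 10, nu >= 0, nu <= 1)
  set.seed(seed)
  n_steps <- as.integer(n_steps)

  sample_steps <- integer(0)
  if (!is.null(sample_ages)) {
    stopifnot(all(diff(sample_ages) < 0), all(sample_ages >= 0))
    total_my <- n_steps * my_per_step
    if (any(sample_ages > total_my)) {
      abort("sample_ages exceed the simulated time span")
    }
    sample_steps <- pmax(1L, pmin(n_steps,
                                  as.integer(round(n_steps - sample_ages / my_per_step))))
  }

  cap <- J + as.integer(ceiling(n_steps * nu + 6 * sqrt(n_steps * nu + 1))) + 16L
  abund <- integer(cap)
  born <- rep(NA_integer_, cap)
  died <- rep(NA_integer_, cap)
  integral <- numeric(cap)
  last_t <- integer(cap)

  com <- rep(1L, J)             # founding monodominant species (censored)
  abund[1] <- J
  n_sp <- 1L

  # pre-drawn randomness, consumed in blocks for speed
  u_death <- ceiling(runif(n_steps) * J)
  u_spec <- runif(n_steps)
  u_parent <- ceiling(runif(n_steps) * (J - 1))

  snapshots <- vector("list", length(sample_steps))
  snap_next <- 1L

  for (t in seq_len(n_steps)) {
    d <- u_death[t]
    sp_d <- com[d]
    if (u_spec[t] < nu) {
      n_sp <- n_sp + 1L
      if (n_sp > cap) {            # rare: extend bookkeeping arrays
        extra <- cap
        abund <- c(abund, integer(extra))
        born <- c(born, rep(NA_integer_, extra))
        died <- c(died, rep(NA_integer_, extra))
        integral <- c(integral, numeric(extra))
        last_t <- c(last_t, integer(extra))
        cap <- cap + extra
      }
      sp_n <- n_sp
      born[sp_n] <- t
      last_t[sp_n] <- t
    } else {
      p <- u_parent[t]
      if (p >= d) p <- p + 1L      # parent drawn among the J - 1 survivors
      sp_n <- com[p]
    }
    if (sp_n != sp_d) {
      integral[sp_d] <- integral[sp_d] + abund[sp_d] * (t - last_t[sp_d])
      last_t[sp_d] <- t
      integral[sp_n] <- integral[sp_n] + abund[sp_n] * (t - last_t[sp_n])
      last_t[sp_n] <- t
      abund[sp_d] <- abund[sp_d] - 1L
      abund[sp_n] <- abund[sp_n] + 1L
      if (abund[sp_d] == 0L) died[sp_d] <- t
      com[d] <- sp_n
    }
    if (snap_next <= length(sample_steps) && t == sample_steps[snap_next]) {
      while (snap_next <= length(sample_steps) && t == sample_steps[snap_next]) {
        snapshots[[snap_next]] <- tabulate(com, nbins = n_sp)
        snap_next <- snap_next + 1L
      }
    }
  }

  ids <- seq_len(n_sp)
  done <- ids[!is.na(born[ids]) & !is.na(died[ids])]
  species <- tibble::tibble(
    species = paste0("sp", done),
    birth_step = born[done],
    death_step = died[done],
    lifetime_steps = died[done] - born[done],
    longevity_my = (died[done] - born[done]) * my_per_step,
    mean_abundance = integral[done] / (died[done] - born[done])
  )

  out <- list(species = species, n_species_born = n_sp - 1L,
              my_per_step = my_per_step,
              final_community = tabulate(com, nbins = n_sp))

  if (length(sample_steps) > 0) {
    counts <- matrix(0L, nrow = length(sample_steps), ncol = n_sp,
                     dimnames = list(sprintf("sim%03d", seq_along(sample_steps)),
                                     paste0("sp", seq_len(n_sp))))
    for (j in seq_along(snapshots)) {
      comp <- snapshots[[j]]
      counts[j, seq_along(comp)] <-
        as.integer(rmultinom(1, specimens_per_sample, prob = comp / sum(comp)))
    }
    seen <- colSums(counts) > 0
    counts <- counts[, seen, drop = FALSE]
    samples <- tibble::tibble(
      sample_id = rownames(counts), site_id = "sim",
      age = sample_ages
    )
    meta <- tibble::tibble(
      taxon_id = colnames(counts),
      order_code = "N", biogeo_code = "E", species_level = TRUE
    )
    out$table <- occurrence_table(counts, samples, meta)
  }
  out
}

#' Draw the niche generator's per-species ground truth
#'
#' Samples species mean abundances from a lognormal species abundance
#' distribution and assigns each species a true longevity
#' `L = L0 + beta * (ln a - mean ln a) + noise`, truncated at
#' `min_longevity` by redrawing the noise. Centering the abundance term
#' keeps the marginal longevity distribution at `L0` whatever the coupling,
#' so the truncation stays a rare event and does not distort the coupling
#' slope. With `coupling_beta = 0` this is the null world in which
#' abundance carries no information about longevity; positive `beta`
#' builds in the neutral-theory expectation.
#'
#' @param n_species number of species.
#' @param l0 median/mean longevity (my) at the mean ln abundance.
#' @param coupling_beta my of longevity per ln-unit of mean abundance.
#' @param abundance_meanlog,abundance_sigma location/shape of ln mean
#'   percent abundance (defaults span roughly four orders of magnitude,
#'   as real assemblage data do).
#' @param noise_sd residual longevity sd (my).
#' @param min_longevity truncation floor (my).
#' @param seed integer seed.
#' @return Tibble: `taxon_id`, `ln_mean_ab` (ln percent), `mean_ab`
#'   (percent), `longevity_true` (my).
#' @export
simulate_species_truth <- function(n_species = 200, l0 = 8.2,
                                   coupling_beta = 0,
                                   abundance_meanlog = log(0.04),
                                   abundance_sigma = 2, noise_sd = 2,
                                   min_longevity = 0.5, seed = 1) {
  set.seed(seed)
  ln_a <- rnorm(n_species, abundance_meanlog, abundance_sigma)
  mu <- l0 + coupling_beta * (ln_a - abundance_meanlog)
  L <- mu + rnorm(n_species, 0, noise_sd)
  for (iter in 1:1000) {
    bad <- L <= min_longevity
    if (!any(bad)) break
    L[bad] <- mu[bad] + rnorm(sum(bad), 0, noise_sd)
  }
  L <- pmax(L, min_longevity + 1e-6)  # pathological configs only
  tibble::tibble(
    taxon_id = sprintf("niche%03d", seq_len(n_species)),
    ln_mean_ab = ln_a, mean_ab = exp(ln_a), longevity_true = L
  )
}

#' Niche-structured occurrence generator with known abundance-longevity
#' coupling
#'
#' Builds a full fossil occurrence dataset from the ground truth of
#' [simulate_species_truth()]: each species' range (of its true longevity)
#' is placed uniformly within the study interval, its within-range
#' abundance wiggles lognormally around its mean, and each sample is a
#' multinomial draw of `specimens_per_sample` specimens from the species
#' present at that age. Because the true `(ln a, L)` pairs are returned
#' alongside the [occurrence_table()], the whole pipeline (vetting,
#' abundance summaries, regression) can be tested for parameter recovery.
#'
#' @inheritParams simulate_species_truth
#' @param sample_ages strictly decreasing sampling grid (Ma).
#' @param specimens_per_sample species-level specimens per sample.
#' @param within_sd sdlog of the within-range lognormal abundance wiggle.
#' @return List with `table` (an [occurrence_table()]) and `truth` (the
#'   ground-truth tibble, plus the realized `fo_true`/`lo_true` ages).
#' @export
simulate_niche_community <- function(n_species = 200, l0 = 8.2,
                                     coupling_beta = 0,
                                     abundance_meanlog = log(0.04),
                                     abundance_sigma = 2, noise_sd = 2,
                                     min_longevity = 0.5,
                                     sample_ages = seq(25, 0.1,
                                                       length.out = 100),
                                     specimens_per_sample = 3000,
                                     within_sd = 0.5, seed = 1) {
  stopifnot(all(diff(sample_ages) < 0))
  truth <- simulate_species_truth(
    n_species = n_species, l0 = l0, coupling_beta = coupling_beta,
    abundance_meanlog = abundance_meanlog, abundance_sigma = abundance_sigma,
    noise_sd = noise_sd, min_longevity = min_longevity, seed = seed
  )
  # simulate_species_truth() set the seed; continue the same stream
  max_age <- max(sample_ages)
  min_age <- min(sample_ages)
  span <- max_age - min_age
  L <- pmin(truth$longevity_true, span)
  lo_true <- min_age + runif(nrow(truth)) * (span - L)
  fo_true <- lo_true + L
  truth$fo_true <- fo_true
  truth$lo_true <- lo_true

  n_s <- length(sample_ages)
  counts <- matrix(0L, nrow = n_s, ncol = nrow(truth),
                   dimnames = list(sprintf("ns%03d", seq_len(n_s)),
                                   truth$taxon_id))
  for (j in seq_len(n_s)) {
    a <- sample_ages[j]
    present <- which(fo_true >= a & lo_true <= a)
    if (length(present) == 0) present <- which.max(fo_true - lo_true)
    w <- truth$mean_ab[present] *
      rlnorm(length(present), -within_sd^2 / 2, within_sd)
    counts[j, present] <-
      as.integer(rmultinom(1, specimens_per_sample, prob = w))
  }
  samples <- tibble::tibble(sample_id = rownames(counts), site_id = "niche",
                            age = sample_ages)
  meta <- tibble::tibble(
    taxon_id = truth$taxon_id,
    order_code = sample(c("C", "N", "S"), nrow(truth), replace = TRUE,
                        prob = c(15, 135, 39)),
    biogeo_code = sample(c("E", "C"), nrow(truth), replace = TRUE,
                         prob = c(0.6, 0.4)),
    species_level = TRUE
  )
  list(table = occurrence_table(counts, samples, meta), truth = truth)
}

#' Region-shaped synthetic occurrence fixtures
#'
#' Generates occurrence datasets with the gross shape of the two study
#' regions so the pipeline can be exercised end to end without external
#' data: `"SO"` — a Southern-Ocean-like composite of 97 samples spanning
#' 22.65–0.04 Ma with about 7,190 species-level specimens and 100–200
#' species per sample; `"EEP"` — an eastern-equatorial-Pacific-like single
#' site of 14 samples spanning 10.3–0 Ma with about 2,500 species-level
#' specimens and ~356 species per sample. Species ranges, lognormal
#' abundances, taxonomic order codes (C/N/S in region-like proportions),
#' biogeographic codes and a handful of genus-level columns are all
#' synthetic; these fixtures reproduce dataset *shape*, not the published
#' measurements.
#'
#' @param which `"SO"` or `"EEP"`.
#' @param seed integer seed.
#' @return An [occurrence_table()].
#' @export
simulate_fixture <- function(which = c("SO", "EEP"), seed = 1) {
  which <- match.arg(which)
  set.seed(seed)
  if (which == "SO") {
    ages <- seq(22.65, 0.04, length.out = 97)
    n_species <- 650; n_genus <- 8
    specimens <- 7190; genus_specimens <- 250
    dur_meanlog <- log(8); dur_sdlog <- 0.6
    sigma <- 1.5
    order_prob <- c(15, 135, 39)
    sites <- rep(sprintf("site%d", 1:4), length.out = 97)
    prefix <- "so"
  } else {
    ages <- seq(10.3, 0, length.out = 14)
    n_species <- 800; n_genus <- 6
    specimens <- 2500; genus_specimens <- 120
    dur_meanlog <- log(8); dur_sdlog <- 0.9
    sigma <- 0.8
    order_prob <- c(12, 58, 31)
    sites <- rep("U-site", 14)
    prefix <- "eep"
  }
  max_age <- max(ages); min_age <- min(ages)
  dur <- rlnorm(n_species, dur_meanlog, dur_sdlog)
  # origination uniform over an interval padded by the mean duration so
  # ranges straddle both ends of the record, as real data do
  fo <- runif(n_species, min_age - exp(dur_meanlog) / 2,
              max_age + exp(dur_meanlog))
  lo <- fo - dur
  base_ab <- rlnorm(n_species, 0, sigma)
  wiggle_sd <- 0.6

  n_s <- length(ages)
  counts <- matrix(0L, nrow = n_s, ncol = n_species + n_genus)
  taxa <- c(sprintf("%s_sp%03d", prefix, seq_len(n_species)),
            sprintf("%s_gen%02d", prefix, seq_len(n_genus)))
  dimnames(counts) <- list(sprintf("%s%03d", prefix, seq_len(n_s)), taxa)
  genus_ab <- rlnorm(n_genus, 0, 0.8)
  for (j in seq_len(n_s)) {
    a <- ages[j]
    present <- which(fo >= a & lo <= a)
    w <- base_ab[present] * rlnorm(length(present), -wiggle_sd^2 / 2, wiggle_sd)
    counts[j, present] <- as.integer(rmultinom(1, specimens, prob = w))
    counts[j, n_species + seq_len(n_genus)] <-
      as.integer(rmultinom(1, genus_specimens, prob = genus_ab))
  }
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  is_sp <- grepl("_sp", colnames(counts))
  meta <- tibble::tibble(
    taxon_id = colnames(counts),
    order_code = sample(c("C", "N", "S"), ncol(counts), replace = TRUE,
                        prob = order_prob),
    biogeo_code = sample(c("E", "C"), ncol(counts), replace = TRUE),
    species_level = is_sp
  )
  samples <- tibble::tibble(sample_id = rownames(counts), site_id = sites,
                            age = ages)
  occurrence_table(counts, samples, meta)
}
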