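# Shared in-code fixtures. The toy vetting matrix is hand-enumerated:
# 10 samples, ages 10..1 Ma (oldest first), edge zone = samples {1,2,9,10}.
#
#   sp_included  occurs at indices 3-7, gap-free.
#                  g = 0, e = 1, fo_int = [9,8] (ages), lo_int = [4,3];
#                  raw = 8-4 = 4, ext = 9-3 = 6 <= 8  -> included,
#                  L = 8.5 - 3.5 = 5 my.
#   sp_edge      occurs at index 2 (second-oldest) and 5 -> excluded_edge.
#   sp_overflow  occurs at 3 and 8 only: one zero-run of 4 -> g = 4, e = 4;
#                  fo needs index -1 -> fo interval overflows
#                  -> excluded_overflow.
#   sp_doubling  occurs at 4 and 5: g = 0, e = 1, raw = 7-6 = 1,
#                  ext = 8-5 = 3 > 2 -> excluded_doubling.
#   sp_single    occurs only at 5: raw = 0, ext > 0 -> excluded_doubling.
#   sp_absent    never occurs -> excluded_no_occurrence.
toy_statuses <- c(
  sp_included = "included", sp_edge = "excluded_edge",
  sp_overflow = "excluded_overflow", sp_doubling = "excluded_doubling",
  sp_single = "excluded_doubling", sp_absent = "excluded_no_occurrence"
)

toy_table <- function() {
  occ <- rbind(
    sp_included = c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0),
    sp_edge     = c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0),
    sp_overflow = c(0, 0, 2, 0, 0, 0, 0, 3, 0, 0),
    sp_doubling = c(0, 0, 0, 2, 2, 0, 0, 0, 0, 0),
    sp_single   = c(0, 0, 0, 0, 7, 0, 0, 0, 0, 0),
    sp_absent   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  counts <- t(occ)
  rownames(counts) <- sprintf("s%02d", 1:10)
  occurrence_table(
    counts,
    samples = tibble::tibble(sample_id = rownames(counts), site_id = "toy",
                             age = 10:1),
    meta = tibble::tibble(taxon_id = colnames(counts), order_code = "N",
                          biogeo_code = "E", species_level = TRUE)
  )
}

# minimal 3-sample x 2-taxon table from the read/write examples
tiny_table <- function() {
  counts <- matrix(c(0L, 3L, 1L, 2L, 0L, 4L), nrow = 3,
                   dimnames = list(c("s1", "s2", "s3"), c("t1", "t2")))
  occurrence_table(
    counts,
    samples = tibble::tibble(sample_id = c("s1", "s2", "s3"),
                             site_id = "A", age = c(10, 5, 1)),
    meta = tibble::tibble(taxon_id = c("t1", "t2"), order_code = "N",
                          biogeo_code = "E", species_level = TRUE)
  )
}

# closed-form two-variable least squares, the independent OLS oracle
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  se_b1 <- sqrt(sse / (n - 2) / sxx)
  tstat <- b1 / se_b1
  list(b0 = b0, b1 = b1, r2 = 1 - sse / sst,
       p = 2 * pt(-abs(tstat), n - 2))
}

# one-way ANOVA as a regression on group dummies, the independent oracle
anova_oracle <- function(y, g) {
  g <- factor(g)
  X <- model.matrix(~g)
  fit <- lm.fit(X, y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  df_b <- nlevels(g) - 1
  df_w <- length(y) - nlevels(g)
  f <- ((sst - sse) / df_b) / (sse / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}
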