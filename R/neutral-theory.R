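#' Expected age of a neutral allele at a given frequency
#'
#' Mean age (in generations) of a segregating neutral allele observed at
#' population frequency `x` in a Wright-Fisher population of effective size
#' `Ne`, from the classical diffusion result of Kimura & Ohta (1973, "The
#' age of a neutral mutant persisting in a finite population", Genetics 75):
#' \deqn{\bar t(x) = \frac{-4 N_e \, x \log x}{1 - x}.}
#' The function is strictly increasing in `x` and tends to `4 Ne` as
#' `x -> 1`.
#'
#' @param x derived allele frequency, strictly between 0 and 1 (vectorized).
#' @param Ne effective population size (diploid), `>= 1`.
#' @return Expected allele age in generations.
#' @export
expected_neutral_age <- function(x, Ne) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    abort("allele frequency x must lie strictly inside (0, 1)")
  }
  if (Ne < 1) abort("Ne must be >= 1")
  -4 * Ne * x * log(x) / (1 - x)
}

#' Sanity-check allele ages against the neutral age-frequency relationship
#'
#' Under neutrality, older alleles are found on average at higher
#' frequencies. This check bins neutral sites by derived allele frequency,
#' contrasts the mean observed age per bin with the Kimura-Ohta expectation
#' [expected_neutral_age()], and reports the Spearman rank correlation
#' between age and frequency. The verdict is `"pass"` when the correlation
#' is positive and significant (p < `alpha`), otherwise `"warn"`.
#'
#' @param sites a tibble of neutral sites with `derived_freq` and `age`
#'   columns; at least 100 age-annotated sites are required.
#' @param Ne effective population size used for the theoretical curve.
#' @param n_bins number of equal-width frequency bins for the report table.
#' @param alpha significance level for the correlation test.
#' @return An object of class `age_sanity_report`: a list with `table`
#'   (per-bin observed vs expected mean ages), `rho`, `p_value`, `verdict`.
#' @export
age_frequency_sanity_check <- function(sites, Ne, n_bins = 10, alpha = 0.01) {
  s <- sites[!is.na(sites$age) & is.finite(sites$derived_freq) &
               sites$derived_freq > 0 & sites$derived_freq < 1, , drop = FALSE]
  if (nrow(s) < 100) {
    abort(paste0("need at least 100 age-annotated neutral sites, got ", nrow(s)))
  }
  ct <- suppressWarnings(
    cor.test(s$derived_freq, s$age, method = "spearman", exact = FALSE,
             alternative = "greater"))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  s$.bin <- cut(s$derived_freq, breaks = breaks, include.lowest = TRUE)
  tab <- s |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_freq = mean(.data$derived_freq),
      mean_age_observed = mean(.data$age),
      .groups = "drop") |>
    dplyr::mutate(mean_age_expected = expected_neutral_age(.data$mean_freq, Ne)) |>
    dplyr::rename(freq_bin = ".bin")
  verdict <- if (!is.na(ct$p.value) && ct$estimate > 0 && ct$p.value < alpha)
    "pass" else "warn"
  structure(
    list(table = tab, rho = unname(ct$estimate), p_value = ct$p.value,
         n_sites = nrow(s), Ne = Ne, verdict = verdict),
    class = "age_sanity_report")
}

#' @export
print.age_sanity_report <- function(x, ...) {
  cat("Allele age vs frequency sanity check\n")
  cat(sprintf("  sites: %d   Ne: %g\n", x$n_sites, x$Ne))
  cat(sprintf("  Spearman rho = %.3f (one-sided p = %.3g)\n", x$rho, x$p_value))
  cat(sprintf("  verdict: %s\n", x$verdict))
  print(x$table)
  invisible(x)
}

#' @exportS3Method
tidy.age_sanity_report <- function(x, ...) x$table

#' @exportS3Method
glance.age_sanity_report <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n_sites = x$n_sites,
         Ne = x$Ne, verdict = x$verdict)
}
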