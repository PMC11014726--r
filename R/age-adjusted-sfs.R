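#' Assign equal-count allele-age bins
#'
#' Sorts sites by age (stable, ties broken by `variant_id`) and splits them
#' into `n_bins` bins holding equal numbers of observations, youngest bin
#' first. When `n` is not divisible by `n_bins`, the first `n mod n_bins`
#' bins hold one extra site.
#'
#' @param sites a tibble with `age` (generations, no `NA`) and `variant_id`
#'   columns.
#' @param n_bins number of age bins (default 5).
#' @param min_bin_count if not `NULL`, warn when any bin holds fewer sites
#'   than this (small bins make the per-bin delta-frequency estimates
#'   noisy).
#' @return An object of class `age_binning`: a list with `assignment` (the
#'   input sites plus a `bin` integer column), `bins` (per-bin `n`,
#'   `age_min`, `age_max`) and `n_bins`.
#' @export
assign_equal_count_age_bins <- function(sites, n_bins = 5, min_bin_count = NULL) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (any(is.na(sites$age))) abort("all sites must be age-annotated (no NA ages)")
  n <- nrow(sites)
  if (n < n_bins) abort(paste0("need at least n_bins = ", n_bins, " sites, got ", n))
  ord <- order(sites$age, sites$variant_id, method = "radix")
  s <- sites[ord, , drop = FALSE]
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= rem)
  s$bin <- rep.int(seq_len(n_bins), times = sizes)
  bins <- s |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), age_min = min(.data$age),
                     age_max = max(.data$age), .groups = "drop")
  if (!is.null(min_bin_count) && any(bins$n < min_bin_count)) {
    warn(paste0("some age bins hold fewer than ", min_bin_count,
                " sites; per-bin delta-frequency estimates will be noisy"))
  }
  structure(list(assignment = s, bins = bins, n_bins = n_bins),
            class = "age_binning")
}

#' Age-matched down-sampling of the neutral pool
#'
#' For each focal age bin, samples (without replacement) as many neutral
#' sites as the bin holds, restricted to neutral sites whose ages fall in
#' the bin's age range, so the matched neutral set reproduces both the size
#' and the age distribution of the focal set. When a bin's age range holds
#' too few unused neutral sites, the nearest-age unused neutral sites are
#' borrowed, with a warning.
#'
#' @param neutral a tibble of neutral sites with `age` and `derived_freq`.
#' @param binning an [assign_equal_count_age_bins()] result from the focal
#'   sites.
#' @param seed optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return The matched neutral subset with a `bin` column.
#' @export
match_downsample_neutral <- function(neutral, binning, seed = NULL) {
  stopifnot(inherits(binning, "age_binning"))
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(neutral$age))) neutral <- neutral[!is.na(neutral$age), , drop = FALSE]
  n_needed <- sum(binning$bins$n)
  if (nrow(neutral) < n_needed) {
    abort(paste0("neutral pool (", nrow(neutral),
                 ") smaller than the focal set (", n_needed, ")"))
  }
  idx <- match_indices(neutral$age, binning$bins)
  out <- neutral[idx$index, , drop = FALSE]
  out$bin <- idx$bin
  if (idx$n_borrowed > 0) {
    warn(paste0("neutral pool short in some age bins; borrowed ",
                idx$n_borrowed, " nearest-age neutral sites"))
  }
  out
}

# core matching engine: returns indices into the original age vector plus
# bin labels. Works on the age-sorted order so per-bin candidates are
# contiguous; callers that resample repeatedly pass the sort once.
match_indices <- function(ages, bins, ord = order(ages, method = "radix"),
                          sorted = ages[ord]) {
  n <- length(sorted)
  used <- logical(n)
  take_idx <- integer(0)
  take_bin <- integer(0)
  n_borrowed <- 0L
  for (b in seq_len(nrow(bins))) {
    k <- bins$n[b]
    lo <- bins$age_min[b]
    hi <- bins$age_max[b]
    i1 <- findInterval(lo, sorted, left.open = TRUE) + 1L  # first >= lo
    i2 <- findInterval(hi, sorted)                         # last <= hi
    cand <- if (i2 >= i1) (i1:i2)[!used[i1:i2]] else integer(0)
    if (length(cand) >= k) {
      pick <- if (length(cand) == k) cand else cand[sample.int(length(cand), k)]
    } else {
      pick <- cand
      short <- k - length(cand)
      n_borrowed <- n_borrowed + short
      avail <- which(!used)
      avail <- setdiff(avail, cand)
      # distance from each available neutral age to the bin's age range
      d <- pmax(0, lo - sorted[avail], sorted[avail] - hi)
      if (length(avail) < short) {
        abort("neutral pool exhausted while matching age bins")
      }
      pick <- c(pick, avail[order(d, method = "radix")[seq_len(short)]])
    }
    used[pick] <- TRUE
    take_idx <- c(take_idx, ord[pick])
    take_bin <- c(take_bin, rep.int(b, length(pick)))
  }
  list(index = take_idx, bin = take_bin, n_borrowed = n_borrowed)
}

#' Delta frequency of one age bin
#'
#' The difference between the average derived allele frequency of the focal
#' sites and of the (age-matched) neutral sites in one age bin:
#' `delta = mean(focal) - mean(neutral)`. Close to 0 when the focal sites
#' evolve neutrally; negative under purifying selection.
#'
#' @param focal_freqs,neutral_freqs non-empty numeric vectors of derived
#'   allele frequencies.
#' @return A scalar in \[-1, 1\].
#' @export
delta_frequency <- function(focal_freqs, neutral_freqs) {
  if (length(focal_freqs) == 0 || length(neutral_freqs) == 0) {
    abort("delta_frequency requires non-empty frequency vectors")
  }
  mean(focal_freqs) - mean(neutral_freqs)
}

#' Resampled per-bin delta-frequency estimates (age-adjusted SFS)
#'
#' Computes the age-adjusted SFS: focal sites are split into equal-count
#' age bins, and `reps` independent age-matched down-samples of the neutral
#' pool each yield one delta-frequency estimate per bin.
#'
#' @param focal tibble of focal sites (`age`, `derived_freq`, `variant_id`).
#' @param neutral tibble of neutral sites (`age`, `derived_freq`).
#' @param n_bins number of equal-count age bins (default 5).
#' @param reps number of down-sampling repetitions (default 100).
#' @param seed master seed; per-repetition seeds are derived from it.
#' @param min_bin_count passed to [assign_equal_count_age_bins()].
#' @return An object of class `delta_frequency_result`: a list with
#'   `deltas` (tibble: `replicate`, `bin`, `delta`), `binning`, `reps`,
#'   `seed`, `n_focal`, `n_neutral`.
#' @export
resample_delta <- function(focal, neutral, n_bins = 5, reps = 100, seed = 1,
                           min_bin_count = NULL) {
  if (reps < 2) abort("reps must be >= 2")
  focal <- focal[!is.na(focal$age), , drop = FALSE]
  neutral <- neutral[!is.na(neutral$age), , drop = FALSE]
  binning <- assign_equal_count_age_bins(focal, n_bins = n_bins,
                                         min_bin_count = min_bin_count)
  focal_means <- binning$assignment |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(m = mean(.data$derived_freq), .groups = "drop")

  nb <- nrow(binning$bins)
  ages <- neutral$age
  freqs <- neutral$derived_freq
  ord <- order(ages, method = "radix")
  sorted <- ages[ord]
  borrowed <- 0L
  mat <- matrix(NA_real_, nrow = reps, ncol = nb)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 104729, r))
    idx <- match_indices(ages, binning$bins, ord = ord, sorted = sorted)
    borrowed <- borrowed + idx$n_borrowed
    f <- factor(idx$bin, levels = seq_len(nb))
    neut_mean <- vapply(split(freqs[idx$index], f), mean, numeric(1))
    mat[r, ] <- focal_means$m - as.numeric(neut_mean)
  }
  if (borrowed > 0) {
    warn(paste0("age matching borrowed ", borrowed,
                " nearest-age neutral sites across ", reps, " repetitions"))
  }
  deltas <- tibble(
    replicate = rep(seq_len(reps), each = nb),
    bin = rep(seq_len(nb), times = reps),
    delta = as.vector(t(mat))
  )
  structure(
    list(deltas = deltas, binning = binning, reps = reps, seed = seed,
         n_focal = nrow(focal), n_neutral = nrow(neutral)),
    class = "delta_frequency_result")
}

#' @export
print.delta_frequency_result <- function(x, ...) {
  cat(sprintf("Age-adjusted SFS: %d focal sites, %d neutral sites, %d bins, %d repetitions\n",
              x$n_focal, x$n_neutral, x$binning$n_bins, x$reps))
  print(tidy(x))
  invisible(x)
}

#' Pooled per-replicate delta estimates for a replicate ensemble
#'
#' For a set of replicate datasets (e.g. the 20 replicates of one simulated
#' (r, S) cell), computes the age-adjusted SFS of each replicate separately
#' -- its own equal-count age binning and `reps` age-matched down-samples --
#' and pools the per-bin delta-frequency estimates across replicates. The
#' pooled estimates feed the same test battery as a single dataset; this is
#' how simulation cells are evaluated, so between-replicate variation enters
#' the tests alongside the down-sampling variation.
#'
#' Because the replicates of one cell are independent samples of the same
#' stationary process, their neutral markers are exchangeable; by default
#' the neutral sites of all replicates form one shared matching pool, so
#' each (small) focal set is matched against a many-fold larger neutral
#' panel -- the situation the down-sampling design presumes, and the one
#' real data present (a large SNP panel against a small TE set).
#'
#' @param samples a list of `wf_sample` tibbles or site tables (each needs
#'   focal and neutral classes; see [as_site_table()]).
#' @param n_bins,reps,seed as in [resample_delta()]; per-replicate seeds are
#'   derived from `seed`.
#' @param shared_neutral_pool when `TRUE` (default), match every
#'   replicate's focal set against the neutral sites pooled across all
#'   replicates; when `FALSE`, each replicate is matched against its own
#'   neutral sites only.
#' @return A `delta_frequency_result` whose `deltas` carry an extra
#'   `replicate_run` column; the binning summary aggregates the
#'   per-replicate bins. Replicates with too few focal or neutral sites are
#'   dropped with a warning (`n_dropped` records how many).
#' @export
resample_delta_ensemble <- function(samples, n_bins = 5, reps = 100, seed = 1,
                                    shared_neutral_pool = TRUE) {
  tables <- lapply(samples, as_site_table)
  pooled_neutral <- if (shared_neutral_pool) {
    p <- dplyr::bind_rows(lapply(tables, function(s) {
      s[s$class == "neutral" & !is.na(s$age), , drop = FALSE]
    }))
    if (nrow(p) == 0) abort("no neutral sites in any replicate")
    p
  } else NULL
  parts <- lapply(seq_along(tables), function(k) {
    sites <- tables[[k]]
    focal <- sites[sites$class == "focal" & !is.na(sites$age), , drop = FALSE]
    neutral <- pooled_neutral %||%
      sites[sites$class == "neutral" & !is.na(sites$age), , drop = FALSE]
    if (nrow(focal) < n_bins || nrow(neutral) < nrow(focal)) return(NULL)
    rd <- resample_delta(focal, neutral, n_bins = n_bins, reps = reps,
                         seed = derive_seed(seed, 31337, k))
    list(deltas = dplyr::mutate(rd$deltas, replicate_run = k),
         bins = rd$binning$bins,
         n_focal = rd$n_focal, n_neutral = rd$n_neutral)
  })
  dropped <- sum(vapply(parts, is.null, logical(1)))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    abort("no replicate held enough focal and neutral sites to evaluate")
  }
  if (dropped > 0) {
    warn(paste0(dropped, " replicates dropped for holding too few sites"))
  }
  bins <- dplyr::bind_rows(lapply(parts, `[[`, "bins")) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = sum(.data$n), age_min = min(.data$age_min),
                     age_max = max(.data$age_max), .groups = "drop")
  structure(
    list(deltas = dplyr::bind_rows(lapply(parts, `[[`, "deltas")),
         binning = list(assignment = NULL, bins = bins, n_bins = n_bins),
         reps = reps, seed = seed,
         n_focal = sum(vapply(parts, `[[`, numeric(1), "n_focal")),
         n_neutral = sum(vapply(parts, `[[`, numeric(1), "n_neutral")),
         n_replicates = length(samples), n_dropped = dropped),
    class = "delta_frequency_result")
}

#' Frequency-matched resampling of the neutral pool
#'
#' Bias-control mode: resamples the neutral pool (without replacement,
#' stratified over ten frequency strata on \[0, 1\]) so its allele-frequency
#' histogram matches that of the focal set. Used to check that differences
#' in how TE and SNP frequencies are estimated do not drive the
#' age-adjusted SFS; it is a separate control, not composed with age
#' matching in the same run.
#'
#' @param neutral tibble of neutral sites with `derived_freq`.
#' @param target_freqs derived allele frequencies of the focal set.
#' @param seed optional integer seed.
#' @param n_strata number of equal-width frequency strata (default 10).
#' @return A resampled neutral tibble whose frequency histogram matches the
#'   target's within one site per stratum (exactly, unless a stratum had to
#'   borrow from its neighbours, which warns).
#' @export
frequency_match_resample <- function(neutral, target_freqs, seed = NULL,
                                     n_strata = 10) {
  if (!is.null(seed)) set.seed(seed)
  breaks <- seq(0, 1, length.out = n_strata + 1)
  strat <- function(x) pmin(pmax(findInterval(x, breaks, left.open = TRUE), 1L), n_strata)
  target_n <- tabulate(strat(target_freqs), nbins = n_strata)
  pool_s <- strat(neutral$derived_freq)
  used <- logical(nrow(neutral))
  take <- integer(0)
  borrowed <- 0L
  for (s in seq_len(n_strata)) {
    k <- target_n[s]
    if (k == 0) next
    cand <- which(pool_s == s & !used)
    if (length(cand) >= k) {
      pick <- if (length(cand) == k) cand else cand[sample.int(length(cand), k)]
    } else {
      pick <- cand
      short <- k - length(cand)
      borrowed <- borrowed + short
      avail <- which(!used)
      avail <- setdiff(avail, cand)
      d <- abs(pool_s[avail] - s)
      pick <- c(pick, avail[order(d)[seq_len(min(short, length(avail)))]])
    }
    used[pick] <- TRUE
    take <- c(take, pick)
  }
  if (borrowed > 0) {
    warn(paste0("frequency matching borrowed ", borrowed,
                " sites from neighbouring strata"))
  }
  neutral[take, , drop = FALSE]
}

#' Test per-bin delta frequency against zero
#'
#' One-sample one-sided Wilcoxon signed-rank tests of the resampled
#' delta-frequency estimates against 0 (alternative: less), Bonferroni
#' corrected over the bins of the dataset.
#'
#' @param result a [resample_delta()] result.
#' @param alpha significance level applied to the corrected p-values.
#' @return A tibble with `bin`, `median_delta`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
test_delta_below_zero <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "delta_frequency_result"))
  B <- result$binning$n_bins
  by_bin <- split(result$deltas$delta,
                  factor(result$deltas$bin, levels = seq_len(B)))
  p <- vapply(by_bin, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0 || all(d == 0)) return(1)
    suppressWarnings(
      wilcox.test(d, mu = 0, alternative = "less", exact = FALSE)$p.value)
  }, numeric(1))
  tibble(
    bin = as.integer(names(by_bin)),
    median_delta = vapply(by_bin, stats::median, numeric(1), na.rm = TRUE),
    p_value = unname(p),
    p_adjusted = pmin(1, unname(p) * B),
    significant = pmin(1, unname(p) * B) < alpha
  )
}

#' Test whether the oldest bin's delta frequency is below all other bins
#'
#' Two-sample one-sided Wilcoxon rank-sum tests of the oldest bin's
#' delta-frequency estimates against each other bin (alternative: less),
#' Bonferroni corrected over the `n_bins - 1` comparisons. The
#' `pattern_reproduced` attribute is `TRUE` when every comparison is
#' significant -- the signature of purifying selection on the focal set.
#'
#' @inheritParams test_delta_below_zero
#' @return A tibble with one row per non-oldest bin (`bin`, `p_value`,
#'   `p_adjusted`, `significant`) carrying attribute `pattern_reproduced`;
#'   read it with [pattern_reproduced()].
#' @export
test_oldest_vs_others <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "delta_frequency_result"))
  B <- result$binning$n_bins
  by_bin <- split(result$deltas$delta,
                  factor(result$deltas$bin, levels = seq_len(B)))
  oldest <- by_bin[[as.character(B)]]
  others <- setdiff(as.integer(names(by_bin)), B)
  p <- vapply(others, function(b) {
    suppressWarnings(
      wilcox.test(oldest, by_bin[[as.character(b)]], alternative = "less",
                  exact = FALSE)$p.value)
  }, numeric(1))
  out <- tibble(
    bin = others,
    p_value = p,
    p_adjusted = pmin(1, p * (B - 1)),
    significant = pmin(1, p * (B - 1)) < alpha
  )
  attr(out, "pattern_reproduced") <- all(out$significant)
  out
}

#' Extract the pattern-reproduced flag from [test_oldest_vs_others()]
#' @param x a [test_oldest_vs_others()] result.
#' @return `TRUE` when the oldest bin's delta frequency was significantly
#'   below every other bin.
#' @export
pattern_reproduced <- function(x) {
  isTRUE(attr(x, "pattern_reproduced"))
}

#' Run the full age-adjusted SFS analysis
#'
#' Convenience wrapper: optional frequency-matched control resampling of
#' the neutral pool, resampled per-bin delta-frequency estimation, and the
#' two Wilcoxon test batteries.
#'
#' @inheritParams resample_delta
#' @param alpha significance level for the Bonferroni-corrected tests.
#' @param freq_match when `TRUE`, first resample the neutral pool to match
#'   the focal frequency distribution ([frequency_match_resample()]); this
#'   is a bias-control mode and deliberately not composed with age matching
#'   in the same run (matching both age and frequency would force delta
#'   toward 0 by construction).
#' @return A `delta_frequency_result` with extra elements `below_zero` and
#'   `oldest_vs_others` (test tables) and `pattern_reproduced`.
#' @export
age_adjusted_sfs <- function(focal, neutral, n_bins = 5, reps = 100, seed = 1,
                             alpha = 0.01, freq_match = FALSE,
                             min_bin_count = 50) {
  focal <- focal[!is.na(focal$age), , drop = FALSE]
  neutral <- neutral[!is.na(neutral$age), , drop = FALSE]
  if (freq_match) {
    neutral <- frequency_match_resample(neutral, focal$derived_freq,
                                        seed = derive_seed(seed, 7))
  }
  res <- resample_delta(focal, neutral, n_bins = n_bins, reps = reps,
                        seed = seed, min_bin_count = min_bin_count)
  res$below_zero <- test_delta_below_zero(res, alpha = alpha)
  res$oldest_vs_others <- test_oldest_vs_others(res, alpha = alpha)
  res$pattern_reproduced <- pattern_reproduced(res$oldest_vs_others)
  res
}

#' Down-sample comparison site sets to a fixed maximum
#'
#' Caps the number of sites per group (e.g. non-synonymous and high-effect
#' SNP sets per clade) at `max_n` by simple random sampling without
#' replacement, leaving smaller groups untouched.
#'
#' @param sites a site tibble.
#' @param by grouping columns present in `sites` (missing ones ignored).
#' @param max_n maximum sites per group (default 10000).
#' @param seed integer seed.
#' @return The down-sampled tibble.
#' @export
cap_group_size <- function(sites, by = c("clade", "effect", "class"),
                           max_n = 10000, seed = 1) {
  set.seed(seed)
  sites |>
    dplyr::group_by(dplyr::across(dplyr::any_of(by))) |>
    dplyr::slice_sample(n = max_n) |>
    dplyr::ungroup()
}
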