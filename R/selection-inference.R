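#' Screen a simulation grid for the purifying-selection spectrum shape
#'
#' For every (neutral ratio r, selection strength S) cell of a simulated
#' grid, computes the age-adjusted SFS of every replicate (focal mutations
#' against neutral markers), pools the per-replicate delta-frequency
#' estimates ([resample_delta_ensemble()]), and flags whether the oldest
#' bin's pooled estimates are significantly below every other bin
#' ([test_oldest_vs_others()]) -- the pattern observed for retrotransposon
#' polymorphisms.
#'
#' @param grid a `sim_grid` tibble from [simulate_grid()].
#' @param n_bins,reps,alpha,seed analysis parameters passed to
#'   [resample_delta_ensemble()] and the test battery.
#' @return A tibble of class `selection_screen` with one row per cell:
#'   `r`, `S`, `n_focal`, `n_neutral`, `n_dropped`, `pattern_reproduced`
#'   (logical; `NA` when the cell could not be evaluated).
#' @export
pattern_reproduction_screen <- function(grid, n_bins = 5, reps = 100,
                                        alpha = 0.01, seed = 1) {
  cells <- dplyr::distinct(tibble(r = grid$r, S = grid$S))
  rows <- purrr::pmap(cells, function(r, S) {
    samples <- grid$sample[grid$r == r & grid$S == S]
    res <- tryCatch(
      suppressWarnings(resample_delta_ensemble(
        samples, n_bins = n_bins, reps = reps,
        seed = derive_seed(seed, r, S))),
      error = function(e) NULL)
    if (is.null(res)) {
      warn(sprintf("cell (r = %g, S = %g) has too few sites; not evaluated", r, S))
      return(tibble(r = r, S = S, n_focal = 0L, n_neutral = 0L,
                    n_dropped = length(samples), pattern_reproduced = NA))
    }
    flag <- pattern_reproduced(test_oldest_vs_others(res, alpha = alpha))
    tibble(r = r, S = S, n_focal = res$n_focal, n_neutral = res$n_neutral,
           n_dropped = res$n_dropped, pattern_reproduced = flag)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("selection_screen", class(out))
  out
}

#' Infer the maximum neutral ratio compatible with the observed pattern
#'
#' Aggregates the per-cell flags of [pattern_reproduction_screen()]: the
#' inferred `r*` is the smallest grid value of r at which the pattern is
#' NOT reproduced for a strict majority of the selection strengths tested.
#' The effectively neutral cell `S = -1` is excluded from the majority by
#' default (selection that weak cannot produce the pattern regardless of r).
#'
#' @param screen a [pattern_reproduction_screen()] result.
#' @param exclude_S selection strengths excluded from the majority vote
#'   (default `-1`); use `NULL` to include all.
#' @return A list with `r_star` (smallest r whose flag fails a strict
#'   majority of S values; `NA` with a warning when the pattern is
#'   reproduced everywhere), `per_r` (votes per r) and `per_S`
#'   (largest reproduced r per S).
#' @export
infer_max_neutral_ratio <- function(screen, exclude_S = -1) {
  sc <- screen[!is.na(screen$pattern_reproduced), , drop = FALSE]
  if (!is.null(exclude_S)) sc <- sc[!sc$S %in% exclude_S, , drop = FALSE]
  if (nrow(sc) == 0) abort("no evaluated cells left after exclusions")
  n_S <- length(unique(sc$S))
  per_r <- sc |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(n_S = dplyr::n(),
                     n_not_reproduced = sum(!.data$pattern_reproduced),
                     majority_failed = .data$n_not_reproduced > .data$n_S / 2,
                     .groups = "drop") |>
    dplyr::arrange(.data$r)
  per_S <- sc |>
    dplyr::group_by(.data$S) |>
    dplyr::summarise(
      max_r_reproduced = if (any(.data$pattern_reproduced))
        max(.data$r[.data$pattern_reproduced]) else NA_real_,
      .groups = "drop")
  failed <- per_r$r[per_r$majority_failed]
  r_star <- if (length(failed)) min(failed) else NA_real_
  if (is.na(r_star)) {
    warn("pattern reproduced at every neutral ratio tested; r* undefined")
  }
  list(r_star = r_star, per_r = per_r, per_S = per_S, n_S = n_S)
}

#' Age quantiles of the oldest equal-count age bin
#'
#' @param sites a tibble of (focal) sites with `age` and `variant_id`.
#' @param n_bins number of equal-count age bins (default 5).
#' @param probs quantile probabilities (default 25/50/75%).
#' @return Named numeric vector of empirical quantiles (linear
#'   interpolation) of the ages in the oldest bin.
#' @export
oldest_bin_age_quantiles <- function(sites, n_bins = 5,
                                     probs = c(0.25, 0.50, 0.75)) {
  binning <- assign_equal_count_age_bins(sites, n_bins = n_bins)
  oldest <- binning$assignment$age[binning$assignment$bin == n_bins]
  if (length(oldest) == 0) abort("oldest age bin is empty")
  quantile(oldest, probs = probs, type = 7)
}

#' Relative age difference between simulated and observed age quantiles
#'
#' `(simulated - observed) / max(|simulated - observed|)`, the maximum
#' taken over the compared selection-strength grid for the given quantile,
#' so values lie in \[-1, 1\] and exactly one S attains |1| unless tied.
#' Positive values mean the simulated mutations are older than observed.
#'
#' @param sim_q numeric vector of simulated age quantiles (one per grid S).
#' @param obs_q observed age quantile (scalar).
#' @return Numeric vector of relative differences; all zero when every
#'   simulated quantile equals the observed one.
#' @export
relative_age_difference <- function(sim_q, obs_q) {
  stopifnot(length(obs_q) == 1)
  d <- sim_q - obs_q
  mx <- max(abs(d))
  if (mx == 0) return(rep(0, length(d)))
  d / mx
}

#' Estimate the scaled selection coefficient from oldest-bin ages
#'
#' Grid matching: the ages of the oldest observed focal mutations are
#' compared with the oldest-bin ages in simulations run at each selection
#' strength S; the inferred S* (per age quantile) is the grid value
#' minimizing the absolute relative age difference. The consensus across
#' quantiles is the modal S, reported as a set when tied.
#'
#' @param observed_sites tibble of observed focal sites with `age`.
#' @param grid a `sim_grid` from [simulate_grid()].
#' @param n_bins number of equal-count age bins (default 5).
#' @param probs quantile probabilities (default 25/50/75%).
#' @param r_use which neutral-ratio row of the grid to compare against
#'   (default: the smallest simulated r).
#' @param pool_replicates pool the replicates of a cell before taking
#'   quantiles (default `TRUE`); otherwise quantiles are computed per
#'   replicate and averaged.
#' @return An object of class `selection_estimate`: list with `table`
#'   (per S x quantile: simulated and observed quantiles and relative age
#'   difference), `best` (S* per quantile), `consensus` (modal S* set).
#' @export
estimate_selection_strength <- function(observed_sites, grid, n_bins = 5,
                                        probs = c(0.25, 0.50, 0.75),
                                        r_use = NULL,
                                        pool_replicates = TRUE) {
  r_use <- r_use %||% min(grid$r)
  g <- grid[grid$r == r_use, , drop = FALSE]
  S_grid <- sort(unique(g$S))
  if (length(S_grid) < 2) abort("grid must cover at least two S values")

  obs_q <- oldest_bin_age_quantiles(observed_sites, n_bins = n_bins, probs = probs)

  sim_q <- purrr::map(S_grid, function(S) {
    reps <- g$sample[g$S == S]
    if (pool_replicates) {
      sites <- as_site_table(dplyr::bind_rows(reps))
      focal <- sites[sites$class == "focal", , drop = FALSE]
      oldest_bin_age_quantiles(focal, n_bins = n_bins, probs = probs)
    } else {
      qs <- purrr::map(reps, function(smp) {
        sites <- as_site_table(smp)
        focal <- sites[sites$class == "focal", , drop = FALSE]
        if (nrow(focal) < n_bins) return(NULL)
        oldest_bin_age_quantiles(focal, n_bins = n_bins, probs = probs)
      })
      qs <- qs[!vapply(qs, is.null, logical(1))]
      colMeans(do.call(rbind, qs))
    }
  })
  sim_mat <- do.call(rbind, sim_q)  # S x quantile

  tab <- purrr::map_dfr(seq_along(probs), function(j) {
    rel <- relative_age_difference(sim_mat[, j], obs_q[j])
    tibble(S = S_grid, quantile = probs[j], sim_age = sim_mat[, j],
           obs_age = obs_q[j], rel_age_diff = rel)
  })
  best <- tab |>
    dplyr::group_by(.data$quantile) |>
    dplyr::slice_min(abs(.data$rel_age_diff), with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("quantile", S_star = "S")
  counts <- table(best$S_star)
  consensus <- sort(as.numeric(names(counts)[counts == max(counts)]))
  structure(
    list(table = tab, best = best, consensus = consensus,
         r_use = r_use, n_bins = n_bins, probs = probs),
    class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat("Scaled selection coefficient estimate (oldest-bin age matching)\n")
  cat("  per-quantile S*:\n")
  print(x$best)
  cat("  consensus S*:", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.selection_estimate <- function(x, ...) x$table

#' @exportS3Method
glance.selection_estimate <- function(x, ...) {
  tibble(S_star = paste(x$consensus, collapse = ","),
         n_quantiles = length(x$probs), r_use = x$r_use)
}

#' @exportS3Method
tidy.selection_screen <- function(x, ...) as_tibble(x)

#' @exportS3Method
glance.selection_screen <- function(x, ...) {
  inf <- infer_max_neutral_ratio(x)
  tibble(r_star = inf$r_star, n_cells = nrow(x),
         n_reproduced = sum(x$pattern_reproduced, na.rm = TRUE))
}
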