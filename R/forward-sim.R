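#' Forward Wright-Fisher simulation configuration
#'
#' Builds the configuration for [run_wf_simulation()]: a diploid
#' Wright-Fisher population with partial selfing, uniform recombination and
#' two mutation streams. Neutral markers (the stand-in for synonymous SNPs)
#' arise at rate `mu_neutral` per bp per generation; focal mutations (the
#' stand-in for TE insertions) arise at rate `mu_focal` and are neutral with
#' probability `neutral_ratio_r`, otherwise deleterious with scaled
#' coefficient `scaled_S = Ne * s` (so `s = scaled_S / Ne`). Fitness is
#' multiplicative across loci with genotype fitnesses `1`, `1 + h s`,
#' `1 + s` (codominance at `h = 0.5`).
#'
#' `Ne_mode` controls which effective size converts `scaled_S` into the
#' per-generation `s`: `"census"` uses the configured `N` (the usual
#' convention when parameterizing forward simulations), while
#' `"selfing_adjusted"` uses `N / (1 + F)` with `F = sigma / (2 - sigma)`.
#'
#' @param N diploid census population size.
#' @param L fragment length in bp.
#' @param mu_neutral,mu_focal per-bp per-generation mutation rates of the
#'   neutral-marker and focal streams.
#' @param rho per-bp per-generation recombination rate; the default is set
#'   high (10x the mutation rate) to minimize linked selection on the short
#'   simulated fragment.
#' @param selfing probability that an offspring is produced by
#'   self-fertilization (default 0.7).
#' @param neutral_ratio_r fraction of focal mutations that evolve neutrally.
#' @param scaled_S scaled selection coefficient `Ne * s` (`<= 0`) of the
#'   selected focal mutations.
#' @param h dominance coefficient (default 0.5, codominance).
#' @param n_generations total generations simulated (default `10 * N`, used
#'   as burn-in to mutation-selection-drift equilibrium before sampling).
#' @param sample_size diploid individuals sampled at the final generation.
#' @param demography optional tibble/data.frame with columns `generation`
#'   and `N` scheduling population-size changes.
#' @param Ne_mode `"census"` or `"selfing_adjusted"` (see Details).
#' @return A `sim_config` list.
#' @export
sim_config <- function(N = 10000, L = 1e6, mu_neutral = 7e-9,
                       mu_focal = 7e-9, rho = 10 * mu_neutral,
                       selfing = 0.7, neutral_ratio_r = 0, scaled_S = 0,
                       h = 0.5, n_generations = 10 * N, sample_size = 30,
                       demography = NULL, Ne_mode = c("census", "selfing_adjusted")) {
  Ne_mode <- match.arg(Ne_mode)
  if (N < 2) abort("N must be >= 2")
  if (L < 1) abort("L must be >= 1 bp")
  if (any(c(mu_neutral, mu_focal, rho) < 0)) abort("rates must be >= 0")
  if (selfing < 0 || selfing > 1) abort("selfing rate must lie in [0, 1]")
  if (neutral_ratio_r < 0 || neutral_ratio_r > 1) {
    abort("neutral_ratio_r must lie in [0, 1]")
  }
  if (scaled_S > 0) abort("scaled_S must be <= 0 (purifying selection)")
  if (sample_size > N) abort("sample_size cannot exceed N")
  if (!is.null(demography)) {
    demography <- as.data.frame(demography)
    stopifnot(all(c("generation", "N") %in% names(demography)))
    if (any(demography$N < 2)) abort("demography must keep N >= 2")
  }
  structure(
    list(N = as.integer(N), L = L, mu_neutral = mu_neutral,
         mu_focal = mu_focal, rho = rho, selfing = selfing,
         neutral_ratio_r = neutral_ratio_r, scaled_S = scaled_S, h = h,
         n_generations = as.integer(n_generations),
         sample_size = as.integer(sample_size), demography = demography,
         Ne_mode = Ne_mode, rescale_factor = 1),
    class = "sim_config")
}

effective_size <- function(config) {
  if (config$Ne_mode == "selfing_adjusted") {
    Fcoef <- config$selfing / (2 - config$selfing)
    config$N / (1 + Fcoef)
  } else {
    config$N
  }
}

#' Rescale a simulation configuration
#'
#' Standard population-genetic rescaling by a factor `lambda >= 1`:
#' `N' = N / lambda`, `mu' = mu * lambda`, `rho' = rho * lambda`,
#' `generations' = generations / lambda`. The scaled selection coefficient
#' `S = Ne s` and the population mutation rate `theta = 4 Ne mu L` are
#' preserved exactly; per-generation `s` grows by `lambda` implicitly via
#' the smaller `Ne`.
#'
#' @param config a [sim_config()].
#' @param lambda rescaling factor `>= 1`; `N / lambda` must stay `>= 50` so
#'   the drift regime is preserved.
#' @return The rescaled `sim_config`.
#' @export
rescale_config <- function(config, lambda) {
  stopifnot(inherits(config, "sim_config"))
  if (lambda < 1) abort("lambda must be >= 1")
  if (lambda == 1) return(config)
  N2 <- round(config$N / lambda)
  if (N2 < 50) abort("N / lambda < 50: rescaling would break the drift regime")
  config$N <- as.integer(N2)
  config$mu_neutral <- config$mu_neutral * lambda
  config$mu_focal <- config$mu_focal * lambda
  config$rho <- config$rho * lambda
  config$n_generations <- as.integer(round(config$n_generations / lambda))
  config$sample_size <- as.integer(min(config$sample_size, N2))
  if (!is.null(config$demography)) {
    config$demography$generation <- round(config$demography$generation / lambda)
    config$demography$N <- pmax(2, round(config$demography$N / lambda))
  }
  config$rescale_factor <- config$rescale_factor * lambda
  config
}

#' Run one forward Wright-Fisher replicate
#'
#' Simulates `n_generations` of Wright-Fisher reproduction with partial
#' selfing under `config`, then draws `sample_size` diploid individuals and
#' reports every mutation segregating in the sample with its sample
#' frequency and age. Ages are counted in generations from the generation
#' the mutation arose to the sampling point (a mutation born in the final
#' generation has age 1). Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A tibble of class `wf_sample` with columns `variant_id`,
#'   `position`, `origin_generation`, `mut_class` (one of `neutral_marker`,
#'   `focal_neutral`, `focal_selected`), `s`, `count`, `het_count`,
#'   `sample_frequency`, `age`. Attributes: `config`, `fixations` (tibble),
#'   `introduced`, `introduced_cohort`, `fixed_cohort`, `unresolved_cohort`
#'   (named counts by class), `n_sampled`, `seed`.
#' @export
run_wf_simulation <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  Ne <- effective_size(config)
  s_sel <- config$scaled_S / Ne
  demog <- if (is.null(config$demography)) {
    matrix(integer(0), ncol = 2)
  } else {
    as.matrix(config$demography[, c("generation", "N")])
  }
  storage.mode(demog) <- "integer"
  # fixation-probability bookkeeping is restricted to mutations that arose
  # early enough to be resolved (fixed or lost) by the sampling generation
  cutoff <- max(1L, as.integer(config$n_generations - 6L * config$N))

  res <- .wf_sim_cpp(config$N, config$L, config$mu_neutral, config$mu_focal,
                     config$rho, config$selfing, config$neutral_ratio_r,
                     s_sel, config$h, config$n_generations,
                     config$sample_size, demog, cutoff)

  cls_levels <- c("neutral_marker", "focal_neutral", "focal_selected")
  smp <- as_tibble(res$sample)
  n_chr <- 2L * res$n_sampled
  out <- tibble(
    variant_id = paste0("sim_", smp$mut_id),
    position = floor(smp$position) + 1,
    origin_generation = smp$origin_generation,
    mut_class = factor(cls_levels[smp$class_code + 1L], levels = cls_levels),
    s = smp$s,
    count = smp$count,
    het_count = smp$het_count,
    sample_frequency = smp$count / n_chr,
    age = res$n_generations - smp$origin_generation + 1
  )
  lbl <- function(v) setNames(as.numeric(v), cls_levels)
  attr(out, "config") <- config
  attr(out, "fixations") <- as_tibble(res$fixations)
  attr(out, "introduced") <- lbl(res$introduced)
  attr(out, "introduced_cohort") <- lbl(res$introduced_cohort)
  attr(out, "fixed_cohort") <- lbl(res$fixed_cohort)
  attr(out, "unresolved_cohort") <- lbl(res$unresolved_cohort)
  attr(out, "cohort_cutoff") <- cutoff
  attr(out, "n_sampled") <- res$n_sampled
  attr(out, "final_N") <- res$final_N
  attr(out, "seed") <- seed
  class(out) <- c("wf_sample", class(out))
  out
}

#' Simulate a grid of (neutral ratio, selection strength) combinations
#'
#' Runs `n_replicates` independent replicates of [run_wf_simulation()] for
#' every combination of `r_grid` and `S_grid`, with per-replicate seeds
#' derived deterministically from `(seed, r, S, replicate)`.
#'
#' @param r_grid neutral ratios to simulate (default the standard grid
#'   `c(0, 0.05, 0.10, 0.25, 0.50)`).
#' @param S_grid scaled selection coefficients (default
#'   `c(-1, -5, -8, -10, -12, -15, -20, -50)`).
#' @param config base [sim_config()]; `neutral_ratio_r` and `scaled_S` are
#'   overridden per cell.
#' @param n_replicates replicates per cell (default 20).
#' @param seed master seed.
#' @return A tibble of class `sim_grid` with columns `r`, `S`, `replicate`,
#'   `seed` and a `sample` list-column of `wf_sample` tibbles.
#' @export
simulate_grid <- function(r_grid = c(0, 0.05, 0.10, 0.25, 0.50),
                          S_grid = c(-1, -5, -8, -10, -12, -15, -20, -50),
                          config = sim_config(), n_replicates = 20, seed = 1) {
  if (length(r_grid) == 0 || length(S_grid) == 0) abort("grids must be non-empty")
  plan <- tidyr::expand_grid(r = r_grid, S = S_grid,
                             replicate = seq_len(n_replicates))
  plan$seed <- purrr::pmap_int(plan, function(r, S, replicate) {
    derive_seed(seed, r, S, replicate)
  })
  plan$sample <- purrr::pmap(plan, function(r, S, replicate, seed) {
    cfg <- config
    cfg$neutral_ratio_r <- r
    cfg$scaled_S <- S
    run_wf_simulation(cfg, seed = seed)
  })
  class(plan) <- c("sim_grid", class(plan))
  plan
}

#' Convert a simulated sample to the shared site table
#'
#' Maps simulator output onto the site-table layout shared with the real
#' data path: focal mutations become class `"focal"`, neutral markers class
#' `"neutral"`; the ground-truth label (`truly_neutral`) is carried along.
#'
#' @param sample a `wf_sample` tibble (or several row-bound ones).
#' @return A tibble with columns `variant_id`, `class`, `derived_freq`,
#'   `minor_freq`, `age`, `position`, `truly_neutral`.
#' @export
as_site_table <- function(sample) {
  if (all(c("class", "derived_freq", "age") %in% names(sample))) {
    return(as_tibble(sample))  # already a site table
  }
  tibble(
    variant_id = sample$variant_id,
    class = ifelse(sample$mut_class == "neutral_marker", "neutral", "focal"),
    derived_freq = sample$sample_frequency,
    minor_freq = pmin(sample$sample_frequency, 1 - sample$sample_frequency),
    age = sample$age,
    position = sample$position,
    truly_neutral = sample$mut_class != "focal_selected"
  )
}

#' Estimate the inbreeding coefficient from a simulated sample
#'
#' Pools segregating neutral markers and contrasts observed heterozygosity
#' with Hardy-Weinberg expectation: `F = 1 - Hobs / Hexp`. At equilibrium
#' under partial selfing, `F = sigma / (2 - sigma)`.
#'
#' @param sample a `wf_sample` tibble (or row-bound replicates with matching
#'   sample sizes).
#' @param n_individuals diploid sample size (taken from the sample
#'   attribute when present).
#' @return The pooled estimate of `F`.
#' @export
estimate_inbreeding <- function(sample, n_individuals = attr(sample, "n_sampled")) {
  if (is.null(n_individuals)) abort("n_individuals must be supplied")
  neut <- sample[sample$mut_class == "neutral_marker", , drop = FALSE]
  if (nrow(neut) == 0) abort("no segregating neutral markers in the sample")
  p <- neut$count / (2 * n_individuals)
  h_obs <- neut$het_count / n_individuals
  h_exp <- 2 * p * (1 - p) * (2 * n_individuals) / (2 * n_individuals - 1)
  1 - sum(h_obs) / sum(h_exp)
}

#' Write a simulated or synthetic site table to disk
#'
#' Emits the shared tab-separated site/age format consumed by the analysis
#' functions, so simulated and real data go through one code path.
#'
#' @param sites a site tibble (e.g. from [as_site_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#' @param path path to a tab-separated site table.
#' @return A tibble.
#' @export
read_site_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
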