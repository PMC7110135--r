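#' Exact Mann-Whitney-Wilcoxon comparison of fitted rates
#'
#' Rank-sum test between two small groups of fitted rate constants (the
#' study design yields n = 3 per condition), using the exact small-sample
#' null distribution when there are no ties; with ties, mid-ranks and the
#' normal approximation are used (as [stats::wilcox.test()] does).
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives refer to `group_a` relative to `group_b`).
#' @return The p-value.
#' @examples
#' compare_rates(c(1, 2, 3), c(4, 5, 6), alternative = "less") # 0.05
#' @export
compare_rates <- function(group_a, group_b,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = !has_ties, correct = has_ties)$p.value
  )
}

summarise_modes <- function(modes) {
  m <- do.call(rbind, modes)
  data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = if (nrow(m) >= 2L) apply(m, 2, stats::sd) else NA_real_,
    row.names = NULL
  )
}

fit_replicate <- function(curves, priors, builder, n_particles,
                          n_generations, quantile, seed, verbose) {
  fit <- abc_smc_fit(builder, curves, priors,
                     n_particles = n_particles,
                     n_generations = n_generations,
                     quantile = quantile, seed = seed, verbose = verbose)
  list(fit = fit, mode = posterior_mode(fit))
}

check_curves <- function(curves, design) {
  missing <- setdiff(design$entries$substrate, names(curves))
  if (length(missing) > 0L) {
    stop("study is missing curves for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  curves[design$entries$substrate]
}

#' Run the wild-type joint-fit study
#'
#' Fits the eight-curve wild-type design (four ssDNA + four dsDNA
#' substrates) by ABC-SMC with a single dissociation constant shared across
#' all curves: `ss_kp, ss_ku, ss_kq, ss_ks` drive the ssDNA curves,
#' `ds_kp, ds_ku, ds_ks` the dsDNA curves. Each replicate is fitted
#' separately and the per-replicate posterior-mode particles are aggregated
#' as mean +- SD.
#'
#' @param replicates A list of replicates, each a named list of
#'   `normalized_curve`s covering the design's substrates; or `NULL` to
#'   generate `n_replicates` synthetic replicates from
#'   [wt_parameter_preset()] under the study design.
#' @param design The [experiment_design()] (default [wt_design_preset()]).
#' @param priors Prior specification (default [wt_prior_spec()]).
#' @param n_replicates Number of synthetic replicates when `replicates` is
#'   `NULL` (default 3).
#' @param n_particles,n_generations,quantile ABC-SMC settings.
#' @param noise_sd_ru Noise level for synthetic replicates, RU.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param verbose Print per-generation progress.
#' @return A `study_report`: list with per-replicate `modes` and `fits`,
#'   the `summary` (mean +- SD per parameter) and provenance (`seed`,
#'   settings).
#' @export
run_wt_study <- function(replicates = NULL, design = wt_design_preset(),
                         priors = wt_prior_spec(), n_replicates = 3L,
                         n_particles = 512L, n_generations = 8L,
                         quantile = 0.5, noise_sd_ru = design$noise_sd_ru,
                         seed = 1L, verbose = FALSE) {
  if (is.null(replicates)) {
    design$noise_sd_ru <- noise_sd_ru
    truth <- wt_parameter_preset()
    replicates <- lapply(seq_len(n_replicates), function(r) {
      normalize_study(generate_sensorgrams(design, truth, seed = seed + r))
    })
  }
  builder <- wt_model_builder(design)
  res <- lapply(seq_along(replicates), function(r) {
    fit_replicate(check_curves(replicates[[r]], design), priors, builder,
                  n_particles, n_generations, quantile,
                  seed = seed + 1000L + r, verbose = verbose)
  })
  modes <- lapply(res, `[[`, "mode")
  structure(
    list(variant = "WT",
         modes = modes,
         fits = lapply(res, `[[`, "fit"),
         summary = summarise_modes(modes),
         n_replicates = length(replicates),
         settings = list(n_particles = n_particles,
                         n_generations = n_generations,
                         quantile = quantile, seed = seed)),
    class = "study_report"
  )
}

#' Run the F86E flexibility-series study
#'
#' Fits the four-curve F86E design (dT-50, dN-50, dA-50, dN-50p at 30 uM)
#' with the single-reverse-rate model: per-curve `kp` and `kpr` (eight
#' rates) plus one shared dissociation constant — nine free parameters.
#' Reports per-substrate lifetimes `1 / kpr` alongside the rates.
#'
#' @inheritParams run_wt_study
#' @export
run_f86e_study <- function(replicates = NULL, design = f86e_design_preset(),
                           priors = f86e_prior_spec(), n_replicates = 3L,
                           n_particles = 512L, n_generations = 8L,
                           quantile = 0.5, noise_sd_ru = design$noise_sd_ru,
                           seed = 1L, verbose = FALSE) {
  if (is.null(replicates)) {
    design$noise_sd_ru <- noise_sd_ru
    truth <- f86e_parameter_preset()
    replicates <- lapply(seq_len(n_replicates), function(r) {
      normalize_study(generate_sensorgrams(design, truth, seed = seed + r))
    })
  }
  builder <- f86e_model_builder(design)
  res <- lapply(seq_along(replicates), function(r) {
    fit_replicate(check_curves(replicates[[r]], design), priors, builder,
                  n_particles, n_generations, quantile,
                  seed = seed + 1000L + r, verbose = verbose)
  })
  modes <- lapply(res, `[[`, "mode")
  summary <- summarise_modes(modes)
  kpr_rows <- grep("^kpr_", summary$parameter)
  lifetimes <- data.frame(
    substrate = sub("^kpr_", "", summary$parameter[kpr_rows]),
    lifetime_s = 1 / summary$mean[kpr_rows],
    row.names = NULL
  )
  structure(
    list(variant = "F86E",
         modes = modes,
         fits = lapply(res, `[[`, "fit"),
         summary = summary,
         lifetimes = lifetimes,
         n_replicates = length(replicates),
         settings = list(n_particles = n_particles,
                         n_generations = n_generations,
                         quantile = quantile, seed = seed)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s study, %d replicate(s)\n",
              x$variant, x$n_replicates))
  cat(sprintf("  ABC-SMC: %d particles x %d generations (seed %d)\n",
              x$settings$n_particles, x$settings$n_generations,
              x$settings$seed))
  cat("  Posterior-mode parameters (mean +- SD over replicates):\n")
  print(x$summary, digits = 4)
  if (!is.null(x$lifetimes)) {
    cat("  Bound-protomer lifetimes 1/kpr (s):\n")
    print(x$lifetimes, digits = 4)
  }
  invisible(x)
}

#' Write a study report to JSON
#'
#' @param report A `study_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  out <- list(variant = report$variant,
              n_replicates = report$n_replicates,
              settings = report$settings,
              modes = lapply(report$modes, as.list),
              summary = report$summary)
  if (!is.null(report$lifetimes)) out$lifetimes <- report$lifetimes
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
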