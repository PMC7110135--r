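#' Distance between model and data curve sets
#'
#' Sum over curves of the mean squared deviation of N(t), each curve scaled
#' by a weight that defaults to `1 / max(1, capacity^2)` so long substrates
#' (which reach N of up to 16) do not drown out short ones.
#'
#' @param model_curves,data_curves Named lists of `normalized_curve`s (or
#'   bare `N(t)` vectors) on identical time grids; names must match.
#' @param weights Optional named per-curve weights; default derived from
#'   substrate capacities via [curve_weights()].
#' @return Non-negative scalar.
#' @export
curve_distance <- function(model_curves, data_curves, weights = NULL) {
  if (!setequal(names(model_curves), names(data_curves))) {
    stop("model and data curve sets must cover the same substrates",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- curve_weights(names(data_curves))
  total <- 0
  for (nm in names(data_curves)) {
    m <- curve_n(model_curves[[nm]])
    d <- curve_n(data_curves[[nm]])
    if (length(m) != length(d)) {
      stop("curve '", nm, "': model and data grids differ", call. = FALSE)
    }
    total <- total + weights[[nm]] * mean((m - d)^2)
  }
  total
}

#' Per-curve weights for the default distance
#'
#' @param substrate_names Character vector of substrate names.
#' @param catalog Substrate catalogue.
#' @return Named numeric vector `1 / max(1, capacity^2)`.
#' @export
curve_weights <- function(substrate_names, catalog = substrate_catalog()) {
  w <- vapply(substrate_names, function(nm) {
    1 / max(1, get_substrate(nm, catalog)$capacity^2)
  }, numeric(1))
  names(w) <- substrate_names
  w
}

#' Amplitude-balanced distance weights
#'
#' Alternative to the capacity-based [curve_weights()]: each curve is
#' weighted by the inverse square of its own peak amplitude, so every term
#' of the distance is a mean squared *relative* deviation and curves whose
#' occupancy stays far below capacity still constrain the fit. A floor on
#' the amplitude guards against a near-empty curve dominating.
#'
#' @param data_curves Named list of `normalized_curve`s.
#' @param floor_n Amplitude floor (mean protomers per DNA).
#' @return Named numeric vector of weights.
#' @export
amplitude_weights <- function(data_curves, floor_n = 1e-4) {
  w <- vapply(data_curves, function(cv) {
    1 / max(max(abs(cv$n_bound)), floor_n)^2
  }, numeric(1))
  names(w) <- names(data_curves)
  w
}

curve_n <- function(x) if (is.numeric(x)) x else x$n_bound

sample_prior <- function(priors, n) {
  lo <- log10(priors$lower)
  hi <- log10(priors$upper)
  m <- matrix(stats::runif(n * length(lo), rep(lo, each = n),
                           rep(hi, each = n)), nrow = n)
  colnames(m) <- priors$name
  m
}

weighted_var <- function(x, w) {
  mu <- sum(w * x)
  sum(w * (x - mu)^2) / max(1 - sum(w^2), .Machine$double.eps)
}

weighted_cov <- function(x, w) {
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu, "-")
  v <- crossprod(xc * w, xc) / max(1 - sum(w^2), .Machine$double.eps)
  (v + t(v)) / 2
}

#' Fit a kinetic model by ABC-SMC
#'
#' Likelihood-free sequential Monte Carlo: generation 1 draws particles from
#' independent log-uniform priors (every draw accepted by default; with
#' `n_prior_draws` above the particle count, the best draws of a larger
#' pool form generation 1 under a finite first tolerance). Each later
#' generation sets its tolerance to the
#' `quantile`-quantile of the previous generation's accepted distances,
#' resamples (by importance weight) the previous particles that already
#' satisfy the new tolerance, perturbs them with a multivariate Gaussian
#' kernel in log10 parameter space whose covariance is twice the weighted
#' sample covariance of that resampled set, and accepts proposals whose
#' simulated distance falls below the tolerance. Importance weights follow
#' the standard SMC correction (flat prior inside the support over the
#' kernel-mixture density of the proposal set).
#'
#' @param simulate_fn Function mapping a named parameter vector (natural
#'   units) to a named list of model `normalized_curve`s on the data grids.
#' @param data_curves Named list of observed/synthetic `normalized_curve`s.
#' @param priors A [prior_spec()].
#' @param n_particles Particles per generation (default 512).
#' @param n_generations Number of generations (default 8).
#' @param quantile Tolerance-shrinkage quantile in (0, 1), default 0.5.
#' @param seed Integer seed (fixed seed gives bit-reproducible populations).
#' @param weights Optional per-curve distance weights.
#' @param n_prior_draws Prior draws evaluated for generation 1 (default
#'   `n_particles`, i.e. an infinite first tolerance); larger pools keep
#'   the best `n_particles` draws, setting the first tolerance to the
#'   pool's `n_particles`-th best distance.
#' @param min_acceptance Abort (with diagnostics) if a generation's
#'   acceptance rate falls below this floor (default 1e-4).
#' @param verbose Print per-generation tolerance and acceptance rate.
#' @return An `abc_smc_fit`: list of generations, each with `particles`
#'   (natural units), `log10_particles`, `weights`, `distances`, `epsilon`
#'   and `acceptance_rate`.
#' @export
abc_smc_fit <- function(simulate_fn, data_curves, priors,
                        n_particles = 512L, n_generations = 8L,
                        quantile = 0.5, seed = NULL, weights = NULL,
                        n_prior_draws = n_particles,
                        min_acceptance = 1e-4, verbose = FALSE) {
  stopifnot(inherits(priors, "prior_spec"), n_particles >= 2L,
            n_generations >= 1L, quantile > 0, quantile < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- curve_weights(names(data_curves))
  d <- nrow(priors)
  lo <- log10(priors$lower)
  hi <- log10(priors$upper)

  dist_of <- function(theta_log) {
    theta <- 10^theta_log
    names(theta) <- priors$name
    curve_distance(simulate_fn(theta), data_curves, weights)
  }

  generations <- vector("list", n_generations)

  ## generation 1: prior sampling; with n_prior_draws > n_particles the
  ## first tolerance is the n_particles-th best prior distance and the
  ## population is the draws below it (prior draws accepted under eps_1
  ## carry uniform weights)
  n_prior_draws <- max(as.integer(n_prior_draws), n_particles)
  pool <- sample_prior(priors, n_prior_draws)
  pool_d <- apply(pool, 1, dist_of)
  eps1 <- if (n_prior_draws > n_particles) {
    sort(pool_d)[n_particles]
  } else {
    Inf
  }
  sel <- order(pool_d)[seq_len(n_particles)]
  part <- pool[sel, , drop = FALSE]
  dists <- pool_d[sel]
  w <- rep(1 / n_particles, n_particles)
  generations[[1]] <- list(log10_particles = part, weights = w,
                           distances = dists, epsilon = eps1,
                           acceptance_rate = n_particles / n_prior_draws)
  if (verbose) {
    message(sprintf("gen 1: eps = %.4g, median dist = %.4g", eps1,
                    stats::median(dists)))
  }

  for (t in seq_len(n_generations)[-1]) {
    prev <- generations[[t - 1L]]
    eps <- stats::quantile(prev$distances, quantile, names = FALSE)
    # keep at least 16 source particles so the kernel covariances stay
    # estimable even at very small quantiles
    eps <- max(eps, sort(prev$distances)[min(16L, n_particles)])
    # resample from the previous particles that already satisfy the new
    # tolerance (they exist by construction: eps is a quantile of their
    # distances); proposal mixture and weight denominator use the same set,
    # so the importance correction stays exact
    keep <- which(prev$distances <= eps)
    src <- prev$log10_particles[keep, , drop = FALSE]
    src_w <- prev$weights[keep] / sum(prev$weights[keep])
    n_src <- nrow(src)
    # perturbation kernel: multivariate Gaussian with twice the weighted
    # sample covariance of the resampled set (log10 space)
    S <- 2 * weighted_cov(src, src_w)
    diag(S) <- diag(S) + 1e-10
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L)) {
      S <- diag(pmax(diag(S), 1e-8), d)
      L <- chol(S)
    }
    Sinv <- chol2inv(L)
    acc <- matrix(NA_real_, n_particles, d)
    acc_dist <- numeric(n_particles)
    n_acc <- 0L
    n_prop <- 0L
    max_prop <- ceiling(n_particles / min_acceptance)
    while (n_acc < n_particles) {
      if (n_prop >= max_prop) {
        stop(sprintf(paste0("ABC-SMC acceptance collapse in generation %d: ",
                            "%d/%d accepted after %d proposals ",
                            "(epsilon = %.4g)"),
                     t, n_acc, n_particles, n_prop, eps), call. = FALSE)
      }
      idx <- sample.int(n_src, 1L, prob = src_w)
      prop <- src[idx, ] + as.numeric(crossprod(L, stats::rnorm(d)))
      n_prop <- n_prop + 1L
      if (any(prop < lo | prop > hi)) next
      dd <- dist_of(prop)
      if (dd <= eps) {
        n_acc <- n_acc + 1L
        acc[n_acc, ] <- prop
        acc_dist[n_acc] <- dd
      }
    }
    colnames(acc) <- priors$name
    # importance weights: flat prior in log space / kernel mixture density
    lw <- numeric(n_particles)
    for (j in seq_len(n_particles)) {
      z <- sweep(src, 2, acc[j, ], "-")
      q <- rowSums((z %*% Sinv) * z)
      lw[j] <- 1 / max(sum(src_w * exp(-0.5 * q)), .Machine$double.xmin)
    }
    w <- lw / sum(lw)
    generations[[t]] <- list(log10_particles = acc, weights = w,
                             distances = acc_dist, epsilon = eps,
                             acceptance_rate = n_particles / n_prop)
    if (verbose) {
      message(sprintf("gen %d: eps = %.4g, acceptance = %.3f", t, eps,
                      n_particles / n_prop))
    }
  }

  for (t in seq_along(generations)) {
    generations[[t]]$particles <- 10^generations[[t]]$log10_particles
  }
  structure(list(generations = generations, priors = priors,
                 quantile = quantile, n_particles = n_particles),
            class = "abc_smc_fit")
}

#' @export
print.abc_smc_fit <- function(x, ...) {
  eps <- vapply(x$generations, `[[`, numeric(1), "epsilon")
  acc <- vapply(x$generations, `[[`, numeric(1), "acceptance_rate")
  cat(sprintf("<abc_smc_fit> %d generations x %d particles\n",
              length(x$generations), x$n_particles))
  print(data.frame(generation = seq_along(eps), epsilon = eps,
                   acceptance = acc))
  invisible(x)
}

#' Final particle population of a fit
#'
#' @param fit An `abc_smc_fit`.
#' @return The last generation (list with particles, weights, distances).
#' @export
final_population <- function(fit) {
  stopifnot(inherits(fit, "abc_smc_fit"))
  fit$generations[[length(fit$generations)]]
}

# weighted Gaussian-kernel density mode of one coordinate, evaluated at the
# particle locations themselves (the "mode particle" convention): Silverman
# bandwidth on the effective sample size; ties broken toward the lower value
wkde_mode <- function(x, w) {
  if (length(x) == 1L) return(x)
  n_eff <- 1 / sum(w^2)
  mu <- sum(w * x)
  sdv <- sqrt(sum(w * (x - mu)^2))
  iqr <- diff(wquantile(x, w, c(0.25, 0.75)))
  spread <- min(sdv, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) spread <- max(sdv, 1e-8)
  bw <- 0.9 * spread * n_eff^(-1 / 5)
  if (bw <= 0) return(min(x))
  cand <- sort(unique(x))
  dens <- vapply(cand, function(g) sum(w * stats::dnorm(g, x, bw)),
                 numeric(1))
  cand[which.max(dens)] # which.max takes the first (lowest) maximiser
}

wquantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}

#' Posterior mode of a particle population
#'
#' Per-parameter mode of a weighted Gaussian kernel density estimated in
#' log10 parameter space (Silverman's bandwidth on the effective sample
#' size), mapped back to natural units. The density is evaluated at the
#' particle coordinates and the highest-density coordinate is reported
#' (ties break toward the lower value), so the result is always a particle
#' value rather than a smoothed interpolate.
#'
#' @param pop A generation (e.g. [final_population()]) or an `abc_smc_fit`
#'   (its final generation is used).
#' @return Named numeric vector of parameter modes.
#' @export
posterior_mode <- function(pop) {
  if (inherits(pop, "abc_smc_fit")) pop <- final_population(pop)
  if (is.null(pop$log10_particles) || nrow(pop$log10_particles) < 1L) {
    stop("empty particle population", call. = FALSE)
  }
  lp <- pop$log10_particles
  w <- pop$weights / sum(pop$weights)
  out <- 10^vapply(seq_len(ncol(lp)), function(i) wkde_mode(lp[, i], w),
                   numeric(1))
  names(out) <- colnames(lp)
  out
}

#' Model-curve builders for the two study layouts
#'
#' Map a named parameter vector to the full set of model curves of a design,
#' for use as `simulate_fn` in [abc_smc_fit()]. The wild-type builder reads
#' `kd_um, ss_kp, ss_ku, ss_kq, ss_ks, ds_kp, ds_ku, ds_ks` and routes
#' ssDNA/dsDNA substrates to the matching variant; the F86E builder reads
#' `kd_um` plus per-substrate `kp_<name>` / `kpr_<name>` and drives every
#' curve with the single-reverse-rate model.
#'
#' @param design An [experiment_design()].
#' @param catalog Substrate catalogue.
#' @return A function `theta -> named list of N(t) vectors` on the design
#'   grids (the form [curve_distance()] and [abc_smc_fit()] consume; use
#'   [simulate_curve()] for classed curves with time stamps).
#' @export
wt_model_builder <- function(design, catalog = substrate_catalog()) {
  subs <- lapply(design$entries$substrate, get_substrate, catalog = catalog)
  concs <- design$entries$concentration_um
  protos <- lapply(concs, design_protocol, design = design)
  uconc <- unique(concs)
  function(theta) {
    params <- list(
      ss = kinetic_params("ssWT", kd_um = theta[["kd_um"]],
                          kp = theta[["ss_kp"]], ku = theta[["ss_ku"]],
                          kq = theta[["ss_kq"]], ks = theta[["ss_ks"]]),
      ds = kinetic_params("dsWT", kd_um = theta[["kd_um"]],
                          kp = theta[["ds_kp"]], ku = theta[["ds_ku"]],
                          ks = theta[["ds_ks"]])
    )
    dists <- lapply(uconc, polymer_distribution, kd_um = theta[["kd_um"]])
    out <- lapply(seq_along(subs), function(i) {
      sim_n_fast(subs[[i]], params_for_substrate(params, subs[[i]]),
                 dists[[match(concs[i], uconc)]], protos[[i]])
    })
    names(out) <- design$entries$substrate
    out
  }
}

#' @rdname wt_model_builder
#' @export
f86e_model_builder <- function(design, catalog = substrate_catalog()) {
  subs <- lapply(design$entries$substrate, get_substrate, catalog = catalog)
  concs <- design$entries$concentration_um
  protos <- lapply(concs, design_protocol, design = design)
  uconc <- unique(concs)
  function(theta) {
    dists <- lapply(uconc, polymer_distribution, kd_um = theta[["kd_um"]])
    out <- lapply(seq_along(subs), function(i) {
      nm <- subs[[i]]$name
      p <- kinetic_params("singleReverse", kd_um = theta[["kd_um"]],
                          kp = theta[[paste0("kp_", nm)]],
                          kpr = theta[[paste0("kpr_", nm)]])
      sim_n_fast(subs[[i]], p, dists[[match(concs[i], uconc)]], protos[[i]])
    })
    names(out) <- design$entries$substrate
    out
  }
}
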