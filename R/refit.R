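#' Bounded least-squares refit of selected rate constants
#'
#' Refits a small subset of rate constants of one kinetic model to a single
#' normalized curve, with every other parameter held fixed — the
#' single-parameter (e.g. `kp`) and two-parameter (`ks` and `kp`) refits
#' used to compare substrates of different flexibility. Optimisation runs
#' in log10 space with box bounds via Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]).
#'
#' @param data_curve A `normalized_curve` to fit.
#' @param substrate The [dna_substrate] the curve was measured on.
#' @param params A [kinetic_params] supplying the fixed parameter values
#'   (and the starting point for the free ones).
#' @param free Character vector of parameters to fit, subset of the
#'   variant's rate names (e.g. `"kp"`, or `c("ks", "kp")`).
#' @param protocol The [injection_protocol()] of the curve; defaults to one
#'   rebuilt from the curve metadata and standard phase durations.
#' @param lower,upper Named (or scalar) bounds on the free parameters in
#'   natural units; defaults 1e-8 and 1e4.
#' @param n_max Longest solution polymer tracked.
#' @return List with `par` (named fitted values), `residual_ss`,
#'   `converged`, `message` and the full `nls.lm` object as `fit`.
#' @examples
#' \donttest{
#' sub <- get_substrate("dN-50")
#' truth <- wt_parameter_preset()$ss
#' proto <- injection_protocol(0.15)
#' curve <- simulate_curve(sub, truth, proto)
#' lsq_refit(curve, sub, truth, free = "kp", protocol = proto)$par
#' }
#' @export
lsq_refit <- function(data_curve, substrate, params, free = "kp",
                      protocol = NULL, lower = 1e-8, upper = 1e4,
                      n_max = 16L) {
  stopifnot(inherits(data_curve, "normalized_curve"),
            inherits(substrate, "dna_substrate"),
            inherits(params, "kinetic_params"))
  rate_names <- setdiff(names(params),
                        c("variant", "kd_um", "reverse_topology"))
  if (!all(free %in% c(rate_names, "kd_um"))) {
    stop("free parameters must be among: ",
         paste(c(rate_names, "kd_um"), collapse = ", "), call. = FALSE)
  }
  if (is.null(protocol)) {
    conc <- attr(data_curve, "concentration_um")
    if (is.na(conc)) {
      stop("supply 'protocol' or a curve with concentration metadata",
           call. = FALSE)
    }
    protocol <- injection_protocol(conc)
  }
  expand <- function(x) {
    if (is.null(names(x))) stats::setNames(rep_len(x, length(free)), free)
    else x[free]
  }
  lo <- log10(expand(lower))
  hi <- log10(expand(upper))
  start <- log10(pmin(pmax(unlist(params[free]), 10^lo), 10^hi))

  model_n <- function(lp) {
    p <- params
    for (i in seq_along(free)) p[[free[i]]] <- 10^lp[[i]]
    simulate_curve(substrate, p, protocol, n_max = n_max)$n_bound
  }
  resid_fn <- function(lp) model_n(lp) - data_curve$n_bound

  fit <- minpack.lm::nls.lm(par = start, lower = lo, upper = hi,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-12))
  par <- 10^fit$par
  names(par) <- free
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("lsq_refit did not converge: ", fit$message, call. = FALSE)
  }
  list(par = par, residual_ss = sum(fit$fvec^2), converged = converged,
       message = fit$message, fit = fit)
}
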