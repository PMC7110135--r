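#' Reference kinetic parameter sets
#'
#' `wt_parameter_preset()` returns the wild-type RAD51 parameter set used as
#' synthetic ground truth: the jointly fitted protomer-protomer dissociation
#' constant (K_D = 1.14 nM = 1.14e-3 uM), the ssDNA and dsDNA forward rates
#' (2.6e-2 and 4e-3 /uM/s), a dsDNA stable reverse rate below its reported
#' 1e-3 /s upper bound, and reverse-rate classes on scales consistent with
#' the observed substrate behaviour: unstable nuclei (1-3 protomers) too
#' short-lived to accumulate (`ku` = 0.1 /s), quasi-stable 4-mer nuclei of
#' intermediate stability (`kq` = 1e-2 /s), and near-irreversible loss of
#' protomers from stable filaments (`ks` = 1e-4 /s, lifetime hours).
#'
#' `f86e_parameter_preset()` returns the self-association-weakened F86E
#' variant: shared K_D = 10.2 uM and per-substrate forward/reverse pairs in
#' which the forward rate increases, and the bound lifetime 1/kpr
#' decreases, with DNA flexibility (dT-50 most flexible, dN-50p stiffest;
#' the dN-50p reverse rate sits below its reported 1e-3 /s upper bound).
#'
#' @return `wt_parameter_preset()`: list with `kd_um`, `ss`
#'   ([kinetic_params] for ssDNA) and `ds` (for dsDNA).
#'   `f86e_parameter_preset()`: list with `kd_um` and `curves`, a named list
#'   (dT-50, dN-50, dA-50, dN-50p) of `singleReverse` [kinetic_params].
#' @export
wt_parameter_preset <- function() {
  kd <- 1.14e-3
  list(
    kd_um = kd,
    ss = kinetic_params("ssWT", kd_um = kd, kp = 2.6e-2,
                        ku = 0.1, kq = 1e-2, ks = 1e-4),
    ds = kinetic_params("dsWT", kd_um = kd, kp = 4e-3,
                        ku = 0.1, ks = 5e-4)
  )
}

#' @rdname wt_parameter_preset
#' @export
f86e_parameter_preset <- function() {
  kd <- 10.2
  mk <- function(kp, kpr) {
    kinetic_params("singleReverse", kd_um = kd, kp = kp, kpr = kpr)
  }
  list(
    kd_um = kd,
    curves = list(
      `dT-50`  = mk(kp = 2e-3,   kpr = 1e-2),
      `dN-50`  = mk(kp = 1.2e-3, kpr = 4e-3),
      `dA-50`  = mk(kp = 5e-4,   kpr = 1e-3),
      `dN-50p` = mk(kp = 4e-4,   kpr = 1e-4)
    )
  )
}

#' Log-uniform prior specifications for ABC-SMC
#'
#' `wt_prior_spec()` carries the eight wild-type joint-fit bounds (all in
#' the package's internal units, uM and s): shared K_D in \[1e-4, 1e-1\],
#' both forward rates in \[1e-4, 1e4\], every reverse rate in \[1e-6, 1e3\].
#' `f86e_prior_spec()` carries the nine F86E bounds: shared K_D in
#' \[1e-4, 1e3\], per-curve forward rates in \[1e-6, 1e4\] and reverse
#' rates in \[1e-6, 1e3\].
#'
#' @return A `prior_spec`: data frame with columns `name`, `lower`, `upper`
#'   (bounds of the log-uniform marginals).
#' @export
wt_prior_spec <- function() {
  prior_spec(data.frame(
    name  = c("kd_um", "ss_kp", "ss_ku", "ss_kq", "ss_ks",
              "ds_kp", "ds_ku", "ds_ks"),
    lower = c(1e-4, 1e-4, 1e-6, 1e-6, 1e-6, 1e-4, 1e-6, 1e-6),
    upper = c(1e-1, 1e4, 1e3, 1e3, 1e3, 1e4, 1e3, 1e3)
  ))
}

#' @rdname wt_prior_spec
#' @export
f86e_prior_spec <- function() {
  nm <- c("dT-50", "dN-50", "dA-50", "dN-50p")
  prior_spec(data.frame(
    name  = c("kd_um", paste0("kp_", nm), paste0("kpr_", nm)),
    lower = c(1e-4, rep(1e-6, 4), rep(1e-6, 4)),
    upper = c(1e3, rep(1e4, 4), rep(1e3, 4))
  ))
}

#' Construct a prior specification
#'
#' @param tab Data frame with columns `name`, `lower`, `upper`; each
#'   parameter gets an independent log-uniform prior on `[lower, upper]`.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("name", "lower", "upper") %in% names(tab)))
  if (any(tab$lower <= 0) || any(tab$upper <= tab$lower)) {
    stop("prior bounds must satisfy 0 < lower < upper", call. = FALSE)
  }
  structure(tab[c("name", "lower", "upper")], class = c("prior_spec",
                                                        "data.frame"))
}
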