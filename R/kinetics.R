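#' Kinetic parameter sets for RAD51 filament formation on DNA
#'
#' Bundles the rate constants of one kinetic model variant:
#' \describe{
#'   \item{`ssWT`}{wild-type RAD51 on ssDNA: forward rate `kp` (/uM/s, one
#'     rate for adsorption of any n-mer and every elongation step), plus
#'     three reverse-rate classes: `ku` (/s, unstable nuclei of 1-3
#'     protomers), `kq` (/s, quasi-stable 4-mer nuclei) and `ks` (/s,
#'     stable polymers of 5+, losing single protomers).}
#'   \item{`dsWT`}{wild-type on dsDNA: `kp`, `ku` (lone monomers) and `ks`
#'     (polymers of 2+); no quasi-stable class.}
#'   \item{`singleReverse`}{a single reverse rate `kpr` (/s) for every bound
#'     state, used for the self-association-weakened F86E variant.}
#' }
#' All variants share the solution-phase dissociation constant `kd_um`.
#'
#' @param variant One of `"ssWT"`, `"dsWT"`, `"singleReverse"`.
#' @param kd_um Protomer-protomer dissociation constant in uM.
#' @param kp Polymerisation forward rate constant, /uM/s.
#' @param ku,kq,ks Reverse rate constants, /s (per variant, see above).
#' @param kpr Single reverse rate, /s (`singleReverse` only).
#' @param reverse_topology `"stepwise"` (default): unstable and quasi-stable
#'   nuclei shrink one protomer at a time; `"whole_nucleus"`: states 1-3
#'   release the whole nucleus to state 0 at `ku` and state 4 at `kq`.
#' @return A `kinetic_params` object.
#' @examples
#' kinetic_params("ssWT", kd_um = 1.14e-3, kp = 2.6e-2,
#'                ku = 0.1, kq = 1e-2, ks = 1e-4)
#' @export
kinetic_params <- function(variant = c("ssWT", "dsWT", "singleReverse"),
                           kd_um, kp, ku = NULL, kq = NULL, ks = NULL,
                           kpr = NULL,
                           reverse_topology = c("stepwise", "whole_nucleus")) {
  variant <- match.arg(variant)
  reverse_topology <- match.arg(reverse_topology)
  chk <- function(x, nm, allow_zero = TRUE) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < 0 || (!allow_zero && x == 0)) {
      stop("variant '", variant, "' requires ", nm,
           if (allow_zero) " >= 0" else " > 0", call. = FALSE)
    }
    as.numeric(x)
  }
  kd_um <- chk(kd_um, "'kd_um'", allow_zero = FALSE)
  kp <- chk(kp, "'kp'")
  p <- switch(variant,
    ssWT = list(kp = kp, ku = chk(ku, "'ku'"), kq = chk(kq, "'kq'"),
                ks = chk(ks, "'ks'")),
    dsWT = list(kp = kp, ku = chk(ku, "'ku'"), ks = chk(ks, "'ks'")),
    singleReverse = list(kp = kp, kpr = chk(kpr, "'kpr'"))
  )
  structure(c(list(variant = variant, kd_um = kd_um,
                   reverse_topology = reverse_topology), p),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  rates <- x[setdiff(names(x), c("variant", "kd_um", "reverse_topology"))]
  cat(sprintf("<kinetic_params> %s (K_D = %g uM, %s reverse topology)\n",
              x$variant, x$kd_um, x$reverse_topology))
  cat("  ", paste(sprintf("%s = %g", names(rates), unlist(rates)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Injection protocol for one SPR cycle
#'
#' @param concentration_um Injected RAD51 monomer concentration, uM.
#' @param t_association_s Association-phase duration, s.
#' @param t_dissociation_s Dissociation (buffer-only) duration, s.
#' @param dt_association_s,dt_dissociation_s Sampling intervals, s.
#' @return An `injection_protocol` object.
#' @export
injection_protocol <- function(concentration_um,
                               t_association_s = 60,
                               t_dissociation_s = 1200,
                               dt_association_s = 1,
                               dt_dissociation_s = 2) {
  stopifnot(concentration_um > 0, t_association_s > 0, t_dissociation_s > 0,
            dt_association_s > 0, dt_dissociation_s > 0)
  structure(list(concentration_um = concentration_um,
                 t_association_s = t_association_s,
                 t_dissociation_s = t_dissociation_s,
                 dt_association_s = dt_association_s,
                 dt_dissociation_s = dt_dissociation_s),
            class = "injection_protocol")
}

protocol_times <- function(protocol) {
  t_a <- seq(0, protocol$t_association_s, by = protocol$dt_association_s)
  t_d <- seq(protocol$dt_dissociation_s, protocol$t_dissociation_s,
             by = protocol$dt_dissociation_s) + protocol$t_association_s
  list(association = t_a, dissociation = t_d)
}

#' Transition-rate matrix of filament states on one DNA molecule
#'
#' States 0..c index the length of the single RAD51 polymer carried by a DNA
#' molecule (c = substrate capacity; state 0 is bare DNA). Forward
#' transitions j -> j+m occur at rate `kp * [A_m]` for every solution m-mer
#' that fits (adsorption from j = 0, elongation from j >= 1). Reverse
#' transitions depend on the variant (see [kinetic_params()]). Columns sum
#' to zero, so total DNA is conserved.
#'
#' @param substrate A [dna_substrate].
#' @param params A [kinetic_params].
#' @param dist A [polymer_distribution()] evaluated at the injection
#'   concentration (use concentrations of zero for the dissociation phase).
#' @return A `(c+1) x (c+1)` generator matrix `Q` such that `dD/dt = Q D`.
#' @examples
#' sub <- get_substrate("dN-17")
#' par <- kinetic_params("ssWT", kd_um = 1.14e-3, kp = 2.6e-2,
#'                       ku = 0.1, kq = 1e-2, ks = 1e-4)
#' dist <- polymer_distribution(1.14e-3, 3)
#' Q <- build_rate_matrix(sub, par, dist)
#' colSums(Q) # all ~0
#' @export
build_rate_matrix <- function(substrate, params, dist) {
  stopifnot(inherits(substrate, "dna_substrate"),
            inherits(params, "kinetic_params"),
            inherits(dist, "solution_distribution"))
  cc <- substrate$capacity
  if (cc < 1L) {
    stop("substrate '", substrate$name,
         "' has zero RAD51 capacity; no kinetic model to build",
         call. = FALSE)
  }
  conc <- dist$concentrations_um
  if (dist$n_max < cc) conc <- c(conc, rep(0, cc - dist$n_max))
  Q <- matrix(0, cc + 1L, cc + 1L)
  # forward: j -> j + m at kp * [A_m]
  for (j in 0:(cc - 1L)) {
    m <- seq_len(cc - j)
    Q[cbind(j + m + 1L, j + 1L)] <- Q[cbind(j + m + 1L, j + 1L)] +
      params$kp * conc[m]
  }
  # reverse transitions per variant
  add_rev <- function(from, to, rate) {
    Q[to + 1L, from + 1L] <<- Q[to + 1L, from + 1L] + rate
  }
  if (params$variant == "ssWT") {
    stepwise <- identical(params$reverse_topology, "stepwise")
    for (j in seq_len(min(3L, cc))) {
      add_rev(j, if (stepwise) j - 1L else 0L, params$ku)
    }
    if (cc >= 4L) add_rev(4L, if (stepwise) 3L else 0L, params$kq)
    if (cc >= 5L) for (j in 5:cc) add_rev(j, j - 1L, params$ks)
  } else if (params$variant == "dsWT") {
    add_rev(1L, 0L, params$ku)
    if (cc >= 2L) for (j in 2:cc) add_rev(j, j - 1L, params$ks)
  } else { # singleReverse
    for (j in seq_len(cc)) add_rev(j, j - 1L, params$kpr)
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Zero-concentration copy of a solution distribution
#'
#' Convenience for building the dissociation-phase rate matrix: buffer flow
#' removes all free RAD51, so solution concentrations drop to zero.
#'
#' @param dist A `solution_distribution`.
#' @return A `solution_distribution` with all concentrations zero.
#' @export
zero_distribution <- function(dist) {
  stopifnot(inherits(dist, "solution_distribution"))
  dist$concentrations_um <- rep(0, dist$n_max)
  dist$total_monomer_um <- 0
  dist
}

# propagate dD/dt = Q D from D0 over `times` (constant coefficients) by
# matrix exponentials. On the uniform grids produced by injection protocols
# a doubling scheme reuses already-computed columns: with P_k = expm(Q k dt),
# D(:, k+i) = P_k D(:, i), so only O(log n) matrix products are needed.
propagate_linear <- function(Q, D0, times) {
  nd <- nrow(Q)
  nt <- length(times)
  if (nt == 0L) {
    return(matrix(numeric(0), nrow = nd, ncol = 0))
  }
  dt <- diff(c(0, times))
  uniform <- max(abs(dt - dt[1])) <= 1e-9 * dt[1]
  if (uniform) {
    D <- matrix(0, nd, nt)
    P <- expm_dense(Q * dt[1])
    D[, 1] <- P %*% D0
    k <- 1L
    while (k < nt) {
      m <- min(k, nt - k)
      D[, k + seq_len(m)] <- P %*% D[, seq_len(m), drop = FALSE]
      if (m == k && k + m < nt) P <- P %*% P
      k <- k + m
    }
  } else {
    D <- matrix(0, nd, nt)
    cur <- D0
    for (i in seq_len(nt)) {
      cur <- as.numeric(expm_dense(Q * dt[i]) %*% cur)
      D[, i] <- cur
    }
  }
  # clip rounding-scale negatives
  D[D < 0 & D > -1e-12] <- 0
  D
}

# scaling-and-squaring Taylor/Pade-free matrix exponential for small dense Q
expm_dense <- function(A) {
  n <- nrow(A)
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  As <- A / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in 1:20) {
    term <- term %*% As / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Propagate filament occupancies through an SPR injection cycle
#'
#' Starting from bare DNA (all probability in state 0), propagates the
#' linear system `dD/dt = Q D` through the association phase (rate matrix
#' built with the injection-concentration solution distribution, which flow
#' holds constant) and then the dissociation phase (rate matrix built with
#' zero solution concentrations).
#'
#' @param Q_assoc,Q_dissoc Generator matrices from [build_rate_matrix()].
#' @param protocol An [injection_protocol()].
#' @param method `"expm"` (matrix-exponential propagation, default) or
#'   `"ode"` (adaptive stiff integration via [deSolve::lsoda()], used as an
#'   independent cross-check).
#' @return An `occupancy_series`: list with `time_s`, `phase`
#'   (`"association"`/`"dissociation"`), matrix `D` (states x times, rows are
#'   polymer lengths 0..c) and `capacity`.
#' @export
simulate_occupancy <- function(Q_assoc, Q_dissoc, protocol,
                               method = c("expm", "ode")) {
  method <- match.arg(method)
  stopifnot(is.matrix(Q_assoc), is.matrix(Q_dissoc),
            nrow(Q_assoc) == ncol(Q_assoc),
            all(dim(Q_assoc) == dim(Q_dissoc)),
            inherits(protocol, "injection_protocol"))
  if (!all(is.finite(Q_assoc)) || !all(is.finite(Q_dissoc))) {
    stop("rate matrices contain non-finite entries", call. = FALSE)
  }
  n <- nrow(Q_assoc)
  D0 <- c(1, rep(0, n - 1L))
  tt <- protocol_times(protocol)
  if (method == "expm") {
    Da <- propagate_linear(Q_assoc, D0, tt$association[-1])
    Da <- cbind(D0, Da)
    D_end <- Da[, ncol(Da)]
    Dd <- propagate_linear(Q_dissoc, D_end,
                           tt$dissociation - protocol$t_association_s)
  } else {
    f <- function(t, y, Q) list(as.numeric(Q %*% y))
    sa <- deSolve::lsoda(D0, times = tt$association, func = f,
                         parms = Q_assoc, rtol = 1e-10, atol = 1e-12)
    Da <- t(unname(sa[, -1, drop = FALSE]))
    D_end <- Da[, ncol(Da)]
    sd_ <- deSolve::lsoda(D_end,
                          times = c(0, tt$dissociation -
                                      protocol$t_association_s),
                          func = f, parms = Q_dissoc,
                          rtol = 1e-10, atol = 1e-12)
    Dd <- t(unname(sd_[-1, -1, drop = FALSE]))
  }
  structure(
    list(time_s = c(tt$association, tt$dissociation),
         phase = c(rep("association", length(tt$association)),
                   rep("dissociation", length(tt$dissociation))),
         D = cbind(Da, Dd),
         capacity = n - 1L),
    class = "occupancy_series"
  )
}

#' Mean number of RAD51 protomers bound per DNA molecule
#'
#' `N(t) = sum_j j D_j(t)`, the model-side analogue of a normalized SPR
#' sensorgram; bounded by the substrate capacity.
#'
#' @param occ An `occupancy_series` from [simulate_occupancy()].
#' @param substrate_name,concentration_um Optional metadata carried onto the
#'   returned curve.
#' @return A `normalized_curve`: data frame with `time_s`, `n_bound` and
#'   attributes `substrate_name`, `concentration_um`, `phase`.
#' @export
mean_occupancy <- function(occ, substrate_name = NA_character_,
                           concentration_um = NA_real_) {
  stopifnot(inherits(occ, "occupancy_series"))
  j <- 0:occ$capacity
  normalized_curve(occ$time_s, as.numeric(crossprod(j, occ$D)),
                   substrate_name = substrate_name,
                   concentration_um = concentration_um,
                   phase = occ$phase)
}

#' Composition of DNA-bound RAD51 by polymer length
#'
#' At a chosen time, the percentage of all DNA-bound RAD51 protomers held in
#' polymers of each length j: `100 * j * D_j / sum_k k * D_k`.
#'
#' @param occ An `occupancy_series`.
#' @param t_s Time at which to tabulate (nearest sampled point is used).
#' @return Data frame with columns `length` (1..c) and `percent`; if nothing
#'   is bound at `t_s`, zero rows and attribute `empty = TRUE`.
#' @export
occupancy_composition <- function(occ, t_s) {
  stopifnot(inherits(occ, "occupancy_series"), length(t_s) == 1L)
  i <- which.min(abs(occ$time_s - t_s))
  d <- occ$D[-1L, i]
  j <- seq_len(occ$capacity)
  tot <- sum(j * d)
  if (tot <= 0) {
    out <- data.frame(length = integer(0), percent = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- data.frame(length = j, percent = 100 * j * d / tot)
  attr(out, "empty") <- FALSE
  out
}

# fast internal path for inference loops: N(t) on the protocol grid as a
# bare numeric vector, skipping the classed containers of simulate_curve()
sim_n_fast <- function(substrate, params, dist, protocol) {
  Qa <- build_rate_matrix(substrate, params, dist)
  Qd <- build_rate_matrix(substrate, params, zero_distribution(dist))
  nd <- nrow(Qa)
  D0 <- c(1, rep(0, nd - 1L))
  tt <- protocol_times(protocol)
  Da <- propagate_linear(Qa, D0, tt$association[-1])
  D_end <- Da[, ncol(Da)]
  Dd <- propagate_linear(Qd, D_end,
                         tt$dissociation - protocol$t_association_s)
  as.numeric(crossprod(0:(nd - 1L), cbind(D0, Da, Dd)))
}

#' Simulate one normalized model curve for a substrate
#'
#' Convenience wrapper: computes the solution distribution at the injection
#' concentration, builds association/dissociation rate matrices and returns
#' the mean-occupancy curve `N(t)`.
#'
#' @param substrate A [dna_substrate].
#' @param params A [kinetic_params].
#' @param protocol An [injection_protocol()].
#' @param n_max Longest solution polymer tracked.
#' @param method Propagation backend, see [simulate_occupancy()].
#' @param dist Optional precomputed [polymer_distribution()] at the
#'   injection concentration (reused across curves sharing one
#'   concentration).
#' @return A `normalized_curve`.
#' @export
simulate_curve <- function(substrate, params, protocol, n_max = 16L,
                           method = "expm", dist = NULL) {
  if (is.null(dist)) {
    dist <- polymer_distribution(params$kd_um, protocol$concentration_um,
                                 n_max)
  }
  Qa <- build_rate_matrix(substrate, params, dist)
  Qd <- build_rate_matrix(substrate, params, zero_distribution(dist))
  occ <- simulate_occupancy(Qa, Qd, protocol, method = method)
  mean_occupancy(occ, substrate_name = substrate$name,
                 concentration_um = protocol$concentration_um)
}
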