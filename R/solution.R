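#' Steady-state distribution of RAD51 polymers in solution
#'
#' RAD51 self-associates isodesmically: every protomer-protomer interface has
#' the same dissociation constant `kd_um`, and any n-mer may associate with
#' any m-mer (n + m <= n_max) or fall apart at any interface. At equilibrium
#' detailed balance across every association channel gives the closed form
#' \deqn{[A_n] = [A_1]^n / K_D^{n-1}}
#' with the free monomer concentration `[A_1]` fixed by monomer conservation
#' \eqn{\sum_n n [A_n] = } `total_monomer_um`, solved by bracketed root
#' finding on `(0, total_monomer_um]`.
#'
#' @param kd_um Protomer-protomer dissociation constant, in uM (> 0).
#' @param total_monomer_um Total RAD51 monomer concentration, in uM (>= 0).
#' @param n_max Longest polymer tracked in solution (default 16, the
#'   capacity of a 50-mer substrate).
#' @return A `solution_distribution`: list with `concentrations_um` (length
#'   `n_max`, entry n is the molar concentration of n-mers), `total_monomer_um`,
#'   `kd_um` and `n_max`.
#' @examples
#' d <- polymer_distribution(kd_um = 1, total_monomer_um = 3, n_max = 2)
#' d$concentrations_um # c(1, 1): monomer 1 uM, dimer 1 uM
#' @export
polymer_distribution <- function(kd_um, total_monomer_um, n_max = 16L) {
  stopifnot(length(kd_um) == 1L, length(total_monomer_um) == 1L)
  if (!is.numeric(kd_um) || is.na(kd_um) || kd_um <= 0) {
    stop("'kd_um' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(total_monomer_um) || is.na(total_monomer_um) ||
      total_monomer_um < 0) {
    stop("'total_monomer_um' must be non-negative", call. = FALSE)
  }
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("'n_max' must be >= 1", call. = FALSE)

  n <- seq_len(n_max)
  if (total_monomer_um == 0) {
    conc <- rep(0, n_max)
  } else {
    # total bound monomer as a function of free monomer a; increasing in a,
    # equals total_monomer_um somewhere in (0, total]
    total_of <- function(a) sum(n * a * (a / kd_um)^(n - 1))
    f <- function(a) total_of(a) - total_monomer_um
    root <- stats::uniroot(f, lower = 0, upper = total_monomer_um,
                           tol = .Machine$double.eps^0.75, maxiter = 1000L)
    a1 <- root$root
    # polish by Newton steps on log(a) for tight conservation
    for (i in 1:5) {
      tot <- total_of(a1)
      dtot <- sum(n^2 * (a1 / kd_um)^(n - 1)) # d total / d a
      step <- (tot - total_monomer_um) / dtot
      a1 <- max(a1 - step, a1 * 1e-3)
    }
    conc <- a1 * (a1 / kd_um)^(n - 1)
  }
  structure(
    list(concentrations_um = conc,
         total_monomer_um = total_monomer_um,
         kd_um = kd_um,
         n_max = n_max),
    class = "solution_distribution"
  )
}

#' @export
print.solution_distribution <- function(x, ...) {
  cat(sprintf(
    "<solution_distribution> K_D = %g uM, total monomer = %g uM, n_max = %d\n",
    x$kd_um, x$total_monomer_um, x$n_max))
  print(utils::head(data.frame(n = seq_len(x$n_max),
                               concentration_um = x$concentrations_um,
                               percent = percent_in_state(x)), 16))
  invisible(x)
}

#' Percent of total RAD51 held in each polymer state
#'
#' For each n-mer, the percentage of all RAD51 monomers residing in that
#' state: `100 * n * [A_n] / total`. Components sum to 100.
#'
#' @param dist A `solution_distribution` with positive total monomer.
#' @return Numeric vector of percentages, one per polymer length.
#' @export
percent_in_state <- function(dist) {
  stopifnot(inherits(dist, "solution_distribution"))
  if (dist$total_monomer_um <= 0) {
    stop("percent_in_state() is undefined for zero total monomer",
         call. = FALSE)
  }
  n <- seq_len(dist$n_max)
  100 * n * dist$concentrations_um / dist$total_monomer_um
}

#' Export a solution distribution as a data frame
#'
#' @param x A `solution_distribution`.
#' @param ... Unused.
#' @return `data.frame` with columns `n`, `concentration_um`, `percent`.
#' @export
as.data.frame.solution_distribution <- function(x, ...) {
  data.frame(n = seq_len(x$n_max),
             concentration_um = x$concentrations_um,
             percent = if (x$total_monomer_um > 0) percent_in_state(x) else
               rep(NA_real_, x$n_max))
}

#' Brute-force ODE steady state of the solution polymerisation network
#'
#' Independent check on the closed form used by [polymer_distribution()]:
#' integrates the full mass-action network (every association n + m ->
#' (n+m)-mer with forward rate `k_on`, every split of every k-mer with
#' reverse rate `kd_um * k_on`) to steady state with a stiff integrator.
#'
#' @inheritParams polymer_distribution
#' @param k_on Forward rate constant per channel (/uM/s); its value cancels
#'   at equilibrium and only sets the relaxation timescale.
#' @param symmetry If `TRUE`, apply a statistical factor 1/2 to both the
#'   forward and reverse flux of identical-reactant channels (n + n); the
#'   factor cancels at detailed balance so the equilibrium is unchanged.
#' @param rtol,atol Integrator tolerances.
#' @param max_time Hard cap on integration time (s).
#' @return A `solution_distribution` (plus attribute `"converged"`).
#' @export
steady_state_oracle <- function(kd_um, total_monomer_um, n_max = 16L,
                                k_on = 1, symmetry = FALSE,
                                rtol = 1e-12, atol = NULL,
                                max_time = 1e12) {
  n_max <- as.integer(n_max)
  stopifnot(kd_um > 0, total_monomer_um >= 0, n_max >= 1L)
  if (total_monomer_um == 0) {
    out <- polymer_distribution(kd_um, 0, n_max)
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (is.null(atol)) atol <- 1e-16 * total_monomer_um
  k_off <- kd_um * k_on

  # reaction list: one channel per unordered pair (n, m), n <= m, n + m <= n_max
  pairs <- do.call(rbind, lapply(seq_len(n_max %/% 2L), function(n) {
    m <- n:(n_max - n)
    cbind(n = n, m = m)
  }))
  fac <- ifelse(pairs[, "n"] == pairs[, "m"] & symmetry, 0.5, 1)

  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    fwd <- fac * k_on * y[pairs[, "n"]] * y[pairs[, "m"]]
    rev <- fac * k_off * y[pairs[, "n"] + pairs[, "m"]]
    net <- fwd - rev
    dy <- numeric(n_max)
    for (r in seq_along(net)) {
      n <- pairs[r, "n"]; m <- pairs[r, "m"]
      dy[n] <- dy[n] - net[r]
      dy[m] <- dy[m] - net[r]
      dy[n + m] <- dy[n + m] + net[r]
    }
    list(dy)
  }

  y <- c(total_monomer_um, rep(0, n_max - 1L))
  # relaxation is governed by the slowest (dissociation) timescale
  t_end <- min(max(1e3 / (k_on * max(total_monomer_um, kd_um)), 1e3 / k_off),
               max_time)
  converged <- FALSE
  for (i in 1:12) {
    sol <- deSolve::lsoda(y, times = c(0, t_end), func = deriv, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 5e5)
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    d <- unlist(deriv(0, y, NULL))
    if (max(abs(d)) < 1e-13 * total_monomer_um * max(k_on, k_off)) {
      converged <- TRUE
      break
    }
    t_end <- min(t_end * 10, max_time)
  }
  if (!converged) {
    warning("steady_state_oracle: residual derivative ",
            format(max(abs(unlist(deriv(0, y, NULL))))),
            " after t = ", format(t_end), " s")
  }
  out <- structure(
    list(concentrations_um = y,
         total_monomer_um = total_monomer_um,
         kd_um = kd_um,
         n_max = n_max),
    class = "solution_distribution"
  )
  attr(out, "converged") <- converged
  out
}
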