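## Constant-elasticity-of-transformation land allocation.
##
## Two standard variants are provided. "frontier" is the textbook CET:
## revenue maximization on a transformation frontier calibrated through the
## benchmark point (benchmark rents normalised to 1); it satisfies the CET
## aggregate constraint exactly but, like all frontier CETs, does not
## preserve the physical sum of hectares away from the benchmark.
## "additive" is the sum-preserving relative-rent-share variant (the
## allocation of a continuum of plots with idiosyncratic returns); child
## areas always add up to the parent exactly, which is why the equilibrium
## model uses it for its land-supply nests. Both collapse to fixed benchmark
## proportions at sigma = 0 and return the benchmark allocation at unchanged
## rents.

#' Allocate a parent land area across child covers by relative rents
#'
#' @param parent_area total area to allocate (> 0).
#' @param benchmark_child_areas named nonnegative vector, summing to the
#'   benchmark parent area.
#' @param child_rents rents relative to the benchmark (all 1 at benchmark);
#'   must be positive.
#' @param sigma transformation elasticity >= 0.
#' @param method `"frontier"` (revenue maximization on the calibrated CET
#'   frontier) or `"additive"` (sum-preserving share form).
#' @return named vector of child areas.
#' @examples
#' cet_allocate(100, c(f = 60, a = 40), c(f = 1.1, a = 1.0), sigma = 1)
#' @export
cet_allocate <- function(parent_area, benchmark_child_areas, child_rents,
                         sigma, method = c("frontier", "additive")) {
  method <- match.arg(method)
  a0 <- benchmark_child_areas
  abort_if(parent_area <= 0, "parent_area must be positive")
  abort_if(any(child_rents <= 0), "child rents must be positive")
  abort_if(any(a0 < 0) || sum(a0) <= 0, "invalid benchmark child areas")
  abort_if(sigma < 0, "sigma must be >= 0")
  A0 <- sum(a0)
  s0 <- a0 / A0
  if (sigma == 0) return(parent_area * s0)
  if (method == "additive") {
    u <- s0 * child_rents^sigma
    return(parent_area * u / sum(u))
  }
  ## frontier: aggregate G(a) = (sum gamma_i a_i^rho)^(1/rho) with
  ## gamma_i = s0_i^(1-rho), so G(a0) = A0 and the benchmark lies on the
  ## frontier with unit rents. Revenue max gives a_i = kappa (r_i/gamma_i)^sigma
  ## with kappa set by G(a) = parent_area.
  rho <- (sigma + 1) / sigma
  gamma <- s0^(1 - rho)
  base <- (child_rents / gamma)^sigma
  kappa <- parent_area / sum(gamma * base^rho)^(1 / rho)
  kappa * base
}

#' Brute-force revenue-maximization oracle on the CET frontier
#'
#' Independent check for two-cover problems: grid search (with golden-section
#' refinement) over the calibrated CET frontier for the allocation that
#' maximizes rental revenue. Used in tests against [cet_allocate()].
#'
#' @inheritParams cet_allocate
#' @param n_grid initial grid resolution.
#' @return named vector of the two child areas.
#' @export
cet_frontier_oracle <- function(parent_area, benchmark_child_areas,
                                child_rents, sigma, n_grid = 4000L) {
  abort_if(length(benchmark_child_areas) != 2,
           "oracle is defined for two covers")
  a0 <- benchmark_child_areas
  A0 <- sum(a0)
  s0 <- a0 / A0
  rho <- (sigma + 1) / sigma
  gamma <- s0^(1 - rho)
  ## frontier: gamma1 a1^rho + gamma2 a2^rho = parent_area^rho
  rhs <- parent_area^rho
  a2_of <- function(a1) ((rhs - gamma[1] * a1^rho) / gamma[2])^(1 / rho)
  a1_max <- (rhs / gamma[1])^(1 / rho)
  rev <- function(a1) child_rents[1] * a1 + child_rents[2] * a2_of(a1)
  g <- seq(1e-9 * a1_max, a1_max * (1 - 1e-9), length.out = n_grid)
  i <- which.max(vapply(g, rev, numeric(1)))
  lo <- g[max(i - 1, 1)]; hi <- g[min(i + 1, n_grid)]
  opt <- stats::optimize(rev, c(lo, hi), maximum = TRUE,
                         tol = 1e-12 * a1_max)
  a1 <- opt$maximum
  out <- c(a1, a2_of(a1))
  names(out) <- names(a0)
  out
}
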