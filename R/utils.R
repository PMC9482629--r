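#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, class = "soyshift_error") {
  if (isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' CES price index with calibrated value shares
#'
#' Unit-cost index of a CES aggregate, expressed relative to a benchmark in
#' which all component prices are 1 and `shares` are the benchmark value
#' shares. Handles the Cobb-Douglas (`sigma = 1`) and Leontief (`sigma = 0`)
#' limits explicitly.
#'
#' @param phat numeric vector of component price ratios (price / benchmark).
#' @param shares benchmark value shares, summing to 1 (zeros allowed).
#' @param sigma substitution elasticity, >= 0.
#' @return scalar price index (1 at `phat = 1`).
#' @keywords internal
ces_price <- function(phat, shares, sigma) {
  keep <- shares > 0
  phat <- phat[keep]; shares <- shares[keep]
  if (length(phat) == 0L) return(1)
  if (abs(sigma - 1) < 1e-12) {
    exp(sum(shares * log(phat)))
  } else if (sigma == 0) {
    sum(shares * phat)
  } else {
    sum(shares * phat^(1 - sigma))^(1 / (1 - sigma))
  }
}

#' CES compensated demand ratio for one component
#'
#' Quantity ratio (demand / benchmark demand) per unit of the aggregate,
#' given component price ratio `phat` and aggregate price index `pindex`.
#' @keywords internal
ces_demand <- function(phat, pindex, sigma) {
  if (sigma == 0) return(rep(1, length(phat)))
  (phat / pindex)^(-sigma)
}

## CET revenue index over child rents (benchmark rents/areas normalized).
## Exponent 1 + sigma: rises with any child rent; equals 1 at benchmark.
cet_revenue_index <- function(rhat, shares, sigma) {
  keep <- shares > 0
  rhat <- rhat[keep]; shares <- shares[keep]
  if (length(rhat) == 0L) return(1)
  sum(shares * rhat^(1 + sigma))^(1 / (1 + sigma))
}

## Deterministic per-call RNG scope: evaluates expr with the given seed and
## restores the caller's RNG state afterwards (seeds are explicit arguments,
## never global state).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Short stable hash of an R object (run manifests).
config_hash <- function(x) rlang::hash(x)
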