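# Internal helpers shared across modules.

# Euler-Mascheroni constant, used to centre Gumbel deviates at zero mean.
EULER_GAMMA <- 0.57721566490153286

stop_arg <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_arg(name, " must lie in [0, 1]")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) stop_arg(name, " must be non-negative")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic top-level operations route
# through this so that results are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed %% .Machine$integer.max)
  }
  expr
}

# Zero-mean Gumbel (annual-extreme) deviates with scale beta.
rgumbel0 <- function(n, beta) {
  if (beta == 0) return(numeric(n))
  mu <- -beta * EULER_GAMMA
  mu - beta * log(-log(runif(n)))
}

# Stable CRRA power-utility kernel used by crra_utility().
pow_utility <- function(x, one_minus_rho) {
  expm1(one_minus_rho * log(x)) / one_minus_rho
}
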