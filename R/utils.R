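# Internal helpers shared across modules.

# Gyromagnetic ratio of 1H in rad s^-1 T^-1.
.gamma_default <- 2.6752218744e8

# Effective gamma for the package's internal unit system (time in ms,
# length in um, gradient in mT/m, b in ms/um^2): with this scaling
# b = gamma_eff^2 * delta^2 * (Delta - delta/3) * |g|^2 holds exactly.
.gamma_eff <- function(gamma = .gamma_default) gamma * 1e-12

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs expr as-is.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sub-seed derivation: keeps derived seeds positive and below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
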