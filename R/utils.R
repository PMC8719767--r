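# Internal helpers shared across modules.

# Deterministic counter-based seed derivation: independent substreams per
# (stream, index) so e.g. adding taxa never perturbs host covariates drawn
# under the same master seed.  Plain modular arithmetic on doubles (exact
# below 2^53), reduced mod 2^31 - 1 to stay a valid .Random.seed input.
derive_seed <- function(seed, stream, index = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + as.numeric(stream) * 1299709 + as.numeric(index) * 7919) %% m
  as.integer(s + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  abort(paste0("invalid `", field, "`: ", msg), class = "morphburden_config_error")
}

check_scalar_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop_field(field, paste0("must be a single integer >= ", min))
  invisible(as.integer(x))
}

check_scalar_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  invisible(as.numeric(x))
}

# Matrix square root usable for positive *semi*definite covariances
# (degenerate components allowed, e.g. a taxon term switched off).
psd_factor <- function(sigma, field = "taxon_cov") {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma))
    stop_field(field, "must be a square matrix")
  if (max(abs(sigma - t(sigma))) > 1e-8)
    stop_field(field, "must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop_field(field, "must be positive semidefinite")
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(sigma)) %*% t(ev$vectors)
}
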