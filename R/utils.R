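# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_input <- function(...) stop(..., call. = FALSE)

# Zero-truncated Poisson draws via inverse-CDF conditioning on k >= 1.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

# Benjamini-Hochberg via stats::p.adjust; NA-tolerant passthrough.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

as_dgc <- function(m) methods::as(methods::as(methods::as(m, "dMatrix"),
                                              "generalMatrix"), "CsparseMatrix")
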