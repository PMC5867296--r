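# Internal helpers: error constructors, seeded RNG scoping, row-wise moments.

stop_validation <- function(msg, ...) {
  abort(msg, class = c("morphr_validation_error", "morphr_error"), ...)
}

stop_parameter <- function(msg, ...) {
  abort(msg, class = c("morphr_parameter_error", "morphr_error"), ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = c("morphr_parse_error", "morphr_error"), ...)
}

stop_empty_scorable <- function(msg = "no bait gene is scorable in any module") {
  abort(msg, class = c("morphr_empty_scorable_error", "morphr_error"))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is untouched, so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_parameter("`seed` must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-task seed stream: one master seed, tasks indexed by
# counters, so parallel and serial execution draw identical streams.
# Kept strictly below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- as.double(master) %% m
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% m
  }
  as.integer(s)
}

row_sds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(pmax(0, rowSums((x - mu)^2) / (n - 1)))
}

# Pearson correlation between rows of x, with zero-variance rows mapped to
# correlation 0 (not NA) so degenerate profiles stay inert in scoring.
row_cor <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  s <- row_sds(x)
  s[s < 1e-12] <- Inf        # standardized row becomes 0 -> correlations 0
  z <- (x - mu) / s
  tcrossprod(z) / (n - 1)
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)
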