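#' @importFrom rlang abort warn %||%
#' @importFrom stats median sd mad rnorm runif rpois fft wilcox.test lm
#' @importFrom utils head tail
NULL

# Sample-index helpers. Sample i (1-based) is taken at t_i = (i - 1) / rate.
# Half-open [a, b): first/last sample index with a <= t < b, clipped to [1, n].
samples_in <- function(a, b, rate, n) {
  i1 <- floor(a * rate + 1e-9) + 1
  i2 <- ceiling(b * rate - 1e-9)
  i1 <- max(1L, as.integer(i1))
  i2 <- min(as.integer(n), as.integer(i2))
  if (i2 < i1) return(integer(0))
  seq.int(i1, i2)
}

# Closed interval [a, b]
samples_in_closed <- function(a, b, rate, n) {
  i1 <- max(1L, as.integer(floor(a * rate + 1e-9) + 1))
  i2 <- min(as.integer(n), as.integer(floor(b * rate + 1e-9) + 1))
  if (i2 < i1) return(integer(0))
  seq.int(i1, i2)
}

# Deterministic sub-stream seeds derived from one master seed, so that the
# schedule / noise / spike components are independently reproducible.
derive_subseeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, min, max),
          class = "probeseize_invalid_argument")
  }
  invisible(x)
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
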