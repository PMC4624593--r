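# Internal helpers shared across the pipeline.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept inside
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream)) %% 2147483647)
}

# Linear-interpolation percentile (type 7), the convention used for the
# sd10 normalization factor and all quartile summaries.
pctl <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))

# Five-number summary: min, Q1, median, Q3, max (linear interpolation).
five_number <- function(x) {
  stopifnot(length(x) >= 1)
  q <- pctl(x, c(0, 0.25, 0.5, 0.75, 1))
  names(q) <- c("min", "q1", "median", "q3", "max")
  q
}

# Full-precision numeric formatting for TSV round-trips (17 significant
# digits survive double -> text -> double bit-exactly).
num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
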