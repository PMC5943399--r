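# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic per-stage seed derived from a global seed; stays < 2^31
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 31 + h * 131) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stopf("`%s` must be a number in [%g, %g]", name, lo, hi)
  x
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Dirichlet draw via gamma representation
rdirichlet1 <- function(concentration) {
  g <- rgamma(length(concentration), shape = concentration, rate = 1)
  if (sum(g) == 0) { # numerically degenerate tiny concentrations
    g[sample.int(length(g), 1)] <- 1
  }
  g / sum(g)
}

phred_to_char <- function(q) {
  vapply(q, function(qs) intToUtf8(qs + 33L), character(1))
}

char_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}
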