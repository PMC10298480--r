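# internal helpers

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lo = -Inf, hi = Inf,
                             lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config(field, "must be a single non-missing number")
  if (x < lo || (lo_open && x == lo)) stop_config(field, paste("must be >", if (lo_open) lo else paste0("= ", lo)))
  if (x > hi || (hi_open && x == hi)) stop_config(field, paste("must be <", if (hi_open) hi else paste0("= ", hi)))
  x
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

# deterministic 31-adic string hash folded with a seed; used so per-contig
# random choices are stable under contig reordering
hash_string <- function(s, seed = 0L) {
  v <- utf8ToInt(s)
  h <- as.double(seed) %% 2147483647
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# run `code` without disturbing the caller's RNG stream
with_local_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# normal read totals truncated at zero (degenerate sd = 0 gives the mean)
rtrunc_norm <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

phred_chars <- function(q) rawToChar(as.raw(q + 33L), multiple = TRUE)

random_dna <- function(len) {
  vapply(len, function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = ""), character(1))
}
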