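# internal helpers

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# recycle all arguments to a common length (scalar-or-n semantics)
recycle_common <- function(...) {
  args <- list(...)
  lens <- lengths(args)
  n <- max(lens)
  bad <- lens != 1L & lens != n
  if (any(bad)) {
    stopf(
      "arguments %s cannot be recycled to a common length %d",
      paste(names(args)[bad], collapse = ", "), n
    )
  }
  lapply(args, rep_len, length.out = n)
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict && x <= lower) stopf("`%s` must be > %s", name, lower)
  if (!strict && x < lower) stopf("`%s` must be >= %s", name, lower)
  invisible(x)
}

check_times_positive <- function(t, name = "t") {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stopf("`%s` must be finite and numeric", name)
  }
  if (any(t <= 0)) {
    stopf("`%s` must be > 0: the kernels start from a Dirac release and are undefined at t = 0", name)
  }
  invisible(t)
}

# run expr with a locally-seeded RNG, restoring global RNG state afterwards
with_local_seed <- function(seed, kind, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = kind)
  expr
}
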