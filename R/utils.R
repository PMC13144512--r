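# internal validation helpers; all fail with the offending field name

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE, unit = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  if (unit && (x < 0 || x > 1)) stop_field(field, "must be in [0, 1]")
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_field(field, "must be a whole number")
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed))
    stop_field("seed", "a seed is mandatory for generator reproducibility")
  check_scalar(seed, "seed", integerish = TRUE)
  as.integer(seed)
}

# set the RNG for the duration of the calling function only
with_seed <- function(seed, expr) {
  seed <- check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}
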