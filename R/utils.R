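#' @keywords internal
"_PACKAGE"

## All randomness in the package flows from a single root seed through
## derive_seed(): a stage/entity tag is hashed together with the root so that
## independent pipeline stages draw from independent, reproducible streams.

#' Derive a child seed from a root seed and a tag
#'
#' Deterministic splitting scheme for the package's random streams: the root
#' seed and a character tag (stage name, subject id, fold id, ...) are folded
#' into a 31-bit integer with a polynomial byte hash. Identical inputs always
#' give the identical child seed.
#'
#' @param root integer root seed.
#' @param ... tag components; coerced to character and concatenated with ":".
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647
  tag <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = ":")
  h <- as.numeric(root) %% m
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Distribution specs: small serializable descriptions of the per-subject
## count / gap / noise laws used by the simulator.
## kinds: fixed(value), normal(mean, sd), lognormal(meanlog, sdlog),
##        poisson(lambda), uniform(min, max)

#' Build a distribution specification
#'
#' @param kind one of `"fixed"`, `"normal"`, `"lognormal"`, `"poisson"`,
#'   `"uniform"`.
#' @param ... named parameters of the chosen law.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("fixed", "normal", "lognormal", "poisson", "uniform"),
                      ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, ...), class = "dist_spec")
}

#' Draw from a distribution specification
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    fixed     = rep(spec$value, n),
    normal    = stats::rnorm(n, spec$mean, spec$sd),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    poisson   = stats::rpois(n, spec$lambda),
    uniform   = stats::runif(n, spec$min, spec$max),
    stop("unknown dist_spec kind: ", spec$kind)
  )
}

# condition helper: classed errors so callers can distinguish data problems
# from programming errors
ecgbp_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "ecgbp_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# sample standard deviation that tolerates length-1 input (returns NA)
sd_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

iso8601 <- function(t_seconds, origin = "2020-01-01 00:00:00") {
  format(as.POSIXct(t_seconds, origin = origin, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

parse_iso8601 <- function(x, origin = "2020-01-01 00:00:00") {
  as.numeric(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) -
    as.numeric(as.POSIXct(origin, tz = "UTC"))
}
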