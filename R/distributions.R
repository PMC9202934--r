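#' Distribution specifications for stochastic model inputs
#'
#' A `dist_spec` describes one stochastic assumption of the risk model: the
#' distribution family and its parameters. Supported families are `fixed`
#' (a degenerate point mass), `normal` (truncated at zero when sampled,
#' because all model inputs are physical, non-negative quantities),
#' `lognormal` (parameterized by its *arithmetic* mean and sd, or by mean
#' and coefficient of variation), `triangular` (min, mode, max) and
#' `uniform` (min, max).
#'
#' The lognormal is moment-matched: for arithmetic mean `m` and sd `s` the
#' log-space parameters are `sigma^2 = log(1 + s^2/m^2)` and
#' `mu = log(m) - sigma^2/2`, so the arithmetic mean and sd of draws
#' converge to `m` and `s`. `s = 0` (or `cv = 0`) degenerates to a point
#' mass at `m`.
#'
#' @param value Point-mass value for `dist_fixed()`.
#' @param mean,sd Arithmetic mean and standard deviation.
#' @param cv Coefficient of variation (`sd/mean`); alternative to `sd` for
#'   `dist_lognormal()`.
#' @param min,mode,max Support parameters for the triangular and uniform
#'   families.
#' @return An object of class `dist_spec`: a list with elements `family`
#'   and the family's parameters.
#' @examples
#' dist_triangular(180, 345, 365)  # exposure frequency, days/year
#' dist_lognormal(32.7, cv = 0.10) # body weight, kg
#' @seealso [make_sampler()], [central_value()], [dist_mean()]
#' @name dist_spec
NULL

new_dist_spec <- function(family, ...) {
  structure(list(family = family, ...), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist_spec("fixed", value = as.numeric(value))
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  if (!is.numeric(sd) || sd < 0) {
    stop("normal spec: 'sd' must be >= 0", call. = FALSE)
  }
  new_dist_spec("normal", mean = as.numeric(mean), sd = as.numeric(sd))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(mean, sd = NULL, cv = NULL) {
  if (!is.numeric(mean) || mean <= 0) {
    stop("lognormal spec: arithmetic 'mean' must be > 0", call. = FALSE)
  }
  if (is.null(sd) && is.null(cv)) {
    stop("lognormal spec: give 'sd' or 'cv'", call. = FALSE)
  }
  if (is.null(sd)) sd <- cv * mean
  if (sd < 0) stop("lognormal spec: 'sd' must be >= 0", call. = FALSE)
  new_dist_spec("lognormal", mean = as.numeric(mean), sd = as.numeric(sd))
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max) {
  if (!(min <= mode && mode <= max)) {
    stop("triangular spec: need min <= mode <= max", call. = FALSE)
  }
  new_dist_spec("triangular", min = as.numeric(min), mode = as.numeric(mode),
                max = as.numeric(max))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max) {
  if (!(min <= max)) stop("uniform spec: need min <= max", call. = FALSE)
  new_dist_spec("uniform", min = as.numeric(min), max = as.numeric(max))
}

dist_families <- c("fixed", "normal", "lognormal", "triangular", "uniform")

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a dist_spec from a plain list (e.g. parsed YAML/JSON)
#'
#' @param x A list with a `family` element and the family's parameters.
#' @return A validated [dist_spec] object.
#' @export
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (!is.list(x) || is.null(x$family)) {
    stop("a distribution spec needs a 'family' element", call. = FALSE)
  }
  if (!x$family %in% dist_families) {
    stop(sprintf("unknown distribution family '%s'; supported: %s",
                 x$family, paste(dist_families, collapse = ", ")),
         call. = FALSE)
  }
  switch(x$family,
    fixed      = dist_fixed(x$value),
    normal     = dist_normal(x$mean, x$sd),
    lognormal  = dist_lognormal(x$mean, sd = x$sd, cv = x$cv),
    triangular = dist_triangular(x$min, x$mode, x$max),
    uniform    = dist_uniform(x$min, x$max))
}

#' Central value of a distribution spec
#'
#' The deterministic "most likely" value used by the point-estimate risk
#' assessment: `fixed` -> value, `normal` -> mean (untruncated),
#' `lognormal` -> arithmetic mean, `triangular` -> mode,
#' `uniform` -> midpoint.
#'
#' Note this is not always the sampling mean of [make_sampler()]: a normal
#' spec is truncated at zero when sampled, and a triangular sampling mean
#' is `(min + mode + max)/3`. See [dist_mean()] for the sampling mean.
#'
#' @param spec A [dist_spec].
#' @return A single numeric value.
#' @export
central_value <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    fixed      = spec$value,
    normal     = spec$mean,
    lognormal  = spec$mean,
    triangular = spec$mode,
    uniform    = (spec$min + spec$max) / 2)
}

#' Sampling mean and variance of a distribution spec
#'
#' Closed-form first and second moments of the stream produced by
#' [make_sampler()]. For the `normal` family these are the moments of the
#' zero-truncated normal that the sampler actually draws:
#' `E[X] = mu + sigma * lambda`, `Var[X] = sigma^2 (1 + alpha*lambda -
#' lambda^2)` with `alpha = -mu/sigma` and `lambda =
#' phi(alpha)/(1 - Phi(alpha))`.
#'
#' @param spec A [dist_spec].
#' @return A single numeric value.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    fixed     = spec$value,
    lognormal = spec$mean,
    uniform   = (spec$min + spec$max) / 2,
    triangular = (spec$min + spec$mode + spec$max) / 3,
    normal = {
      if (spec$sd == 0) return(spec$mean)
      a <- -spec$mean / spec$sd
      lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
      spec$mean + spec$sd * lam
    })
}

#' @rdname dist_mean
#' @export
dist_var <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    fixed     = 0,
    lognormal = spec$sd^2,
    uniform   = (spec$max - spec$min)^2 / 12,
    triangular = {
      a <- spec$min; b <- spec$mode; c <- spec$max
      (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18
    },
    normal = {
      if (spec$sd == 0) return(0)
      al <- -spec$mean / spec$sd
      lam <- stats::dnorm(al) / (1 - stats::pnorm(al))
      spec$sd^2 * (1 + al * lam - lam^2)
    })
}

#' Is a spec a point mass?
#' @param spec A [dist_spec].
#' @return `TRUE` if the spec has zero spread.
#' @export
is_degenerate <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  spec$family == "fixed" ||
    (spec$family %in% c("normal", "lognormal") && spec$sd == 0) ||
    (spec$family %in% c("uniform") && spec$min == spec$max) ||
    (spec$family == "triangular" && spec$min == spec$max)
}

# Draw n i.i.d. values from a spec using the current global RNG stream.
# Sampling rules (the engine's contract):
#   fixed      -> constant
#   normal     -> rnorm truncated at 0 by resampling the offending draws
#   lognormal  -> moment-matched rlnorm (sd = 0 degenerates to the mean)
#   triangular -> inverse-CDF transform of runif
#   uniform    -> runif
draw_spec <- function(spec, n) {
  if (!spec$family %in% dist_families) {
    stop(sprintf("unknown distribution family '%s'", spec$family),
         call. = FALSE)
  }
  switch(spec$family,
    fixed = rep.int(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    normal = {
      if (spec$sd == 0) return(rep.int(spec$mean, n))
      x <- stats::rnorm(n, spec$mean, spec$sd)
      while (any(bad <- x <= 0)) {
        x[bad] <- stats::rnorm(sum(bad), spec$mean, spec$sd)
      }
      x
    },
    lognormal = {
      if (spec$sd == 0) return(rep.int(spec$mean, n))
      sig2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - sig2 / 2,
                    sdlog = sqrt(sig2))
    },
    triangular = {
      a <- spec$min; b <- spec$mode; c <- spec$max
      if (a == c) return(rep.int(a, n))
      u <- stats::runif(n)
      f <- (b - a) / (c - a)
      ifelse(u < f,
             a + sqrt(u * (c - a) * (b - a)),
             c - sqrt((1 - u) * (c - a) * (c - b)))
    })
}

#' Create a seeded, stateful sampler for a distribution spec
#'
#' Returns a function `f(n)` drawing `n` i.i.d. values. The sampler owns a
#' private RNG stream: two samplers built with the same `seed` produce
#' identical streams, successive calls continue the stream, and drawing
#' never disturbs the caller's global RNG state.
#'
#' @param spec A [dist_spec].
#' @param seed Integer seed for the sampler's private stream, or `NULL` to
#'   draw from (and advance) the global stream.
#' @return A function of `n` returning a numeric vector of draws.
#' @examples
#' s <- make_sampler(dist_triangular(180, 345, 365), seed = 1)
#' mean(s(1e4))
#' @export
make_sampler <- function(spec, seed = NULL) {
  spec <- as_dist_spec(unclass(spec))  # revalidate
  if (is.null(seed)) {
    return(function(n) draw_spec(spec, n))
  }
  state <- local({
    old <- get0(".Random.seed", globalenv())
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  function(n) {
    old <- get0(".Random.seed", globalenv())
    assign(".Random.seed", state, globalenv())
    x <- draw_spec(spec, n)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
}

#' Derive reproducible stage seeds from a master seed
#'
#' Stage `i` receives the `i`-th draw of `sample.int(2^31 - 2)` under
#' `set.seed(master)`. The rule is deterministic, keeps every derived seed
#' a valid 32-bit integer, and gives effectively independent streams to
#' pipeline stages and replicate simulation runs. The caller's RNG state is
#' left untouched.
#'
#' @param master Integer master seed.
#' @param n Number of seeds to derive.
#' @return An integer vector of `n` derived seeds.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- get0(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (!is.null(get0(".Random.seed", globalenv())))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(master)
  sample.int(2147483646L, n)
}
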