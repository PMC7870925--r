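#' Response-transform families for LOS regression
#'
#' Each family fits ordinary least squares to a transform of the LOS
#' response and back-transforms predictions to days. The four families are
#' `identity` (y), `log` (log y), `sqrt` (sqrt y) and `inverse` (1/y).
#'
#' So that information criteria are comparable across transforms, the
#' family also carries the derivative of its transform: log-likelihoods are
#' evaluated on the original day scale via the change-of-variables
#' Jacobian, `logLik_days = logLik_transformed + sum(log |t'(y)|)`, exactly
#' as in Box-Cox model comparison. Without the Jacobian the log family
#' would win any comparison on day-scale data simply because log days have
#' smaller variance than days.
#'
#' @param name One of `"identity"`, `"log"`, `"sqrt"`, `"inverse"`.
#' @return An object of class `los_family` with elements `name`,
#'   `transform`, `inverse` and `dtransform` (derivative of the transform,
#'   used for the Jacobian term).
#' @export
#' @examples
#' fam <- los_family("log")
#' fam$inverse(fam$transform(12.5))
los_family <- function(name = c("identity", "log", "sqrt", "inverse")) {
  name <- match.arg(name)
  f <- switch(name,
    identity = list(transform = function(y) y,
                    inverse = function(z) z,
                    dtransform = function(y) rep(1, length(y))),
    log = list(transform = function(y) log(y),
               inverse = function(z) exp(z),
               dtransform = function(y) 1 / y),
    sqrt = list(transform = function(y) sqrt(y),
                inverse = function(z) z^2,
                dtransform = function(y) 0.5 / sqrt(y)),
    inverse = list(transform = function(y) 1 / y,
                   inverse = function(z) 1 / z,
                   dtransform = function(y) -1 / y^2)
  )
  structure(c(list(name = name), f), class = "los_family")
}

#' @export
print.los_family <- function(x, ...) {
  cat("<los_family>", x$name, "\n")
  invisible(x)
}

#' All four response-transform families
#'
#' @return Named list of [los_family()] objects.
#' @export
los_families <- function() {
  fams <- c("identity", "log", "sqrt", "inverse")
  stats::setNames(lapply(fams, los_family), fams)
}

# Back-transform a vector of transformed-scale predictions to days,
# clamped to at least one day. Near-zero or negative inverse-scale
# predictions would back-transform to absurd or negative stays; they are
# capped at `cap` days.
.back_transform_days <- function(family, z, cap = 365) {
  y <- family$inverse(z)
  if (family$name == "inverse") y[!is.finite(y) | z <= 1 / cap] <- cap
  if (family$name == "sqrt") y[z < 0] <- 1
  pmin(pmax(y, 1), cap)
}
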