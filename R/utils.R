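#' @importFrom rlang %||% .data
#' @importFrom stats quantile rnorm runif rpois dnorm pnorm median sd prcomp
#'   kruskal.test p.adjust glm glm.fit poisson coef logLik predict var
#' @importFrom utils head
NULL

# Canonical predictor vocabulary: 7 variables x 4 depths = 28 predictor ids,
# in fixed order. All modules key environmental values by these ids.
ENV_VARIABLES <- c(
  "temperature", "salinity", "dissolved_oxygen", "oxygen_saturation",
  "silicate", "phosphate", "nitrate"
)
ENV_DEPTHS <- c(0, 5, 10, 20)

#' Canonical predictor identifiers
#'
#' Returns the 28 predictor ids (`<variable>_<depth>m`) in canonical order:
#' variables in fixed order, depths 0, 5, 10, 20 m within each variable.
#' This order is the tie-break of last resort wherever predictors must be
#' ordered deterministically.
#'
#' @return Character vector of length 28.
#' @export
predictor_ids <- function() {
  as.vector(t(outer(ENV_VARIABLES, ENV_DEPTHS, function(v, d) {
    paste0(v, "_", d, "m")
  })))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shortest angular distance between longitudes, in degrees.
lon_distance <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

# Round half away from zero, decimal-digit version. Chosen over round()
# because banker's rounding at .5 boundaries is platform-trap territory for
# coordinate binning.
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
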