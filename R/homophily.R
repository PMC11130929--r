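#' Mixing inputs for the homophily balance equation
#'
#' Describes one partnership layer's mixing between the high-activity (HA)
#' and low-activity (LA) groups: group sizes, per-person mean partnership
#' numbers (momentary mean degree by default, or cumulative 12-month counts
#' -- the balance algebra is identical), and the HA concordance fraction.
#' The homophily rate of a group is the proportion of that group's
#' partnerships whose partner belongs to the same group.
#'
#' @param n_ha,n_la Positive group sizes.
#' @param deg_ha,deg_la Non-negative mean partnerships per person.
#' @param h_ha HA homophily rate in [0, 1].
#' @return An object of class `mixing_inputs`.
#' @export
mixing_inputs <- function(n_ha, n_la, deg_ha, deg_la, h_ha) {
  stopifnot(n_ha > 0, n_la > 0, deg_ha >= 0, deg_la >= 0,
            h_ha >= 0, h_ha <= 1)
  structure(list(n_ha = n_ha, n_la = n_la, deg_ha = deg_ha, deg_la = deg_la,
                 h_ha = h_ha), class = "mixing_inputs")
}

#' Low-activity homophily implied by cross-group balance
#'
#' In a closed population every partnership between an HA and an LA person is
#' counted once from each side, so the number of HA persons' LA-partnerships
#' must equal the number of LA persons' HA-partnerships:
#' `(1 - h_HA) n_HA d_HA = (1 - h_LA) n_LA d_LA`. Solving gives
#' `h_LA = 1 - (n_HA d_HA / (n_LA d_LA)) (1 - h_HA)`. A negative result
#' signals that the requested `h_HA` is infeasible for the given sizes and
#' degrees (the LA group cannot absorb that many cross-partnerships).
#'
#' @param inputs A [mixing_inputs()] object.
#' @return `h_la` in [0, 1].
#' @export
la_homophily <- function(inputs) {
  stopifnot(inherits(inputs, "mixing_inputs"))
  if (inputs$n_la * inputs$deg_la <= 0)
    stop("LA partnership total must be positive")
  r <- (inputs$n_ha * inputs$deg_ha) / (inputs$n_la * inputs$deg_la)
  h_la <- 1 - r * (1 - inputs$h_ha)
  if (h_la < 0)
    stop(sprintf(
      "infeasible mixing: h_HA = %.3f implies h_LA = %.3f < 0", inputs$h_ha,
      h_la))
  h_la
}

#' Invert the balance equation
#'
#' Recovers the HA homophily rate from an LA rate under the same
#' cross-partnership conservation.
#'
#' @param inputs A [mixing_inputs()] object (its `h_ha` field is ignored).
#' @param h_la LA homophily rate in [0, 1].
#' @return `h_ha` in [0, 1].
#' @export
ha_homophily <- function(inputs, h_la) {
  stopifnot(inherits(inputs, "mixing_inputs"), h_la >= 0, h_la <= 1)
  if (inputs$n_ha * inputs$deg_ha <= 0)
    stop("HA partnership total must be positive")
  r <- (inputs$n_la * inputs$deg_la) / (inputs$n_ha * inputs$deg_ha)
  h_ha <- 1 - r * (1 - h_la)
  if (h_ha < 0)
    stop("infeasible mixing: implied h_HA < 0")
  h_ha
}

#' Group-level mixing matrix implied by the homophily rates
#'
#' Entry (g, g') is the expected number of partnerships of group-g members
#' whose partner belongs to group g'. The off-diagonal entries are equal by
#' construction -- the balance identity.
#'
#' @inheritParams la_homophily
#' @return 2x2 numeric matrix with dimnames HA/LA.
#' @export
mixing_matrix <- function(inputs) {
  h_la <- la_homophily(inputs)
  ends_ha <- inputs$n_ha * inputs$deg_ha
  ends_la <- inputs$n_la * inputs$deg_la
  m <- matrix(c(inputs$h_ha * ends_ha, (1 - inputs$h_ha) * ends_ha,
                (1 - h_la) * ends_la, h_la * ends_la),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("HA", "LA"), c("HA", "LA")))
  m
}

#' Partnership counts by group pair consistent with two homophily rates
#'
#' Splits a layer's total edge count into HA-HA, LA-LA and HA-LA
#' partnerships such that the realised homophily rate of each group equals
#' the requested one: with x cross edges, `2 e_HH = x h_HA / (1 - h_HA)` and
#' `2 e_LL = x h_LA / (1 - h_LA)`. If either rate is exactly 1 there are no
#' cross edges and the concordant edges are split by `ha_end_share`.
#'
#' @param n_edges Total number of edges in the layer (non-negative).
#' @param h_ha,h_la Homophily rates in [0, 1].
#' @param ha_end_share Fallback share of partnership ends belonging to HA,
#'   used only when there are no cross edges (default 0.5).
#' @return Named numeric vector `c(HH =, LL =, HL =)` summing to `n_edges`
#'   (expected, real-valued counts).
#' @export
pair_mix <- function(n_edges, h_ha, h_la, ha_end_share = 0.5) {
  stopifnot(n_edges >= 0, h_ha >= 0, h_ha <= 1, h_la >= 0, h_la <= 1)
  if (n_edges == 0) return(c(HH = 0, LL = 0, HL = 0))
  if (h_ha >= 1 || h_la >= 1) {
    if (h_ha < 1 || h_la < 1)
      warning("one homophily rate is 1: forcing zero cross edges")
    return(c(HH = n_edges * ha_end_share, LL = n_edges * (1 - ha_end_share),
             HL = 0))
  }
  denom <- 1 + h_ha / (2 * (1 - h_ha)) + h_la / (2 * (1 - h_la))
  x <- n_edges / denom
  c(HH = x * h_ha / (2 * (1 - h_ha)), LL = x * h_la / (2 * (1 - h_la)),
    HL = x)
}
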