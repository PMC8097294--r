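#' The d statistic: variance-asymmetry between the sexes
#'
#' `d = sqrt(m f) / ((m + f) / 2)`, the ratio of the geometric and
#' arithmetic means of the male and female genetic variances. It equals 1
#' when the variances are equal and decays slowly with asymmetry: at a
#' 2:1 ratio d is 0.94, and it is not halved until the ratio is nearly
#' 14:1.
#'
#' @param m,f Positive sex-specific genetic variances (vectorized).
#' @return d in (0, 1].
#' @examples
#' d_statistic(2, 1)
#' @export
d_statistic <- function(m, f) {
  if (any(m <= 0 | f <= 0)) stop("Variances must be positive.")
  sqrt(m * f) / ((m + f) / 2)
}

#' Single-trait dimorphism change under antagonistic and concordant selection
#'
#' For one trait with male variance `m`, female variance `f` and cross-sex
#' covariance `b`, the change in dimorphism per generation is
#' `Delta_A = beta (gbar - b) = beta gbar (1 - d rMF)` under antagonistic
#' selection and `Delta_C = beta (m - f) / 2`, whose magnitude is
#' `|beta| gbar sqrt(1 - d^2)`, under concordant selection
#' (`gbar = (m + f)/2`). A positive rMF restricts the antagonistic
#' response; unequal variances drive the concordant response.
#'
#' @param m,f Nonnegative sex-specific genetic variances.
#' @param b Cross-sex covariance, `|b| <= sqrt(m f)`.
#' @param beta Scalar selection gradient applied to the male copy (the
#'   female copy gets `-beta` under the antagonistic scheme, `+beta` under
#'   the concordant one).
#' @return Tibble with `delta_A`, `delta_C`, `g_bar`, `d`, `r_mf`.
#' @examples
#' single_trait_deltas(2, 1, 0.5)
#' @export
single_trait_deltas <- function(m, f, b, beta = 1) {
  if (any(m < 0 | f < 0)) stop("Variances must be nonnegative.")
  if (any(abs(b) > sqrt(m * f) + 1e-12)) {
    stop("|b| must not exceed sqrt(m * f).")
  }
  g_bar <- (m + f) / 2
  d <- ifelse(m > 0 & f > 0, sqrt(m * f) / g_bar, NA_real_)
  r_mf <- ifelse(m > 0 & f > 0, b / sqrt(m * f), NA_real_)
  tibble::tibble(
    delta_A = beta * (g_bar - b),
    delta_C = beta * (m - f) / 2,
    g_bar = g_bar, d = d, r_mf = r_mf
  )
}

#' When does concordant selection change dimorphism faster?
#'
#' Concordant selection of equal strength changes single-trait dimorphism
#' faster than antagonistic selection when `d < 2 rMF / (rMF^2 + 1)`.
#' This returns the d threshold for a given rMF; the companion
#' [d_to_variance_ratio()] converts a d value to the implied ratio of the
#' larger to the smaller sex-specific variance by solving
#' `2 sqrt(rho) / (1 + rho) = d` for `rho >= 1`.
#'
#' @param r_mf Intersexual genetic correlation in (0, 1].
#' @return d threshold: concordant selection dominates when d is below it.
#' @examples
#' concordant_dominance_condition(0.75)
#' d_to_variance_ratio(0.5)
#' @export
concordant_dominance_condition <- function(r_mf) {
  if (any(r_mf <= 0 | r_mf > 1)) stop("`r_mf` must be in (0, 1].")
  2 * r_mf / (r_mf^2 + 1)
}

#' @rdname concordant_dominance_condition
#' @param d A d value in (0, 1].
#' @export
d_to_variance_ratio <- function(d) {
  if (any(d <= 0 | d > 1)) stop("`d` must be in (0, 1].")
  # 2 sqrt(rho)/(1+rho) = d  =>  s^2 - (2/d) s + 1 = 0 with s = sqrt(rho)
  s <- (1 + sqrt(1 - d^2)) / d
  s^2
}

# Builds the unit-variance two-trait sexed correlation matrix used by the
# two-trait closed forms. b12 = cov(male trait 1, female trait 2);
# b21 = cov(male trait 2, female trait 1) (rows male, columns female).
two_trait_g <- function(r_mm, r_ff, b12, b21, r_mf1, r_mf2,
                        validate = TRUE) {
  pars <- c(r_mm, r_ff, b12, b21, r_mf1, r_mf2)
  if (any(abs(pars) > 1)) stop("Correlations must lie in [-1, 1].")
  B <- rbind(c(r_mf1, b12), c(b21, r_mf2))
  assemble_sexed_g(
    G_M = rbind(c(1, r_mm), c(r_mm, 1)),
    G_F = rbind(c(1, r_ff), c(r_ff, 1)),
    B = B,
    male_traits = c("z1", "z2"), female_traits = c("z1", "z2"),
    is_correlation = FALSE, validate = validate
  )
}

#' Two-trait indirect dimorphism response
#'
#' With unit genetic variances in both traits and sexes and selection on
#' trait 1 only, the dimorphism of the unselected trait 2 changes at rate
#' `Delta_A2 = beta ((r_mm + r_ff)/2 - (b12 + b21)/2)` under antagonistic
#' selection (average within-sex cross-trait correlation minus average
#' cross-sex cross-trait correlation), and
#' `Delta_C2 = beta ((r_mm - r_ff)/2 + (b21 - b12)/2)` under concordant
#' selection (driven purely by the asymmetries). Correlations are named by
#' placement: `b12 = cor(trait 1 in males, trait 2 in females)`,
#' `b21 = cor(trait 2 in males, trait 1 in females)`.
#'
#' @param r_mm,r_ff Within-sex cross-trait correlations (males, females).
#' @param b12,b21 Cross-sex cross-trait correlations (see above).
#' @param r_mf1,r_mf2 Homologous cross-sex correlations of traits 1 and 2
#'   (only needed for validity of the implied matrix).
#' @param scheme `"antagonistic"` or `"concordant"`.
#' @param beta Scalar gradient on trait 1 (male copy).
#' @return The scalar change in trait-2 dimorphism; equals the general
#'   engine's prediction on the implied 4x4 matrix to machine precision.
#' @export
two_trait_indirect <- function(r_mm, r_ff, b12, b21, r_mf1 = 0, r_mf2 = 0,
                               scheme = c("antagonistic", "concordant"),
                               beta = 1) {
  scheme <- match.arg(scheme)
  if (any(abs(c(r_mm, r_ff, b12, b21, r_mf1, r_mf2)) > 1)) {
    stop("Correlations must lie in [-1, 1].")
  }
  if (scheme == "antagonistic") {
    beta * ((r_mm + r_ff) / 2 - (b12 + b21) / 2)
  } else {
    beta * ((r_mm - r_ff) / 2 + (b21 - b12) / 2)
  }
}

#' Two-trait dimorphism response with both traits selected
#'
#' With unit genetic variances and both traits under selection, the
#' antagonistic gradient (+, +, -, -) yields a dimorphism change per trait
#' of `beta (1 - rMF_t + rw_bar - rb_bar)`, where
#' `rw_bar = (r_mm + r_ff)/2` and `rb_bar = (b12 + b21)/2`: the direct
#' response (constrained by rMF) plus indirect responses through the
#' average within-sex and cross-sex cross-trait correlations, which always
#' act antagonistically to each other. The concordant gradient
#' (+, +, +, +) has no direct term; each trait changes by
#' `(beta/2) (rdw -/+ rdb)` with `rdw = r_mm - r_ff` and
#' `rdb = b21 - b12` (trait 1 takes `-rdb`, trait 2 `+rdb`): dimorphism
#' arises only from the asymmetry between the sexes' correlation
#' structures and within B.
#'
#' @inheritParams two_trait_indirect
#' @return Named numeric vector `c(z1, z2)` of dimorphism changes; equals
#'   the general engine's prediction on the implied 4x4 matrix.
#' @export
two_trait_both_selected <- function(r_mm, r_ff, b12, b21, r_mf1, r_mf2,
                                    scheme = c("antagonistic", "concordant"),
                                    beta = 1) {
  scheme <- match.arg(scheme)
  if (any(abs(c(r_mm, r_ff, b12, b21, r_mf1, r_mf2)) > 1)) {
    stop("Correlations must lie in [-1, 1].")
  }
  if (scheme == "antagonistic") {
    rw_bar <- (r_mm + r_ff) / 2
    rb_bar <- (b12 + b21) / 2
    out <- beta * c(1 - r_mf1 + rw_bar - rb_bar,
                    1 - r_mf2 + rw_bar - rb_bar)
  } else {
    rdw <- r_mm - r_ff
    rdb <- b21 - b12
    out <- (beta / 2) * c(rdw - rdb, rdw + rdb)
  }
  stats::setNames(out, c("z1", "z2"))
}
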