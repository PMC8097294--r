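#' Selection gradients over sexed variables
#'
#' Builds a selection gradient beta aligned with the variables of a
#' `sexed_g`. Under the antagonistic scheme the male and female copies of
#' each selected shared trait get opposite-sign entries (beta_M = -beta_F,
#' selection for increased dimorphism); under the concordant scheme they
#' get equal entries (beta_M = beta_F). With `norm = "unit_total"` the
#' gradient is scaled to unit Euclidean norm over the full sexed vector,
#' so a one-trait antagonistic gradient is (+1/sqrt(2), -1/sqrt(2)).
#'
#' @param g A `sexed_g` object.
#' @param scheme `"antagonistic"`, `"concordant"`, or `"custom"`.
#' @param traits Shared traits to select on (default: all shared traits).
#'   Ignored for `"custom"`.
#' @param beta For `"custom"`: a named numeric vector over `trait:sex`
#'   keys (missing entries are 0), or an unnamed vector over all variables.
#' @param norm `"unit_total"` (scale to unit norm) or `"raw"`.
#' @return A `selection_gradient`: list with `beta` (named vector aligned
#'   to `g`), `scheme`, `traits`, `norm`.
#' @examples
#' g <- rand_sexed_g(2)
#' selection_gradient(g, "antagonistic", traits = "UB1")$beta
#' @export
selection_gradient <- function(g, scheme = c("antagonistic", "concordant",
                                             "custom"),
                               traits = NULL, beta = NULL,
                               norm = c("unit_total", "raw")) {
  scheme <- match.arg(scheme)
  norm <- match.arg(norm)
  v <- g$variables
  key <- paste(v$trait, v$sex, sep = ":")
  b <- stats::setNames(numeric(nrow(v)), key)
  if (scheme == "custom") {
    if (is.null(beta)) stop("`beta` is required for a custom gradient.")
    if (!is.null(names(beta))) {
      bad <- setdiff(names(beta), key)
      if (length(bad)) stop("Unknown variables in `beta`: ",
                            paste(bad, collapse = ", "))
      b[names(beta)] <- beta
    } else {
      if (length(beta) != length(b)) {
        stop("Unnamed `beta` must have one entry per variable (",
             length(b), ").")
      }
      b[] <- beta
    }
    traits <- character(0)
  } else {
    shared <- shared_traits(g)
    if (is.null(traits)) traits <- shared
    if (!all(traits %in% shared)) {
      stop("Selected traits must be shared between the sexes: ",
           paste(setdiff(traits, shared), collapse = ", "))
    }
    sgn_f <- if (scheme == "antagonistic") -1 else 1
    b[paste(traits, "M", sep = ":")] <- 1
    b[paste(traits, "F", sep = ":")] <- sgn_f
  }
  if (all(b == 0)) stop("Selection gradient is all zero.")
  if (norm == "unit_total") b <- b / sqrt(sum(b^2))
  structure(list(beta = b, scheme = scheme, traits = traits, norm = norm),
            class = "selection_gradient")
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat(sprintf("<selection_gradient> scheme=%s, |beta|=%.4g\n",
              x$scheme, sqrt(sum(x$beta^2))))
  print(round(x$beta[x$beta != 0], 4))
  invisible(x)
}
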