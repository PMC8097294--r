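#' Predicted response to sex-specific selection
#'
#' Applies the two-sex multivariate breeder's equation
#' \deqn{[\Delta \bar z_M; \Delta \bar z_F] = (1/2) G [\beta_M; \beta_F]}
#' where `G` is the full sexed covariance matrix (the 1/2 reflects that
#' each sex contributes half the autosomal genes of the next generation).
#' Alongside the per-variable responses it reports the dimorphism-change
#' vector Delta (male minus female response, per shared trait), its norm,
#' the evolvability `e = beta' G beta / (beta' beta)` (response in the
#' direction of selection), the respondability `R = |G beta| / |beta|`
#' (length of the total response), and the vector correlation between the
#' male and female response sub-vectors over shared traits. `e` and `R`
#' follow the evolvability-statistics convention without the 1/2; every
#' ratio reported by the pipeline is invariant to that choice.
#'
#' @param g A `sexed_g` covariance matrix (correlation matrices are
#'   refused unless `allow_correlation = TRUE`).
#' @param gradient A [selection_gradient()] conformable with `g`.
#' @param allow_correlation Permit a correlation-scale `g` (responses are
#'   then on the correlation-standardized scale).
#' @return A `response_summary`: list with `dz` (tibble: trait, sex, dz),
#'   `dimorphism` (tibble: trait, delta), `e`, `R`, `delta_norm`,
#'   `vec_corr`, plus the inputs.
#' @examples
#' g <- assemble_sexed_g(matrix(1), matrix(1), matrix(0.8), "t", "t")
#' grad <- selection_gradient(g, "antagonistic", norm = "raw")
#' predict_response(g, grad)$dimorphism
#' @export
predict_response <- function(g, gradient, allow_correlation = FALSE) {
  stopifnot(inherits(g, "sexed_g"), inherits(gradient, "selection_gradient"))
  if (isTRUE(g$is_correlation) && !allow_correlation) {
    stop("`g` stores correlations; pass a covariance matrix or set ",
         "`allow_correlation = TRUE`.")
  }
  beta <- gradient$beta
  if (length(beta) != nrow(g$cov)) {
    stop("Gradient is not conformable with `g`.")
  }
  if (all(beta == 0)) stop("Selection gradient is all zero.")
  dz <- drop(g$cov %*% beta) / 2
  summarize_response(g, gradient, dz)
}

# Shared back-end: builds a response_summary from a per-variable response.
summarize_response <- function(g, gradient, dz) {
  v <- g$variables
  beta <- gradient$beta
  shared <- shared_traits(g)
  im <- match(paste(shared, "M", sep = ":"), paste(v$trait, v$sex, sep = ":"))
  i_f <- match(paste(shared, "F", sep = ":"), paste(v$trait, v$sex, sep = ":"))
  delta <- dz[im] - dz[i_f]
  vec_corr <- if (length(shared) >= 2 &&
                  stats::sd(dz[im]) > 0 && stats::sd(dz[i_f]) > 0) {
    stats::cor(dz[im], dz[i_f])
  } else {
    NA_real_
  }
  structure(list(
    dz = tibble::tibble(trait = v$trait, sex = v$sex, dz = unname(dz)),
    dimorphism = tibble::tibble(trait = shared, delta = unname(delta)),
    e = sum(beta * drop(g$cov %*% beta)) / sum(beta^2),
    R = sqrt(sum(drop(g$cov %*% beta)^2)) / sqrt(sum(beta^2)),
    delta_norm = sqrt(sum(delta^2)),
    vec_corr = vec_corr,
    gradient = gradient
  ), class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf(
    "<response_summary> scheme=%s  e=%.4g  R=%.4g  |Delta|=%.4g  vec_corr=%s\n",
    x$gradient$scheme, x$e, x$R, x$delta_norm,
    ifelse(is.na(x$vec_corr), "NA", sprintf("%.3f", x$vec_corr))
  ))
  print(x$dimorphism)
  invisible(x)
}

#' @rdname predict_response
#' @param x A `response_summary`.
#' @param ... Unused.
#' @export
tidy.response_summary <- function(x, ...) {
  dplyr::left_join(
    x$dz,
    dplyr::rename(x$dimorphism, dimorphism_change = "delta"),
    by = "trait"
  )
}

#' @rdname predict_response
#' @export
glance.response_summary <- function(x, ...) {
  tibble::tibble(
    scheme = x$gradient$scheme, e = x$e, R = x$R,
    delta_norm = x$delta_norm, vec_corr = x$vec_corr
  )
}

#' Per-variable response plot
#' @param object A `response_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of predicted responses by trait and sex.
#' @export
autoplot.response_summary <- function(object, ...) {
  ggplot2::ggplot(object$dz,
                  ggplot2::aes(x = .data$trait, y = .data$dz,
                               fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(Delta * bar(z)),
                  title = sprintf("Predicted response (%s selection)",
                                  object$gradient$scheme)) +
    ggplot2::theme_minimal()
}

#' Closed-form dimorphism change under symmetric selection schemes
#'
#' For a gradient restricted to shared traits, the change in dimorphism
#' has a closed form in the matrix components (the 1/2 of the two-sex
#' breeder's equation absorbed): under antagonistic selection
#' `Delta = (Gbar - B_S) beta_M` with `Gbar = (G_M + G_F)/2` and
#' `B_S = (B + B^T)/2`; under concordant selection
#' `Delta = ((G_M - G_F)/2 + (B - B^T)/2) beta_M`. Antagonistic responses
#' therefore depend only on the symmetric components, concordant responses
#' only on the asymmetries.
#'
#' @inheritParams predict_response
#' @return Named numeric vector of dimorphism changes over shared traits;
#'   equals `predict_response()`'s `dimorphism$delta` to machine precision.
#' @export
dimorphism_change_closed_form <- function(g, gradient) {
  if (!gradient$scheme %in% c("antagonistic", "concordant")) {
    stop("No closed form for a custom selection scheme.")
  }
  bl <- extract_blocks(g)
  shared <- bl$shared
  if (length(shared) == 0) stop("`g` has no shared traits.")
  ism <- match(shared, bl$male_traits)
  isf <- match(shared, bl$female_traits)
  Gm <- bl$G_M[ism, ism, drop = FALSE]
  Gf <- bl$G_F[isf, isf, drop = FALSE]
  B <- bl$B
  beta_m <- gradient$beta[paste(shared, "M", sep = ":")]
  M <- if (gradient$scheme == "antagonistic") {
    (Gm + Gf) / 2 - (B + t(B)) / 2
  } else {
    (Gm - Gf) / 2 + (B - t(B)) / 2
  }
  stats::setNames(drop(M %*% beta_m), shared)
}

#' Conditional response to selection
#'
#' Response when all trait combinations orthogonal to the selection
#' gradient are held fixed by strong stabilizing selection: the response
#' is constrained to the direction of beta, with magnitude given by the
#' conditional evolvability `c(beta) = (betahat' G^-1 betahat)^-1` for the
#' unit gradient betahat. Always `c(beta) <= e(beta)`. Rank-deficient
#' matrices are regularized by flooring eigenvalues at `1e-8 * lambda_max`
#' before inversion (recorded in the result).
#'
#' @inheritParams predict_response
#' @return A `response_summary` whose `dz` is the constrained response
#'   (the 1/2 of the breeder's equation applied), with extra fields
#'   `conditional_evolvability` and `regularized`.
#' @export
conditional_response <- function(g, gradient, allow_correlation = FALSE) {
  stopifnot(inherits(g, "sexed_g"), inherits(gradient, "selection_gradient"))
  if (isTRUE(g$is_correlation) && !allow_correlation) {
    stop("`g` stores correlations; pass a covariance matrix or set ",
         "`allow_correlation = TRUE`.")
  }
  beta <- gradient$beta
  bhat <- beta / sqrt(sum(beta^2))
  e <- eigen((g$cov + t(g$cov)) / 2, symmetric = TRUE)
  floor_ev <- 1e-8 * max(e$values)
  regularized <- any(e$values < floor_ev)
  lam <- pmax(e$values, floor_ev)
  if (max(lam) <= 0) stop("Matrix is singular and cannot be regularized.")
  w <- drop(crossprod(e$vectors, bhat))
  cond_e <- 1 / sum(w^2 / lam)
  # constrained response along beta, scaled like dz (1/2 applied) for the
  # actual (possibly non-unit) gradient strength
  dz <- cond_e * sqrt(sum(beta^2)) * bhat / 2
  out <- summarize_response(g, gradient, dz)
  out$conditional_evolvability <- cond_e
  out$regularized <- regularized
  out$e <- cond_e    # response in the gradient direction under constraint
  out$R <- cond_e    # constrained response lies along beta
  out
}

#' Dimorphism-response ratios for modified G matrices
#'
#' For each (selection gradient, matrix modification) pair, predicts the
#' dimorphism-change norm from the modified matrix and reports its ratio
#' to the norm from the unmodified matrix. Structural results: under
#' antagonistic selection the ratio is exactly 1 for `avg_G`, `sym_B` and
#' `avg_G_sym_B`; under concordant selection it is exactly 0 for
#' `avg_G_sym_B` and `avg_G_zero_B`.
#'
#' @param g A `sexed_g` covariance matrix.
#' @param gradients A list of [selection_gradient()] objects, or `NULL`
#'   for the default set: antagonistic and concordant selection on each
#'   shared trait singly and on all shared traits jointly.
#' @param mods Character vector of modification modes
#'   (see [apply_modification()]).
#' @return Tibble with columns `selection`, `scheme`, `mod`, `delta_norm`,
#'   `delta_norm_unmodified`, `ratio` (NA when the unmodified norm is 0).
#' @export
modification_ratio_table <- function(g, gradients = NULL,
                                     mods = c("avg_G", "sym_B", "zero_B",
                                              "avg_G_sym_B", "avg_G_zero_B")) {
  shared <- shared_traits(g)
  if (is.null(gradients)) {
    sel <- c(as.list(shared), if (length(shared) > 1) list(shared))
    gradients <- purrr::flatten(purrr::map(sel, function(tr) {
      list(selection_gradient(g, "antagonistic", traits = tr),
           selection_gradient(g, "concordant", traits = tr))
    }))
  }
  mod_gs <- purrr::map(mods, ~ suppressWarnings(apply_modification(g, .x)))
  purrr::map_dfr(gradients, function(grad) {
    base <- predict_response(g, grad)$delta_norm
    purrr::map_dfr(seq_along(mods), function(k) {
      dn <- predict_response(mod_gs[[k]], grad)$delta_norm
      tibble::tibble(
        selection = paste(if (length(grad$traits)) grad$traits else "custom",
                          collapse = "+"),
        scheme = grad$scheme,
        mod = mods[k],
        delta_norm = dn,
        delta_norm_unmodified = base,
        ratio = ifelse(base > 0, dn / base, NA_real_)
      )
    })
  })
}

#' Median and quantile summaries of responses over replicate G matrices
#'
#' Thin uncertainty-propagation loop: applies a scalar statistic to each
#' replicate `sexed_g` and reports the median and 2.5%/97.5% quantiles
#' (linear-interpolation, type-7 quantiles).
#'
#' @param replicates List of `sexed_g` objects (e.g. from
#'   [sample_g_replicates()]).
#' @param statistic Function mapping a `sexed_g` to a scalar.
#' @param probs Quantile probabilities for the lower/upper summaries.
#' @return Tibble with `median`, `q2.5`, `q97.5`, `n_used`, `n_missing`.
#' @export
summarize_over_replicates <- function(replicates, statistic,
                                      probs = c(0.025, 0.975)) {
  if (inherits(replicates, "g_samples")) replicates <- replicates$replicates
  vals <- purrr::map_dbl(replicates, function(r) {
    out <- tryCatch(statistic(r), error = function(e) NA_real_)
    if (length(out) != 1) NA_real_ else as.numeric(out)
  })
  ok <- vals[is.finite(vals)]
  if (length(ok) == 0) stop("Statistic undefined on every replicate.")
  q <- stats::quantile(ok, probs = probs, type = 7, names = FALSE)
  tibble::tibble(
    median = stats::median(ok), q2.5 = q[1], q97.5 = q[2],
    n_used = length(ok), n_missing = length(vals) - length(ok)
  )
}
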