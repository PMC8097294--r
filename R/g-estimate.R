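#' Estimate the sexed-trait G matrix from replicated line scores
#'
#' MANOVA-style moment estimator for a balanced inbred-line design, with
#' lines assumed unrelated: the genetic covariance is the between-line
#' covariance of line-mean score vectors minus the within-line (residual)
#' covariance divided by the replicate count,
#' `G = cov(line means) - E / n_reps`. The estimate is projected to the
#' nearest positive semi-definite matrix (eigenvalue clipping) and then
#' truncated to the rank selected by AICc over Gaussian rank-r factor
#' models of the line means: for each candidate rank r the line-mean
#' covariance is modelled as `G_r + E / n_reps` with `G_r` the rank-r
#' eigen-truncation, parameter count `p r - r (r - 1) / 2`, and sample
#' size the number of lines.
#'
#' Each candidate rank is fitted by maximum likelihood in the
#' error-whitened space: with `S` the whitened line-mean covariance and
#' eigenvalues `l_i`, the rank-r model `I + G_r` has the closed-form fit
#' `d_i = max(l_i, 1)` for the top r eigenvalues and 1 elsewhere, so the
#' genetic part never goes negative and lower ranks are not handicapped
#' by plug-in truncation.
#'
#' @param scores A `trait_scores` object from [build_trait_scores()], or
#'   a tibble with columns `line`, `rep` and one numeric column per sexed
#'   trait named `"trait:sex"`.
#' @param max_rank Largest candidate rank (default: full dimension).
#' @return A `g_estimate`: list with `g` (rank-r ML fit, PSD,
#'   `sexed_g`), `g_raw` (unprojected moment estimate), `rank`,
#'   `error_cov`, `n_lines`, `n_reps`, `criteria` (tibble: rank, loglik,
#'   k, aicc).
#' @export
estimate_g <- function(scores, max_rank = NULL) {
  tbl <- if (inherits(scores, "trait_scores")) scores$rep_scores else
    tibble::as_tibble(scores)
  stopifnot(all(c("line", "rep") %in% names(tbl)))
  trait_cols <- setdiff(names(tbl), c("line", "rep"))
  p <- length(trait_cols)
  X <- as.matrix(tbl[trait_cols])
  lines <- unique(tbl$line)
  L <- length(lines)
  reps_per_line <- table(tbl$line)
  R <- unname(reps_per_line[1])
  if (!all(reps_per_line == R)) {
    stop("`estimate_g()` requires a balanced design (equal replicates per line).")
  }
  line_idx <- match(tbl$line, lines)
  Xbar <- apply(X, 2, function(col) tapply(col, line_idx, mean))
  Sigma_B <- stats::cov(Xbar)
  if (R >= 2) {
    dev <- X - Xbar[line_idx, , drop = FALSE]
    E <- crossprod(dev) / (L * (R - 1))
    G_raw <- Sigma_B - E / R
  } else {
    warning("No replication: residual covariance unidentifiable; ",
            "using the raw line-mean covariance as G.")
    E <- matrix(NA_real_, p, p, dimnames = dimnames(Sigma_B))
    G_raw <- Sigma_B
  }
  if (is.null(max_rank)) max_rank <- p
  max_rank <- min(max_rank, p)
  fit <- fit_ranked_g(Sigma_B, if (R >= 2) E else NULL, L, R,
                      max_rank = max_rank)
  G_best <- fit$G
  dimnames(G_best) <- dimnames(Sigma_B)
  structure(list(
    g = sexed_g_from_labels(G_best, trait_cols),
    g_raw = G_raw, rank = fit$rank, error_cov = E,
    n_lines = L, n_reps = R, criteria = fit$criteria
  ), class = "g_estimate")
}

# ML fit of the rank-r genetic covariance in the error-whitened space,
# with AICc selection over r (sample size = number of lines). With no
# usable error covariance, falls back to PSD projection + truncation of
# the raw between-line covariance.
fit_ranked_g <- function(Sigma_B, E, L, R, max_rank, rank = NULL) {
  p <- nrow(Sigma_B)
  if (is.null(E)) {
    eg <- eigen(psd_project(Sigma_B), symmetric = TRUE)
    r <- if (is.null(rank)) max_rank else rank
    return(list(G = eigen_truncate(eg, r), rank = r,
                criteria = tibble::tibble(rank = r, loglik = NA_real_,
                                          k = NA_real_, aicc = NA_real_)))
  }
  U <- chol(near_pd_scale(E / R))          # E/R = U'U
  Uinv <- backsolve(U, diag(p))
  S_w <- t(Uinv) %*% Sigma_B %*% Uinv      # whitened line-mean covariance
  ew <- eigen((S_w + t(S_w)) / 2, symmetric = TRUE)
  lam <- pmax(ew$values, 1e-12)
  n_eff <- L - 1
  fit_r <- function(r) {
    d <- rep(1, p)
    if (r > 0) d[seq_len(r)] <- pmax(lam[seq_len(r)], 1)
    ll <- -0.5 * n_eff * (p * log(2 * pi) + 2 * sum(log(diag(U))) +
                            sum(log(d)) + sum(lam / d))
    ll
  }
  ranks <- seq_len(max_rank)
  crit <- purrr::map_dfr(ranks, function(r) {
    k <- p * r - r * (r - 1) / 2
    ll <- fit_r(r)
    aicc <- if (L - k - 1 > 0) {
      -2 * ll + 2 * k + 2 * k * (k + 1) / (L - k - 1)
    } else {
      Inf
    }
    tibble::tibble(rank = r, loglik = ll, k = k, aicc = aicc)
  })
  if (is.null(rank)) {
    # Parsimony rule: under a true rank r, the largest residual eigenvalue
    # of the error-whitened between-line covariance sits near the upper
    # bulk edge of a Fisher (Wachter) spectrum - both the between-line
    # scatter and the estimated error covariance fluctuate - not at 1, so
    # the minimal-AICc rank tends to absorb one edge fluctuation. Take the
    # smallest rank whose AICc is within the spurious log-likelihood gain
    # implied by that edge.
    df_w <- max(L * (R - 1), p + 1)
    edge_allow <- vapply(crit$rank, function(r) {
      y1 <- (p - r) / n_eff
      y2 <- p / df_w
      if (y1 <= 0) return(0)
      h <- sqrt(y1 + y2 - y1 * y2)
      b <- (1 + h)^2 / (1 - y2)^2
      n_eff * (b - 1 - log(b))
    }, numeric(1))
    ok <- crit$aicc <= min(crit$aicc) + edge_allow
    best <- min(crit$rank[ok])
  } else {
    best <- rank
  }
  d <- rep(1, p)
  d[seq_len(best)] <- pmax(lam[seq_len(best)], 1)
  Gw <- ew$vectors %*% ((d - 1) * t(ew$vectors))
  G <- t(U) %*% Gw %*% U
  G <- (G + t(G)) / 2
  list(G = G, rank = best, criteria = crit)
}

# Parse "trait:sex" column labels into a sexed_g.
sexed_g_from_labels <- function(cov, labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  variables <- tibble::tibble(
    trait = vapply(parts, `[`, "", 1),
    sex = vapply(parts, `[`, "", 2)
  )
  new_sexed_g(cov, variables, validate = FALSE)
}

psd_project <- function(mat) {
  e <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  out <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(mat)
  out
}

eigen_truncate <- function(eg, r) {
  lam <- pmax(eg$values, 0)
  lam[seq_along(lam) > r] <- 0
  eg$vectors %*% (lam * t(eg$vectors))
}

#' @export
print.g_estimate <- function(x, ...) {
  cat(sprintf("<g_estimate> %d traits, rank %d (AICc), %d lines x %d reps\n",
              nrow(x$g$cov), x$rank, x$n_lines, x$n_reps))
  invisible(x)
}

#' @rdname estimate_g
#' @param x A `g_estimate`.
#' @param ... Unused.
#' @export
glance.g_estimate <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x$g$cov), rank = x$rank,
    n_lines = x$n_lines, n_reps = x$n_reps,
    aicc = min(x$criteria$aicc)
  )
}

#' @rdname estimate_g
#' @export
tidy.g_estimate <- function(x, ...) tidy.sexed_g(x$g)

#' Sampling-distribution replicates of an estimated G matrix
#'
#' Propagates estimation uncertainty by parametric resampling of the
#' balanced design's scatter matrices: the between-line scatter is drawn
#' from a central Wishart at the fitted line-mean covariance with
#' `n_lines - 1` degrees of freedom, the within-line scatter from a
#' central Wishart at the residual covariance with
#' `n_lines (n_reps - 1)` degrees of freedom, and G is re-estimated from
#' each draw (moment subtraction, PSD projection, truncation to the
#' selected rank). A workable stand-in for sampling from the asymptotic
#' (information-matrix) distribution of REML estimates, preserving the
#' replicate-matrix / median / quantile workflow.
#'
#' @param est A `g_estimate` from [estimate_g()].
#' @param n Number of replicate matrices (default 1000).
#' @param seed Integer seed.
#' @return A `g_samples`: list with `replicates` (list of `sexed_g`),
#'   `method`, `seed`.
#' @export
sample_g_replicates <- function(est, n = 1000, seed) {
  stopifnot(inherits(est, "g_estimate"))
  if (missing(seed)) stop("`seed` is required.")
  p <- nrow(est$g$cov)
  L <- est$n_lines
  R <- est$n_reps
  if (p >= L) {
    stop("Dimension must be below the number of lines for the Wishart sampler.")
  }
  if (R < 2 || anyNA(est$error_cov)) {
    stop("Replication is required to sample G uncertainty.")
  }
  set.seed(seed)
  Sigma_B <- est$g$cov + est$error_cov / R
  df_b <- L - 1
  df_w <- L * (R - 1)
  # (L-1) * Sigma_B_hat ~ W(Sigma_B, L-1), so draw at scale Sigma_B and
  # divide by df. Wishart scales must be PD; a whisper of ridge if needed.
  Sb <- near_pd_scale(Sigma_B)
  Sw <- near_pd_scale(est$error_cov)
  draws_b <- stats::rWishart(n, df_b, Sb)
  draws_w <- stats::rWishart(n, df_w, Sw)
  reps <- purrr::map(seq_len(n), function(i) {
    # re-estimate from the drawn scatters with the same fixed-rank ML fit
    Sigma_B_i <- draws_b[, , i] / df_b
    E_i <- draws_w[, , i] / df_w
    Gi <- fit_ranked_g(Sigma_B_i, E_i, L, R, max_rank = p,
                       rank = max(est$rank, 1))$G
    dimnames(Gi) <- dimnames(est$g$cov)
    new_sexed_g(Gi, est$g$variables, validate = FALSE)
  })
  structure(list(replicates = reps, method = "wishart_moment", seed = seed),
            class = "g_samples")
}

near_pd_scale <- function(S) {
  p <- nrow(S)
  for (ridge in c(0, 1e-10, 1e-8, 1e-6)) {
    Sr <- S + diag(ridge * max(diag(S), 1e-12), p)
    if (!inherits(tryCatch(chol(Sr), error = function(e) e, "error"),
                  "error")) {
      return(Sr)
    }
  }
  S + diag(1e-4 * max(diag(S), 1e-12), p)
}

#' @export
print.g_samples <- function(x, ...) {
  cat(sprintf("<g_samples> %d replicate matrices (%s, seed %d)\n",
              length(x$replicates), x$method, x$seed))
  invisible(x)
}
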