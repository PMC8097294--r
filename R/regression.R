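#' Multiple regression of dimorphism on G-derived predictors
#'
#' Ordinary least squares of transformed dimorphism `log10(|D| + 0.01)`
#' on gene-level predictors, over genes. Default predictors (those
#' present in `summaries`): mean expression `e_bar`, tissue specificity
#' `tau`, `log10_gbar`, the intersexual correlation `r_mf`,
#' `log10_abs_m_minus_f` (concordant-selection signal), the aggregate
#' correlation statistics `rw_bar`, `rb_bar`, `abs_rdw` and
#' `log10_abs_rdb`, plus any 0/1 indicator columns added with
#' [add_indicator_covariates()]. Per-predictor variance explained is the
#' squared semipartial correlation: the increment in model R-squared when
#' the predictor is added last, in percent. Complete-case over the
#' predictors; constant or aliased predictors are dropped with a warning.
#'
#' @param summaries Gene summary tibble from [gene_summaries()] (or any
#'   tibble with `D` and predictor columns).
#' @param predictors Character vector of predictor column names; `NULL`
#'   for the default set intersected with available columns. Derived
#'   columns (`log10_gbar`, `log10_abs_m_minus_f`, `log10_abs_rdb`) are
#'   computed on the fly from `g_bar`, `m`, `f`, `abs_rdb`.
#' @param subset `"all"`, `"biased"` (|D| > 1) or `"unbiased"`
#'   (|D| <= 1).
#' @return A `dim_reg_fit`: list with `coefs` (tibble: term, estimate,
#'   partial_r2 in percent), `model_r2` (proportion), `n`, `dropped`,
#'   `subset`.
#' @export
fit_dimorphism_regression <- function(summaries, predictors = NULL,
                                      subset = c("all", "biased",
                                                 "unbiased")) {
  subset <- match.arg(subset)
  df <- prepare_regression_frame(summaries, predictors, subset)
  fit_regression_frame(df$frame, df$predictors)
}

default_predictors <- c("e_bar", "tau", "log10_gbar", "r_mf",
                        "log10_abs_m_minus_f", "rw_bar", "rb_bar",
                        "abs_rdw", "log10_abs_rdb")

# Adds derived columns, applies the subset rule and complete-case filter.
prepare_regression_frame <- function(summaries, predictors, subset) {
  s <- tibble::as_tibble(summaries)
  if (!"log10_D_abs" %in% names(s)) {
    s$log10_D_abs <- transform_dimorphism(s$D)
  }
  if (!"log10_gbar" %in% names(s) && "g_bar" %in% names(s)) {
    s$log10_gbar <- log10(s$g_bar)
  }
  if (!"log10_abs_m_minus_f" %in% names(s) && all(c("m", "f") %in% names(s))) {
    s$log10_abs_m_minus_f <- log10(abs(s$m - s$f))
  }
  if (!"log10_abs_rdb" %in% names(s) && "abs_rdb" %in% names(s)) {
    s$log10_abs_rdb <- log10(s$abs_rdb + 0.01)
  }
  if (is.null(predictors)) {
    predictors <- intersect(default_predictors, names(s))
    predictors <- predictors[vapply(s[predictors],
                                    function(x) !all(is.na(x)), TRUE)]
  }
  missing_cols <- setdiff(predictors, names(s))
  if (length(missing_cols)) {
    stop("Missing predictor columns: ", paste(missing_cols, collapse = ", "))
  }
  if (subset == "biased") s <- dplyr::filter(s, abs(.data$D) > 1)
  if (subset == "unbiased") s <- dplyr::filter(s, abs(.data$D) <= 1)
  frame <- s[c("log10_D_abs", predictors)]
  ok <- stats::complete.cases(frame) &
    apply(as.matrix(frame), 1, function(r) all(is.finite(r)))
  frame <- frame[ok, ]
  if (nrow(frame) < length(predictors) + 2) {
    stop("Not enough complete cases for the regression.")
  }
  list(frame = frame, predictors = predictors, subset = subset)
}

# OLS + semipartial R^2, dropping constant/aliased predictors.
fit_regression_frame <- function(frame, predictors, warn = TRUE) {
  y <- frame$log10_D_abs
  X <- as.matrix(frame[predictors])
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  Xk <- X[, keep, drop = FALSE]
  # detect aliased columns via QR of the centered design
  q <- qr(cbind(1, Xk))
  if (q$rank < ncol(Xk) + 1) {
    aliased <- colnames(Xk)[q$pivot[-seq_len(q$rank)] - 1]
    keep[aliased] <- FALSE
    Xk <- X[, keep, drop = FALSE]
  }
  dropped <- colnames(X)[!keep]
  if (warn && length(dropped)) {
    warning("Dropped constant/aliased predictors: ",
            paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xk), y)
  tss <- sum((y - mean(y))^2)
  r2_full <- 1 - sum(fit$residuals^2) / tss
  partial <- vapply(colnames(Xk), function(term) {
    Xr <- Xk[, setdiff(colnames(Xk), term), drop = FALSE]
    fr <- stats::lm.fit(cbind(1, Xr), y)
    r2r <- 1 - sum(fr$residuals^2) / tss
    100 * (r2_full - r2r)
  }, numeric(1))
  est <- fit$coefficients[colnames(Xk)]
  coefs <- tibble::tibble(
    term = predictors,
    estimate = est[predictors],
    partial_r2 = partial[predictors]
  )
  structure(list(coefs = coefs, model_r2 = r2_full, n = length(y),
                 dropped = dropped),
            class = "dim_reg_fit")
}

#' @export
print.dim_reg_fit <- function(x, ...) {
  cat(sprintf("<dim_reg_fit> n=%d  R2=%.3f\n", x$n, x$model_r2))
  print(x$coefs)
  invisible(x)
}

#' @rdname fit_dimorphism_regression
#' @param x A `dim_reg_fit`.
#' @param ... Unused.
#' @export
tidy.dim_reg_fit <- function(x, ...) x$coefs

#' @rdname fit_dimorphism_regression
#' @export
glance.dim_reg_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$model_r2, n = x$n,
                 n_dropped = length(x$dropped))
}

#' Line-level bootstrapped dimorphism regression
#'
#' Resamples inbred lines with replacement; each replicate recomputes the
#' line means (by line selection), every G*-derived predictor (m, f, b,
#' rMF, g_bar, the aggregate cross-gene correlation statistics), the mean
#' expression, the dimorphism D and its transformation, and refits the
#' regression. Reports per-predictor medians and 2.5%/97.5% quantiles
#' (type-7); an effect is flagged significant when both quantiles share a
#' sign. Tissue specificity is gene-level and does not vary across line
#' resamples. Predictors that are constant in a replicate are recorded as
#' missing for that replicate.
#'
#' @param data Long expression tibble (see [screen_genes()]).
#' @param tissue_table Optional tissue table (see
#'   [expression_covariates()]).
#' @param gene_sets Optional named list of gene-id vectors added as 0/1
#'   indicator predictors.
#' @param predictors Predictor names (`NULL` = default set).
#' @param subset Gene subset rule, as in [fit_dimorphism_regression()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (required: resampling is stochastic).
#' @param alpha Screening threshold (the screen runs once, on the
#'   original panel).
#' @return A `dim_reg_boot`: list with `summary` (tibble: term, median,
#'   q2.5, q97.5, significant, partial_r2_median, n_missing), `model_r2`
#'   (median over replicates), `observed` (the `dim_reg_fit` on the
#'   original data), `n_boot`, `seed`, `n_lines`.
#' @export
bootstrap_dimorphism_regression <- function(data, tissue_table = NULL,
                                            gene_sets = NULL,
                                            predictors = NULL,
                                            subset = c("all", "biased",
                                                       "unbiased"),
                                            n_boot = 1000, seed,
                                            alpha = 0.01) {
  subset <- match.arg(subset)
  if (missing(seed)) stop("`seed` is required.")
  scr <- screen_genes(data, alpha = alpha)
  keep <- scr$gene_id[!is.na(scr$retained) & scr$retained]
  if (length(keep) < 10) stop("Too few screened genes to regress on.")
  lm_tbl <- line_means(data, genes = keep)
  mats <- line_mean_matrices(lm_tbl)
  tau_tbl <- if (!is.null(tissue_table)) {
    expression_covariates(dplyr::filter(data, .data$gene_id %in% keep),
                          tissue_table)[c("gene_id", "tau")]
  } else {
    NULL
  }
  L <- nrow(mats$M)
  if (L < 5) stop("Need at least 5 lines to bootstrap at the line level.")

  build_summaries <- function(idx) {
    Mm <- mats$M[idx, , drop = FALSE]
    Fm <- mats$F[idx, , drop = FALSE]
    s <- gene_moments_mat(Mm, Fm)
    s <- dplyr::bind_cols(s, aggregate_correlations_mat(Mm, Fm))
    if (!is.null(tau_tbl)) {
      s <- dplyr::left_join(s, tau_tbl, by = "gene_id")
    }
    if (!is.null(gene_sets)) {
      s <- add_indicator_covariates(s, gene_sets, quiet = TRUE)
    }
    s
  }
  obs_sum <- build_summaries(seq_len(L))
  prep <- prepare_regression_frame(obs_sum, predictors, subset)
  observed <- fit_regression_frame(prep$frame, prep$predictors)

  set.seed(seed)
  terms <- prep$predictors
  slopes <- matrix(NA_real_, n_boot, length(terms),
                   dimnames = list(NULL, terms))
  pr2 <- slopes
  r2 <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    sb <- build_summaries(idx)
    res <- tryCatch({
      pb <- prepare_regression_frame(sb, terms, subset)
      suppressWarnings(fit_regression_frame(pb$frame, pb$predictors))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      slopes[b, res$coefs$term] <- res$coefs$estimate
      pr2[b, res$coefs$term] <- res$coefs$partial_r2
      r2[b] <- res$model_r2
    }
  }
  qs <- apply(slopes, 2, function(v) {
    ok <- v[is.finite(v)]
    if (length(ok) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(stats::median(ok),
      stats::quantile(ok, c(0.025, 0.975), type = 7, names = FALSE))
  })
  summary_tbl <- tibble::tibble(
    term = terms,
    median = qs[1, ],
    q2.5 = qs[2, ],
    q97.5 = qs[3, ],
    significant = is.finite(qs[2, ]) & is.finite(qs[3, ]) &
      sign(qs[2, ]) == sign(qs[3, ]) & qs[2, ] != 0,
    partial_r2_median = apply(pr2, 2, stats::median, na.rm = TRUE),
    n_missing = colSums(!is.finite(slopes))
  )
  structure(list(
    summary = summary_tbl,
    model_r2 = stats::median(r2, na.rm = TRUE),
    observed = observed, n_boot = n_boot, seed = seed, n_lines = L,
    subset = subset
  ), class = "dim_reg_boot")
}

# Vectorized per-gene moments from line-mean matrices.
gene_moments_mat <- function(Mm, Fm) {
  L <- nrow(Mm)
  cm <- colMeans(Mm)
  cf <- colMeans(Fm)
  Mc <- sweep(Mm, 2, cm)
  Fc <- sweep(Fm, 2, cf)
  m <- colSums(Mc^2) / (L - 1)
  f <- colSums(Fc^2) / (L - 1)
  b <- colSums(Mc * Fc) / (L - 1)
  tibble::tibble(
    gene_id = colnames(Mm),
    D = cm - cf,
    m = m, f = f, b = b,
    r_mf = ifelse(m > 0 & f > 0, b / sqrt(m * f), NA_real_),
    g_bar = (m + f) / 2,
    e_bar = (cm + cf) / 2
  )
}

#' @export
print.dim_reg_boot <- function(x, ...) {
  cat(sprintf(
    "<dim_reg_boot> %s genes, %d lines, %d bootstrap replicates (seed %d)\n",
    x$subset, x$n_lines, x$n_boot, x$seed))
  cat(sprintf("median model R2 = %.3f\n", x$model_r2))
  print(x$summary)
  invisible(x)
}

#' @rdname bootstrap_dimorphism_regression
#' @param x A `dim_reg_boot`.
#' @param ... Unused.
#' @export
tidy.dim_reg_boot <- function(x, ...) x$summary

#' @rdname bootstrap_dimorphism_regression
#' @export
glance.dim_reg_boot <- function(x, ...) {
  tibble::tibble(r.squared = x$model_r2, n_boot = x$n_boot,
                 n_lines = x$n_lines, subset = x$subset, seed = x$seed)
}

#' Bootstrap slope interval plot
#' @param object A `dim_reg_boot`.
#' @param ... Unused.
#' @return A ggplot showing median slopes with 95% bootstrap intervals.
#' @export
autoplot.dim_reg_boot <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$median, y = .data$term,
                               colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q2.5,
                                          xmax = .data$q97.5)) +
    ggplot2::labs(x = "slope (median, 95% bootstrap interval)", y = NULL,
                  title = "Dimorphism regression, line-level bootstrap") +
    ggplot2::theme_minimal()
}

#' Add gene-set indicator predictors
#'
#' Adds a 0/1 column per named gene set (for example genes with a fitness
#' main effect or a sex-by-fitness interaction in an external selection
#' screen), usable as regression predictors. Ids absent from `summaries`
#' are counted and reported, not fatal.
#'
#' @param summaries Gene summary tibble (must contain `gene_id`).
#' @param gene_sets Named list of gene-id character vectors.
#' @param quiet Suppress the unmatched-id message.
#' @return `summaries` with one extra 0/1 column per set.
#' @export
add_indicator_covariates <- function(summaries, gene_sets, quiet = FALSE) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  for (nm in names(gene_sets)) {
    ids <- gene_sets[[nm]]
    n_absent <- sum(!ids %in% summaries$gene_id)
    if (!quiet && n_absent > 0) {
      message(sprintf("Gene set '%s': %d of %d ids not in summaries.",
                      nm, n_absent, length(ids)))
    }
    summaries[[nm]] <- as.numeric(summaries$gene_id %in% ids)
  }
  summaries
}
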