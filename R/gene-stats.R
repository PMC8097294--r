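#' Screen genes for significant genetic variation
#'
#' Per gene, fits the mixed model with fixed sex (plus probe and
#' probe-by-sex for multi-probe genes) and random line, line-by-sex (and
#' line-by-probe) effects, and compares its restricted likelihood against
#' the model with all random terms removed. The likelihood-ratio statistic
#' is referred to a chi-square with 2 df for single-probe genes and 3 df
#' for multi-probe genes; genes are retained when `p < alpha`. Because the
#' variance components sit on the boundary under the null, the plain LRT
#' is conservative (realized type-I rate below nominal).
#'
#' For the balanced single-probe design (every line-by-sex cell with the
#' same number of replicates) the restricted likelihood is profiled in
#' closed form: the data decompose into orthogonal within-cell,
#' line-difference and line-mean strata whose variance scales are ordered
#' (`sigma_e^2 <= sigma_e^2 + R sigma_ls^2 <= ... + 2 R sigma_l^2`), so
#' the constrained REML fit is a three-point weighted isotonic regression.
#' This path is vectorized over genes. Unbalanced or multi-probe genes
#' fall back to `lme4::lmer()`.
#'
#' @param data Long expression tibble with columns `gene_id`, `line`,
#'   `sex` ("M"/"F"), `rep`, `value` and optionally `probe` (log2 scale).
#' @param alpha Retention threshold on the LRT p-value.
#' @return Tibble with one row per gene: `lrt`, `df`, `p_value`,
#'   `retained`, and the fitted variance components `sigma2_line`,
#'   `sigma2_line_sex`, `sigma2_resid` (balanced path only; `NA` on the
#'   lme4 fallback, whose components are model-specific). Genes with a
#'   degenerate design (one line or one sex) are flagged `retained = NA`.
#' @export
screen_genes <- function(data, alpha = 0.01) {
  check_expression_data(data)
  has_probe <- "probe" %in% names(data) &&
    any(!is.na(data$probe)) && dplyr::n_distinct(data$probe) > 1
  design <- data |>
    dplyr::distinct(.data$gene_id, .data$line, .data$sex)
  deg <- design |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_lines = dplyr::n_distinct(.data$line),
      n_sexes = dplyr::n_distinct(.data$sex), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_lines < 2 | .data$n_sexes < 2)
  bad_genes <- deg$gene_id

  multi <- if (has_probe) {
    data |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(np = dplyr::n_distinct(.data$probe),
                       .groups = "drop") |>
      dplyr::filter(.data$np > 1) |>
      dplyr::pull(.data$gene_id)
  } else {
    character(0)
  }

  ok <- data |> dplyr::filter(!.data$gene_id %in% c(bad_genes, multi))
  res_bal <- screen_balanced(ok)
  slow_genes <- union(multi, res_bal$unbalanced)
  res_fb <- purrr::map_dfr(slow_genes, function(gid) {
    screen_one_lmer(dplyr::filter(data, .data$gene_id == gid))
  })
  out <- dplyr::bind_rows(
    res_bal$table, res_fb,
    tibble::tibble(gene_id = bad_genes, lrt = NA_real_, df = NA_integer_,
                   p_value = NA_real_, retained = NA,
                   sigma2_line = NA_real_, sigma2_line_sex = NA_real_,
                   sigma2_resid = NA_real_)
  )
  out$retained <- ifelse(is.na(out$p_value), out$retained,
                         out$p_value < alpha)
  dplyr::arrange(out, match(.data$gene_id, unique(data$gene_id)))
}

# Closed-form REML screen for the balanced single-probe design.
# Returns list(table, unbalanced = gene ids needing the lme4 fallback).
screen_balanced <- function(data) {
  empty <- tibble::tibble(
    gene_id = character(0), lrt = numeric(0), df = integer(0),
    p_value = numeric(0), retained = logical(0), sigma2_line = numeric(0),
    sigma2_line_sex = numeric(0), sigma2_resid = numeric(0)
  )
  if (nrow(data) == 0) return(list(table = empty, unbalanced = character(0)))
  counts <- data |>
    dplyr::count(.data$gene_id, .data$line, .data$sex)
  bal <- counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      R = .data$n[1],
      ok = dplyr::n_distinct(.data$n) == 1 && .data$n[1] >= 2 &&
        dplyr::n() == dplyr::n_distinct(.data$line) * 2,
      .groups = "drop"
    )
  unbalanced <- bal$gene_id[!bal$ok]
  genes <- bal$gene_id[bal$ok]
  if (length(genes) == 0) return(list(table = empty, unbalanced = unbalanced))

  d <- data |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::arrange(.data$gene_id, .data$line, .data$sex, .data$rep)
  # per-gene constants (R may differ by gene; L too)
  cell <- d |>
    dplyr::group_by(.data$gene_id, .data$line, .data$sex) |>
    dplyr::summarise(mu = mean(.data$value), sse = sum((.data$value -
                                                        mean(.data$value))^2),
                     R = dplyr::n(), .groups = "drop")
  per_gene <- cell |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(SSE = sum(.data$sse), R = .data$R[1],
                     L = dplyr::n() / 2, .groups = "drop")
  zw <- cell |>
    dplyr::mutate(z = sqrt(.data$R) * .data$mu) |>
    tidyr::pivot_wider(id_cols = c("gene_id", "line"), names_from = "sex",
                       values_from = "z") |>
    dplyr::mutate(u = (.data$M - .data$F) / sqrt(2),
                  s = (.data$M + .data$F) / sqrt(2)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(SS_u = sum((.data$u - mean(.data$u))^2),
                     SS_s = sum((.data$s - mean(.data$s))^2),
                     .groups = "drop")
  pg <- dplyr::inner_join(per_gene, zw, by = "gene_id")

  df_e <- 2 * pg$L * (pg$R - 1)
  w_u <- pg$L - 1
  e0 <- pg$SSE / df_e
  u0 <- pg$SS_u / w_u
  s0 <- pg$SS_s / w_u
  iso <- pava3(e0, u0, s0, df_e, w_u, w_u)
  f_full <- df_e * log(iso$x1) + pg$SSE / iso$x1 +
    w_u * log(iso$x2) + pg$SS_u / iso$x2 +
    w_u * log(iso$x3) + pg$SS_s / iso$x3
  df0 <- df_e + 2 * w_u
  sig0 <- (pg$SSE + pg$SS_u + pg$SS_s) / df0
  f0 <- df0 * (log(sig0) + 1)
  lrt <- pmax(f0 - f_full, 0)
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  bad <- !is.finite(lrt)
  table <- tibble::tibble(
    gene_id = pg$gene_id,
    lrt = ifelse(bad, NA_real_, lrt),
    df = 2L,
    p_value = ifelse(bad, NA_real_, p),
    retained = NA,
    sigma2_line = (iso$x3 - iso$x2) / (2 * pg$R),
    sigma2_line_sex = (iso$x2 - iso$x1) / pg$R,
    sigma2_resid = iso$x1
  )
  list(table = table, unbalanced = unbalanced)
}

# Weighted isotonic regression (PAVA) for three ordered points, vectorized.
pava3 <- function(x1, x2, x3, w1, w2, w3) {
  p12 <- (w1 * x1 + w2 * x2) / (w1 + w2)
  p23 <- (w2 * x2 + w3 * x3) / (w2 + w3)
  pall <- (w1 * x1 + w2 * x2 + w3 * x3) / (w1 + w2 + w3)
  o1 <- x1; o2 <- x2; o3 <- x3
  # case x1 > x2: pool 1-2, then possibly all three
  c12 <- x1 > x2
  o1 <- ifelse(c12, p12, o1); o2 <- ifelse(c12, p12, o2)
  all12 <- c12 & (p12 > x3)
  o1 <- ifelse(all12, pall, o1); o2 <- ifelse(all12, pall, o2)
  o3 <- ifelse(all12, pall, o3)
  # case x1 <= x2 but x2 > x3: pool 2-3, then possibly all three
  c23 <- !c12 & (x2 > x3)
  o2 <- ifelse(c23, p23, o2); o3 <- ifelse(c23, p23, o3)
  all23 <- c23 & (x1 > p23)
  o1 <- ifelse(all23, pall, o1); o2 <- ifelse(all23, pall, o2)
  o3 <- ifelse(all23, pall, o3)
  list(x1 = o1, x2 = o2, x3 = o3)
}

# lme4 fallback for one gene (multi-probe and/or unbalanced designs).
screen_one_lmer <- function(d) {
  multi <- "probe" %in% names(d) && dplyr::n_distinct(d$probe) > 1
  d$line <- factor(d$line)
  d$sex <- factor(d$sex)
  fit <- tryCatch({
    if (multi) {
      d$probe <- factor(d$probe)
      full <- lme4::lmer(
        value ~ sex * probe + (1 | line) + (1 | line:sex) + (1 | line:probe),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))
      )
      null_x <- stats::model.matrix(~ sex * probe, data = d)
    } else {
      full <- lme4::lmer(
        value ~ sex + (1 | line) + (1 | line:sex),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))
      )
      null_x <- stats::model.matrix(~ sex, data = d)
    }
    crit0 <- lm_reml_crit(null_x, d$value)
    lrt <- max(crit0 - lme4::REMLcrit(full), 0)
    df <- if (multi) 3L else 2L
    tibble::tibble(
      gene_id = d$gene_id[1], lrt = lrt, df = df,
      p_value = stats::pchisq(lrt, df, lower.tail = FALSE), retained = NA,
      sigma2_line = NA_real_, sigma2_line_sex = NA_real_,
      sigma2_resid = NA_real_
    )
  }, error = function(e) {
    tibble::tibble(gene_id = d$gene_id[1], lrt = NA_real_, df = NA_integer_,
                   p_value = NA_real_, retained = NA,
                   sigma2_line = NA_real_, sigma2_line_sex = NA_real_,
                   sigma2_resid = NA_real_)
  })
  fit
}

# REML criterion (-2 restricted log-likelihood, lme4's convention) for a
# fixed-effects-only Gaussian linear model.
lm_reml_crit <- function(X, y) {
  qrX <- qr(X)
  p <- qrX$rank
  n <- length(y)
  rss <- sum(qr.resid(qrX, y)^2)
  sig2 <- rss / (n - p)
  Rq <- qr.R(qrX)[seq_len(p), seq_len(p), drop = FALSE]
  (n - p) * (log(2 * pi * sig2) + 1) + 2 * sum(log(abs(diag(Rq))))
}

#' Least-squares line means
#'
#' Per (gene, line, sex) least-squares mean of log2 expression. For the
#' balanced single-probe design this is the arithmetic replicate mean; for
#' multi-probe genes it is the probe-effect-adjusted cell mean with probes
#' equally weighted (additive probe model).
#'
#' @inheritParams screen_genes
#' @param genes Optional gene ids to keep (e.g. the screened set).
#' @return Tibble `gene_id`, `line`, `sex`, `ls_mean`. Missing
#'   (line, sex) cells are absent from the output; downstream cross-gene
#'   statistics drop genes with incomplete cells.
#' @export
line_means <- function(data, genes = NULL) {
  check_expression_data(data)
  if (!is.null(genes)) data <- dplyr::filter(data, .data$gene_id %in% genes)
  multi <- if ("probe" %in% names(data)) {
    data |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(np = dplyr::n_distinct(.data$probe),
                       .groups = "drop") |>
      dplyr::filter(.data$np > 1) |>
      dplyr::pull(.data$gene_id)
  } else {
    character(0)
  }
  simple <- data |>
    dplyr::filter(!.data$gene_id %in% multi) |>
    dplyr::group_by(.data$gene_id, .data$line, .data$sex) |>
    dplyr::summarise(ls_mean = mean(.data$value), .groups = "drop")
  if (length(multi) == 0) return(simple)
  adj <- data |>
    dplyr::filter(.data$gene_id %in% multi) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(~ ls_means_one(.x)) |>
    dplyr::ungroup()
  dplyr::bind_rows(simple, adj)
}

# Probe-adjusted LS means for one multi-probe gene: additive model
# cell(line, sex) + probe with sum-to-zero probe effects.
ls_means_one <- function(d) {
  d$cell <- interaction(d$line, d$sex, drop = TRUE)
  d$probe <- factor(d$probe)
  X <- stats::model.matrix(~ 0 + cell + probe, data = d,
                           contrasts.arg = list(probe = "contr.sum"))
  fit <- stats::lm.fit(X, d$value)
  co <- fit$coefficients
  cells <- levels(d$cell)
  est <- co[paste0("cell", cells)]
  parts <- do.call(rbind, strsplit(cells, ".", fixed = TRUE))
  tibble::tibble(line = parts[, 1], sex = parts[, 2],
                 ls_mean = unname(est))
}

#' Dimorphism and sex-bias classification
#'
#' `D` is the mean over lines of (male minus female) least-squares mean
#' log2 expression, i.e. the log2 male:female expression ratio. Classes:
#' male-biased (`MB`, D > 1, male expression more than twice female),
#' female-biased (`FB`, D < -1), relatively unbiased (`UB`, |D| <= 1).
#'
#' @param lm_tbl Line means from [line_means()].
#' @return Tibble `gene_id`, `D`, `bias_class`. Genes missing a sex are
#'   dropped.
#' @export
gene_dimorphism <- function(lm_tbl) {
  lm_tbl |>
    tidyr::pivot_wider(id_cols = c("gene_id", "line"), names_from = "sex",
                       values_from = "ls_mean") |>
    dplyr::filter(!is.na(.data$M), !is.na(.data$F)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(D = mean(.data$M - .data$F), .groups = "drop") |>
    dplyr::mutate(bias_class = dplyr::case_when(
      .data$D > 1 ~ "MB",
      .data$D < -1 ~ "FB",
      TRUE ~ "UB"
    ))
}

#' Per-gene genetic parameters from line means
#'
#' Between-line sample variances of the male (`m`) and female (`f`) line
#' means, their sample covariance (`b`), the intersexual correlation
#' `r_mf = b / sqrt(m f)`, the average variance `g_bar = (m + f)/2` and
#' the variance-asymmetry statistic `d`. These are entries of the
#' exploratory G* matrix, on the inbred-line (between-line) variance
#' scale; no outbred conversion factor is applied.
#'
#' @param lm_tbl Line means from [line_means()].
#' @return Tibble `gene_id`, `m`, `f`, `b`, `r_mf`, `g_bar`, `d`,
#'   `n_lines`. Requires at least 3 lines per gene; `r_mf` and `d` are
#'   `NA` when either sex has zero variance.
#' @export
gene_genetics <- function(lm_tbl) {
  wide <- lm_tbl |>
    tidyr::pivot_wider(id_cols = c("gene_id", "line"), names_from = "sex",
                       values_from = "ls_mean") |>
    dplyr::filter(!is.na(.data$M), !is.na(.data$F))
  out <- wide |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_lines = dplyr::n(),
      m = stats::var(.data$M),
      f = stats::var(.data$F),
      b = stats::cov(.data$M, .data$F),
      .groups = "drop"
    )
  if (any(out$n_lines < 3)) {
    stop("`gene_genetics()` requires at least 3 lines per gene.")
  }
  out |>
    dplyr::mutate(
      r_mf = ifelse(.data$m > 0 & .data$f > 0,
                    .data$b / sqrt(.data$m * .data$f), NA_real_),
      g_bar = (.data$m + .data$f) / 2,
      d = ifelse(.data$m > 0 & .data$f > 0,
                 sqrt(.data$m * .data$f) / .data$g_bar, NA_real_)
    )
}

#' Aggregate cross-gene correlation statistics
#'
#' For gene i, across all other genes j, using correlations of line means:
#' `rw_bar_i = sum(rMiMj + rFiFj) / (2 (n - 1))` (average within-sex
#' cross-gene correlation), `rb_bar_i = sum(rMiFj + rFiMj) / (2 (n - 1))`
#' (average between-sex cross-gene correlation),
#' `abs_rdw_i = |sum(rMiMj - rFiFj) / (2 (n - 1))|` and
#' `abs_rdb_i = |sum(rMiFj - rFiMj) / (2 (n - 1))|` (asymmetries that
#' drive concordant dimorphism responses). Computed via standardized
#' matrix products in O(genes^2) rather than the quadruple loop. Genes
#' with zero variance in either sex are excluded from the sums, with `n`
#' reduced accordingly, and get `NA` statistics.
#'
#' @param lm_tbl Line means from [line_means()].
#' @return Tibble `gene_id`, `rw_bar`, `rb_bar`, `abs_rdw`, `abs_rdb`,
#'   `n_genes_used`.
#' @export
aggregate_correlations <- function(lm_tbl) {
  mats <- line_mean_matrices(lm_tbl)
  agg <- aggregate_correlations_mat(mats$M, mats$F)
  tibble::tibble(gene_id = colnames(mats$M)) |>
    dplyr::bind_cols(agg)
}

# Wide line-mean matrices (lines x genes) for each sex, complete cases.
line_mean_matrices <- function(lm_tbl) {
  wide <- lm_tbl |>
    tidyr::pivot_wider(id_cols = c("gene_id", "line"), names_from = "sex",
                       values_from = "ls_mean") |>
    dplyr::filter(!is.na(.data$M), !is.na(.data$F))
  genes <- unique(wide$gene_id)
  lines <- unique(wide$line)
  Mm <- matrix(NA_real_, length(lines), length(genes),
               dimnames = list(lines, genes))
  Fm <- Mm
  Mm[cbind(match(wide$line, lines), match(wide$gene_id, genes))] <- wide$M
  Fm[cbind(match(wide$line, lines), match(wide$gene_id, genes))] <- wide$F
  keep <- colSums(is.na(Mm)) == 0 & colSums(is.na(Fm)) == 0
  list(M = Mm[, keep, drop = FALSE], F = Fm[, keep, drop = FALSE])
}

# Core of aggregate_correlations, on lines x genes matrices.
aggregate_correlations_mat <- function(Mm, Fm) {
  n_all <- ncol(Mm)
  sdM <- apply(Mm, 2, stats::sd)
  sdF <- apply(Fm, 2, stats::sd)
  use <- sdM > 0 & sdF > 0
  n <- sum(use)
  out <- tibble::tibble(
    rw_bar = rep(NA_real_, n_all), rb_bar = NA_real_,
    abs_rdw = NA_real_, abs_rdb = NA_real_, n_genes_used = n
  )
  if (n < 2) return(out)
  CM <- stats::cor(Mm[, use, drop = FALSE])
  CF <- stats::cor(Fm[, use, drop = FALSE])
  CB <- stats::cor(Mm[, use, drop = FALSE], Fm[, use, drop = FALSE])
  denom <- 2 * (n - 1)
  rw <- (rowSums(CM) - 1 + rowSums(CF) - 1) / denom
  rb <- (rowSums(CB) + colSums(CB) - 2 * diag(CB)) / denom
  rdw <- abs((rowSums(CM) - rowSums(CF)) / denom)
  rdb <- abs((rowSums(CB) - colSums(CB)) / denom)
  out$rw_bar[use] <- rw
  out$rb_bar[use] <- rb
  out$abs_rdw[use] <- rdw
  out$abs_rdb[use] <- rdb
  out
}

#' Mean expression and tissue specificity
#'
#' `e_bar` is the grand mean log2 expression of each gene over all
#' samples. Tissue specificity uses the max-normalized index
#' `tau = sum_t (1 - x_t / max_t x_t) / (N_tissues - 1)`, 0 for uniformly
#' expressed genes and 1 for single-tissue genes. Intensities must be
#' nonnegative; if the tissue table contains negative (log-scale) values
#' the whole table is shifted by its minimum, with a message. Multiple
#' rows (transcripts) per gene are averaged after computing tau.
#'
#' @inheritParams screen_genes
#' @param tissue_table Optional tibble: `gene_id` plus one numeric column
#'   per tissue (at least 2 tissues).
#' @return Tibble `gene_id`, `e_bar`, `tau` (`tau` `NA` without a tissue
#'   table or for all-zero tissue vectors).
#' @export
expression_covariates <- function(data, tissue_table = NULL) {
  check_expression_data(data)
  eb <- data |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(e_bar = mean(.data$value), .groups = "drop")
  if (is.null(tissue_table)) {
    return(dplyr::mutate(eb, tau = NA_real_))
  }
  tt <- tibble::as_tibble(tissue_table)
  num_cols <- setdiff(names(tt), "gene_id")
  if (length(num_cols) < 2) {
    stop("`tissue_table` needs at least 2 tissue columns.")
  }
  X <- as.matrix(tt[num_cols])
  if (min(X, na.rm = TRUE) < 0) {
    X <- X - min(X, na.rm = TRUE)
    message("Negative tissue intensities shifted by the table minimum.")
  }
  mx <- apply(X, 1, max)
  tau_row <- ifelse(mx > 0,
                    rowSums(1 - X / mx) / (ncol(X) - 1),
                    NA_real_)
  tau_tbl <- tibble::tibble(gene_id = tt$gene_id, tau_row = tau_row) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(tau = mean(.data$tau_row), .groups = "drop")
  dplyr::left_join(eb, tau_tbl, by = "gene_id")
}

#' Dimorphism transformation for regression
#'
#' `log10(|D| + 0.01)`: compresses the long right tail of |D| while the
#' 0.01 offset keeps near-zero values from creating a left tail. Monotone
#' in |D|, with minimum -2 at D = 0.
#'
#' @param D Numeric dimorphism values (log2 male:female ratios).
#' @return Transformed values.
#' @examples
#' transform_dimorphism(c(0, 0.99, -1.5))
#' @export
transform_dimorphism <- function(D) {
  stopifnot(all(is.finite(D)))
  log10(abs(D) + 0.01)
}

#' Full per-gene genetic summary table
#'
#' Runs the gene-wise pipeline: screen for genetic variance, line means
#' of the retained genes, dimorphism and bias class, per-gene genetic
#' parameters, aggregate cross-gene correlation statistics, expression
#' level and tissue specificity, and the transformed dimorphism.
#'
#' @inheritParams screen_genes
#' @inheritParams expression_covariates
#' @return Tibble with one row per retained gene and columns `gene_id`,
#'   `p_value`, `D`, `bias_class`, `m`, `f`, `b`, `r_mf`, `g_bar`, `d`,
#'   `rw_bar`, `rb_bar`, `abs_rdw`, `abs_rdb`, `e_bar`, `tau`,
#'   `log10_D_abs` (the transformed dimorphism).
#' @export
gene_summaries <- function(data, tissue_table = NULL, alpha = 0.01) {
  scr <- screen_genes(data, alpha = alpha)
  keep <- scr$gene_id[!is.na(scr$retained) & scr$retained]
  if (length(keep) == 0) stop("No genes passed the screen.")
  lm_tbl <- line_means(data, genes = keep)
  dim_tbl <- gene_dimorphism(lm_tbl)
  gen_tbl <- gene_genetics(lm_tbl)
  agg_tbl <- aggregate_correlations(lm_tbl)
  cov_tbl <- expression_covariates(
    dplyr::filter(data, .data$gene_id %in% keep), tissue_table
  )
  scr |>
    dplyr::filter(.data$gene_id %in% keep) |>
    dplyr::select("gene_id", "p_value") |>
    dplyr::inner_join(dim_tbl, by = "gene_id") |>
    dplyr::inner_join(dplyr::select(gen_tbl, -"n_lines"), by = "gene_id") |>
    dplyr::left_join(agg_tbl, by = "gene_id") |>
    dplyr::left_join(cov_tbl, by = "gene_id") |>
    dplyr::mutate(log10_D_abs = transform_dimorphism(.data$D))
}

# Input contract shared by the gene-wise functions.
check_expression_data <- function(data) {
  req <- c("gene_id", "line", "sex", "rep", "value")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("Expression data lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(data$sex %in% c("M", "F"))) stop("`sex` must be 'M' or 'F'.")
  if (!all(is.finite(data$value))) stop("Expression values must be finite.")
  invisible(data)
}
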