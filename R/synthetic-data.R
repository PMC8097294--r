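#' Scenario configurations for synthetic expression panels
#'
#' Returns a configuration for [simulate_expression_panel()] emulating an
#' inbred-line microarray design: by default 40 lines, 2 sexes, 2
#' replicates, and genes in three sex-bias classes (male-biased,
#' female-biased, relatively unbiased) with per-gene sex-specific genetic
#' variances (m, f), cross-sex covariance b, a low-rank cross-gene factor
#' structure, and i.i.d. Gaussian replicate noise.
#'
#' Named scenarios:
#' \describe{
#'   \item{`table2_like`}{Eight latent factors defining 2 male-only, 2
#'     female-only and 4 shared expression traits. Within each of the four
#'     shared (UB) factor blocks the female gene-level structure is
#'     proportional to the male structure, so the implied trait-level
#'     intersexual correlations are exactly the four cross-sex factor
#'     correlations (0.90, 0.86, 0.80, 0.72; mean 0.82), with unequal sex
#'     variances and a small asymmetric cross-block coupling making B
#'     asymmetric.}
#'   \item{`null`}{No genetic variance anywhere; calibrates the screen.}
#'   \item{`sas_architecture`}{Dimorphism concentrated in low-rMF genes
#'     (the signature of sexually antagonistic selection).}
#'   \item{`scs_architecture`}{Dimorphism concentrated in genes with
#'     unequal male/female variances (the signature of sexually
#'     concordant selection).}
#' }
#'
#' @param name Scenario name.
#' @param n_lines,n_reps Panel design.
#' @param gene_scale Multiplier on the default per-class gene counts
#'   (MB 150, FB 200, UB 700), useful for quick tests.
#' @return A `synth_config` list, documented fields throughout.
#' @examples
#' cfg <- scenario_config("null", gene_scale = 0.1)
#' @export
scenario_config <- function(name = c("table2_like", "null",
                                     "sas_architecture", "scs_architecture"),
                            n_lines = 40, n_reps = 2, gene_scale = 1) {
  name <- match.arg(name)
  n_mb <- max(round(150 * gene_scale), 4)
  n_fb <- max(round(200 * gene_scale), 4)
  n_ub <- max(round(700 * gene_scale), 8)
  base_class <- function(n_genes, d_mean, d_sd) {
    list(
      n_genes = n_genes, d_mean = d_mean, d_sd = d_sd,
      m_meanlog = log(0.15), m_sdlog = 0.7,
      f_log_ratio_sd = 0.6, r_mf_mean = 0.6, r_mf_sd = 0.25,
      frac_factor = 0.3, factors = integer(0),
      proportional = FALSE, d_link = "none", d_scale = 0
    )
  }
  cfg <- list(
    name = name, n_lines = n_lines, n_reps = n_reps,
    sigma2_e = 0.05, mu_mean = 6, mu_sd = 1.5,
    factor_rho = numeric(0), factor_c = numeric(0),
    factor_cross_eps = 0,
    classes = list(
      MB = base_class(n_mb, 1.6, 0.3),
      FB = base_class(n_fb, -1.6, 0.3),
      UB = base_class(n_ub, 0, 0.35)
    )
  )
  if (name == "null") {
    for (cl in names(cfg$classes)) {
      cfg$classes[[cl]]$m_meanlog <- -Inf   # zero genetic variance
      cfg$classes[[cl]]$frac_factor <- 0
    }
  } else if (name == "table2_like") {
    # factors 1-4: shared (UB) blocks; 5-6 male-only (MB); 7-8 female-only (FB)
    cfg$factor_rho <- c(0.90, 0.86, 0.80, 0.72, 0, 0, 0, 0)
    cfg$factor_c <- c(0.75, 1.25, 0.60, 1.40, 0.15, 0.15, 4.0, 4.0)
    cfg$factor_cross_eps <- 0.04
    cfg$classes$UB$factors <- 1:4
    cfg$classes$UB$proportional <- TRUE
    cfg$classes$UB$frac_factor <- 0.6
    cfg$classes$MB$factors <- 5:6
    cfg$classes$MB$proportional <- TRUE
    cfg$classes$MB$frac_factor <- 0.6
    cfg$classes$FB$factors <- 7:8
    cfg$classes$FB$proportional <- TRUE
    cfg$classes$FB$frac_factor <- 0.6
  } else if (name == "sas_architecture") {
    for (cl in names(cfg$classes)) {
      cfg$classes[[cl]]$r_mf_mean <- 0.5
      cfg$classes[[cl]]$r_mf_sd <- 0.35
      cfg$classes[[cl]]$f_log_ratio_sd <- 0.15
      cfg$classes[[cl]]$d_link <- "rmf"
      cfg$classes[[cl]]$d_scale <- 1.5
      cfg$classes[[cl]]$d_sd <- 0.1
    }
  } else if (name == "scs_architecture") {
    for (cl in names(cfg$classes)) {
      cfg$classes[[cl]]$r_mf_mean <- 0.8
      cfg$classes[[cl]]$r_mf_sd <- 0.1
      cfg$classes[[cl]]$f_log_ratio_sd <- 1.0
      cfg$classes[[cl]]$d_link <- "asym"
      cfg$classes[[cl]]$d_scale <- 2.5
      cfg$classes[[cl]]$d_sd <- 0.1
    }
  }
  structure(cfg, class = "synth_config")
}

#' Simulate an inbred-line expression panel with known genetic architecture
#'
#' Generates log2 expression values
#' `y = mu_g + (sex == M ? +D/2 : -D/2) + a_{gls} + e` where the line
#' genetic value `a` combines shared line-level factors (with sex-specific
#' gene loadings and cross-sex factor correlations) and per-gene
#' idiosyncratic effects with planted (m, f, b), and `e` is i.i.d.
#' Gaussian replicate noise. Per-gene sample moments match the planted
#' values in expectation; output is reproducible under `seed`.
#'
#' @param config A `synth_config` from [scenario_config()].
#' @param seed Integer seed; required for reproducibility.
#' @return List with `data` (long tibble: `gene_id`, `line`, `sex`, `rep`,
#'   `value`) and `truth` (a `synth_truth`: per-gene planted parameters,
#'   loadings, factor cross-sex correlation matrix, noise variance).
#' @examples
#' sim <- simulate_expression_panel(scenario_config("null", gene_scale = 0.05),
#'                                  seed = 1)
#' head(sim$data)
#' @export
simulate_expression_panel <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"))
  if (missing(seed)) stop("`seed` is required.")
  set.seed(seed)
  genes <- draw_gene_params(config)
  K <- max(length(config$factor_rho), 1L)
  P <- factor_cross_matrix(config, K)
  L <- config$n_lines
  R <- config$n_reps
  G <- nrow(genes)

  # line-level factor scores: 2K-dim normal, Omega = [I P; P' I]
  Omega <- rbind(cbind(diag(K), P), cbind(t(P), diag(K)))
  ch <- tryCatch(chol(Omega), error = function(e)
    stop("Factor cross-sex correlation structure is not PSD."))
  eta <- matrix(stats::rnorm(L * 2 * K), L, 2 * K) %*% ch
  eta_m <- t(eta[, seq_len(K), drop = FALSE])          # K x L
  eta_f <- t(eta[, K + seq_len(K), drop = FALSE])

  # idiosyncratic line effects: per-gene 2x2 Cholesky, vectorized
  a11 <- sqrt(genes$m_idio)
  c1 <- ifelse(a11 > 0, genes$b_idio / a11, 0)
  c2 <- sqrt(pmax(genes$f_idio - c1^2, 0))
  z1 <- matrix(stats::rnorm(G * L), G, L)
  z2 <- matrix(stats::rnorm(G * L), G, L)
  idio_m <- a11 * z1
  idio_f <- c1 * z1 + c2 * z2

  fac_idx <- ifelse(is.na(genes$factor), 1L, genes$factor)
  a_m <- genes$lam_m * eta_m[fac_idx, , drop = FALSE] + idio_m
  a_f <- genes$lam_f * eta_f[fac_idx, , drop = FALSE] + idio_f

  line_ids <- sprintf("L%02d", seq_len(L))
  blocks <- vector("list", 2 * R)
  k <- 0
  for (sx in c("M", "F")) {
    a <- if (sx == "M") a_m else a_f
    mu_sex <- genes$mu + ifelse(sx == "M", 1, -1) * genes$d_true / 2
    for (r in seq_len(R)) {
      k <- k + 1
      vals <- mu_sex + a +
        matrix(stats::rnorm(G * L, sd = sqrt(config$sigma2_e)), G, L)
      blocks[[k]] <- tibble::tibble(
        gene_id = rep(genes$gene_id, times = L),
        line = rep(line_ids, each = G),
        sex = sx, rep = r,
        value = as.vector(vals)
      )
    }
  }
  truth <- structure(list(
    genes = genes, factor_cross = P, sigma2_e = config$sigma2_e,
    n_lines = L, n_reps = R, seed = seed, config = config
  ), class = "synth_truth")
  list(data = dplyr::bind_rows(blocks), truth = truth)
}

# Per-gene planted parameters for all classes.
draw_gene_params <- function(config) {
  rho <- config$factor_rho
  cc <- config$factor_c
  purrr::imap_dfr(config$classes, function(cl, cl_name) {
    n <- cl$n_genes
    mu <- stats::rnorm(n, config$mu_mean, config$mu_sd)
    m <- if (is.finite(cl$m_meanlog)) {
      stats::rlnorm(n, cl$m_meanlog, cl$m_sdlog)
    } else {
      rep(0, n)
    }
    phi <- if (length(cl$factors)) cl$frac_factor else 0
    fac <- if (length(cl$factors)) {
      sample(rep_len(cl$factors, n))
    } else {
      rep(NA_integer_, n)
    }
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    if (isTRUE(cl$proportional)) {
      c_k <- cc[fac]
      rho_k <- rho[fac]
      f <- c_k^2 * m
      r_mf <- rho_k
      lam_m <- sgn * sqrt(phi * m)
      lam_f <- c_k * lam_m
      m_idio <- (1 - phi) * m
      f_idio <- c_k^2 * m_idio
      b_idio <- rho_k * c_k * m_idio
      b <- r_mf * sqrt(m * f)
    } else {
      f <- m * exp(stats::rnorm(n, 0, cl$f_log_ratio_sd))
      r_mf <- pmin(pmax(stats::rnorm(n, cl$r_mf_mean, cl$r_mf_sd),
                        -0.99), 0.99)
      b <- r_mf * sqrt(m * f)
      lam_m <- sgn * sqrt(phi * m)
      lam_f <- sgn * sqrt(phi * f)
      m_idio <- (1 - phi) * m
      f_idio <- (1 - phi) * f
      b_fac <- if (length(cl$factors)) {
        diag_rho <- if (length(rho)) rho[fac] else 0
        diag_rho * lam_m * lam_f
      } else {
        0
      }
      lim <- 0.999 * sqrt(m_idio * f_idio)
      b_idio <- pmin(pmax(b - b_fac, -lim), lim)
      b <- b_fac + b_idio    # planted covariance after feasibility clipping
      r_mf <- ifelse(m > 0 & f > 0, b / sqrt(m * f), NA_real_)
    }
    d_true <- switch(cl$d_link,
      none = stats::rnorm(n, cl$d_mean, cl$d_sd),
      rmf = sign(stats::rnorm(n, cl$d_mean + 0.01, 1)) *
        pmax(cl$d_scale * (1 - r_mf), 0) + stats::rnorm(n, 0, cl$d_sd),
      asym = sign(stats::rnorm(n, cl$d_mean + 0.01, 1)) *
        cl$d_scale * sqrt(abs(m - f)) + stats::rnorm(n, 0, cl$d_sd)
    )
    if (cl$d_link == "none" && cl_name == "MB") d_true <- pmax(d_true, 1.05)
    if (cl$d_link == "none" && cl_name == "FB") d_true <- pmin(d_true, -1.05)
    tibble::tibble(
      gene_id = sprintf("%s_%04d", cl_name, seq_len(n)),
      class = cl_name, mu = mu, d_true = d_true,
      m = m, f = f, b = b, r_mf = r_mf,
      factor = fac, lam_m = lam_m, lam_f = lam_f,
      m_idio = m_idio, f_idio = f_idio, b_idio = b_idio
    )
  })
}

# K x K matrix of cor(eta_k^M, eta_k'^F): planted rho on the diagonal and
# a small asymmetric off-diagonal coupling (B asymmetry source).
factor_cross_matrix <- function(config, K) {
  rho <- rep(0, K)
  rho[seq_along(config$factor_rho)] <- config$factor_rho
  P <- diag(rho, K)
  eps <- config$factor_cross_eps
  if (eps != 0 && K > 1) {
    for (i in seq_len(K - 1)) {
      P[i, i + 1] <- eps
      P[i + 1, i] <- -eps / 2
    }
  }
  P
}

#' Analytic trait-level G implied by the planted architecture
#'
#' For trait loadings `W` over the simulated genes, the gene-level genetic
#' covariance structure implies the trait-level sexed covariance matrix
#' exactly: `G_M = W' C_M W` with `C_M = Lambda_M Lambda_M' +
#' diag(m_idio)` (similarly for females) and cross-sex block
#' `W' (Lambda_M P Lambda_F' + diag(b_idio)) W`. Used as ground truth for
#' G-estimation recovery tests.
#'
#' @param truth A `synth_truth` from [simulate_expression_panel()].
#' @param loadings Matrix (genes x traits) with rownames matching
#'   `truth$genes$gene_id`, or `NULL` to use the normalized factor
#'   loadings (one trait per latent factor, see
#'   [factor_trait_loadings()]).
#' @param trait_sex Character vector per trait: `"both"`, `"M"` or `"F"`.
#'   Defaults to `"both"` for every trait, except with `loadings = NULL`
#'   where sex-limited factors (zero loading scale in one sex... detected
#'   by the factor's class) keep only their expressed sex.
#' @return A `sexed_g` over the traits.
#' @export
implied_trait_g <- function(truth, loadings = NULL, trait_sex = NULL) {
  stopifnot(inherits(truth, "synth_truth"))
  g <- truth$genes
  if (is.null(loadings)) {
    loadings <- factor_trait_loadings(truth)
    if (is.null(trait_sex)) {
      cls <- g$class[match(colnames(loadings), paste0("T", g$factor))]
      # factor blocks inherit the sex of their class
      fac_class <- vapply(colnames(loadings), function(tn) {
        k <- as.integer(sub("^T", "", tn))
        unique(g$class[!is.na(g$factor) & g$factor == k])[1]
      }, character(1))
      trait_sex <- dplyr::case_when(
        fac_class == "MB" ~ "M", fac_class == "FB" ~ "F", TRUE ~ "both"
      )
    }
  }
  W <- as.matrix(loadings)
  if (is.null(rownames(W))) {
    if (nrow(W) != nrow(g)) stop("`loadings` rows must map to genes.")
    rownames(W) <- g$gene_id
  }
  idx <- match(rownames(W), g$gene_id)
  if (anyNA(idx)) stop("Unknown gene ids in `loadings` rownames.")
  gg <- g[idx, ]
  K <- nrow(truth$factor_cross)
  Lam_m <- matrix(0, nrow(gg), K)
  Lam_f <- matrix(0, nrow(gg), K)
  has_fac <- !is.na(gg$factor)
  Lam_m[cbind(which(has_fac), gg$factor[has_fac])] <- gg$lam_m[has_fac]
  Lam_f[cbind(which(has_fac), gg$factor[has_fac])] <- gg$lam_f[has_fac]
  LmW <- crossprod(Lam_m, W)   # K x T
  LfW <- crossprod(Lam_f, W)
  G_M <- crossprod(LmW) + t(W) %*% (gg$m_idio * W)
  G_F <- crossprod(LfW) + t(W) %*% (gg$f_idio * W)
  B_full <- t(LmW) %*% truth$factor_cross %*% LfW +
    t(W) %*% (gg$b_idio * W)
  trait_names <- colnames(W)
  if (is.null(trait_names)) trait_names <- paste0("T", seq_len(ncol(W)))
  if (is.null(trait_sex)) trait_sex <- rep("both", ncol(W))
  stopifnot(length(trait_sex) == ncol(W))
  ord <- order(trait_sex != "both")   # shared traits first
  trait_names <- trait_names[ord]
  trait_sex <- trait_sex[ord]
  G_M <- G_M[ord, ord, drop = FALSE]
  G_F <- G_F[ord, ord, drop = FALSE]
  B_full <- B_full[ord, ord, drop = FALSE]
  im <- which(trait_sex %in% c("both", "M"))
  i_f <- which(trait_sex %in% c("both", "F"))
  assemble_sexed_g(
    G_M = G_M[im, im, drop = FALSE],
    G_F = G_F[i_f, i_f, drop = FALSE],
    B = B_full[im, i_f, drop = FALSE],
    male_traits = trait_names[im],
    female_traits = trait_names[i_f]
  )
}

#' @rdname implied_trait_g
#' @param normalize Scale each factor's male loading vector to unit norm.
#' @return For `factor_trait_loadings()`: genes x factors matrix of male
#'   loading directions (columns `T1`, `T2`, ...).
#' @export
factor_trait_loadings <- function(truth, normalize = TRUE) {
  g <- truth$genes
  K <- nrow(truth$factor_cross)
  W <- matrix(0, nrow(g), K, dimnames = list(g$gene_id, paste0("T", 1:K)))
  has_fac <- !is.na(g$factor)
  W[cbind(which(has_fac), g$factor[has_fac])] <- g$lam_m[has_fac]
  # sex-limited factors have negligible male loadings for FB; use the
  # female loadings as the direction there
  for (k in seq_len(K)) {
    if (sum(W[, k]^2) == 0) {
      sel <- has_fac & g$factor == k
      W[sel, k] <- g$lam_f[sel]
    }
  }
  keep <- colSums(W^2) > 0
  W <- W[, keep, drop = FALSE]
  if (normalize) W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  W
}
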