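#' Sex-specific genetic covariance matrices
#'
#' A `sexed_g` object stores the full genetic covariance matrix over
#' (trait, sex)-labelled variables: the within-sex blocks `G_M` and `G_F`
#' and the cross-sex block `B`. Traits may be expressed in one sex only
#' (for example male-biased expression traits measured only in males);
#' traits present under both sexes are the *shared* traits, and the `B`
#' block proper is the cross-sex block restricted to them. Variables are
#' ordered male block first (shared traits, then male-only), female block
#' second (shared, then female-only). `B` is oriented rows = male
#' variables, columns = female variables, so `B[i, j]` is the genetic
#' covariance of trait i expressed in males with trait j expressed in
#' females.
#'
#' @param G_M,G_F Within-sex genetic covariance matrices, over all male
#'   (resp. female) variables, shared traits first.
#' @param B Cross-sex covariance block, rows male, columns female. Either
#'   a shared x shared matrix (remaining cross-sex covariances set to 0) or
#'   the full male x female block. `NULL` means all zero.
#' @param male_traits,female_traits Character vectors of trait labels for
#'   each sex. Shared traits are those present in both and must come first
#'   in each vector.
#' @param is_correlation Logical; `TRUE` when the matrix stores genetic
#'   correlations (unit diagonal) rather than covariances.
#' @param validate Check symmetry and positive semi-definiteness.
#'
#' @return A `sexed_g` object: list with elements `cov` (labelled matrix),
#'   `variables` (tibble with columns `trait`, `sex`) and `is_correlation`.
#' @examples
#' g <- assemble_sexed_g(matrix(1), matrix(1), matrix(0.8), "t1", "t1")
#' extract_blocks(g)$B
#' @export
assemble_sexed_g <- function(G_M, G_F, B = NULL, male_traits, female_traits,
                             is_correlation = FALSE, validate = TRUE) {
  G_M <- as.matrix(G_M)
  G_F <- as.matrix(G_F)
  nm <- length(male_traits)
  nf <- length(female_traits)
  if (!all(dim(G_M) == c(nm, nm))) {
    stop("`G_M` must be ", nm, " x ", nm, " to match `male_traits`.")
  }
  if (!all(dim(G_F) == c(nf, nf))) {
    stop("`G_F` must be ", nf, " x ", nf, " to match `female_traits`.")
  }
  shared <- intersect(male_traits, female_traits)
  if (!identical(male_traits[seq_along(shared)], shared) ||
      !identical(female_traits[seq_along(shared)], shared)) {
    stop("Shared traits must come first, in the same order, in both ",
         "`male_traits` and `female_traits`.")
  }
  cross <- matrix(0, nm, nf)
  if (!is.null(B)) {
    B <- as.matrix(B)
    ns <- length(shared)
    if (all(dim(B) == c(ns, ns))) {
      cross[seq_len(ns), seq_len(ns)] <- B
    } else if (all(dim(B) == c(nm, nf))) {
      cross <- B
    } else {
      stop("`B` must be shared x shared (", ns, " x ", ns, ") or the full ",
           "male x female block (", nm, " x ", nf, ").")
    }
  }
  cov <- rbind(cbind(G_M, cross), cbind(t(cross), G_F))
  variables <- tibble::tibble(
    trait = c(male_traits, female_traits),
    sex = rep(c("M", "F"), c(nm, nf))
  )
  new_sexed_g(cov, variables, is_correlation = is_correlation,
              validate = validate)
}

#' @rdname assemble_sexed_g
#' @param cov Full square covariance matrix over the sexed variables.
#' @param variables Data frame with columns `trait` and `sex` (one row per
#'   variable of `cov`, male block first).
#' @export
new_sexed_g <- function(cov, variables, is_correlation = FALSE,
                        validate = TRUE) {
  cov <- as.matrix(cov)
  variables <- tibble::as_tibble(variables)
  stopifnot(all(c("trait", "sex") %in% names(variables)))
  if (nrow(variables) != nrow(cov) || nrow(cov) != ncol(cov)) {
    stop("`cov` must be square with one row per variable.")
  }
  if (!all(variables$sex %in% c("M", "F"))) {
    stop("`sex` must be 'M' or 'F'.")
  }
  key <- paste(variables$trait, variables$sex, sep = ":")
  if (anyDuplicated(key)) stop("(trait, sex) pairs must be unique.")
  dimnames(cov) <- list(key, key)
  x <- structure(
    list(cov = cov, variables = variables, is_correlation = is_correlation),
    class = "sexed_g"
  )
  if (validate) validate_sexed_g(x)
  x
}

#' Validate a sexed G matrix
#'
#' Checks symmetry (relative tolerance 1e-10), positive semi-definiteness
#' (smallest eigenvalue no less than `-psd_tol` times the largest), and the
#' unit diagonal for correlation matrices.
#'
#' @param x A `sexed_g` object.
#' @param psd_tol Relative eigenvalue tolerance for the PSD check.
#' @param warn_only Report PSD violations as warnings instead of errors
#'   (used after `sym_B` modifications, which can make the full matrix
#'   indefinite even though predictions from it remain meaningful).
#' @return `x`, invisibly.
#' @export
validate_sexed_g <- function(x, psd_tol = 1e-8, warn_only = FALSE) {
  cov <- x$cov
  scale <- max(abs(cov), 1e-300)
  if (max(abs(cov - t(cov))) > 1e-10 * scale) {
    stop("Covariance matrix is not symmetric (relative tolerance 1e-10).")
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(ev, 0)
  if (min(ev) < -psd_tol * max(lam_max, 1e-300)) {
    msg <- sprintf(
      "Matrix is not positive semi-definite: smallest eigenvalue %.3e (largest %.3e).",
      min(ev), lam_max
    )
    if (warn_only) warning(msg) else stop(msg)
  }
  if (isTRUE(x$is_correlation) && max(abs(diag(cov) - 1)) > 1e-8) {
    stop("Correlation matrix must have a unit diagonal.")
  }
  invisible(x)
}

#' @export
print.sexed_g <- function(x, ...) {
  ns <- length(shared_traits(x))
  cat(sprintf(
    "<sexed_g> %d variables (%d male, %d female; %d shared traits)%s\n",
    nrow(x$variables), sum(x$variables$sex == "M"),
    sum(x$variables$sex == "F"), ns,
    if (isTRUE(x$is_correlation)) ", correlations" else ""
  ))
  print(round(x$cov, 4))
  invisible(x)
}

#' Shared traits of a sexed G matrix
#'
#' @param g A `sexed_g` object.
#' @return Character vector of trait labels present under both sexes.
#' @export
shared_traits <- function(g) {
  v <- g$variables
  intersect(v$trait[v$sex == "M"], v$trait[v$sex == "F"])
}

#' Extract the G_M, G_F and B blocks
#'
#' @param g A `sexed_g` object.
#' @return A list with `G_M` and `G_F` (within-sex blocks over all male /
#'   female variables), `B` (cross-sex block restricted to shared traits,
#'   rows male, columns female), `cross` (full male x female block), and
#'   `shared` (shared trait labels). `assemble_sexed_g()` on `G_M`, `G_F`
#'   and `cross` reproduces the input exactly.
#' @export
extract_blocks <- function(g) {
  v <- g$variables
  im <- which(v$sex == "M")
  i_f <- which(v$sex == "F")
  shared <- shared_traits(g)
  cross <- g$cov[im, i_f, drop = FALSE]
  ism <- im[match(shared, v$trait[im])]
  isf <- i_f[match(shared, v$trait[i_f])]
  list(
    G_M = g$cov[im, im, drop = FALSE],
    G_F = g$cov[i_f, i_f, drop = FALSE],
    B = g$cov[ism, isf, drop = FALSE],
    cross = cross,
    shared = shared,
    male_traits = v$trait[im],
    female_traits = v$trait[i_f]
  )
}

#' Modified G matrices for symmetry experiments
#'
#' Forms the modified matrices used to ask which asymmetries of `G` drive
#' the evolution of dimorphism: substituting the sex-averaged within-sex
#' block Gbar = (G_M + G_F)/2 for both `G_M` and `G_F` (shared traits),
#' the symmetric part B_S = (B + B^T)/2 for `B`, the zero matrix for `B`,
#' or combinations. Under antagonistic selection the dimorphism response
#' depends only on Gbar and B_S, so `avg_G`/`sym_B` leave it unchanged;
#' under concordant selection the joint Gbar + B_S substitution removes
#' every source of dimorphism response.
#'
#' @param g A `sexed_g` object with at least one shared trait.
#' @param mode One of `"none"`, `"avg_G"`, `"sym_B"`, `"zero_B"`,
#'   `"avg_G_sym_B"`, `"avg_G_zero_B"`.
#' @return The modified `sexed_g`. Substitutions can make the full matrix
#'   indefinite; validation then warns rather than errors, because the
#'   predictions from the modified matrices are the point of the exercise.
#' @examples
#' g <- assemble_sexed_g(matrix(2), matrix(1), matrix(0.5), "t", "t")
#' extract_blocks(apply_modification(g, "avg_G"))$G_M
#' @export
apply_modification <- function(g, mode = c("none", "avg_G", "sym_B", "zero_B",
                                           "avg_G_sym_B", "avg_G_zero_B")) {
  mode <- match.arg(mode)
  if (mode == "none") return(g)
  v <- g$variables
  shared <- shared_traits(g)
  if (length(shared) == 0) {
    stop("Matrix modification requires at least one shared trait.")
  }
  ism <- which(v$sex == "M" & v$trait %in% shared)
  isf <- which(v$sex == "F" & v$trait %in% shared)
  ism <- ism[match(shared, v$trait[ism])]
  isf <- isf[match(shared, v$trait[isf])]
  cov <- g$cov
  if (mode %in% c("avg_G", "avg_G_sym_B", "avg_G_zero_B")) {
    gbar <- (cov[ism, ism, drop = FALSE] + cov[isf, isf, drop = FALSE]) / 2
    cov[ism, ism] <- gbar
    cov[isf, isf] <- gbar
  }
  if (mode %in% c("sym_B", "avg_G_sym_B")) {
    b <- cov[ism, isf, drop = FALSE]
    bs <- (b + t(b)) / 2
    cov[ism, isf] <- bs
    cov[isf, ism] <- t(bs)
  }
  if (mode %in% c("zero_B", "avg_G_zero_B")) {
    cov[ism, isf] <- 0
    cov[isf, ism] <- 0
  }
  out <- structure(
    list(cov = cov, variables = v, is_correlation = g$is_correlation),
    class = "sexed_g"
  )
  # substituted matrices are artificial constructs and need not stay PSD
  # (e.g. averaging the within-sex blocks against an asymmetric B, or
  # against sex-limited traits); predictions from them are still the
  # point of the exercise, so violations warn rather than error
  validate_sexed_g(out, warn_only = TRUE)
  out
}

#' Intersexual genetic correlations of the shared traits
#'
#' The diagonal of `B` scaled by the sex-specific variances:
#' rMF = b / sqrt(m * f) per shared trait.
#'
#' @param g A `sexed_g` object.
#' @return Tibble with columns `trait`, `m`, `f`, `b`, `r_mf`.
#' @export
r_mf_table <- function(g) {
  bl <- extract_blocks(g)
  shared <- bl$shared
  m <- diag(bl$G_M)[match(shared, bl$male_traits)]
  f <- diag(bl$G_F)[match(shared, bl$female_traits)]
  b <- diag(bl$B)
  tibble::tibble(
    trait = shared, m = unname(m), f = unname(f), b = unname(b),
    r_mf = ifelse(m > 0 & f > 0, b / sqrt(m * f), NA_real_)
  )
}

#' Bend a matrix to positive semi-definiteness
#'
#' Clips negative eigenvalues to zero and rescales so the trace is
#' preserved. Off by default everywhere; offered as a repair utility for
#' estimated matrices.
#'
#' @param g A `sexed_g` object (validation skipped on input).
#' @return A PSD `sexed_g`.
#' @export
bend_sexed_g <- function(g) {
  e <- eigen((g$cov + t(g$cov)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  tr_old <- sum(diag(g$cov))
  cov <- e$vectors %*% (lam * t(e$vectors))
  if (tr_old > 0 && sum(lam) > 0) cov <- cov * (tr_old / sum(lam))
  cov <- (cov + t(cov)) / 2
  new_sexed_g(cov, g$variables, is_correlation = FALSE, validate = FALSE)
}

#' Random valid sexed G matrices
#'
#' Draws a positive-definite covariance matrix over the requested layout
#' (Wishart-style construction), useful for property checks and the
#' symmetrization experiments, which hold for *any* valid matrix.
#'
#' @param n_shared Number of traits expressed in both sexes.
#' @param n_male_only,n_female_only Numbers of sex-limited traits.
#' @param scale Average variance scale.
#' @return A `sexed_g` object.
#' @export
rand_sexed_g <- function(n_shared = 4, n_male_only = 0, n_female_only = 0,
                         scale = 1) {
  p <- 2 * n_shared + n_male_only + n_female_only
  X <- matrix(stats::rnorm((p + 4) * p), p + 4, p)
  cov <- crossprod(X) / (p + 4) * scale
  shared <- paste0("UB", seq_len(n_shared))
  male <- c(shared, if (n_male_only) paste0("MB", seq_len(n_male_only)))
  female <- c(shared, if (n_female_only) paste0("FB", seq_len(n_female_only)))
  variables <- tibble::tibble(
    trait = c(male, female),
    sex = rep(c("M", "F"), c(length(male), length(female)))
  )
  new_sexed_g(cov, variables)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sexed G matrix into long form
#'
#' @param x A `sexed_g` object.
#' @param ... Unused.
#' @return Tibble with one row per matrix cell: `row_trait`, `row_sex`,
#'   `col_trait`, `col_sex`, `value` and `block` (`"G_M"`, `"G_F"`,
#'   `"B"` for male-row cross-sex cells, `"B_t"` for their transposes).
#' @export
tidy.sexed_g <- function(x, ...) {
  v <- x$variables
  n <- nrow(v)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  tibble::tibble(
    row_trait = v$trait[idx$i], row_sex = v$sex[idx$i],
    col_trait = v$trait[idx$j], col_sex = v$sex[idx$j],
    value = x$cov[cbind(idx$i, idx$j)],
    block = dplyr::case_when(
      v$sex[idx$i] == "M" & v$sex[idx$j] == "M" ~ "G_M",
      v$sex[idx$i] == "F" & v$sex[idx$j] == "F" ~ "G_F",
      v$sex[idx$i] == "M" ~ "B",
      TRUE ~ "B_t"
    )
  )
}

#' Heatmap of a sexed G matrix
#'
#' @param object A `sexed_g` object.
#' @param ... Unused.
#' @return A ggplot object showing the covariance (or correlation) cells,
#'   with variables ordered male block first.
#' @export
autoplot.sexed_g <- function(object, ...) {
  td <- tidy.sexed_g(object)
  key_levels <- paste(object$variables$trait, object$variables$sex, sep = ":")
  td$row <- factor(paste(td$row_trait, td$row_sex, sep = ":"),
                   levels = rev(key_levels))
  td$col <- factor(paste(td$col_trait, td$col_sex, sep = ":"),
                   levels = key_levels)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(
      x = NULL, y = NULL,
      fill = if (isTRUE(object$is_correlation)) "r" else "cov",
      title = "Sex-specific genetic covariance matrix"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
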