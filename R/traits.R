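#' Principal components within a sex-bias class
#'
#' Covariance-matrix PCA (column-centered, not variance-standardized) of
#' least-squares line means for a set of genes. For relatively unbiased
#' genes the observations are the pooled line-sex mean vectors (2 rows per
#' line), giving one shared loading set scored in both sexes; for biased
#' classes the observations are the dominant-sex line means only.
#' Components are oriented so the largest-magnitude loading is positive.
#'
#' @param lm_tbl Line means from [line_means()].
#' @param genes Gene ids of the class.
#' @param n_components Number of components to keep.
#' @param obs Observation set: `"pooled"` (line-sex rows, both sexes),
#'   `"M"` or `"F"` (dominant-sex line means), or `"averaged"`
#'   (sex-averaged line means, one row per line).
#' @return List with `loadings` (genes x k, orthonormal), `centers`
#'   (per-gene observation means), `scores` (tibble of observation
#'   scores), `var_explained` (per component), `total_var` (trace of the
#'   observation covariance matrix).
#' @export
class_pca <- function(lm_tbl, genes, n_components,
                      obs = c("pooled", "M", "F", "averaged")) {
  obs <- match.arg(obs)
  wide <- lm_tbl |>
    dplyr::filter(.data$gene_id %in% genes) |>
    tidyr::pivot_wider(id_cols = c("line", "sex"), names_from = "gene_id",
                       values_from = "ls_mean")
  gene_cols <- setdiff(names(wide), c("line", "sex"))
  X <- switch(obs,
    pooled = wide,
    M = dplyr::filter(wide, .data$sex == "M"),
    F = dplyr::filter(wide, .data$sex == "F"),
    averaged = wide |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(gene_cols), mean),
                       .groups = "drop") |>
      dplyr::mutate(sex = "avg")
  )
  mat <- as.matrix(X[gene_cols])
  if (anyNA(mat)) stop("Missing line means in the PCA observation set.")
  if (n_components > min(dim(mat) - c(1, 0))) {
    stop("`n_components` exceeds the available rank.")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(mat, 2, pc$center) %*% load
  score_tbl <- tibble::as_tibble(scores)
  names(score_tbl) <- paste0("PC", seq_len(n_components))
  score_tbl <- dplyr::bind_cols(
    tibble::tibble(line = X$line,
                   sex = if ("sex" %in% names(X)) X$sex else "avg"),
    score_tbl
  )
  list(
    loadings = load, centers = pc$center, scores = score_tbl,
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    total_var = sum(pc$sdev^2)
  )
}

#' Build the sexed trait set from bias-class PCAs
#'
#' Assembles the low-dimensional trait table used for G estimation:
#' by default the first 2 PCs of male-biased genes (MB, scored in males
#' only), the first 2 PCs of female-biased genes (FB, females only) and
#' the first 4 PCs of relatively unbiased genes (UB, one shared loading
#' set scored in both sexes, so a UB trait's dimorphism is
#' `loadings' (male - female gene means)`). Subordinate-sex scores of the
#' biased classes are not constructed (mirroring the absence of genetic
#' variance in the low-expressing sex and their removal from G).
#'
#' Replicate-level scores project each (line, sex, replicate) expression
#' vector onto the class loadings with the PCA centers, providing the
#' replication needed to separate genetic from residual (co)variance.
#'
#' @param data Long expression tibble (see [screen_genes()]).
#' @param class_tbl Tibble `gene_id`, `bias_class` (e.g. from
#'   [gene_dimorphism()]), covering the genes to use.
#' @param spec Named integer vector: components per class,
#'   default `c(MB = 2, FB = 2, UB = 4)`; a class with 0 is skipped.
#' @param ub_obs Observation set for the UB PCA: `"pooled"` (2 x lines
#'   line-sex rows; default) or `"averaged"` (sex-averaged line means).
#' @return A `trait_scores` object: list with `line_scores` (tibble
#'   `line`, plus one column per sexed trait `"UB1:M"` ...),
#'   `rep_scores` (same but per `line`, `rep`), `loadings`, `centers`,
#'   `trait_sex` (named vector), `spec`.
#' @export
build_trait_scores <- function(data, class_tbl,
                               spec = c(MB = 2, FB = 2, UB = 4),
                               ub_obs = c("pooled", "averaged")) {
  ub_obs <- match.arg(ub_obs)
  check_expression_data(data)
  data <- dplyr::filter(data, .data$gene_id %in% class_tbl$gene_id)
  lm_tbl <- line_means(data)
  loadings <- list()
  centers <- list()
  trait_cols <- list()
  trait_sex <- character(0)

  score_block <- function(class, k, sexes, obs) {
    genes <- class_tbl$gene_id[class_tbl$bias_class == class]
    if (length(genes) < k) {
      stop(sprintf("Class %s has %d genes but %d components requested.",
                   class, length(genes), k))
    }
    pca <- class_pca(lm_tbl, genes, k, obs = obs)
    loadings[[class]] <<- pca$loadings
    centers[[class]] <<- pca$centers
    gene_order <- rownames(pca$loadings)
    # replicate-level projections per sex
    for (sx in sexes) {
      wide <- data |>
        dplyr::filter(.data$gene_id %in% genes, .data$sex == sx) |>
        tidyr::pivot_wider(id_cols = c("line", "rep"),
                           names_from = "gene_id", values_from = "value")
      mat <- as.matrix(wide[gene_order])
      sc <- sweep(mat, 2, pca$centers[gene_order]) %*% pca$loadings
      cn <- paste0(class, seq_len(k), ":", sx)
      sc_tbl <- tibble::as_tibble(sc, .name_repair = "minimal")
      names(sc_tbl) <- cn
      trait_cols[[paste(class, sx)]] <<- dplyr::bind_cols(
        tibble::tibble(line = wide$line, rep = wide$rep), sc_tbl
      )
      trait_sex[cn] <<- sx
    }
    invisible(NULL)
  }

  if (!is.na(spec["UB"]) && spec["UB"] > 0) {
    score_block("UB", spec[["UB"]], c("M", "F"), ub_obs)
  }
  if (!is.na(spec["MB"]) && spec["MB"] > 0) {
    score_block("MB", spec[["MB"]], "M", "M")
  }
  if (!is.na(spec["FB"]) && spec["FB"] > 0) {
    score_block("FB", spec[["FB"]], "F", "F")
  }
  rep_scores <- purrr::reduce(trait_cols,
                              ~ dplyr::full_join(.x, .y,
                                                 by = c("line", "rep")))
  # order: shared (UB, both sexes) first, then sex-limited
  tn <- names(trait_sex)
  base <- sub(":[MF]$", "", tn)
  is_shared <- base %in% base[duplicated(base)]
  ord_cols <- c("line", "rep",
                tn[order(!is_shared, match(base, unique(base)))])
  rep_scores <- rep_scores[ord_cols]
  trait_names <- setdiff(names(rep_scores), c("line", "rep"))
  line_scores <- rep_scores |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(trait_names), mean),
                     .groups = "drop")
  structure(list(
    line_scores = line_scores, rep_scores = rep_scores,
    loadings = loadings, centers = centers, trait_sex = trait_sex,
    spec = spec
  ), class = "trait_scores")
}

#' @export
print.trait_scores <- function(x, ...) {
  cat(sprintf("<trait_scores> %d sexed traits x %d lines (%d replicate rows)\n",
              length(x$trait_sex), nrow(x$line_scores), nrow(x$rep_scores)))
  cat("traits:", paste(names(x$trait_sex), collapse = ", "), "\n")
  invisible(x)
}
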