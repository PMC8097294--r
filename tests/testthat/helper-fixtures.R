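# Small in-code fixtures shared across test files.

# Balanced single-probe expression tibble with planted line effects.
make_panel <- function(n_genes = 5, n_lines = 10, n_reps = 2,
                       sigma_line = 0.5, sigma_line_sex = 0.3,
                       sigma_e = 0.2, d_true = 0.5, seed = 1) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  grid <- expand.grid(line = lines, sex = c("M", "F"),
                      rep = seq_len(n_reps), gene = seq_len(n_genes),
                      stringsAsFactors = FALSE)
  a <- matrix(rnorm(n_genes * n_lines, 0, sigma_line), n_genes, n_lines,
              dimnames = list(NULL, lines))
  cint <- array(rnorm(n_genes * n_lines * 2, 0, sigma_line_sex),
                c(n_genes, n_lines, 2), dimnames = list(NULL, lines,
                                                        c("M", "F")))
  grid$value <- 5 + ifelse(grid$sex == "M", d_true / 2, -d_true / 2) +
    a[cbind(grid$gene, match(grid$line, lines))] +
    cint[cbind(grid$gene, match(grid$line, lines),
               match(grid$sex, c("M", "F")))] +
    rnorm(nrow(grid), 0, sigma_e)
  tibble::tibble(
    gene_id = sprintf("g%03d", grid$gene),
    line = grid$line, sex = grid$sex, rep = grid$rep, value = grid$value
  )
}

# Random PD covariance of dimension p.
rand_cov <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm((p + 3) * p), p + 3, p)
  crossprod(X) / (p + 3)
}

# Replicate trait scores simulated directly at the trait level:
# line genetic vectors ~ N(0, G), replicate noise ~ N(0, E).
simulate_scores <- function(G, E, L, R, labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(G)
  a <- matrix(rnorm(L * p), L, p) %*% chol(G + diag(1e-12, p))
  rows <- purrr::map_dfr(seq_len(L), function(l) {
    vals <- matrix(rnorm(R * p), R, p) %*% chol(E) +
      matrix(a[l, ], R, p, byrow = TRUE)
    out <- tibble::as_tibble(vals, .name_repair = "minimal")
    names(out) <- labels
    dplyr::bind_cols(tibble::tibble(line = sprintf("L%03d", l),
                                    rep = seq_len(R)), out)
  })
  rows
}
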