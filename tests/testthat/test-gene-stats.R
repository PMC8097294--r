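test_that("closed-form REML screen matches lme4 on balanced designs", {
  d <- make_panel(n_genes = 3, n_lines = 15, n_reps = 3, seed = 4)
  fast <- screen_genes(d)
  for (gid in unique(d$gene_id)) {
    slow <- dimorphr:::screen_one_lmer(dplyr::filter(d, gene_id == gid))
    expect_equal(fast$lrt[fast$gene_id == gid], slow$lrt, tolerance = 1e-4)
  }
  # variance components against lme4 for one gene
  d1 <- dplyr::filter(d, gene_id == "g001")
  d1$line <- factor(d1$line); d1$sex <- factor(d1$sex)
  fit <- lme4::lmer(value ~ sex + (1 | line) + (1 | line:sex), data = d1,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  row1 <- fast[fast$gene_id == "g001", ]
  expect_equal(row1$sigma2_line, vc$vcov[vc$grp == "line"],
               tolerance = 1e-4)
  expect_equal(row1$sigma2_line_sex, vc$vcov[vc$grp == "line:sex"],
               tolerance = 1e-4)
  expect_equal(row1$sigma2_resid, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-4)
})

test_that("screen is conservative under the null and powerful with real variance", {
  # null: no line effects at all; boundary makes the LRT conservative
  null_panel <- make_panel(n_genes = 2000, n_lines = 40, n_reps = 2,
                           sigma_line = 0, sigma_line_sex = 0,
                           sigma_e = 0.3, seed = 100)
  scr <- screen_genes(null_panel)
  rate <- mean(scr$retained)
  mc_sd <- sqrt(0.01 * 0.99 / 2000)
  expect_lte(rate, 0.01 + 3 * mc_sd)

  # planted line variance 5x residual: essentially always detected
  pow_panel <- make_panel(n_genes = 500, n_lines = 40, n_reps = 2,
                          sigma_line = sqrt(5 * 0.09),
                          sigma_line_sex = 0, sigma_e = 0.3, seed = 101)
  scr2 <- screen_genes(pow_panel)
  expect_gt(mean(scr2$p_value < 0.01), 0.99)
})

test_that("single-probe genes get 2 df, multi-probe 3 df, degenerate flagged", {
  d <- make_panel(n_genes = 1, n_lines = 8, n_reps = 2, seed = 6)
  expect_equal(screen_genes(d)$df, 2L)
  dp <- dplyr::bind_rows(
    dplyr::mutate(d, probe = "p1"),
    dplyr::mutate(d, probe = "p2",
                  value = value + 0.4 + rnorm(nrow(d), 0, 0.1))
  )
  expect_equal(screen_genes(dp)$df, 3L)
  done_sex <- dplyr::filter(d, sex == "M")
  expect_true(is.na(screen_genes(done_sex)$retained))
})

test_that("line means equal replicate means when balanced, LS means otherwise", {
  d <- tibble::tibble(
    gene_id = "g1", line = rep(c("L1", "L2"), each = 4),
    sex = rep(c("M", "M", "F", "F"), 2), rep = rep(1:2, 4),
    value = c(5.0, 5.2, 4.0, 4.4, 6.0, 6.2, 5.0, 5.6)
  )
  lm_tbl <- line_means(d)
  expect_equal(lm_tbl$ls_mean[lm_tbl$line == "L1" & lm_tbl$sex == "M"], 5.1)

  # constant gene: all means equal the constant
  dc <- dplyr::mutate(d, value = 3)
  expect_true(all(line_means(dc)$ls_mean == 3))

  # unbalanced probe design: LS mean equals the normal-equations solution
  set.seed(23)
  du <- tidyr::expand_grid(line = c("L1", "L2", "L3"), sex = c("M", "F"),
                           rep = 1:2, probe = c("p1", "p2"))
  du <- du[-c(1, 10), ]   # drop cells to unbalance probes
  du$gene_id <- "g1"
  du$value <- rnorm(nrow(du)) +
    ifelse(du$probe == "p2", 0.7, 0) + as.numeric(factor(du$line))
  lms <- line_means(du)
  # direct normal-equations oracle: solve the additive cell + probe model
  X <- stats::model.matrix(~ 0 + interaction(line, sex) + probe, data = du,
                           contrasts.arg = list(probe = "contr.sum"))
  beta <- solve(crossprod(X), crossprod(X, du$value))
  cells <- levels(interaction(du$line, du$sex))
  oracle <- stats::setNames(
    beta[paste0("interaction(line, sex)", cells), 1], cells
  )
  got <- stats::setNames(lms$ls_mean, paste(lms$line, lms$sex, sep = "."))
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
})

test_that("dimorphism classes use the stated thresholds with a closed boundary", {
  lm_tbl <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 4),
    line = rep(rep(c("L1", "L2"), each = 2), 3),
    sex = rep(c("M", "F"), 6),
    ls_mean = c(
      5 + 1.2, 5, 6 + 1.2, 6,    # D = 1.2 -> MB
      5 - 1.5, 5, 6 - 1.5, 6,    # D = -1.5 -> FB
      5 + 1.0, 5, 6 + 1.0, 6     # D = 1.0 -> UB (boundary)
    )
  )
  dd <- gene_dimorphism(lm_tbl)
  expect_equal(dd$bias_class, c("MB", "FB", "UB"))
  expect_equal(dd$D, c(1.2, -1.5, 1.0))
})

test_that("per-gene genetics recover hand-computed sample moments", {
  lm_tbl <- tibble::tibble(
    gene_id = "g1",
    line = rep(c("L1", "L2", "L3", "L4"), each = 2),
    sex = rep(c("M", "F"), 4),
    ls_mean = c(0, 0, 1, 2, 2, 1, 3, 3)
  )
  gg <- gene_genetics(lm_tbl)
  expect_equal(gg$m, 5 / 3, tolerance = 1e-12)
  expect_equal(gg$f, 5 / 3, tolerance = 1e-12)
  expect_equal(gg$b, 4 / 3, tolerance = 1e-12)
  expect_equal(gg$r_mf, 0.8, tolerance = 1e-12)

  # identical vectors: r_mf = 1, d = 1; reversed: r_mf = -1
  t1 <- tibble::tibble(gene_id = "a", line = rep(c("L1", "L2", "L3"), 2),
                       sex = rep(c("M", "F"), each = 3),
                       ls_mean = c(1, 2, 3, 1, 2, 3))
  expect_equal(gene_genetics(t1)[c("r_mf", "d")],
               tibble::tibble(r_mf = 1, d = 1))
  t2 <- t1; t2$ls_mean <- c(1, 2, 3, 3, 2, 1)
  expect_equal(gene_genetics(t2)$r_mf, -1)
  expect_error(gene_genetics(dplyr::filter(t1, line != "L3")), "3 lines")
})

test_that("per-gene genetics recover planted values as lines grow", {
  set.seed(55)
  L <- 400; n_genes <- 200
  m <- 0.4; f <- 0.2; b <- 0.15
  ch <- chol(rbind(c(m, b), c(b, f)))
  rel_err <- replicate(1, {
    z <- array(rnorm(n_genes * L * 2), c(n_genes * L, 2)) %*% ch
    lm_tbl <- tibble::tibble(
      gene_id = rep(sprintf("g%03d", 1:n_genes), each = L * 2),
      line = rep(rep(sprintf("L%03d", 1:L), each = 2), n_genes),
      sex = rep(c("M", "F"), n_genes * L),
      ls_mean = as.vector(t(z))
    )
    gg <- gene_genetics(lm_tbl)
    c(mean(abs(gg$m - m)) / m, mean(abs(gg$f - f)) / f,
      mean(abs(gg$b - b)) / abs(b))
  })
  expect_lt(max(rel_err), 0.10)
})

test_that("fast aggregate correlations equal the brute-force double loop", {
  set.seed(66)
  L <- 12; n_genes <- 50
  Mm <- matrix(rnorm(L * n_genes), L, n_genes,
               dimnames = list(NULL, sprintf("g%02d", 1:n_genes)))
  Fm <- 0.5 * Mm + matrix(rnorm(L * n_genes), L, n_genes)
  colnames(Fm) <- colnames(Mm)
  fast <- dimorphr:::aggregate_correlations_mat(Mm, Fm)
  CM <- cor(Mm); CF <- cor(Fm); CB <- cor(Mm, Fm)
  n <- n_genes
  for (i in c(1, 17, 50)) {
    j <- setdiff(1:n, i)
    expect_equal(fast$rw_bar[i],
                 sum(CM[i, j] + CF[i, j]) / (2 * (n - 1)), tolerance = 1e-10)
    expect_equal(fast$rb_bar[i],
                 sum(CB[i, j] + CB[j, i]) / (2 * (n - 1)), tolerance = 1e-10)
    expect_equal(fast$abs_rdw[i],
                 abs(sum(CM[i, j] - CF[i, j]) / (2 * (n - 1))),
                 tolerance = 1e-10)
    expect_equal(fast$abs_rdb[i],
                 abs(sum(CB[i, j] - CB[j, i]) / (2 * (n - 1))),
                 tolerance = 1e-10)
  }
})

test_that("aggregate correlations: analytic special cases and exclusions", {
  # two genes: rw_bar_1 = (rM1M2 + rF1F2) / 2
  set.seed(67)
  L <- 30
  Mm <- matrix(rnorm(2 * L), L, 2, dimnames = list(NULL, c("a", "b")))
  Fm <- matrix(rnorm(2 * L), L, 2, dimnames = list(NULL, c("a", "b")))
  fast <- dimorphr:::aggregate_correlations_mat(Mm, Fm)
  expect_equal(fast$rw_bar[1], (cor(Mm)[1, 2] + cor(Fm)[1, 2]) / 2,
               tolerance = 1e-12)
  # symmetric cross-sex structure: abs_rdb = 0
  fast_sym <- dimorphr:::aggregate_correlations_mat(Mm, Mm)
  expect_equal(fast_sym$abs_rdb, c(0, 0), tolerance = 1e-12)
  # zero-variance gene excluded, n adjusted
  M3 <- cbind(Mm, c = 1)
  F3 <- cbind(Fm, c = rnorm(L))
  fast3 <- dimorphr:::aggregate_correlations_mat(M3, F3)
  expect_true(is.na(fast3$rw_bar[3]))
  expect_equal(fast3$n_genes_used[1], 2)
})

test_that("tissue specificity follows the max-normalized index", {
  d <- make_panel(n_genes = 3, n_lines = 4, seed = 2)
  tt <- tibble::tibble(
    gene_id = c("g001", "g002", "g003"),
    t1 = c(4, 4, 4), t2 = c(4, 0, 2), t3 = c(4, 0, 0)
  )
  cov_tbl <- expression_covariates(d, tt)
  expect_equal(cov_tbl$tau[cov_tbl$gene_id == "g001"], 0)
  expect_equal(cov_tbl$tau[cov_tbl$gene_id == "g002"], 1)
  expect_equal(cov_tbl$tau[cov_tbl$gene_id == "g003"], 0.75)
  # e_bar is the grand mean
  expect_equal(cov_tbl$e_bar[1],
               mean(d$value[d$gene_id == "g001"]), tolerance = 1e-12)
  # all-zero tissue vector: tau missing
  tt0 <- tibble::tibble(gene_id = c("g001", "g002"), t1 = c(0, 1),
                        t2 = c(0, 2))
  expect_true(is.na(expression_covariates(d, tt0)$tau[1]))
})

test_that("dimorphism transformation matches its definition", {
  expect_equal(transform_dimorphism(0), -2)
  expect_equal(transform_dimorphism(0.99), 0)
  expect_equal(transform_dimorphism(-1.5), log10(1.51))
  expect_equal(round(transform_dimorphism(-1.5), 4), 0.1790)
})

test_that("gene_summaries assembles a coherent table and classes partition", {
  sim <- simulate_expression_panel(
    scenario_config("table2_like", gene_scale = 0.08), seed = 12
  )
  s <- gene_summaries(sim$data)
  expect_true(all(c("D", "bias_class", "m", "f", "b", "r_mf", "g_bar",
                    "rw_bar", "abs_rdb", "e_bar", "log10_D_abs")
                  %in% names(s)))
  expect_equal(sum(s$bias_class %in% c("MB", "FB", "UB")), nrow(s))
  expect_true(all(s$p_value < 0.01))
  expect_true(all(abs(s$r_mf) <= 1, na.rm = TRUE))
})
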