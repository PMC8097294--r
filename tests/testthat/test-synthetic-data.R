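test_that("simulation is byte-identical under a fixed seed", {
  cfg <- scenario_config("table2_like", gene_scale = 0.05)
  a <- simulate_expression_panel(cfg, seed = 33)
  b <- simulate_expression_panel(cfg, seed = 33)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$genes, b$truth$genes)
  c <- simulate_expression_panel(cfg, seed = 34)
  expect_false(identical(a$data$value, c$data$value))
})

test_that("realized per-gene moments match the planted architecture", {
  cfg <- scenario_config("table2_like", gene_scale = 0.1,
                         n_lines = 1000, n_reps = 1)
  cfg$sigma2_e <- 1e-8   # isolate the genetic layer
  sim <- simulate_expression_panel(cfg, seed = 35)
  lm_tbl <- line_means(sim$data)
  gg <- gene_genetics(lm_tbl)
  tr <- dplyr::inner_join(gg, sim$truth$genes, by = "gene_id",
                          suffix = c("_hat", "_true"))
  L <- cfg$n_lines
  # sampling SEs of sample variance / covariance under normality
  se_m <- sqrt(2 / (L - 1)) * tr$m_true
  se_f <- sqrt(2 / (L - 1)) * tr$f_true
  se_b <- sqrt((tr$m_true * tr$f_true + tr$b_true^2) / (L - 1))
  ok <- abs(tr$m_hat - tr$m_true) < 3 * se_m &
    abs(tr$f_hat - tr$f_true) < 3 * se_f &
    abs(tr$b_hat - tr$b_true) < 3 * se_b
  expect_gte(mean(ok), 0.95)
})

test_that("planted dimorphism drives realized D and class recovery", {
  cfg <- scenario_config("table2_like", gene_scale = 0.2)
  sim <- simulate_expression_panel(cfg, seed = 36)
  lm_tbl <- line_means(sim$data)
  dd <- gene_dimorphism(lm_tbl)
  tr <- dplyr::inner_join(dd, sim$truth$genes, by = "gene_id")
  mb <- tr[tr$class == "MB", ]
  expect_equal(mean(mb$D), mean(mb$d_true), tolerance = 0.1)
  expect_gt(mean(tr$bias_class == tr$class), 0.95)
})

test_that("implied trait G reduces to planted per-gene parameters", {
  cfg <- scenario_config("table2_like", gene_scale = 0.05)
  sim <- simulate_expression_panel(cfg, seed = 37)
  gene <- sim$truth$genes[10, ]
  W <- matrix(1, 1, 1, dimnames = list(gene$gene_id, "T"))
  g2 <- implied_trait_g(sim$truth, W, trait_sex = "both")
  expect_equal(g2$cov[1, 1], gene$m, tolerance = 1e-12)
  expect_equal(g2$cov[2, 2], gene$f, tolerance = 1e-12)
  expect_equal(g2$cov[1, 2], gene$b, tolerance = 1e-12)

  # orthogonal loadings on independent (factor-free) genes: block diagonal
  sim_nf <- simulate_expression_panel(
    scenario_config("sas_architecture", gene_scale = 0.05), seed = 44
  )
  idio <- sim_nf$truth$genes$gene_id[is.na(sim_nf$truth$genes$factor)][1:2]
  W2 <- matrix(0, 2, 2, dimnames = list(idio, c("Ta", "Tb")))
  W2[1, 1] <- 1; W2[2, 2] <- 1
  g3 <- implied_trait_g(sim_nf$truth, W2, trait_sex = c("both", "both"))
  expect_equal(g3$cov["Ta:M", "Tb:M"], 0)
  expect_equal(g3$cov["Ta:M", "Tb:F"], 0)
})

test_that("implied trait G matches a brute-force simulation of line values", {
  cfg <- scenario_config("table2_like", gene_scale = 0.05, n_lines = 40)
  sim <- simulate_expression_panel(cfg, seed = 38)
  truth <- sim$truth
  g <- truth$genes
  set.seed(39)
  W <- matrix(rnorm(nrow(g) * 2), nrow(g), 2,
              dimnames = list(g$gene_id, c("Ta", "Tb")))
  implied <- implied_trait_g(truth, W, trait_sex = c("both", "both"))

  # brute force: simulate many line genetic values from the architecture
  n_mc <- 60000
  K <- nrow(truth$factor_cross)
  Omega <- rbind(cbind(diag(K), truth$factor_cross),
                 cbind(t(truth$factor_cross), diag(K)))
  eta <- matrix(rnorm(n_mc * 2 * K), n_mc, 2 * K) %*% chol(Omega)
  a11 <- sqrt(g$m_idio)
  c1 <- ifelse(a11 > 0, g$b_idio / a11, 0)
  c2 <- sqrt(pmax(g$f_idio - c1^2, 0))
  z1 <- matrix(rnorm(nrow(g) * n_mc), nrow(g), n_mc)
  z2 <- matrix(rnorm(nrow(g) * n_mc), nrow(g), n_mc)
  fac <- ifelse(is.na(g$factor), 1L, g$factor)
  a_m <- g$lam_m * t(eta[, fac, drop = FALSE]) + a11 * z1
  a_f <- g$lam_f * t(eta[, K + fac, drop = FALSE]) + c1 * z1 + c2 * z2
  scores <- cbind(t(a_m) %*% W, t(a_f) %*% W)   # n_mc x 4 (M traits, F traits)
  emp <- stats::cov(scores)
  th <- implied$cov[c("Ta:M", "Tb:M", "Ta:F", "Tb:F"),
                    c("Ta:M", "Tb:M", "Ta:F", "Tb:F")]
  scale <- max(abs(th))
  expect_lt(max(abs(emp - th)) / scale, 0.05)
})

test_that("scenarios reproduce their architectural signatures", {
  # null: all genetic variance zero
  cfg0 <- scenario_config("null", gene_scale = 0.05)
  sim0 <- simulate_expression_panel(cfg0, seed = 40)
  expect_true(all(sim0$truth$genes$m == 0))
  expect_true(all(sim0$truth$genes$b == 0))

  # scs: dimorphism tracks variance asymmetry
  cfg_scs <- scenario_config("scs_architecture", gene_scale = 0.2)
  sim_scs <- simulate_expression_panel(cfg_scs, seed = 41)
  tg <- sim_scs$truth$genes
  expect_gt(cor(log10(abs(tg$m - tg$f)), abs(tg$d_true)), 0)

  # sas: dimorphism concentrated in low-rMF genes
  cfg_sas <- scenario_config("sas_architecture", gene_scale = 0.2)
  sim_sas <- simulate_expression_panel(cfg_sas, seed = 42)
  ts <- sim_sas$truth$genes
  expect_lt(cor(ts$r_mf, abs(ts$d_true)), 0)

  expect_error(scenario_config("unknown"), "arg")
})

test_that("table2_like scenario has the 12-trait sexed layout", {
  cfg <- scenario_config("table2_like", gene_scale = 0.05)
  sim <- simulate_expression_panel(cfg, seed = 43)
  ig <- implied_trait_g(sim$truth)
  expect_equal(nrow(ig$cov), 12)
  expect_equal(length(shared_traits(ig)), 4)
  # asymmetric B off-diagonals from the cross-block factor coupling
  B <- extract_blocks(ig)$B
  expect_gt(max(abs(B - t(B))), 1e-6)
})
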