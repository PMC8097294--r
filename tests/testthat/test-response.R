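test_that("engine matches hand evaluations of the two-sex breeder's equation", {
  # identity matrix, unit-norm antagonistic gradient
  g <- assemble_sexed_g(matrix(1), matrix(1), NULL, "t1", "t1")
  grad <- selection_gradient(g, "antagonistic")
  r <- predict_response(g, grad)
  expect_equal(r$dz$dz, c(1, -1) / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(r$delta_norm, 1 / sqrt(2), tolerance = 1e-12)

  # m = f = 1, b = 0.8, raw antagonistic beta = (1, -1)
  g2 <- assemble_sexed_g(matrix(1), matrix(1), matrix(0.8), "t1", "t1")
  grad2 <- selection_gradient(g2, "antagonistic", norm = "raw")
  r2 <- predict_response(g2, grad2)
  expect_equal(r2$dz$dz, c(0.1, -0.1), tolerance = 1e-12)
  expect_equal(r2$dimorphism$delta, 0.2, tolerance = 1e-12)

  # concordant on a fully symmetric matrix: no dimorphism change
  grad3 <- selection_gradient(g2, "concordant", norm = "raw")
  r3 <- predict_response(g2, grad3)
  expect_equal(r3$dimorphism$delta, 0, tolerance = 1e-15)
})

test_that("gradient schemes and normalization follow the conventions", {
  g <- rand_sexed_g(3)
  ga <- selection_gradient(g, "antagonistic", traits = "UB1")
  expect_equal(unname(ga$beta[c("UB1:M", "UB1:F")]),
               c(1, -1) / sqrt(2), tolerance = 1e-12)
  expect_equal(sqrt(sum(ga$beta^2)), 1, tolerance = 1e-12)
  gc <- selection_gradient(g, "concordant")
  expect_equal(unname(gc$beta["UB2:M"]), unname(gc$beta["UB2:F"]))
  expect_error(selection_gradient(g, "antagonistic", traits = "nope"),
               "shared")
  expect_error(
    predict_response(g, structure(list(beta = rep(0, 6), scheme = "custom"),
                                  class = "selection_gradient")),
    "zero"
  )
})

test_that("closed-form dimorphism changes equal the engine to 1e-12", {
  set.seed(42)
  for (i in 1:50) {
    g <- rand_sexed_g(sample(2:5, 1), sample(0:2, 1), sample(0:2, 1))
    traits <- shared_traits(g)
    sel <- sample(traits, sample(seq_along(traits), 1))
    for (scheme in c("antagonistic", "concordant")) {
      grad <- selection_gradient(g, scheme, traits = sel)
      cf <- dimorphism_change_closed_form(g, grad)
      en <- predict_response(g, grad)$dimorphism$delta
      expect_lt(max(abs(cf - en)), 1e-12)
    }
  }
})

test_that("antagonistic responses depend only on Gbar and B_S", {
  set.seed(9)
  g <- rand_sexed_g(4)
  bl <- extract_blocks(g)
  # perturb the sex-difference of the within-sex blocks and the
  # antisymmetric part of B; the antagonistic response must not move
  S <- matrix(rnorm(16, 0, 0.02), 4, 4); S <- (S + t(S)) / 2
  A <- matrix(rnorm(16, 0, 0.02), 4, 4); A <- (A - t(A)) / 2
  g2 <- assemble_sexed_g(bl$G_M + S, bl$G_F - S, bl$B + A,
                         bl$male_traits, bl$female_traits,
                         validate = FALSE)
  for (tr in list("UB1", c("UB2", "UB3"), shared_traits(g))) {
    grad <- selection_gradient(g, "antagonistic", traits = tr)
    d1 <- predict_response(g, grad)$dimorphism$delta
    d2 <- predict_response(g2, grad)$dimorphism$delta
    expect_lt(max(abs(d1 - d2)), 1e-12)
  }
})

test_that("responses are linear in the gradient", {
  set.seed(13)
  g <- rand_sexed_g(3, 1, 1)
  b1 <- selection_gradient(g, "antagonistic", traits = "UB1", norm = "raw")
  b2 <- selection_gradient(g, "concordant", traits = c("UB2", "UB3"),
                           norm = "raw")
  bsum <- selection_gradient(g, "custom", beta = b1$beta + b2$beta,
                             norm = "raw")
  expect_equal(predict_response(g, bsum)$dz$dz,
               predict_response(g, b1)$dz$dz + predict_response(g, b2)$dz$dz,
               tolerance = 1e-12)
})

test_that("vec_corr is 1 under concordant selection on a sex-symmetric matrix", {
  set.seed(21)
  Gs <- rand_cov(3)
  B <- (rand_cov(3) + t(rand_cov(3))) / 2
  B <- B * 0.1   # keep the full matrix PSD
  g <- assemble_sexed_g(Gs, Gs, B, paste0("t", 1:3), paste0("t", 1:3))
  r <- predict_response(g, selection_gradient(g, "concordant"))
  expect_equal(r$vec_corr, 1, tolerance = 1e-10)
  expect_equal(r$delta_norm, 0, tolerance = 1e-12)
})

test_that("conditional responses equal conditional evolvability and c <= e", {
  # hand case: 2x2 correlation 0.9, select first variable
  g <- assemble_sexed_g(matrix(1), matrix(1), matrix(0.9), "t", "t")
  grad <- selection_gradient(
    g, "custom", beta = c(`t:M` = 1), norm = "raw"
  )
  r <- conditional_response(g, grad)
  expect_equal(r$conditional_evolvability, 1 - 0.81, tolerance = 1e-12)

  # diagonal case: c equals the selected variable's variance
  gd <- assemble_sexed_g(diag(c(2, 3)), diag(c(1, 4)), NULL,
                         c("a", "b"), c("a", "b"))
  gr <- selection_gradient(gd, "custom", beta = c(`b:M` = 1), norm = "raw")
  expect_equal(conditional_response(gd, gr)$conditional_evolvability, 3,
               tolerance = 1e-10)

  # property: c(beta) <= e(beta) over random PSD matrices
  set.seed(77)
  for (i in 1:200) {
    g <- rand_sexed_g(3)
    grad <- selection_gradient(g, sample(c("antagonistic", "concordant"), 1))
    ce <- conditional_response(g, grad)$conditional_evolvability
    ev <- predict_response(g, grad)$e
    expect_lte(ce, ev + 1e-10)
  }
})

test_that("modification ratios show the structural zeros and ones", {
  set.seed(31)
  g <- rand_sexed_g(4)
  tab <- modification_ratio_table(g)
  ant <- tab[tab$scheme == "antagonistic" &
               tab$mod %in% c("avg_G", "sym_B", "avg_G_sym_B"), ]
  expect_true(all(abs(ant$ratio - 1) < 1e-10))
  con0 <- tab[tab$scheme == "concordant" &
                tab$mod %in% c("avg_G_sym_B", "avg_G_zero_B"), ]
  expect_true(all(abs(con0$ratio) < 1e-10))
  none <- modification_ratio_table(g, mods = "none")
  expect_true(all(abs(none$ratio - 1) < 1e-15))
})

test_that("summarize_over_replicates reports type-7 quantiles and exclusions", {
  gs <- lapply(1:11, function(i) {
    assemble_sexed_g(matrix(i), matrix(i), NULL, "t", "t")
  })
  stat <- function(g) g$cov[1, 1]
  s <- summarize_over_replicates(gs, stat)
  expect_equal(s$median, 6)
  expect_equal(s$q2.5, stats::quantile(1:11, 0.025, type = 7, names = FALSE))
  # undefined on some replicates: excluded with count
  stat2 <- function(g) if (g$cov[1, 1] > 9) stop("undefined") else g$cov[1, 1]
  s2 <- summarize_over_replicates(gs, stat2)
  expect_equal(s2$n_missing, 2)
  expect_equal(s2$n_used, 9)
  # constant statistic collapses all three summaries
  s3 <- summarize_over_replicates(gs, function(g) 1.5)
  expect_equal(c(s3$median, s3$q2.5, s3$q97.5), rep(1.5, 3))
})
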