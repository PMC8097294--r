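test_that("assembly places blocks as specified and round-trips", {
  g <- assemble_sexed_g(matrix(1), matrix(1), matrix(0.8), "t1", "t1")
  expect_equal(unname(g$cov), rbind(c(1, 0.8), c(0.8, 1)))

  g2 <- assemble_sexed_g(diag(2), diag(2), matrix(0, 2, 2),
                         c("a", "b"), c("a", "b"))
  expect_equal(unname(g2$cov), diag(4))

  # 12-variable layout: 4 shared + 2 male-only + 2 female-only
  set.seed(11)
  g12 <- rand_sexed_g(4, 2, 2)
  expect_equal(nrow(g12$cov), 12)
  bl <- extract_blocks(g12)
  expect_equal(bl$shared, paste0("UB", 1:4))
  expect_equal(dim(bl$G_M), c(6, 6))
  expect_equal(dim(bl$G_F), c(6, 6))
  expect_equal(dim(bl$B), c(4, 4))
  # reassembly from extracted blocks is bit-exact
  re <- assemble_sexed_g(bl$G_M, bl$G_F, bl$cross,
                         bl$male_traits, bl$female_traits)
  expect_identical(re$cov, g12$cov)
})

test_that("extract_blocks returns within- and cross-sex blocks", {
  g <- assemble_sexed_g(matrix(1), matrix(1), matrix(0.8), "t1", "t1")
  bl <- extract_blocks(g)
  expect_equal(unname(bl$G_M), matrix(1))
  expect_equal(unname(bl$G_F), matrix(1))
  expect_equal(unname(bl$B), matrix(0.8))

  gd <- assemble_sexed_g(rand_cov(2, 1), rand_cov(2, 2), NULL,
                         c("a", "b"), c("a", "b"))
  expect_equal(unname(extract_blocks(gd)$B), matrix(0, 2, 2))
})

test_that("validation rejects asymmetry, non-PSD and bad correlation matrices", {
  m <- rbind(c(1, 0.5), c(0.4, 1))
  expect_error(
    new_sexed_g(m, tibble::tibble(trait = "t", sex = c("M", "F"))),
    "symmetric"
  )
  # eigenvalue -1e-6 on unit scale must be rejected
  bad <- rbind(c(1, 1 + 1e-6), c(1 + 1e-6, 1))
  expect_error(
    new_sexed_g(bad, tibble::tibble(trait = "t", sex = c("M", "F"))),
    "positive semi-definite"
  )
  expect_error(
    new_sexed_g(rbind(c(2, 0.5), c(0.5, 1)),
                tibble::tibble(trait = "t", sex = c("M", "F")),
                is_correlation = TRUE),
    "unit diagonal"
  )
  expect_error(
    new_sexed_g(diag(2), tibble::tibble(trait = c("t", "t"),
                                        sex = c("M", "M"))),
    "unique"
  )
})

test_that("matrix modifications implement the five substitutions", {
  g <- assemble_sexed_g(matrix(2), matrix(1), matrix(0.5), "t", "t")
  expect_identical(apply_modification(g, "none"), g)

  avg <- apply_modification(g, "avg_G")
  expect_equal(unname(extract_blocks(avg)$G_M), matrix(1.5))
  expect_equal(unname(extract_blocks(avg)$G_F), matrix(1.5))
  expect_equal(unname(extract_blocks(avg)$B), matrix(0.5))

  z <- apply_modification(g, "zero_B")
  expect_equal(unname(extract_blocks(z)$B), matrix(0))

  # symmetric B is unchanged by sym_B
  set.seed(3)
  gs <- rand_sexed_g(3)
  bl <- extract_blocks(gs)
  Bs <- (bl$B + t(bl$B)) / 2
  gsym <- assemble_sexed_g(bl$G_M, bl$G_F, Bs, bl$male_traits,
                           bl$female_traits, validate = FALSE)
  expect_equal(suppressWarnings(apply_modification(gsym, "sym_B"))$cov,
               gsym$cov)
})

test_that("avg_G_sym_B is idempotent and B = B_S + B_A", {
  set.seed(7)
  for (i in 1:5) {
    g <- rand_sexed_g(3, 1, 1)
    m1 <- suppressWarnings(apply_modification(g, "avg_G_sym_B"))
    m2 <- suppressWarnings(apply_modification(m1, "avg_G_sym_B"))
    expect_equal(m1$cov, m2$cov, tolerance = 1e-14)
    B <- extract_blocks(g)$B
    B_S <- (B + t(B)) / 2
    B_A <- (B - t(B)) / 2
    expect_equal(B_S + B_A, B, tolerance = 1e-15)
  }
})

test_that("modification on a matrix with no shared traits errors", {
  g <- assemble_sexed_g(matrix(1), matrix(1), NULL, "mb", "fb")
  expect_error(apply_modification(g, "avg_G"), "shared trait")
})

test_that("bend_sexed_g clips negative eigenvalues and preserves trace", {
  m <- diag(c(2, 1, -0.1))
  v <- tibble::tibble(trait = c("a", "b", "c"), sex = c("M", "M", "F"))
  g <- structure(list(cov = m, variables = v, is_correlation = FALSE),
                 class = "sexed_g")
  bent <- bend_sexed_g(g)
  ev <- eigen(bent$cov, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-12)
  expect_equal(sum(diag(bent$cov)), sum(diag(m)))
})

test_that("r_mf_table computes diagonal-B correlations", {
  g <- assemble_sexed_g(matrix(2), matrix(1), matrix(0.5), "t", "t")
  tab <- r_mf_table(g)
  expect_equal(tab$r_mf, 0.5 / sqrt(2))
})

test_that("tidy() labels the blocks of a sexed G", {
  g <- rand_sexed_g(2, 1, 0)
  td <- tidy(g)
  expect_equal(nrow(td), 25)
  expect_setequal(unique(td$block), c("G_M", "G_F", "B", "B_t"))
  bm <- td[td$block == "G_M", ]
  expect_true(all(bm$row_sex == "M" & bm$col_sex == "M"))
})

test_that("G matrix CSV round-trips bit-exactly with its sidecar", {
  set.seed(19)
  g <- rand_sexed_g(4, 2, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sexed_g(g, path, provenance = list(seed = 19))
  g2 <- read_sexed_g(path)
  expect_equal(g2$cov, g$cov, tolerance = 1e-12)
  expect_identical(g2$variables, g$variables)
  expect_false(g2$is_correlation)
  expect_true(file.exists(paste0(path, ".json")))
})
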