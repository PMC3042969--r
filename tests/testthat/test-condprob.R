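feasible_achias <- rbind(c(2, 2), c(2, 1), c(1, 2), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
all_classes <- rbind(feasible_achias, c(2, 0), c(0, 2))

test_that("conditional probabilities are normalized and match gamete enumeration", {
  for (r in c(0.05, 0.09, 0.16, 0.3)) {
    for (frac in c(0.1, 0.33, 0.5, 0.77, 0.95)) {
      r1 <- r * frac
      r2 <- (r - r1) / (1 - 2 * r1)
      oa <- enumerate_cond_probs("achiasmate", r1, r2)
      oc <- enumerate_cond_probs("chiasmate", r1, r2)
      pa <- cond_prob_achiasmate(feasible_achias[, 1], feasible_achias[, 2], r1, r2)
      pc <- cond_prob_chiasmate(all_classes[, 1], all_classes[, 2], r1, r2)
      expect_equal(rowSums(pa), rep(1, 7), tolerance = 1e-12)
      expect_equal(rowSums(pc), rep(1, 9), tolerance = 1e-12)
      for (i in seq_len(7)) {
        key <- paste(feasible_achias[i, 1], feasible_achias[i, 2])
        expect_equal(unname(pa[i, ]), unname(oa[[key]]), tolerance = 1e-10)
      }
      for (i in seq_len(9)) {
        key <- paste(all_classes[i, 1], all_classes[i, 2])
        expect_equal(unname(pc[i, ]), unname(oc[[key]]), tolerance = 1e-10)
      }
    }
  }
})

test_that("achiasmate-impossible classes error distinctly from missing data", {
  expect_error(cond_prob_achiasmate(2, 0, 0.04, 0.05), "achiasmate-impossible")
  expect_error(cond_prob_achiasmate(0, 2, 0.04, 0.05), "achiasmate-impossible")
  expect_error(cond_prob_achiasmate(NA, 2, 0.04, 0.05), "missing")
  expect_error(cond_prob_achiasmate(3, 2, 0.04, 0.05), "coded")
  # gamete enumeration assigns those classes zero probability
  o <- enumerate_cond_probs("achiasmate", 0.03, 0.062)
  expect_true(all(is.na(o[["2 0"]])))
  expect_true(all(is.na(o[["0 2"]])))
})

test_that("both designs collapse to the same point masses for a coincident locus", {
  pa <- cond_prob_achiasmate(c(2, 1, 0), c(2, 1, 1), 0, 0.09)
  pc <- cond_prob_chiasmate(c(2, 1, 0), c(2, 1, 1), 0, 0.09)
  expect_equal(pa[, "pQQ"], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(pa, pc)
  # and converge as r1, r2 -> 0
  pa <- cond_prob_achiasmate(feasible_achias[, 1], feasible_achias[, 2], 1e-9, 1e-9)
  pc <- cond_prob_chiasmate(feasible_achias[, 1], feasible_achias[, 2], 1e-9, 1e-9)
  expect_equal(pa, pc, tolerance = 1e-7)
})

test_that("coefficients reproduce the closed-form achiasmate table entries", {
  r1 <- 0.03; r2 <- 0.062
  s1 <- 1 - r1; s2 <- 1 - r2
  r <- r1 * s2 + r2 * s1; s <- 1 - r
  cf <- qtl_coefficients(cond_prob_achiasmate(feasible_achias[, 1],
                                              feasible_achias[, 2], r1, r2))
  expect_equal(unname(cf[1, ]), c(s1 * s2 / s, (r1 * r2 - s1 * s2) / (2 * s)))
  expect_equal(unname(cf[2, ]), c(s1 * r2 / r, (r1 * s2 - s1 * r2) / (2 * r)))
  expect_equal(unname(cf[3, ]), c(r1 * s2 / r, (s1 * r2 - r1 * s2) / (2 * r)))
  expect_equal(unname(cf[4, ]), c(0, (s1 * s2 - r1 * r2) / (2 * s)))
  expect_equal(unname(cf[6, ]), c(-s1 * r2 / r, (r1 * s2 - s1 * r2) / (2 * r)))
  expect_equal(unname(cf[7, ]), c(-s1 * s2 / s, (r1 * r2 - s1 * s2) / (2 * s)))
  # degenerate and symmetric cases
  expect_equal(unname(qtl_coefficients(cbind(pQQ = 0.25, pQq = 0.5, pqq = 0.25))[1, ]),
               c(0, 0))
  expect_equal(unname(qtl_coefficients(cbind(pQQ = 1, pQq = 0, pqq = 0))[1, ]),
               c(1, -0.5))
})

test_that("epistatic coefficients are the per-locus products and stay bounded", {
  ci <- cbind(xA = 1, xD = -0.5); cj <- cbind(xA = 1, xD = -0.5)
  expect_equal(unname(epistasis_coefficients(ci, cj)[1, ]), c(1, -0.5, -0.5, 0.25))
  ci <- cbind(xA = 0, xD = 0.5)
  expect_equal(unname(epistasis_coefficients(ci, cj)[1, ]), c(0, 0, 0.5, -0.25))
  set.seed(4)
  for (i in 1:50) {
    p <- prop.table(runif(3)); q <- prop.table(runif(3))
    e <- epistasis_coefficients(
      qtl_coefficients(cbind(pQQ = p[1], pQq = p[2], pqq = p[3])),
      qtl_coefficients(cbind(pQQ = q[1], pQq = q[2], pqq = q[3])))
    expect_true(abs(e[1, "xAA"]) <= 1)
    expect_true(all(abs(e[1, c("xAD", "xDA")]) <= 0.5))
    expect_true(abs(e[1, "xDD"]) <= 0.25)
  }
})

test_that("missing markers receive flanking-conditional coefficient expectations", {
  map <- grid_map(1, 3, 10)
  geno <- matrix(c(2L, NA, 2L,
                   1L, NA, 1L,
                   2L, 2L, 2L,
                   0L, NA, NA), 4, 3, byrow = TRUE,
                 dimnames = list(NULL, map$marker))
  pop <- cross_pop(map, geno, sex = c(1, 2, 1, 2), y = rnorm(4))
  z <- expected_marker_coeffs(pop, "M1_02")
  r1 <- map_to_recomb(10)
  exp1 <- qtl_coefficients(cond_prob_achiasmate(2, 2, r1, r1))
  expect_equal(unname(z[1, ]), unname(exp1[1, ]))
  exp2 <- qtl_coefficients(cond_prob_achiasmate(1, 1, r1, r1))
  expect_equal(unname(z[2, ]), unname(exp2[1, ]))
  expect_equal(unname(z[3, ]), c(1, -0.5))  # observed genotype keeps its coding
  # single left flank for individual 4
  exp4 <- qtl_coefficients(silkqtl:::single_flank_probs("achiasmate", 0, r1))
  expect_equal(unname(z[4, ]), unname(exp4[1, ]))
  # no informative neighbours -> marginal (0, 0) with a warning
  geno[4, ] <- NA
  pop <- cross_pop(map, geno, sex = c(1, 2, 1, 2), y = rnorm(4))
  expect_warning(z <- expected_marker_coeffs(pop, "M1_02"), "marginal")
  expect_equal(unname(z[4, ]), c(0, 0))
})
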