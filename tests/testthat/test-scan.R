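# One shared strong-QTL population keeps these tests fast
pop <- one_qtl_pop()

test_that("background selection finds the interval flanking a strong QTL", {
  bg <- select_background_markers(pop, n_perm = 150, seed = 3)
  expect_true(length(bg$selected) >= 1)
  sel <- bg$intervals[bg$selected, ]
  # the true QTL at C1:23 lies inside one selected interval
  expect_true(any(sel$chrom == "C1" & sel$left_pos <= 23 & sel$right_pos >= 23))
  # reproducible threshold under the same seed
  bg2 <- select_background_markers(pop, n_perm = 150, seed = 3)
  expect_identical(bg$threshold, bg2$threshold)
  expect_identical(bg$selected, bg2$selected)
  # precondition: at least two markers per chromosome
  tiny <- cross_pop(genetic_map("C1", "m1", 0),
                    matrix(1L, 4, 1, dimnames = list(NULL, "m1")),
                    sex = c(1, 1, 2, 2), y = rnorm(4))
  expect_error(select_background_markers(tiny), "two markers")
})

test_that("the one-dimensional scan localizes the QTL and is affine invariant", {
  bg <- select_background_markers(pop, n_perm = 150, seed = 3)
  sc <- scan_main(pop, bg, step_cM = 1, n_perm = 150, seed = 4)
  expect_true(nrow(sc$detected) >= 1)
  best <- sc$detected[which.max(sc$detected$F), ]
  expect_equal(best$chrom, "C1")
  expect_lt(abs(best$pos_cM - 23), 10)
  expect_true(all(sc$profile$F >= 0))
  # affine transform of y leaves detected positions unchanged
  pop2 <- pop; pop2$y <- -3 * pop$y + 7
  bg2 <- select_background_markers(pop2, n_perm = 150, seed = 3)
  sc2 <- scan_main(pop2, bg2, step_cM = 1, n_perm = 150, seed = 4)
  expect_equal(sc2$detected$pos_cM, sc$detected$pos_cM)
  expect_equal(sc2$detected$F, sc$detected$F, tolerance = 1e-8)
  # grid refinement moves the peak by less than the coarse step
  sc_half <- scan_main(pop, bg, step_cM = 0.5, n_perm = 150, seed = 4)
  best_half <- sc_half$detected[which.max(sc_half$detected$F), ]
  expect_lt(abs(best_half$pos_cM - best$pos_cM), 1)
})

test_that("the scan-stage per-sex estimates recover the simulated effect", {
  bg <- select_background_markers(pop, n_perm = 150, seed = 3)
  sc <- scan_main(pop, bg, step_cM = 1, n_perm = 150, seed = 4)
  best <- sc$detected[which.max(sc$detected$F), ]
  # a = 4 with no sex interaction: both per-sex additive estimates near 4
  expect_equal(unname((best$a1 + best$a2) / 2), 4, tolerance = 0.35)
})

test_that("model variants differ only through the probability backend", {
  cfg <- silkworm_scenario(n = 150)
  spop <- simulate_f2(cfg, seed = 2)
  bg <- select_background_markers(spop, n_perm = 100, seed = 71)
  m_ach <- scan_main(spop, bg, design = "achiasmate", step_cM = 2,
                     n_perm = 100, seed = 72)
  m_chi <- scan_main(spop, bg, design = "chiasmate", step_cM = 2,
                     n_perm = 100, seed = 72)
  m_ach2 <- scan_main(spop, bg, design = "achiasmate", step_cM = 2,
                      n_perm = 100, seed = 72)
  # same backend: bitwise identical; different backend: different profile
  expect_identical(m_ach$profile, m_ach2$profile)
  expect_false(isTRUE(all.equal(m_ach$profile$F, m_chi$profile$F)))
  # the variant-I pipeline reproduces the achiasmate-backend scan exactly
  res1 <- map_qtl(spop, "I", step_cM = 2, n_perm = 100, seed = 10, fit = FALSE)
  sd2 <- (10 * 7 + 2) %% .Machine$integer.max
  bg1 <- select_background_markers(spop, n_perm = 100,
                                   seed = (10 * 7 + 1) %% .Machine$integer.max)
  again <- scan_main(spop, bg1, design = "achiasmate", step_cM = 2,
                     n_perm = 100, seed = sd2)
  expect_identical(res1$main$profile, again$profile)
})

test_that("interval-pair enumeration and the epistasis scan behave structurally", {
  map1 <- grid_map(1, 3, 10)  # single chromosome, 2 intervals -> 1 pair
  qtls <- data.frame(id = "Q", chrom = "C1", pos_cM = 5, a = 3, d = 0)
  cfg <- scenario_config(map1, qtls, n = 120, var_e = 2)
  p1 <- simulate_f2(cfg, seed = 6)
  bg <- select_background_markers(p1, n_perm = 100, seed = 5)
  pr <- select_interval_pairs(p1, bg, n_perm = 100, seed = 5)
  expect_equal(nrow(pr$pairs), 1L)
  # variant III skips the epistasis stages entirely
  res3 <- map_qtl(p1, "III", step_cM = 2, n_perm = 100, seed = 8, fit = FALSE)
  expect_null(res3$pairs)
  expect_null(res3$epistasis)
})

test_that("the full-model design has the documented block structure", {
  main <- list(detected = data.frame(chrom = c("C1", "C2"), pos_cM = c(23, 31),
                                     interval = c(3, 9), F = c(20, 15),
                                     grid_row = c(1, 2)))
  epi <- list(detected = data.frame(pair = 1, chrom_i = "C1", pos_i = 23,
                                    chrom_j = "C2", pos_j = 31, F = 9))
  dm <- assemble_full_model(pop, main, epi)
  expect_equal(ncol(dm$X), 1 + 2 * 2 + 4)  # mu + (a,d) per QTL + 4 epistasis
  expect_equal(names(dm$U_list),
               c("S", "AS", "DS", "AAS", "ADS", "DAS", "DDS"))
  expect_equal(ncol(dm$U_list$AS), 4)  # 2 QTLs x 2 sexes
  expect_equal(ncol(dm$U_list$AAS), 2)  # 1 pair x 2 sexes
  # zero detections: mean + sex-only model
  dm0 <- assemble_full_model(pop, list(detected = NULL), NULL)
  expect_equal(colnames(dm0$X), "mu")
  expect_equal(names(dm0$U_list), "S")
})

test_that("stepwise elimination protects the strongest term", {
  set.seed(30)
  n <- 100
  X0 <- matrix(1, n, 1)
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, 0, 0.05); x3 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  terms <- list(cbind(x1), cbind(x2), cbind(x3))
  Fm <- vapply(terms, function(Tm) partial_f(y, cbind(X0, Tm), X0)$F, numeric(1))
  keep <- silkqtl:::stepwise_eliminate(y, X0, terms, threshold = 4, marginal_F = Fm)
  expect_true(which.max(Fm) %in% keep)      # the real signal survives
  expect_false(all(c(1, 2) %in% keep))      # its collinear ghost is removed
})
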