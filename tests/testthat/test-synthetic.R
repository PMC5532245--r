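test_that("transition matrices are validated as row-stochastic", {
  expect_silent(transition_matrix(diag(14)))
  bad <- diag(14); bad[2, 1] <- 0.1
  expect_error(transition_matrix(bad), "sum to 1")
  bad2 <- diag(14); bad2[2, 1] <- -0.1; bad2[2, 2] <- 1.1
  expect_error(transition_matrix(bad2), "non-negative")
  expect_error(transition_matrix(diag(5)), "14 x 14")
})

test_that("initial grids are deterministic and match the mixture", {
  scn1 <- scenario(20, 20, mixture = c(`2` = 1))
  g <- gen_initial_grid(scn1, seed = 4)
  expect_true(all(g$codes == 2L))
  # same seed twice -> identical grids; different seed -> different
  scn <- scenario(100, 100, mixture = c(`2` = 0.5, `6` = 0.5))
  ga <- gen_initial_grid(scn, seed = 10)
  gb <- gen_initial_grid(scn, seed = 10)
  gc2 <- gen_initial_grid(scn, seed = 11)
  expect_identical(ga$codes, gb$codes)
  expect_false(identical(ga$codes, gc2$codes))
  # iid cells at patchiness 1: share within 3 binomial SE of the mixture
  share <- mean(ga$codes == 2L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(share - 0.5), 3 * se)
  expect_error(scenario(0, 5, mixture = c(`2` = 1)), "degenerate")
  expect_error(scenario(5, 5, mixture = c(`2` = 0.7)), "sum to 1")
})

test_that("patchy grids have contiguous structure but unbiased class shares", {
  scn <- scenario(80, 80, mixture = c(`2` = 0.5, `6` = 0.5), patchiness = 5)
  g <- gen_initial_grid(scn, seed = 2)
  expect_true(all(g$codes %in% c(2L, 6L)))
  # neighbouring cells agree far more often than the 50% iid baseline
  agree <- mean(g$codes[-1, ] == g$codes[-80, ])
  expect_gt(agree, 0.7)
  # share within 3 SE, binomial over nuclei (one per patchiness^2 cells)
  m <- round(80 * 80 / 25)
  expect_lt(abs(mean(g$codes == 2L) - 0.5), 3 * sqrt(0.25 / m))
})

test_that("advance_epoch redraws cells per the transition matrix", {
  scn <- scenario(100, 100, mixture = c(`2` = 1))
  g <- gen_initial_grid(scn, seed = 1)
  # identity leaves the grid unchanged
  g_id <- advance_epoch(g, transition_matrix(diag(14)), seed = 8)
  expect_identical(g_id$codes, g$codes)
  # a certain transition applies everywhere
  tm1 <- diag(14); tm1[2, 2] <- 0; tm1[2, 1] <- 1
  expect_true(all(advance_epoch(g, tm1, seed = 8)$codes == 1L))
  # P(2->1) = 0.1 over 10,000 class-2 cells: count within 3 binomial SE
  tmp <- diag(14); tmp[2, 2] <- 0.9; tmp[2, 1] <- 0.1
  moved <- sum(advance_epoch(g, tmp, seed = 9)$codes == 1L)
  expect_lt(abs(moved - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  # nodata untouched
  codes <- g$codes; codes[1:10] <- 0L
  gn <- land_cover_grid(codes, 1)
  expect_true(all(advance_epoch(gn, tm1, seed = 2)$codes[1:10] == 0L))
  bad <- diag(14); bad[3, 3] <- 0.5
  expect_error(advance_epoch(g, bad, seed = 1), "sum to 1")
})

test_that("recover_transitions inverts the generating matrix within 3 SE", {
  scn <- scenario(200, 200, mixture = c(`2` = 0.4, `5` = 0.2, `6` = 0.4),
                  patchiness = 1)
  g0 <- gen_initial_grid(scn, seed = 21)
  tm <- diag(14)
  tm[2, 2] <- 0.93; tm[2, 1] <- 0.05; tm[2, 6] <- 0.02
  tm[5, 5] <- 0.96; tm[5, 6] <- 0.04
  g1 <- advance_epoch(g0, transition_matrix(tm), seed = 22)
  est <- recover_transitions(g0, g1)
  n_by <- table(factor(g0$codes, levels = 1:14))
  for (i in c(2, 5, 6)) {
    for (j in 1:14) {
      se <- sqrt(tm[i, j] * (1 - tm[i, j]) / as.numeric(n_by[i]))
      expect_lt(abs(est[i, j] - tm[i, j]), max(3 * se, 1e-12))
    }
  }
  # rows with no source cells are absent (NA), not zero
  expect_true(all(is.na(est[11, ])))
  # identity process recovers the identity exactly
  est_id <- recover_transitions(g0, g0)
  expect_equal(unname(diag(est_id)[c(2, 5, 6)]), c(1, 1, 1))
})

test_that("soil samples are deterministic and follow per-cover distributions", {
  scn <- scenario(60, 60, mixture = c(`2` = 0.5, `6` = 0.5))
  g <- gen_initial_grid(scn, seed = 31)
  s1 <- gen_soil_samples(g, 2000, seed = 32)
  s2 <- gen_soil_samples(g, 2000, seed = 32)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # tree-covered soils carry more carbon than cropped soils (defaults)
  med <- tapply(s1$soc_g_per_kg, s1$cover, median)
  expect_gt(med[["6"]], med[["2"]])
  # and are more acidic
  mph <- tapply(s1$ph, s1$cover, median)
  expect_lt(mph[["6"]], mph[["2"]])
  # samples sit on cells of their recorded cover
  idx <- cbind(s1$row, s1$col)
  expect_equal(g$codes[idx], s1$cover)
  # zero-variance parameters collapse each cover to a point
  p0 <- default_cover_params()
  p0$soc_sdlog <- 1e-12; p0$ph_sd <- 1e-12; p0$peat_prob <- 0
  s0 <- gen_soil_samples(g, 50, params = p0, seed = 1)
  expect_lt(max(tapply(s0$soc_g_per_kg, s0$cover, sd), na.rm = TRUE), 1e-6)
  expect_error(gen_soil_samples(g, 60 * 60 + 1, seed = 1), "exceeds")
})

test_that("simulated extent accounts recover expected net change within 3 SE", {
  scn <- eu25_toy_scenario(nrow = 120, ncol = 120, n_samples = 100)
  sim <- simulate_scenario(scn, seed = 51)
  g0 <- sim$grids[[1]]; g1 <- sim$grids[[2]]
  acct <- as.data.frame(build_extent_account(change_matrix(g0, g1)))
  n0 <- as.numeric(table(factor(g0$codes, levels = 1:14)))
  tm <- unclass(scn$transition)
  expected_net <- as.numeric(n0 %*% tm) - n0
  se_net <- sqrt(colSums(n0 * tm * (1 - tm)))
  net <- ifelse(is.na(acct$closing), 0, acct$closing - acct$opening)
  for (j in which(n0 > 0 | expected_net != 0)) {
    expect_lt(abs(net[j] - expected_net[j]), max(3 * se_net[j], 1e-9))
  }
})

test_that("whole-scenario simulation is a pure function of (scenario, seed)", {
  scn <- eu25_toy_scenario(nrow = 40, ncol = 40, n_samples = 50)
  a <- simulate_scenario(scn, seed = 77)
  b <- simulate_scenario(scn, seed = 77)
  expect_identical(lapply(a$grids, `[[`, "codes"),
                   lapply(b$grids, `[[`, "codes"))
  expect_identical(as.data.frame(a$samples), as.data.frame(b$samples))
  # the generators leave the session RNG stream alone
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_scenario(scn, seed = 77))
  expect_identical(runif(1), before)
})
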