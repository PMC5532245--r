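test_that("peat mask uses strict exceedance of the probability threshold", {
  pg <- matrix(c(0.40, 0.35, 0.351, 0, 1, 0.2), 2, 3)
  m <- peat_mask(pg)
  expect_equal(m, matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 2, 3))
  expect_false(any(peat_mask(matrix(0, 3, 3))))
  expect_error(peat_mask(matrix(c(0.5, 1.2), 1, 2)), "\\[0, 1\\]")
  expect_true(peat_mask(matrix(0.36, 1, 1), threshold = 0.35)[1])
})

test_that("SOC classification honours thresholds and peat precedence", {
  # boundary battery: g/kg inputs, percent thresholds at 120 and 30 g/kg
  cases <- data.frame(
    soc = c(150, 121, 120.0001, 120, 119.9, 30.1, 30, 29.9, 25, 0),
    want = c("organo_mineral", "organo_mineral", "organo_mineral",
             "humus_mineral", "humus_mineral", "humus_mineral",
             "humus_mineral", "mineral", "mineral", "mineral"))
  expect_equal(as.character(classify_soc(cases$soc)), cases$want)
  # peat flag overrides any concentration
  expect_equal(as.character(classify_soc(c(25, 500), peat = TRUE)),
               c("peat", "peat"))
  expect_error(classify_soc(-1), "non-negative")
})

test_that("pH bins are lower-inclusive with a closed 7-8.3 top", {
  cases <- data.frame(
    ph = c(4.2, 4.4999, 4.5, 4.99, 5, 5.99, 6, 6.5, 6.99, 7, 8.3,
           8.3001, 13.9, 0.1),
    want = c("<4.5", "<4.5", "4.5-5", "4.5-5", "5-6", "5-6", "6-7",
             "6-7", "6-7", "7-8.3", "7-8.3", ">8.3", ">8.3", "<4.5"))
  expect_equal(as.character(classify_ph(cases$ph)), cases$want)
  expect_error(classify_ph(0), "between 0 and 14")
  expect_error(classify_ph(14), "between 0 and 14")
})

test_that("classes partition any sample set and SOC is monotone in carbon", {
  set.seed(99)
  n <- 10000
  soc <- rlnorm(n, log(30), 1.2)
  ph <- runif(n, 0.5, 13.5)
  peat <- runif(n) < 0.1
  ks <- classify_soc(soc, peat)
  kp <- classify_ph(ph)
  expect_equal(sum(table(ks)), n)     # every sample in exactly one class
  expect_equal(sum(table(kp)), n)
  expect_false(anyNA(ks)); expect_false(anyNA(kp))
  # monotonicity: more carbon never yields a lower-carbon class
  rank_of <- c(mineral = 1, humus_mineral = 2, organo_mineral = 3)
  s <- sort(rlnorm(2000, log(40), 1.5))
  r <- rank_of[as.character(classify_soc(s, peat = FALSE))]
  expect_true(all(diff(r) >= 0))
})

test_that("condition cross-tab splits area proportionally and conserves it", {
  s <- soil_samples(data.frame(
    sample_id = 1:4, row = 1, col = 1:4, cover = 2,
    soc_g_per_kg = c(10, 15, 60, 20), ph = 6,
    peat = c(FALSE, FALSE, FALSE, TRUE)))
  tab <- condition_crosstab(s, c(`2` = 100), "soc")
  expect_equal(tab["2", "mineral"], 50)
  expect_equal(tab["2", "humus_mineral"], 25)
  expect_equal(tab["2", "peat"], 25)
  expect_equal(tab["2", "organo_mineral"], 0)
  # all samples one class -> full area there
  s1 <- soil_samples(data.frame(sample_id = 1:3, row = 1, col = 1:3,
                                cover = 6, soc_g_per_kg = 150, ph = 5,
                                peat = FALSE))
  t1 <- condition_crosstab(s1, c(`6` = 42), "soc")
  expect_equal(t1["6", "organo_mineral"], 42)
})

test_that("two-cover cross-tab matches a hand-computed proportional table", {
  s <- soil_samples(data.frame(
    sample_id = 1:10, row = 1, col = 1:10,
    cover = c(rep(2, 6), rep(6, 4)),
    soc_g_per_kg = c(10, 20, 35, 35, 150, 10, 60, 130, 140, 25),
    ph = c(6.5, 7.2, 5.1, 6.1, 4.4, 8.5, 4.7, 5.2, 4.9, 6.0),
    peat = FALSE))
  areas <- c(`2` = 600, `6` = 200)
  soc_tab <- condition_crosstab(s, areas, "soc")
  # cover 2: 3/6 mineral, 2/6 humus, 1/6 organo
  expect_equal(unname(soc_tab["2", c("mineral", "humus_mineral",
                                     "organo_mineral", "peat")]),
               c(300, 200, 100, 0))
  # cover 6: 1/4 humus (60), 2/4 organo, 1/4 mineral (25)
  expect_equal(unname(soc_tab["6", c("mineral", "humus_mineral",
                                     "organo_mineral", "peat")]),
               c(50, 50, 100, 0))
  ph_tab <- condition_crosstab(s, areas, "ph")
  expect_equal(unname(rowSums(ph_tab)), unname(areas[rownames(ph_tab)]))
  expect_equal(ph_tab["2", "<4.5"], 100)
  expect_equal(ph_tab["6", "4.5-5"], 100)
  # area conservation to relative 1e-9
  expect_lt(max(abs(rowSums(soc_tab) - areas[rownames(soc_tab)]) /
                  areas[rownames(soc_tab)]), 1e-9)
})

test_that("a cover with area but no samples is an error naming the cover", {
  s <- soil_samples(data.frame(sample_id = 1, row = 1, col = 1, cover = 2,
                               soc_g_per_kg = 10, ph = 6, peat = FALSE))
  expect_error(condition_crosstab(s, c(`2` = 10, `6` = 5), "soc"), "6")
})

test_that("change cross-tab assigns nearest sample, lowest id on ties", {
  g0 <- land_cover_grid(matrix(2L, 5, 5), 0.01, "2000")
  b <- g0$codes; b[1, 1] <- 1L; b[5, 5] <- 1L; b[3, 3] <- 6L; b[2, 4] <- 1L
  g1 <- land_cover_grid(b, 0.01, "2006")
  s <- soil_samples(data.frame(
    sample_id = 1:3, row = c(1, 5, 3), col = c(2, 4, 3),
    cover = 2, soc_g_per_kg = c(10, 60, 150), ph = 6,
    peat = FALSE))
  got <- as.data.frame(change_condition_crosstab(s, g0, g1, "soc"))
  oracle <- brute_nearest_condition(s, g0, g1, "soc")
  got <- got[order(got$from, got$to, as.character(got$condition)), ]
  expect_equal(got$area_ha, oracle$area_ha)
  expect_equal(as.character(got$condition), oracle$condition)
  # no change -> empty table
  empty <- change_condition_crosstab(s, g0, g0, "soc")
  expect_equal(nrow(empty), 0)
  # single changed cell, single sample
  b1 <- g0$codes; b1[2, 2] <- 1L
  one <- as.data.frame(change_condition_crosstab(
    s[1, ], g0, land_cover_grid(b1, 0.01), "soc"))
  expect_equal(one,
               data.frame(from = 2L, to = 1L,
                          condition = factor("mineral",
                                             levels = soc_classes()),
                          area_ha = 1),
               ignore_attr = TRUE)
})

test_that("change cross-tab equals the exhaustive oracle on random cases", {
  set.seed(5)
  for (trial in 1:20) {
    g0 <- random_seea_grid(5, 5, classes = c(1, 2, 6), cell_area = 0.01)
    g1 <- random_seea_grid(5, 5, classes = c(1, 2, 6), cell_area = 0.01)
    ns <- sample(1:6, 1)
    s <- soil_samples(data.frame(
      sample_id = seq_len(ns), row = sample(1:5, ns, TRUE),
      col = sample(1:5, ns, TRUE), cover = 2,
      soc_g_per_kg = rlnorm(ns, log(40), 1), ph = runif(ns, 4, 8),
      peat = runif(ns) < 0.2))
    for (cl in c("soc", "ph")) {
      got <- as.data.frame(change_condition_crosstab(s, g0, g1, cl))
      got <- got[order(got$from, got$to, as.character(got$condition)), ]
      oracle <- brute_nearest_condition(s, g0, g1, cl)
      oracle <- oracle[order(oracle$from, oracle$to, oracle$condition), ]
      expect_equal(got$area_ha, oracle$area_ha)
      expect_equal(as.character(got$condition), oracle$condition)
      expect_equal(got$from, oracle$from)
      expect_equal(got$to, oracle$to)
    }
  }
})

test_that("marginals of the change cross-tab sum to the changed area", {
  set.seed(6)
  g0 <- random_seea_grid(10, 10, classes = c(2, 5, 6), cell_area = 0.01)
  g1 <- random_seea_grid(10, 10, classes = c(2, 5, 6), cell_area = 0.01)
  s <- soil_samples(data.frame(sample_id = 1:5, row = sample(1:10, 5),
                               col = sample(1:10, 5), cover = 2,
                               soc_g_per_kg = c(10, 40, 130, 200, 20),
                               ph = c(4, 5.5, 6.5, 7.5, 9),
                               peat = FALSE))
  x <- change_condition_crosstab(s, g0, g1, "ph")
  marg <- change_crosstab_marginals(x)
  changed_ha <- sum(g0$codes != g1$codes & g0$codes != 0L) * 1
  expect_equal(sum(marg$condition), changed_ha)
  expect_equal(sum(marg$origin), changed_ha)
  expect_equal(sum(marg$destination), changed_ha)
})

test_that("sample tables validate and round-trip through CSV", {
  s <- soil_samples(data.frame(sample_id = 1:3, row = 1:3, col = 3:1,
                               cover = c(2, 6, 9),
                               soc_g_per_kg = c(12.5, 48.2, 250),
                               ph = c(6.1, 4.8, 5.5),
                               peat = c(0, 0, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_soil_samples(s, path, comment = "test")
  s2 <- read_soil_samples(path)
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_error(soil_samples(data.frame(sample_id = 1, row = 1, col = 1,
                                       cover = 2, soc_g_per_kg = -3,
                                       ph = 6, peat = 0)), "soc")
  expect_error(soil_samples(data.frame(sample_id = c(1, 1), row = 1, col = 1,
                                       cover = 2, soc_g_per_kg = 3,
                                       ph = 6, peat = 0)), "duplicate")
  expect_error(soil_samples(data.frame(sample_id = 1, row = 1, col = 1,
                                       cover = 2, soc_g_per_kg = 3,
                                       peat = 0)), "ph")
})
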