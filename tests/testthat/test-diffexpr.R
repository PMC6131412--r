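test_that("cpm follows its definition, including hand-set factors", {
  m <- matrix(c(10, 0, 90,
                20, 0, 180), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("A_1", "B_1")))
  x <- toy_counts(m)
  fac <- data.frame(sample = c("A_1", "B_1"), lib_size = c(100, 200),
                    factor = c(1, 1), eff_lib_size = c(1e7, 2e7))
  cc <- cpm(x, fac)
  expect_equal(cc["g1", "A_1"], 1.0)       # 10 / 1e7 * 1e6
  expect_equal(unname(cc["g2", ]), c(0, 0))

  fac2 <- data.frame(sample = c("A_1", "B_1"), lib_size = c(100, 200),
                     factor = c(0.8, 1.25),
                     eff_lib_size = c(100 * 0.8, 200 * 1.25))
  cc2 <- cpm(x, fac2)
  expect_equal(cc2, t(t(m) / c(80, 250)) * 1e6)

  fac2$eff_lib_size[1] <- 0
  expect_error(cpm(x, fac2), "zero")
})

test_that("filter_transcribed keeps group-mean CPM > 1 in either group", {
  # eff lib sizes 1e6 so CPM == count; group means: g1 (0,0), g2 (5,0),
  # g3 exactly (1,1), g4 (2,2)
  m <- matrix(c(0, 6, 1, 2,
                0, 4, 1, 2,
                0, 0, 1, 2,
                0, 0, 1, 2), ncol = 4,
              dimnames = list(paste0("g", 1:4),
                              c("A_1", "A_2", "B_1", "B_2")))
  x <- toy_counts(m)
  fac <- data.frame(sample = colnames(m), lib_size = colSums(m),
                    factor = 1, eff_lib_size = 1e6)
  kept <- filter_transcribed(x, fac, c("A", "B"))
  expect_false("g1" %in% kept)   # silent everywhere
  expect_true("g2" %in% kept)    # transcribed in A only
  expect_false("g3" %in% kept)   # boundary: mean CPM exactly 1, strict >
  expect_true("g4" %in% kept)
  expect_error(filter_transcribed(x, fac, c("A", "Z")), "unknown group")
})

test_that("TMM factors: symmetry, scale invariance, worked oracle, edgeR", {
  set.seed(101)
  m <- matrix(rnbinom(600, mu = 200, size = 2), ncol = 4)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- c("A_1", "A_2", "B_1", "B_2")
  x <- toy_counts(m)

  # identical samples: all factors 1
  mi <- m[, c(1, 1, 1, 1)]; colnames(mi) <- colnames(m)
  expect_equal(tmm_factors(toy_counts(mi))$factor, rep(1, 4))

  # doubling every count of one sample leaves M and A values (hence the trim
  # set) unchanged; only the precision weights shift slightly with depth, so
  # invariance is near-exact rather than exact
  f0 <- tmm_factors(x, ref = 1)
  m2 <- m; m2[, 3] <- m2[, 3] * 2L
  f2 <- tmm_factors(toy_counts(m2), ref = 1)
  expect_equal(f0$factor, f2$factor, tolerance = 0.05)

  # 6-gene 2-sample worked table against the step-by-step oracle
  w <- matrix(c(100, 200, 300, 400, 500, 1000,
                200, 200, 350, 300, 700, 2200), ncol = 2,
              dimnames = list(paste0("g", 1:6), c("A_1", "B_1")))
  fw <- tmm_factors(toy_counts(w), ref = 1)
  raw <- c(1, brute_tmm_pair(w[, 2], w[, 1]))
  expect_equal(fw$factor, raw / exp(mean(log(raw))), tolerance = 1e-10)

  # geometric mean exactly 1
  expect_equal(exp(mean(log(tmm_factors(x)$factor))), 1, tolerance = 1e-8)

  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(tmm_factors(x)$factor, unname(fe), tolerance = 1e-8)
  m3 <- m; m3[sample(length(m3), 150)] <- 0L
  fe3 <- edgeR::calcNormFactors(m3, method = "TMM")
  expect_equal(tmm_factors(toy_counts(m3))$factor, unname(fe3),
               tolerance = 1e-8)
})

test_that("dispersion estimation recovers simulated values", {
  set.seed(7)
  # Poisson data: common estimate near zero
  mp <- matrix(rpois(500 * 12, lambda = 100), ncol = 12)
  rownames(mp) <- paste0("g", 1:500)
  colnames(mp) <- paste0(rep(c("A", "B"), each = 6), "_", 1:6)
  xp <- toy_counts(mp)
  dp <- estimate_dispersion(xp, unit_factors(xp))
  expect_lt(dp$common, 0.05)

  # NB dispersion 0.4
  mn <- matrix(rnbinom(1000 * 12, mu = 150, size = 1 / 0.4), ncol = 12)
  dimnames(mn) <- list(paste0("g", 1:1000),
                       paste0(rep(c("A", "B"), each = 6), "_", 1:6))
  xn <- toy_counts(mn)
  dn <- estimate_dispersion(xn, unit_factors(xn))
  expect_gt(dn$common, 0.3)
  expect_lt(dn$common, 0.5)

  # a zero-variance gene shrinks to near the floor
  mz <- rbind(mp[1:200, ], gconst = rep(80L, 12))
  xz <- toy_counts(mz)
  dz <- estimate_dispersion(xz, unit_factors(xz))
  expect_lt(dz$tagwise["gconst"], 0.01)

  # single replicate everywhere: instructive error
  m1 <- mp[, c(1, 7)]
  expect_error(estimate_dispersion(toy_counts(m1), unit_factors(toy_counts(m1))),
               "fixed dispersion")
})

test_that("test_dt classifies a strong injected effect with the right sign", {
  set.seed(21)
  mu <- matrix(200, 50, 12)
  mu[1:5, 7:12] <- 200 * 8    # logFC = +3 in the test group
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), 50, 12)
  dimnames(m) <- list(paste0("g", 1:50),
                      paste0(rep(c("A", "B"), each = 6), "_", 1:6))
  x <- toy_counts(m)
  fac <- unit_factors(x)
  dt <- test_dt(x, fac, 0.05, "A", "B")
  expect_true(all(dt$class[1:5] == "up"))
  expect_true(all(dt$logfc[1:5] > 2))
  expect_equal(sort(unique(dt$class)), sort(intersect(
    c("up", "down", "not_DT"), dt$class)))
  # class partition: every tested gene gets exactly one class
  expect_equal(sum(dt$class %in% c("up", "down", "not_DT")), nrow(dt))
  # q >= p always
  expect_true(all(dt$qvalue >= dt$pvalue - 1e-12))
})

test_that("bh_adjust matches the hand case, a brute oracle and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(33)
  for (n in c(1, 2, 7, 40, 100)) {
    p <- round(runif(n), 3)   # rounding forces ties
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
})

test_that("fpkm follows its definition and length scaling", {
  m <- matrix(c(100, 100, 0), ncol = 1,
              dimnames = list(c("g1", "g2", "g3"), "A_1"))
  x <- count_matrix(m, data.frame(sample = "A_1", group = "A",
                                  replicate = 1))
  fac <- data.frame(sample = "A_1", lib_size = 200, factor = 1,
                    eff_lib_size = 1e7)
  fk <- fpkm(x, fac, c(g1 = 1000, g2 = 2000, g3 = 1500))
  expect_equal(fk["g1", 1], 10.0)   # 100 * 1e9 / (1e7 * 1000)
  expect_equal(fk["g1", 1] / fk["g2", 1], 2)
  expect_equal(fk["g3", 1], 0)
  expect_error(fpkm(x, fac, c(g1 = 1000, g2 = 2000)), "g3")
})

test_that("contrast summaries partition transcribed genes", {
  s <- contrast_summary(200, 30, 20)
  expect_equal(s$count[s$category == "not_DT"] +
               s$count[s$category == "DT"], 200)
  expect_equal(s$count[s$category == "up"] + s$count[s$category == "down"],
               s$count[s$category == "DT"])
  s0 <- contrast_summary(50, 0, 0)
  expect_equal(s0$pct[s0$category == "DT"], 0)
  expect_equal(s0$pct[s0$category == "not_DT"], 100)
  expect_error(contrast_summary(10, 6, 5), "exceeds")

  rec <- data.frame(gene_id = paste0("g", 1:10),
                    class = c(rep("up", 2), rep("down", 3), rep("not_DT", 5)))
  expect_equal(summarize_contrast(rec)$count, c(10, 5, 5, 2, 3))
})

test_that("count_silenced requires exact zeros in every replicate", {
  fk <- matrix(c(0, 0, 0,
                 0, 0.2, 0,
                 5, 6, 7), ncol = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"),
                               c("A_1", "A_2", "A_3")))
  samples <- data.frame(sample = colnames(fk), group = "A", replicate = 1:3)
  expect_equal(count_silenced(fk, samples, "A"), "g1")
  expect_error(count_silenced(fk, samples, "B"), "empty group")
})

test_that("expression bins use half-open intervals with a detection floor", {
  b <- expression_bins(c(0, 0.5, 1, 3, 5, 19.9, 20, 1360))
  expect_equal(as.character(b[1:2]), rep("not detectable", 2))
  expect_equal(as.character(b[3:4]), rep("1-5", 2))
  expect_equal(as.character(b[5]), "5-20")    # boundary leaves the 1-5 bin
  expect_equal(as.character(b[7:8]), rep(">=20", 2))
  expect_error(expression_bins(1, edges = c(5, 1)), "increasing")
})
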