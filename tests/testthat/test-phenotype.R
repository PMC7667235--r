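mkCurve <- function(ci, a, ca = ci / 0.33) {
  aciCurve(ca = ca, ci = ci, a = a, gs = rep(0.1, length(ci)))
}

test_that("initial slope is exact OLS on the low-Ci points", {
  crv <- mkCurve(ci = c(20, 50, 80, 300, 600), a = c(0.9, 2.4, 3.9, 20, 30))
  fit <- fitInitialSlope(crv)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.1, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
  expect_equal(estimateGamma(crv)$gamma, 2.0, tolerance = 1e-9)
  # one qualifying point is not a fit
  crv1 <- mkCurve(ci = c(50, 150, 300, 600), a = c(2, 10, 20, 30))
  expect_error(fitInitialSlope(crv1), "at least 2")
})

test_that("gamma floors at zero when A extrapolates positive at Ci 0", {
  crv <- mkCurve(ci = c(20, 50, 80, 300), a = c(2, 3.5, 5, 20))
  g <- estimateGamma(crv)
  expect_equal(g$gamma, 0)
  expect_true(g$floored)
})

test_that("parameter recovery: noiseless exact, noisy unbiased over 200 seeds", {
  crv <- simulateAciCurve(slope = 0.36, gamma = 2.5, a_max = 30.5,
                          noise_sd = 0)
  expect_equal(fitInitialSlope(crv)$slope, 0.36, tolerance = 1e-6 * 0.36)
  expect_equal(estimateGamma(crv)$gamma, 2.5, tolerance = 1e-6 * 2.5)
  slopes <- vapply(1:200, function(s) {
    fitInitialSlope(simulateAciCurve(slope = 0.25, gamma = 4.5, a_max = 31.3,
                                     noise_sd = 0.5, seed = s))$slope
  }, 0)
  expect_lt(abs(mean(slopes) - 0.25) / 0.25, 0.02)
})

test_that("point metrics derive the gas-exchange table arithmetic", {
  # Ca steps at 400 and 1200 plus a low-Ci limb with slope 0.05
  ci <- c(20, 50, 80, 132, 396)
  ca <- c(60, 150, 242, 400, 1200)
  a <- c(0.9, 2.4, 3.9, 7.0, 23.5)
  crv <- aciCurve(ca = ca, ci = ci, a = a, gs = c(0.1, 0.1, 0.1, 0.07, 0.05))
  m <- pointMetrics(crv)
  expect_equal(m$a_ratio, 7.0 / 23.5)
  expect_equal(round(m$a_ratio, 2), 0.30)
  expect_equal(m$norm_ce, m$initial_slope / m$a1200)   # identity holds exactly
  expect_equal(m$wue, 7.0 / 0.07)
  expect_equal(m$ci_ca, 132 / 400)
  expect_equal(m$a_ratio * m$a1200, m$a400)
  # missing 1200 step is an error
  crv2 <- mkCurve(ci = c(20, 50, 80, 132), a = c(0.9, 2.4, 3.9, 7),
                  ca = c(60, 150, 242, 400))
  expect_error(pointMetrics(crv2), "1200")
  # a400 == a1200 gives ratio 1
  crv3 <- aciCurve(ca = c(50, 100, 400, 1200), ci = c(16, 33, 132, 396),
                   a = c(1, 2, 25, 25), gs = rep(0.1, 4))
  expect_equal(pointMetrics(crv3)$a_ratio, 1)
})

test_that("chlorophyll equations match hand arithmetic and scale linearly", {
  out <- chlorophyllFromAbsorbance(a645 = 0.3, a663 = 0.8,
                                   dilution_l_per_m2 = 25)
  expect_equal(out$chl_a_mg_l, 9.353)
  expect_equal(out$chl_b_mg_l, 3.126)
  expect_equal(out$ab_ratio, (9.353 / 893.5) / (3.126 / 907.5))
  expect_equal(round(out$ab_ratio, 2), 3.04)
  zero <- chlorophyllFromAbsorbance(0, 0, 1)
  expect_equal(zero$total_mmol_m2, 0)
  dbl <- chlorophyllFromAbsorbance(0.6, 1.6, 25)
  expect_equal(dbl$chl_a_mg_l, 2 * out$chl_a_mg_l)
  expect_equal(dbl$ab_ratio, out$ab_ratio)
  expect_error(chlorophyllFromAbsorbance(a645 = 0.8, a663 = 0.1, 1), "swapped")
})

test_that("A340 slope converts to leaf-area activity with volume scaling", {
  act <- activityFromA340(0.373, extract_vol_ml = 1, assay_vol_ml = 1,
                          aliquot_ml = 1, leaf_area_cm2 = 1)
  expect_equal(act, 0.373 / 6.22 / 1e-4 / 60, tolerance = 1e-12)
  expect_equal(round(act, 3), 9.995)
  expect_equal(activityFromA340(0, 1, 1, 1, 1), 0)
  half <- activityFromA340(0.373, 1, 1, 2, 1)       # doubled aliquot halves it
  expect_equal(half, act / 2)
  expect_error(activityFromA340(0.3, 1, 1, 1, 0), "leaf area")
})

test_that("subtype calls follow the dominant decarboxylase with robustness", {
  b <- enzymePanel(pepc = 111.8, nadp_me = 50.1, nad_me = 2.1,
                   chlorophyll = 0.43)
  cb <- callSubtype(b, a400 = 23.0)
  expect_equal(cb$subtype, "NADP-ME")
  expect_true(cb$robust)
  a <- enzymePanel(pepc = 131.7, nadp_me = 0, nad_me = 27.7, chlorophyll = 0.30)
  ca <- callSubtype(a, a400 = 26.8)
  expect_equal(ca$subtype, "NAD-ME")
  expect_true(ca$robust)
  n <- enzymePanel(pepc = 15.1, nadp_me = 0, nad_me = 0, chlorophyll = 0.56)
  expect_equal(callSubtype(n, a400 = 7.0)$subtype, "none")
  # marginal activity: call stands but flagged
  m <- enzymePanel(pepc = 50, nadp_me = 15, nad_me = 1, chlorophyll = 0.4)
  cm <- callSubtype(m, a400 = 25)
  expect_equal(cm$subtype, "NADP-ME")
  expect_false(cm$robust)
  expect_true(cm$warning)
  # per-chlorophyll arithmetic
  expect_equal(unname(b$per_chl["pepc"]), 111.8 / 0.43, tolerance = 1e-9)
})

test_that("subtype agreement is perfect on clearly dominant generator panels", {
  set.seed(19)
  for (i in 1:25) {
    a400 <- runif(1, 15, 30)
    dominant <- runif(1, 1, 3) * a400
    minor <- runif(1, 0, 0.1) * a400
    truth <- sample(c("NADP-ME", "NAD-ME"), 1)
    p <- enzymePanel(pepc = 4 * a400,
                     nadp_me = if (truth == "NADP-ME") dominant else minor,
                     nad_me = if (truth == "NAD-ME") dominant else minor,
                     chlorophyll = runif(1, 0.25, 0.6))
    cc <- callSubtype(p, a400)
    expect_equal(cc$subtype, truth)
    expect_true(cc$robust)
  }
})

test_that("one-tailed Welch comparison is symmetric and direction-free", {
  expect_equal(oneTailedCompare(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(oneTailedCompare(c(2, 2), c(2, 2)), 0.5)   # degenerate variance
  p <- oneTailedCompare(c(1, 1.1, 0.9), c(5, 5.1, 4.9))
  expect_lt(p, 0.001)
  # Welch formula oracle
  a <- c(1, 1.1, 0.9); b <- c(5, 5.1, 4.9)
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(p, pt(tstat, df), tolerance = 1e-12)
  expect_equal(oneTailedCompare(b, a), p)                 # swap-invariant
})

test_that("ultrastructure summary computes coverage and Tukey letters", {
  set.seed(4)
  mk <- function(sp, mito_scale) do.call(rbind, lapply(1:3, function(p) {
    data.frame(species = sp, plant = paste0(sp, p), cell = 1:5,
               cell_area = 500 + rnorm(5, 0, 10),
               mito_scale = mito_scale)
  }))
  cells <- rbind(mk("big_mito", 3), mk("c3a", 1))
  orgs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    rbind(data.frame(plant = cells$plant[i], cell = cells$cell[i],
                     kind = "mitochondrion",
                     area = rnorm(10 * cells$mito_scale[i], 2, 0.1)),
          data.frame(plant = cells$plant[i], cell = cells$cell[i],
                     kind = "chloroplast", area = rnorm(8, 12, 0.5)))
  }))
  # c3b is measurement-for-measurement identical to c3a
  c3a_cells <- cells[cells$species == "c3a", ]
  c3b_cells <- transform(c3a_cells, species = "c3b",
                         plant = sub("c3a", "c3b", plant))
  c3a_orgs <- orgs[orgs$plant %in% c3a_cells$plant, ]
  c3b_orgs <- transform(c3a_orgs, plant = sub("c3a", "c3b", plant))
  cells <- rbind(cells, c3b_cells)
  orgs <- rbind(orgs, c3b_orgs)
  # constructed data have near-zero residuals on some metrics; the fitters
  # warn about perfect fits, which is expected here
  us <- suppressWarnings(ultrastructureSummary(cells[, 1:4], orgs))
  s <- us$species
  expect_true(all(s$pct_mitochondrion_mean >= 0 & s$pct_mitochondrion_mean <= 100))
  expect_true(all(s$pct_chloroplast_mean + s$pct_mitochondrion_mean <= 100))
  lt <- us$letters[us$letters$metric == "pct_mitochondrion", ]
  expect_false(lt[["big_mito"]] %in% c(lt[["c3a"]], lt[["c3b"]]))
  expect_equal(lt[["c3a"]], lt[["c3b"]])   # equivalent species share a letter
  # independent Tukey oracle agrees that only big_mito separates
  pp <- us$per_plant
  tuk <- TukeyHSD(aov(pct_mitochondrion ~ species,
                      data = transform(pp, species = factor(species))))$species
  sig <- rownames(tuk)[tuk[, "p adj"] < 0.05]
  expect_setequal(sig, c("c3a-big_mito", "c3b-big_mito"))
  # simple coverage arithmetic
  c1 <- data.frame(species = "s", plant = c("p1", "p2"), cell = 1,
                   cell_area = 100)
  o1 <- data.frame(plant = c("p1", "p1", "p2", "p2"), cell = 1,
                   kind = "chloroplast", area = c(10, 15, 10, 15))
  us1 <- ultrastructureSummary(c1, o1)
  expect_equal(us1$species$pct_chloroplast_mean, 25)
  # single plant per species: no letters
  us2 <- ultrastructureSummary(c1[1, ], o1[1:2, ])
  expect_null(us2$letters)
})
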