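test_that("exact k_obs points recover the generating line perfectly", {
  C_nM <- c(0.25, 0.5, 0.75, 1.0)
  pts <- tibble::tibble(
    bait = "PD-L2", channel = 0:3, experiment = 1L,
    concentration_nM = C_nM,
    k_obs = 1e6 * C_nM * 1e-9 + 1e-4, k_obs_sd = NA_real_
  )
  kin <- pool_kobs(pts, prey = "PD-1")
  expect_equal(kin$kon_bi, 1e6, tolerance = 1e-9)
  expect_equal(kin$koff_bi, 1e-4, tolerance = 1e-9)
  expect_equal(kin$r_squared, 1, tolerance = 1e-12)
  expect_equal(kin$kd_bi, kin$koff_bi / kin$kon_bi, tolerance = 1e-12)
})

test_that("two points give the exact line with flagged (NA) SEs", {
  pts <- tibble::tibble(bait = "X", channel = 0:1, experiment = 1L,
                        concentration_nM = c(0.5, 1),
                        k_obs = c(6e-4, 1.1e-3), k_obs_sd = NA_real_)
  kin <- pool_kobs(pts)
  expect_equal(kin$kon_bi, (1.1e-3 - 6e-4) / 0.5e-9, tolerance = 1e-9)
  expect_true(is.na(kin$se_kon) && is.na(kin$se_koff) && is.na(kin$se_kd))
})

test_that("pooling is invariant to point order and experiment partition", {
  set.seed(11)
  pts <- tibble::tibble(
    bait = "X", channel = rep(0:3, 3),
    experiment = rep(1:3, each = 4),
    concentration_nM = rep(c(1, 0.75, 0.5, 0.25), 3),
    k_obs = 1e6 * rep(c(1, 0.75, 0.5, 0.25), 3) * 1e-9 + 1e-4 +
      rnorm(12, 0, 5e-5),
    k_obs_sd = NA_real_
  )
  a <- pool_kobs(pts)
  b <- pool_kobs(pts[sample(12), ])
  c_ <- pool_kobs(dplyr::mutate(pts, experiment = 1L))
  expect_equal(a$kon_bi, b$kon_bi, tolerance = 1e-12)
  expect_equal(a$kon_bi, c_$kon_bi, tolerance = 1e-12)
  expect_equal(a$se_kon, b$se_kon, tolerance = 1e-12)
})

test_that("degenerate regressions raise the specific errors", {
  one_conc <- tibble::tibble(bait = "X", channel = 0:1, experiment = 1L,
                             concentration_nM = c(0.5, 0.5),
                             k_obs = c(6e-4, 6.2e-4), k_obs_sd = NA_real_)
  expect_error(pool_kobs(one_conc), "rank-deficiency")
  single <- one_conc[1, ]
  expect_error(pool_kobs(single), "insufficient-data")
  # negative intercept reported with warning, not clamped
  neg <- tibble::tibble(bait = "X", channel = 0:3, experiment = 1L,
                        concentration_nM = c(0.25, 0.5, 0.75, 1),
                        k_obs = c(0.5, 2, 3.5, 5) * 1e-4,
                        k_obs_sd = NA_real_)
  expect_warning(kin <- pool_kobs(neg), "negative fitted intercept")
  expect_lt(kin$koff_bi, 0)
})

test_that("avidity conversion: identity at valency 1, closed form at 2", {
  expect_equal(kd_monovalent(1e-10, c_eff = 0.27, valency = 1)$kd_mono_M,
               1e-10)
  mono <- kd_monovalent(1e-10, c_eff = 0.27, valency = 2)
  expect_equal(mono$kd_mono_M, sqrt(1e-10 * 0.27), tolerance = 1e-12)
  expect_equal(mono$kd_mono_uM, sqrt(2.7e-11) * 1e6, tolerance = 1e-12)
  # the magnitude lands in the micromolar range typical of these
  # low-affinity checkpoint interactions
  expect_gt(mono$kd_mono_uM, 1); expect_lt(mono$kd_mono_uM, 50)
  expect_error(kd_monovalent(-1e-10, c_eff = 0.27), "domain")
  expect_error(kd_monovalent(1e-10, c_eff = 0), "domain")
})

test_that("avidity conversion round-trips with its inverse", {
  for (v in 1:3) {
    kd_bi <- 3.2e-10
    mono <- kd_monovalent(kd_bi, c_eff = 0.1, valency = v)$kd_mono_M
    expect_equal(kd_bivalent_from_mono(mono, c_eff = 0.1, valency = v),
                 kd_bi, tolerance = 1e-12)
  }
})

test_that("kd_mono is strictly increasing in kd_bi and c_eff (v >= 2)", {
  kds <- c(1e-11, 1e-10, 1e-9)
  m1 <- vapply(kds, function(k)
    kd_monovalent(k, c_eff = 0.27, valency = 2)$kd_mono_M, numeric(1))
  expect_true(all(diff(m1) > 0))
  ceffs <- c(0.01, 0.1, 1)
  m2 <- vapply(ceffs, function(ce)
    kd_monovalent(1e-10, c_eff = ce, valency = 2)$kd_mono_M, numeric(1))
  expect_true(all(diff(m2) > 0))
})

test_that("valency sensitivity quantifies the binding-mode discrepancy", {
  tab <- valency_sensitivity(1e-10, c_eff = 0.27)
  expect_equal(nrow(tab), 3L)
  # kd_bi < c_eff: inferred kd_mono grows with assumed valency
  expect_true(all(diff(tab$kd_mono_M) > 0))
  # fixed point: c_eff = kd_bi makes all valencies agree
  fp <- valency_sensitivity(1e-10, c_eff = 1e-10)
  expect_equal(max(fp$kd_mono_M) / min(fp$kd_mono_M), 1, tolerance = 1e-10)
  # strong avidity: spread ratio exceeds 10 whenever kd_bi/c_eff < 1e-3
  for (ratio in c(1e-3 * 0.99, 1e-5, 1e-8)) {
    sp <- valency_sensitivity(ratio * 0.27, c_eff = 0.27)
    expect_gt(attr(sp, "spread_ratio"), 10)
  }
})

test_that("interaction report renders both orientations and N/A", {
  pts <- function(kon, koff) tibble::tibble(
    bait = "B", channel = 0:3, experiment = 1L,
    concentration_nM = c(0.25, 0.5, 0.75, 1),
    k_obs = kon * c(0.25, 0.5, 0.75, 1) * 1e-9 + koff, k_obs_sd = NA_real_)
  k1 <- pool_kobs(pts(1e6, 1e-4), prey = "A")
  k2 <- pool_kobs(pts(8e5, 2e-4), prey = "B")
  k2$bait <- "A"; k2$prey <- "B"
  rep_tab <- report_interactions(list(k1, k2), c_eff = 0.27)
  expect_equal(nrow(rep_tab), 2L)
  expect_equal(rep_tab$prey, c("A", "B"))
  expect_equal(rep_tab$bait, c("B", "A"))
  # micromolar formatting at 2 significant digits
  expect_equal(rep_tab$kd_mono_uM[1],
               as.character(signif(sqrt(1e-10 * 0.27) * 1e6, 2)))
  # missing conversions render as N/A
  rep_na <- report_interactions(list(k1), c_eff = NA_real_)
  expect_equal(rep_na$kd_mono_uM, "N/A")
})

test_that("tidy/glance/autoplot methods expose the regression", {
  pts <- tibble::tibble(bait = "X", channel = rep(0:3, 2),
                        experiment = rep(1:2, each = 4),
                        concentration_nM = rep(c(0.25, 0.5, 0.75, 1), 2),
                        k_obs = 1e6 * rep(c(0.25, 0.5, 0.75, 1), 2) * 1e-9 +
                          1e-4 + c(1:8) * 1e-6,
                        k_obs_sd = NA_real_)
  kin <- pool_kobs(pts)
  td <- tidy(kin)
  expect_equal(td$term, c("kon_bi", "koff_bi", "kd_bi"))
  gl <- glance(kin)
  expect_equal(gl$nobs, 8L)
  expect_equal(gl$n.experiments, 2L)
  expect_s3_class(autoplot(kin), "ggplot")
})
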