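test_that("percent viability is a linear normalization to the reference mean", {
  expect_equal(percent_viability(100, 100), 100)
  expect_equal(percent_viability(0, 100), 0)
  expect_equal(percent_viability(c(80, 100, 120), 100), c(80, 100, 120))
  expect_error(percent_viability(50, 0), "positive")
})

test_that("background level is the mean of at least two vehicle wells", {
  expect_equal(background_level(c(50, 70)), 60)
  expect_equal(background_level(c(0, 0)), 0)
  expect_error(background_level(55), "at least 2")
})

test_that("relative induction interpolates between background and reference", {
  expect_equal(relative_induction(60, 60, 1060), 0)
  expect_equal(relative_induction(1060, 60, 1060), 100)
  expect_equal(relative_induction(560, 60, 1060), 50)
  expect_error(relative_induction(100, 200, 150), "flat")
})

test_that("relative induction is invariant under an additive RLU offset", {
  set.seed(41)
  for (i in 1:25) {
    rlu <- runif(5, 0, 2000)
    bg <- runif(1, 10, 200)
    ref <- bg + runif(1, 100, 3000)
    shift <- runif(1, -50, 500)
    expect_equal(relative_induction(rlu + shift, bg + shift, ref + shift),
                 relative_induction(rlu, bg, ref))
  }
})

test_that("basal re-normalization scales and is idempotent on its own scale", {
  expect_equal(to_basal(40, 40), 100)
  expect_equal(to_basal(80, 40), 200)
  expect_equal(to_basal(to_basal(37, 52), 100), to_basal(37, 52))
  expect_error(to_basal(50, 0), "positive")
  expect_error(to_basal(50, 10, loq = 15), class = "h295calux_invalid_run")
})

test_that("CALUX concentrations use the mean fold dilution", {
  sch <- dilution_scheme()
  expect_equal(as.numeric(calux_concentration(1e-6, sch, "AR")),
               1e-6 / (200 / 67))
  expect_equal(as.numeric(calux_concentration(1e-6, c(8), "ER")), 0.125e-6)
  # arithmetic mean of per-plate folds, against brute-force averaging
  folds <- c(20 / 3, 50 / 7, 8)
  oracle <- 1e-6 / ((folds[1] + folds[2] + folds[3]) / 3)
  expect_equal(as.numeric(calux_concentration(1e-6, folds, "ER")), oracle,
               tolerance = 1e-12)
  expect_equal(round(oracle * 1e6, 4), 0.1376)
  # strictly monotone in the nominal concentration
  concs <- sort(runif(20, 1e-9, 1e-4))
  out <- as.numeric(calux_concentration(concs, sch, "ER"))
  expect_true(all(diff(out) > 0))
  expect_equal(attr(calux_concentration(1e-6, sch, "ER"),
                    "max_relative_error"), 0.23)
})

test_that("normalizing a noise-free plate set recovers the constructed scales", {
  sim <- noisefree_sim("inactive", n_bio = 1)
  norm <- normalize_plateset(sim$measurements)

  # vehicle wells sit at 100% of basal by construction
  veh <- norm[norm$role == "vehicle_control" & !is.na(norm$pct_of_basal), ]
  expect_true(all(abs(veh$pct_of_basal - 100) < 1e-9))

  # sham wells of an inactive chemical carry no signal: ER agonist-mode
  # %RI at 0, AR antagonist-mode %RI at its 100% reference
  sham_er <- norm[norm$endpoint == "direct_estrogenicity" &
                    is.na(norm$control), ]
  expect_true(all(abs(sham_er$pct_ri) < 1e-9))
  sham_ar <- norm[norm$endpoint == "direct_antiandrogenicity" &
                    is.na(norm$control), ]
  expect_true(all(abs(sham_ar$pct_ri - 100) < 1e-6))

  # an inactive chemical leaves steroidogenesis at basal
  tr <- norm[norm$role == "h295r_treated" &
               norm$endpoint %in% c("estrogen_activity",
                                    "androgen_activity"), ]
  expect_true(all(abs(tr$pct_of_basal - 100) < 1e-6))

  # viability of healthy wells is 100%
  hv <- norm[norm$endpoint == "h295r_viability" &
               norm$role == "h295r_treated", ]
  expect_true(all(abs(hv$pct_viability - 100) < 1e-9))

  # dilution-adjusted concentrations divide by the plate-family fold
  er_rows <- norm[norm$assay == "ER_CALUX" & !is.na(norm$conc_h295r), ]
  expect_equal(er_rows$conc_calux,
               er_rows$conc_h295r / mean(dilution_scheme()$er_fold))
})

test_that("an inhibitor's normalized activity tracks the constructed truth", {
  sim <- noisefree_sim("prochloraz_like", n_bio = 1)
  norm <- normalize_plateset(sim$measurements)
  tr <- norm[norm$role == "h295r_treated" &
               norm$endpoint == "estrogen_activity", ]
  m <- tapply(tr$pct_of_basal, tr$conc_h295r, mean)
  # monotone decreasing with concentration and far below basal at the top
  expect_true(all(diff(m[order(as.numeric(names(m)))]) < 0))
  expect_lt(min(m), 25)
})
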