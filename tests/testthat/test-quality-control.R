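test_that("LOQ follows the mean-plus-ten-SD rule", {
  v <- c(1, 2, 3)  # mean 2, sd 1
  expect_equal(loq(v), 12)
  expect_equal(loq(c(0, 0, 0)), 0)
  expect_error(loq(c(1, 2)), "at least 3")

  # mean 1, sd 2 -> 21, beyond the estrogen limit of 20
  v2 <- c(-1, 1, 3)
  expect_equal(loq(v2), 21)
  expect_false(qc_check("loq", loq(v2), qc_thresholds()$estrogens$loq_max,
                        "le")$pass)

  # translation equivariance: shifting all vehicle values shifts the LOQ
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(6, 3, 1)
    cc <- runif(1, -5, 5)
    expect_equal(loq(v + cc), loq(v) + cc)
  }
})

test_that("induction factor is the positive/negative mean ratio", {
  expect_equal(induction_factor(800, 100), 8)
  expect_equal(induction_factor(5, 5), 1)
  expect_equal(induction_factor(1700, 100), 17)
  expect_false(qc_check("if", 17, qc_thresholds()$androgens$if_min,
                        "ge")$pass)
  expect_error(induction_factor(100, 0), "positive")
})

test_that("Z-factor matches its formula and structural properties", {
  expect_equal(z_factor(100, 0, 0, 0), 1)
  expect_equal(z_factor(100, 5, 0, 5), 0.7)
  expect_equal(z_factor(100, 10, 0, 10), 0.4)
  expect_error(z_factor(50, 1, 50, 1), "equal")

  set.seed(7)
  for (i in 1:50) {
    mp <- runif(1, 0, 1000); mn <- runif(1, 0, 1000)
    if (mp == mn) next
    sp <- runif(1, 0, 100); sn <- runif(1, 0, 100)
    z <- z_factor(mp, sp, mn, sn)
    expect_lte(z, 1)
    # label exchange leaves Z unchanged
    expect_equal(z_factor(mn, sn, mp, sp), z)
    # strictly decreasing in the pooled spread
    expect_lt(z_factor(mp, sp + 1, mn, sn), z)
  }
})

test_that("standard-curve fits recover clean curves and flag bad ones", {
  grid <- standard_curve_spec("E2")$grid
  conc <- rep(grid, each = 2)
  ri <- four_pl(conc, 0, 100, 1.4e-11, 1)
  res <- fit_standard_curve(conc, ri, "estrogens")
  expect_true(res$fit$converged)
  expect_lt(abs(res$fit$ac50 - 1.4e-11) / 1.4e-11, 0.01)
  expect_gte(res$fit$r_squared, 0.999)
  expect_true(res$r2$pass)
  expect_true(res$ac50$pass)

  # an AC50 outside the acceptance window fails the criterion
  ri2 <- four_pl(conc, 0, 100, 5e-11, 1)
  res2 <- fit_standard_curve(conc, ri2, "estrogens")
  expect_false(res2$ac50$pass)

  # flat data cannot be fitted
  flat <- fit_standard_curve(conc, rep(50, length(conc)), "estrogens")
  expect_false(flat$fit$converged)
  expect_false(isTRUE(flat$r2$pass))
})

test_that("4PL fits at 2% noise recover the AC50 within 10%", {
  grid <- standard_curve_spec("E2")$grid
  conc <- rep(grid, each = 3)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    sdlog <- sqrt(log(1 + 0.02^2))
    ri <- four_pl(conc, 0, 100, 1.4e-11, 1) *
      rlnorm(length(conc), -sdlog^2 / 2, sdlog)
    f <- fit_four_pl(conc, ri)
    abs(f$ac50 - 1.4e-11) / 1.4e-11
  }, numeric(1))
  expect_true(all(errs < 0.10))
})

test_that("control-substance checks apply the published thresholds", {
  th <- qc_thresholds()
  ck <- control_checks(list(forskolin = 180, prochloraz = 30,
                            menadione_viability = 15), "estrogens", th)
  expect_true(all(vapply(ck, `[[`, logical(1), "pass")))

  ck2 <- control_checks(list(pfos = 120, prochloraz = 55,
                             menadione_viability = 15), "androgens", th)
  expect_true(ck2$pfos$pass)
  expect_false(ck2$prochloraz$pass)
  # 55 vs 50 is exactly 10% beyond the threshold: rescued as tolerated
  v <- plate_verdict(ck2)
  expect_equal(v$verdict, "tolerated")
  expect_equal(unname(v$tolerated), "prochloraz_inhibition")

  # a missing control is unevaluable and fails the plate
  ck3 <- control_checks(list(prochloraz = 30), "estrogens", th)
  expect_true(is.na(ck3$forskolin$pass))
  expect_equal(plate_verdict(ck3)$verdict, "fail")
})

test_that("CV checks and the verdict tolerance band behave at boundaries", {
  cv <- cv_checks(c(90, 100, 110, 50, 100, 150), rep(c("p1", "p2"), each = 3))
  expect_equal(unname(cv$cv_within["p1"]), 10)
  expect_equal(unname(cv$cv_within["p2"]), 50)
  expect_equal(cv_checks(c(5, 5, 5), rep("p", 3))$cv_within[["p"]], 0)
  expect_error(cv_checks(c(-10, 0, 10), rep("p", 3)), "non-positive")

  # single failure 9% beyond threshold -> tolerated; 15% beyond -> fail
  near <- list(qc_check("z", 0.5 * 0.91, 0.5, "ge"))
  expect_equal(plate_verdict(near)$verdict, "tolerated")
  far <- list(qc_check("z", 0.5 * 0.85, 0.5, "ge"))
  expect_equal(plate_verdict(far)$verdict, "fail")
  allpass <- list(qc_check("z", 0.9, 0.5, "ge"))
  expect_equal(plate_verdict(allpass)$verdict, "pass")
})

test_that("qc_report judges simulated plates and flattens to a table", {
  sim <- noisefree_sim("inactive", n_bio = 1)
  qc <- qc_report(sim$measurements)
  expect_equal(length(qc$plates), 4)  # 3 ER + 1 AR
  fams <- vapply(qc$plates, `[[`, character(1), "family")
  expect_equal(sort(as.integer(table(fams))), c(1L, 3L))
  tab <- qc_table(qc)
  expect_true(all(c("plate", "criterion", "value", "pass") %in% names(tab)))
  expect_true(all(tab$pass))
})
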