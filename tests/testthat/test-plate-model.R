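test_that("default layout maps all 96 wells exactly once with the expected roles", {
  lay <- default_layout()
  expect_equal(nrow(lay), 96)
  expect_false(anyDuplicated(paste(lay$row, lay$col)) > 0)
  expect_false(anyNA(lay$role))

  well <- function(r, c) lay[lay$row == r & lay$col == c, ]
  expect_equal(well("A", 1)$role, "standard_curve")
  expect_equal(well("C", 8)$role, "sham")

  # left half: 48 wells minus the 10 standard-curve wells are H295R-seeded
  left <- lay[lay$col <= 6, ]
  expect_equal(sum(left$role != "standard_curve"), 48 - 10)
  expect_equal(sum(lay$role == "h295r_treated"), 8 * 3)
  expect_equal(sum(lay$role == "vehicle_control"), 3)
  expect_equal(sum(lay$role == "medium_control"), 3)
  expect_equal(sum(lay$role == "positive_control"), 8)
  # duplicate positive controls
  pos <- lay[lay$role == "positive_control", ]
  expect_equal(as.integer(table(pos$control)[c("forskolin", "menadione",
                                               "pfos", "prochloraz")]),
               rep(2L, 4))
  # standard curve duplicated across rows A and B, 10 points
  curve <- lay[lay$role == "standard_curve", ]
  expect_equal(nrow(curve), 20)
  expect_equal(sort(unique(curve$curve_point)), 1:10)
})

test_that("measurement I/O round-trips and normalizes units", {
  sim <- noisefree_sim(n_bio = 1)
  f <- tempfile(fileext = ".csv")
  write_measurements(sim$measurements, f)
  back <- read_measurements(f)
  expect_equal(back$rlu_reporter, sim$measurements$rlu_reporter)
  expect_equal(back$conc_h295r, sim$measurements$conc_h295r)
  expect_equal(back$role, sim$measurements$role)

  # unit normalization: uM and IU/ml converted to mol/L on read
  df <- data.frame(
    plate_id = "P1", assay = "H295R", mode = "none", row = "C",
    col = 1:2, role = "h295r_treated",
    chemical_id = c("prochloraz", "hcg"),
    conc_h295r = c(0.03, 1), conc_standard = NA_real_,
    conc_unit = c("uM", "IU_per_ml"),
    bio_rep = 1, tech_rep = 1:2, rlu_reporter = 100, rlu_viability = 100,
    supernatant_vol_ul = 67, total_vol_ul = 200,
    stringsAsFactors = FALSE)
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  m <- read_measurements(f2)
  expect_equal(m$conc_h295r, c(3e-8, 3.9e-6))
  # converting twice is refused
  expect_error(normalize_units(m), "twice")
})

test_that("structural violations raise parse errors naming the well", {
  base <- data.frame(
    plate_id = "P1", assay = "H295R", mode = "none", row = "C", col = 1,
    role = "h295r_treated", chemical_id = "x", conc_h295r = 1e-6,
    conc_standard = NA_real_, bio_rep = 1, tech_rep = 1,
    rlu_reporter = 10, rlu_viability = 10,
    supernatant_vol_ul = 67, total_vol_ul = 200, stringsAsFactors = FALSE)

  dup <- rbind(base, base)
  expect_error(validate_measurements(dup), "duplicate well",
               class = "h295calux_parse_error")
  expect_error(validate_measurements(dup), "P1")

  bad_role <- base
  bad_role$role <- "mystery"
  expect_error(validate_measurements(bad_role), "unknown role")

  missing_col <- base[, setdiff(names(base), "rlu_reporter")]
  expect_error(validate_measurements(missing_col), "missing required")

  bad_vol <- base
  bad_vol$supernatant_vol_ul <- 300
  expect_error(validate_measurements(bad_vol), "supernatant volume")

  neg <- base
  neg$rlu_reporter <- -5
  expect_error(validate_measurements(neg), "negative rlu_reporter")
})

test_that("pair_sham pairs treated and sham groups and reports gaps", {
  grid <- 10^seq(-9, -6, length.out = 8)
  treated <- data.frame(chemical_id = "x",
                        conc_h295r = rep(grid, each = 3))
  sham <- treated
  pairs <- pair_sham(treated, sham)
  expect_equal(nrow(pairs), 8)
  expect_equal(pairs$n_treated, rep(3L, 8))
  expect_equal(pairs$n_sham, rep(3L, 8))

  sham_missing <- sham[sham$conc_h295r != max(grid), ]
  expect_error(pair_sham(treated, sham_missing), "without sham")
  expect_error(pair_sham(treated, sham_missing), "1e-06")
})

test_that("dilution schemes and standard-curve specs enforce their ranges", {
  sch <- dilution_scheme()
  expect_equal(sch$ar_fold, 200 / 67)
  expect_equal(sch$er_fold, c(200 / 30, 200 / 28, 200 / 25))
  expect_true(all(sch$er_fold >= 6.25 & sch$er_fold <= 10))
  expect_error(dilution_scheme(ar = c(300, 200)))

  e2 <- standard_curve_spec("E2")
  expect_equal(range(e2$grid), c(0.5e-12, 500e-12))
  flt <- standard_curve_spec("FLT")
  expect_equal(flt$co_agonist$conc, 0.3e-9)
  expect_error(standard_curve_spec("E2", grid = c(1e-12, 1e-12)),
               "increasing")
  expect_error(standard_curve_spec("DHT", grid = c(1e-12, 1e-6)),
               "outside")
})

test_that("plate-matrix blocks convert to long format", {
  mat <- matrix(seq_len(96), nrow = 8, ncol = 12)
  long <- plate_matrix_to_long(mat, "rlu_reporter")
  expect_equal(nrow(long), 96)
  expect_equal(long$rlu_reporter[long$row == "A" & long$col == 1], 1)
  expect_equal(long$rlu_reporter[long$row == "H" & long$col == 12], 96)
})
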