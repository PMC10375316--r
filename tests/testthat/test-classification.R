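make_calls <- function(conc, sig, dir = "down", mean_level = 50) {
  data.frame(chemical_id = "x", endpoint = "estrogen_activity",
             conc_h295r = conc, significant = sig,
             direction = if (length(dir) == 1) rep(dir, length(conc)) else dir,
             mean_level = mean_level, stringsAsFactors = FALSE)
}

test_that("cytotoxicity flags use the 80% mean-viability rule", {
  v <- data.frame(chemical_id = "x", assay = "H295R",
                  conc = c(1, 3, 10), viability = c(95, 75, 38.2))
  fl <- flag_cytotoxicity(v)
  expect_equal(fl$cytotoxic, c(FALSE, TRUE, TRUE))
  # isolated dip with no concentration-response is flagged but annotated
  v2 <- data.frame(chemical_id = "x", assay = "H295R",
                   conc = c(1, 3, 10), viability = c(95, 70, 95))
  fl2 <- flag_cytotoxicity(v2)
  expect_true(fl2$cytotoxic[2])
  expect_true(fl2$possibly_spurious[2])
})

test_that("the positivity rule combines consecutive runs and the top concentration", {
  conc <- c(1, 2, 3, 4, 5)
  # (ns, ns, *, *, **): positive, run starts at the third concentration
  p1 <- positivity_rule(make_calls(conc, c(F, F, T, T, T)))
  expect_true(p1$positive)
  expect_equal(min(p1$candidate_concs), 3)

  # an isolated low-concentration hit is discarded
  p2 <- positivity_rule(make_calls(conc, c(T, F, F, F, F)))
  expect_false(p2$positive)

  # a significant maximum noncytotoxic concentration is enough
  p3 <- positivity_rule(make_calls(conc, c(F, F, F, F, T)))
  expect_true(p3$positive)
  expect_equal(p3$candidate_concs, 5)

  # ... but not when that top concentration is cytotoxic
  p4 <- positivity_rule(make_calls(conc, c(F, F, F, F, T)),
                        cytotoxic = c(F, F, F, F, T))
  expect_false(p4$positive)
})

test_that("LOEC is the lowest concentration of the qualifying run", {
  conc <- c(0.03, 0.1, 0.3, 1, 3)
  # chance hit at 0.03, gap at 0.1, real run from 0.3
  p <- positivity_rule(make_calls(conc, c(T, F, T, T, T), "up"))
  expect_equal(loec(p), 0.3)
  p_all <- positivity_rule(make_calls(conc, rep(T, 5)))
  expect_equal(loec(p_all), 0.03)
  expect_error(loec(positivity_rule(make_calls(conc, rep(F, 5)))),
               "negative endpoint")
})

test_that("direction profiles resolve monotone and biphasic effects", {
  conc <- c(1, 2, 3, 4, 5, 6)
  up <- positivity_rule(make_calls(conc, rep(T, 6), "up", 150))
  expect_equal(direction_profile(up), "up")
  dn <- positivity_rule(make_calls(conc, rep(T, 6), "down", 50))
  expect_equal(direction_profile(dn), "down")
  bi <- positivity_rule(make_calls(conc, rep(T, 6),
                                   c("down", "down", "down", "up", "up", "up")))
  expect_equal(direction_profile(bi), "down_then_up")
})

test_that("direct receptor calls exclude CALUX-cytotoxic evidence and rescale", {
  conc <- c(1, 3, 10, 30)
  calls <- data.frame(chemical_id = "x",
                      endpoint = "direct_antiandrogenicity",
                      conc_h295r = conc,
                      significant = c(F, F, T, T),
                      direction = "down", mean_level = c(95, 90, 70, 40),
                      stringsAsFactors = FALSE)
  d <- direct_receptor_calls(calls, fold = 3)
  expect_true(d$present)
  expect_equal(d$loec_nominal, 10)
  expect_equal(d$loec_calux, 10 / 3)

  # the top concentration is CALUX-cytotoxic: its evidence is discarded and
  # the remaining isolated hit survives only as the max noncytotoxic conc
  d2 <- direct_receptor_calls(calls, calux_cytotoxic = c(F, F, F, T),
                              fold = 3)
  expect_true(d2$present)
  expect_equal(d2$loec_nominal, 10)

  none <- direct_receptor_calls(
    transform(calls, significant = FALSE), fold = 3)
  expect_false(none$present)
})

test_that("masking demotes confounded candidates and never promotes", {
  conc <- c(10, 30, 100, 300)
  cand <- positivity_rule(make_calls(conc, c(F, F, T, T)))
  key <- function(x) as.character(signif(x, 10))
  no_cyto <- stats::setNames(rep(FALSE, 4), key(conc))

  direct_sig <- data.frame(conc_h295r = conc,
                           significant = c(F, F, F, T),
                           mean_level = c(95, 94, 92, 58))
  # significant, biologically relevant antagonism at a candidate conc
  m1 <- masking_rule(cand, "down", direct_sig, 100, no_cyto, no_cyto)
  expect_equal(m1$effect, "nd")
  expect_equal(m1$masked_by, "direct_receptor")

  # decrease at H295R-cytotoxic concentrations with healthy CALUX cells
  h_cyto <- stats::setNames(c(FALSE, FALSE, TRUE, TRUE), key(conc))
  quiet <- transform(direct_sig, significant = FALSE)
  m2 <- masking_rule(cand, "down", quiet, 100, h_cyto, no_cyto)
  expect_equal(m2$masked_by, "cytotoxicity")

  # unconfounded candidate keeps its effect and LOEC
  m3 <- masking_rule(cand, "down", quiet, 100, no_cyto, no_cyto)
  expect_equal(m3$effect, "down")
  expect_equal(m3$loec, 100)

  # a negative endpoint can never be promoted
  neg <- positivity_rule(make_calls(conc, rep(F, 4)))
  m4 <- masking_rule(neg, "nd", direct_sig, 100, no_cyto, no_cyto)
  expect_equal(m4$effect, "nd")
  expect_equal(m4$masked_by, "none")
})

test_that("LOEC never increases when higher concentrations become significant", {
  set.seed(13)
  conc <- c(1, 2, 3, 4, 5, 6)
  for (i in 1:50) {
    sig <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    p1 <- positivity_rule(make_calls(conc, sig))
    sig2 <- sig
    extra <- which(!sig & conc > 3)
    if (length(extra) > 0) sig2[sample(extra, 1)] <- TRUE
    p2 <- positivity_rule(make_calls(conc, sig2))
    if (p1$positive) {
      expect_true(p2$positive)
      expect_lte(loec(p2), loec(p1))
    }
  }
})

test_that("bootstrap CI diagnostics separate distinct and identical groups", {
  a <- c(35, 40, 45, 50, 55, 56)
  b <- c(64, 80, 95, 100, 110, 118)
  d <- ci_overlap_diagnostic(a, b, seed = 1)
  expect_false(d$overlap)
  expect_true(d$exceeds_relevance)

  same <- ci_overlap_diagnostic(c(90, 100, 110), c(91, 99, 112), seed = 2)
  expect_true(same$overlap)
  expect_false(same$exceeds_relevance)
})
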