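# Plate quality control: LOQ, induction factor, Z-factor, standard-curve
# fit criteria, control-substance checks, CV checks, and the plate verdict
# with its 10%-of-threshold tolerance rule.

#' Default quality-control thresholds
#'
#' Acceptance constants per hormone family (estrogens on the E2 curve,
#' androgens on the DHT curve, anti-androgens on the FLT antagonist curve):
#' maximum LOQ in %RI, minimum basal-to-LOQ ratio, basal signal window (% of
#' the curve maximum, or of the agonist-only wells for anti-androgens),
#' minimum curve R-squared, AC50 acceptance window (mol/L), minimum
#' induction factor, minimum Z-factor, control-substance thresholds and CV
#' limits. All values are overridable.
#'
#' @return nested list of thresholds.
#' @export
qc_thresholds <- function() {
  list(
    estrogens = list(
      loq_max = 20, basal_loq_ratio = 2.5, basal_window = c(20, 80),
      r2_min = 0.95, ac50_window = c(6.5e-12, 3e-11),
      if_min = 8, z_min = 0.5),
    androgens = list(
      loq_max = 15, basal_loq_ratio = 5, basal_window = c(20, 80),
      r2_min = 0.96, ac50_window = c(1.2e-10, 4.3e-10),
      if_min = 18, z_min = 0.6),
    antiandrogens = list(
      loq_max = 15, basal_loq_ratio = 5, basal_window = c(40, 160),
      r2_min = 0.96, ac50_window = c(2.4e-7, 1.4e-6),
      if_min = 10, z_min = 0.5),
    controls = list(
      forskolin_min = 150,   # % of DMSO control, estrogens, 1 uM
      pfos_min = 115,        # % of DMSO control, (anti-)androgens, 100 uM
      prochloraz_max = 50,   # % of DMSO control, all families, 1 uM
      menadione_viab_max = 20),  # % viability in the H295R plate, strict <
    cv = list(within_max = 30, between_max = 30),
    tolerance = 0.10)
}

#' Limit of quantification
#'
#' Mean %RI of the vehicle-control wells plus ten sample standard
#' deviations.
#'
#' @param vehicle_ri vehicle-well %RI values (at least 3).
#' @return LOQ in %RI units.
#' @export
loq <- function(vehicle_ri) {
  if (length(vehicle_ri) < 3) stop("need at least 3 vehicle %RI values")
  mean(vehicle_ri) + 10 * stats::sd(vehicle_ri)
}

#' Induction factor
#'
#' Ratio of the positive-control to negative-control mean RLU on the
#' standard curve.
#'
#' @param mu_pos,mu_neg mean RLUs; `mu_neg` must be positive.
#' @return the ratio.
#' @export
induction_factor <- function(mu_pos, mu_neg) {
  if (!is.finite(mu_neg) || mu_neg <= 0) {
    stop("negative-control mean must be positive")
  }
  mu_pos / mu_neg
}

#' Z-factor
#'
#' Screening-window statistic
#' `1 - 3 * (sd_pos + sd_neg) / |mu_pos - mu_neg|`; at most 1, decreasing in
#' the pooled spread, and symmetric under exchange of the positive and
#' negative labels.
#'
#' @param mu_pos,sd_pos,mu_neg,sd_neg control means and standard deviations.
#' @return Z-factor.
#' @export
z_factor <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (mu_pos == mu_neg) stop("Z-factor undefined for equal control means")
  1 - 3 * (sd_pos + sd_neg) / abs(mu_pos - mu_neg)
}

qc_check <- function(name, value, threshold, direction) {
  pass <- if (is.na(value)) {
    NA
  } else {
    switch(direction,
           ge = value >= threshold,
           le = value <= threshold,
           lt = value < threshold,
           window = value >= threshold[1] && value <= threshold[2])
  }
  list(name = name, value = value, threshold = threshold,
       direction = direction, pass = pass)
}

check_margin <- function(check) {
  # relative distance beyond the (violated) threshold; 0 when passing
  v <- check$value
  th <- check$threshold
  if (is.na(v)) return(Inf)
  if (isTRUE(check$pass)) return(0)
  if (check$direction == "window") {
    edge <- if (v < th[1]) th[1] else th[2]
    return(abs(v - edge) / abs(edge))
  }
  abs(v - th) / abs(th)
}

#' Fit and judge a standard curve
#'
#' Fits a 4PL ([fit_four_pl()]) to the standard-curve %RI values and checks
#' the fit R-squared and AC50 acceptance window for the family. A
#' non-converged fit fails both criteria.
#'
#' @param conc curve concentrations (mol/L).
#' @param ri curve %RI values.
#' @param family `"estrogens"`, `"androgens"` or `"antiandrogens"`.
#' @param thresholds see [qc_thresholds()].
#' @return list with the `fit` and the two checks.
#' @export
fit_standard_curve <- function(conc, ri,
                               family = c("estrogens", "androgens",
                                          "antiandrogens"),
                               thresholds = qc_thresholds()) {
  family <- match.arg(family)
  th <- thresholds[[family]]
  fit <- tryCatch(fit_four_pl(conc, ri), error = function(e) {
    structure(list(bottom = NA_real_, top = NA_real_, ac50 = NA_real_,
                   hill = NA_real_, r_squared = NA_real_, converged = FALSE),
              class = "four_pl_fit")
  })
  list(fit = fit,
       r2 = qc_check(paste0(family, "_r2"), fit$r_squared, th$r2_min, "ge"),
       ac50 = qc_check(paste0(family, "_ac50"), fit$ac50, th$ac50_window,
                       "window"))
}

#' Control-substance checks
#'
#' Judges the plate positive controls against their thresholds: forskolin
#' (1 uM) estrogen induction, PFOS (100 uM) androgen induction, prochloraz
#' (1 uM) inhibition, and menadione cytotoxicity in the H295R plate. A
#' missing control is marked unevaluable (`pass = NA`), which fails the
#' plate.
#'
#' @param values named list of observed values (% of DMSO control for the
#'   steroidogenesis controls; % viability for menadione). Entries:
#'   `forskolin`, `pfos`, `prochloraz`, `menadione_viability`; unneeded
#'   entries may be omitted with `NA`.
#' @param family hormone family the plate reads out.
#' @param thresholds see [qc_thresholds()].
#' @return list of checks.
#' @export
control_checks <- function(values,
                           family = c("estrogens", "androgens",
                                      "antiandrogens"),
                           thresholds = qc_thresholds()) {
  family <- match.arg(family)
  th <- thresholds$controls
  gv <- function(nm) if (is.null(values[[nm]])) NA_real_ else values[[nm]]
  checks <- list()
  if (family == "estrogens") {
    checks$forskolin <- qc_check("forskolin_induction", gv("forskolin"),
                                 th$forskolin_min, "ge")
  } else {
    checks$pfos <- qc_check("pfos_induction", gv("pfos"), th$pfos_min, "ge")
  }
  checks$prochloraz <- qc_check("prochloraz_inhibition", gv("prochloraz"),
                                th$prochloraz_max, "le")
  checks$menadione <- qc_check("menadione_viability",
                               gv("menadione_viability"),
                               th$menadione_viab_max, "lt")
  checks
}

#' Coefficient-of-variation checks
#'
#' `CV = 100 * sd/mean` of the DMSO-control signal within each plate, and of
#' the per-plate basal means across the biological replicates.
#'
#' @param values numeric vector of DMSO-control values.
#' @param plate grouping factor (one level per plate/biological replicate).
#' @return list with `cv_within` (named per plate) and `cv_between`.
#' @export
cv_checks <- function(values, plate) {
  groups <- split(values, plate)
  cv1 <- function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m <= 0) stop("CV undefined for non-positive mean")
    100 * stats::sd(v) / m
  }
  within <- vapply(groups, cv1, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  between <- if (length(means) >= 2) cv1(means) else NA_real_
  list(cv_within = within, cv_between = between)
}

#' Plate verdict with the 10% tolerance rescue
#'
#' `pass` when every criterion passes; `tolerated` when every failing
#' criterion lies within 10% (relative to its threshold) of the acceptance
#' limit; `fail` otherwise, or when any criterion is unevaluable.
#'
#' @param checks flat list of checks (see [control_checks()]).
#' @param tolerance relative tolerance (default 0.10).
#' @return list with `verdict` and the names of tolerated criteria.
#' @export
plate_verdict <- function(checks, tolerance = 0.10) {
  passes <- vapply(checks, function(ch) ch$pass, logical(1))
  if (anyNA(passes)) {
    return(list(verdict = "fail",
                tolerated = character(0),
                unevaluable = vapply(checks[is.na(passes)],
                                     function(ch) ch$name, character(1))))
  }
  if (all(passes)) {
    return(list(verdict = "pass", tolerated = character(0)))
  }
  failing <- checks[!passes]
  margins <- vapply(failing, check_margin, numeric(1))
  if (all(margins <= tolerance)) {
    list(verdict = "tolerated",
         tolerated = vapply(failing, function(ch) ch$name, character(1)))
  } else {
    list(verdict = "fail", tolerated = character(0))
  }
}

calux_plate_context <- function(plate) {
  curve <- plate[plate$role == "standard_curve", , drop = FALSE]
  veh <- curve[curve$curve_role == "vehicle", , drop = FALSE]
  bg <- background_level(veh$rlu_reporter)
  antagonist <- any(curve$curve_role == "agonist_only")
  std <- curve[curve$curve_role == "standard", , drop = FALSE]
  if (antagonist) {
    ref <- mean(curve$rlu_reporter[curve$curve_role == "agonist_only"])
  } else {
    conc_means <- tapply(std$rlu_reporter, signif(std$conc_standard, 8), mean)
    ref <- max(conc_means)
  }
  list(bg = bg, ref = ref, antagonist = antagonist, curve = curve,
       std = std, vehicle = veh)
}

plate_family <- function(plate) {
  if (plate$assay[1] == "ER_CALUX") return("estrogens")
  ctx_antag <- any(plate$curve_role == "agonist_only", na.rm = TRUE)
  if (ctx_antag) "antiandrogens" else "androgens"
}

#' Full quality-control report for a plate-set measurement table
#'
#' Evaluates, per CALUX plate, the LOQ, basal-signal criteria, 4PL fit
#' criteria, induction factor, Z-factor and control-substance checks, plus
#' the within/between-plate CV of the DMSO control per plate family, and
#' issues a verdict per plate under the 10% tolerance rule.
#'
#' @param measurements validated measurement table (all plates, all
#'   biological replicates).
#' @param scheme a [dilution_scheme()].
#' @param thresholds see [qc_thresholds()].
#' @return object of class `qc_report`: per-plate results and verdicts.
#' @export
qc_report <- function(measurements, scheme = dilution_scheme(),
                      thresholds = qc_thresholds()) {
  calux <- measurements[measurements$assay != "H295R", , drop = FALSE]
  h295r <- measurements[measurements$assay == "H295R", , drop = FALSE]
  plates <- split(calux, plate_key(calux))
  out <- list()
  basal_by_family <- list()
  for (pk in names(plates)) {
    plate <- plates[[pk]]
    family <- plate_family(plate)
    th <- thresholds[[family]]
    ctx <- calux_plate_context(plate)
    ri <- function(rlu) relative_induction(rlu, ctx$bg, ctx$ref)
    veh_ri <- ri(ctx$vehicle$rlu_reporter)
    # LOQ needs >= 3 wells; curve vehicle wells are duplicated, so pool
    # with the chemical-free sham-side blanks at the background level
    # (vehicle and medium shams in agonist mode; on antagonist-mode plates
    # the DHT-spiked sham vehicle sits at the reference, not background,
    # so only the medium blanks qualify there)
    sham_blank <- plate$role == "sham" & !is.na(plate$control) &
      plate$control %in% c("vehicle", "medium") & plate$mode == "agonist"
    loq_values <- c(veh_ri, ri(plate$rlu_reporter[sham_blank]))
    loq_val <- if (length(loq_values) >= 3) loq(loq_values) else NA_real_

    basal_wells <- plate$role == "vehicle_control"
    basal_ri <- mean(ri(plate$rlu_reporter[basal_wells]))
    basal_by_family[[family]] <-
      rbind(basal_by_family[[family]],
            data.frame(plate = pk,
                       value = ri(plate$rlu_reporter[basal_wells])))

    curve_fit <- fit_standard_curve(ctx$std$conc_standard,
                                    ri(ctx$std$rlu_reporter),
                                    family, thresholds)
    # IF and Z: positive = top curve response (agonist) or agonist-only
    # wells (antagonist curve); negative = curve vehicle wells
    if (ctx$antagonist) {
      pos_rlu <- ctx$curve$rlu_reporter[ctx$curve$curve_role == "agonist_only"]
    } else {
      conc_means <- tapply(ctx$std$rlu_reporter,
                           signif(ctx$std$conc_standard, 8), mean)
      top_conc <- as.numeric(names(conc_means))[which.max(conc_means)]
      pos_rlu <- ctx$std$rlu_reporter[
        abs(ctx$std$conc_standard - top_conc) <= 1e-6 * top_conc]
    }
    neg_rlu <- ctx$vehicle$rlu_reporter
    if_val <- induction_factor(mean(pos_rlu), mean(neg_rlu))
    z_val <- z_factor(mean(pos_rlu), stats::sd(pos_rlu),
                      mean(neg_rlu), stats::sd(neg_rlu))

    # positive-control substances, on the % of basal scale
    ctl_value <- function(ctl) {
      w <- plate$role == "positive_control" & !is.na(plate$control) &
        plate$control == ctl
      if (!any(w)) return(NA_real_)
      mean(to_basal(ri(plate$rlu_reporter[w]), basal_ri))
    }
    men_wells <- h295r$role == "positive_control" &
      !is.na(h295r$control) & h295r$control == "menadione" &
      h295r$bio_rep == plate$bio_rep[1]
    men_viab <- if (any(men_wells)) {
      veh_h <- h295r$role == "vehicle_control" &
        h295r$bio_rep == plate$bio_rep[1]
      mean(percent_viability(h295r$rlu_viability[men_wells],
                             mean(h295r$rlu_viability[veh_h])))
    } else NA_real_
    ctl_checks <- control_checks(
      list(forskolin = ctl_value("forskolin"), pfos = ctl_value("pfos"),
           prochloraz = ctl_value("prochloraz"),
           menadione_viability = men_viab),
      family, thresholds)

    checks <- c(list(
      loq = qc_check(paste0(family, "_loq"), loq_val, th$loq_max, "le"),
      basal_loq = qc_check("basal_vs_loq",
                           if (is.na(loq_val)) NA_real_ else
                             if (loq_val <= 0) Inf else basal_ri / loq_val,
                           th$basal_loq_ratio, "ge"),
      # basal window evaluated on background-subtracted signal (%RI is the
      # background-subtracted fraction of the curve maximum)
      basal_window = qc_check("basal_window", basal_ri, th$basal_window,
                              "window"),
      r2 = curve_fit$r2, ac50 = curve_fit$ac50,
      induction_factor = qc_check(paste0(family, "_if"), if_val, th$if_min,
                                  "ge"),
      z_factor = qc_check(paste0(family, "_z"), z_val, th$z_min, "ge")),
      ctl_checks)
    verdict <- plate_verdict(checks, thresholds$tolerance)
    out[[pk]] <- list(plate = pk, family = family, loq = loq_val,
                      basal_ri = basal_ri, fit = curve_fit$fit,
                      induction_factor = if_val, z_factor = z_val,
                      checks = checks, verdict = verdict$verdict,
                      tolerated = verdict$tolerated)
  }
  # CV of the DMSO control within plates and across biological replicates
  cv <- lapply(basal_by_family, function(df) {
    res <- cv_checks(df$value, df$plate)
    list(cv_within = res$cv_within, cv_between = res$cv_between,
         within_pass = all(res$cv_within <= thresholds$cv$within_max,
                           na.rm = TRUE),
         between_pass = is.na(res$cv_between) ||
           res$cv_between <= thresholds$cv$between_max)
  })
  structure(list(plates = out, cv = cv), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  for (p in x$plates) {
    cat(sprintf("%-16s %-14s LOQ %6.2f  IF %6.2f  Z %5.2f  verdict: %s\n",
                p$plate, p$family, p$loq, p$induction_factor, p$z_factor,
                p$verdict))
  }
  invisible(x)
}

#' Flatten a QC report into a criteria table
#'
#' @param report a [qc_report()].
#' @return data frame with one row per plate per criterion.
#' @export
qc_table <- function(report) {
  rows <- lapply(report$plates, function(p) {
    do.call(rbind, lapply(p$checks, function(ch) {
      data.frame(plate = p$plate, family = p$family, criterion = ch$name,
                 value = ch$value,
                 threshold = paste(ch$threshold, collapse = ".."),
                 direction = ch$direction, pass = ch$pass,
                 verdict = p$verdict, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
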