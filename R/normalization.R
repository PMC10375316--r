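# Conversion of raw RLUs into % viability, % relative induction and
# % of basal hormone production.

#' Percent cell viability
#'
#' Each well's viability RLU expressed as a percentage of the mean RLU of
#' the reference wells (DMSO-treated H295R wells on the H295R plate;
#' standard-curve vehicle wells on CALUX plates).
#'
#' @param rlu numeric vector of viability RLUs.
#' @param reference_mean positive reference mean RLU.
#' @return percentages (100 = reference level).
#' @export
percent_viability <- function(rlu, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    stop("viability reference mean must be positive")
  }
  100 * rlu / reference_mean
}

#' Background reporter signal
#'
#' Mean raw RLU of the vehicle wells on the CALUX standard curve; subtracted
#' from every raw reporter reading before normalization.
#'
#' @param standard_vehicle_wells numeric vector (at least 2 wells).
#' @return mean RLU.
#' @export
background_level <- function(standard_vehicle_wells) {
  if (length(standard_vehicle_wells) < 2) {
    stop("need at least 2 standard-curve vehicle wells for background")
  }
  mean(standard_vehicle_wells)
}

#' Percent relative induction (%RI)
#'
#' Background-subtracted reporter signal as a percentage of the
#' background-subtracted reference: the largest per-concentration mean of
#' the standard curve in agonist mode, or the agonist-only well of the
#' antagonist-mode curve. Values may be negative or exceed 100 and are not
#' clipped.
#'
#' @param rlu raw reporter RLU(s).
#' @param background background RLU ([background_level()]).
#' @param reference reference RLU (raw scale, not background-subtracted).
#' @return %RI values.
#' @export
relative_induction <- function(rlu, background, reference) {
  span <- reference - background
  if (!is.finite(span) || span <= 0) {
    stop("flat or failed standard curve: reference does not exceed background")
  }
  100 * (rlu - background) / span
}

#' Re-normalize %RI to basal hormone production
#'
#' Expresses a %RI value as a percentage of the basal activity of
#' vehicle-treated H295R cells. Values above 100 represent induction of the
#' hormone pathway, values below 100 inhibition.
#'
#' @param pct_ri %RI value(s).
#' @param basal_ri mean %RI of the vehicle-treated H295R wells (must be
#'   positive).
#' @param loq optional limit of quantification; a basal at or below the LOQ
#'   means the hormone is outside the quantifiable range and the run is
#'   invalid.
#' @return % of basal production.
#' @export
to_basal <- function(pct_ri, basal_ri, loq = NULL) {
  if (!is.finite(basal_ri) || basal_ri <= 0) {
    stop("basal %RI must be positive")
  }
  if (!is.null(loq) && basal_ri <= loq) {
    stop(errorCondition(
      sprintf("basal %%RI (%.3g) at or below LOQ (%.3g): hormone below quantifiable range",
              basal_ri, loq),
      class = c("h295calux_invalid_run", "error")))
  }
  100 * pct_ri / basal_ri
}

#' Dilution-adjusted concentration in the CALUX well
#'
#' Divides the nominal H295R treatment concentration by the arithmetic-mean
#' fold dilution of the plates/experiments used for that chemical. Averaging
#' the fold dilutions (rather than tracking each plate's exact fold) can
#' introduce up to 23% error in the reported concentration, well within the
#' assay's inherent variation; the error bound is attached as an attribute.
#'
#' @param conc_h295r nominal concentration(s) in the H295R well, mol/L.
#' @param scheme a [dilution_scheme()] (or numeric vector of fold dilutions).
#' @param context `"ER"` or `"AR"`: which plate family the readout came from.
#' @return concentration(s) in the CALUX well, mol/L.
#' @export
calux_concentration <- function(conc_h295r, scheme, context = c("ER", "AR")) {
  context <- match.arg(context)
  folds <- if (inherits(scheme, "dilution_scheme")) {
    if (context == "ER") scheme$er_fold else scheme$ar_fold
  } else {
    as.numeric(scheme)
  }
  out <- conc_h295r / mean(folds)
  attr(out, "max_relative_error") <- 0.23
  out
}

mode_reference_level <- function(endpoint) {
  # reference level against which effect direction / biological relevance is
  # judged: 100 for basal-normalized and antagonist-mode readouts, 0 for
  # direct agonist-mode readouts.
  switch(endpoint,
         estrogen_activity = 100, androgen_activity = 100,
         direct_antiandrogenicity = 100,
         direct_estrogenicity = 0, direct_androgenicity = 0,
         stop("unknown endpoint: ", endpoint))
}

plate_key <- function(df) paste(df$plate_id, df$bio_rep, sep = "/")

#' Normalize a full plate-set measurement table
#'
#' Orchestrates per-plate normalization of a long measurement table covering
#' one or more biological replicates of the five-plate experiment (1 H295R +
#' 3 ER CALUX + 1 AR CALUX). For every CALUX plate the background is the
#' mean of the standard-curve vehicle wells; agonist-mode %RI is referenced
#' to the largest per-concentration curve mean, antagonist-mode %RI to the
#' background-subtracted agonist-only wells. H295R-side readouts are then
#' re-normalized to the basal activity of the plate's vehicle wells; sham
#' (direct receptor) readouts stay on the %RI scale. Technical replicates
#' are kept as individual records so that downstream statistics can pool
#' them.
#'
#' @param measurements validated measurement data frame (mol/L).
#' @param scheme a [dilution_scheme()].
#' @return data frame of normalized activity records: one row per well per
#'   endpoint, with `pct_viability`, `pct_ri`, `pct_of_basal`, `conc_calux`.
#' @export
normalize_plateset <- function(measurements, scheme = dilution_scheme()) {
  df <- measurements
  if (is.null(df$control)) df$control <- NA_character_
  out <- list()
  h295r <- df[df$assay == "H295R", , drop = FALSE]
  h295r_viab_ref <- vapply(
    split(h295r, plate_key(h295r)),
    function(p) mean(p$rlu_viability[p$role == "vehicle_control"]),
    numeric(1))

  calux <- df[df$assay != "H295R", , drop = FALSE]
  for (pk in unique(plate_key(calux))) {
    plate <- calux[plate_key(calux) == pk, , drop = FALSE]
    curve <- plate[plate$role == "standard_curve", , drop = FALSE]
    veh <- curve[curve$curve_role == "vehicle", , drop = FALSE]
    bg <- background_level(veh$rlu_reporter)
    viab_ref <- mean(veh$rlu_viability)
    antagonist_curve <- any(curve$curve_role == "agonist_only")
    if (antagonist_curve) {
      ref <- mean(curve$rlu_reporter[curve$curve_role == "agonist_only"])
    } else {
      std <- curve[curve$curve_role == "standard", , drop = FALSE]
      conc_means <- tapply(std$rlu_reporter, signif(std$conc_standard, 8),
                           mean)
      ref <- max(conc_means)
    }
    wells <- plate[plate$role %in% c("h295r_treated", "sham",
                                     "vehicle_control", "medium_control",
                                     "positive_control"), , drop = FALSE]
    ri <- relative_induction(wells$rlu_reporter, bg, ref)
    viab <- percent_viability(wells$rlu_viability, viab_ref)
    context <- if (plate$assay[1] == "ER_CALUX") "ER" else "AR"
    endpoint <- ifelse(
      wells$role == "sham",
      if (context == "ER") "direct_estrogenicity" else
        if (any(wells$mode[wells$role == "sham"] == "antagonist"))
          "direct_antiandrogenicity" else "direct_androgenicity",
      if (context == "ER") "estrogen_activity" else "androgen_activity")

    basal_idx <- wells$role == "vehicle_control"
    basal <- mean(ri[basal_idx])
    pct_basal <- rep(NA_real_, nrow(wells))
    h_side <- wells$role %in% c("h295r_treated", "vehicle_control",
                                "positive_control")
    pct_basal[h_side] <- to_basal(ri[h_side], basal)

    rec <- data.frame(
      plate_id = wells$plate_id, assay = wells$assay, mode = wells$mode,
      role = wells$role, control = wells$control,
      chemical_id = wells$chemical_id,
      conc_h295r = wells$conc_h295r,
      conc_calux = as.numeric(calux_concentration(wells$conc_h295r, scheme,
                                                  context)),
      endpoint = endpoint,
      pct_viability = viab, pct_ri = ri, pct_of_basal = pct_basal,
      bio_rep = wells$bio_rep, tech_rep = wells$tech_rep,
      stringsAsFactors = FALSE)
    out[[pk]] <- rec
  }
  norm <- do.call(rbind, out)
  rownames(norm) <- NULL

  # attach same-well H295R viability records as their own endpoint rows
  hw <- h295r[h295r$role %in% c("h295r_treated", "vehicle_control",
                                "positive_control"), , drop = FALSE]
  if (nrow(hw) > 0) {
    hv <- data.frame(
      plate_id = hw$plate_id, assay = hw$assay, mode = hw$mode,
      role = hw$role, control = hw$control, chemical_id = hw$chemical_id,
      conc_h295r = hw$conc_h295r, conc_calux = NA_real_,
      endpoint = "h295r_viability",
      pct_viability = {
        refs <- h295r_viab_ref[plate_key(hw)]
        if (any(!is.finite(refs) | refs <= 0)) {
          stop("viability reference mean must be positive")
        }
        100 * hw$rlu_viability / refs
      },
      pct_ri = NA_real_, pct_of_basal = NA_real_,
      bio_rep = hw$bio_rep, tech_rep = hw$tech_rep,
      stringsAsFactors = FALSE)
    norm <- rbind(norm, hv)
  }
  attr(norm, "dilution_scheme") <- scheme
  norm
}
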