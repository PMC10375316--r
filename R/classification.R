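# Per-chemical endocrine classification: positivity rules, LOEC
# determination, direct receptor calls, and demotion of steroidogenic
# candidates confounded by direct receptor activity or cytotoxicity.

#' Flag cytotoxic concentrations
#'
#' A concentration is cytotoxic for a cell line when its mean-of-means
#' viability falls below the threshold (default 80%). Isolated dips with no
#' concentration-response (cytotoxic at one concentration but not at any
#' higher one) are annotated as possibly spurious but still flagged.
#'
#' @param viability data frame with `chemical_id`, `assay`, `conc`,
#'   `viability` (replicate rows allowed; means are taken per group).
#' @param threshold viability cut-off in percent.
#' @return data frame of flags per (`chemical_id`, `assay`, `conc`).
#' @export
flag_cytotoxicity <- function(viability, threshold = 80) {
  key <- paste(viability$chemical_id, viability$assay,
               signif(viability$conc, 10), sep = "|")
  idx <- match(unique(key), key)
  means <- vapply(split(viability$viability, key)[unique(key)], mean,
                  numeric(1))
  out <- data.frame(chemical_id = viability$chemical_id[idx],
                    assay = viability$assay[idx],
                    conc = viability$conc[idx],
                    mean_viability = unname(means),
                    stringsAsFactors = FALSE)
  out$cytotoxic <- out$mean_viability < threshold
  out <- out[order(out$chemical_id, out$assay, out$conc), ]
  out$possibly_spurious <- FALSE
  for (k in unique(paste(out$chemical_id, out$assay))) {
    i <- which(paste(out$chemical_id, out$assay) == k)
    flags <- out$cytotoxic[i]
    for (j in seq_along(flags)) {
      if (flags[j] && j < length(flags) && !any(flags[(j + 1):length(flags)])) {
        # a dip followed only by non-cytotoxic higher concentrations
        if (j < length(flags)) out$possibly_spurious[i[j]] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  out
}

# split ordered per-concentration calls into maximal runs of consecutive
# significant calls with a consistent direction
significance_runs <- function(calls) {
  runs <- list()
  cur <- NULL
  for (i in seq_len(nrow(calls))) {
    sig <- isTRUE(calls$significant[i]) && !is.na(calls$direction[i])
    if (sig) {
      if (!is.null(cur) && calls$direction[i] == cur$direction) {
        cur$rows <- c(cur$rows, i)
      } else {
        if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
        cur <- list(direction = calls$direction[i], rows = i)
      }
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

#' Positivity rule for one endpoint
#'
#' An endpoint is positive when (a) at least 2 consecutive tested
#' concentrations are significant with the same direction, or (b) the
#' maximum noncytotoxic concentration is significant ("and/or": logical OR
#' of the branches). Isolated significant concentrations meeting neither
#' branch are discarded as chance hits.
#'
#' @param calls per-concentration calls for one chemical and endpoint:
#'   columns `conc_h295r` (or `conc`), `significant`, `direction`, ordered
#'   or orderable by concentration.
#' @param cytotoxic logical vector aligned with `calls` rows (H295R
#'   cytotoxicity for steroidogenic endpoints, CALUX for direct ones).
#' @return list: `positive`, `runs` (qualifying runs with direction and
#'   concentrations), `candidate_concs`.
#' @export
positivity_rule <- function(calls, cytotoxic = rep(FALSE, nrow(calls))) {
  conc_col <- if ("conc_h295r" %in% names(calls)) "conc_h295r" else "conc"
  o <- order(calls[[conc_col]])
  calls <- calls[o, , drop = FALSE]
  cytotoxic <- cytotoxic[o]
  concs <- calls[[conc_col]]
  max_nc <- if (any(!cytotoxic)) max(concs[!cytotoxic]) else NA_real_
  runs <- significance_runs(calls)
  qual <- Filter(function(r) {
    length(r$rows) >= 2 ||
      (!is.na(max_nc) && any(concs[r$rows] == max_nc))
  }, runs)
  qual <- lapply(qual, function(r) {
    list(direction = r$direction, concs = concs[r$rows])
  })
  list(positive = length(qual) > 0, runs = qual,
       candidate_concs = sort(unique(unlist(lapply(qual, `[[`, "concs")))))
}

#' Lowest observed effect concentration
#'
#' The lowest concentration of the qualifying run(s); isolated significant
#' hits below the run have already been discarded by [positivity_rule()],
#' so a chance hit at a low concentration does not drag the LOEC down.
#'
#' @param positivity result of [positivity_rule()].
#' @return LOEC (same units as the input concentrations).
#' @export
loec <- function(positivity) {
  if (!positivity$positive) {
    stop("LOEC requested for a negative endpoint")
  }
  min(positivity$candidate_concs)
}

#' Direction profile of a positive endpoint
#'
#' `"up"` when every qualifying run lies above the reference, `"down"` when
#' below, `"down_then_up"` when a lower-concentration down-run precedes a
#' higher-concentration up-run (and `"up_then_down"` for the reverse).
#'
#' @param positivity result of [positivity_rule()] with `positive = TRUE`.
#' @return effect direction string.
#' @export
direction_profile <- function(positivity) {
  dirs <- vapply(positivity$runs, `[[`, character(1), "direction")
  if (all(dirs == "up")) return("up")
  if (all(dirs == "down")) return("down")
  starts <- vapply(positivity$runs, function(r) min(r$concs), numeric(1))
  first <- dirs[which.min(starts)]
  if (first == "down") "down_then_up" else "up_then_down"
}

#' Direct receptor activity calls from sham-well comparisons
#'
#' Applies the positivity rule to the sham-well statistical calls, excluding
#' CALUX-cytotoxic concentrations from the evidence, and reports the LOEC on
#' both the nominal H295R scale and the CALUX-well scale (dividing by the
#' fold dilution).
#'
#' @param calls sham-well per-concentration calls (nominal H295R
#'   concentrations).
#' @param calux_cytotoxic logical vector aligned with `calls`.
#' @param fold fold dilution into the CALUX plate (mean fold for ER).
#' @return list: `present`, `loec_nominal`, `loec_calux`, `direction`.
#' @export
direct_receptor_calls <- function(calls, calux_cytotoxic =
                                    rep(FALSE, nrow(calls)), fold = 1) {
  calls2 <- calls
  calls2$significant <- calls2$significant & !calux_cytotoxic
  pos <- positivity_rule(calls2, calux_cytotoxic)
  if (!pos$positive) {
    return(list(present = FALSE, loec_nominal = NA_real_,
                loec_calux = NA_real_, direction = NA_character_))
  }
  l <- loec(pos)
  list(present = TRUE, loec_nominal = l, loec_calux = l / fold,
       direction = direction_profile(pos))
}

#' Demotion of confounded steroidogenic candidates
#'
#' A steroidogenic positive is demoted to `nd`:
#' * with `masked_by = "direct_receptor"` when statistically significant and
#'   biologically relevant (at least `relevance` percentage points from the
#'   mode's reference level) direct receptor activity co-occurs at any of
#'   the candidate's nominal H295R concentrations;
#' * with `masked_by = "cytotoxicity"` when the candidate effect is a
#'   decrease, every candidate concentration is cytotoxic to H295R cells,
#'   and CALUX viability at those concentrations is normal (so the hormone
#'   readout itself is trustworthy but reflects dying producer cells).
#'
#' The rule only ever demotes; a negative endpoint is never promoted.
#'
#' @param candidate result of [positivity_rule()] for the steroidogenic
#'   endpoint.
#' @param effect direction from [direction_profile()] (or `"nd"`).
#' @param direct_calls sham-well calls for the matching receptor, with
#'   `mean_level` and `significant` columns (nominal concentrations).
#' @param ref_level reference level of the direct mode (100 antagonist,
#'   0 agonist).
#' @param h295r_cytotoxic,calux_cytotoxic per-concentration logical flags
#'   named by nominal concentration (as `as.character(signif(conc, 10))`).
#' @param relevance biological-relevance band in percentage points
#'   (default 10).
#' @return list with final `effect`, `loec`, `masked_by`.
#' @export
masking_rule <- function(candidate, effect, direct_calls, ref_level,
                         h295r_cytotoxic, calux_cytotoxic,
                         relevance = 10) {
  if (!candidate$positive) {
    return(list(effect = "nd", loec = NA_real_, masked_by = "none"))
  }
  cc <- candidate$candidate_concs
  key <- function(x) as.character(signif(x, 10))
  relevant <- direct_calls$significant &
    abs(direct_calls$mean_level - ref_level) >= relevance
  conc_col <- if ("conc_h295r" %in% names(direct_calls)) "conc_h295r" else
    "conc"
  relevant_concs <- direct_calls[[conc_col]][relevant]
  if (length(relevant_concs) > 0 && any(key(cc) %in% key(relevant_concs))) {
    return(list(effect = "nd", loec = NA_real_,
                masked_by = "direct_receptor"))
  }
  is_decrease <- effect %in% c("down", "down_then_up")
  h_cyto <- h295r_cytotoxic[key(cc)]
  c_cyto <- calux_cytotoxic[key(cc)]
  h_cyto[is.na(h_cyto)] <- FALSE
  c_cyto[is.na(c_cyto)] <- FALSE
  if (is_decrease && length(h_cyto) > 0 && all(h_cyto) && !any(c_cyto)) {
    return(list(effect = "nd", loec = NA_real_, masked_by = "cytotoxicity"))
  }
  list(effect = effect, loec = min(cc), masked_by = "none")
}

#' Bootstrap confidence-interval overlap diagnostic
#'
#' Percentile-bootstrap 95% confidence intervals of the group means, with
#' the overlap indicator and whether the mean separation exceeds the
#' biological-relevance band (two activities closer than that band are
#' within normal assay variation even when their intervals are disjoint).
#'
#' @param activity,sham numeric vectors (n >= 3 each).
#' @param n_boot bootstrap draws.
#' @param level confidence level.
#' @param relevance separation band in percentage points.
#' @param seed optional RNG seed for reproducibility.
#' @return list: `ci_activity`, `ci_sham`, `overlap`, `delta`,
#'   `exceeds_relevance`.
#' @export
ci_overlap_diagnostic <- function(activity, sham, n_boot = 2000,
                                  level = 0.95, relevance = 10,
                                  seed = NULL) {
  stopifnot(length(activity) >= 3, length(sham) >= 3)
  if (!is.null(seed)) set.seed(seed)
  boot_ci <- function(v) {
    means <- vapply(seq_len(n_boot), function(i) {
      mean(sample(v, length(v), replace = TRUE))
    }, numeric(1))
    stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  }
  ci_a <- boot_ci(activity)
  ci_b <- boot_ci(sham)
  overlap <- ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2]
  delta <- abs(mean(activity) - mean(sham))
  list(ci_activity = ci_a, ci_sham = ci_b, overlap = overlap,
       delta = delta, exceeds_relevance = delta >= relevance)
}

# fold dilutions may vary by chemical/experiment: a named vector is looked
# up per chemical, with a "default" entry (or the mean) as fallback
fold_for <- function(fold, chem) {
  if (is.null(names(fold))) return(fold[1])
  if (chem %in% names(fold)) return(unname(fold[chem]))
  if ("default" %in% names(fold)) return(unname(fold["default"]))
  mean(fold)
}

endpoint_family <- function(endpoint) {
  switch(endpoint,
         estrogen_activity = "estrogens",
         direct_estrogenicity = "estrogens",
         androgen_activity = "androgens",
         direct_antiandrogenicity = "androgens",
         direct_androgenicity = "androgens",
         NA_character_)
}

#' Classify chemicals from per-concentration calls and viability
#'
#' End-stage classification: for every chemical and hormone family, applies
#' the positivity rule to the steroidogenic calls (with H295R cytotoxicity),
#' derives direct receptor calls from the sham comparisons (with CALUX
#' cytotoxicity and the dilution fold), and resolves masking. Chemicals
#' whose only activity is at the receptor come out as steroidogenesis `nd`
#' with the direct call recorded.
#'
#' @param calls per-concentration call table: `chemical_id`, `endpoint`
#'   (one of the five endpoint names), `conc_h295r` (nominal),
#'   `significant`, `direction`, `mean_level`.
#' @param viability viability table for [flag_cytotoxicity()] (nominal
#'   H295R concentrations for every assay).
#' @param er_fold,ar_fold fold dilutions used to express direct-receptor
#'   LOECs on the CALUX-well concentration scale; either a single value or
#'   a named vector keyed by chemical (with an optional `default` entry)
#'   when the dilution varied between chemicals.
#' @param relevance biological-relevance band (percentage points).
#' @param cyto_threshold viability threshold in percent.
#' @return data frame: one row per chemical per family with `effect`,
#'   `loec`, `masked_by`, `direct_present`, `direct_loec_nominal`,
#'   `direct_loec_calux`, `cytotoxic_concs`.
#' @export
classify_chemicals <- function(calls, viability,
                               er_fold = mean(c(200 / 30, 200 / 28, 200 / 25)),
                               ar_fold = 200 / 67, relevance = 10,
                               cyto_threshold = 80) {
  flags <- flag_cytotoxicity(viability, cyto_threshold)
  key <- function(x) as.character(signif(x, 10))
  cyto_map <- function(chem, assay) {
    f <- flags[flags$chemical_id == chem & flags$assay == assay, ,
               drop = FALSE]
    stats::setNames(f$cytotoxic, key(f$conc))
  }
  out <- list()
  for (chem in unique(calls$chemical_id)) {
    for (fam in c("androgens", "estrogens")) {
      ster_ep <- if (fam == "androgens") "androgen_activity" else
        "estrogen_activity"
      direct_eps <- if (fam == "androgens") {
        c("direct_antiandrogenicity", "direct_androgenicity")
      } else "direct_estrogenicity"
      calux_assay <- if (fam == "androgens") "AR_CALUX" else "ER_CALUX"
      fold <- fold_for(if (fam == "androgens") ar_fold else er_fold, chem)

      ster <- calls[calls$chemical_id == chem & calls$endpoint == ster_ep, ,
                    drop = FALSE]
      direct <- calls[calls$chemical_id == chem &
                        calls$endpoint %in% direct_eps, , drop = FALSE]
      if (nrow(ster) == 0 && nrow(direct) == 0) next
      h_cyto <- cyto_map(chem, "H295R")
      c_cyto <- cyto_map(chem, calux_assay)
      align <- function(df, map) {
        v <- map[key(df$conc_h295r)]
        v[is.na(v)] <- FALSE
        unname(v)
      }
      dcall <- if (nrow(direct) > 0) {
        direct_receptor_calls(direct, align(direct, c_cyto), fold)
      } else {
        list(present = FALSE, loec_nominal = NA_real_,
             loec_calux = NA_real_, direction = NA_character_)
      }
      if (nrow(ster) > 0) {
        pos <- positivity_rule(ster, align(ster, h_cyto))
        eff <- if (pos$positive) direction_profile(pos) else "nd"
        ref_level <- if (nrow(direct) > 0)
          mode_reference_level(direct$endpoint[1]) else 100
        masked <- masking_rule(pos, eff,
                               if (nrow(direct) > 0) direct else
                                 data.frame(conc_h295r = numeric(0),
                                            significant = logical(0),
                                            mean_level = numeric(0)),
                               ref_level, h_cyto, c_cyto, relevance)
      } else {
        masked <- list(effect = "nd", loec = NA_real_, masked_by = "none")
      }
      cyto_concs <- names(h_cyto)[h_cyto]
      out[[paste(chem, fam)]] <- data.frame(
        chemical_id = chem, family = fam,
        effect = masked$effect, loec = masked$loec,
        masked_by = masked$masked_by,
        direct_present = dcall$present,
        direct_loec_nominal = dcall$loec_nominal,
        direct_loec_calux = dcall$loec_calux,
        direct_direction = dcall$direction,
        cytotoxic_concs = paste(cyto_concs, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
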