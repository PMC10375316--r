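# Five-plate simulator with known ground truth: 4PL standard curves,
# treatment-driven Hill-shaped changes in basal estrogen/androgen
# production, direct receptor (ant)agonism appearing in sham wells,
# cytotoxicity, supernatant dilution and multiplicative measurement noise.

#' Chemical behaviour model for the simulator
#'
#' Parameterizes the phenomenology the coupled assay observes: Hill-shaped
#' steroidogenic effects per hormone family (`max_fold` > 1 induction,
#' < 1 inhibition; an optional second term makes the profile biphasic),
#' direct ER agonism as an E2-equivalence factor, direct AR antagonism as a
#' competitive IC50, and cytotoxicity per cell type.
#'
#' @param chemical_id identifier.
#' @param estrogens,androgens `NULL` or a list `list(ec50=, max_fold=,
#'   hill=)`, optionally with `ec50_2`, `max_fold_2`, `hill_2` for a second
#'   (biphasic) term.
#' @param direct_er `NULL` or `list(e2_equivalence=)`: mol E2-equivalent
#'   per mol of chemical, acting additively on the effective agonist
#'   concentration.
#' @param direct_ar `NULL` or `list(ic50=)`: competitive antagonism shifts
#'   the agonist AC50 by `(1 + conc/ic50)`.
#' @param cytotox_h295r,cytotox_calux `NULL` or `list(lc50=, hill=)`.
#' @return object of class `chemical_model`.
#' @export
chemical_model <- function(chemical_id, estrogens = NULL, androgens = NULL,
                           direct_er = NULL, direct_ar = NULL,
                           cytotox_h295r = NULL, cytotox_calux = NULL) {
  check_term <- function(t) {
    if (is.null(t)) return(invisible(NULL))
    stopifnot(t$ec50 > 0, t$max_fold > 0, t$hill > 0)
  }
  check_term(estrogens); check_term(androgens)
  if (!is.null(direct_er)) stopifnot(direct_er$e2_equivalence > 0)
  if (!is.null(direct_ar)) stopifnot(direct_ar$ic50 > 0)
  for (cy in list(cytotox_h295r, cytotox_calux)) {
    if (!is.null(cy)) stopifnot(cy$lc50 > 0, cy$hill > 0)
  }
  structure(list(chemical_id = chemical_id, estrogens = estrogens,
                 androgens = androgens, direct_er = direct_er,
                 direct_ar = direct_ar, cytotox_h295r = cytotox_h295r,
                 cytotox_calux = cytotox_calux),
            class = "chemical_model")
}

hill_fraction <- function(conc, ec50, hill) {
  ifelse(conc <= 0, 0, conc^hill / (conc^hill + ec50^hill))
}

fold_response <- function(conc, term) {
  if (is.null(term)) return(rep(1, length(conc)))
  f <- 1 + (term$max_fold - 1) * hill_fraction(conc, term$ec50, term$hill)
  if (!is.null(term$ec50_2)) {
    f <- f * (1 + (term$max_fold_2 - 1) *
                hill_fraction(conc, term$ec50_2, term$hill_2))
  }
  f
}

viability_fraction <- function(conc, cy) {
  if (is.null(cy)) return(rep(1, length(conc)))
  1 / (1 + (conc / cy$lc50)^cy$hill)
}

#' Preset chemical behaviour library
#'
#' Archetypes covering the behaviours the assay must distinguish: a strong
#' steroidogenesis inhibitor (prochloraz-like), an estrogen-synthesis
#' inducer (forskolin-like), a picomolar-potency aromatase inhibitor with
#' weak AR antagonism at high concentrations (letrozole-like), a pure
#' direct ER agonist / AR antagonist with no steroidogenic term (BPA-like),
#' an H295R-selective cytotoxicant with sham-well AR antagonism
#' (benomyl-like), a broad cytotoxicant (cadmium-like), a weak dual inducer
#' with borderline cytotoxicity (PFOS-like), and an inactive chemical.
#'
#' @return named list of [chemical_model()] objects.
#' @export
preset_chemicals <- function() {
  list(
    prochloraz_like = chemical_model(
      "prochloraz_like",
      estrogens = list(ec50 = 1e-8, max_fold = 0.05, hill = 1.5),
      androgens = list(ec50 = 1e-8, max_fold = 0.05, hill = 1.5)),
    forskolin_like = chemical_model(
      "forskolin_like",
      estrogens = list(ec50 = 1e-7, max_fold = 6, hill = 1)),
    letrozole_like = chemical_model(
      "letrozole_like",
      estrogens = list(ec50 = 3e-11, max_fold = 0.1, hill = 1),
      direct_ar = list(ic50 = 1e-5)),
    bpa_like = chemical_model(
      "bpa_like",
      direct_er = list(e2_equivalence = 3e-5),
      direct_ar = list(ic50 = 3e-7)),
    benomyl_like = chemical_model(
      "benomyl_like",
      estrogens = list(ec50 = 3e-6, max_fold = 0.5, hill = 2),
      direct_ar = list(ic50 = 2e-6),
      cytotox_h295r = list(lc50 = 5e-6, hill = 2)),
    cadmium_like = chemical_model(
      "cadmium_like",
      cytotox_h295r = list(lc50 = 3e-6, hill = 1.5),
      cytotox_calux = list(lc50 = 5e-5, hill = 1.5)),
    pfos_like = chemical_model(
      "pfos_like",
      estrogens = list(ec50 = 3e-5, max_fold = 2, hill = 1),
      androgens = list(ec50 = 3e-5, max_fold = 2, hill = 1),
      cytotox_h295r = list(lc50 = 2.5e-4, hill = 3)),
    inhibitor_step = chemical_model(
      # inhibitor whose effect threshold falls between the 3rd and 4th
      # default grid concentrations (1e-8 and 3e-8 M)
      "inhibitor_step",
      estrogens = list(ec50 = 5e-8, max_fold = 0.1, hill = 3),
      androgens = list(ec50 = 5e-8, max_fold = 0.1, hill = 3)),
    inactive = chemical_model("inactive"))
}

# behaviour models for the plate positive controls
control_models <- function() {
  list(
    forskolin = chemical_model(
      "forskolin", estrogens = list(ec50 = 1e-7, max_fold = 6, hill = 1)),
    pfos = chemical_model(
      "pfos",
      estrogens = list(ec50 = 3e-5, max_fold = 2, hill = 1),
      androgens = list(ec50 = 3e-5, max_fold = 2, hill = 1)),
    prochloraz = chemical_model(
      "prochloraz",
      estrogens = list(ec50 = 3e-8, max_fold = 0.05, hill = 1.5),
      androgens = list(ec50 = 3e-8, max_fold = 0.05, hill = 1.5)),
    menadione = chemical_model(
      "menadione", cytotox_h295r = list(lc50 = 3e-6, hill = 2)))
}

control_concs <- c(forskolin = 1e-6, pfos = 1e-4, prochloraz = 1e-6,
                   menadione = 1e-5)

#' Simulation configuration
#'
#' The stated world of the simulator: basal hormone-equivalent
#' concentrations in the H295R supernatant are chosen so that the diluted
#' basal lands at about a 50% response on the CALUX standard curves (the
#' design premise of the 3-fold AR dilution); default curve AC50s sit at
#' the geometric midpoints of the acceptance windows; measurement noise is
#' multiplicative log-normal with a 10% CV.
#'
#' @param seed integer RNG seed.
#' @param n_bio biological replicates (default 3).
#' @param conc_grid default 8-point half-log test concentration grid
#'   (mol/L, ascending).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param basal_e2,basal_t basal hormone-equivalent concentrations (mol/L)
#'   in undiluted H295R supernatant.
#' @param scheme a [dilution_scheme()].
#' @param viab_rlu mean viability RLU of healthy wells.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_bio = 3,
                              conc_grid = c(1e-9, 3e-9, 1e-8, 3e-8,
                                            1e-7, 3e-7, 1e-6, 3e-6),
                              noise_cv = 0.10,
                              basal_e2 = 1.0e-10, basal_t = 6.8e-10,
                              scheme = dilution_scheme(),
                              viab_rlu = 5000) {
  stopifnot(noise_cv >= 0, basal_e2 > 0, basal_t > 0)
  curves <- list(
    E2 = list(bg = 100, span = 900,
              ac50 = sqrt(6.5e-12 * 3e-11), hill = 1,
              grid = standard_curve_spec("E2")$grid),
    DHT = list(bg = 100, span = 1900,
               ac50 = sqrt(1.2e-10 * 4.3e-10), hill = 1,
               grid = standard_curve_spec("DHT")$grid),
    FLT = list(bg = 100, span = 1900, ki = 3e-7,
               co_agonist_conc = 0.3e-9,
               grid = standard_curve_spec("FLT")$grid))
  structure(list(seed = as.integer(seed), n_bio = n_bio,
                 conc_grid = conc_grid, noise_cv = noise_cv,
                 basal_e2 = basal_e2, basal_t = basal_t, scheme = scheme,
                 curves = curves, viab_rlu = viab_rlu),
            class = "simulation_config")
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Hormone-equivalent production of treated H295R cells
#'
#' Basal production scaled by the chemical's Hill fold-change terms and by
#' the viable-cell fraction (production scales with surviving cells).
#'
#' @param model a [chemical_model()].
#' @param conc treatment concentration(s), mol/L.
#' @param cfg a [simulation_config()].
#' @return list with `e2_equiv`, `t_equiv` (mol/L in supernatant) and
#'   `viability` (fraction).
#' @export
simulate_hormones <- function(model, conc, cfg = simulation_config()) {
  viab <- viability_fraction(conc, model$cytotox_h295r)
  list(e2_equiv = cfg$basal_e2 * fold_response(conc, model$estrogens) * viab,
       t_equiv = cfg$basal_t * fold_response(conc, model$androgens) * viab,
       viability = viab)
}

#' Reporter signal of a CALUX well
#'
#' Deterministic part of the luminescence model: the effective agonist
#' concentration is the diluted hormone equivalent plus the
#' agonist-equivalents of the carried chemical; competitive antagonism by
#' the carried chemical shifts the curve AC50 by `(1 + conc/ic50)`; the RLU
#' is `bg + span * response`, scaled by the CALUX viability fraction.
#' Multiplicative noise is applied by the caller.
#'
#' @param hormone_equiv diluted agonist-equivalent hormone concentration
#'   (mol/L).
#' @param model the carried chemical's [chemical_model()] (or `NULL`).
#' @param chem_conc carried chemical concentration in the CALUX well.
#' @param receptor `"ER"` or `"AR"`.
#' @param mode `"agonist"` or `"antagonist"` (antagonist mode adds the
#'   co-agonist at its fixed concentration).
#' @param cfg a [simulation_config()].
#' @return list with `rlu` (noise-free) and `viability` fraction.
#' @export
calux_signal <- function(hormone_equiv, model, chem_conc,
                         receptor = c("ER", "AR"),
                         mode = c("agonist", "antagonist"),
                         cfg = simulation_config()) {
  receptor <- match.arg(receptor)
  mode <- match.arg(mode)
  curve <- if (receptor == "ER") cfg$curves$E2 else cfg$curves$DHT
  agonist <- hormone_equiv
  if (mode == "antagonist") {
    agonist <- agonist + cfg$curves$FLT$co_agonist_conc
  }
  if (receptor == "ER" && !is.null(model$direct_er)) {
    agonist <- agonist + model$direct_er$e2_equivalence * chem_conc
  }
  ac50 <- curve$ac50
  if (receptor == "AR" && !is.null(model$direct_ar)) {
    ac50 <- ac50 * (1 + chem_conc / model$direct_ar$ic50)
  }
  resp <- four_pl(agonist, 0, 1, ac50, curve$hill)
  viab <- viability_fraction(chem_conc,
                             if (is.null(model)) NULL else model$cytotox_calux)
  list(rlu = (curve$bg + curve$span * resp) * viab, viability = viab)
}

# standard-curve well RLU (noise-free) for one curve point
curve_rlu <- function(compound, conc, cfg) {
  cv <- cfg$curves
  if (compound == "E2") {
    cv$E2$bg + cv$E2$span * four_pl(conc, 0, 1, cv$E2$ac50, cv$E2$hill)
  } else if (compound == "DHT") {
    cv$DHT$bg + cv$DHT$span * four_pl(conc, 0, 1, cv$DHT$ac50, cv$DHT$hill)
  } else { # FLT antagonist curve: fixed DHT co-agonist, FLT shifts AC50
    d <- cv$FLT$co_agonist_conc
    ac <- cv$DHT$ac50 * (1 + conc / cv$FLT$ki)
    cv$FLT$bg + cv$FLT$span * four_pl(d, 0, 1, ac, cv$DHT$hill)
  }
}

noisy <- function(x, cfg) x * lognormal_noise(length(x), cfg$noise_cv)

#' Assemble a complete simulated experiment
#'
#' Builds, for every chemical model and biological replicate, the raw
#' long-format measurement tables of the five-plate design (one H295R
#' plate, three ER CALUX plates at their respective dilutions, one AR CALUX
#' plate with the FLT antagonist curve), including standard curves,
#' vehicle/medium controls, the four positive controls, and sham wells.
#' Direct receptor activity of the carried chemical acts identically in
#' treated and sham wells -- the identifiability premise of the coupled
#' design. Fully reproducible from the seed; a ground-truth ledger records
#' each model's parameters and the tested grid.
#'
#' @param models list of [chemical_model()] objects (e.g. from
#'   [preset_chemicals()]).
#' @param cfg a [simulation_config()].
#' @return list with `measurements` (validated data frame) and `truth`.
#' @export
assemble_experiment <- function(models, cfg = simulation_config()) {
  set.seed(cfg$seed)
  if (inherits(models, "chemical_model")) models <- list(models)
  layout <- default_layout(length(cfg$conc_grid))
  ctl_models <- control_models()
  all_rows <- list()
  for (model in models) {
    grids <- list()
    for (bio in seq_len(cfg$n_bio)) {
      ps <- simulate_plateset(model, bio, layout, cfg, ctl_models)
      all_rows[[paste(model$chemical_id, bio)]] <- ps
    }
  }
  meas <- do.call(rbind, all_rows)
  rownames(meas) <- NULL
  attr(meas, "units_normalized") <- TRUE
  validate_measurements(meas)
  truth <- lapply(models, function(m) {
    list(model = m, conc_grid = cfg$conc_grid)
  })
  names(truth) <- vapply(models, `[[`, character(1), "chemical_id")
  list(measurements = meas, truth = truth)
}

# one biological replicate: 1 H295R + 3 ER + 1 AR plate for one chemical
simulate_plateset <- function(model, bio, layout, cfg, ctl_models) {
  chem <- model$chemical_id
  grid <- cfg$conc_grid
  n <- nrow(layout)

  well_model <- function(chemical) {
    if (is.na(chemical)) NULL
    else if (chemical == chem) model
    else ctl_models[[chemical]]
  }

  # chemical and concentration per layout slot (shared by all 5 plates)
  chem_of <- rep(NA_character_, n)
  conc_of <- rep(NA_real_, n)
  treatlike <- layout$role %in% c("h295r_treated", "sham") &
    is.na(layout$control)
  chem_of[treatlike] <- chem
  conc_of[treatlike] <- grid[layout$conc_rank[treatlike]]
  posctl <- !is.na(layout$control) &
    layout$control %in% names(control_concs)
  chem_of[posctl] <- layout$control[posctl]
  conc_of[posctl] <- control_concs[layout$control[posctl]]
  veh <- !is.na(layout$control) & layout$control == "vehicle"
  chem_of[veh] <- "DMSO"

  has_cells_h295r <- layout$col <= 6 & layout$role != "standard_curve"
  hseq <- lapply(seq_len(n), function(i) {
    if (!has_cells_h295r[i]) return(list(e2_equiv = 0, t_equiv = 0,
                                         viability = 0))
    m <- well_model(chem_of[i])
    if (is.null(m)) {
      return(list(e2_equiv = cfg$basal_e2, t_equiv = cfg$basal_t,
                  viability = 1))
    }
    simulate_hormones(m, ifelse(is.na(conc_of[i]), 0, conc_of[i]), cfg)
  })
  e2_sup <- vapply(hseq, `[[`, numeric(1), "e2_equiv")
  t_sup <- vapply(hseq, `[[`, numeric(1), "t_equiv")
  viab_h <- vapply(hseq, `[[`, numeric(1), "viability")

  base_df <- function(plate_id, assay) {
    data.frame(plate_id = plate_id, assay = assay, mode = "none",
               row = layout$row, col = layout$col, role = layout$role,
               control = layout$control, curve_role = NA_character_,
               chemical_id = chem_of, conc_h295r = conc_of,
               conc_standard = NA_real_,
               bio_rep = bio, tech_rep = layout$tech_rep,
               rlu_reporter = NA_real_, rlu_viability = NA_real_,
               supernatant_vol_ul = NA_real_, total_vol_ul = NA_real_,
               stringsAsFactors = FALSE)
  }

  # H295R plate: same-well viability assay only
  h <- base_df(sprintf("%s_H295R_b%d", chem, bio), "H295R")
  cellw <- has_cells_h295r
  h$rlu_viability[cellw] <- noisy(cfg$viab_rlu * viab_h[cellw], cfg)
  h$rlu_viability[!cellw] <- noisy(rep(cfg$viab_rlu * 0.01, sum(!cellw)),
                                   cfg)
  plates <- list(h)

  calux_plate <- function(k, receptor) {
    assay <- if (receptor == "ER") "ER_CALUX" else "AR_CALUX"
    vols <- if (receptor == "ER") cfg$scheme$er[[k]] else cfg$scheme$ar
    fold <- vols[2] / vols[1]
    p <- base_df(sprintf("%s_%s%d_b%d", chem, assay, k, bio), assay)
    p$supernatant_vol_ul <- vols[1]
    p$total_vol_ul <- vols[2]
    curve_compound <- if (receptor == "ER") "E2" else "FLT"
    cgrid <- cfg$curves[[curve_compound]]$grid
    is_curve <- layout$role == "standard_curve"
    cp <- layout$curve_point
    # curve point 1: vehicle; on the FLT curve point 2 is the agonist-only
    # well; remaining points walk the concentration grid
    for (i in which(is_curve)) {
      if (cp[i] == 1) {
        p$curve_role[i] <- "vehicle"
        p$rlu_reporter[i] <- noisy(cfg$curves[[curve_compound]]$bg, cfg)
      } else if (curve_compound == "FLT" && cp[i] == 2) {
        p$curve_role[i] <- "agonist_only"
        p$rlu_reporter[i] <- noisy(curve_rlu("FLT", 0, cfg), cfg)
      } else {
        offset <- if (curve_compound == "FLT") 2 else 1
        cc <- cgrid[cp[i] - offset]
        p$curve_role[i] <- "standard"
        p$conc_standard[i] <- cc
        p$rlu_reporter[i] <- noisy(curve_rlu(curve_compound, cc, cfg), cfg)
      }
      p$rlu_viability[i] <- noisy(cfg$viab_rlu, cfg)
    }
    # treated-side and sham wells
    test_wells <- which(!is_curve)
    for (i in test_wells) {
      m <- well_model(chem_of[i])
      cw <- if (is.na(conc_of[i])) 0 else conc_of[i] / fold
      sham_side <- layout$role[i] == "sham" |
        (layout$col[i] > 6 & layout$role[i] != "standard_curve")
      if (sham_side) {
        horm <- 0
        # medium-only sham wells are chemical- and co-agonist-free blanks;
        # the other sham wells on the AR plate run in antagonist mode
        is_medium <- !is.na(layout$control[i]) &&
          layout$control[i] == "medium"
        mode <- if (receptor == "AR" && !is_medium) "antagonist" else
          "agonist"
      } else {
        horm <- if (receptor == "ER") e2_sup[i] / fold else t_sup[i] / fold
        mode <- "agonist"
      }
      sig <- calux_signal(horm, m, cw, receptor, mode, cfg)
      p$mode[i] <- mode
      p$rlu_reporter[i] <- noisy(sig$rlu, cfg)
      p$rlu_viability[i] <- noisy(cfg$viab_rlu * sig$viability, cfg)
    }
    p
  }
  for (k in 1:3) plates[[length(plates) + 1]] <- calux_plate(k, "ER")
  plates[[length(plates) + 1]] <- calux_plate(1, "AR")
  do.call(rbind, plates)
}
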