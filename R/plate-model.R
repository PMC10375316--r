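#' @keywords internal
"_PACKAGE"

# Enumerations used across the package. Kept as plain character constants so
# that tables serialize cleanly to CSV/JSON.
ASSAYS <- c("H295R", "ER_CALUX", "AR_CALUX")
MODES <- c("agonist", "antagonist", "none")
ROLES <- c("h295r_treated", "sham", "standard_curve", "vehicle_control",
           "medium_control", "positive_control")
CURVE_ROLES <- c("vehicle", "agonist_only", "standard")
ENDPOINTS <- c("estrogen_activity", "androgen_activity",
               "direct_estrogenicity", "direct_antiandrogenicity",
               "direct_androgenicity")

# Moles of hormone per international unit: 1 IU/ml HCG = 3.9e-6 M.
IU_PER_ML_TO_M <- 3.9e-6

MEASUREMENT_COLUMNS <- c(
  "plate_id", "assay", "mode", "row", "col", "role", "chemical_id",
  "conc_h295r", "conc_standard", "bio_rep", "tech_rep",
  "rlu_reporter", "rlu_viability", "supernatant_vol_ul", "total_vol_ul")

parse_error <- function(msg, plate = NULL, row = NULL, col = NULL) {
  where <- if (!is.null(plate)) {
    sprintf(" [plate %s, well %s%s]",
            paste(plate, collapse = ","),
            paste(row, collapse = ","), paste(col, collapse = ","))
  } else ""
  stop(errorCondition(paste0(msg, where),
                      class = c("h295calux_parse_error", "error")))
}

#' Validate a table of per-well measurements
#'
#' Checks the structural invariants of a long-format well measurement table:
#' required columns, known enum levels, non-negative luminescence, unique
#' well coordinates within a plate, and supernatant volume not exceeding the
#' final well volume.
#'
#' @param df data frame with one row per well (see
#'   `system.file("extdata", "measurement_schema.json", package =
#'   "h295calux")` for the column contract).
#' @return the validated data frame, invisibly.
#' @export
validate_measurements <- function(df) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing) > 0) {
    parse_error(paste0("missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  bad_role <- !df$role %in% ROLES
  if (any(bad_role)) {
    i <- which(bad_role)[1]
    parse_error(sprintf("unknown role '%s'", df$role[i]),
                df$plate_id[i], df$row[i], df$col[i])
  }
  bad_assay <- !df$assay %in% ASSAYS
  if (any(bad_assay)) {
    i <- which(bad_assay)[1]
    parse_error(sprintf("unknown assay '%s'", df$assay[i]),
                df$plate_id[i], df$row[i], df$col[i])
  }
  for (colname in c("rlu_reporter", "rlu_viability")) {
    v <- df[[colname]]
    if (!is.numeric(v)) parse_error(sprintf("non-numeric %s", colname))
    bad <- !is.na(v) & v < 0
    if (any(bad)) {
      i <- which(bad)[1]
      parse_error(sprintf("negative %s", colname),
                  df$plate_id[i], df$row[i], df$col[i])
    }
  }
  key <- paste(df$plate_id, df$row, df$col)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    parse_error("duplicate well", df$plate_id[i], df$row[i], df$col[i])
  }
  bad_vol <- !is.na(df$supernatant_vol_ul) & !is.na(df$total_vol_ul) &
    df$supernatant_vol_ul > df$total_vol_ul
  if (any(bad_vol)) {
    i <- which(bad_vol)[1]
    parse_error("supernatant volume exceeds total well volume",
                df$plate_id[i], df$row[i], df$col[i])
  }
  both <- !is.na(df$conc_h295r) & !is.na(df$conc_standard)
  if (any(both)) {
    i <- which(both)[1]
    parse_error("both conc_h295r and conc_standard set",
                df$plate_id[i], df$row[i], df$col[i])
  }
  invisible(df)
}

#' Normalize concentration units to mol/L
#'
#' Concentrations are stored internally in mol/L. Input tables may carry a
#' `conc_unit` column with values `"M"`, `"uM"` or `"IU_per_ml"` (the latter
#' for gonadotropin dosing, converted at 1 IU/ml = 3.9e-6 M). Applying the
#' conversion twice is detected and refused.
#'
#' @param df measurement data frame.
#' @return data frame with `conc_h295r`/`conc_standard` in mol/L and an
#'   attribute `units_normalized = TRUE`.
#' @export
normalize_units <- function(df) {
  if (isTRUE(attr(df, "units_normalized"))) {
    stop("units already normalized to mol/L; refusing to convert twice")
  }
  if (!is.null(df$conc_unit)) {
    factor <- c(M = 1, uM = 1e-6, IU_per_ml = IU_PER_ML_TO_M)[df$conc_unit]
    if (anyNA(factor[!is.na(df$conc_unit)])) {
      parse_error(paste0("unknown conc_unit: ",
                         paste(unique(df$conc_unit[is.na(factor)]),
                               collapse = ", ")))
    }
    factor[is.na(factor)] <- 1
    df$conc_h295r <- df$conc_h295r * factor
    df$conc_standard <- df$conc_standard * factor
    df$conc_unit <- NULL
  }
  attr(df, "units_normalized") <- TRUE
  df
}

#' Read a long-format well measurement table
#'
#' One CSV row per well. Numeric concentrations are normalized to mol/L (see
#' [normalize_units()]). Structural problems raise a parse error naming the
#' offending plate/row/column.
#'
#' @param path CSV file path.
#' @return validated measurement data frame (concentrations in mol/L).
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (colname in c("conc_h295r", "conc_standard")) {
    if (!is.null(df[[colname]]) && !is.numeric(df[[colname]])) {
      suppressWarnings(num <- as.numeric(df[[colname]]))
      bad <- !is.na(df[[colname]]) & df[[colname]] != "" & is.na(num)
      if (any(bad)) parse_error(sprintf("non-numeric %s", colname))
      df[[colname]] <- num
    }
  }
  if (is.null(df$curve_role)) {
    df$curve_role <- ifelse(df$role == "standard_curve", "standard",
                            NA_character_)
  }
  if (is.null(df$control)) df$control <- NA_character_
  df$control[!is.na(df$control) & df$control == ""] <- NA_character_
  df$curve_role[!is.na(df$curve_role) & df$curve_role == ""] <- NA_character_
  df <- normalize_units(df)
  validate_measurements(df)
  df
}

#' Write a measurement table to CSV
#'
#' Round-trips all fields written by [read_measurements()] (numeric fields to
#' full double precision).
#'
#' @param df measurement data frame.
#' @param path output CSV path.
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Default 96-well plate layout
#'
#' Role map for the shared plate design: standard-curve wells in duplicate on
#' rows A-B, columns 1-5 and 7-11 (10 curve points; point 1 is the vehicle
#' well, point 2 the agonist-only well on antagonist-mode curves); H295R-side
#' wells on rows C-H, columns 1-5 (8 test concentrations in technical
#' triplicate plus triplicate vehicle and medium-only controls); duplicate
#' positive controls in column 6; and a mirrored sham half on columns 7-12.
#'
#' @param n_conc number of test concentrations (default 8).
#' @return data frame with one row per well: `row`, `col`, `role`,
#'   `conc_rank`, `tech_rep`, `curve_point`, `control`.
#' @export
default_layout <- function(n_conc = 8) {
  stopifnot(n_conc >= 1, n_conc <= 8)
  rows <- LETTERS[1:8]
  wells <- expand.grid(row = rows, col = 1:12, stringsAsFactors = FALSE)
  wells$role <- NA_character_
  wells$conc_rank <- NA_integer_
  wells$tech_rep <- NA_integer_
  wells$curve_point <- NA_integer_
  wells$control <- NA_character_
  idx <- function(r, c) match(paste(r, c), paste(wells$row, wells$col))

  # standard curve: rows A-B, columns 1-5 and 7-11, duplicated across rows
  curve_cols <- c(1:5, 7:11)
  for (k in seq_along(curve_cols)) {
    for (r in c("A", "B")) {
      i <- idx(r, curve_cols[k])
      wells$role[i] <- "standard_curve"
      wells$curve_point[i] <- k
      wells$tech_rep[i] <- match(r, c("A", "B"))
    }
  }

  fill_half <- function(wells, cols, role_treat) {
    slots <- expand.grid(row = rows[3:8], col = cols,
                         stringsAsFactors = FALSE)
    slots <- slots[order(slots$col, match(slots$row, rows)), ]
    n_treat <- 3 * n_conc
    for (s in seq_len(nrow(slots))) {
      i <- idx(slots$row[s], slots$col[s])
      if (s <= n_treat) {
        wells$role[i] <- role_treat
        wells$conc_rank[i] <- ((s - 1) %/% 3) + 1L
        wells$tech_rep[i] <- ((s - 1) %% 3) + 1L
      } else if (s <= n_treat + 3) {
        wells$role[i] <- if (role_treat == "sham") "sham" else
          "vehicle_control"
        wells$control[i] <- "vehicle"
        wells$tech_rep[i] <- s - n_treat
      } else if (s <= n_treat + 6) {
        wells$role[i] <- if (role_treat == "sham") "sham" else
          "medium_control"
        wells$control[i] <- "medium"
        wells$tech_rep[i] <- s - n_treat - 3
      }
    }
    wells
  }
  wells <- fill_half(wells, 1:5, "h295r_treated")
  wells <- fill_half(wells, 7:11, "sham")

  # duplicate positive controls, columns 6 (H295R side) and 12 (sham side)
  pos <- rep(c("forskolin", "pfos", "prochloraz", "menadione"), each = 2)
  for (k in 1:8) {
    for (cc in c(6, 12)) {
      i <- idx(rows[k], cc)
      wells$role[i] <- if (cc == 6) "positive_control" else "sham"
      wells$control[i] <- pos[k]
      wells$tech_rep[i] <- ((k - 1) %% 2) + 1L
    }
  }
  wells[order(match(wells$row, rows), wells$col), ]
}

#' Pair treated wells with their sham counterparts
#'
#' Every treated (chemical, concentration) group must have sham wells at the
#' same nominal concentration; the treated-vs-sham contrast is what separates
#' steroidogenesis from direct receptor activity of the carried chemical.
#'
#' @param treated,sham measurement data frames (same plate set).
#' @return data frame keyed by (`chemical_id`, `conc_h295r`) with
#'   `n_treated` and `n_sham` well counts.
#' @export
pair_sham <- function(treated, sham) {
  key <- function(df) paste(df$chemical_id, signif(df$conc_h295r, 10))
  tk <- key(treated)
  sk <- key(sham)
  keys <- unique(tk)
  missing <- setdiff(keys, unique(sk))
  if (length(missing) > 0) {
    stop("treated groups without sham counterpart: ",
         paste(missing, collapse = "; "))
  }
  out <- data.frame(
    chemical_id = treated$chemical_id[match(keys, tk)],
    conc_h295r = treated$conc_h295r[match(keys, tk)],
    n_treated = as.integer(table(tk)[keys]),
    n_sham = as.integer(table(sk)[keys]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Supernatant dilution scheme
#'
#' Volumes (microlitres of supernatant, final well volume) for the transfer
#' of H295R supernatant into the CALUX plates. Defaults follow the standard
#' protocol: three ER plates at 30/200, 28/200 and 25/200 (6.67- to 8-fold)
#' and one AR plate at 67/200 (nominally 3-fold).
#'
#' @param er list of length-2 numeric vectors `c(supernatant_ul, total_ul)`,
#'   one per ER plate.
#' @param ar length-2 numeric vector for the AR plate.
#' @return object of class `dilution_scheme` with per-plate fold dilutions.
#' @export
dilution_scheme <- function(er = list(c(30, 200), c(28, 200), c(25, 200)),
                            ar = c(67, 200)) {
  fold <- function(v) {
    stopifnot(length(v) == 2, v[1] > 0, v[1] <= v[2])
    v[2] / v[1]
  }
  out <- list(er = er, ar = ar,
              er_fold = vapply(er, fold, numeric(1)), ar_fold = fold(ar))
  class(out) <- "dilution_scheme"
  out
}

#' @export
print.dilution_scheme <- function(x, ...) {
  cat(sprintf("dilution scheme: ER %s-fold (mean %.2f), AR %.2f-fold\n",
              paste(sprintf("%.2f", x$er_fold), collapse = "/"),
              mean(x$er_fold), x$ar_fold))
  invisible(x)
}

#' Standard-curve specification
#'
#' Concentration grid for a reference-compound curve. Grids are constrained
#' to the validated assay ranges: E2 0.5-500 pM, DHT 5 pM-0.5 uM, FLT
#' 0.005-50 uM (the FLT antagonist curve carries a 0.3 nM DHT co-agonist).
#'
#' @param compound one of `"E2"`, `"DHT"`, `"FLT"`.
#' @param grid strictly increasing concentrations in mol/L; `NULL` for the
#'   default log-spaced grid spanning the validated range.
#' @param co_agonist optional list `list(compound=, conc=)`.
#' @return object of class `standard_curve_spec`.
#' @export
standard_curve_spec <- function(compound = c("E2", "DHT", "FLT"),
                                grid = NULL, co_agonist = NULL) {
  compound <- match.arg(compound)
  ranges <- list(E2 = c(0.5e-12, 500e-12), DHT = c(5e-12, 0.5e-6),
                 FLT = c(0.005e-6, 50e-6))
  rng <- ranges[[compound]]
  if (is.null(grid)) {
    n <- if (compound == "FLT") 8 else 9
    grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  }
  if (any(diff(grid) <= 0)) stop("concentration grid must be increasing")
  if (min(grid) < rng[1] * 0.999 || max(grid) > rng[2] * 1.001) {
    stop(sprintf("grid outside validated range for %s", compound))
  }
  if (compound == "FLT" && is.null(co_agonist)) {
    co_agonist <- list(compound = "DHT", conc = 0.3e-9)
  }
  structure(list(compound = compound, grid = grid, co_agonist = co_agonist),
            class = "standard_curve_spec")
}

#' Convert an 8x12 plate-matrix block to long format
#'
#' Convenience importer for plate-reader exports organized as an 8-row by
#' 12-column matrix of RLU values (rows A-H).
#'
#' @param mat numeric 8x12 matrix.
#' @param value_name name for the value column.
#' @return long data frame with `row`, `col` and the value column.
#' @export
plate_matrix_to_long <- function(mat, value_name = "rlu") {
  stopifnot(is.matrix(mat), nrow(mat) == 8, ncol(mat) == 12)
  out <- data.frame(row = rep(LETTERS[1:8], times = 12),
                    col = rep(1:12, each = 8),
                    value = as.vector(mat), stringsAsFactors = FALSE)
  names(out)[3] <- value_name
  out
}
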