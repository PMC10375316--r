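# Direction-aware confusion matrices comparing the coupled-assay
# classifications against reference datasets (multi-laboratory validation
# calls, combined known in vitro activities, in vivo data), with
# sensitivity/specificity/accuracy under the minimum-4-substances rule.

#' Load the reference classification table
#'
#' Per-chemical, per-hormone-family calls: this study's effect and LOECs,
#' the multi-laboratory validation study's calls (with the number of
#' laboratories for equivocal entries), literature receptor-assay calls, in
#' vivo calls, and the inclusion flags for each comparison. Shipped as a
#' documented CSV fixture.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return data frame of reference records.
#' @export
reference_calls <- function(path = system.file("extdata",
                                               "reference_classifications.csv",
                                               package = "h295calux")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("chemical", "family", "study_effect", "study_direct",
              "oecd_effect", "oecd_labs", "lit_receptor",
              "invitro_ref_override", "invivo_effect",
              "include_oecd", "include_invivo")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("reference table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Resolve an equivocal multi-laboratory call
#'
#' An equivocal validation-study entry counts as positive only when the
#' effect was detected with significance by at least 2 laboratories;
#' otherwise it resolves to `nd`. Entries without laboratory metadata are
#' taken at face value.
#'
#' @param effect effect string (`"up"`, `"down"`, `"nd"`, ...).
#' @param labs number of laboratories detecting the effect (`NA` for firm
#'   calls).
#' @return resolved effect string.
#' @export
resolve_equivocal <- function(effect, labs) {
  mapply(function(e, l) {
    if (!is.na(l) && l < 2) "nd" else e
  }, effect, labs, USE.NAMES = FALSE)
}

is_positive_effect <- function(effect) {
  !is.na(effect) & effect %in% c("up", "down", "down_then_up",
                                 "up_then_down")
}

#' Match a test call against a reference call
#'
#' Direction-aware cell assignment: both negative is a true negative; a
#' missed reference positive is a false negative; a detection without
#' reference support is a false positive; matched detections are true
#' positives only when the effect directions agree (a biphasic profile
#' matches either single direction) -- an opposite-direction detection is a
#' false positive. With `direction_matters = FALSE` any positive matches
#' any positive.
#'
#' @param test_call,ref_call effect strings.
#' @param direction_matters apply the direction-matching rule.
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
match_calls <- function(test_call, ref_call, direction_matters = TRUE) {
  tp <- is_positive_effect(test_call)
  rp <- is_positive_effect(ref_call)
  if (!tp && !rp) return("TN")
  if (!tp && rp) return("FN")
  if (tp && !rp) return("FP")
  if (!direction_matters) return("TP")
  biphasic <- c("down_then_up", "up_then_down")
  if (test_call %in% biphasic || ref_call %in% biphasic) {
    t_dirs <- if (test_call %in% biphasic) c("up", "down") else test_call
    r_dirs <- if (ref_call %in% biphasic) c("up", "down") else ref_call
    return(if (length(intersect(t_dirs, r_dirs)) > 0) "TP" else "FP")
  }
  if (test_call == ref_call) "TP" else "FP"
}

#' Build a confusion matrix for one comparison and hormone family
#'
#' Comparisons:
#' * `"vs_oecd"`: this study's steroidogenesis call against the resolved
#'   multi-laboratory validation call, direction-aware.
#' * `"vs_known_invitro"`: any detected activity (steroidogenic or direct
#'   receptor) against any reported in vitro activity (validation study or
#'   literature receptor data), ignoring modality and direction. A
#'   per-record override column encodes the study's own categorization
#'   where it departs from the mechanical union.
#' * `"vs_invivo"`: this study's steroidogenesis call against the in vivo
#'   call, direction-aware.
#' * `"vs_invivo_oecd"`: the resolved validation-study call against the in
#'   vivo call, direction-aware (the original assay's predictivity).
#'
#' @param refs reference table ([reference_calls()]).
#' @param comparison comparison name.
#' @param family `"androgens"` or `"estrogens"`.
#' @return object of class `confusion_matrix` with counts and per-chemical
#'   cell assignments.
#' @export
build_matrix <- function(refs,
                         comparison = c("vs_oecd", "vs_known_invitro",
                                        "vs_invivo", "vs_invivo_oecd"),
                         family = c("androgens", "estrogens")) {
  comparison <- match.arg(comparison)
  family <- match.arg(family)
  sub <- refs[refs$family == family, , drop = FALSE]
  include <- if (comparison %in% c("vs_invivo", "vs_invivo_oecd")) {
    sub$include_invivo
  } else {
    sub$include_oecd
  }
  sub <- sub[include, , drop = FALSE]
  if (anyNA(sub$study_effect) || anyNA(sub$oecd_effect)) {
    stop("missing reference entry for an included chemical")
  }
  oecd <- resolve_equivocal(sub$oecd_effect, sub$oecd_labs)
  cells <- character(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    cells[i] <- switch(
      comparison,
      vs_oecd = match_calls(sub$study_effect[i], oecd[i]),
      vs_invivo = match_calls(sub$study_effect[i], sub$invivo_effect[i]),
      vs_invivo_oecd = match_calls(oecd[i], sub$invivo_effect[i]),
      vs_known_invitro = {
        test_pos <- is_positive_effect(sub$study_effect[i]) ||
          isTRUE(sub$study_direct[i])
        ref_pos <- if (!is.na(sub$invitro_ref_override[i])) {
          sub$invitro_ref_override[i]
        } else {
          is_positive_effect(oecd[i]) ||
            identical(sub$lit_receptor[i], "positive")
        }
        match_calls(if (test_pos) "up" else "nd",
                    if (ref_pos) "up" else "nd",
                    direction_matters = FALSE)
      })
  }
  counts <- table(factor(cells, levels = c("TP", "FP", "TN", "FN")))
  structure(list(comparison = comparison, family = family,
                 tp = unname(counts["TP"]), fp = unname(counts["FP"]),
                 tn = unname(counts["TN"]), fn = unname(counts["FN"]),
                 chemicals = stats::setNames(cells, sub$chemical)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("%s / %s: TP %d  FP %d  TN %d  FN %d\n",
              x$comparison, x$family, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Performance metrics with the minimum-4 rule
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/total`, each reported only when its denominator pool contains
#' at least `min_n` substances (`NA` otherwise). Raw fractions are kept;
#' rounding to 2 decimals happens only in the `rounded` element for report
#' parity.
#'
#' @param cm a [build_matrix()] result.
#' @param min_n minimum substances in a denominator (default 4).
#' @param digits reporting digits.
#' @return list with `sensitivity`, `specificity`, `accuracy` (raw) and
#'   `rounded`.
#' @export
cm_metrics <- function(cm, min_n = 4, digits = 2) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  sens <- if (cm$tp + cm$fn >= min_n) cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$tn + cm$fp >= min_n) cm$tn / (cm$tn + cm$fp) else NA_real_
  acc <- if (total >= min_n) (cm$tp + cm$tn) / total else NA_real_
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       total = total,
       rounded = list(sensitivity = round(sens, digits),
                      specificity = round(spec, digits),
                      accuracy = round(acc, digits)))
}

#' All performance tables
#'
#' Computes the confusion matrices and rounded metric triplets for every
#' comparison and hormone family.
#'
#' @param refs reference table ([reference_calls()]).
#' @return data frame: one row per comparison per family, with counts and
#'   rounded metrics.
#' @export
performance_tables <- function(refs = reference_calls()) {
  rows <- list()
  for (comparison in c("vs_oecd", "vs_known_invitro", "vs_invivo",
                       "vs_invivo_oecd")) {
    for (family in c("androgens", "estrogens")) {
      cm <- build_matrix(refs, comparison, family)
      m <- cm_metrics(cm)
      rows[[paste(comparison, family)]] <- data.frame(
        comparison = comparison, family = family,
        tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
        total = m$total,
        sensitivity = m$rounded$sensitivity,
        specificity = m$rounded$specificity,
        accuracy = m$rounded$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
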