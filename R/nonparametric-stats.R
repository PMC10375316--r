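# Pooled-replicate nonparametric testing: Kruskal-Wallis omnibus,
# Mann-Whitney U pairwise comparisons with exact small-sample p-values,
# significance binning and a report-only Shapiro-Wilk normality screen.

#' Pool technical replicates across biological replicates
#'
#' Groups normalized records by (chemical, endpoint, concentration), keeping
#' every technical replicate across the biological replicates as an
#' individual observation (nominally n = 9 = 3 bio x 3 tech; smaller groups
#' are tolerated and their n recorded). A record appearing twice (same
#' plate, well and replicate coordinates) is an error.
#'
#' @param records normalized activity data frame ([normalize_plateset()]).
#' @param value `"pct_of_basal"` (steroidogenesis readouts) or `"pct_ri"`
#'   (direct receptor readouts).
#' @return data frame with list-column `values` plus `n`, keyed by
#'   (`chemical_id`, `endpoint`, `conc_h295r`).
#' @export
pool_replicates <- function(records, value = "pct_of_basal") {
  if (nrow(records) == 0) stop("no records to pool")
  well_key <- paste(records$plate_id, records$bio_rep, records$tech_rep,
                    records$chemical_id, signif(records$conc_h295r, 10),
                    records$endpoint)
  if (anyDuplicated(well_key)) {
    stop("duplicate record (same plate/well twice): ",
         well_key[which(duplicated(well_key))[1]])
  }
  key <- paste(records$chemical_id, records$endpoint,
               signif(records$conc_h295r, 10), sep = "|")
  groups <- split(records[[value]], key)
  idx <- match(names(groups), key)
  out <- data.frame(chemical_id = records$chemical_id[idx],
                    endpoint = records$endpoint[idx],
                    conc_h295r = records$conc_h295r[idx],
                    stringsAsFactors = FALSE)
  out$values <- unname(groups)
  out$n <- lengths(groups)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value,
#' applied to the treatment groups together with the control. When every
#' value in every group is identical the test is degenerate and p = 1 by
#' convention.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) {
    return(list(H = 0, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

# Exact null distribution of the Mann-Whitney U statistic by enumeration of
# all C(n1+n2, n1) assignments of the pooled ranks. Only valid without ties.
mw_exact_distribution <- function(n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  u <- colSums(combos) - n1 * (n1 + 1) / 2
  tabulate(u + 1, nbins = n1 * n2 + 1)  # counts for U = 0..n1*n2
}

#' Mann-Whitney U test (two-sided)
#'
#' U statistic for the treated sample with a two-sided p-value: exact by
#' enumeration of all rank assignments when the combined sample size is at
#' most `exact_max_n` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. The exact two-sided
#' p-value is twice the smaller tail probability, capped at 1.
#'
#' @param treated,control numeric vectors (non-empty; n < 3 on either side
#'   is flagged underpowered).
#' @param exact_max_n largest combined n for the exact path (default 12).
#' @return list with `U`, `p_value`, `method`, `underpowered`.
#' @export
mann_whitney <- function(treated, control, exact_max_n = 12) {
  n1 <- length(treated)
  n2 <- length(control)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  pooled <- c(treated, control)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && (n1 + n2) <= exact_max_n) {
    dist <- mw_exact_distribution(n1, n2)
    total <- sum(dist)
    lower <- sum(dist[seq_len(u + 1)]) / total        # P(U <= u)
    upper <- sum(dist[(u + 1):(n1 * n2 + 1)]) / total # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (u == mu) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  list(U = u, p_value = p, method = method,
       underpowered = n1 < 3 || n2 < 3)
}

#' Significance bin for a p-value
#'
#' Bins at 0.05, 0.01, 0.001 and 0.0001 (boundaries inclusive), rendered as
#' stars for the steroidogenic comparisons and hashes for the sham (direct
#' receptor) comparisons.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param family `"steroidogenic"` (stars) or `"direct"` (hashes).
#' @return character vector: `"ns"`, or 1-4 glyphs.
#' @export
star_bin <- function(p, family = c("steroidogenic", "direct")) {
  family <- match.arg(family)
  glyph <- if (family == "steroidogenic") "*" else "#"
  stopifnot(all(p >= 0 & p <= 1))
  k <- findInterval(-p, -c(0.05, 0.01, 0.001, 0.0001)) # 0..4 glyphs
  ifelse(k == 0, "ns", strrep(glyph, k))
}

#' Shapiro-Wilk normality screen (report-only)
#'
#' Diagnostic per-group normality p-values; the analysis pathway is
#' nonparametric regardless of the outcome, so every chemical is evaluated
#' by the same methodology. Degenerate (constant) groups are flagged with
#' `NA`.
#'
#' @param groups list of numeric vectors (n >= 3 each for a p-value).
#' @return data frame with `group`, `n`, `shapiro_p`, `flag`.
#' @export
normality_screen <- function(groups) {
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  res <- lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    p <- if (length(v) < 3 || stats::sd(v) == 0) NA_real_ else
      stats::shapiro.test(v)$p.value
    data.frame(group = nm, n = length(v), shapiro_p = p,
               flag = is.na(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-concentration statistical calls for pooled groups
#'
#' For each (chemical, endpoint): a Kruskal-Wallis omnibus test across all
#' concentration groups plus the control, followed by pairwise Mann-Whitney
#' comparisons of each concentration against the control. Pairwise
#' significance requires p <= alpha and, when the omnibus gate is on
#' (default), an omnibus p <= alpha as well. Direction is the sign of the
#' pooled treated median relative to the endpoint's reference level (100
#' for basal-normalized and antagonist-mode readouts, 0 for direct agonist
#' readouts); a median exactly at the reference leaves the direction
#' undefined and the call non-significant.
#'
#' @param pooled output of [pool_replicates()] (one endpoint's groups,
#'   including the control rows flagged by `is.na(conc_h295r)` or
#'   `conc_h295r == 0`).
#' @param control_values numeric vector of control observations.
#' @param alpha significance level (default 0.05).
#' @param omnibus_gate gate pairwise significance on the omnibus test.
#' @param exact_max_n passed to [mann_whitney()].
#' @return data frame of per-concentration calls (one row per group).
#' @export
stat_calls <- function(pooled, control_values, alpha = 0.05,
                       omnibus_gate = TRUE, exact_max_n = 12) {
  out <- list()
  for (ck in unique(paste(pooled$chemical_id, pooled$endpoint, sep = "|"))) {
    sub <- pooled[paste(pooled$chemical_id, pooled$endpoint, sep = "|") == ck,
                  , drop = FALSE]
    sub <- sub[order(sub$conc_h295r), , drop = FALSE]
    ref_level <- mode_reference_level(sub$endpoint[1])
    family <- if (startsWith(sub$endpoint[1], "direct")) "direct" else
      "steroidogenic"
    kw <- kruskal_wallis(c(sub$values, list(control_values)))
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      v <- sub$values[[i]]
      mw <- mann_whitney(v, control_values, exact_max_n)
      med <- stats::median(v)
      direction <- if (med > ref_level) "up" else
        if (med < ref_level) "down" else NA_character_
      sig <- mw$p_value <= alpha && !is.na(direction) &&
        (!omnibus_gate || kw$p_value <= alpha)
      data.frame(chemical_id = sub$chemical_id[i],
                 endpoint = sub$endpoint[i],
                 conc_h295r = sub$conc_h295r[i],
                 n_treated = length(v), n_control = length(control_values),
                 u_statistic = mw$U, p_value = mw$p_value,
                 kw_p = kw$p_value,
                 star_bin = star_bin(mw$p_value, family),
                 significant = sig, direction = direction,
                 mean_level = mean(v),
                 underpowered = mw$underpowered,
                 stringsAsFactors = FALSE)
    })
    out[[ck]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
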