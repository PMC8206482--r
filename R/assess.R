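#' Loading-recovery error, split by item polarity
#'
#' Mean bias error `MBE = sum(est - true)/k` and mean absolute error
#' `MAE = sum(|est - true|)/k`, computed separately over positively and
#' negatively worded items. An `MBE` of 0 reflects a total lack of bias;
#' by construction `MAE >= |MBE|`.
#'
#' @param est,true equal-length numeric vectors of estimated and generating
#'   loadings (signed).
#' @param polarity character vector of `"PW"`/`"NW"` per item.
#' @return named vector `c(mbe_pw, mae_pw, mbe_nw, mae_nw)`; `NA` with a
#'   warning for an empty polarity group.
#' @export
#' @examples
#' loading_error(c(0.6, 0.8), c(0.7, 0.7), c("PW", "PW"))
loading_error <- function(est, true, polarity) {
  if (length(est) != length(true) || length(est) != length(polarity))
    stop("est, true and polarity must have equal length")
  one <- function(mask) {
    if (!any(mask)) {
      warning("empty polarity group; error undefined")
      return(c(NA_real_, NA_real_))
    }
    e <- est[mask] - true[mask]
    c(mean(e), mean(abs(e)))
  }
  pw <- one(polarity == "PW")
  nw <- one(polarity == "NW")
  c(mbe_pw = pw[1], mae_pw = pw[2], mbe_nw = nw[1], mae_nw = nw[2])
}

#' Person-score recovery correlations
#'
#' Pearson correlations between scores estimated on the uncontaminated data
#' and scores estimated on the contaminated data, over all respondents, over
#' consistent respondents only, and over inconsistent respondents only.
#'
#' @param uncont,cont equal-length numeric score vectors.
#' @param flags logical; `TRUE` marks inconsistent respondents.
#' @return named vector `c(r_total, r_consistent, r_inconsistent)`; a subset
#'   with fewer than 3 respondents or zero variance yields `NA` with a
#'   warning.
#' @export
score_recovery <- function(uncont, cont, flags) {
  if (length(uncont) != length(cont) || length(uncont) != length(flags))
    stop("score vectors and flags must have equal length")
  r_of <- function(idx) {
    if (sum(idx) < 3) {
      warning("fewer than 3 respondents in subset; correlation undefined")
      return(NA_real_)
    }
    if (sd(uncont[idx]) == 0 || sd(cont[idx]) == 0) {
      warning("zero-variance subset; correlation undefined")
      return(NA_real_)
    }
    cor(uncont[idx], cont[idx])
  }
  c(r_total = r_of(rep(TRUE, length(flags))),
    r_consistent = r_of(!flags),
    r_inconsistent = r_of(flags))
}

#' Wording-factor score diagnostics
#'
#' Correlates RIIFA wording-factor scores with the uncontaminated
#' substantive scores, overall and within the consistent / inconsistent
#' subgroups (and optionally within misresponse-direction subgroups), to
#' reveal whether the wording scores carry substantive trait information.
#'
#' @param uncont_sf uncontaminated substantive scores.
#' @param scores_wf wording-factor scores from a RIIFA fit.
#' @param flags logical inconsistency flags.
#' @param direction optional character vector (e.g. `"PW"`/`"NW"`) giving
#'   the misresponse direction of each inconsistent respondent (`NA` for
#'   consistent ones).
#' @return named list of correlations (`NA` where undefined).
#' @export
wording_score_diagnostics <- function(uncont_sf, scores_wf, flags,
                                      direction = NULL) {
  r_of <- function(idx) {
    if (sum(idx) < 3 || sd(scores_wf[idx]) == 0 || sd(uncont_sf[idx]) == 0) {
      warning("undefined wording-score correlation for a subgroup")
      return(NA_real_)
    }
    cor(uncont_sf[idx], scores_wf[idx])
  }
  out <- list(overall = r_of(rep(TRUE, length(flags))),
              consistent = r_of(!flags),
              inconsistent = r_of(flags))
  if (!is.null(direction)) {
    for (d in unique(stats::na.omit(direction)))
      out[[paste0("inconsistent_", d)]] <- r_of(flags & direction %in% d)
  }
  out
}

#' Split-plot (mixed) ANOVA partial eta squared for model comparisons
#'
#' Fits the classical split-plot decomposition with the fitted model (1F vs
#' RIIFA) as the two-level repeated factor on each replicate and the design
#' factors as between-replicate factors, and returns partial eta squared for
#' the model main effect and every model-by-design interaction, each tested
#' against the within-replicate (model x replicate) error.
#'
#' With a two-level within factor the within stratum is equivalent to a
#' between-factor ANOVA on the per-replicate difference scores
#' `d = y_1F - y_RIIFA`: the intercept stratum of that ANOVA is the model
#' main effect and each between effect is the corresponding interaction with
#' model. Replicates missing either model's value (non-convergence) are
#' dropped pairwise; unbalanced cells are handled with Type-III sums of
#' squares under sum-to-zero contrasts.
#'
#' @param table data frame with columns `value` (the dependent variable),
#'   `model` (two levels), `replicate` (unique id per subject), and any
#'   subset of the between-factor columns `perc_we`, `n`, `test_length`.
#' @param value name of the dependent-variable column (default
#'   `"r_total"`).
#' @return data frame with columns `effect` and `eta_p_sq`.
#' @export
mixed_anova_eta <- function(table, value = "r_total") {
  need <- c(value, "model", "replicate")
  if (!all(need %in% names(table))) stop("missing required columns")
  models <- sort(unique(as.character(table$model)))
  if (length(models) != 2) stop("exactly two model levels required")
  wide <- merge(
    table[table$model == models[1], c("replicate", value,
                                      intersect(c("perc_we", "n", "test_length"),
                                                names(table)))],
    table[table$model == models[2], c("replicate", value)],
    by = "replicate", suffixes = c("_1", "_2"))
  if (nrow(wide) < 3) stop("too few paired replicates for an ANOVA")
  wide$d <- wide[[paste0(value, "_1")]] - wide[[paste0(value, "_2")]]
  between <- intersect(c("perc_we", "n", "test_length"), names(wide))
  between <- between[vapply(between,
                            function(f) length(unique(wide[[f]])) > 1,
                            logical(1))]
  eta <- function(ss_eff, ss_res) {
    ifelse(ss_eff <= 0, 0, ss_eff / (ss_eff + ss_res))
  }
  if (length(between) == 0) {
    ss_int <- nrow(wide) * mean(wide$d)^2
    ss_res <- sum((wide$d - mean(wide$d))^2)
    return(data.frame(effect = "model", eta_p_sq = eta(ss_int, ss_res)))
  }
  for (f in between) wide[[f]] <- factor(wide[[f]])
  if (var(wide$d) < 1e-18) {
    # degenerate: a constant model difference has no error stratum
    labs <- c("model", paste0("model:", between))
    return(data.frame(effect = labs,
                      eta_p_sq = c(as.numeric(mean(wide$d) != 0),
                                   rep(0, length(between)))))
  }
  fml <- as.formula(paste("d ~", paste(between, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(between)), between)
  fit <- lm(fml, data = wide, contrasts = contr)
  a3 <- car::Anova(fit, type = 3)
  ss <- a3[["Sum Sq"]]
  names(ss) <- rownames(a3)
  ss_res <- ss[["Residuals"]]
  eff <- setdiff(rownames(a3), "Residuals")
  lab <- ifelse(eff == "(Intercept)", "model",
                paste0("model:", gsub(":", ":", eff)))
  data.frame(effect = lab, eta_p_sq = unname(eta(ss[eff], ss_res)))
}
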