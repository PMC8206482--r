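#' Configuration of a Monte Carlo wording-effects study
#'
#' The canonical design crosses amount of wording effect (PERC.WE: 0-50%),
#' sample size (200/500/1000) and test length (12/24/60 items) with 100
#' replicates per cell; `scale_factor` shrinks the replicate count for
#' desk-scale runs (the default 0.1 gives 10 replicates per cell).
#'
#' @param effect_type `"carelessness"`, `"ivd"` or `"acquiescence"`.
#' @param perc_levels percentages of misresponded items to run.
#' @param n_levels sample sizes.
#' @param length_levels test lengths.
#' @param reps replicates per cell at full scale.
#' @param scale_factor multiplier on `reps` (effective replicates =
#'   `max(1, round(reps * scale_factor))`).
#' @param inconsistent_frac fraction of respondents flagged inconsistent.
#' @param master_seed master seed; every cell and replicate derives its own
#'   substream from it via [substream_seed()].
#' @param n_quad quadrature points per dimension for EAP scoring.
#' @return object of class `study_config`.
#' @export
study_config <- function(effect_type = c("carelessness", "ivd", "acquiescence"),
                         perc_levels = c(10, 20, 30, 40, 50),
                         n_levels = c(200, 500, 1000),
                         length_levels = c(12, 24, 60),
                         reps = 100L, scale_factor = 0.1,
                         inconsistent_frac = 0.40,
                         master_seed = 1L, n_quad = 21L) {
  effect_type <- match.arg(effect_type)
  if (reps < 1) stop("reps must be >= 1")
  if (!length(perc_levels) || !length(n_levels) || !length(length_levels))
    stop("design levels must be nonempty")
  structure(list(effect_type = effect_type, perc_levels = perc_levels,
                 n_levels = n_levels, length_levels = length_levels,
                 reps = as.integer(reps), scale_factor = scale_factor,
                 inconsistent_frac = inconsistent_frac,
                 master_seed = as.integer(master_seed),
                 n_quad = as.integer(n_quad)),
            class = "study_config")
}

.empty_row <- function(effect, perc, n, k, rep_id, model, reason) {
  data.frame(effect = effect, perc_we = perc, n = n, test_length = k,
             replicate = rep_id, model = model, converged = FALSE,
             reason = reason, r_total = NA_real_, r_consistent = NA_real_,
             r_inconsistent = NA_real_, mbe_pw = NA_real_, mae_pw = NA_real_,
             mbe_nw = NA_real_, mae_nw = NA_real_, omega = NA_real_,
             beta_sf = NA_real_, beta_wf = NA_real_, r2 = NA_real_,
             chi2 = NA_real_, df = NA_integer_, cfi = NA_real_,
             tli = NA_real_, rmsea = NA_real_, stringsAsFactors = FALSE)
}

#' Run one replicate of a wording-effects study
#'
#' Generates one uncontaminated sample for a (N, test length) cell, fits the
#' 1F model to it to obtain the uncontaminated reference scores (also used
#' to classify respondents for IVD contamination), then for every requested
#' PERC.WE level derives a contaminated matrix from the *same* uncontaminated
#' sample, fits 1F and RIIFA, scores respondents, and assembles one
#' assessment row per model.
#'
#' @param effect effect type (`"carelessness"`, `"ivd"`, `"acquiescence"`).
#' @param n sample size.
#' @param k test length.
#' @param perc_levels PERC.WE levels to derive from this replicate.
#' @param rep_id replicate index.
#' @param master_seed master seed (see [substream_seed()]).
#' @param inconsistent_frac fraction of inconsistent respondents.
#' @param n_quad quadrature points per dimension.
#' @return data frame with one row per (PERC.WE level x model).
#' @export
run_replicate <- function(effect, n, k, perc_levels, rep_id,
                          master_seed = 1L, inconsistent_frac = 0.40,
                          n_quad = 21L) {
  cell <- design_cell(effect, 0, n, k, rep_id, custom = TRUE)
  spec_seed <- substream_seed(master_seed, effect, n, k, rep_id, "spec")
  sample_seed <- substream_seed(master_seed, effect, n, k, rep_id, "sample")
  gs <- generate_sample(cell, spec_seed, sample_seed, inconsistent_frac)
  dat0 <- gs$data
  polarity <- dat0$item_polarity
  true_lam <- gs$spec$loadings
  R0 <- mixed_cor(dat0)
  spec_1f <- model_spec("onefactor", k)
  spec_ri <- model_spec("riifa", k)
  fit0 <- fit_dwls(R0, spec_1f, orient = polarity)
  if (!fit0$converged) {
    return(rbind(
      do.call(rbind, lapply(perc_levels, function(p)
        .empty_row(effect, p, n, k, rep_id, "1F", "reference_fit_failed"))),
      do.call(rbind, lapply(perc_levels, function(p)
        .empty_row(effect, p, n, k, rep_id, "RIIFA", "reference_fit_failed")))))
  }
  ref <- eap_scores(dat0, fit0, n_quad)$sf

  rows <- vector("list", 2L * length(perc_levels))
  ri <- 0L
  for (perc in perc_levels) {
    if (perc == 0) {
      dat_c <- dat0
      Rc <- R0
    } else {
      set.seed(substream_seed(master_seed, effect, n, k, rep_id, perc, "contam"))
      dat_c <- contaminate(dat0, effect, perc, trait_scores = ref)
      Rc <- mixed_cor(dat_c)
    }
    for (kind in c("onefactor", "riifa")) {
      label <- if (kind == "onefactor") "1F" else "RIIFA"
      fit <- fit_dwls(Rc, if (kind == "onefactor") spec_1f else spec_ri,
                      orient = polarity)
      ri <- ri + 1L
      if (!fit$converged) {
        rows[[ri]] <- .empty_row(effect, perc, n, k, rep_id, label, fit$reason)
        next
      }
      sc <- eap_scores(dat_c, fit, n_quad)
      rec <- score_recovery(ref, sc$sf, dat_c$inconsistent_flags)
      le <- loading_error(fit$loadings, true_lam, polarity)
      rows[[ri]] <- data.frame(
        effect = effect, perc_we = perc, n = n, test_length = k,
        replicate = rep_id, model = label, converged = TRUE, reason = "ok",
        r_total = rec[["r_total"]], r_consistent = rec[["r_consistent"]],
        r_inconsistent = rec[["r_inconsistent"]],
        mbe_pw = le[["mbe_pw"]], mae_pw = le[["mae_pw"]],
        mbe_nw = le[["mbe_nw"]], mae_nw = le[["mae_nw"]],
        omega = if (kind == "riifa") fit$omega else NA_real_,
        beta_sf = fit$beta_sf,
        beta_wf = if (kind == "riifa") fit$beta_wf else NA_real_,
        r2 = fit$r2, chi2 = fit$chi2, df = fit$df, cfi = fit$cfi,
        tli = fit$tli, rmsea = fit$rmsea, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run a full wording-effects simulation study
#'
#' Maps [run_replicate()] over the factorial design of a [study_config()],
#' then aggregates converged replicates into per-cell summaries, a
#' convergence-rate table, and the split-plot ANOVA effect sizes on total
#' score recovery (PERC.WE levels of 20% and above, mirroring the exclusion
#' of the weakly-identified 10% condition).
#'
#' @param config a [study_config()].
#' @param verbose print per-cell timing messages.
#' @param out_dir optional directory; replicate rows are re-written there
#'   after every cell so partial results survive interruption.
#' @return object of class `wording_study`: list with `replicates`,
#'   `cell_summary`, `convergence`, `anova`, `config`.
#' @export
run_study <- function(config, verbose = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  reps <- max(1L, round_half_up(config$reps * config$scale_factor))
  all_rows <- list()
  for (n in config$n_levels) {
    for (k in config$length_levels) {
      t0 <- Sys.time()
      cell_rows <- lapply(seq_len(reps), function(r)
        run_replicate(config$effect_type, n, k, config$perc_levels, r,
                      master_seed = config$master_seed,
                      inconsistent_frac = config$inconsistent_frac,
                      n_quad = config$n_quad))
      all_rows[[paste(n, k)]] <- do.call(rbind, cell_rows)
      if (verbose)
        message(sprintf("cell N=%d k=%d: %d replicates in %.1fs", n, k, reps,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(do.call(rbind, all_rows),
                         file.path(out_dir, "replicates.csv"),
                         row.names = FALSE)
      }
    }
  }
  replicates <- do.call(rbind, all_rows)
  rownames(replicates) <- NULL
  replicates$replicate_uid <- interaction(replicates$perc_we, replicates$n,
                                          replicates$test_length,
                                          replicates$replicate, drop = TRUE)

  conv <- stats::aggregate(converged ~ model + perc_we + test_length,
                           data = replicates, FUN = mean)
  names(conv)[names(conv) == "converged"] <- "convergence_rate"

  ok <- replicates[replicates$converged, ]
  summ_vars <- c("r_total", "r_consistent", "r_inconsistent", "mbe_pw",
                 "mae_pw", "mbe_nw", "mae_nw", "beta_sf", "beta_wf", "r2",
                 "cfi", "rmsea", "omega")
  cell_summary <- stats::aggregate(
    ok[summ_vars],
    by = ok[c("model", "perc_we", "n", "test_length")],
    FUN = function(x) mean(x, na.rm = TRUE))
  cell_summary$n_converged <- stats::aggregate(
    ok$r_total, by = ok[c("model", "perc_we", "n", "test_length")],
    FUN = length)$x

  anova_tab <- NULL
  asub <- ok[ok$perc_we >= 20, ]
  asub$replicate <- as.character(asub$replicate_uid)
  if (length(unique(asub$model)) == 2) {
    anova_tab <- tryCatch(mixed_anova_eta(asub, value = "r_total"),
                          error = function(e) NULL)
  }
  out <- structure(list(replicates = replicates, cell_summary = cell_summary,
                        convergence = conv, anova = anova_tab,
                        config = config),
                   class = "wording_study")
  if (!is.null(out_dir)) write_study_csv(out, out_dir)
  out
}

#' @export
print.wording_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<wording_study> effect = %s, %d replicate rows\n",
              cfg$effect_type, nrow(x$replicates)))
  ok <- x$replicates[x$replicates$converged, ]
  for (m in sort(unique(ok$model)))
    cat(sprintf("  %s: mean total recovery r = %.3f over %d converged fits\n",
                m, mean(ok$r_total[ok$model == m]), sum(ok$model == m)))
  if (!is.null(x$anova)) {
    i <- x$anova$effect == "model"
    cat(sprintf("  model main-effect partial eta squared = %.3f\n",
                x$anova$eta_p_sq[i]))
  }
  invisible(x)
}

#' Write the tables of a study to CSV files
#'
#' Emits `replicates.csv`, `cell_summary.csv`, `convergence.csv` and (when
#' available) `anova.csv` into `dir`.
#'
#' @param study a `wording_study` from [run_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$cell_summary, file.path(dir, "cell_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$convergence, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  if (!is.null(study$anova))
    utils::write.csv(study$anova, file.path(dir, "anova.csv"),
                     row.names = FALSE)
  invisible(dir)
}
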