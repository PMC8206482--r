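#' Structural model specification (1F or RIIFA)
#'
#' The `onefactor` ("do-nothing") model has one substantive factor with free
#' loadings and, optionally, the continuous criterion regressed on that
#' factor. The `riifa` model adds a random-intercept method factor,
#' orthogonal to the substantive factor, with all unstandardized item
#' loadings fixed to 1 and variance `omega` free; the criterion is then
#' regressed on both factors. All models are fitted in the correlation
#' (delta) metric: uniquenesses are the remainders to a unit diagonal and
#' the substantive factor variance is fixed to 1 for identification.
#'
#' @param kind `"onefactor"` or `"riifa"`.
#' @param k number of substantive items.
#' @param criterion_included logical; whether the criterion variable enters
#'   the model.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("onefactor", "riifa"), k,
                       criterion_included = TRUE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k),
                 criterion_included = isTRUE(criterion_included),
                 wording_loadings_fixed = if (kind == "riifa") 1.0 else NULL),
            class = "model_spec")
}

#' Number of non-redundant correlation moments of a model
#' @param spec a [model_spec()].
#' @return integer count of fitted item-item (and item-criterion) moments.
#' @export
n_moments <- function(spec) {
  spec$k * (spec$k - 1L) / 2L + if (spec$criterion_included) spec$k else 0L
}

#' Number of free structural parameters of a model
#' @param spec a [model_spec()].
#' @return integer parameter count (loadings, regressions, omega).
#' @export
n_free_parameters <- function(spec) {
  spec$k +
    (spec$kind == "riifa") +
    if (spec$criterion_included) 1L + (spec$kind == "riifa") else 0L
}

#' Model degrees of freedom
#' @param spec a [model_spec()].
#' @return `n_moments(spec) - n_free_parameters(spec)`.
#' @export
model_df <- function(spec) n_moments(spec) - n_free_parameters(spec)

#' Model-implied latent correlation matrix
#'
#' For `onefactor`, item-item entries are `lambda_i lambda_j` and
#' item-criterion entries `lambda_i beta_sf`. For `riifa`, the orthogonal
#' standardized method factor adds `omega` to every item-item entry and
#' `sqrt(omega) beta_wf` to the item-criterion entries. The diagonal is unity
#' (uniquenesses absorb the remainder); negative implied uniquenesses are
#' reported by the fitter as inadmissible, not here.
#'
#' @param params list with `loadings` (length k), and as applicable
#'   `beta_sf`, `beta_wf`, `omega`.
#' @param spec a [model_spec()].
#' @return symmetric implied correlation matrix.
#' @export
#' @examples
#' implied_correlations(list(loadings = c(0.7, -0.7), omega = 0.1),
#'                      model_spec("riifa", 2, criterion_included = FALSE))
implied_correlations <- function(params, spec) {
  lam <- params$loadings
  stopifnot(length(lam) == spec$k)
  M <- outer(lam, lam)
  if (spec$kind == "riifa") M <- M + params$omega
  diag(M) <- 1
  if (spec$criterion_included) {
    sc <- lam * params$beta_sf
    if (spec$kind == "riifa") sc <- sc + sqrt(params$omega) * params$beta_wf
    M <- rbind(cbind(M, sc), c(sc, 1))
  }
  M
}

# pack/unpack: 1F theta = (lam, [beta_sf]); RIIFA theta = (lam, [beta_sf,
# beta_wf], sw) with omega = sw^2 so box bounds keep omega >= 0
.unpack_theta <- function(th, spec) {
  k <- spec$k
  lam <- th[seq_len(k)]
  out <- list(loadings = lam)
  i <- k
  if (spec$criterion_included) {
    out$beta_sf <- th[i + 1L]
    i <- i + 1L
    if (spec$kind == "riifa") {
      out$beta_wf <- th[i + 1L]
      i <- i + 1L
    }
  }
  if (spec$kind == "riifa") out$sw <- th[i + 1L]
  out
}

.dwls_objective <- function(th, spec, S, Wm, wc, sc_obs) {
  p <- .unpack_theta(th, spec)
  lam <- p$loadings
  M <- outer(lam, lam)
  if (spec$kind == "riifa") M <- M + p$sw^2
  E <- S - M
  diag(E) <- 0
  f <- 0.5 * sum(Wm * E * E)
  if (spec$criterion_included) {
    sig_c <- lam * p$beta_sf
    if (spec$kind == "riifa") sig_c <- sig_c + p$sw * p$beta_wf
    ec <- sc_obs - sig_c
    f <- f + sum(wc * ec * ec)
  }
  f
}

.dwls_gradient <- function(th, spec, S, Wm, wc, sc_obs) {
  p <- .unpack_theta(th, spec)
  lam <- p$loadings
  M <- outer(lam, lam)
  if (spec$kind == "riifa") M <- M + p$sw^2
  E <- S - M
  diag(E) <- 0
  WE <- Wm * E
  g_lam <- -2 * as.vector(WE %*% lam)
  g <- NULL
  if (spec$criterion_included) {
    sig_c <- lam * p$beta_sf
    if (spec$kind == "riifa") sig_c <- sig_c + p$sw * p$beta_wf
    ec <- sc_obs - sig_c
    g_lam <- g_lam - 2 * wc * ec * p$beta_sf
    g_bsf <- -2 * sum(wc * ec * lam)
    if (spec$kind == "riifa") {
      g_bwf <- -2 * sum(wc * ec * p$sw)
      g_sw <- -2 * p$sw * sum(WE) - 2 * sum(wc * ec) * p$beta_wf
      g <- c(g_lam, g_bsf, g_bwf, g_sw)
    } else {
      g <- c(g_lam, g_bsf)
    }
  } else {
    if (spec$kind == "riifa") {
      g <- c(g_lam, -2 * p$sw * sum(WE))
    } else {
      g <- g_lam
    }
  }
  g
}

# Jacobian of the implied non-redundant moments wrt the free parameters,
# moments ordered as pairs (i<j, column-major upper triangle) then the k
# item-criterion moments. Used for the Satterthwaite mean scaling.
.moment_jacobian <- function(p, spec) {
  k <- spec$k
  lam <- p$loadings
  ut <- which(upper.tri(diag(k)), arr.ind = TRUE)
  npair <- nrow(ut)
  ncrit <- if (spec$criterion_included) k else 0L
  q <- n_free_parameters(spec)
  D <- matrix(0, npair + ncrit, q)
  for (l in seq_len(k)) {
    hit_i <- ut[, 1] == l
    hit_j <- ut[, 2] == l
    D[which(hit_i), l] <- lam[ut[hit_i, 2]]
    D[which(hit_j), l] <- lam[ut[hit_j, 1]]
  }
  col <- k
  if (spec$criterion_included) {
    crit_rows <- npair + seq_len(k)
    for (l in seq_len(k)) D[npair + l, l] <- p$beta_sf
    D[crit_rows, col + 1L] <- lam
    col <- col + 1L
    if (spec$kind == "riifa") {
      D[crit_rows, col + 1L] <- sqrt(max(p$sw^2, 0))
      col <- col + 1L
    }
  }
  if (spec$kind == "riifa") {
    # omega parameterization: d sigma_ij / d omega = 1
    D[seq_len(npair), col + 1L] <- 1
    if (spec$criterion_included && p$sw^2 > 1e-8)
      D[npair + seq_len(k), col + 1L] <- p$beta_wf / (2 * p$sw)
  }
  D
}

# Scaled-and-shifted chi-square for a quadratic-form statistic F whose
# asymptotic distribution is a weighted chi-square mixture with weights the
# eigenvalues of U Gamma. Q is the thin orthonormal basis of the model
# Jacobian (U = I - QQ'), or NULL for the saturated-projector-free baseline.
# tr(U Gamma) is exact; tr((U Gamma)^2) is exact for small moment vectors
# and Hutchinson-estimated (fixed probe sequence) for large ones.
.scaled_shifted <- function(f, df, Psi, n, Q) {
  p_star <- ncol(Psi)
  PsiU <- if (is.null(Q)) Psi else Psi - (Psi %*% Q) %*% t(Q)
  if (p_star <= 600) {
    G <- crossprod(PsiU) / n^2
    tr1 <- sum(diag(G))
    tr2 <- sum(G * G)
  } else {
    tr1 <- sum(PsiU * PsiU) / n^2
    # Hutchinson estimate of tr((U Gamma)^2) with fixed-seed Rademacher
    # probes (restores the caller's RNG state)
    seed_bak <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(1299709L)
    nprobe <- 16L
    tr2 <- 0
    for (b in seq_len(nprobe)) {
      v <- sample(c(-1, 1), p_star, replace = TRUE)
      Mv <- crossprod(PsiU, PsiU %*% v) / n^2
      tr2 <- tr2 + sum(Mv^2)
    }
    tr2 <- tr2 / nprobe
    if (is.null(seed_bak)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", seed_bak, envir = globalenv())
    }
  }
  if (tr2 <= 0 || tr1 <= 0) return(f)
  a <- sqrt(df / tr2)
  max(a * f + df - a * tr1, 0)
}

#' Fit a 1F or RIIFA model by (weighted) least squares on latent correlations
#'
#' Minimizes the sum of squared residuals between the sample
#' polychoric/polyserial correlations and the model-implied ones (bounded
#' quasi-Newton, three deterministic starts seeded by the first eigenvector
#' of the item correlation block; best admissible solution kept). With
#' `estimator = "uls"` (default) the residuals are unweighted, the robust
#' least-squares flavor whose loading behavior matches this design best;
#' `"dwls"` weights each residual by the inverse asymptotic variance of its
#' correlation estimate. Either way the test statistic is mean-scaled
#' (Satterthwaite-style) using the per-correlation asymptotic variances
#' under a diagonal-covariance approximation, and the baseline model for
#' incremental indices is the zero-correlation model with free thresholds.
#'
#' Convergence requires optimizer success, all implied uniquenesses
#' `1 - lambda_i^2 - omega >= 0`, and for RIIFA `omega >= 1e-6`
#' (boundary-omega solutions count as non-converged: there is no wording
#' variance to absorb).
#'
#' @param R a [mixed_cor()] estimate.
#' @param spec a [model_spec()] with `spec$k == R$n_items`.
#' @param orient optional item polarity (`"PW"`/`"NW"` per item): the fitted
#'   solution, which is sign-indeterminate, is flipped so PW items load
#'   positively on average.
#' @param estimator `"uls"` (unweighted fitting, mean-scaled statistic) or
#'   `"dwls"` (inverse-variance weighted fitting).
#' @return object of class `wefa_fit` with standardized `loadings`, `omega`,
#'   `beta_sf`, `beta_wf`, `r2`, `chi2`, `df`, `cfi`, `tli`, `rmsea`,
#'   `converged`, `reason`, plus the inputs needed for scoring.
#' @export
fit_dwls <- function(R, spec, orient = NULL, estimator = c("uls", "dwls")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(R, "mixed_cor"), inherits(spec, "model_spec"))
  if (spec$k != R$n_items) stop("model and correlation matrix disagree on k")
  if (spec$criterion_included && !R$has_criterion)
    stop("model includes a criterion but the correlation matrix has none")
  k <- spec$k
  S_full <- R$corr
  S <- S_full[seq_len(k), seq_len(k)]
  V <- R$avar[seq_len(k), seq_len(k)]
  v_med <- stats::median(V[upper.tri(V)], na.rm = TRUE)
  if (!is.finite(v_med) || v_med <= 0) v_med <- 1 / R$n
  V[!is.finite(V)] <- v_med
  V <- pmax(V, 1e-12)
  if (estimator == "dwls") {
    Wm <- 1 / V
  } else {
    Wm <- matrix(1, k, k)
  }
  diag(Wm) <- 0
  wc <- sc_obs <- vc <- NULL
  if (spec$criterion_included) {
    sc_obs <- S_full[seq_len(k), k + 1L]
    vc <- R$avar[seq_len(k), k + 1L]
    vc[!is.finite(vc)] <- v_med
    vc <- pmax(vc, 1e-12)
    wc <- if (estimator == "dwls") 1 / vc else rep(1, k)
  }

  # deterministic starts from the reduced-rank first eigenvector
  e1 <- eigen(S, symmetric = TRUE)$vectors[, 1]
  sgn <- sign(e1)
  sgn[sgn == 0] <- 1
  start_scale <- c(0.5, 0.7, 0.3)
  sw0 <- sqrt(c(0.05, 0.02, 0.10))
  lower <- rep(-0.999, k)
  upper <- rep(0.999, k)
  if (spec$criterion_included) {
    lower <- c(lower, -0.999)
    upper <- c(upper, 0.999)
    if (spec$kind == "riifa") {
      lower <- c(lower, -0.999)
      upper <- c(upper, 0.999)
    }
  }
  if (spec$kind == "riifa") {
    lower <- c(lower, 0)
    upper <- c(upper, 0.95)
  }

  best <- NULL
  best_any <- NULL
  for (s in seq_along(start_scale)) {
    lam0 <- start_scale[s] * sgn
    th0 <- lam0
    if (spec$criterion_included) {
      b0 <- max(min(sum(sc_obs * lam0) / sum(lam0^2), 0.9), -0.9)
      th0 <- c(th0, b0)
      if (spec$kind == "riifa") th0 <- c(th0, 0)
    }
    if (spec$kind == "riifa") th0 <- c(th0, sw0[s])
    opt <- tryCatch(
      optim(th0, .dwls_objective, .dwls_gradient, spec = spec, S = S,
            Wm = Wm, wc = wc, sc_obs = sc_obs, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    p <- .unpack_theta(opt$par, spec)
    omega <- if (spec$kind == "riifa") p$sw^2 else 0
    uniq <- 1 - p$loadings^2 - omega
    admissible <- opt$convergence == 0 && min(uniq) >= -1e-8
    if (spec$kind == "riifa") admissible <- admissible && omega >= 1e-6
    if (spec$criterion_included) {
      r2 <- p$beta_sf^2 + if (spec$kind == "riifa") p$beta_wf^2 else 0
      admissible <- admissible && r2 <= 1 + 1e-8
    }
    cand <- list(opt = opt, p = p, omega = omega, uniq = uniq,
                 admissible = admissible)
    if (is.null(best_any) || opt$value < best_any$opt$value) best_any <- cand
    if (admissible && (is.null(best) || opt$value < best$opt$value))
      best <- cand
  }

  # an omega this small may sit on a likelihood plateau: if constraining the
  # wording variance to zero fits essentially as well, the method factor is
  # unidentified and the solution is a boundary case
  if (!is.null(best) && spec$kind == "riifa" && best$omega < 5e-3) {
    up0 <- upper
    up0[length(up0)] <- 0
    th0 <- best$opt$par
    th0[length(th0)] <- 0
    opt0 <- tryCatch(
      optim(th0, .dwls_objective, .dwls_gradient, spec = spec, S = S,
            Wm = Wm, wc = wc, sc_obs = sc_obs, method = "L-BFGS-B",
            lower = lower, upper = up0,
            control = list(maxit = 1000, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(opt0) && opt0$value - best$opt$value < 1e-8) {
      best_any <- best
      best_any$omega <- 0
      best <- NULL
    }
  }
  converged <- !is.null(best)
  reason <- if (converged) "ok" else if (is.null(best_any)) "optimizer_failure"
            else if (spec$kind == "riifa" && best_any$omega < 1e-6) "omega_boundary"
            else "inadmissible_solution"
  use <- if (converged) best else best_any
  if (is.null(use))
    return(structure(list(kind = spec$kind, converged = FALSE,
                          reason = reason), class = "wefa_fit"))

  lam_hat <- use$p$loadings
  beta_sf <- if (spec$criterion_included) use$p$beta_sf else NA_real_
  beta_wf <- if (spec$criterion_included && spec$kind == "riifa")
    use$p$beta_wf else NA_real_
  # resolve the global sign indeterminacy of (lambda, beta_sf)
  if (!is.null(orient)) {
    dir <- ifelse(orient == "PW", 1, -1)
    if (sum(lam_hat * dir) < 0) {
      lam_hat <- -lam_hat
      if (!is.na(beta_sf)) beta_sf <- -beta_sf
    }
  }
  fmin <- use$opt$value
  df <- model_df(spec)
  # baseline: all latent correlations zero, thresholds free
  E0 <- S; diag(E0) <- 0
  f_base <- 0.5 * sum(Wm * E0 * E0)
  df_base <- k * (k - 1L) / 2L
  if (spec$criterion_included) {
    f_base <- f_base + sum(wc * sc_obs^2)
    df_base <- df_base + k
  }
  v_all <- c(V[upper.tri(V)], vc)
  if (estimator == "dwls" || is.null(R$scores)) {
    # weights are inverse variances: fmin is already on the chi-square scale
    chi2 <- fmin
    chi2_base <- f_base
  } else {
    # robust mean-and-variance adjusted (scaled-and-shifted) statistic:
    # T = a*F + b with a = sqrt(df/tr((U Gamma)^2)), b = df - a*tr(U Gamma),
    # Gamma the empirical asymptotic covariance of the correlation vector
    # (influence scores) and U the residual projector of the ULS estimator
    D <- .moment_jacobian(use$p, spec)
    st <- .scaled_shifted(fmin, df, R$scores, R$n, qr.Q(qr(D)))
    stb <- .scaled_shifted(f_base, df_base, R$scores, R$n, NULL)
    chi2 <- st
    chi2_base <- stb
  }
  fi <- fit_indices(chi2, df, chi2_base, df_base, R$n)
  r2 <- if (spec$criterion_included)
    beta_sf^2 + (if (spec$kind == "riifa") beta_wf^2 else 0) else NA_real_

  structure(list(kind = spec$kind, k = k,
                 criterion_included = spec$criterion_included,
                 loadings = lam_hat, omega = use$omega,
                 beta_sf = beta_sf, beta_wf = beta_wf, r2 = r2,
                 uniquenesses = pmax(use$uniq, 0),
                 chi2 = chi2, df = df, chi2_base = chi2_base,
                 df_base = df_base, estimator = estimator,
                 cfi = fi[["cfi"]], tli = fi[["tli"]], rmsea = fi[["rmsea"]],
                 fmin = fmin, n = R$n, thresholds = R$thresholds,
                 converged = converged, reason = reason),
            class = "wefa_fit")
}

#' @export
print.wefa_fit <- function(x, ...) {
  cat(sprintf("<wefa_fit> %s model, k = %d, converged = %s (%s)\n",
              x$kind, if (is.null(x$k)) NA_integer_ else x$k,
              x$converged, x$reason))
  if (isTRUE(x$converged)) {
    cat(sprintf("  chi2 = %.2f (df %d), CFI = %.3f, RMSEA = %.3f\n",
                x$chi2, x$df, x$cfi, x$rmsea))
    if (x$kind == "riifa") cat(sprintf("  omega = %.3f\n", x$omega))
    if (x$criterion_included)
      cat(sprintf("  beta_sf = %.3f%s, R2 = %.3f\n", x$beta_sf,
                  if (x$kind == "riifa")
                    sprintf(", beta_wf = %.3f", x$beta_wf) else "",
                  x$r2))
  }
  invisible(x)
}

#' Incremental and absolute fit indices
#'
#' CFI and TLI compare the fitted model with the zero-correlation baseline;
#' RMSEA is the per-degree-of-freedom misfit. All indices clamp to their
#' perfect-fit value when the model chi-square does not exceed its degrees
#' of freedom, and CFI/TLI clamp to 1 when the baseline itself fits
#' (undefined comparison).
#'
#' @param chi2,df model test statistic and degrees of freedom.
#' @param chi2_base,df_base baseline test statistic and degrees of freedom.
#' @param n sample size.
#' @return named numeric vector `c(cfi, tli, rmsea)`.
#' @export
#' @examples
#' fit_indices(100, 10, 1000, 45, 101)
fit_indices <- function(chi2, df, chi2_base, df_base, n) {
  if (df <= 0 || df_base <= 0) stop("degrees of freedom must be positive")
  d <- max(chi2 - df, 0)
  d_base <- max(chi2_base - df_base, 0)
  cfi <- if (chi2_base <= df_base || max(d_base, d) == 0) 1 else
    1 - d / max(d_base, d)
  tli <- if (chi2_base <= df_base || chi2 <= df) {
    1
  } else {
    min(((chi2_base / df_base) - (chi2 / df)) / ((chi2_base / df_base) - 1), 1)
  }
  rmsea <- sqrt(d / (df * (n - 1)))
  c(cfi = cfi, tli = tli, rmsea = rmsea)
}
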