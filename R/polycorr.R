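#' Estimate normal-theory thresholds from an ordinal column
#'
#' First stage of the two-step polychoric estimator: thresholds are the
#' standard normal quantiles of the cumulative category proportions.
#' Categories with no mass at the extremes yield infinite thresholds, which
#' downstream code tolerates.
#'
#' @param col integer vector of categories in `1..n_categories`.
#' @param n_categories number of scale categories.
#' @return numeric vector of `n_categories - 1` interior thresholds.
#' @export
#' @examples
#' estimate_thresholds(categorize(qnorm((1:999) / 1000)))
estimate_thresholds <- function(col, n_categories = 4L) {
  counts <- tabulate(col, nbins = n_categories)
  if (sum(counts > 0) < 2) stop("degenerate item: a single observed category")
  qnorm(cumsum(counts[-n_categories]) / sum(counts))
}

# 4x4 (or nc x nc) contingency table via a single tabulate pass
.cross_counts <- function(x, y, nc) {
  matrix(tabulate((x - 1L) * nc + y, nbins = nc * nc),
         nrow = nc, byrow = TRUE)
}

# observed-information variance of a 1-D ML estimate by central differences
.numeric_info_var <- function(nll, at, h = 1e-4) {
  d2 <- (nll(at + h) - 2 * nll(at) + nll(at - h)) / h^2
  if (!is.finite(d2) || d2 <= 0) return(NA_real_)
  1 / d2
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood: thresholds are fixed at their marginal
#' estimates, then the latent correlation maximizes the bivariate-normal
#' cell-probability likelihood over `[-0.999, 0.999]` (golden-section /
#' parabolic search, tolerance 1e-8). The asymptotic variance comes from the
#' inverse observed information at the optimum.
#'
#' @param x,y integer vectors of categories in `1..n_categories`.
#' @param n_categories number of scale categories.
#' @return list with `rho`, `var` (asymptotic variance of `rho`),
#'   `thresholds_x`, `thresholds_y`.
#' @export
polychoric <- function(x, y, n_categories = 4L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  tx <- estimate_thresholds(x, n_categories)
  ty <- estimate_thresholds(y, n_categories)
  # collapse to the observed categories: empty cells carry no likelihood, and
  # collapsing keeps thresholds and table dimensions consistent
  ox <- sort(unique(x)); oy <- sort(unique(y))
  x2 <- match(x, ox); y2 <- match(y, oy)
  ta <- qnorm(cumsum(tabulate(x2, length(ox))[-length(ox)]) / length(x))
  tb <- qnorm(cumsum(tabulate(y2, length(oy))[-length(oy)]) / length(y))
  cts <- .cross_counts(x2, y2, max(length(ox), length(oy)))[seq_along(ox),
                                                           seq_along(oy),
                                                           drop = FALSE]
  nll <- function(r) polychoric_nll_cpp(r, ta, tb, cts)
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-8)
  rho <- opt$minimum
  list(rho = rho, var = .numeric_info_var(nll, rho),
       thresholds_x = tx, thresholds_y = ty)
}

#' Polyserial correlation of a continuous and an ordinal variable
#'
#' Two-step maximum likelihood with the ordinal thresholds fixed at their
#' marginal estimates and the continuous variable standardized by its sample
#' moments; the latent correlation maximizes the conditional ordinal
#' likelihood given the observed continuous scores.
#'
#' @param z numeric vector (non-constant).
#' @param y integer vector of categories.
#' @param n_categories number of scale categories.
#' @return list with `rho`, `var`, `thresholds_y`.
#' @export
polyserial <- function(z, y, n_categories = 4L) {
  if (length(z) != length(y)) stop("z and y must have equal length")
  if (sd(z) == 0) stop("degenerate continuous variable: zero variance")
  zs <- (z - mean(z)) / sd(z)
  ty <- estimate_thresholds(y, n_categories)
  tau <- c(-Inf, ty, Inf)
  lo <- tau[y]; hi <- tau[y + 1L]
  nll <- function(r) {
    s <- sqrt(1 - r^2)
    p <- pnorm((hi - r * zs) / s) - pnorm((lo - r * zs) / s)
    -sum(log(pmax(p, 1e-12)))
  }
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-8)
  rho <- opt$minimum
  list(rho = rho, var = .numeric_info_var(nll, rho), thresholds_y = ty)
}

#' Mixed polychoric/polyserial correlation matrix of a sample
#'
#' Assembles the `(k+1) x (k+1)` latent correlation matrix of the items and
#' the continuous criterion (last row/column), the estimated item
#' thresholds, and the per-correlation asymptotic variances used as
#' diagonally-weighted-least-squares weights. If the assembled matrix is not
#' positive definite it is repaired by clipping eigenvalues at 1e-6 and
#' re-normalizing to unit diagonal (flagged in the result).
#'
#' @param data a [sample_data()].
#' @param include_criterion include the criterion row/column (default TRUE).
#' @return object of class `mixed_cor` with fields `corr`, `thresholds`
#'   (`k x (n_categories-1)` matrix), `avar` (matrix of asymptotic variances,
#'   `NA` on the diagonal), `n`, `repaired`.
#' @export
mixed_cor <- function(data, include_criterion = TRUE) {
  stopifnot(inherits(data, "sample_data"))
  resp <- data$responses
  k <- ncol(resp)
  nc <- data$n_categories
  p <- k + as.integer(include_criterion)
  R <- diag(p)
  V <- matrix(NA_real_, p, p)
  thr <- matrix(NA_real_, k, nc - 1L)
  for (i in seq_len(k)) thr[i, ] <- estimate_thresholds(resp[, i], nc)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      pc <- polychoric(resp[, i], resp[, j], nc)
      R[i, j] <- R[j, i] <- pc$rho
      V[i, j] <- V[j, i] <- pc$var
    }
  }
  if (include_criterion) {
    for (i in seq_len(k)) {
      ps <- polyserial(data$criterion, resp[, i], nc)
      R[i, p] <- R[p, i] <- ps$rho
      V[i, p] <- V[p, i] <- ps$var
    }
  }
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    repaired <- TRUE
    lam <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    diag(R) <- 1
  }
  nm <- c(paste0("item_", seq_len(k)), if (include_criterion) "criterion")
  dimnames(R) <- dimnames(V) <- list(nm, nm)
  # per-observation influence scores of every correlation estimate: the
  # empirical asymptotic covariance Gamma = crossprod(scores)/n^2 feeds the
  # robust (mean-and-variance adjusted) test statistic
  z <- if (include_criterion)
    (data$criterion - mean(data$criterion)) / sd(data$criterion)
  else numeric(0)
  scores <- pair_scores_cpp(resp, thr, R, z)
  structure(list(corr = R, thresholds = thr, avar = V,
                 n = nrow(resp), repaired = repaired,
                 n_items = k, has_criterion = include_criterion,
                 scores = scores),
            class = "mixed_cor")
}

#' @export
print.mixed_cor <- function(x, ...) {
  cat(sprintf("<mixed_cor> %d items%s, n = %d%s\n", x$n_items,
              if (x$has_criterion) " + criterion" else "", x$n,
              if (x$repaired) " (PD-repaired)" else ""))
  invisible(x)
}
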