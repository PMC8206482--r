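# Gauss-Hermite nodes/weights transformed for a standard normal density
.gh_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# log P(category | nodes) array of dim (Q, nc, 1 item) for a graded
# normal-ogive item: latent y* = lam*eta (+ sqrt(omega)*zeta) + e,
# Var(e) = 1 - lam^2 - omega, cutpoints tau.
.item_logprobs <- function(tau, mean_star, theta_u) {
  sdu <- sqrt(theta_u)
  Q <- length(mean_star)
  nc <- length(tau) + 1L
  cum <- matrix(0, Q, nc + 1L)
  cum[, nc + 1L] <- 1
  for (c in seq_along(tau)) cum[, c + 1L] <- pnorm((tau[c] - mean_star) / sdu)
  p <- cum[, -1L, drop = FALSE] - cum[, -(nc + 1L), drop = FALSE]
  log(pmax(p, 1e-300))
}

#' Expected a posteriori (EAP) factor scores
#'
#' Scores respondents under the normal-ogive graded-response
#' reparameterization of a fitted categorical factor model, using
#' Gauss-Hermite quadrature (`n_quad` points per dimension; one dimension
#' for the substantive factor, two for RIIFA where the orthogonal wording
#' dimension is scaled by `sqrt(omega)`). When the fitted model contains the
#' criterion regression, the (standardized) criterion enters the posterior
#' as a normal outcome with mean `beta_sf * eta (+ beta_wf * zeta)` and
#' residual variance `1 - R^2` — the posterior conditions on every observed
#' variable of the model, as SEM software does when computing factor
#' scores; set `use_criterion = FALSE` for items-only scores. Refuses
#' non-converged fits.
#'
#' @param data a [sample_data()] whose responses are to be scored.
#' @param fit a converged [fit_dwls()] result (supplies loadings, omega,
#'   thresholds and the structural coefficients).
#' @param n_quad quadrature points per dimension (default 21).
#' @param use_criterion condition the posterior on the criterion variable;
#'   defaults to whether the fitted model includes it.
#' @return list with `sf` (substantive EAP scores, length N) and `wf`
#'   (wording EAP scores in the unit-variance metric; `NULL` for 1F).
#' @export
eap_scores <- function(data, fit, n_quad = 21L,
                       use_criterion = isTRUE(fit$criterion_included)) {
  stopifnot(inherits(data, "sample_data"), inherits(fit, "wefa_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to score a non-converged fit (", fit$reason, ")")
  resp <- data$responses
  k <- ncol(resp)
  if (k != fit$k) stop("data and fit disagree on the number of items")
  lam <- fit$loadings
  omega <- if (fit$kind == "riifa") fit$omega else 0
  theta_u <- pmax(1 - lam^2 - omega, 1e-3)
  tau <- fit$thresholds
  nc <- ncol(tau) + 1L
  gh <- .gh_normal(n_quad)

  if (fit$kind == "riifa") {
    eta <- rep(gh$x, times = n_quad)
    zeta <- rep(gh$x, each = n_quad)
    wq <- rep(gh$w, times = n_quad) * rep(gh$w, each = n_quad)
    mean_star <- function(i) lam[i] * eta + sqrt(omega) * zeta
  } else {
    eta <- gh$x
    zeta <- NULL
    wq <- gh$w
    mean_star <- function(i) lam[i] * eta
  }
  Q <- length(eta)
  logp <- array(0, dim = c(Q, nc, k))
  for (i in seq_len(k))
    logp[, , i] <- .item_logprobs(tau[i, ], mean_star(i), theta_u[i])
  ll <- ll_accum_cpp(resp, logp)
  if (use_criterion) {
    if (!isTRUE(fit$criterion_included))
      stop("fit has no criterion regression to condition on")
    z <- (data$criterion - mean(data$criterion)) / sd(data$criterion)
    mu <- fit$beta_sf * eta
    if (fit$kind == "riifa") mu <- mu + fit$beta_wf * zeta
    s_eps <- sqrt(max(1 - fit$r2, 0.05))
    ll <- ll + outer(z, mu, function(a, b) dnorm(a, b, s_eps, log = TRUE))
  }
  ll <- ll + rep(log(wq), each = nrow(ll))
  m <- apply(ll, 1, max)
  post <- exp(ll - m)
  denom <- rowSums(post)
  sf <- as.vector(post %*% eta) / denom
  wf <- if (fit$kind == "riifa") as.vector(post %*% zeta) / denom else NULL
  list(sf = sf, wf = wf)
}
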