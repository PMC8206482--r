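#' Population model for a balanced wording-effects scale
#'
#' Defines the generating model: one substantive factor measured by `k`
#' 4-category items (half positively worded, half negatively worded, i.e.
#' half the loadings negative), plus a continuous criterion variable loading
#' 1.0 on a second factor that correlates `factor_corr` with the substantive
#' factor.
#'
#' @param loadings numeric vector of signed substantive loadings; absolute
#'   values must lie in `[0.60, 0.80]` and exactly `floor(k/2)` entries must
#'   be negative (balanced scale).
#' @param factor_corr correlation between the substantive and the criterion
#'   factor, in (-1, 1). Default 0.50 (a strong criterion relation).
#' @param thresholds strictly increasing cutpoints used to discretize the
#'   latent item responses into 4 symmetric categories.
#' @param criterion_loading loading of the criterion variable on its factor.
#' @return an object of class `population_spec`.
#' @export
#' @examples
#' population_spec(c(0.7, -0.7))
population_spec <- function(loadings,
                            factor_corr = 0.5,
                            thresholds = c(-1.5, 0, 1.5),
                            criterion_loading = 1.0) {
  k <- length(loadings)
  if (k < 2) stop("at least two items are required")
  if (any(abs(loadings) < 0.60 - 1e-9) || any(abs(loadings) > 0.80 + 1e-9))
    stop("absolute loadings must lie in [0.60, 0.80]")
  if (sum(loadings < 0) != floor(k / 2))
    stop("balanced scale requires exactly floor(k/2) negative loadings")
  if (abs(factor_corr) >= 1) stop("factor_corr must lie in (-1, 1)")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  structure(
    list(n_items = k, loadings = as.numeric(loadings),
         criterion_loading = criterion_loading, factor_corr = factor_corr,
         thresholds = as.numeric(thresholds),
         n_categories = length(thresholds) + 1L),
    class = "population_spec")
}

#' Draw signed substantive factor loadings for a balanced scale
#'
#' Loadings are drawn from U(0.60, 0.80) (mean 0.70) and exactly half of
#' them, at uniformly random positions, are given a negative sign to play the
#' role of negatively worded items. Uses the current RNG stream.
#'
#' @param k even number of items, `k >= 2`.
#' @return numeric vector of length `k`.
#' @export
draw_loadings <- function(k) {
  if (k < 2 || k %% 2 != 0)
    stop("balanced scale violation: k must be even and >= 2")
  lam <- runif(k, 0.60, 0.80)
  neg <- sample.int(k, k / 2)
  lam[neg] <- -lam[neg]
  lam
}

#' Reproduced population correlation matrix
#'
#' Computes the model-implied correlation matrix of the `k` items plus the
#' criterion variable: `Lambda Phi Lambda'` off the diagonal with unities
#' inserted on the diagonal. The criterion occupies the last row/column.
#'
#' @param spec a [population_spec()].
#' @return symmetric `(k+1) x (k+1)` positive-definite matrix.
#' @export
population_matrix <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  k <- spec$n_items
  Lambda <- rbind(cbind(spec$loadings, 0),
                  c(0, spec$criterion_loading))
  Phi <- matrix(c(1, spec$factor_corr, spec$factor_corr, 1), 2)
  R <- Lambda %*% Phi %*% t(Lambda)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("population matrix not positive definite (min eigenvalue %.3g)",
                 min(ev)))
  dimnames(R) <- list(c(paste0("item_", seq_len(k)), "criterion"),
                      c(paste0("item_", seq_len(k)), "criterion"))
  R
}

#' Simulate multivariate standard normal data with a target correlation matrix
#'
#' Draws `Z U` where `U` is the upper Cholesky factor of `pop_matrix` and `Z`
#' a matrix of independent standard normal deviates, so columns are standard
#' normal with the target correlation structure.
#'
#' @param pop_matrix positive-definite correlation matrix.
#' @param n number of rows (respondents).
#' @return `n x ncol(pop_matrix)` numeric matrix.
#' @export
simulate_continuous <- function(pop_matrix, n) {
  U <- tryCatch(chol(pop_matrix),
                error = function(e) stop("Cholesky decomposition of the population matrix failed: ",
                                         conditionMessage(e)))
  Z <- matrix(rnorm(n * ncol(pop_matrix)), nrow = n)
  X <- Z %*% U
  colnames(X) <- colnames(pop_matrix)
  X
}

#' Discretize continuous responses into ordered categories
#'
#' Category is `1 + #(thresholds < x)`; a value falling exactly on a
#' threshold goes to the lower category. With the default symmetric
#' thresholds (-1.5, 0, 1.5) on standard normal input, the expected category
#' proportions are (0.067, 0.433, 0.433, 0.067).
#'
#' @param x numeric vector or matrix.
#' @param thresholds strictly increasing cutpoints.
#' @return integer vector/matrix of categories in `1..(length(thresholds)+1)`.
#' @export
categorize <- function(x, thresholds = c(-1.5, 0, 1.5)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  out <- array(1L, dim = if (is.matrix(x)) dim(x) else length(x))
  for (t in thresholds) out <- out + (x > t)
  if (is.matrix(x)) {
    out <- matrix(as.integer(out), nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    out <- as.integer(out)
  }
  out
}

#' Bundle an ordinal response matrix with its criterion and metadata
#'
#' @param responses `N x k` integer matrix of categories.
#' @param criterion length-`N` numeric criterion vector.
#' @param item_polarity character vector of `"PW"`/`"NW"` labels per item.
#' @param inconsistent_flags logical length-`N`; `TRUE` marks respondents
#'   selected to answer inconsistently.
#' @param n_categories number of response categories.
#' @param seed integer seed the sample was drawn with (bookkeeping only).
#' @return object of class `sample_data`.
#' @export
sample_data <- function(responses, criterion, item_polarity,
                        inconsistent_flags, n_categories = 4L, seed = NA_integer_) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (any(responses < 1L | responses > n_categories))
    stop("response entries outside category bounds")
  if (length(criterion) != nrow(responses))
    stop("criterion length must equal the number of respondents")
  if (length(item_polarity) != ncol(responses))
    stop("one polarity label per item required")
  if (length(inconsistent_flags) != nrow(responses))
    stop("one consistency flag per respondent required")
  structure(list(responses = responses, criterion = as.numeric(criterion),
                 item_polarity = item_polarity,
                 inconsistent_flags = as.logical(inconsistent_flags),
                 n_categories = as.integer(n_categories),
                 seed = seed),
            class = "sample_data")
}

#' @export
print.sample_data <- function(x, ...) {
  cat(sprintf("<sample_data> %d respondents x %d items (%d PW, %d NW), %d flagged inconsistent\n",
              nrow(x$responses), ncol(x$responses),
              sum(x$item_polarity == "PW"), sum(x$item_polarity == "NW"),
              sum(x$inconsistent_flags)))
  invisible(x)
}

#' A single cell of the factorial simulation design
#'
#' @param effect_type one of `"none"`, `"carelessness"`, `"ivd"`,
#'   `"acquiescence"`.
#' @param perc_we percentage of items each inconsistent respondent
#'   misresponds to; design levels are 0, 10, 20, 30, 40, 50.
#' @param n sample size; design levels 200, 500, 1000.
#' @param test_length number of substantive items; design levels 12, 24, 60.
#' @param replicate_id replicate index within the cell.
#' @param custom allow levels outside the canonical factorial design.
#' @return object of class `design_cell`.
#' @export
design_cell <- function(effect_type = c("none", "carelessness", "ivd", "acquiescence"),
                        perc_we = 0, n = 200, test_length = 12,
                        replicate_id = 1L, custom = FALSE) {
  effect_type <- match.arg(effect_type)
  if (!custom) {
    if (!perc_we %in% c(0, 10, 20, 30, 40, 50))
      stop("perc_we outside the factorial levels; use custom = TRUE")
    if (!n %in% c(200, 500, 1000))
      stop("n outside the factorial levels; use custom = TRUE")
    if (!test_length %in% c(12, 24, 60))
      stop("test_length outside the factorial levels; use custom = TRUE")
  }
  structure(list(effect_type = effect_type, perc_we = perc_we, n = n,
                 test_length = test_length, replicate_id = as.integer(replicate_id)),
            class = "design_cell")
}

#' Generate an uncontaminated ordinal sample for a design cell
#'
#' Composes [draw_loadings()] -> [population_matrix()] ->
#' [simulate_continuous()] -> [categorize()], then randomly flags
#' `round(inconsistent_frac * N)` respondents (round-half-up) as the ones a
#' later contamination step will target. The criterion column is left
#' continuous.
#'
#' @param cell a [design_cell()].
#' @param spec_seed seed for drawing the population loadings.
#' @param sample_seed seed for the sample data and the inconsistency flags.
#' @param inconsistent_frac fraction of respondents flagged inconsistent.
#' @return list with elements `spec` ([population_spec()]) and `data`
#'   ([sample_data()]).
#' @export
#' @examples
#' gs <- generate_sample(design_cell("carelessness", 30, 200, 12), 11, 12)
#' sum(gs$data$inconsistent_flags)  # 80
generate_sample <- function(cell, spec_seed, sample_seed,
                            inconsistent_frac = 0.40) {
  stopifnot(inherits(cell, "design_cell"))
  k <- cell$test_length
  set.seed(spec_seed)
  lam <- draw_loadings(k)
  spec <- population_spec(lam)
  R <- population_matrix(spec)
  set.seed(sample_seed)
  X <- simulate_continuous(R, cell$n)
  resp <- categorize(X[, seq_len(k), drop = FALSE], spec$thresholds)
  n_flag <- round_half_up(inconsistent_frac * cell$n)
  flags <- rep(FALSE, cell$n)
  flags[sample.int(cell$n, n_flag)] <- TRUE
  dat <- sample_data(resp, X[, k + 1L],
                     item_polarity = ifelse(lam < 0, "NW", "PW"),
                     inconsistent_flags = flags, seed = sample_seed)
  list(spec = spec, data = dat)
}

#' Write a sample to CSV with a JSON sidecar
#'
#' Columns `item_1..item_k`, `criterion`, `inconsistent`; the sidecar records
#' the generating loadings, thresholds and seed.
#'
#' @param x list as returned by [generate_sample()] (elements `spec`, `data`).
#' @param file path of the CSV file; the sidecar gets extension `.json`.
#' @return `file`, invisibly.
#' @export
write_sample_csv <- function(x, file) {
  d <- x$data
  df <- as.data.frame(d$responses)
  names(df) <- paste0("item_", seq_len(ncol(d$responses)))
  df$criterion <- d$criterion
  df$inconsistent <- as.integer(d$inconsistent_flags)
  utils::write.csv(df, file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(loadings = x$spec$loadings, thresholds = x$spec$thresholds,
                 factor_corr = x$spec$factor_corr, seed = d$seed)
    jsonlite::write_json(side, sub("\\.csv$", ".json", file),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
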