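#' Specification of a wording-effect contamination
#'
#' Derives the number of items each inconsistent respondent misresponds to:
#' `round(perc_we/100 * k)` with round-half-up, with a minimum of one item
#' whenever `perc_we > 0`. Acquiescence carries the category selection
#' weights 0.50/0.33/0.17 for categories 1/2/3 (category 4 already expresses
#' maximal agreement and is never changed).
#'
#' @param effect_type `"carelessness"`, `"ivd"` or `"acquiescence"`.
#' @param perc_we percentage of the test's items misresponded per
#'   inconsistent respondent.
#' @param k number of substantive items.
#' @return object of class `contamination_spec`.
#' @export
contamination_spec <- function(effect_type = c("carelessness", "ivd", "acquiescence"),
                               perc_we, k) {
  effect_type <- match.arg(effect_type)
  if (perc_we < 0 || perc_we > 100) stop("perc_we must be a percentage")
  target <- if (perc_we > 0) max(1L, round_half_up(perc_we / 100 * k)) else 0L
  out <- list(effect_type = effect_type, perc_we = perc_we, k = as.integer(k),
              target_item_count = as.integer(target))
  if (effect_type == "acquiescence")
    out$switch_probs <- c("1" = 0.50, "2" = 0.33, "3" = 0.17)
  structure(out, class = "contamination_spec")
}

#' Reverse ordered response categories at selected positions
#'
#' Maps 1<->4 and 2<->3 (i.e. `5 - x` on a 4-point scale) at `positions`,
#' leaving other entries unchanged. Applying the same reversal twice is the
#' identity.
#'
#' @param responses integer vector with entries in `1..4`.
#' @param positions indices to reverse (may be empty).
#' @return reversed integer vector.
#' @export
#' @examples
#' reverse_categories(c(3L, 3L, 4L, 4L, 4L), 1:5)  # 2 2 1 1 1
reverse_categories <- function(responses, positions) {
  if (any(responses < 1L | responses > 4L))
    stop("response categories out of range 1..4")
  if (length(positions)) responses[positions] <- 5L - responses[positions]
  responses
}

# shared helper: pull the change log together
.change_log <- function(respondent, item, old, new) {
  data.frame(respondent = respondent, item = item, old = old, new = new)
}

#' Inject carelessness into a sample
#'
#' For every flagged (inconsistent) respondent, a uniformly random subset of
#' the negatively worded items of size `target_item_count` has its responses
#' reversed (1=4, 2=3, 3=2, 4=1) — i.e. the respondent answers NW items as if
#' they were positively worded. Consistent respondents are untouched. Uses
#' the current RNG stream.
#'
#' @param data a [sample_data()].
#' @param spec a [contamination_spec()] with `effect_type = "carelessness"`.
#' @return a new `sample_data`; the cell-level change log is attached as
#'   attribute `"changes"`.
#' @export
apply_carelessness <- function(data, spec) {
  stopifnot(inherits(data, "sample_data"), inherits(spec, "contamination_spec"))
  if (spec$effect_type != "carelessness") stop("spec is not a carelessness spec")
  nw <- which(data$item_polarity == "NW")
  if (spec$target_item_count > length(nw))
    stop(sprintf("infeasible: %d items to misrespond but only %d NW items",
                 spec$target_item_count, length(nw)))
  resp <- data$responses
  logs <- list()
  if (spec$target_item_count > 0L) {
    for (r in which(data$inconsistent_flags)) {
      pick <- nw[sample.int(length(nw), spec$target_item_count)]
      old <- resp[r, pick]
      resp[r, pick] <- 5L - old
      logs[[length(logs) + 1L]] <- .change_log(r, pick, old, resp[r, pick])
    }
  }
  out <- data
  out$responses <- resp
  attr(out, "changes") <- if (length(logs)) do.call(rbind, logs) else
    .change_log(integer(0), integer(0), integer(0), integer(0))
  out
}

#' Inject item-verification-difficulty misresponses
#'
#' Trait-conditional reversal: an inconsistent respondent with an
#' uncontaminated substantive score below 0 reverses positively worded items
#' (false affirmations are hard to reject); one with a score of 0 or above
#' reverses negatively worded items (false negations). Within the eligible
#' item set, `target_item_count` items are chosen uniformly at random and
#' reversed.
#'
#' @param data a [sample_data()].
#' @param spec a [contamination_spec()] with `effect_type = "ivd"`.
#' @param trait_scores length-`N` numeric vector of substantive factor scores
#'   estimated on the uncontaminated data (see [eap_scores()]).
#' @return contaminated `sample_data` with a `"changes"` attribute.
#' @export
apply_ivd <- function(data, spec, trait_scores) {
  stopifnot(inherits(data, "sample_data"), inherits(spec, "contamination_spec"))
  if (spec$effect_type != "ivd") stop("spec is not an ivd spec")
  if (length(trait_scores) != nrow(data$responses))
    stop("one trait score per respondent required")
  pw <- which(data$item_polarity == "PW")
  nw <- which(data$item_polarity == "NW")
  if (spec$target_item_count > min(length(pw), length(nw)))
    stop("infeasible: target item count exceeds the eligible item set")
  resp <- data$responses
  logs <- list()
  if (spec$target_item_count > 0L) {
    for (r in which(data$inconsistent_flags)) {
      eligible <- if (trait_scores[r] < 0) pw else nw
      pick <- eligible[sample.int(length(eligible), spec$target_item_count)]
      old <- resp[r, pick]
      resp[r, pick] <- 5L - old
      logs[[length(logs) + 1L]] <- .change_log(r, pick, old, resp[r, pick])
    }
  }
  out <- data
  out$responses <- resp
  attr(out, "changes") <- if (length(logs)) do.call(rbind, logs) else
    .change_log(integer(0), integer(0), integer(0), integer(0))
  out
}

#' Inject acquiescence (agreement-shift) misresponses
#'
#' For each inconsistent respondent, items are drawn sequentially without
#' replacement with selection weights 0.50/0.33/0.17 according to their
#' current category (1/2/3; category-4 items are ineligible) until
#' `target_item_count` items have been changed or the eligible items are
#' exhausted. A selected item is remapped upward: 1 -> 3, 2 -> 3 or 4 (fair
#' coin), 3 -> 4, and becomes ineligible for re-selection. Every change
#' strictly increases the response category.
#'
#' @param data a [sample_data()].
#' @param spec a [contamination_spec()] with `effect_type = "acquiescence"`.
#' @return contaminated `sample_data`; attribute `"changes"` holds the change
#'   log and attribute `"exhausted"` the respondents whose eligible items ran
#'   out before the target count.
#' @export
apply_acquiescence <- function(data, spec) {
  stopifnot(inherits(data, "sample_data"), inherits(spec, "contamination_spec"))
  if (spec$effect_type != "acquiescence") stop("spec is not an acquiescence spec")
  w_cat <- c(0.50, 0.33, 0.17, 0)
  resp <- data$responses
  logs <- list()
  exhausted <- integer(0)
  if (spec$target_item_count > 0L) {
    for (r in which(data$inconsistent_flags)) {
      row <- resp[r, ]
      changed <- 0L
      done <- rep(FALSE, length(row))
      while (changed < spec$target_item_count) {
        w <- ifelse(done, 0, w_cat[row])
        if (sum(w) <= 0) { exhausted <- c(exhausted, r); break }
        j <- sample.int(length(row), 1L, prob = w)
        old <- row[j]
        row[j] <- switch(old,
                         `1` = 3L,
                         `2` = if (runif(1) < 0.5) 3L else 4L,
                         `3` = 4L)
        done[j] <- TRUE
        changed <- changed + 1L
        logs[[length(logs) + 1L]] <- .change_log(r, j, old, row[j])
      }
      resp[r, ] <- row
    }
  }
  out <- data
  out$responses <- resp
  attr(out, "changes") <- if (length(logs)) do.call(rbind, logs) else
    .change_log(integer(0), integer(0), integer(0), integer(0))
  attr(out, "exhausted") <- unique(exhausted)
  out
}

#' Apply a wording effect to a sample
#'
#' Dispatches to [apply_carelessness()], [apply_ivd()] or
#' [apply_acquiescence()]; with `perc_we = 0` (or `effect = "none"`) the
#' sample is returned unchanged.
#'
#' @param data a [sample_data()].
#' @param effect effect type (`"none"`, `"carelessness"`, `"ivd"`,
#'   `"acquiescence"`).
#' @param perc_we percentage of items misresponded per inconsistent
#'   respondent.
#' @param trait_scores uncontaminated substantive scores (required for IVD).
#' @return contaminated `sample_data`.
#' @export
contaminate <- function(data, effect, perc_we, trait_scores = NULL) {
  if (effect == "none" || perc_we == 0) return(data)
  spec <- contamination_spec(effect, perc_we, ncol(data$responses))
  switch(effect,
         carelessness = apply_carelessness(data, spec),
         ivd = {
           if (is.null(trait_scores))
             stop("ivd contamination needs uncontaminated trait scores")
           apply_ivd(data, spec, trait_scores)
         },
         acquiescence = apply_acquiescence(data, spec))
}
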