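#' The eight BRUMS-32 mood factors
#' @return Character vector of factor names.
#' @export
brums_factors <- function() {
  c("anger", "tension", "depression", "vigor",
    "fatigue", "confusion", "happy", "calmness")
}

#' Default item-to-factor mapping for the BRUMS-32
#'
#' The published item wording and order of the 32-item Brunel Mood Scale are
#' not redistributable, so the default mapping assigns items in labeled
#' blocks of four (items 1--4 anger, 5--8 tension, ... 29--32 calmness).
#' The scoring arithmetic is invariant to which concrete mapping is supplied;
#' pass your own two-column table to use the validated instrument.
#'
#' @return Tibble with columns `item` (1--32) and `factor`.
#' @export
brums_default_mapping <- function() {
  tibble::tibble(item = 1:32, factor = rep(brums_factors(), each = 4))
}

validate_mapping <- function(mapping) {
  if (!all(c("item", "factor") %in% names(mapping)))
    stop("mapping needs 'item' and 'factor' columns")
  if (!setequal(mapping$item, 1:32) || anyDuplicated(mapping$item))
    stop("mapping must assign each of items 1-32 exactly once")
  counts <- table(mapping$factor)
  if (!setequal(names(counts), brums_factors()) || any(counts != 4))
    stop("mapping must assign exactly 4 items to each of the 8 factors")
  invisible(mapping)
}

#' Score a BRUMS-32 answer sheet into eight factor scores
#'
#' Each item is rated on the 5-point scale 0 ("not at all") to 4
#' ("extremely"); a factor score is the sum of its four item ratings, so each
#' factor ranges 0--16.
#'
#' @param ratings Integer vector of 32 ratings in `0:4` (named or in item
#'   order 1--32).
#' @param mapping Item-to-factor table (default [brums_default_mapping()]).
#' @return Named numeric vector of 8 factor scores.
#' @export
score_brums <- function(ratings, mapping = brums_default_mapping()) {
  validate_mapping(mapping)
  if (length(ratings) != 32) stop("expected exactly 32 item ratings")
  if (anyNA(ratings) || !all(ratings %in% 0:4))
    stop("ratings must be integers between 0 and 4")
  vapply(brums_factors(), function(f)
    sum(ratings[mapping$item[mapping$factor == f]]), numeric(1))
}

#' Per-factor change between two scored sheets
#'
#' @param post,pre Named factor-score vectors from [score_brums()] for the
#'   same subject.
#' @return Named vector of `post - pre` changes, each in `[-16, 16]`.
#' @export
delta_scores <- function(post, pre) {
  if (!setequal(names(post), names(pre)))
    stop("factor sets differ between pre and post")
  post[names(pre)] - pre
}

#' Score a table of BRUMS-32 responses
#'
#' @param responses Data frame with identifier columns plus `item_01` ...
#'   `item_32` rating columns (one row per sheet).
#' @param mapping Item-to-factor table.
#' @return Tibble: the identifier columns plus one column per factor.
#' @export
score_brums_table <- function(responses, mapping = brums_default_mapping()) {
  item_cols <- sprintf("item_%02d", 1:32)
  if (!all(item_cols %in% names(responses)))
    stop("responses must contain columns item_01 ... item_32")
  ids <- responses[setdiff(names(responses), item_cols)]
  scores <- t(apply(as.matrix(responses[item_cols]), 1,
                    score_brums, mapping = mapping))
  tibble::as_tibble(cbind(ids, as.data.frame(scores)))
}

#' Simulate BRUMS-32 answer sheets for a cohort
#'
#' Generates pre- and post-stimulus sheets per subject and condition. Each
#' item starts from a common mild baseline tendency; the post sheet shifts
#' the four items of each factor by `delta[[condition]][factor] / 4` on
#' average (so the factor-score change targets `delta`), with integer
#' rounding and clipping to the 0--4 scale.
#'
#' @param n Subjects.
#' @param deltas Named list (by condition) of named numeric vectors (by
#'   factor) of target mean factor-score changes.
#' @param seed Integer seed.
#' @param item_sd SD of the per-item latent noise (default 0.8).
#' @param mapping Item-to-factor table.
#' @return Tibble with `subject`, `condition`, `timepoint`, `item_01` ...
#'   `item_32`.
#' @export
simulate_brums <- function(n, deltas, seed = 1L, item_sd = 0.8,
                           mapping = brums_default_mapping()) {
  validate_mapping(mapping)
  set.seed(as.integer(seed))
  rows <- list()
  for (cond in names(deltas)) {
    dl <- deltas[[cond]]
    for (s in seq_len(n)) {
      base <- pmax(0, pmin(4, round(stats::rnorm(32, mean = 1.5, sd = item_sd))))
      shift <- numeric(32)
      for (f in names(dl)) {
        items <- mapping$item[mapping$factor == f]
        shift[items] <- dl[[f]] / 4
      }
      post <- pmax(0, pmin(4, round(base + shift +
                                      stats::rnorm(32, sd = item_sd))))
      rows[[length(rows) + 1L]] <- c(list(subject = s, condition = cond,
                                          timepoint = "pre"),
                                     as.list(stats::setNames(base,
                                       sprintf("item_%02d", 1:32))))
      rows[[length(rows) + 1L]] <- c(list(subject = s, condition = cond,
                                          timepoint = "post"),
                                     as.list(stats::setNames(post,
                                       sprintf("item_%02d", 1:32))))
    }
  }
  do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
}
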