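#' The modified Kano evaluation matrix
#'
#' Maps a (forward, reverse) answer pair to a Kano label. Rows index the
#' forward question answer (1 = "I don't like it" ... 5 = "Be fond of"),
#' columns the reverse question answer in the same option order. The default
#' is the modified table: forward 1 gives (Q, R, R, R, R), forward 2..4 give
#' (M, I, I, I, R), forward 5 gives (O, A, A, A, Q).
#'
#' @return 5x5 character matrix with labels in `{Q, R, M, O, A, I}`.
#' @export
#' @examples
#' evaluation_matrix()[5, 1] # "O"
evaluation_matrix <- function() {
  m <- rbind(
    c("Q", "R", "R", "R", "R"),
    c("M", "I", "I", "I", "R"),
    c("M", "I", "I", "I", "R"),
    c("M", "I", "I", "I", "R"),
    c("O", "A", "A", "A", "Q"))
  dimnames(m) <- list(forward = 1:5, reverse = 1:5)
  m
}

#' Classify one forward/reverse answer pair
#'
#' @param forward,reverse integer answers in 1..5 (vectorized).
#' @param matrix evaluation matrix, by default [evaluation_matrix()]; an
#'   alternative 5x5 table (e.g. the unmodified Kano table) may be supplied.
#' @return character vector of labels in `{A, O, M, I, R, Q}`.
#' @export
classify_pair <- function(forward, reverse, matrix = evaluation_matrix()) {
  forward <- as.integer(forward)
  reverse <- as.integer(reverse)
  if (anyNA(forward) || anyNA(reverse) ||
      any(forward < 1L | forward > 5L) || any(reverse < 1L | reverse > 5L)) {
    stop_ck("answers must be integers in 1..5")
  }
  matrix[cbind(forward, reverse)]
}

#' Tabulate evaluation-table outcomes for one item
#'
#' Counts labels over all respondents with both the forward and the reverse
#' answer present for the item; respondents missing either answer are
#' excluded.
#'
#' @param rs a [kano_responses()] object.
#' @param item item code present in the catalog.
#' @param matrix evaluation matrix.
#' @return named integer vector over `c(A, O, M, I, R, Q)` of class
#'   `kano_counts`.
#' @export
tabulate_item <- function(rs, item, matrix = evaluation_matrix()) {
  stopifnot(inherits(rs, "kano_responses"))
  if (!item %in% rs$catalog$code) stop_ck("unknown item: ", item)
  f <- rs$data[[paste0(item, "_f")]]
  r <- rs$data[[paste0(item, "_r")]]
  ok <- !is.na(f) & !is.na(r)
  labels <- if (any(ok)) classify_pair(f[ok], r[ok], matrix) else character()
  counts <- table(factor(labels, levels = KANO_LABELS))
  structure(stats::setNames(as.integer(counts), KANO_LABELS),
            item = item, class = "kano_counts")
}

#' Frequency (modal) classification
#'
#' Standard traditional-method rule: the item takes the most frequent label.
#' Ties are broken conservatively by the priority M > O > A > I > R > Q.
#'
#' @param counts named vector of label counts over (a subset of)
#'   `c(A, O, M, I, R, Q)`, e.g. from [tabulate_item()].
#' @return single label.
#' @export
#' @examples
#' frequency_classify(c(M = 10, O = 10)) # "M" by tie priority
frequency_classify <- function(counts) {
  priority <- c("M", "O", "A", "I", "R", "Q")
  full <- stats::setNames(rep(0L, 6L), priority)
  full[names(counts)] <- as.integer(counts)
  if (all(full == 0L)) stop_ck("all-zero counts")
  names(full)[which.max(full)] # which.max takes the first max: priority order
}

#' Better-Worse satisfaction coefficients
#'
#' `SI = (A + O) / (A + O + M + I)` and
#' `DSI = -(O + M) / (A + O + M + I)`; Reverse and Questionable responses
#' are excluded from numerator and denominator.
#'
#' @param counts named label counts (see [frequency_classify()]).
#' @return list with `SI` in `[0, 1]` and `DSI` in `[-1, 0]`.
#' @export
#' @examples
#' bw_coefficients(c(A = 30, O = 40, M = 20, I = 10)) # SI 0.7, DSI -0.6
bw_coefficients <- function(counts) {
  full <- stats::setNames(rep(0L, 6L), KANO_LABELS)
  full[names(counts)] <- as.integer(counts)
  denom <- sum(full[c("A", "O", "M", "I")])
  if (denom == 0L) stop_ck("undefined coefficients: A + O + M + I is zero")
  list(SI = (full[["A"]] + full[["O"]]) / denom,
       DSI = -(full[["O"]] + full[["M"]]) / denom)
}

#' Better-Worse quadrant classification
#'
#' Boundary-inclusive quadrant rule on (`SI`, `|DSI|`): both at or above the
#' cutoff is One-dimensional, only `SI` Attractive, only `|DSI|` Must-be,
#' neither Indifferent. The cutoff is a convention (0.5 by default), not an
#' estimated quantity.
#'
#' @param b list with `SI` and `DSI`, e.g. from [bw_coefficients()].
#' @param cut cutoff in (0, 1).
#' @return single label in `{A, O, M, I}`.
#' @export
bw_classify <- function(b, cut = 0.5) {
  stopifnot(cut > 0, cut < 1)
  hi_si <- b$SI >= cut
  hi_dsi <- abs(b$DSI) >= cut
  if (hi_si && hi_dsi) "O" else if (hi_si) "A" else if (hi_dsi) "M" else "I"
}

#' Traditional / BW classification of every item
#'
#' @param rs a [kano_responses()] object.
#' @param method `"traditional"` (frequency rule) or `"bw"`.
#' @param cut BW cutoff (ignored for traditional).
#' @param matrix evaluation matrix.
#' @return a `kano_classification` data.frame (code, label) with the
#'   parameters used stored in `attr(, "params")`.
#' @export
classify_traditional <- function(rs, method = c("traditional", "bw"),
                                 cut = 0.5, matrix = evaluation_matrix()) {
  method <- match.arg(method)
  labels <- vapply(rs$catalog$code, function(code) {
    counts <- tabulate_item(rs, code, matrix)
    if (method == "traditional") frequency_classify(counts)
    else bw_classify(bw_coefficients(counts), cut)
  }, character(1))
  new_classification(rs$catalog$code, unname(labels), method,
                     params = if (method == "bw") list(cut = cut) else list())
}
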