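#' Likert coding of a questionnaire answer
#'
#' Forward questions score the chosen option directly (`M_i = i`); reverse
#' questions mirror it (`M_i = 6 - i`), so "I don't like it" about a missing
#' service scores 5 in the dissatisfaction direction. The reverse map is an
#' involution on 1..5 with fixed point 3.
#'
#' @param option integer answer(s) in 1..5.
#' @param direction `"forward"` or `"reverse"`.
#' @return integer score(s) in 1..5.
#' @export
#' @examples
#' code_answer(1, "reverse") # 5
code_answer <- function(option, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  option <- as.integer(option)
  if (anyNA(option) || any(option < 1L | option > 5L)) {
    stop_ck("option must be an integer in 1..5")
  }
  if (direction == "forward") option else 6L - option
}

#' Per-item aggregate satisfaction scores
#'
#' Sums coded scores over respondents, per item and direction:
#' `alpha_pos[j] = sum_k X[k, j]` of coded forward answers and likewise
#' `alpha_neg` for coded reverse answers. Respondents missing an answer are
#' excluded from that item-direction sum only; per-item respondent counts
#' are kept alongside.
#'
#' @param rs a non-empty [kano_responses()] object.
#' @return data.frame of class `kano_aggregate` with columns `code`,
#'   `alpha_pos`, `alpha_neg`, `q_pos`, `q_neg`, `importance_mean`.
#' @export
aggregate_scores <- function(rs) {
  stopifnot(inherits(rs, "kano_responses"))
  if (n_respondents(rs) == 0L) stop_ck("empty response set")
  codes <- rs$catalog$code
  res <- lapply(codes, function(code) {
    f <- rs$data[[paste0(code, "_f")]]
    r <- rs$data[[paste0(code, "_r")]]
    imp <- rs$data[[paste0(code, "_imp")]]
    data.frame(
      code = code,
      alpha_pos = sum(code_answer(f[!is.na(f)], "forward")),
      alpha_neg = sum(code_answer(r[!is.na(r)], "reverse")),
      q_pos = sum(!is.na(f)),
      q_neg = sum(!is.na(r)),
      importance_mean = if (any(!is.na(imp))) mean(imp, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), class = c("kano_aggregate", "data.frame"))
}

#' Relative satisfaction profile
#'
#' Ratio normalization of aggregate scores: each item's share of the total
#' coded score per direction, `beta_pos[j] = alpha_pos[j] / sum(alpha_pos)`
#' and likewise `beta_neg`. Both columns sum to 1 and all shares are
#' strictly positive (coded scores are at least 1 per answer).
#'
#' @param a a `kano_aggregate` from [aggregate_scores()].
#' @return data.frame of class `kano_profile` with columns `code`,
#'   `beta_pos`, `beta_neg`, `importance`.
#' @export
normalize_scores <- function(a) {
  stopifnot(is.data.frame(a), all(c("alpha_pos", "alpha_neg") %in% names(a)))
  if (any(a$alpha_pos <= 0) || any(a$alpha_neg <= 0)) {
    stop_ck("all aggregate scores must be positive (no item may be unanswered)")
  }
  structure(data.frame(
    code = a$code,
    beta_pos = a$alpha_pos / sum(a$alpha_pos),
    beta_neg = a$alpha_neg / sum(a$alpha_neg),
    importance = if ("importance_mean" %in% names(a)) a$importance_mean else NA_real_,
    stringsAsFactors = FALSE
  ), class = c("kano_profile", "data.frame"))
}

#' One-step relative satisfaction profile from responses
#'
#' Convenience wrapper: [aggregate_scores()] then [normalize_scores()].
#'
#' @inheritParams aggregate_scores
#' @return a `kano_profile` data.frame.
#' @export
satisfaction_profile <- function(rs) normalize_scores(aggregate_scores(rs))

# Accept either a kano_profile or a bare data.frame with beta columns
# (e.g. the packaged profile fixture).
as_profile <- function(p) {
  stopifnot(is.data.frame(p), all(c("beta_pos", "beta_neg") %in% names(p)))
  p
}

#' Interval thresholds for the Candy classifier
#'
#' The grand mean of the relative shares is `theta = 1/n`. The floating
#' range `phi` is the spread of the combined satisfaction and
#' dissatisfaction shares (max minus min over all `2n` values), and the
#' classification interval is symmetric about theta:
#' `[theta - v * phi, theta + v * phi]` with floating ratio `v` (about 1/6
#' by convention).
#'
#' @param p profile with `beta_pos` and `beta_neg` columns.
#' @param v floating ratio, `v >= 0`.
#' @return object of class `kano_thresholds`: list with `n`, `theta`,
#'   `phi`, `v`, `theta_low`, `theta_up`.
#' @export
#' @examples
#' t <- compute_thresholds(get_fixture("profiles_table9"))
#' round_half_up(c(t$theta_low, t$theta_up), 5) # 0.02057 0.02291
compute_thresholds <- function(p, v = 1 / 6) {
  p <- as_profile(p)
  stopifnot(v >= 0, nrow(p) > 0)
  n <- nrow(p)
  betas <- c(p$beta_pos, p$beta_neg)
  phi <- max(betas) - min(betas)
  theta <- 1 / n
  structure(list(n = n, theta = theta, phi = phi, v = v,
                 theta_low = theta - v * phi,
                 theta_up = theta + v * phi),
            class = "kano_thresholds")
}

#' @export
print.kano_thresholds <- function(x, ...) {
  cat("<kano_thresholds> n=", x$n,
      " theta=", round_half_up(x$theta, 5),
      " phi=", round_half_up(x$phi, 5),
      " v=", signif(x$v, 4),
      " interval=[", round_half_up(x$theta_low, 5), ", ",
      round_half_up(x$theta_up, 5), "]\n", sep = "")
  invisible(x)
}

#' Ratio-quadrant classification
#'
#' Point-threshold comparator: quadrants around the center `(theta, theta)`.
#' Both shares above theta is One-dimensional; only `beta_pos` above is
#' Attractive; only `beta_neg` above is Must-be; neither is Indifferent
#' (boundaries go to the lower side).
#'
#' @param beta_pos,beta_neg positive relative shares (vectorized).
#' @param theta center threshold, typically `1/n`.
#' @return character vector of labels in `{O, A, M, I}`.
#' @export
classify_ratio <- function(beta_pos, beta_neg, theta) {
  stopifnot(all(beta_pos > 0), all(beta_neg > 0), theta > 0)
  ifelse(beta_pos > theta & beta_neg > theta, "O",
  ifelse(beta_pos > theta, "A",
  ifelse(beta_neg > theta, "M", "I")))
}

#' Interval (Candy) classification
#'
#' Five-region partition by position relative to the interval
#' `[theta_low, theta_up]`: inside in both directions is One-dimensional
#' (O); above in both is Critical (C); below in both is Indifferent (I);
#' otherwise Attractive (A) when satisfaction clears the lower bound while
#' dissatisfaction stays under the upper bound, else Must-be (M). Interval
#' membership is boundary-inclusive and the conditions are evaluated in the
#' order O, C, I, A, M, which makes the function total: every positive
#' `(beta_pos, beta_neg)` pair receives exactly one label.
#'
#' @param beta_pos,beta_neg positive relative shares (vectorized).
#' @param thresholds a [compute_thresholds()] object (or any list with
#'   `theta_low`, `theta_up`).
#' @return character vector of labels in `{C, M, O, A, I}`.
#' @export
classify_candy <- function(beta_pos, beta_neg, thresholds) {
  stopifnot(all(beta_pos > 0), all(beta_neg > 0))
  lo <- thresholds$theta_low
  up <- thresholds$theta_up
  in_pos <- beta_pos >= lo & beta_pos <= up
  in_neg <- beta_neg >= lo & beta_neg <= up
  ifelse(in_pos & in_neg, "O",
  ifelse(beta_pos > up & beta_neg > up, "C",
  ifelse(beta_pos < lo & beta_neg < lo, "I",
  ifelse(beta_pos > lo & beta_neg < up, "A", "M"))))
}

# Shared classification-result constructor.
new_classification <- function(codes, labels, method, params = list()) {
  stopifnot(length(codes) == length(labels), !anyDuplicated(codes))
  structure(data.frame(code = codes, label = labels,
                       stringsAsFactors = FALSE),
            method = method, params = params,
            class = c("kano_classification", "data.frame"))
}

#' Classify every item of a profile
#'
#' @param p profile with `beta_pos`/`beta_neg` columns (a `kano_profile` or
#'   the packaged profile fixture).
#' @param method `"candy"` or `"ratio"`.
#' @param v floating ratio for the interval (candy only), used when
#'   `thresholds` is not supplied.
#' @param theta center for the ratio method; defaults to `1/n`.
#' @param thresholds optional precomputed [compute_thresholds()] object.
#' @return a `kano_classification` data.frame (code, label); the thresholds
#'   or theta actually used are stored in `attr(, "params")`.
#' @export
#' @examples
#' cl <- classify_all(get_fixture("profiles_table9"), "candy")
#' count_categories(cl)
classify_all <- function(p, method = c("candy", "ratio"), v = 1 / 6,
                         theta = NULL, thresholds = NULL) {
  method <- match.arg(method)
  p <- as_profile(p)
  if (method == "candy") {
    thresholds <- thresholds %||% compute_thresholds(p, v)
    labels <- classify_candy(p$beta_pos, p$beta_neg, thresholds)
    new_classification(p$code, labels, "candy", params = unclass(thresholds))
  } else {
    theta <- theta %||% (1 / nrow(p))
    labels <- classify_ratio(p$beta_pos, p$beta_neg, theta)
    new_classification(p$code, labels, "ratio", params = list(theta = theta))
  }
}

#' Count items per requirement category
#'
#' @param r a `kano_classification` (or any data.frame with a `label`
#'   column, e.g. one label column of the packaged profile fixture).
#' @param levels label set to tabulate over.
#' @return named integer vector of counts summing to the item count.
#' @export
count_categories <- function(r, levels = c("O", "I", "M", "A", "C")) {
  labels <- if (is.data.frame(r)) r$label else r
  counts <- table(factor(labels, levels = union(levels, unique(labels))))
  stats::setNames(as.integer(counts), names(counts))
}

#' Scatter-data export for quadrant plots
#'
#' Emits one row per item with its shares, label and the threshold geometry,
#' suitable for plotting a quadrant/interval chart in any tool.
#'
#' @param p profile with beta columns.
#' @param method `"candy"` or `"ratio"`.
#' @param v floating ratio (candy).
#' @return data.frame with columns code, beta_pos, beta_neg, label, theta,
#'   theta_low, theta_up.
#' @export
scatter_data <- function(p, method = c("candy", "ratio"), v = 1 / 6) {
  method <- match.arg(method)
  p <- as_profile(p)
  t <- compute_thresholds(p, v)
  cl <- classify_all(p, method, v = v)
  data.frame(code = p$code, beta_pos = p$beta_pos, beta_neg = p$beta_neg,
             label = cl$label, theta = t$theta,
             theta_low = t$theta_low, theta_up = t$theta_up,
             stringsAsFactors = FALSE)
}
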