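#' Importance summary by requirement category
#'
#' For each requirement category, ranks its items by mean importance
#' (descending; ties broken by item code for deterministic reports) and
#' reports the maximum, minimum and mean importance.
#'
#' @param classification a `kano_classification` (code, label).
#' @param importance named numeric vector of per-item mean importance, or a
#'   data.frame with `code` and `importance` columns (e.g. a `kano_profile`
#'   or the packaged profile fixture).
#' @param levels category display order.
#' @return data.frame of class `kano_importance_summary` with one row per
#'   present category: `category`, `ranking` (codes joined by " > "),
#'   `max`, `min`, `average`; means reported at full precision (round for
#'   display with [round_half_up()]).
#' @export
#' @examples
#' t9 <- get_fixture("profiles_table9")
#' cl <- classify_all(t9, "candy")
#' category_importance_summary(cl, t9)
category_importance_summary <- function(classification, importance,
                                        levels = c("C", "M", "O", "A", "I")) {
  imp <- as_importance(importance)
  miss <- setdiff(classification$code, names(imp))
  if (length(miss)) {
    stop_ck("missing importance for: ", paste(miss, collapse = ", "))
  }
  present <- intersect(levels, unique(classification$label))
  rows <- lapply(present, function(cat) {
    codes <- classification$code[classification$label == cat]
    vals <- imp[codes]
    ord <- order(-vals, codes)
    data.frame(category = cat,
               ranking = paste(codes[ord], collapse = " > "),
               max = max(vals), min = min(vals), average = mean(vals),
               n_items = length(codes), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("kano_importance_summary", "data.frame"))
}

as_importance <- function(importance) {
  if (is.data.frame(importance)) {
    stopifnot(all(c("code", "importance") %in% names(importance)))
    stats::setNames(importance$importance, importance$code)
  } else {
    stopifnot(is.numeric(importance), !is.null(names(importance)))
    importance
  }
}

#' Importance summary by service category
#'
#' Ranks items inside each service group (life, intelligent, health,
#' security, spiritual) by mean importance and attaches the requirement
#' label when a classification is supplied, mirroring the "A6(C) > A5(C) >
#' ..." report layout.
#'
#' @param catalog a [kano_catalog()].
#' @param importance per-item importance (see
#'   [category_importance_summary()]).
#' @param classification optional `kano_classification` used to annotate
#'   the ranking with requirement labels.
#' @return data.frame of class `kano_importance_summary`: `category`,
#'   `ranking`, `max`, `min`, `average`, `n_items`.
#' @export
service_group_summary <- function(catalog, importance, classification = NULL) {
  catalog <- kano_catalog(catalog)
  imp <- as_importance(importance)
  labels <- if (!is.null(classification)) {
    stats::setNames(classification$label, classification$code)
  }
  groups <- intersect(SERVICE_CATEGORIES, unique(catalog$service_category))
  rows <- lapply(groups, function(g) {
    codes <- catalog$code[catalog$service_category == g]
    vals <- imp[codes]
    ord <- order(-vals, codes)
    shown <- if (is.null(labels)) codes[ord] else {
      paste0(codes[ord], "(", labels[codes[ord]], ")")
    }
    data.frame(category = g, ranking = paste(shown, collapse = " > "),
               max = max(vals), min = min(vals), average = mean(vals),
               n_items = length(codes), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("kano_importance_summary", "data.frame"))
}

#' Check the C >= M >= O >= A >= I importance ordering
#'
#' Sorts requirement categories by their mean importance and reports whether
#' the observed order respects the expected hierarchy (weak inequalities, so
#' exactly equal means never fail). Categories absent from the summary are
#' skipped with a note.
#'
#' @param summary a [category_importance_summary()] result.
#' @param expected expected order, most important first.
#' @return list with `order` (categories sorted by decreasing mean),
#'   `means`, `ok` (logical), `skipped` (absent categories).
#' @export
priority_check <- function(summary, expected = c("C", "M", "O", "A", "I")) {
  means <- stats::setNames(summary$average, summary$category)
  skipped <- setdiff(expected, names(means))
  present <- expected[expected %in% names(means)]
  observed <- names(sort(means, decreasing = TRUE))
  # ok iff means are weakly decreasing along the expected order
  ok <- all(diff(means[present]) <= 0)
  list(order = observed, means = means, ok = ok, skipped = skipped)
}

# Pearson r with two-sided t-test p-value and a CI by Fisher z or bootstrap.
pearson_with_ci <- function(x, y, conf = 0.95,
                            ci = c("fisher", "bootstrap"),
                            boot = 2000, seed = NULL) {
  ci <- match.arg(ci)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ck("undefined correlation: zero variance")
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  if (ci == "fisher") {
    z <- atanh(r)
    half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
    lo <- tanh(z - half); hi <- tanh(z + half)
  } else {
    rs <- with_seed(seed, vapply(seq_len(boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, numeric(1)))
    qs <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(r = r, ci_low = lo, ci_high = hi, p = p, n = n)
}

#' Correlation between importance and satisfaction sensitivity
#'
#' Pearson correlations of mean importance with 100 x beta_pos
#' (satisfaction), 100 x beta_neg (dissatisfaction), and
#' 100 x (beta_pos + beta_neg). The x100 rescaling follows the source
#' convention; Pearson r is scale-invariant, so it does not affect the
#' coefficients.
#'
#' @param p profile with `beta_pos`, `beta_neg` and `importance` columns
#'   (at least 3 items).
#' @param conf confidence level for the intervals.
#' @param ci `"fisher"` (normal approximation on the z scale) or
#'   `"bootstrap"` (percentile, resampling items).
#' @param boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `kano_correlation`: list of three entries
#'   (`satisfaction`, `dissatisfaction`, `sum`), each with `r`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
#' @examples
#' rep <- importance_satisfaction_correlation(get_fixture("profiles_table9"))
#' round_half_up(rep$satisfaction$r, 3) # 0.924
importance_satisfaction_correlation <- function(p, conf = 0.95,
                                                ci = c("fisher", "bootstrap"),
                                                boot = 2000, seed = NULL) {
  p <- as_profile(p)
  if (!"importance" %in% names(p)) stop_ck("profile has no importance column")
  if (nrow(p) < 3) stop_ck("need at least 3 items")
  ci <- match.arg(ci)
  imp <- p$importance
  out <- list(
    satisfaction = pearson_with_ci(imp, 100 * p$beta_pos, conf, ci, boot, seed),
    dissatisfaction = pearson_with_ci(imp, 100 * p$beta_neg, conf, ci, boot, seed),
    sum = pearson_with_ci(imp, 100 * (p$beta_pos + p$beta_neg), conf, ci,
                          boot, seed))
  structure(out, class = "kano_correlation")
}

#' @export
print.kano_correlation <- function(x, ...) {
  for (k in names(x)) {
    e <- x[[k]]
    cat(sprintf("%-15s r = %.3f, 95%% CI [%.3f, %.3f], p = %.3g (n = %d)\n",
                k, e$r, e$ci_low, e$ci_high, e$p, e$n))
  }
  invisible(x)
}
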