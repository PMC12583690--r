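#' Cronbach's alpha
#'
#' Internal-consistency reliability:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param scores numeric matrix or data.frame, respondents x items, no
#'   missing cells (apply listwise deletion upstream).
#' @return scalar alpha (at most 1; can be negative for incoherent scales).
#' @export
cronbach_alpha <- function(scores) {
  m <- as.matrix(scores)
  if (anyNA(m)) stop_ck("missing cells: apply listwise deletion first")
  k <- ncol(m)
  if (k < 2 || nrow(m) < 2) stop_ck("need at least 2 items and 2 respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop_ck("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: `sum(r^2) / (sum(r^2) + sum(partial^2))` over off-diagonal
#' entries, with partial correlations obtained from the inverse of the
#' correlation matrix (the anti-image approach).
#'
#' @param scores respondents x items matrix (no missing cells).
#' @return scalar KMO in `[0, 1]`.
#' @export
kmo <- function(scores) {
  m <- as.matrix(scores)
  if (anyNA(m)) stop_ck("missing cells: apply listwise deletion first")
  r <- stats::cor(m)
  inv <- tryCatch(solve(r), error = function(e) {
    stop_ck("singular correlation matrix")
  })
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2k + 5)/6) * log det(R)` with `k(k-1)/2` degrees of
#' freedom.
#'
#' @param scores respondents x items matrix, more respondents than items.
#' @return list with `chi2`, `df`, `p`.
#' @export
bartlett <- function(scores) {
  m <- as.matrix(scores)
  if (anyNA(m)) stop_ck("missing cells: apply listwise deletion first")
  n <- nrow(m); k <- ncol(m)
  if (n <= k) stop_ck("need more respondents than items")
  r <- stats::cor(m)
  det_r <- det(r)
  if (det_r <= 0) stop_ck("correlation matrix not positive definite")
  chi2 <- -(n - 1 - (2 * k + 5) / 6) * log(det_r)
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Coded score matrix for one direction; listwise deletion of respondents
# with any missing answer in the requested scope.
score_matrix <- function(rs, scope = c("forward", "reverse", "overall")) {
  scope <- match.arg(scope)
  codes <- rs$catalog$code
  # vectorized coding with NA passthrough
  build <- function(direction) {
    suffix <- if (direction == "forward") "_f" else "_r"
    cols <- lapply(codes, function(code) {
      x <- rs$data[[paste0(code, suffix)]]
      out <- rep(NA_integer_, length(x))
      ok <- !is.na(x)
      out[ok] <- code_answer(x[ok], direction)
      out
    })
    m <- do.call(cbind, cols)
    colnames(m) <- paste0(codes, suffix)
    m
  }
  m <- switch(scope,
    forward = build("forward"),
    reverse = build("reverse"),
    overall = cbind(build("forward"), build("reverse")))
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Reliability and validity report
#'
#' Cronbach's alpha, overall KMO and Bartlett's sphericity for the forward
#' question block, the reverse block, and the column-concatenated overall
#' questionnaire. Scores are the coded answers (reverse answers mirrored to
#' 6 - i); respondents with missing answers in a scope are dropped listwise
#' within that scope.
#'
#' @param rs a [kano_responses()] object.
#' @return data.frame of class `kano_reliability` with one row per scope:
#'   `scope`, `alpha`, `kmo`, `bartlett_chi2`, `bartlett_df`, `bartlett_p`,
#'   `n_respondents`.
#' @export
reliability_report <- function(rs) {
  stopifnot(inherits(rs, "kano_responses"))
  rows <- lapply(c("forward", "reverse", "overall"), function(scope) {
    m <- score_matrix(rs, scope)
    b <- bartlett(m)
    data.frame(scope = scope,
               alpha = cronbach_alpha(m),
               kmo = kmo(m),
               bartlett_chi2 = b$chi2, bartlett_df = b$df, bartlett_p = b$p,
               n_respondents = nrow(m), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("kano_reliability", "data.frame"))
}
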