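#' Service catalog constructor
#'
#' A catalog lists the surveyed service items: a short unique code, a label,
#' and one of the five service categories (life, intelligent, health,
#' security, spiritual).
#'
#' @param x data.frame with columns `code`, `label`, `service_category`.
#' @return object of class `kano_catalog` (a validated data.frame).
#' @export
#' @examples
#' kano_catalog(data.frame(code = "A1", label = "Meal delivery",
#'                         service_category = "life"))
kano_catalog <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("code", "label", "service_category")
  if (!all(need %in% names(x))) {
    stop_ck("catalog needs columns: ", paste(need, collapse = ", "))
  }
  x$code <- as.character(x$code)
  x$service_category <- as.character(x$service_category)
  if (anyDuplicated(x$code)) {
    stop_ck("duplicate item codes in catalog: ",
            paste(unique(x$code[duplicated(x$code)]), collapse = ", "))
  }
  bad <- setdiff(unique(x$service_category), SERVICE_CATEGORIES)
  if (length(bad)) {
    stop_ck("unknown service_category: ", paste(bad, collapse = ", "))
  }
  structure(x, class = c("kano_catalog", "data.frame"))
}

#' @rdname kano_catalog
#' @format NULL
#' @export
SERVICE_CATEGORIES <- c("life", "intelligent", "health", "security", "spiritual")

#' Column-mapping schema for wide questionnaire CSVs
#'
#' One row per respondent; per item `<code>_f` (forward question: service
#' provided), `<code>_r` (reverse question: service absent) and `<code>_imp`
#' (importance rating), all on 1..5. Suffixes and the id/demographic columns
#' are configurable so platform exports can be mapped without renaming.
#'
#' @param catalog a [kano_catalog()].
#' @param id_col name of the respondent identifier column.
#' @param demographics character vector of demographic column names (may be
#'   absent from a file; missing demographics never invalidate a record).
#' @param forward_suffix,reverse_suffix,importance_suffix column suffixes.
#' @return a `kano_schema` list mapping item codes to column names.
#' @export
response_schema <- function(catalog,
                            id_col = "respondent_id",
                            demographics = DEMOGRAPHIC_ATTRIBUTES,
                            forward_suffix = "_f",
                            reverse_suffix = "_r",
                            importance_suffix = "_imp") {
  catalog <- kano_catalog(catalog)
  codes <- catalog$code
  structure(list(
    id_col = id_col,
    demographics = demographics,
    forward = stats::setNames(paste0(codes, forward_suffix), codes),
    reverse = stats::setNames(paste0(codes, reverse_suffix), codes),
    importance = stats::setNames(paste0(codes, importance_suffix), codes)
  ), class = "kano_schema")
}

#' @rdname response_schema
#' @format NULL
#' @export
DEMOGRAPHIC_ATTRIBUTES <- c("role", "sex", "residence", "income", "spouse",
                            "assets", "child_relationship", "distance",
                            "self_care")

# Coerce a raw answer column to integer 1..5; anything else becomes NA
# (flagged missing, never silently dropped).
coerce_answer <- function(x) {
  v <- suppressWarnings(as.integer(as.character(x)))
  v[!is.na(v) & (v < 1L | v > 5L)] <- NA_integer_
  v
}

#' Response set constructor
#'
#' Holds the catalog plus one wide data.frame of responses in canonical
#' column order (`respondent_id`, demographics, then `<code>_f`, `<code>_r`,
#' `<code>_imp` per item). Out-of-range or unparseable answers are stored as
#' `NA`.
#'
#' @param data wide data.frame of responses.
#' @param catalog a [kano_catalog()].
#' @param schema a [response_schema()]; defaults to the canonical layout.
#' @return object of class `kano_responses`.
#' @export
kano_responses <- function(data, catalog, schema = response_schema(catalog)) {
  catalog <- kano_catalog(catalog)
  stopifnot(is.data.frame(data))
  unknown <- setdiff(names(schema$forward), catalog$code)
  if (length(unknown)) {
    stop_ck("schema references item codes not in catalog: ",
            paste(unknown, collapse = ", "))
  }
  if (!schema$id_col %in% names(data)) {
    stop_ck("missing respondent id column '", schema$id_col, "'")
  }
  need <- c(schema$forward, schema$reverse, schema$importance)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_ck("missing answer columns: ", paste(miss, collapse = ", "))
  }
  id <- as.character(data[[schema$id_col]])
  if (anyDuplicated(id)) {
    stop_ck("duplicate respondent_id: ",
            paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  out <- data.frame(respondent_id = id, stringsAsFactors = FALSE)
  for (d in schema$demographics) {
    out[[d]] <- if (d %in% names(data)) as.character(data[[d]]) else NA_character_
  }
  for (code in catalog$code) {
    out[[paste0(code, "_f")]] <- coerce_answer(data[[schema$forward[[code]]]])
    out[[paste0(code, "_r")]] <- coerce_answer(data[[schema$reverse[[code]]]])
    out[[paste0(code, "_imp")]] <- coerce_answer(data[[schema$importance[[code]]]])
  }
  structure(list(catalog = catalog, data = out,
                 demographics = schema$demographics),
            class = "kano_responses")
}

#' @export
print.kano_responses <- function(x, ...) {
  cat("<kano_responses> ", nrow(x$data), " respondents, ",
      nrow(x$catalog), " items\n", sep = "")
  invisible(x)
}

#' Number of respondents in a response set
#' @param rs a [kano_responses()] object.
#' @return integer count.
#' @export
n_respondents <- function(rs) nrow(rs$data)

#' Read questionnaire responses from CSV
#'
#' @param path CSV file (UTF-8, header row), one row per respondent.
#' @param catalog a [kano_catalog()].
#' @param schema a [response_schema()] mapping columns; defaults to the
#'   canonical `<code>_f` / `<code>_r` / `<code>_imp` layout.
#' @return a [kano_responses()] object with raw (unfiltered) records;
#'   unparseable or out-of-range cells are flagged `NA`, not dropped.
#' @export
load_responses <- function(path, catalog, schema = response_schema(catalog)) {
  if (!file.exists(path)) stop_ck("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  kano_responses(raw, catalog, schema)
}

#' Write questionnaire responses to CSV
#'
#' Inverse of [load_responses()] on the canonical schema: writing then
#' reloading reproduces the response set exactly.
#'
#' @param rs a [kano_responses()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rs, path) {
  stopifnot(inherits(rs, "kano_responses"))
  utils::write.csv(rs$data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Preprocessing summary
#'
#' @param n_received questionnaires received (started).
#' @param n_completed questionnaires completed.
#' @param n_valid questionnaires retained after filtering.
#' @param removal_reasons named integer vector of per-rule removal counts.
#' @return object of class `kano_preprocess`; `effective_rate` is
#'   `n_valid / n_completed` (completed questionnaires are the denominator).
#' @export
#' @examples
#' s <- preprocess_summary(483, 425, 370)
#' round_half_up(100 * s$effective_rate, 2) # 87.06
preprocess_summary <- function(n_received, n_completed, n_valid,
                               removal_reasons = integer()) {
  if (!(n_valid <= n_completed && n_completed <= n_received)) {
    stop_ck("need n_valid <= n_completed <= n_received")
  }
  structure(list(
    n_received = as.integer(n_received),
    n_completed = as.integer(n_completed),
    n_valid = as.integer(n_valid),
    effective_rate = n_valid / n_completed,
    removal_reasons = removal_reasons
  ), class = "kano_preprocess")
}

#' @export
print.kano_preprocess <- function(x, ...) {
  cat("<kano_preprocess> received ", x$n_received, ", completed ",
      x$n_completed, ", valid ", x$n_valid, " (",
      round_half_up(100 * x$effective_rate, 2), "% effective)\n", sep = "")
  if (length(x$removal_reasons)) {
    cat("  removed:", paste(names(x$removal_reasons), x$removal_reasons,
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Per-record validity predicates -------------------------------------------

is_incomplete <- function(row, codes) {
  cols <- c(paste0(codes, "_f"), paste0(codes, "_r"), paste0(codes, "_imp"))
  anyNA(unlist(row[cols], use.names = FALSE))
}

is_straightline <- function(row, codes) {
  f <- unlist(row[paste0(codes, "_f")], use.names = FALSE)
  r <- unlist(row[paste0(codes, "_r")], use.names = FALSE)
  f <- f[!is.na(f)]; r <- r[!is.na(r)]
  length(f) > 0 && length(r) > 0 &&
    length(unique(f)) == 1L && length(unique(r)) == 1L
}

is_q_dominant <- function(row, codes, threshold) {
  f <- unlist(row[paste0(codes, "_f")], use.names = FALSE)
  r <- unlist(row[paste0(codes, "_r")], use.names = FALSE)
  ok <- !is.na(f) & !is.na(r)
  if (!any(ok)) return(FALSE)
  mean(classify_pair(f[ok], r[ok]) == "Q") > threshold
}

#' Filter invalid questionnaires
#'
#' Applies configurable survey-hygiene rules: `completeness` (any missing
#' Kano or importance answer invalidates), `straightline` (one identical
#' option on every forward question and one on every reverse question) and
#' `q_dominance` (more than `q_threshold` of an individual's item pairs
#' classify as Questionable under the evaluation table). A record is removed
#' by the first enabled rule it violates.
#'
#' @param rs a [kano_responses()] object (non-empty).
#' @param rules character vector of enabled rules.
#' @param q_threshold Questionable-share threshold for `q_dominance`.
#' @param n_received optional count of questionnaires received upstream of
#'   `rs` (defaults to the number of records, i.e. completed = received).
#' @return list with `responses` (the filtered set) and `summary`
#'   (a [preprocess_summary()]). Removing every record yields an empty set
#'   plus a warning, not an error.
#' @export
filter_invalid <- function(rs,
                           rules = c("completeness", "straightline",
                                     "q_dominance"),
                           q_threshold = 0.5,
                           n_received = NULL) {
  stopifnot(inherits(rs, "kano_responses"))
  if (n_respondents(rs) == 0L) stop_ck("empty response set")
  rules <- match.arg(rules, c("completeness", "straightline", "q_dominance"),
                     several.ok = TRUE)
  codes <- rs$catalog$code
  reason <- rep(NA_character_, n_respondents(rs))
  for (i in seq_len(n_respondents(rs))) {
    row <- rs$data[i, ]
    for (rule in rules) {
      hit <- switch(rule,
        completeness = is_incomplete(row, codes),
        straightline = is_straightline(row, codes),
        q_dominance  = is_q_dominant(row, codes, q_threshold))
      if (hit) { reason[i] <- rule; break }
    }
  }
  keep <- is.na(reason)
  out <- rs
  out$data <- rs$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  if (!any(keep)) warning("all records removed by filters", call. = FALSE)
  removed <- table(factor(reason[!keep], levels = rules))
  summary <- preprocess_summary(
    n_received = n_received %||% n_respondents(rs),
    n_completed = n_respondents(rs),
    n_valid = sum(keep),
    removal_reasons = stats::setNames(as.integer(removed), names(removed)))
  list(responses = out, summary = summary)
}

#' Packaged study fixtures
#'
#' Returns tables transcribed from the home-based elderly-care study this
#' package reproduces: the 46-item service catalog, the 46-row profile table
#' (importance, relative satisfaction/dissatisfaction shares, and the four
#' method label columns), the 5x5 evaluation matrix, and the stratified
#' label matrix with difference flags.
#'
#' @param name one of `"catalog_table5"`, `"profiles_table9"`,
#'   `"evaluation_matrix_table3"`, `"differentiated_table13"`.
#' @return `catalog_table5`: a [kano_catalog()]; `profiles_table9`: a
#'   data.frame with columns code, importance, beta_pos, beta_neg and the
#'   label columns `label_ratio`, `label_candy`, `label_normal`, `label_bw`;
#'   `evaluation_matrix_table3`: a 5x5 character matrix (see
#'   [evaluation_matrix()]); `differentiated_table13`: list with `labels`
#'   (46 x 10 data.frame), `flags` (logical, TRUE where the printed cell was
#'   bold) and `sizes` (per-column subgroup sample sizes).
#' @export
#' @examples
#' get_fixture("profiles_table9")[5, ] # item A5
get_fixture <- function(name) {
  path <- function(f) system.file("extdata", f, package = "candykano",
                                  mustWork = TRUE)
  switch(name,
    catalog_table5 = kano_catalog(
      utils::read.csv(path("catalog_table5.csv"),
                      stringsAsFactors = FALSE)),
    profiles_table9 =
      utils::read.csv(path("profiles_table9.csv"), stringsAsFactors = FALSE),
    evaluation_matrix_table3 = evaluation_matrix(),
    differentiated_table13 = {
      raw <- utils::read.csv(path("differentiated_table13.csv"),
                             stringsAsFactors = FALSE)
      lab <- raw[-1]
      flags <- as.data.frame(lapply(lab, function(x) grepl("\\*$", x)))
      lab <- as.data.frame(lapply(lab, function(x) sub("\\*$", "", x)))
      rownames(lab) <- rownames(flags) <- raw$code
      sizes <- c(perspective_child = 183L, perspective_old = 187L,
                 income_low = 281L, income_high = 89L,
                 relationship_bad = 156L, relationship_good = 214L,
                 distance_far = 191L, distance_near = 179L,
                 selfcare_poor = 138L, selfcare_good = 232L)
      list(labels = lab, flags = flags, sizes = sizes)
    },
    stop_ck("unknown fixture: ", name))
}
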