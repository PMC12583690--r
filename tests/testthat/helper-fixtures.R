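# Shared builders for in-code fixtures. Everything is generated at test
# time; no binary data.

tiny_catalog <- function(n = 3) {
  kano_catalog(data.frame(
    code = paste0("X", seq_len(n)),
    label = paste("Service", seq_len(n)),
    service_category = rep_len(SERVICE_CATEGORIES, n),
    stringsAsFactors = FALSE))
}

# Wide response data.frame in the canonical schema. `answers` is a list of
# per-respondent lists with elements f, r, imp (vectors over items).
make_wide <- function(catalog, answers, demographics = NULL) {
  n <- length(answers)
  df <- data.frame(respondent_id = paste0("R", seq_len(n)),
                   stringsAsFactors = FALSE)
  if (!is.null(demographics)) df <- cbind(df, demographics)
  for (j in seq_len(nrow(catalog))) {
    code <- catalog$code[j]
    df[[paste0(code, "_f")]] <- vapply(answers, function(a) a$f[j], numeric(1))
    df[[paste0(code, "_r")]] <- vapply(answers, function(a) a$r[j], numeric(1))
    df[[paste0(code, "_imp")]] <- vapply(answers, function(a) a$imp[j], numeric(1))
  }
  df
}

# A respondent answering every item identically.
uniform_answers <- function(n_items, f = 5, r = 1, imp = 4) {
  list(f = rep(f, n_items), r = rep(r, n_items), imp = rep(imp, n_items))
}

tiny_responses <- function(catalog = tiny_catalog(),
                           answers = list(uniform_answers(nrow(catalog)),
                                          uniform_answers(nrow(catalog), 4, 2, 3),
                                          uniform_answers(nrow(catalog), 3, 3, 5)),
                           demographics = NULL) {
  kano_responses(make_wide(catalog, answers, demographics), catalog,
                 response_schema(catalog,
                                 demographics = names(demographics) %||%
                                   character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal classification object for tests that supply labels directly.
new_cl <- function(codes, labels) {
  structure(data.frame(code = codes, label = labels,
                       stringsAsFactors = FALSE),
            class = c("kano_classification", "data.frame"))
}

# Random valid response set (all answers present) for property tests.
random_responses <- function(catalog, q, seed) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    answers <- lapply(seq_len(q), function(i) {
      list(f = sample(1:5, nrow(catalog), replace = TRUE),
           r = sample(1:5, nrow(catalog), replace = TRUE),
           imp = sample(1:5, nrow(catalog), replace = TRUE))
    })
    tiny_responses(catalog, answers)
  })
}

# Independent re-statement of the evaluation table as rules, used as the
# oracle for classify_pair.
oracle_pair <- function(f, r) {
  if (f == 1) { if (r == 1) "Q" else "R" }
  else if (f <= 4) { if (r == 1) "M" else if (r == 5) "R" else "I" }
  else { if (r == 1) "O" else if (r == 5) "Q" else "A" }
}

# Independent region oracle for the interval classifier, for points off the
# interval boundary: each axis falls below (-1), inside (0) or above (+1)
# the interval; equal regions map to I/O/C by level, otherwise the side
# with the higher region wins (satisfaction higher -> A, dissatisfaction
# higher -> M).
oracle_candy <- function(bp, bn, lo, up) {
  region <- function(x) if (x < lo) -1L else if (x > up) 1L else 0L
  rp <- region(bp); rn <- region(bn)
  if (rp == rn) c("I", "O", "C")[rp + 2L]
  else if (rp > rn) "A" else "M"
}
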