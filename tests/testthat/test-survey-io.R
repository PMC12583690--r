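test_that("load_responses reads well-formed CSVs and flags bad cells", {
  cat <- tiny_catalog()
  df <- make_wide(cat, list(uniform_answers(3), uniform_answers(3, 4, 2),
                            uniform_answers(3, 2, 4)))
  df$X1_f[2] <- 6      # out of range -> flagged missing
  df$X2_imp[3] <- "??" # unparseable -> flagged missing
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)

  rs <- load_responses(path, cat)
  expect_s3_class(rs, "kano_responses")
  expect_equal(n_respondents(rs), 3)
  expect_true(is.na(rs$data$X1_f[2]))
  expect_true(is.na(rs$data$X2_imp[3]))
  expect_equal(rs$data$X1_f[1], 5L)
})

test_that("load/write round-trip is the identity", {
  cat <- tiny_catalog(4)
  rs <- random_responses(cat, q = 7, seed = 11)
  rs$data$X1_r[3] <- NA # missing values survive the round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(rs, path)
  back <- load_responses(path, cat,
                         response_schema(cat, demographics = rs$demographics))
  expect_equal(back$data, rs$data)
  expect_equal(back$catalog, rs$catalog)
})

test_that("loader errors: missing file, unknown schema code, duplicate ids", {
  cat <- tiny_catalog()
  expect_error(load_responses("no/such/file.csv", cat), "not found")

  df <- make_wide(cat, list(uniform_answers(3)))
  big <- tiny_catalog(4) # schema mentions X4, absent from the catalog
  expect_error(kano_responses(df, cat, response_schema(big)), "X4")

  df2 <- make_wide(cat, list(uniform_answers(3), uniform_answers(3)))
  df2$respondent_id <- c("R1", "R1")
  expect_error(kano_responses(df2, cat), "duplicate respondent_id")
})

test_that("catalog validation enforces unique codes and the category set", {
  bad <- data.frame(code = c("X1", "X1"), label = c("a", "b"),
                    service_category = c("life", "life"))
  expect_error(kano_catalog(bad), "duplicate")
  bad2 <- data.frame(code = "X1", label = "a", service_category = "leisure")
  expect_error(kano_catalog(bad2), "service_category")
})

test_that("filter_invalid applies the three hygiene rules and reports counts", {
  cat <- tiny_catalog(4)
  good <- list(f = c(5, 4, 3, 2), r = c(1, 2, 2, 3), imp = rep(4, 4))
  incomplete <- list(f = c(5, NA, 3, 2), r = c(1, 2, 2, 3), imp = rep(4, 4))
  straight <- list(f = rep(2, 4), r = rep(4, 4), imp = rep(3, 4))
  # forward 1 with reverse > 1 is Questionable-free; (1,1) pairs are Q
  q_heavy <- list(f = c(1, 1, 1, 5), r = c(1, 1, 1, 1), imp = rep(4, 4))
  rs <- tiny_responses(cat, list(good, incomplete, straight, q_heavy))

  out <- filter_invalid(rs)
  expect_equal(n_respondents(out$responses), 1)
  expect_equal(out$responses$data$respondent_id, "R1")
  expect_equal(out$summary$removal_reasons[["completeness"]], 1L)
  expect_equal(out$summary$removal_reasons[["straightline"]], 1L)
  expect_equal(out$summary$removal_reasons[["q_dominance"]], 1L)
  expect_equal(out$summary$n_valid, 1L)

  # rules are configurable: with only completeness on, 3 records survive
  out2 <- filter_invalid(rs, rules = "completeness")
  expect_equal(n_respondents(out2$responses), 3)
})

test_that("filter_invalid is idempotent and handles edge cases", {
  cat <- tiny_catalog()
  rs <- random_responses(cat, q = 12, seed = 3)
  once <- filter_invalid(rs)
  twice <- filter_invalid(once$responses)
  expect_equal(twice$responses$data, once$responses$data)
  expect_equal(twice$summary$n_valid, twice$summary$n_completed)

  empty <- rs; empty$data <- rs$data[0, ]
  expect_error(filter_invalid(empty), "empty")

  all_straight <- tiny_responses(cat, list(uniform_answers(3, 5, 5)))
  expect_warning(res <- filter_invalid(all_straight), "all records removed")
  expect_equal(n_respondents(res$responses), 0)
})

test_that("effective rate uses completed questionnaires as denominator", {
  s <- preprocess_summary(483, 425, 370)
  expect_equal(round_half_up(100 * s$effective_rate, 2), 87.06)
  expect_error(preprocess_summary(400, 425, 370), "n_valid <= n_completed")
})

test_that("packaged fixtures match their printed sources", {
  cat5 <- get_fixture("catalog_table5")
  expect_equal(nrow(cat5), 46)
  expect_equal(as.vector(table(cat5$service_category)[SERVICE_CATEGORIES]),
               c(11, 6, 11, 10, 8))

  t9 <- get_fixture("profiles_table9")
  expect_equal(nrow(t9), 46)
  a5 <- t9[t9$code == "A5", ]
  expect_equal(a5$importance, 4.5946)
  expect_equal(a5$beta_pos, 0.0234)
  expect_equal(a5$beta_neg, 0.0249)
  expect_equal(a5$label_candy, "C")
  # rounding slack: 46 four-decimal values per direction
  expect_lt(abs(sum(t9$beta_pos) - 1), 0.005)
  expect_lt(abs(sum(t9$beta_neg) - 1), 0.005)

  m <- get_fixture("evaluation_matrix_table3")
  expect_equal(m[5, 1], "O")

  t13 <- get_fixture("differentiated_table13")
  expect_equal(dim(t13$labels), c(46, 10))
  expect_equal(unname(t13$sizes[c("perspective_child", "perspective_old")]),
               c(183L, 187L))

  expect_error(get_fixture("nope"), "unknown fixture")
})
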