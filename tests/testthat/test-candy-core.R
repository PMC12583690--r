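test_that("code_answer codes forward directly and mirrors reverse", {
  expect_equal(code_answer(5, "forward"), 5L)
  expect_equal(code_answer(1, "reverse"), 5L)
  expect_equal(code_answer(3, "forward"), code_answer(3, "reverse"))
  # reverse is an involution on 1..5
  for (i in 1:5) {
    expect_equal(code_answer(code_answer(i, "reverse"), "reverse"), i)
  }
  expect_error(code_answer(0, "forward"), "1..5")
})

test_that("aggregate_scores sums coded answers per item and direction", {
  cat <- tiny_catalog()
  rs <- tiny_responses(cat, list(uniform_answers(3), uniform_answers(3)))
  a <- aggregate_scores(rs)
  expect_equal(a$alpha_pos, rep(10, 3)) # two respondents, forward 5 each
  expect_equal(a$alpha_neg, rep(10, 3)) # reverse 1 codes to 5

  one <- tiny_responses(cat, list(uniform_answers(3, 3, 3, 3)))
  a1 <- aggregate_scores(one)
  expect_equal(a1$alpha_pos, rep(3, 3))
  expect_equal(a1$alpha_neg, rep(3, 3))

  empty <- rs; empty$data <- rs$data[0, ]
  expect_error(aggregate_scores(empty), "empty")
})

test_that("aggregate_scores equals a brute-force double loop, incl. missing", {
  cat <- tiny_catalog(4)
  rs <- random_responses(cat, q = 25, seed = 17)
  rs$data$X2_f[c(3, 8)] <- NA
  rs$data$X4_r[5] <- NA
  a <- aggregate_scores(rs)
  for (j in seq_len(nrow(cat))) {
    code <- cat$code[j]
    exp_pos <- 0L; exp_neg <- 0L; qp <- 0L; qn <- 0L
    for (k in seq_len(25)) {
      f <- rs$data[[paste0(code, "_f")]][k]
      r <- rs$data[[paste0(code, "_r")]][k]
      if (!is.na(f)) { exp_pos <- exp_pos + f; qp <- qp + 1L }
      if (!is.na(r)) { exp_neg <- exp_neg + (6L - r); qn <- qn + 1L }
    }
    expect_equal(a$alpha_pos[j], exp_pos)
    expect_equal(a$alpha_neg[j], exp_neg)
    expect_equal(a$q_pos[j], qp)
    expect_equal(a$q_neg[j], qn)
    # q <= alpha <= 5q
    expect_gte(a$alpha_pos[j], a$q_pos[j])
    expect_lte(a$alpha_pos[j], 5 * a$q_pos[j])
  }
})

test_that("normalize_scores yields shares summing to 1, scale invariant", {
  a <- data.frame(code = c("X1", "X2", "X3"),
                  alpha_pos = c(2, 1, 1), alpha_neg = c(1, 1, 2))
  p <- normalize_scores(a)
  expect_equal(p$beta_pos, c(0.5, 0.25, 0.25))
  expect_equal(sum(p$beta_neg), 1)

  a7 <- a; a7$alpha_pos <- 7 * a$alpha_pos; a7$alpha_neg <- 7 * a$alpha_neg
  expect_equal(normalize_scores(a7)$beta_pos, p$beta_pos)

  uniform <- data.frame(code = paste0("X", 1:8),
                        alpha_pos = rep(3, 8), alpha_neg = rep(3, 8))
  expect_equal(normalize_scores(uniform)$beta_pos, rep(1 / 8, 8))

  bad <- a; bad$alpha_pos[1] <- 0
  expect_error(normalize_scores(bad), "positive")
})

test_that("normalization conservation holds for random positive inputs", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    a <- data.frame(code = paste0("X", seq_len(n)),
                    alpha_pos = runif(n, 1, 100), alpha_neg = runif(n, 1, 100))
    p <- normalize_scores(a)
    expect_equal(sum(p$beta_pos), 1)
    expect_equal(sum(p$beta_neg), 1)
    expect_true(all(p$beta_pos > 0 & p$beta_neg > 0))
  }
})

test_that("compute_thresholds builds the symmetric interval around 1/n", {
  # degenerate: all shares equal
  p0 <- data.frame(beta_pos = rep(0.1, 10), beta_neg = rep(0.1, 10))
  t0 <- compute_thresholds(p0)
  expect_equal(t0$phi, 0)
  expect_equal(t0$theta_low, t0$theta)
  expect_equal(t0$theta_up, t0$theta)

  # arithmetic: n = 10, phi = 0.03, v = 1/6 -> [0.095, 0.105]
  p1 <- data.frame(beta_pos = c(0.13, rep(0.1, 9)),
                   beta_neg = c(0.10, rep(0.1, 9)))
  t1 <- compute_thresholds(p1, v = 1 / 6)
  expect_equal(t1$phi, 0.03)
  expect_equal(t1$theta_low, 0.095)
  expect_equal(t1$theta_up, 0.105)

  # phi ranges over the combined 2n values and the interval is symmetric
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    bp <- runif(n); bn <- runif(n)
    t <- compute_thresholds(data.frame(beta_pos = bp, beta_neg = bn),
                            v = runif(1, 0, 1))
    expect_equal(t$phi, max(c(bp, bn)) - min(c(bp, bn)))
    expect_equal(t$theta - t$theta_low, t$theta_up - t$theta)
    expect_lte(t$theta_low, t$theta)
  }
})

test_that("classify_ratio reproduces printed quadrant labels", {
  theta <- 1 / 46
  expect_identical(classify_ratio(0.0217, 0.0223, theta), "M") # C4
  expect_identical(classify_ratio(0.0220, 0.0213, theta), "A") # C10
  expect_identical(classify_ratio(0.0214, 0.0202, theta), "I") # E7
  # boundary goes to the lower side
  expect_identical(classify_ratio(theta, theta, theta), "I")
})

test_that("classify_candy reproduces printed labels and the center point", {
  t9 <- get_fixture("profiles_table9")
  t <- compute_thresholds(t9)
  expect_identical(classify_candy(0.0234, 0.0249, t), "C") # A5
  expect_identical(classify_candy(0.0225, 0.0231, t), "M") # A1
  expect_identical(classify_candy(0.0213, 0.0204, t), "A") # C5
  expect_identical(classify_candy(0.0221, 0.0224, t), "O") # A2
  expect_identical(classify_candy(0.0203, 0.0202, t), "I") # A3
  expect_identical(classify_candy(t$theta, t$theta, t), "O")
})

test_that("classify_candy is total and agrees with the region oracle", {
  t <- list(theta = 0.1, theta_low = 0.08, theta_up = 0.12)
  grid <- seq(0.0025, 0.1975, by = 0.005) # off the interval boundaries
  for (bp in grid) for (bn in grid) {
    got <- classify_candy(bp, bn, t)
    expect_length(got, 1)
    expect_identical(got, oracle_candy(bp, bn, t$theta_low, t$theta_up),
                     label = sprintf("(%.3f, %.3f)", bp, bn))
  }
})

test_that("with a degenerate interval candy collapses onto the ratio model", {
  set.seed(12)
  theta <- 1 / 20
  t0 <- list(theta = theta, theta_low = theta, theta_up = theta, v = 0)
  for (i in 1:300) {
    bp <- runif(1, 0.01, 0.09); bn <- runif(1, 0.01, 0.09)
    if (bp == theta || bn == theta) next
    candy <- classify_candy(bp, bn, t0)
    ratio <- classify_ratio(bp, bn, theta)
    if (ratio == "O") expect_identical(candy, "C")
    else expect_identical(candy, ratio)
  }
})

test_that("raising one forward answer weakly raises that item's share only", {
  cat <- tiny_catalog(5)
  rs <- random_responses(cat, q = 15, seed = 23)
  rs$data$X3_f[1] <- 2
  before <- satisfaction_profile(rs)
  rs$data$X3_f[1] <- 5
  after <- satisfaction_profile(rs)
  expect_gte(after$beta_pos[3], before$beta_pos[3])
  expect_true(all(after$beta_pos[-3] <= before$beta_pos[-3]))
  expect_equal(after$beta_neg, before$beta_neg)
})

test_that("classify_all labels every item once and records parameters", {
  t9 <- get_fixture("profiles_table9")
  candy <- classify_all(t9, "candy")
  expect_setequal(candy$code, t9$code)
  expect_false(anyDuplicated(candy$code) > 0)
  expect_equal(attr(candy, "method"), "candy")
  expect_equal(round_half_up(attr(candy, "params")$theta_up, 5), 0.02291)

  uniform <- data.frame(code = paste0("X", 1:9),
                        beta_pos = rep(1 / 9, 9), beta_neg = rep(1 / 9, 9))
  expect_true(all(classify_all(uniform, "candy")$label == "O"))

  counts <- count_categories(candy)
  expect_equal(sum(counts), 46L)
  single <- count_categories(data.frame(label = "M"))
  expect_equal(sum(single), 1L)
  expect_equal(single[["M"]], 1L)
})
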