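test_that("an informative feature outlives pure noise in the elimination order", {
  set.seed(1)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- cbind(A = ifelse(y == "a", -2, 2) + stats::rnorm(n, sd = 0.3),
             B = stats::rnorm(n))
  # oracle: single-feature training accuracy identifies A as informative
  acc1 <- function(j) {
    thr <- mean(tapply(x[, j], y, mean))
    max(mean((x[, j] > thr) == (y == "b")), mean((x[, j] <= thr) == (y == "b")))
  }
  expect_gt(acc1(1), 0.95)
  expect_lt(acc1(2), 0.65)
  rk <- rfe_rank(x, y, seed = 3, num_trees = 100)
  expect_identical(rk$elimination_order, c("B", "A"))
})

test_that("elimination rounds are a permutation and ranking is reproducible", {
  d <- make_selection_data(20, 6, seed = 5)
  rk <- rfe_rank(d$x, d$y, seed = 7, num_trees = 100)
  expect_setequal(unname(rk$rounds), seq_len(ncol(d$x)))
  expect_identical(rk$elimination_order,
                   rfe_rank(d$x, d$y, seed = 7, num_trees = 100)$elimination_order)
  expect_length(rfe_rank(d$x[, 1, drop = FALSE], d$y, seed = 1)$elimination_order, 1L)
  expect_error(rfe_rank(d$x, rep("a", nrow(d$x))), "constant")
})

test_that("a duplicated column is eliminated before the informative singleton", {
  set.seed(2)
  n <- 240
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  # A separates class a from {b, c}; C separates b from c; both are needed,
  # but A's information is carried twice (A and its near-duplicate)
  base <- ifelse(y == "a", -3, 3) + stats::rnorm(n, sd = 0.4)
  x <- cbind(A = base, A_dup = base + stats::rnorm(n, sd = 1e-3),
             C = ifelse(y == "c", 2, 0) + stats::rnorm(n, sd = 0.5))
  # oracle: subset accuracy without either duplicate is unchanged, without C
  # it collapses to two recoverable classes
  near_cent <- function(cols) {
    cents <- apply(x[, cols, drop = FALSE], 2, function(v) tapply(v, y, mean))
    pred <- apply(x[, cols, drop = FALSE], 1, function(r) {
      rownames(cents)[which.min(colSums((t(cents) - r)^2))]
    })
    mean(pred == y)
  }
  expect_gt(near_cent(c("A_dup", "C")), 0.95)   # dropping A costs nothing
  expect_lt(near_cent(c("A", "A_dup")), 0.75)   # dropping C loses b vs c
  rk <- rfe_rank(x, y, seed = 11, num_trees = 150)
  first_out <- rk$elimination_order[1]
  expect_true(first_out %in% c("A", "A_dup"))
})

test_that("validation-driven selection recovers the informative subset", {
  d <- make_selection_data(60, 14, seed = 21)
  idx <- sample(nrow(d$x))
  tr <- idx[1:320]; va <- idx[321:480]
  rk <- rfe_rank(d$x[tr, ], d$y[tr], seed = 9, num_trees = 100)
  sel <- select_subset(rk, d$x[tr, ], d$y[tr], d$x[va, ], d$y[va], seed = 9)
  expect_setequal(sel$selected, paste0("inf", 1:4))
  expect_equal(nrow(sel$trace), ncol(d$x))
})

test_that("with all-noise features the smallest subset wins the tie", {
  set.seed(31)
  x <- matrix(stats::rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("n", 1:5)))
  y <- factor(rep(c("a", "b"), each = 100))
  rk <- rfe_rank(x[1:140, ], y[1:140], seed = 2, num_trees = 100)
  sel <- select_subset(rk, x[1:140, ], y[1:140], x[141:200, ], y[141:200],
                       tolerance = 0.05, seed = 2)
  expect_length(sel$selected, 1L)
  expect_error(select_subset(rk, x, y, x[0, ], y[0]), "empty")
})
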