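test_that("Euclidean distance matches an explicit per-axis oracle", {
  expect_equal(landmark_distance(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(landmark_distance(c(5, -2, 7), c(5, -2, 7)), 0)
  set.seed(21)
  for (i in 1:50) {
    t <- rnorm(3, sd = 30); p <- rnorm(3, sd = 30)
    oracle <- 0
    for (ax in 1:3) oracle <- oracle + (t[ax] - p[ax])^2
    expect_equal(landmark_distance(t, p), sqrt(oracle), tolerance = 1e-12)
  }
})

test_that("distance is symmetric and satisfies the triangle inequality", {
  set.seed(22)
  for (i in 1:30) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    expect_equal(landmark_distance(a, b), landmark_distance(b, a))
    expect_lte(landmark_distance(a, c),
               landmark_distance(a, b) + landmark_distance(b, c) + 1e-12)
  }
})

test_that("SDR uses an inclusive boundary and is monotone in the threshold", {
  expect_equal(sdr(c(1, 2, 3), 2), 100 * 2 / 3)
  expect_equal(sdr(rep(0, 5)), 100)
  expect_error(sdr(numeric(0)), "empty")
  set.seed(23)
  d <- runif(1000, 0, 4)
  expect_lt(abs(sdr(d, 2) - 50), 5)
  thresholds <- seq(0, 4, by = 0.25)
  vals <- vapply(thresholds, function(th) sdr(d, th), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("measure errors are signed reference-minus-prediction values", {
  lms <- full46_landmarks()
  ref <- measure_all(lms)
  expect_true(all(measure_error(ref, ref)$error == 0))
  expect_true(all(measure_error(ref, ref)$success))
  # a 2-degree SNA error sits exactly on the success boundary
  pred <- ref
  i <- match("SNA", pred$id)
  pred$value[i] <- pred$value[i] - 2
  me <- measure_error(ref, pred)
  expect_equal(me$error[me$id == "SNA"], 2)
  expect_true(me$success[me$id == "SNA"])
  pred$value[i] <- pred$value[i] - 0.01
  expect_false(measure_error(ref, pred)$success[i])
  # randomized pairs against a direct subtraction oracle
  set.seed(24)
  for (k in 1:20) {
    p2 <- ref
    p2$value <- p2$value + rnorm(16)
    expect_equal(measure_error(ref, p2)$error, ref$value - p2$value,
                 tolerance = 1e-12)
  }
  # unavailable measures are excluded, not scored
  p3 <- ref
  p3$available[2] <- FALSE
  me3 <- measure_error(ref, p3)
  expect_true(me3$excluded[2])
  expect_true(is.na(me3$error[2]))
})

test_that("Mann-Whitney U is exact for clean separation and null identity", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1, tolerance = 1e-12)
  expect_true(r$exact)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p.value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact p-values equal full-permutation enumeration for n,m <= 7", {
  set.seed(25)
  brute <- function(x, y) {
    n <- length(x); m <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combs <- combn(n + m, n)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
  }
  for (rep in 1:50) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- rnorm(n); y <- rnorm(m, mean = runif(1, -1, 1))
    r <- mann_whitney_u(x, y)
    expect_true(r$exact)
    expect_equal(r$p.value, brute(x, y), tolerance = 1e-12)
    # cross-check against the standard library implementation
    expect_equal(r$p.value,
                 suppressWarnings(stats::wilcox.test(x, y)$p.value),
                 tolerance = 1e-12)
    expect_equal(r$U, unname(suppressWarnings(
      stats::wilcox.test(x, y)$statistic)))
  }
})

test_that("the tie-corrected normal approximation matches wilcox.test", {
  set.seed(26)
  for (rep in 1:25) {
    n <- sample(9:25, 1); m <- sample(9:25, 1)
    x <- sample(1:8, n, replace = TRUE) # heavy ties
    y <- sample(1:8, m, replace = TRUE) + runif(1, 0, 1.5)
    r <- mann_whitney_u(x, y)
    expect_false(r$exact)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(27)
  x <- rexp(12); y <- rexp(15, rate = 0.6)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(log(x), log(y))
  c3 <- mann_whitney_u(x^3, y^3)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  expect_equal(a$U, c3$U)
})

test_that("Benjamini-Hochberg matches the sorted-formula oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  oracle <- function(p) {
    mtot <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- rev(cummin(rev(sorted * mtot / seq_len(mtot))))
    pmin(adj, 1)[order(o)]
  }
  set.seed(28)
  for (rep in 1:50) {
    p <- runif(sample(2:40, 1))
    got <- benjamini_hochberg(p)
    expect_equal(got, oracle(p), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
  }
})

test_that("BH adjustment preserves the ordering of p-values", {
  set.seed(29)
  for (rep in 1:20) {
    p <- runif(15)
    adj <- benjamini_hochberg(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("identity evaluation yields zero distances, full SDR, empty review", {
  set.seed(30)
  spec <- phantom_spec(seed = 5)
  refs <- lapply(1:4, function(i)
    generate_case(spec, i, render = FALSE)$landmarks)
  names(refs) <- paste0("c", 1:4)
  ev <- evaluate_predictions(refs, refs)
  expect_true(all(ev$distances$distance == 0))
  expect_true(all(ev$per_landmark$sdr_pct == 100))
  expect_identical(nrow(ev$review), 0L)
  expect_identical(nrow(ev$misses), 0L)
})

test_that("large errors are flagged for review, not removed", {
  spec <- phantom_spec(seed = 6)
  refs <- lapply(1:3, function(i)
    generate_case(spec, i, render = FALSE)$landmarks)
  names(refs) <- paste0("c", 1:3)
  preds <- refs
  preds[["c2"]]$coords["Me", ] <- preds[["c2"]]$coords["Me", ] + c(15, 0, 0)
  ev <- evaluate_predictions(preds, refs)
  expect_identical(nrow(ev$review), 1L)
  expect_identical(ev$review$case_id, "c2")
  expect_identical(ev$review$landmark, "Me")
  # still present in the distance table
  expect_true(any(ev$distances$case_id == "c2" &
                    ev$distances$landmark == "Me"))
  # absent predictions are misses, not distances
  preds[["c3"]]$coords["S", ] <- NA
  ev2 <- evaluate_predictions(preds, refs)
  expect_identical(nrow(ev2$misses), 1L)
})

test_that("case alignment and group comparisons behave", {
  spec <- phantom_spec(seed = 7)
  refs <- lapply(1:6, function(i)
    generate_case(spec, i, render = FALSE)$landmarks)
  names(refs) <- paste0("c", 1:6)
  expect_error(evaluate_predictions(refs[1:5], refs), "alignment")
  set.seed(31)
  preds <- lapply(refs, perturb_landmarks, sd = 1)
  groups <- setNames(rep(c("A", "B"), each = 3), names(refs))
  ev <- evaluate_predictions(preds, refs, groups = groups)
  expect_identical(nrow(ev$per_group), 2L)
  expect_identical(nrow(ev$comparisons), 8L) # one per landmark
  expect_true(all(ev$comparisons$p_adj >= ev$comparisons$p - 1e-15))
  expect_true(all(ev$comparisons$p_adj <= 1))
})
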