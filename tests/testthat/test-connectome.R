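# Structural double threshold and functional Fisher-z group averaging.

test_that("directional combination follows the chosen rule", {
  m <- matrix(c(0, 200, 100, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(combine_directional(m)["A", "B"], 150)
  expect_equal(combine_directional(m, rule = "max")["A", "B"], 200)
  m2 <- matrix(c(0, 500, 500, 0), 2, 2, dimnames = dimnames(m))
  expect_equal(combine_directional(m2)["A", "B"], 500)
  m3 <- m2 * 0
  expect_equal(combine_directional(m3)["A", "B"], 0)
  expect_error(combine_directional(matrix(0, 2, 3)), "square")
})

test_that("Poisson thresholds match a brute-force tail scan", {
  expect_identical(poisson_threshold_value(3), 7L)
  expect_identical(poisson_threshold_value(10), 16L)
  for (lambda in seq(0.5, 50, by = 0.5)) {
    expect_identical(poisson_threshold_value(lambda),
                     as.integer(brute_poisson_threshold(lambda)),
                     label = paste("lambda =", lambda))
  }
})

test_that("poisson_threshold binarizes at the subject-specific rate", {
  labels <- sprintf("r%d", 1:4)
  m <- matrix(0, 4, 4, dimnames = list(labels, labels))
  m[1, 2] <- m[2, 1] <- 9
  m[3, 4] <- m[4, 3] <- 2
  # nonzero mean lambda = 5.5 -> threshold 11: nothing survives
  b <- poisson_threshold(m)
  expect_equal(attr(b, "lambda"), 5.5)
  expect_identical(attr(b, "threshold"),
                   as.integer(brute_poisson_threshold(5.5)))
  expect_true(all(b == 0))
  # a tiny all-entries rate keeps any positive entry (threshold 1)
  lab10 <- sprintf("q%d", 1:10)
  single <- matrix(0, 10, 10, dimnames = list(lab10, lab10))
  single[1, 2] <- single[2, 1] <- 1
  b2 <- poisson_threshold(single, lambda_estimator = "all_mean")
  expect_identical(attr(b2, "threshold"), 1L)
  expect_equal(b2[1, 2], 1)
  expect_warning(z <- poisson_threshold(m * 0), "all-zero")
  expect_true(all(z == 0))
})

test_that("lowering alpha never adds structural edges", {
  d <- tiny_design(seed = 31)
  comb <- combine_directional(generate_structural_cohort(d)[[1]])
  prev <- NULL
  for (alpha in c(0.2, 0.1, 0.05, 0.01, 0.001)) {
    b <- poisson_threshold(comb, alpha = alpha)
    if (!is.null(prev)) expect_true(all(b <= prev))
    prev <- b
  }
})

test_that("group consistency keeps an edge at exactly the half-cohort boundary", {
  labels <- c("A", "B", "C")
  mk <- function(present) {
    m <- matrix(0, 3, 3, dimnames = list(labels, labels))
    if (present) m["A", "B"] <- m["B", "A"] <- 1
    m["B", "C"] <- m["C", "B"] <- 1  # unanimous edge
    m
  }
  cohort12 <- c(replicate(12, mk(TRUE), simplify = FALSE),
                replicate(12, mk(FALSE), simplify = FALSE))
  g12 <- group_consistency(cohort12, 0.5)
  expect_equal(g12$adjacency["A", "B"], 1)  # 12/24 kept (inclusive)
  expect_equal(g12$adjacency["B", "C"], 1)  # unanimity kept
  cohort11 <- c(replicate(11, mk(TRUE), simplify = FALSE),
                replicate(13, mk(FALSE), simplify = FALSE))
  expect_equal(group_consistency(cohort11, 0.5)$adjacency["A", "B"], 0)
  expect_error(group_consistency(list()), "at least one")
  # raising the fraction never adds group edges
  d <- tiny_design(seed = 32)
  bins <- lapply(generate_structural_cohort(d),
                 function(m) poisson_threshold(combine_directional(m)))
  prev <- NULL
  for (f in c(0.25, 0.5, 0.75, 1)) {
    adj <- group_consistency(bins, f)$adjacency
    if (!is.null(prev)) expect_true(all(adj <= prev))
    prev <- adj
  }
})

test_that("motion censoring applies strict 3 mm / 1 degree thresholds", {
  mk <- function(id, tr, ro) {
    structure(list(series = matrix(rnorm(20), 2, 10),
                   motion_translation_mm = tr, motion_rotation_deg = ro,
                   subject_id = id), class = "subject_ts")
  }
  cohort <- list(mk("s1", 3.2, 0.1), mk("s2", 2.9, 0.5), mk("s3", 0, 0),
                 mk("s4", 1.0, 1.2))
  res <- censor_subjects(cohort)
  expect_equal(res$report$excluded, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(res$report$reason[1], "translation")
  expect_match(res$report$reason[4], "rotation")
  expect_equal(length(res$included), 2)
  nomo <- structure(list(series = matrix(rnorm(20), 2, 10), subject_id = "s5"),
                    class = "subject_ts")
  expect_warning(res2 <- censor_subjects(list(nomo)), "no motion")
  expect_equal(length(res2$included), 1)
})

test_that("subject correlation matrices behave at the exact and null limits", {
  x <- rnorm(200)
  series <- rbind(a = x, b = x, c = -x + 0, d = rnorm(200))
  r <- subject_functional_matrix(series)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), setNames(rep(0, 4), rownames(series)))
  set.seed(41)
  indep <- matrix(rnorm(5 * 5000), 5, 5000,
                  dimnames = list(letters[1:5], NULL))
  expect_lt(max(abs(upper_vec(subject_functional_matrix(indep)))), 0.05)
  const <- rbind(a = rep(1, 30), b = rnorm(30))
  expect_error(subject_functional_matrix(const), "constant.*a")
})

test_that("Fisher-z group averaging matches the stated formula", {
  labels <- c("A", "B")
  mk <- function(r) matrix(c(0, r, r, 0), 2, 2, dimnames = list(labels, labels))
  # symmetric cancellation
  g0 <- group_functional_matrix(list(mk(0.5), mk(-0.5)))
  expect_equal(g0$weights["A", "B"], 0)
  # constant input is a fixed point
  gc <- group_functional_matrix(list(mk(0.3), mk(0.3)))
  expect_equal(gc$weights["A", "B"], 0.3)
  # direct evaluation of tanh(mean(atanh)); value frozen from the formula
  g <- group_functional_matrix(list(mk(0.2), mk(0.6)))
  expect_equal(g$weights["A", "B"], 0.42020410288672871, tolerance = 1e-12)
  # negative group values are zeroed, not retained
  gn <- group_functional_matrix(list(mk(-0.2), mk(-0.6)))
  expect_equal(gn$weights["A", "B"], 0)
})

test_that("a single-subject group returns the input with negatives zeroed, exactly", {
  set.seed(42)
  s <- matrix(rnorm(30 * 200), 30, 200,
              dimnames = list(sprintf("r%02d", 1:30), NULL))
  r <- subject_functional_matrix(s)
  g <- group_functional_matrix(list(r))
  expect_identical(g$weights, pmax(r, 0))
})

test_that("group outputs are symmetric with zero diagonal", {
  d <- tiny_design(seed = 33)
  bins <- lapply(generate_structural_cohort(d),
                 function(m) poisson_threshold(combine_directional(m)))
  adj <- group_consistency(bins)$adjacency
  expect_identical(adj, t(adj))
  expect_true(all(diag(adj) == 0))
  corrs <- lapply(generate_functional_cohort(d), subject_functional_matrix)
  w <- group_functional_matrix(corrs)$weights
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))
})
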