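## Toy long-format table builder.
toy_table <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  data.frame(subject_id = rep(sprintf("S%02d", 1:n), each = k),
             montage_name = rep(colnames(Y), times = n),
             value = as.numeric(t(Y)),
             stringsAsFactors = FALSE)
}

set.seed(123)
Y5 <- matrix(rnorm(15, mean = rep(c(1, 1.4, 1.1), each = 5), sd = 0.3), 5, 3)
Y5 <- matrix(Y5, 5, 3, dimnames = list(NULL, c("A", "B", "C")))

test_that("repeated-measures ANOVA matches a hand-computed sums-of-squares oracle", {
  a <- rm_anova(toy_table(Y5), "value")
  ## brute-force oracle: explicit sums of squares and covariance-based epsilon
  n <- 5; k <- 3
  gm <- mean(Y5)
  ssA <- n * sum((colMeans(Y5) - gm)^2)
  ssS <- k * sum((rowMeans(Y5) - gm)^2)
  ssE <- sum((Y5 - gm)^2) - ssA - ssS
  Fo <- (ssA / (k - 1)) / (ssE / ((k - 1) * (n - 1)))
  S <- cov(Y5)
  eps <- (k * (mean(diag(S)) - mean(S)))^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2))
  expect_equal(a$F, Fo, tolerance = 1e-10)
  expect_equal(a$epsilon, eps, tolerance = 1e-10)
  expect_equal(a$df1, eps * (k - 1), tolerance = 1e-10)
  expect_equal(a$df2, eps * (k - 1) * (n - 1), tolerance = 1e-10)
  expect_equal(a$p, pf(Fo, eps * (k - 1), eps * (k - 1) * (n - 1),
                       lower.tail = FALSE), tolerance = 1e-10)
})

test_that("repeated-measures ANOVA agrees with car's multivariate machinery", {
  skip_if_not_installed("car")
  fit <- lm(Y5 ~ 1)
  id <- data.frame(cond = factor(colnames(Y5)))
  av <- car::Anova(fit, idata = id, idesign = ~cond, type = 3)
  s <- summary(av, multivariate = FALSE)
  a <- rm_anova(toy_table(Y5), "value")
  expect_equal(unname(s$univariate.tests["cond", "F value"]), a$F,
               tolerance = 1e-8)
  expect_equal(unname(s$pval.adjustments["cond", "GG eps"]), a$epsilon,
               tolerance = 1e-8)
  expect_equal(unname(s$pval.adjustments["cond", "Pr(>F[GG])"]), a$p,
               tolerance = 1e-8)
})

test_that("two conditions are spherical by construction and location shifts change nothing", {
  a2 <- rm_anova(toy_table(Y5[, 1:2]), "value")
  expect_identical(a2$epsilon, 1)
  shifted <- toy_table(Y5 + 100)
  a <- rm_anova(toy_table(Y5), "value")
  b <- rm_anova(shifted, "value")
  expect_equal(a$F, b$F, tolerance = 1e-8)
  expect_equal(a$epsilon, b$epsilon, tolerance = 1e-8)
})

test_that("design violations raise design errors", {
  tab <- toy_table(Y5)
  expect_error(rm_anova(tab[-1, ], "value"), "incomplete pairing")
  expect_error(rm_anova(tab, "nope"), "design error")
  expect_error(rm_anova(toy_table(Y5[1:2, ]), "value"), "three subjects")
  same <- toy_table(matrix(1, 5, 3, dimnames = list(NULL, c("A", "B", "C"))))
  expect_error(rm_anova(same, "value"), "degenerate-data")
})

test_that("Tukey pairs match TukeyHSD on the subject-blocked model", {
  tp <- tukey_pairs(toy_table(Y5), "value")
  expect_equal(nrow(tp), 3)
  tab <- toy_table(Y5)
  fit <- aov(value ~ factor(subject_id) + factor(montage_name), data = tab)
  hsd <- TukeyHSD(fit, "factor(montage_name)")[[1]]
  for (i in seq_len(nrow(tp))) {
    key <- paste(tp$b[i], tp$a[i], sep = "-")
    expect_equal(unname(hsd[key, "diff"]), -tp$diff[i], tolerance = 1e-10)
    expect_equal(unname(hsd[key, "p adj"]), tp$p_adj[i], tolerance = 1e-10)
  }
  ## identical conditions: no difference, adjusted p near 1
  Yid <- cbind(A = Y5[, 1], B = Y5[, 1], C = Y5[, 2])
  tpi <- tukey_pairs(toy_table(Yid), "value")
  row <- tpi[tpi$a == "A" & tpi$b == "B", ]
  expect_equal(row$diff, 0)
  expect_gt(row$p_adj, 0.999)
  ## k(k-1)/2 comparisons
  Y6 <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, LETTERS[1:6]))
  expect_equal(nrow(tukey_pairs(toy_table(Y6), "value")), 15)
})

test_that("the studentized-range computation matches direct evaluation", {
  tp <- tukey_pairs(toy_table(Y5), "value")
  n <- 5; k <- 3
  gm <- mean(Y5)
  ssE <- sum((Y5 - gm)^2) - n * sum((colMeans(Y5) - gm)^2) -
    k * sum((rowMeans(Y5) - gm)^2)
  msE <- ssE / ((k - 1) * (n - 1))
  for (i in seq_len(nrow(tp))) {
    d <- mean(Y5[, tp$a[i]]) - mean(Y5[, tp$b[i]])
    q <- abs(d) / sqrt(msE / n)
    expect_equal(tp$p_adj[i], ptukey(q, k, (k - 1) * (n - 1), lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("consistency ICC is 1 under agreement, near 0 under independence", {
  x <- rnorm(30)
  expect_equal(icc_consistency(x, x), 1, tolerance = 1e-12)
  expect_equal(icc_consistency(x, x + 5), 1, tolerance = 1e-10)
  expect_equal(icc_consistency(x, 2 + x * 1), 1, tolerance = 1e-10)
  set.seed(99)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(icc_consistency(a, b)), 0.2)
  expect_error(icc_consistency(rep(1, 10), rnorm(10)), "degenerate-data")
  expect_error(icc_consistency(1:2, 1:2), "design error")
  ## hand-computed mean-square oracle on a small table
  set.seed(7)
  u <- rnorm(8); v <- u + rnorm(8, sd = 0.4)
  Y <- cbind(u, v)
  ms_rows <- 2 * sum((rowMeans(Y) - mean(Y))^2) / 7
  ss_cols <- 8 * sum((colMeans(Y) - mean(Y))^2)
  ms_err <- (sum((Y - mean(Y))^2) - 2 * sum((rowMeans(Y) - mean(Y))^2) * 1 -
               ss_cols) / 7
  expect_equal(icc_consistency(u, v), (ms_rows - ms_err) / (ms_rows + ms_err),
               tolerance = 1e-10)
})

test_that("the study-table ICC wrapper pairs ROI with the 99th-percentile metric", {
  set.seed(5)
  roi <- rnorm(12, 0.4, 0.05)
  tab <- data.frame(subject_id = sprintf("S%02d", 1:12),
                    montage_name = "APPS",
                    roi_mean = roi, p99_mean = roi + 0.01)
  r <- icc_roi_vs_p99(tab, "APPS")
  expect_s3_class(r, "icc_result")
  expect_equal(r$icc, 1, tolerance = 1e-8)
  tab$p99_mean <- roi * 1.2 + rnorm(12, sd = 0.005)
  expect_gt(icc_roi_vs_p99(tab, "APPS")$icc, 0.9)
  expect_error(icc_roi_vs_p99(tab, "HD"), "design error")
})
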