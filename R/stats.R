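## Within-subject statistics: one-way repeated-measures ANOVA with
## Greenhouse-Geisser (or Huynh-Feldt) sphericity correction, Tukey HSD
## post-hoc tests on the within-subject error term, and two-way mixed-effects
## consistency ICC.

## Long table -> complete n x k cell matrix (subjects x conditions).
cell_matrix <- function(table, metric, conditions = NULL) {
  if (!metric %in% names(table)) stop("design error: metric ", metric, " missing")
  if (is.null(conditions)) conditions <- unique(table$montage_name)
  tab <- table[table$montage_name %in% conditions, , drop = FALSE]
  subj <- sort(unique(tab$subject_id))
  Y <- matrix(NA_real_, length(subj), length(conditions),
              dimnames = list(subj, conditions))
  for (r in seq_len(nrow(tab))) {
    Y[as.character(tab$subject_id[r]), tab$montage_name[r]] <- tab[[metric]][r]
  }
  if (anyNA(Y)) stop("design error: incomplete pairing (missing subject x condition cells)")
  Y
}

#' Repeated-measures ANOVA with sphericity correction
#'
#' One-way within-subject ANOVA of one metric across montages, with the
#' Greenhouse-Geisser epsilon (default) or Huynh-Feldt epsilon applied to
#' both degrees of freedom, producing the fractional dfs conventional in the
#' repeated-measures literature.
#'
#' @param table Long-format study table (columns `subject_id`,
#'   `montage_name`, and the metric).
#' @param metric Column name to analyze.
#' @param conditions Optional montage subset (order respected).
#' @param correction `"greenhouse-geisser"` or `"huynh-feldt"`.
#' @return Object of class `anova_result`: list with `F`, `df1`, `df2`
#'   (epsilon-corrected), `epsilon`, `p`, `k`, `n`.
#' @export
rm_anova <- function(table, metric, conditions = NULL,
                     correction = c("greenhouse-geisser", "huynh-feldt")) {
  correction <- match.arg(correction)
  Y <- cell_matrix(table, metric, conditions)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop("design error: need at least two conditions")
  if (n < 3) stop("design error: need at least three subjects")
  gm <- mean(Y)
  cm <- colMeans(Y); rm_ <- rowMeans(Y)
  ss_cond <- n * sum((cm - gm)^2)
  ss_subj <- k * sum((rm_ - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  if (ss_err <= 0 && ss_cond <= 0) stop("degenerate-data error: no within-cell variance")
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fstat <- (ss_cond / df1) / (ss_err / df2)
  eps <- gg_epsilon(Y)
  if (correction == "huynh-feldt") {
    eps <- min(1, (n * (k - 1) * eps - 2) / ((k - 1) * (n - 1 - (k - 1) * eps)))
  }
  p <- pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = eps * df1, df2 = eps * df2, epsilon = eps,
                 p = p, k = k, n = n, metric = metric,
                 ss_cond = ss_cond, ss_err = ss_err,
                 correction = correction),
            class = "anova_result")
}

## Greenhouse-Geisser epsilon from the double-centered condition covariance.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  if (k == 2) return(1)   # two levels are spherical by construction
  S <- stats::cov(Y)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  rowm <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * sbar^2)
  if (den <= 0) return(1)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("rm-ANOVA (%s): F(%.1f, %.1f) = %.2f, p = %.3g (epsilon = %.3f)\n",
              x$metric, x$df1, x$df2, x$F, x$p, x$epsilon))
  invisible(x)
}

#' Tukey-corrected pairwise comparisons
#'
#' All pairwise condition differences with Tukey HSD adjustment using the
#' within-subject error term of the repeated-measures ANOVA.
#'
#' @inheritParams rm_anova
#' @return Data frame with columns `a`, `b`, `diff` (mean of a minus mean of
#'   b), `se`, `q`, `p_adj`.
#' @export
tukey_pairs <- function(table, metric, conditions = NULL) {
  Y <- cell_matrix(table, metric, conditions)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop("design error: need at least two conditions")
  if (n < 3) stop("design error: need at least three subjects")
  gm <- mean(Y)
  ss_tot <- sum((Y - gm)^2)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  df_err <- (k - 1) * (n - 1)
  ms_err <- (ss_tot - ss_cond - ss_subj) / df_err
  cm <- colMeans(Y)
  out <- list()
  idx <- 1
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    d <- cm[a] - cm[b]
    se <- sqrt(2 * ms_err / n)
    q <- abs(d) / sqrt(ms_err / n)
    p <- ptukey(q, k, df_err, lower.tail = FALSE)
    out[[idx]] <- data.frame(a = colnames(Y)[a], b = colnames(Y)[b],
                             diff = unname(d), se = se, q = unname(q),
                             p_adj = unname(p), stringsAsFactors = FALSE)
    idx <- idx + 1
  }
  do.call(rbind, out)
}

#' Intraclass correlation between two paired measurements
#'
#' Two-way mixed-effects, single-measure, consistency ICC — ICC(3,1) — of two
#' paired columns across subjects.
#'
#' @param x,y Numeric vectors (one value per subject).
#' @return ICC estimate (<= 1).
#' @export
icc_consistency <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("design error: need >= 3 paired observations")
  }
  Y <- cbind(x, y)
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate-data error: zero variance")
  n <- nrow(Y); k <- 2
  gm <- mean(Y)
  ms_rows <- k * sum((rowMeans(Y) - gm)^2) / (n - 1)
  ss_tot <- sum((Y - gm)^2)
  ss_cols <- n * sum((colMeans(Y) - gm)^2)
  ss_rows <- k * sum((rowMeans(Y) - gm)^2)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' ICC between ROI and 99th-percentile E-field for one montage
#'
#' Agreement (consistency ICC) between the on-target ROI mean and the
#' whole-brain 99th-percentile mean across subjects: high values indicate
#' that the strongest stimulation is at the intended target.
#'
#' @param table Long-format study table.
#' @param montage Montage name.
#' @return Object of class `icc_result`: list with `montage_name`, `icc`,
#'   `model`.
#' @export
icc_roi_vs_p99 <- function(table, montage) {
  tab <- table[table$montage_name == montage, , drop = FALSE]
  if (nrow(tab) < 3) stop("design error: need >= 3 subjects for ICC")
  icc <- icc_consistency(tab$roi_mean, tab$p99_mean)
  structure(list(montage_name = montage, icc = icc,
                 model = "two-way mixed, single measure, consistency (ICC(3,1))"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) %s: %.3f\n", x$montage_name, x$icc))
  invisible(x)
}
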