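## The within-subject study: solve every montage on every phantom with a
## fixed per-subject ROI, and summarize the round-wise orderings.

#' Run the within-subject montage comparison over a phantom population
#'
#' For each subject: build the phantom, place the 10-10 map and the motor ROI
#' once, then solve and score every requested montage with that identical
#' ROI. Subjects whose geometry or solve fails are dropped with a logged
#' reason; the study aborts if more than `max_abort_frac` of subjects fail.
#'
#' @param population List of [phantom_spec()]s (e.g. [sample_population()]).
#' @param montages Character vector of montage names
#'   (default: the distinct names of [montage_catalog()]).
#' @param config A [study_config()] list (current, conductivities, metric
#'   parameters, solver tolerance).
#' @param verbose Print per-subject progress.
#' @return A `study_table` data frame: one row per subject x montage with
#'   columns `subject_id`, `montage_name`, `round_tag`, `roi_mean`,
#'   `p99_mean`, `focality_mm3`, `peak_offset_mm`, `edge_distance_cm`,
#'   `solve_residual`.
#' @export
run_study <- function(population, montages = NULL, config = study_config(),
                      verbose = FALSE) {
  if (is.null(montages)) montages <- unique(montage_catalog()$name)
  unknown <- setdiff(montages, montage_catalog()$name)
  if (length(unknown)) stop("lookup error: unknown montages ", paste(unknown, collapse = ", "))
  rows <- list()
  aborted <- character()
  rounds <- montage_catalog()
  for (si in seq_along(population)) {
    sid <- sprintf("S%03d", si)
    res <- tryCatch({
      spec <- population[[si]]
      spec$voxel_size_mm <- config$voxel_size_mm
      ph <- build_phantom(spec)
      ph$cache <- new.env(parent = emptyenv())
      eeg <- locate_1010(ph)
      roi <- locate_roi(ph, eeg, label = config$roi_label,
                        radius_mm = config$roi_radius_mm)
      cgrid <- conduction_grid(ph, config$conductivities)
      sub_rows <- list()
      solved <- list()   # montages with identical geometry share one solve
      for (mn in montages) {
        m <- build_study_montage(mn, ph, eeg, config$current_mA)
        sig <- montage_signature(m)
        if (!is.null(solved[[sig]])) {
          ms <- solved[[sig]]$ms
          ed <- solved[[sig]]$ed
          res_solver <- solved[[sig]]$res
        } else {
          sys <- assemble_system(ph, cgrid, m)
          sol <- solve_potential(sys, tol = config$solver_tol)
          sol <- scale_to_current(sol, config$current_mA)
          ms <- compute_metrics(sol, m, roi, mask = config$p99_mask,
                                level_fraction = config$level_fraction,
                                peak_percentile = config$peak_percentile)
          ed <- tryCatch(edge_to_edge_distance(m, ph), error = function(e) NA_real_)
          res_solver <- sol$solve_residual
          solved[[sig]] <- list(ms = ms, ed = ed, res = res_solver)
        }
        sub_rows[[mn]] <- data.frame(
          subject_id = sid, montage_name = mn,
          round_tag = rounds$round[match(mn, rounds$name)],
          roi_mean = ms$roi_mean_Vpm, p99_mean = ms$p99_mean_Vpm,
          focality_mm3 = ms$focality_mm3, peak_offset_mm = ms$peak_offset_mm,
          edge_distance_cm = ed, solve_residual = res_solver,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, sub_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      aborted <- c(aborted, sprintf("%s: %s", sid, conditionMessage(res)))
      if (verbose) message("aborted ", sid, ": ", conditionMessage(res))
      next
    }
    rows[[sid]] <- res
    if (verbose) message("done ", sid)
  }
  if (length(population) > 0 &&
      length(aborted) > 0.05 * length(population)) {
    stop("study error: more than 5% of subjects aborted:\n",
         paste(aborted, collapse = "\n"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aborted") <- aborted
  class(out) <- c("study_table", "data.frame")
  out
}

## Geometry fingerprint of a montage (electrode centers, shapes, polarity):
## montages with the same fingerprint have identical field solutions.
montage_signature <- function(m) {
  paste(vapply(m$electrodes, function(e) {
    paste(e$polarity, paste(unlist(e$shape), collapse = ","),
          paste(round(e$center, 6), collapse = ","),
          paste(round(e$e1, 6), collapse = ","), sep = "|")
  }, character(1)), collapse = ";")
}

#' Check the complete paired design
#'
#' @param table A study table.
#' @return `TRUE` invisibly; errors when any subject lacks any montage.
#' @export
check_paired <- function(table) {
  tab <- table(table$subject_id, table$montage_name)
  if (any(tab != 1)) stop("design error: incomplete paired design")
  invisible(TRUE)
}

## Montage membership per modeling round. The anterior-posterior surround
## baseline belongs to Rounds 1 and 3; Round 4 compares the optimized montage
## against the Round 1 set.
round_members <- function() {
  ct <- montage_catalog()
  r1 <- ct$name[ct$round == 1]
  list(`1` = r1,
       `2` = ct$name[ct$round == 2],
       `3` = unique(ct$name[ct$round == 3]),
       `4` = c("OPT_APPS", r1))
}

#' Round-wise ordinal summary of a study table
#'
#' Pure function of the table: per modeling round, ranks montages by
#' population-mean ROI E-field (descending) and focality volume (ascending),
#' and reports paired-difference summaries (mean difference, normal-theory
#' 95% CI, sign consistency) of each montage against the round's ROI-best
#' montage.
#'
#' @param table A study table.
#' @return List with one entry per round: `roi_ranking`, `focality_ranking`,
#'   and `paired_vs_best` data frame.
#' @export
ordinal_report <- function(table) {
  check_paired(table)
  out <- list()
  members <- round_members()
  for (rd in names(members)) {
    mnames <- intersect(members[[rd]], unique(table$montage_name))
    if (length(mnames) < 2) next
    sub <- table[table$montage_name %in% mnames, , drop = FALSE]
    roi_means <- vapply(mnames, function(m) mean(sub$roi_mean[sub$montage_name == m]),
                        numeric(1))
    foc_means <- vapply(mnames, function(m) mean(sub$focality_mm3[sub$montage_name == m]),
                        numeric(1))
    best <- names(which.max(roi_means))
    Y <- cell_matrix(sub, "roi_mean", mnames)
    pv <- list()
    for (m in setdiff(mnames, best)) {
      d <- Y[, best] - Y[, m]
      ci <- mean(d) + c(-1, 1) * stats::qt(0.975, length(d) - 1) * sd(d) / sqrt(length(d))
      pv[[m]] <- data.frame(montage = m, mean_diff = mean(d),
                            ci_lo = ci[1], ci_hi = ci[2],
                            sign_consistency = mean(d > 0),
                            stringsAsFactors = FALSE)
    }
    out[[rd]] <- list(
      roi_ranking = names(sort(roi_means, decreasing = TRUE)),
      roi_means = sort(roi_means, decreasing = TRUE),
      focality_ranking = names(sort(foc_means)),
      focality_means = sort(foc_means),
      best_roi_montage = best,
      paired_vs_best = if (length(pv)) do.call(rbind, pv) else NULL)
  }
  out
}

#' Counts of the full study design
#'
#' @param n_subjects Number of subjects.
#' @return List with `montages_per_subject` (the 15 configurations of
#'   [montage_catalog()]) and `total_models`.
#' @export
study_design <- function(n_subjects = 200) {
  k <- nrow(montage_catalog())
  list(montages_per_subject = k, total_models = as.integer(n_subjects) * k)
}
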