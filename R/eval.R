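#' Euclidean distance between target and predicted coordinates
#'
#' @param t,p length-3 world coordinates (mm).
#' @return Distance in mm.
#' @export
landmark_distance <- function(t, p) {
  sqrt(sum((as.numeric(t) - as.numeric(p))^2))
}

#' Successful detection rate
#'
#' Percentage of distances at or below the clinical-usability threshold
#' (boundary inclusive); the standard summary for landmark localization.
#'
#' @param distances numeric vector of mm distances (non-empty).
#' @param threshold mm (default 2, the clinical-usability cut).
#' @return Percentage in `[0, 100]`.
#' @examples
#' sdr(c(1, 2, 3)) # 66.67
#' @export
sdr <- function(distances, threshold = 2.0) {
  if (length(distances) == 0L)
    stop("SDR is undefined for an empty distance vector", call. = FALSE)
  100 * mean(distances <= threshold)
}

#' Signed errors between two cephalometric reports
#'
#' Per-measure error `reference - predicted`; a measure is successful when
#' the absolute error is at most 2 (mm or degrees, per the measure's
#' units). Measures unavailable in either report are excluded and counted.
#'
#' @param reference,predicted [measure_all()] reports over the same
#'   measure ids.
#' @param threshold_mm,threshold_deg success thresholds (defaults 2 mm and
#'   2 degrees).
#' @return Data frame: `id`, `units`, `error`, `success`, `excluded`.
#' @export
measure_error <- function(reference, predicted, threshold_mm = 2,
                          threshold_deg = 2) {
  ref <- as.data.frame(reference)
  prd <- as.data.frame(predicted)
  if (!identical(ref$id, prd$id))
    stop("schema error: the two reports carry different measure ids",
         call. = FALSE)
  err <- ref$value - prd$value
  thr <- ifelse(ref$units == "mm", threshold_mm, threshold_deg)
  excl <- !(ref$available & prd$available)
  data.frame(id = ref$id, units = ref$units,
             error = ifelse(excl, NA_real_, err),
             success = ifelse(excl, NA, abs(err) <= thr),
             excluded = excl)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p-value is
#' exact (full enumeration of the permutation distribution) when
#' `max(n, m) <= 8` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @return `list(U =, p.value =, exact =)`; `U` counts pairs where `x`
#'   exceeds `y` (ties half-weighted).
#' @examples
#' mann_whitney_u(1:3, 4:6) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && max(n, m) <= 8L) {
    # exact: enumerate every assignment of n of the N ranks to sample x
    N <- n + m
    combs <- utils::combn(N, n)
    Us <- colSums(matrix(rank(pooled)[combs], nrow = n)) - n * (n + 1) / 2
    pl <- mean(Us <= U)
    pu <- mean(Us >= U)
    p <- min(1, 2 * min(pl, pu))
    return(list(U = U, p.value = p, exact = TRUE))
  }
  N <- n + m
  mu <- n * m / 2
  tab <- table(pooled)
  tiecor <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tiecor)
  if (sigma2 <= 0) return(list(U = U, p.value = 1, exact = FALSE))
  z <- U - mu
  cc <- sign(z) * 0.5 # continuity correction toward the mean
  z <- (z - cc) / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order:
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same length and order).
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) && (any(!is.finite(pvals)) || any(pvals < 0) ||
                        any(pvals > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Evaluate predicted landmark sets against references
#'
#' Produces the standard landmark-accuracy report: per-landmark distance
#' statistics (mean, SD, SDR) overall and per group, Mann-Whitney U tests
#' between every pair of groups for each landmark with Benjamini-Hochberg
#' correction across all landmark-level comparisons of the report, miss
#' counts (reference present, prediction absent — never auto-excluded),
#' and a review list of individual distances above `flag_threshold`
#' (flagged for manual inspection, not removed). If both per-case
#' cephalometric reports are supplied, measure errors are aggregated the
#' same way.
#'
#' @param predictions,references named lists of [landmark_set()]s sharing
#'   case ids.
#' @param groups optional named character vector mapping case id to group
#'   label (e.g. cohort or device).
#' @param sdr_threshold SDR threshold in mm (default 2).
#' @param flag_threshold review-list threshold in mm (default 10).
#' @param measure_reports optional `list(reference =, predicted =)` of
#'   named per-case [measure_all()] report lists.
#' @return A `ceph_evaluation` list: `distances` (long table),
#'   `per_landmark`, `per_group`, `comparisons` (with `p_adj`), `misses`,
#'   `review`, `measures` (or NULL), `config`.
#' @export
evaluate_predictions <- function(predictions, references, groups = NULL,
                                 sdr_threshold = 2, flag_threshold = 10,
                                 measure_reports = NULL) {
  ids_p <- names(predictions); ids_r <- names(references)
  if (is.null(ids_p) || is.null(ids_r) ||
      !setequal(ids_p, ids_r) || length(ids_p) != length(ids_r))
    stop("alignment error: prediction and reference case ids differ",
         call. = FALSE)
  rows <- list()
  miss_rows <- list()
  for (cid in ids_r) {
    ref <- references[[cid]]; prd <- predictions[[cid]]
    g <- if (is.null(groups)) "all" else unname(groups[[cid]])
    for (id in present_ids(ref)) {
      q <- lm_coord(prd, id)
      if (is.null(q)) {
        miss_rows[[length(miss_rows) + 1L]] <-
          data.frame(case_id = cid, landmark = id, group = g)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(case_id = cid, landmark = id, group = g,
                     distance = landmark_distance(lm_coord(ref, id), q))
      }
    }
  }
  dists <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), landmark = character(),
               group = character(), distance = numeric())
  misses <- if (length(miss_rows)) do.call(rbind, miss_rows) else
    data.frame(case_id = character(), landmark = character(),
               group = character())

  summarize <- function(d) {
    data.frame(n = length(d), mean_mm = mean(d),
               sd_mm = if (length(d) > 1) stats::sd(d) else NA_real_,
               sdr_pct = if (length(d)) sdr(d, sdr_threshold) else NA_real_)
  }
  per_landmark <- do.call(rbind, lapply(split(dists$distance,
                                              dists$landmark), summarize))
  per_landmark <- cbind(landmark = rownames(per_landmark), per_landmark)
  rownames(per_landmark) <- NULL

  glev <- sort(unique(dists$group))
  per_group <- do.call(rbind, lapply(glev, function(g)
    cbind(group = g, summarize(dists$distance[dists$group == g]))))

  comparisons <- NULL
  if (length(glev) >= 2L) {
    cmp <- list()
    for (pair in utils::combn(glev, 2, simplify = FALSE)) {
      for (lm in unique(dists$landmark)) {
        a <- dists$distance[dists$group == pair[1] & dists$landmark == lm]
        b <- dists$distance[dists$group == pair[2] & dists$landmark == lm]
        if (length(a) && length(b)) {
          mw <- mann_whitney_u(a, b)
          cmp[[length(cmp) + 1L]] <-
            data.frame(landmark = lm, group1 = pair[1], group2 = pair[2],
                       U = mw$U, p = mw$p.value)
        }
      }
    }
    if (length(cmp)) {
      comparisons <- do.call(rbind, cmp)
      # one BH family per report: all landmark-level comparisons
      comparisons$p_adj <- benjamini_hochberg(comparisons$p)
    }
  }

  review <- dists[dists$distance > flag_threshold, , drop = FALSE]

  measures <- NULL
  if (!is.null(measure_reports)) {
    errs <- lapply(ids_r, function(cid)
      cbind(case_id = cid,
            measure_error(measure_reports$reference[[cid]],
                          measure_reports$predicted[[cid]])))
    long <- do.call(rbind, errs)
    keep <- !long$excluded
    measures <- do.call(rbind, lapply(split(long[keep, ], long$id[keep]),
      function(d) data.frame(id = d$id[1], units = d$units[1],
                             n = nrow(d), mean_error = mean(d$error),
                             sd_error = if (nrow(d) > 1) stats::sd(d$error)
                             else NA_real_,
                             sdr_pct = 100 * mean(d$success),
                             excluded = sum(long$id == d$id[1]) - nrow(d))))
    rownames(measures) <- NULL
  }

  structure(list(distances = dists, per_landmark = per_landmark,
                 per_group = per_group, comparisons = comparisons,
                 misses = misses, review = review, measures = measures,
                 config = list(sdr_threshold = sdr_threshold,
                               flag_threshold = flag_threshold)),
            class = "ceph_evaluation")
}

#' @export
print.ceph_evaluation <- function(x, ...) {
  cat(sprintf("<ceph_evaluation> %d distances, %d landmarks, %d group(s)\n",
              nrow(x$distances), nrow(x$per_landmark), nrow(x$per_group)))
  print(x$per_group, row.names = FALSE)
  if (nrow(x$misses)) cat(sprintf("  %d miss(es)\n", nrow(x$misses)))
  if (nrow(x$review))
    cat(sprintf("  %d distance(s) above %.0f mm flagged for review\n",
                nrow(x$review), x$config$flag_threshold))
  invisible(x)
}

#' Write an evaluation report as CSV tables
#'
#' Emits `per_landmark.csv`, `per_group.csv`, and, where present,
#' `comparisons.csv`, `misses.csv`, `review.csv`, `measures.csv` into a
#' directory.
#'
#' @param ev a [evaluate_predictions()] result.
#' @param dir output directory (created if needed).
#' @export
write_evaluation <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, nm) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  emit(ev$per_landmark, "per_landmark")
  emit(ev$per_group, "per_group")
  emit(ev$comparisons, "comparisons")
  emit(ev$misses, "misses")
  emit(ev$review, "review")
  emit(ev$measures, "measures")
  invisible(dir)
}
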