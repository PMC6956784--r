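#' Regression evaluation against the identity line
#'
#' Reported metrics: Pearson correlation (rP), Spearman rank correlation
#' (rS, average ranks on ties), coefficient of determination computed
#' against the identity line (R2 = 1 - SS_res / SS_tot with residuals
#' observed - predicted, not against a refitted regression line; it may be
#' negative), and RMSE (root mean squared error, p-affinity units).
#' Argument order is pinned: predictions first, observations second.
#'
#' @name evaluation
NULL

#' Evaluate predictions against observations
#'
#' @param predicted predicted p-affinities.
#' @param observed measured p-affinities (same length, >= 2).
#' @return a `dockrf_report`: list with `rP`, `rS`, `R2`, `RMSE`, `n` and a
#'   `degenerate` flag (TRUE when observed has zero variance, in which case
#'   rP/rS are NA with a warning rather than silently dropped).
#' @export
evaluate <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_dockrf("predicted and observed lengths differ (%d vs %d)",
                length(predicted), length(observed),
                class = "dockrf_validation_error")
  if (length(observed) < 2L)
    stop_dockrf("need at least 2 pairs", class = "dockrf_validation_error")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop_dockrf("non-finite values in predictions or observations",
                class = "dockrf_validation_error")
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((observed - mean(observed))^2)
  degenerate <- ss_tot == 0 || var(predicted) == 0
  if (ss_tot == 0) {
    warning("observed values have zero variance; rP/rS/R2 undefined")
    rp <- rs <- r2 <- NA_real_
  } else {
    r2 <- 1 - sum(res^2) / ss_tot
    if (var(predicted) == 0) {
      warning("predictions are constant; rP/rS undefined")
      rp <- rs <- NA_real_
    } else {
      rp <- cor(predicted, observed)
      rs <- cor(predicted, observed, method = "spearman")
    }
  }
  structure(list(rP = rp, rS = rs, R2 = r2, RMSE = rmse,
                 n = length(observed), degenerate = degenerate),
            class = "dockrf_report")
}

#' @export
print.dockrf_report <- function(x, ...) {
  cat(sprintf("<evaluation> n = %d  rP = %.3f  rS = %.3f  R2 = %.3f  RMSE = %.3f%s\n",
              x$n, x$rP, x$rS, x$R2, x$RMSE,
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Cross-dataset evaluation matrix
#'
#' Evaluates every trained model on every test set: rows = model labels,
#' columns = test-set labels, cells = Pearson correlation. Cells that fail
#' (e.g. feature-schema mismatch) are NA and listed in the `failures`
#' attribute with their reason; the matrix is always complete.
#'
#' @param models named list of `dockrf_rf` models.
#' @param testsets named list of `dockrf_dataset` tables.
#' @return numeric matrix of rP values with attributes `reports` (full
#'   `dockrf_report` per cell) and `failures`.
#' @export
cross_evaluate <- function(models, testsets) {
  stopifnot(length(models) > 0, length(testsets) > 0,
            !is.null(names(models)), !is.null(names(testsets)))
  m <- matrix(NA_real_, length(models), length(testsets),
              dimnames = list(names(models), names(testsets)))
  reports <- list()
  failures <- list()
  for (mi in names(models)) {
    for (ti in names(testsets)) {
      cell <- paste(mi, ti, sep = " -> ")
      out <- tryCatch({
        pred <- predict(models[[mi]], testsets[[ti]])
        evaluate(pred, testsets[[ti]]$p_affinity)
      }, error = function(e) e)
      if (inherits(out, "error")) {
        failures[[cell]] <- conditionMessage(out)
      } else {
        m[mi, ti] <- out$rP
        reports[[cell]] <- out
      }
    }
  }
  attr(m, "reports") <- reports
  attr(m, "failures") <- failures
  m
}

#' Correlation between per-ligand median raw scores and affinity
#'
#' For one named metric, takes the per-ligand median of the raw per-pose
#' values and correlates it against the measured p-affinity. Scores are
#' used in their native orientation -- lower-is-better scores naturally
#' yield negative correlations; no sign is flipped.
#'
#' @param pose_table a `dockrf_pose_table`.
#' @param affinities affinity table with `ligand_id`, `p_affinity`.
#' @param metric one of the 19 metric names ([metric_schema()]).
#' @return list with `rP`, `rS`, `n`.
#' @export
median_score_correlation <- function(pose_table, affinities, metric) {
  if (!metric %in% METRIC_NAMES)
    stop_dockrf("unknown metric '%s'", metric, class = "dockrf_schema_error")
  med <- vapply(split(pose_table[[metric]], pose_table$ligand_id), median,
                numeric(1))
  i <- match(names(med), affinities$ligand_id)
  keep <- !is.na(i)
  if (sum(keep) < 2L)
    stop_dockrf("need >= 2 ligands with both poses and labels",
                class = "dockrf_validation_error")
  obs <- affinities$p_affinity[i[keep]]
  list(rP = cor(med[keep], obs),
       rS = cor(med[keep], obs, method = "spearman"),
       n = sum(keep))
}
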