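check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary (0/1)")
  labels
}

# Mann-Whitney AUC with half credit for ties (matches the DeLong kernel)
auc_rank <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m == 0L || n == 0L) abort("AUC undefined for single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Confusion counts at a classification threshold
#'
#' @param labels Binary labels (0/1 or logical); 1 = interacting pair.
#' @param scores Predicted probabilities.
#' @param threshold Classification threshold (default 0.5; scores `>=`
#'   threshold are called positive).
#' @return A one-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
eei_confusion <- function(labels, scores, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores >= threshold)
  tibble(
    TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
}

roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  m <- sum(lab == 1L)
  n <- sum(lab == 0L)
  # group tied scores so ties contribute diagonal (trapezoid = 1/2 credit)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab == 1L)[keep]
  fp <- cumsum(lab == 0L)[keep]
  tibble(
    threshold = c(Inf, sc[keep]),
    fpr = c(0, fp / n), tpr = c(0, tp / m),
    precision = c(1, ifelse(tp + fp == 0, 1, tp / (tp + fp))),
    recall = c(0, tp / m)
  )
}

#' Full metrics report for a scored pair set
#'
#' Computes Accuracy, Precision, Recall, F1 (at `threshold`), AUC and AUPR
#' together with the ROC and precision-recall curves. Accuracy is
#' `(TP+TN)/(TP+TN+FP+FN)`; Precision `TP/(TP+FP)`; Recall `TP/(TP+FN)`;
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`. AUC is the
#' trapezoidal integral of the ROC curve (`TPR` vs `FPR`), with tied scores
#' contributing half credit, and equals the normalized Mann-Whitney
#' statistic. AUPR is the step-wise integral of precision over recall.
#'
#' @inheritParams eei_confusion
#' @return An `eei_metrics` object: list with `metrics` (one-row tibble),
#'   `roc` and `pr` curve tibbles, and `counts`.
#' @export
eei_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  if (length(unique(labels)) < 2L) {
    abort("AUC/AUPR undefined for single-class labels")
  }
  cc <- eei_confusion(labels, scores, threshold)
  curve <- roc_points(labels, scores)
  auc_trap <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  aupr <- sum(diff(curve$recall) * curve$precision[-1])
  precision <- if (cc$TP + cc$FP == 0) NA_real_ else cc$TP / (cc$TP + cc$FP)
  recall <- cc$TP / (cc$TP + cc$FN)
  f1 <- if (is.na(precision) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(
      metrics = tibble(
        ACC = (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN),
        Precision = precision,
        Recall = recall, F1 = f1, AUC = auc_trap, AUPR = aupr,
        n = length(labels)
      ),
      roc = curve[, c("threshold", "fpr", "tpr")],
      pr = curve[, c("threshold", "recall", "precision")],
      counts = cc
    ),
    class = "eei_metrics"
  )
}

#' @export
print.eei_metrics <- function(x, ...) {
  cat("<eei_metrics> n =", x$metrics$n, "\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.eei_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"n",
    names_to = "metric", values_to = "value"
  )
}

#' @export
glance.eei_metrics <- function(x, ...) x$metrics

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline labs
#'   coord_equal theme_bw facet_wrap geom_col geom_point geom_tile
#' @export
ggplot2::autoplot

#' @export
autoplot.eei_metrics <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
      geom_line() +
      geom_abline(linetype = "dashed", colour = "grey") +
      coord_equal() +
      labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC (AUC = %.3f)", object$metrics$AUC)
      ) +
      theme_bw()
  } else {
    ggplot(object$pr, aes(x = .data$recall, y = .data$precision)) +
      geom_line() +
      labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall (AUPR = %.3f)", object$metrics$AUPR)
      ) +
      theme_bw()
  }
}

# DeLong structural components: per-positive and per-negative mean kernel
# values with the 1/2 tie kernel
delong_components <- function(pos, neg) {
  v10 <- vapply(pos, function(x) {
    mean((x > neg) + 0.5 * (x == neg))
  }, numeric(1))
  v01 <- vapply(neg, function(y) {
    mean((pos > y) + 0.5 * (pos == y))
  }, numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same labelled test
#' set. Implements the U-statistic estimator: per-positive components `V10`
#' (each positive against all negatives, tie kernel 1/2) and per-negative
#' components `V01` for each model, their 2x2 covariance matrices `S10` and
#' `S01`, `var(dAUC) = w' (S10/m + S01/n) w` with `w = (1, -1)`, a normal
#' z statistic and a two-sided p-value.
#'
#' @param labels Binary labels shared by both models.
#' @param scores_a,scores_b Score vectors of the two models.
#' @return A `delong_result` one-row tibble with `auc_a`, `auc_b`,
#'   `delta_auc`, `var_delta`, `z`, `p_value`.
#' @export
delong_paired <- function(labels, scores_a, scores_b) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  if (length(unique(labels)) < 2L) abort("single-class labels")
  pos <- labels == 1L
  m <- sum(pos)
  n <- sum(!pos)
  ca <- delong_components(scores_a[pos], scores_a[!pos])
  cb <- delong_components(scores_b[pos], scores_b[!pos])
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  w <- c(1, -1)
  var_delta <- drop(t(w) %*% (s10 / m + s01 / n) %*% w)
  delta <- ca$auc - cb$auc
  if (var_delta <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      z <- 0
      p <- 1
    } else {
      warn("degenerate DeLong variance with unequal AUCs; p reported as < 1e-300")
      z <- sign(delta) * Inf
      p <- 1e-300
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    tibble(
      auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta,
      var_delta = var_delta, z = z, p_value = p
    ),
    class = c("delong_result", class(tibble()))
  )
}

#' @export
glance.delong_result <- function(x, ...) as_tibble(x)

#' Metrics stratified by a grouping column
#'
#' Computes one metrics report per level of `group_key` on a scored manifest
#' (a manifest with a `score` column, e.g. from [predict_manifest()]), plus
#' an overall report. Groups smaller than `min_size` or containing a single
#' class are flagged and their metrics omitted.
#'
#' @param scored A manifest tibble with `label`, `score` and the grouping
#'   column.
#' @param group_key Column name to stratify on (e.g. `"se_category"`).
#' @param min_size Minimum group size to report metrics (default 20).
#' @return A tibble with one row per group (plus `"overall"`): `group`, `n`,
#'   `flagged`, and metric columns (NA when flagged).
#' @export
evaluate_by_category <- function(scored, group_key = "se_category",
                                 min_size = 20L) {
  if (!group_key %in% names(scored)) {
    abort(paste0("unknown group_key: ", group_key))
  }
  lab <- as.integer(scored$label == "positive")
  one <- function(idx, name) {
    flagged <- length(idx) < min_size ||
      length(unique(lab[idx])) < 2L
    if (flagged) {
      tibble(
        group = name, n = length(idx), flagged = TRUE,
        ACC = NA_real_, Precision = NA_real_, Recall = NA_real_,
        F1 = NA_real_, AUC = NA_real_, AUPR = NA_real_
      )
    } else {
      m <- eei_metrics(lab[idx], scored$score[idx])$metrics
      bind_cols(tibble(group = name, n = length(idx), flagged = FALSE),
        m[, c("ACC", "Precision", "Recall", "F1", "AUC", "AUPR")]
      )
    }
  }
  groups <- sort(unique(scored[[group_key]]))
  bind_rows(
    purrr::map(groups, function(gv) one(which(scored[[group_key]] == gv), gv)),
    one(seq_len(nrow(scored)), "overall")
  )
}
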