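#' Confusion counts for one evaluation objective
#'
#' Two objectives are scored. `noise_removal`: positives are non-noise
#' ICs (RSN or SOZ by both raters is a true positive, noise by both a
#' true negative). `soz_identification`: positives are SOZ ICs — a true
#' positive requires both raters to say SOZ, consistent with the
#' objective's false-negative definition (the alternative literal
#' reading, in which a true positive is any agreement on SOZ-or-RSN,
#' double-counts ICs and is available via `literal_soz_tp = TRUE` for
#' comparison; its counts do not sum to n).
#'
#' @param pred,truth Character vectors of `"noise"`/`"rsn"`/`"soz"`,
#'   aligned by IC, equal length.
#' @param objective `"noise_removal"` or `"soz_identification"`.
#' @param literal_soz_tp Use the literal (self-contradictory) TP reading
#'   for the SOZ objective.
#' @return List of class `"confusion_counts"`: `tp`, `tn`, `fp`, `fn`,
#'   `objective`, `n`.
#' @export
confusion <- function(pred, truth,
                      objective = c("noise_removal", "soz_identification"),
                      literal_soz_tp = FALSE) {
  objective <- match.arg(objective)
  if (length(pred) != length(truth)) {
    stop("pred and truth differ in length (", length(pred), " vs ",
         length(truth), ")")
  }
  lv <- c("noise", "rsn", "soz")
  stopifnot(all(pred %in% lv), all(truth %in% lv))
  if (objective == "noise_removal") {
    p_pos <- pred != "noise"; t_pos <- truth != "noise"
    tp <- sum(p_pos & t_pos)
  } else {
    p_pos <- pred == "soz"; t_pos <- truth == "soz"
    tp <- if (literal_soz_tp) {
      sum(pred != "noise" & truth != "noise")
    } else {
      sum(p_pos & t_pos)
    }
  }
  structure(list(
    tp = tp,
    tn = sum(!p_pos & !t_pos),
    fp = sum(p_pos & !t_pos),
    fn = sum(!p_pos & t_pos),
    objective = objective,
    n = length(pred)
  ), class = "confusion_counts")
}

#' Derived classification metrics
#'
#' Accuracy, precision, sensitivity and specificity from confusion
#' counts. A zero denominator yields `NA` (an explicit undefined marker),
#' never NaN propagation.
#'
#' @param cc A `"confusion_counts"` object (or list with tp/tn/fp/fn).
#' @return One-row data frame of class `"metric_set"`.
#' @export
metric_set <- function(cc) {
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  stopifnot(total > 0)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- data.frame(
    accuracy = (cc$tp + cc$tn) / total,
    precision = safe_div(cc$tp, cc$tp + cc$fp),
    sensitivity = safe_div(cc$tp, cc$tp + cc$fn),
    specificity = safe_div(cc$tn, cc$tn + cc$fp)
  )
  class(out) <- c("metric_set", class(out))
  out
}

#' Aggregate per-subject metrics
#'
#' Unweighted mean and sample standard deviation of each metric across
#' subjects; undefined (`NA`) entries are excluded, with the number of
#' subjects actually used reported per metric.
#'
#' @param per_subject Data frame with one row per subject (rows from
#'   [metric_set()] bound together).
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`
#'   (`NA` when fewer than two defined values), `n_used`.
#' @export
aggregate_metrics <- function(per_subject) {
  stopifnot(nrow(per_subject) >= 1)
  metrics <- c("accuracy", "precision", "sensitivity", "specificity")
  do.call(rbind, lapply(metrics, function(m) {
    v <- per_subject[[m]]
    v <- v[!is.na(v)]
    data.frame(
      metric = m,
      mean = if (length(v) > 0) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n_used = length(v)
    )
  }))
}

#' Evaluate predicted labels against ground truth
#'
#' Convenience wrapper running both objectives on one subject.
#'
#' @param pred,truth Label data frames (with `ic_index` and `category`)
#'   or plain character vectors.
#' @return List with elements `noise_removal` and `soz_identification`,
#'   each holding `counts` and `metrics`.
#' @export
evaluate_labels <- function(pred, truth) {
  cat_of <- function(x) {
    if (is.data.frame(x)) x$category[order(x$ic_index)] else x
  }
  p <- cat_of(pred); t <- cat_of(truth)
  out <- lapply(c("noise_removal", "soz_identification"), function(obj) {
    cc <- confusion(p, t, obj)
    list(counts = cc, metrics = metric_set(cc))
  })
  names(out) <- c("noise_removal", "soz_identification")
  out
}
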