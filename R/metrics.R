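# Evaluation suite: confusion matrix, per-class precision/recall/F1,
# macro and support-weighted aggregates, and one-vs-rest AUC. The 0/0
# convention for undefined per-class metrics is 0 (with a warning), so that
# classes never predicted do not crash aggregation.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes; row sums are the class
#' supports.
#'
#' @param y_true,y_pred integer labels in `0..C-1`.
#' @param C number of classes.
#' @param class_names optional names for the dimensions.
#' @return C x C integer matrix of class `hfsof_confusion`.
#' @export
confusion <- function(y_true, y_pred, C, class_names = NULL) {
  if (any(y_true < 0L | y_true >= C) || any(y_pred < 0L | y_pred >= C)) {
    stop("labels out of range 0..C-1")
  }
  cm <- table(factor(y_true, levels = 0:(C - 1L)),
              factor(y_pred, levels = 0:(C - 1L)))
  cm <- matrix(as.integer(cm), C, C)
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  class(cm) <- c("hfsof_confusion", class(cm))
  cm
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' `P_c = TP/(TP+FP)`, `R_c = TP/(TP+FN)`, `F1_c = 2PR/(P+R)`; any 0/0 is
#' defined as 0.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param warn warn when a 0/0 convention fires (default FALSE).
#' @return data.frame with `precision`, `recall`, `f1`, `support`.
#' @export
per_class_metrics <- function(cm, warn = FALSE) {
  cm <- unclass(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  if (warn && any(predicted == 0 | support == 0)) {
    warning("some classes have zero support or are never predicted; ",
            "their undefined metrics are reported as 0")
  }
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(precision = precision, recall = recall, f1 = f1,
             support = as.integer(support))
}

#' Macro and support-weighted aggregation of per-class values
#'
#' Macro is the unweighted mean; weighted is `sum(n_c v_c) / N`. For recall
#' the weighted aggregate equals overall accuracy exactly.
#'
#' @param values per-class metric values.
#' @param supports per-class sample counts.
#' @return list with `macro` and `weighted`.
#' @export
aggregate_metrics <- function(values, supports) {
  if (length(values) != length(supports)) stop("length mismatch")
  list(macro = mean(values),
       weighted = sum(supports * values) / sum(supports))
}

macro_f1 <- function(y_true, y_pred, C) {
  mean(per_class_metrics(confusion(y_true, y_pred, C))$f1)
}

auc_binary <- function(pos_scores, neg_scores) {
  # tie-aware Mann-Whitney form: ties count 1/2
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest AUC
#'
#' Per-class AUC of the class-c decision scores against the binary
#' "is class c" labels (tie-aware Mann-Whitney), plus macro and
#' support-weighted aggregates. Classes absent from `y_true` have undefined
#' AUC and are excluded from the aggregates with a warning.
#'
#' @param y_true integer labels `0..C-1`.
#' @param scores N x C decision-score matrix.
#' @return list with `per_class` (NA for absent classes), `macro`, `weighted`.
#' @export
ovr_auc <- function(y_true, scores) {
  scores <- as.matrix(scores)
  C <- ncol(scores)
  auc <- rep(NA_real_, C)
  support <- integer(C)
  for (c in 0:(C - 1L)) {
    pos <- y_true == c
    support[c + 1L] <- sum(pos)
    if (any(pos) && any(!pos)) {
      auc[c + 1L] <- auc_binary(scores[pos, c + 1L], scores[!pos, c + 1L])
    }
  }
  ok <- !is.na(auc)
  if (!all(ok)) {
    warning("classes absent from y_true excluded from AUC aggregates: ",
            paste(which(!ok) - 1L, collapse = ", "))
  }
  list(per_class = auc,
       macro = mean(auc[ok]),
       weighted = sum(support[ok] * auc[ok]) / sum(support[ok]))
}

#' Full metrics report
#'
#' Confusion matrix, accuracy, per-class precision/recall/F1/AUC, and macro
#' and weighted aggregates, in one JSON-serializable structure.
#'
#' @param y_true,y_pred integer labels `0..C-1`.
#' @param scores optional N x C decision-score matrix (enables AUC).
#' @param class_names optional class names.
#' @return object of class `hfsof_metrics`.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, class_names = NULL) {
  C <- if (!is.null(scores)) ncol(scores) else max(c(y_true, y_pred)) + 1L
  if (is.null(class_names)) class_names <- sprintf("class_%d", 0:(C - 1L))
  cm <- confusion(y_true, y_pred, C, class_names)
  pc <- per_class_metrics(cm)
  pc$class <- class_names
  acc <- sum(diag(unclass(cm))) / length(y_true)
  agg <- function(v) aggregate_metrics(v, pc$support)
  macro <- list(precision = agg(pc$precision)$macro,
                recall = agg(pc$recall)$macro, f1 = agg(pc$f1)$macro)
  weighted <- list(precision = agg(pc$precision)$weighted,
                   recall = agg(pc$recall)$weighted, f1 = agg(pc$f1)$weighted)
  if (!is.null(scores)) {
    auc <- ovr_auc(y_true, scores)
    pc$auc <- auc$per_class
    macro$auc <- auc$macro
    weighted$auc <- auc$weighted
  }
  structure(list(accuracy = acc, confusion = cm,
                 per_class = pc[, c("class", intersect(
                   c("precision", "recall", "f1", "support", "auc"),
                   names(pc)))],
                 macro = macro, weighted = weighted),
            class = "hfsof_metrics")
}

#' @export
print.hfsof_metrics <- function(x, ...) {
  cat(sprintf("<hfsof_metrics> accuracy %.4f\n", x$accuracy))
  print(x$per_class, digits = 4)
  cat(sprintf("macro:    P %.4f  R %.4f  F1 %.4f%s\n",
              x$macro$precision, x$macro$recall, x$macro$f1,
              if (!is.null(x$macro$auc)) sprintf("  AUC %.4f", x$macro$auc) else ""))
  cat(sprintf("weighted: P %.4f  R %.4f  F1 %.4f%s\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1,
              if (!is.null(x$weighted$auc)) sprintf("  AUC %.4f", x$weighted$auc) else ""))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report an `hfsof_metrics`.
#' @param path optional output path; if NULL the JSON string is returned.
#' @param digits rounding for the JSON (default 4).
#' @export
write_metrics_json <- function(report, path = NULL, digits = 4L) {
  payload <- list(
    accuracy = round(report$accuracy, digits),
    per_class = lapply(seq_len(nrow(report$per_class)), function(i) {
      r <- report$per_class[i, ]
      out <- list(class = r$class, precision = round(r$precision, digits),
                  recall = round(r$recall, digits), f1 = round(r$f1, digits),
                  support = r$support)
      if (!is.null(r$auc)) out$auc <- round(r$auc, digits)
      out
    }),
    macro = lapply(report$macro, round, digits),
    weighted = lapply(report$weighted, round, digits))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
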