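#' Classification metrics from a 3x3 confusion matrix
#'
#' One-vs-rest reduction per class: precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2TP/(2TP+FP+FN), each with the 0/0 -> 0
#' convention; overall accuracy is trace/total (equivalent to one-vs-rest
#' micro pooling of the binary accuracy formula). Macro averages are
#' unweighted class means. All values are percentages.
#'
#' @param cm 3x3 confusion matrix, rows = true NP/LP/HP.
#' @return list with `accuracy`, `per_class` (data.frame with TP/TN/FP/FN
#'   and per-class metrics) and `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
fold_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == c(3, 3)))
  if (any(cm < 0) || any(cm != round(cm))) {
    stop("confusion matrix must contain non-negative integers")
  }
  total <- sum(cm)
  if (total == 0) stop("all-zero confusion matrix")
  ratio0 <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  precision <- 100 * ratio0(tp, tp + fp)
  recall <- 100 * ratio0(tp, tp + fn)
  f1 <- 100 * ratio0(2 * tp, 2 * tp + fp + fn)
  list(
    accuracy = 100 * sum(tp) / total,
    per_class = data.frame(class = PAIN_CLASSES, tp = tp, tn = tn, fp = fp,
                           fn = fn, precision = precision, recall = recall,
                           f1 = f1, row.names = NULL),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1)
  )
}

# fold-level metric rows for every result row of a sweep
.sweep_fold_metrics <- function(sweep) {
  res <- sweep$results
  mets <- lapply(res$confusion, fold_metrics)
  data.frame(
    modality = res$modality, classifier = res$classifier, k = res$k,
    subject = res$subject,
    accuracy = vapply(mets, `[[`, numeric(1), "accuracy"),
    macro_precision = vapply(mets, `[[`, numeric(1), "macro_precision"),
    macro_recall = vapply(mets, `[[`, numeric(1), "macro_recall"),
    macro_f1 = vapply(mets, `[[`, numeric(1), "macro_f1"),
    np_recall = vapply(mets, function(m) m$per_class$recall[1], numeric(1)),
    lp_recall = vapply(mets, function(m) m$per_class$recall[2], numeric(1)),
    hp_recall = vapply(mets, function(m) m$per_class$recall[3], numeric(1)))
}

#' Per-cell metric summary of a sweep
#'
#' Fold-wise metrics averaged across LOSO folds (mean and sample SD), one
#' row per (modality, classifier, feature count).
#'
#' @param sweep a [run_sweep()] result.
#' @return data.frame of summaries, in percent.
#' @export
summarise_sweep <- function(sweep) {
  fm <- .sweep_fold_metrics(sweep)
  n_subj <- length(sweep$subjects)
  cells <- unique(fm[, c("modality", "classifier", "k")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    rows <- fm[fm$modality == cell$modality & fm$classifier == cell$classifier &
                 fm$k == cell$k, ]
    if (nrow(rows) != n_subj) {
      stop(sprintf("incomplete cell (%s, %s, k=%d): %d of %d folds",
                   cell$modality, cell$classifier, cell$k, nrow(rows), n_subj))
    }
    data.frame(cell,
               accuracy_mean = mean(rows$accuracy), accuracy_sd = sd(rows$accuracy),
               precision_mean = mean(rows$macro_precision), precision_sd = sd(rows$macro_precision),
               recall_mean = mean(rows$macro_recall), recall_sd = sd(rows$macro_recall),
               f1_mean = mean(rows$macro_f1), f1_sd = sd(rows$macro_f1),
               hp_recall_mean = mean(rows$hp_recall), hp_recall_sd = sd(rows$hp_recall))
  })
  do.call(rbind, out)
}

#' Aggregate sweep metrics across the three modalities
#'
#' Per feature count: within each modality the best classifier by mean
#' accuracy is chosen (ties broken by the sweep's classifier order), giving
#' one accuracy / macro-F1 / HP-recall value per modality; the table reports
#' mean and sample SD of those values across modalities.
#'
#' @param sweep a [run_sweep()] result.
#' @return data.frame with one row per grid feature count: `k`, `accuracy`,
#'   `accuracy_sd`, `macro_f1`, `macro_f1_sd`, `hp_recall`, `hp_recall_sd`;
#'   the per-modality classifier choices are attached as attribute
#'   `"choice"`.
#' @export
aggregate_modalities <- function(sweep) {
  summ <- summarise_sweep(sweep)
  modalities <- unique(summ$modality)
  choice <- list()
  rows <- lapply(sweep$grid, function(k) {
    vals <- lapply(modalities, function(m) {
      cand <- summ[summ$modality == m & summ$k == k, ]
      cand <- cand[order(match(cand$classifier, sweep$classifiers)), ]
      best <- cand[which.max(cand$accuracy_mean), ]
      choice[[paste(m, k)]] <<- best$classifier
      best
    })
    acc <- vapply(vals, `[[`, numeric(1), "accuracy_mean")
    f1 <- vapply(vals, `[[`, numeric(1), "f1_mean")
    hp <- vapply(vals, `[[`, numeric(1), "hp_recall_mean")
    data.frame(k = k, accuracy = mean(acc), accuracy_sd = sd(acc),
               macro_f1 = mean(f1), macro_f1_sd = sd(f1),
               hp_recall = mean(hp), hp_recall_sd = sd(hp))
  })
  out <- do.call(rbind, rows)
  attr(out, "choice") <- choice
  out
}

#' Parsimony model selection over a feature-count summary table
#'
#' The proposed feature count is the smallest grid value at which (i) HP
#' recall reaches and stabilises at or above the threshold (holds at that
#' value and at every larger grid value) and (ii) overall accuracy and macro
#' F1 lie within `tolerance_pp` percentage points of the full-feature model
#' (the largest grid value).
#'
#' @param table data.frame with columns `k`, `accuracy`, `macro_f1`,
#'   `hp_recall` (means, %), covering the grid including the full model.
#' @param hp_threshold HP-recall threshold in percent.
#' @param tolerance_pp tolerance against the full model, percentage points.
#' @return object of class `parsimony_decision`: `chosen_k` (NA if no value
#'   passes), `trace` (per-k clause evaluations), `full` (reference row),
#'   `hp_threshold`, `tolerance_pp`.
#' @export
parsimony_select <- function(table, hp_threshold = 50, tolerance_pp = 1.0) {
  stopifnot(all(c("k", "accuracy", "macro_f1", "hp_recall") %in% colnames(table)))
  table <- table[order(table$k), ]
  full <- table[nrow(table), ]
  nk <- nrow(table)
  pass_hp <- vapply(seq_len(nk), function(i) {
    all(table$hp_recall[i:nk] >= hp_threshold)
  }, logical(1))
  pass_tol <- table$accuracy >= full$accuracy - tolerance_pp &
    table$macro_f1 >= full$macro_f1 - tolerance_pp
  pass <- pass_hp & pass_tol
  trace <- data.frame(k = table$k, accuracy = table$accuracy,
                      macro_f1 = table$macro_f1, hp_recall = table$hp_recall,
                      pass_hp_recall = pass_hp, pass_tolerance = pass_tol,
                      pass = pass)
  chosen <- if (any(pass)) table$k[which(pass)[1]] else NA_integer_
  structure(list(chosen_k = chosen, trace = trace, full = full,
                 hp_threshold = hp_threshold, tolerance_pp = tolerance_pp),
            class = "parsimony_decision")
}

#' Feature-stability counts across LOSO folds
#'
#' For every modality and feature: the number of folds in which the feature
#' ranked among the top `top_m` by mutual information, and the
#' corresponding percentage of folds.
#'
#' @param sweep a [run_sweep()] result (with per-fold rankings).
#' @param top_m depth of the ranking prefix examined.
#' @return data.frame (`modality`, `feature`, `count`, `percentage`), sorted
#'   by descending count within modality.
#' @export
stability_counts <- function(sweep, top_m = 10L) {
  if (is.null(sweep$rankings) || length(sweep$rankings) == 0) {
    stop("sweep carries no per-fold rankings")
  }
  n_folds <- length(sweep$subjects)
  out <- lapply(names(sweep$rankings), function(m) {
    tops <- unlist(lapply(sweep$rankings[[m]], head, top_m))
    tab <- sort(table(tops), decreasing = TRUE)
    data.frame(modality = m, feature = names(tab),
               count = as.integer(tab),
               percentage = 100 * as.integer(tab) / n_folds)
  })
  do.call(rbind, out)
}

#' Per-class recall table at a fixed feature count
#'
#' For each modality, the classifier with the best mean accuracy at `k`
#' (ties broken by the sweep's classifier order) is reported with fold-wise
#' accuracy and per-class recalls (mean and sample SD, %).
#'
#' @param sweep a [run_sweep()] result.
#' @param k feature count (must be in the sweep grid).
#' @return data.frame with one row per modality.
#' @export
per_class_recall_table <- function(sweep, k) {
  if (!k %in% sweep$grid) stop("k = ", k, " is not in the sweep grid")
  fm <- .sweep_fold_metrics(sweep)
  summ <- summarise_sweep(sweep)
  out <- lapply(unique(fm$modality), function(m) {
    cand <- summ[summ$modality == m & summ$k == k, ]
    cand <- cand[order(match(cand$classifier, sweep$classifiers)), ]
    best <- cand$classifier[which.max(cand$accuracy_mean)]
    rows <- fm[fm$modality == m & fm$classifier == best & fm$k == k, ]
    data.frame(modality = m, model = best,
               accuracy = mean(rows$accuracy), accuracy_sd = sd(rows$accuracy),
               np_recall = mean(rows$np_recall), np_recall_sd = sd(rows$np_recall),
               lp_recall = mean(rows$lp_recall), lp_recall_sd = sd(rows$lp_recall),
               hp_recall = mean(rows$hp_recall), hp_recall_sd = sd(rows$hp_recall))
  })
  do.call(rbind, out)
}

#' Accuracy-vs-feature-count figures
#'
#' One figure per modality: mean LOSO accuracy per classifier as a function
#' of the number of selected features, with a shaded band of one fold SD.
#' The underlying table is written alongside each figure.
#'
#' @param sweep a [run_sweep()] result.
#' @param out_dir output directory.
#' @param device figure format, e.g. `"png"` or `"svg"`.
#' @return invisible character vector of figure paths.
#' @export
plot_sweep <- function(sweep, out_dir, device = "png") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarise_sweep(sweep)
  paths <- character(0)
  for (m in unique(summ$modality)) {
    d <- summ[summ$modality == m, ]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = k, y = accuracy_mean,
                                         colour = classifier,
                                         fill = classifier)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = accuracy_mean - accuracy_sd,
                                        ymax = accuracy_mean + accuracy_sd),
                           alpha = 0.15, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "number of selected features",
                    y = "LOSO accuracy (%)",
                    title = paste("Accuracy vs feature count,", m)) +
      ggplot2::theme_minimal()
    fig <- file.path(out_dir, sprintf("sweep_%s.%s", tolower(m), device))
    ggplot2::ggsave(fig, p, width = 7, height = 4.5, dpi = 150)
    write.table(d, file.path(out_dir, sprintf("sweep_%s.tsv", tolower(m))),
                sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, fig)
  }
  invisible(paths)
}
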