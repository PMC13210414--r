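#' Leave-one-subject-out fold specifications
#'
#' @param subjects vector of unique subject ids.
#' @return list of folds, each with `held_out` and `train` (sorted by
#'   held-out subject id).
#' @export
loso_folds <- function(subjects) {
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  if (length(subjects) < 2) stop("need at least 2 subjects")
  subjects <- sort(subjects)
  lapply(subjects, function(s) {
    list(held_out = s, train = setdiff(subjects, s))
  })
}

# population SD (divisor n); the convention is declared here once so the
# z-scoring contract is unambiguous
.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardise features within a training fold
#'
#' Each feature is z-scored by its training-fold mean and population SD
#' (divisor n); the identical transform is applied to the test rows.
#' Zero-variance training features map to 0 in both sets.
#'
#' @param train,test numeric feature matrices with identical columns.
#' @return list with standardised `train` and `test`.
#' @export
standardise_fold <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, .sd_pop)
  zero <- sdv == 0
  sdv[zero] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  te <- sweep(sweep(test, 2, mu), 2, sdv, "/")
  tr[, zero] <- 0
  te[, zero] <- 0
  list(train = tr, test = te)
}

# k-th nearest-neighbour distance for every element of a sorted vector
# (excluding self); vectorised over the candidate left/right split
.knn_radius_sorted <- function(xs, kk) {
  n <- length(xs)
  r <- rep(Inf, n)
  for (j in 0:kk) {
    right <- c(xs[(1 + j):n], rep(Inf, j)) - xs
    lshift <- kk - j
    left <- xs - c(rep(-Inf, lshift), xs[seq_len(n - lshift)])
    r <- pmin(r, pmax(left, right))
  }
  r
}

# kNN mutual information between a continuous variable and a discrete label
# (Ross 2014); nats
.mi_cd <- function(x, y, k = 3L) {
  n <- length(x)
  radius <- numeric(n)
  label_counts <- integer(n)
  k_all <- integer(n)
  for (lab in unique(y)) {
    mask <- which(y == lab)
    cnt <- length(mask)
    label_counts[mask] <- cnt
    if (cnt > 1) {
      kk <- min(k, cnt - 1)
      k_all[mask] <- kk
      o <- order(x[mask])
      radius[mask[o]] <- .knn_radius_sorted(x[mask][o], kk)
    }
  }
  keep <- label_counts > 1L
  ns <- sum(keep)
  xk <- x[keep]
  rk <- radius[keep] * (1 - 1e-12)  # strictly inside the kth-NN ball
  xsort <- sort(xk)
  m_all <- findInterval(xk + rk, xsort) - findInterval(xk - rk, xsort)
  mi <- digamma(ns) + mean(digamma(k_all[keep])) -
    mean(digamma(label_counts[keep])) - mean(digamma(m_all))
  max(0, mi)
}

#' Rank features by mutual information with the class label
#'
#' k-nearest-neighbour MI estimator for continuous features against the
#' discrete class label, with a tiny seed-driven jitter to break ties.
#' Ties in the MI score are broken by canonical feature order.
#'
#' @param train numeric feature matrix (training rows only).
#' @param labels class labels for the training rows.
#' @param seed integer seed driving the jitter.
#' @param k number of neighbours for the MI estimator.
#' @param jitter relative jitter amplitude (fraction of each feature's SD).
#' @return object of class `selection_result`: `ranking` (feature names,
#'   descending MI), `scores` (named, in ranking order), `seed`.
#' @export
mi_rank <- function(train, labels, seed = 1L, k = 3L, jitter = 1e-10) {
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  set.seed(seed)
  nf <- ncol(train)
  scores <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- train[, f]
    if (jitter > 0) x <- x + jitter * max(1e-300, .sd_pop(x)) * rnorm(length(x))
    scores[f] <- .mi_cd(x, labels, k)
  }
  names(scores) <- colnames(train)
  ord <- order(-scores)  # stable: ties keep canonical feature order
  structure(list(ranking = colnames(train)[ord], scores = scores[ord],
                 seed = seed),
            class = "selection_result")
}

#' Select the top-k features of a ranking
#'
#' @param selection a [mi_rank()] result.
#' @param k number of features to retain.
#' @return character vector: the first `k` names of the ranking.
#' @export
select_top_k <- function(selection, k) {
  if (k < 1 || k > length(selection$ranking)) {
    stop("k must be in [1, ", length(selection$ranking), "]")
  }
  selection$ranking[seq_len(k)]
}

#' Train a classifier and predict held-out labels
#'
#' Thin pluggable contract over established implementations (e1071 SVM,
#' class KNN, randomForest, xgboost), each with its library defaults; only
#' the random seed is pinned. KNN uses k = 5 neighbours and xgboost 100
#' boosting rounds (conventional defaults, declared here since those
#' libraries require the value explicitly).
#'
#' @param classifier one of `"svm"`, `"knn"`, `"rf"`, `"xgboost"`.
#' @param train,test standardised, column-aligned feature matrices.
#' @param labels training labels (`NP`/`LP`/`HP`).
#' @param seed integer seed.
#' @return character vector of predicted labels, one per test row.
#' @export
fit_predict <- function(classifier, train, labels, test, seed = 1L) {
  valid <- c("svm", "knn", "rf", "xgboost")
  if (!classifier %in% valid) {
    stop("unknown classifier '", classifier, "'; valid: ",
         paste(valid, collapse = ", "))
  }
  present <- intersect(PAIN_CLASSES, unique(labels))
  if (length(present) == 1) {
    return(rep(present, nrow(test)))
  }
  y <- factor(labels, levels = present)
  set.seed(seed)
  pred <- switch(classifier,
    svm = {
      fit <- e1071::svm(x = train, y = y)
      as.character(predict(fit, test))
    },
    knn = as.character(class::knn(train, test, y, k = 5)),
    rf = {
      fit <- randomForest::randomForest(x = train, y = y)
      as.character(predict(fit, test))
    },
    xgboost = {
      code <- as.integer(y) - 1L
      fit <- xgboost::xgboost(
        data = train, label = code, nrounds = 100, verbose = 0,
        params = list(objective = "multi:softmax",
                      num_class = length(present),
                      nthread = 1, seed = seed))
      levels(y)[predict(fit, test) + 1L]
    })
  unname(pred)
}

.confusion3 <- function(true, pred) {
  tab <- table(factor(true, levels = PAIN_CLASSES),
               factor(pred, levels = PAIN_CLASSES))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(true = PAIN_CLASSES, pred = PAIN_CLASSES))
  m
}

#' Feature-count sweep under LOSO cross-validation
#'
#' Full factorial over modality x classifier x feature count x fold. Within
#' every training fold: features are standardised on training rows only, the
#' MI ranking is computed once from training rows only and reused as a
#' prefix for every feature count (mathematically identical to per-k
#' selection), and each classifier is fitted on the selected columns. The
#' sweep is reproducible bit-for-bit given (tables, grid, seed).
#'
#' @param tables named list of per-modality feature tables
#'   ([features_for_dataset()] output).
#' @param grid feature counts to evaluate.
#' @param classifiers classifier names, see [fit_predict()].
#' @param seed master seed; per-(modality, fold, classifier) substreams are
#'   derived from it deterministically.
#' @param mi_k neighbours for the MI estimator.
#' @return object of class `sweep_result`: `results` (data.frame with one
#'   row per modality/classifier/k/fold, accuracy and a list column of 3x3
#'   confusion matrices), `rankings` (full per-(modality, fold) MI
#'   rankings), `grid`, `classifiers`, `subjects`, `seed`.
#' @export
run_sweep <- function(tables, grid, classifiers = c("svm", "knn", "rf", "xgboost"),
                      seed = 1L, mi_k = 3L) {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  subjects <- sort(unique(tables[[1]]$subject))
  for (tab in tables) {
    if (!identical(sort(unique(tab$subject)), subjects)) {
      stop("modalities must share the same subject set")
    }
  }
  grid <- sort(unique(as.integer(grid)))
  nf <- ncol(tables[[1]]) - 2L
  if (any(grid < 1 | grid > nf)) stop("grid values must lie in [1, ", nf, "]")
  folds <- loso_folds(subjects)

  res_rows <- list()
  rankings <- list()
  for (mi_mod in seq_along(tables)) {
    modality <- names(tables)[mi_mod]
    tab <- tables[[mi_mod]]
    feat_cols <- setdiff(colnames(tab), c("subject", "label"))
    Xall <- as.matrix(tab[, feat_cols])
    rankings[[modality]] <- list()
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      tr_idx <- tab$subject != fold$held_out
      std <- standardise_fold(Xall[tr_idx, , drop = FALSE],
                              Xall[!tr_idx, , drop = FALSE])
      y_tr <- tab$label[tr_idx]
      y_te <- tab$label[!tr_idx]
      fold_seed <- seed + 1009L * mi_mod + fi
      sel <- mi_rank(std$train, y_tr, seed = fold_seed, k = mi_k)
      rankings[[modality]][[as.character(fold$held_out)]] <- sel$ranking
      for (k in grid) {
        keep <- select_top_k(sel, k)
        tr_k <- std$train[, keep, drop = FALSE]
        te_k <- std$test[, keep, drop = FALSE]
        for (ci in seq_along(classifiers)) {
          clf <- classifiers[ci]
          pred <- fit_predict(clf, tr_k, y_tr, te_k,
                              seed = fold_seed + 17L * ci)
          cm <- .confusion3(y_te, pred)
          res_rows[[length(res_rows) + 1]] <- list(
            modality = modality, classifier = clf, k = k,
            subject = fold$held_out,
            accuracy = 100 * sum(diag(cm)) / sum(cm),
            confusion = cm)
        }
      }
    }
  }
  results <- data.frame(
    modality = vapply(res_rows, `[[`, character(1), "modality"),
    classifier = vapply(res_rows, `[[`, character(1), "classifier"),
    k = vapply(res_rows, `[[`, numeric(1), "k"),
    subject = vapply(res_rows, `[[`, numeric(1), "subject"),
    accuracy = vapply(res_rows, `[[`, numeric(1), "accuracy"))
  results$confusion <- lapply(res_rows, `[[`, "confusion")
  structure(list(results = results, rankings = rankings, grid = grid,
                 classifiers = classifiers, subjects = subjects, seed = seed),
            class = "sweep_result")
}
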