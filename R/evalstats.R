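#' 2x2 confusion matrix (benign = negative, malignant = positive)
#'
#' @param tn,fp,fn,tp non-negative counts.
#' @return An object of class `confusion_2x2`.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2L, 2L, byrow = TRUE,
              dimnames = list(actual = c("benign", "malignant"),
                              estimated = c("benign", "malignant")))
  print(m)
  invisible(x)
}

#' Confusion matrix from prediction records at a cut-off
#'
#' A record is predicted malignant when its score is at or above the
#' cut-off; at cut-off 0 everything is predicted malignant.
#'
#' @param records data.frame with `score` in \[0, 1\] and `true_label` in
#'   `{benign, malignant}`.
#' @param cutoff malignancy cut-off (default 0.5).
#' @return A [confusion_counts()] object; the four counts partition the
#'   records.
#' @export
confusion <- function(records, cutoff = 0.5) {
  if (nrow(records) == 0L) stop("records must be non-empty", call. = FALSE)
  if (!all(records$true_label %in% c("benign", "malignant"))) {
    stop("unknown label in records; labels must be benign/malignant",
         call. = FALSE)
  }
  pred_mal <- records$score >= cutoff
  act_mal <- records$true_label == "malignant"
  confusion_counts(tn = sum(!act_mal & !pred_mal),
                   fp = sum(!act_mal & pred_mal),
                   fn = sum(act_mal & !pred_mal),
                   tp = sum(act_mal & pred_mal))
}

#' Sensitivity, specificity and overall accuracy of a confusion matrix
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`,
#' `accuracy = (tp + tn) / total`. A zero row total raises an error rather
#' than returning a silent `NaN`.
#'
#' @param m a `confusion_2x2`.
#' @return A named numeric vector `(sensitivity, specificity, accuracy)` at
#'   full precision.
#' @export
summary_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_2x2"))
  pos <- m$tp + m$fn
  neg <- m$tn + m$fp
  if (pos == 0 || neg == 0) {
    stop("undefined metric: a class has zero actual count", call. = FALSE)
  }
  c(sensitivity = m$tp / pos, specificity = m$tn / neg,
    accuracy = (m$tp + m$tn) / (pos + neg))
}

#' ROC curve and AUC from prediction records
#'
#' Sweeps the cut-off over all distinct scores (ties grouped into single
#' steps), yielding a monotone curve from (0,0) to (1,1); the AUC is the
#' trapezoidal area, which equals the Mann-Whitney U statistic with ties
#' counted one half.
#'
#' @param records data.frame with `score` and `true_label`; both classes
#'   must be present.
#' @return A list of class `roc_curve` with `points` (data.frame `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(records) {
  act_mal <- records$true_label == "malignant"
  P <- sum(act_mal)
  N <- sum(!act_mal)
  if (P == 0L || N == 0L) {
    stop("undefined metric: ROC requires both classes present",
         call. = FALSE)
  }
  ord <- order(records$score, decreasing = TRUE)
  s <- records$score[ord]
  y <- act_mal[ord]
  grp <- cumsum(!duplicated(s))
  tp_step <- tapply(as.numeric(y), grp, sum)
  fp_step <- tapply(as.numeric(!y), grp, sum)
  tpr <- unname(c(0, cumsum(tp_step) / P))
  fpr <- unname(c(0, cumsum(fp_step) / N))
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' Holdout plus k-fold split plan
#'
#' The evaluation protocol: a fixed-size validation holdout (used to watch
#' training behaviour) and stratified k-fold cross-validation folds over the
#' remaining evaluation pool. Grouping `"patch"` assigns individual patches
#' (exact holdout size); `"case"` keeps all patches of a case in the same
#' fold/holdout to prevent same-patient leakage, so the holdout size is
#' matched as closely as case boundaries allow.
#'
#' @param holdout validation holdout size in patches (default 173).
#' @param cv_folds number of folds (default 3).
#' @param grouping `"patch"` or `"case"`.
#' @param seed integer seed.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(holdout = 173L, cv_folds = 3L,
                       grouping = c("patch", "case"), seed = 1L) {
  grouping <- match.arg(grouping)
  structure(list(holdout = as.integer(holdout),
                 cv_folds = as.integer(cv_folds), grouping = grouping,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Assign validation holdout and cross-validation folds
#'
#' Rows labeled `excluded` keep split `"excluded"`. The rest are split,
#' stratified by label, into a `"validation"` holdout and folds
#' `"fold1" ... "foldK"` that partition the evaluation pool exactly once.
#' Deterministic given `plan$seed`.
#'
#' @param manifest a patch manifest.
#' @param plan a [split_plan()].
#' @return The manifest with its `split` column filled in.
#' @export
make_splits <- function(manifest, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  eligible <- which(manifest$label %in% c("benign", "malignant"))
  if (length(eligible) <= plan$holdout) {
    stop("manifest has too few labeled patches (", length(eligible),
         ") for a holdout of ", plan$holdout, call. = FALSE)
  }
  manifest$split[manifest$label == "excluded"] <- "excluded"
  with_seed(plan$seed, {
    if (plan$grouping == "patch") {
      units <- data.frame(idx = I(as.list(eligible)),
                          label = manifest$label[eligible],
                          size = 1L, stringsAsFactors = FALSE)
    } else {
      cases <- split(eligible, manifest$case_id[eligible])
      units <- data.frame(
        idx = I(unname(cases)),
        label = vapply(cases, function(ii)
          if (any(manifest$label[ii] == "malignant")) "malignant" else
            "benign", character(1L)),
        size = vapply(cases, length, integer(1L)))
    }
    units <- units[sample.int(nrow(units)), , drop = FALSE]
    # stratified holdout: take units per label proportionally until the
    # holdout budget is met
    hold <- logical(nrow(units))
    budget <- plan$holdout
    frac <- budget / sum(units$size)
    for (lb in unique(units$label)) {
      rows <- which(units$label == lb)
      want <- round(frac * sum(units$size[rows]))
      got <- 0L
      for (r in rows) {
        if (got >= want) break
        hold[r] <- TRUE
        got <- got + units$size[r]
      }
    }
    # patch-level grouping can hit the budget exactly
    if (plan$grouping == "patch") {
      excess <- sum(units$size[hold]) - budget
      if (excess > 0L) hold[which(hold)[seq_len(excess)]] <- FALSE
      if (excess < 0L) hold[which(!hold)[seq_len(-excess)]] <- TRUE
    }
    for (r in which(hold)) manifest$split[units$idx[[r]]] <- "validation"
    # stratified round-robin fold assignment over the remaining pool
    pool <- which(!hold)
    for (lb in unique(units$label)) {
      rows <- pool[units$label[pool] == lb]
      f <- rep_len(seq_len(plan$cv_folds), length(rows))
      for (j in seq_along(rows)) {
        manifest$split[units$idx[[rows[j]]]] <- paste0("fold", f[j])
      }
    }
  })
  manifest
}

#' Comparison table for pretraining methods
#'
#' Builds the per-method metric table (sensitivity, specificity, overall
#' accuracy, AUC) plus row-wise deltas of every method against the
#' `reference` pretraining method (ImageNet by default).
#'
#' @param metrics named list (method -> named vector/list with
#'   `sensitivity`, `specificity`, `accuracy`, `auc`).
#' @param reference reference method name (default `"ImageNet"`).
#' @return A list of class `method_comparison` with data.frames `table` and
#'   `deltas`.
#' @export
method_comparison <- function(metrics, reference = "ImageNet") {
  stopifnot(reference %in% names(metrics))
  tab <- do.call(rbind, lapply(names(metrics), function(m) {
    v <- metrics[[m]]
    data.frame(method = m, sensitivity = v[["sensitivity"]],
               specificity = v[["specificity"]],
               accuracy = v[["accuracy"]], auc = v[["auc"]],
               stringsAsFactors = FALSE)
  }))
  ref <- tab[tab$method == reference, -1L]
  deltas <- tab
  deltas[-1L] <- sweep(as.matrix(tab[-1L]), 2L, as.numeric(ref))
  rownames(tab) <- rownames(deltas) <- NULL
  structure(list(table = tab, deltas = deltas, reference = reference),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 3L, ...) {
  cat("Pretraining method comparison (reference:", x$reference, ")\n")
  tab <- x$table
  tab[-1L] <- round(tab[-1L], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the cross-validated comparison of pretraining methods
#'
#' For each method and each cross-validation fold, calls
#' `trainer(method, train_manifest, seed)` — which must return a fitted
#' object accepted by `predictor(fitted, test_manifest)` yielding
#' prediction records — then pools the per-fold predictions into one
#' confusion matrix per method (single-matrix pooling, matching a single
#' reported confusion table) and computes summary metrics and AUC.
#'
#' @param manifest a manifest whose `split` column was filled by
#'   [make_splits()].
#' @param methods character vector of method names, e.g.
#'   `c("ImageNet", "DCGAN", "PGGAN")`.
#' @param trainer function(method, train_manifest, seed) -> fitted object.
#' @param predictor function(fitted, test_manifest) -> prediction records.
#' @param cutoff confusion-matrix cut-off (default 0.5).
#' @param reference reference method for deltas.
#' @param seed integer seed passed to the trainer.
#' @return A `method_comparison` with an extra `predictions` element (named
#'   list of pooled prediction records).
#' @export
run_comparison <- function(manifest, methods, trainer, predictor,
                           cutoff = 0.5, reference = methods[1L], seed = 1L) {
  folds <- sort(unique(manifest$split[startsWith(manifest$split, "fold")]))
  if (length(folds) == 0L) {
    stop("manifest has no folds; run make_splits() first", call. = FALSE)
  }
  preds <- list()
  metrics <- list()
  for (m in methods) {
    recs <- list()
    for (f in folds) {
      train_man <- manifest[manifest$split %in% setdiff(folds, f), ,
                            drop = FALSE]
      test_man <- manifest[manifest$split == f, , drop = FALSE]
      fitted <- trainer(m, train_man, seed)
      recs[[f]] <- predictor(fitted, test_man)
    }
    pooled <- do.call(rbind, recs)
    rownames(pooled) <- NULL
    preds[[m]] <- pooled
    cm <- confusion(pooled, cutoff)
    metrics[[m]] <- c(summary_metrics(cm), auc = roc_auc(pooled)$auc)
  }
  out <- method_comparison(metrics, reference = reference)
  out$predictions <- preds
  out
}

#' Export ROC points / evaluation report
#'
#' @param records prediction records.
#' @param cutoff cut-off for the confusion matrix.
#' @return A list with `confusion`, `metrics` (3 d.p. at report time),
#'   `auc`, and `roc` points.
#' @export
evaluation_report <- function(records, cutoff = 0.5) {
  cm <- confusion(records, cutoff)
  roc <- roc_auc(records)
  list(confusion = cm,
       metrics = round(summary_metrics(cm), 3L),
       auc = roc$auc, roc = roc$points)
}
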