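#' Encode EP pairs as motif-pair feature vectors
#'
#' Each EP pair becomes a row of `4n + 1` values for `n` motif pairs: for
#' every motif pair, the occurrence counts (both strands, scan threshold) of
#' its E-side motif in the enhancer and in the promoter, and of its P-side
#' motif in the enhancer and in the promoter, plus the class label. Columns
#' are ordered by motif-pair name for determinism.
#'
#' @param ep_pairs EP-pair tibble (positives plus negatives; needs `ep_id`,
#'   `enh_id`, `prom_id`, `label`).
#' @param motif_pairs Tibble with `motif_E`, `motif_P` (e.g. from
#'   [discover_motif_pairs()]).
#' @param occurrences Scanner hits over the exact sequences of the pairs
#'   (attribute `scanned_ids` required, or pass `scanned_ids`).
#' @param scanned_ids Optional explicit scanned-ID vector.
#' @return Tibble with `ep_id`, `label`, and four count columns per motif
#'   pair named `<E>.<P>|<member>_in_<region>`.
#' @export
build_features <- function(ep_pairs, motif_pairs, occurrences,
                           scanned_ids = NULL) {
  scanned_ids <- scanned_ids %||% attr(occurrences, "scanned_ids")
  if (is.null(scanned_ids)) {
    stop("scanned_ids not available; pass the scan_motifs() result or ",
         "scanned_ids explicitly")
  }
  miss <- ep_pairs$ep_id[!(ep_pairs$enh_id %in% scanned_ids) |
                           !(ep_pairs$prom_id %in% scanned_ids)]
  if (length(miss) > 0L) {
    stop("EP pair(s) with unscanned sequences: ",
         paste(head(miss, 3L), collapse = ", "))
  }
  mp <- dplyr::distinct(motif_pairs[, c("motif_E", "motif_P")]) |>
    dplyr::arrange(.data$motif_E, .data$motif_P)
  motifs_needed <- unique(c(mp$motif_E, mp$motif_P))
  scanned_motifs <- attr(occurrences, "motifs") %||% unique(occurrences$motif)
  unseen <- setdiff(motifs_needed, scanned_motifs)
  if (length(unseen) > 0L) {
    stop("motif pair references motif(s) absent from the scan: ",
         paste(unseen, collapse = ", "))
  }
  counts <- occurrences |>
    dplyr::count(.data$seq_id, .data$motif, name = "n")
  count_of <- function(seq_ids, motif) {
    key <- tibble::tibble(seq_id = seq_ids, motif = motif)
    res <- dplyr::left_join(key, counts, by = c("seq_id", "motif"))
    dplyr::coalesce(res$n, 0L)
  }
  out <- tibble::tibble(ep_id = ep_pairs$ep_id, label = ep_pairs$label)
  for (i in seq_len(nrow(mp))) {
    e <- mp$motif_E[i]; p <- mp$motif_P[i]
    base <- paste0(e, ".", p)
    out[[paste0(base, "|E_in_enh")]] <- count_of(ep_pairs$enh_id, e)
    out[[paste0(base, "|E_in_prom")]] <- count_of(ep_pairs$prom_id, e)
    out[[paste0(base, "|P_in_enh")]] <- count_of(ep_pairs$enh_id, p)
    out[[paste0(base, "|P_in_prom")]] <- count_of(ep_pairs$prom_id, p)
  }
  out
}

feature_xy <- function(features, positive_label = "positive") {
  x <- as.matrix(features[, setdiff(names(features), c("ep_id", "label"))])
  y <- as.integer(features$label == positive_label)
  list(x = x, y = y)
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

prf <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Cross-validated L1-penalized classification of EP pairs
#'
#' Fits an L1-penalized (lasso) logistic regression per fold of a stratified
#' 10-fold cross-validation, choosing the penalty by an inner
#' cross-validation on the training folds, and reports per-fold and mean
#' precision, recall and F1 for the positive class. The selected motif pairs
#' are those with at least one nonzero coefficient in a final model refit on
#' all rows.
#'
#' @param features Feature tibble from [build_features()].
#' @param n_folds Number of outer folds (default 10).
#' @param seed Integer seed for fold assignment and the inner CV.
#' @param positive_label Label of the positive class.
#' @param lambda_choice `"lambda.min"` or `"lambda.1se"` from the inner CV.
#' @return An object of class `ep_cv` with elements `folds` (per-fold
#'   metrics tibble), `mean` (named vector), `selected_pairs`,
#'   `n_selected`, `seed`, `lambda`.
#' @export
cross_validate <- function(features, n_folds = 10, seed = 1,
                           positive_label = "positive",
                           lambda_choice = c("lambda.min", "lambda.1se")) {
  lambda_choice <- match.arg(lambda_choice)
  xy <- feature_xy(features, positive_label)
  if (length(unique(xy$y)) < 2L) stop("need both classes to cross-validate")
  if (min(table(xy$y)) < n_folds) {
    stop("fewer rows in a class than folds")
  }
  metrics <- matrix(NA_real_, n_folds, 3L,
                    dimnames = list(NULL, c("precision", "recall", "f1")))
  final <- NULL
  with_local_seed(seed, {
    fold <- stratified_folds(xy$y, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- fit_lasso(xy$x[tr, , drop = FALSE], xy$y[tr], lambda_choice)
      pred <- as.integer(
        predict(fit$model, xy$x[!tr, , drop = FALSE], s = fit$lambda,
                type = "response") > 0.5)
      metrics[f, ] <- prf(xy$y[!tr], pred)
    }
    final <- fit_lasso(xy$x, xy$y, lambda_choice)
  })
  coefs <- as.matrix(predict(final$model, s = final$lambda,
                             type = "coefficients"))[-1L, 1L]
  sel_cols <- names(coefs)[coefs != 0]
  sel_pairs <- sort(unique(sub("\\|.*$", "", sel_cols)))
  structure(
    list(
      folds = tibble::tibble(fold = seq_len(n_folds),
                             precision = metrics[, 1L],
                             recall = metrics[, 2L],
                             f1 = metrics[, 3L]),
      mean = colMeans(metrics),
      selected_pairs = sel_pairs,
      n_selected = length(sel_pairs),
      selected_features = sel_cols,
      seed = seed,
      lambda = final$lambda
    ),
    class = "ep_cv"
  )
}

fit_lasso <- function(x, y, lambda_choice) {
  constant <- apply(x, 2L, function(col) max(col) == min(col))
  if (all(constant)) {
    # degenerate design: intercept-only model predicting the class rate
    model <- structure(list(p = mean(y), cols = colnames(x)),
                       class = "ep_intercept_only")
    return(list(model = model, lambda = Inf))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1, nfolds = 5)
  lambda <- if (lambda_choice == "lambda.min") {
    # restrict the grid to penalties keeping >= 1 active feature: the null
    # model carries no discriminative content, and letting it win under a
    # flat CV curve collapses predictions onto the majority class
    elig <- which(cv$nzero >= 1L)
    if (length(elig) > 0L) {
      cv$lambda[elig[which.min(cv$cvm[elig])]]
    } else {
      cv$lambda.min
    }
  } else {
    cv[[lambda_choice]]
  }
  list(model = cv$glmnet.fit, lambda = lambda)
}

#' @noRd
predict.ep_intercept_only <- function(object, newx, s = NULL,
                                      type = "response", ...) {
  if (type == "coefficients") {
    matrix(0, length(object$cols) + 1L, 1L,
           dimnames = list(c("(Intercept)", object$cols), "s1"))
  } else {
    matrix(object$p, nrow(newx), 1L)
  }
}

#' @export
print.ep_cv <- function(x, ...) {
  cat("<ep_cv> ", nrow(x$folds), "-fold cross-validation\n", sep = "")
  cat(sprintf("  mean precision %.3f, recall %.3f, F1 %.3f\n",
              x$mean["precision"], x$mean["recall"], x$mean["f1"]))
  cat("  selected motif pairs:", x$n_selected, "\n")
  invisible(x)
}

#' @describeIn cross_validate Per-fold metrics as a tibble.
#' @param x An `ep_cv` object.
#' @param ... Unused.
#' @method tidy ep_cv
#' @export
tidy.ep_cv <- function(x, ...) x$folds

#' @describeIn cross_validate One-row summary (mean metrics, `n_selected`).
#' @method glance ep_cv
#' @export
glance.ep_cv <- function(x, ...) {
  tibble::tibble(
    precision = x$mean[["precision"]],
    recall = x$mean[["recall"]],
    f1 = x$mean[["f1"]],
    n_selected = x$n_selected,
    folds = nrow(x$folds),
    seed = x$seed
  )
}

#' Evaluate one condition's motif pairs on another condition's EP pairs
#'
#' Builds features for condition B's EP pairs from the motif pairs
#' discovered in condition A and runs the stratified cross-validation on B.
#'
#' @param motif_pairs_a Motif pairs discovered in condition A.
#' @param ep_pairs_b EP pairs (positives + negatives) of condition B.
#' @param occurrences_b Scanner hits on B's sequences (same motif library).
#' @inheritParams cross_validate
#' @return An `ep_cv` object.
#' @export
cross_condition_eval <- function(motif_pairs_a, ep_pairs_b, occurrences_b,
                                 n_folds = 10, seed = 1) {
  shared <- intersect(unique(c(motif_pairs_a$motif_E, motif_pairs_a$motif_P)),
                      unique(occurrences_b$motif))
  if (length(shared) == 0L) {
    stop("no motifs of condition A's pairs occur in condition B's scan")
  }
  feats <- build_features(ep_pairs_b, motif_pairs_a, occurrences_b)
  cross_validate(feats, n_folds = n_folds, seed = seed)
}
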