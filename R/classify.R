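# Cross-validated multi-class classification over feature blocks.
#
# Each task contributes one feature block; blocks are evaluated alone and in
# combination by repeated stratified k-fold cross-validation with
# training-fold-only median imputation and standardisation.

#' Feature blocks
#'
#' The task-wise grouping of feature slots used in combination search:
#' So1 button choice, So2 preferential looking, Se1 wheel, Mo1 motor
#' following, Mo5/Mo7 bubble popping (distances / force), `Mo-col`
#' colouring, Ob1 caregiver-child interaction, Ob2 questionnaire. Blocks are
#' disjoint and jointly cover all 16 feature slots.
#'
#' @return Named list of character vectors of slot names.
#' @export
feature_blocks <- function() {
  list(
    So1 = "social_choice",
    So2 = "social_preference",
    Se1 = c("wheel_looking", "wheel_dist_min", "wheel_dist_max"),
    Mo1 = c("motor_rmse", "fft_gain_x", "fft_gain_y", "jerk"),
    Mo5 = c("pop_dist_x", "pop_dist_y"),
    Mo7 = "pop_force",
    `Mo-col` = "colour_crossings",
    Ob1 = c("pci_child_init", "pci_caregiver_sync"),
    Ob2 = "questionnaire_score")
}

#' Best-combination block preset
#'
#' The block set reported as the most accurate combination (all blocks except
#' colouring, which carries no block id in that listing).
#'
#' @return Character vector of block ids.
#' @export
best_combination <- function() c("So1", "So2", "Se1", "Mo1", "Mo5", "Mo7", "Ob1", "Ob2")

#' Cross-validation configuration
#'
#' @param folds number of stratified folds (>= 2).
#' @param repeats number of CV repetitions.
#' @param seed integer seed; the whole evaluation is deterministic under it.
#' @param classifier `"logistic_regression"` (ridge-regularised multinomial
#'   logistic regression) or `"lda"` (linear discriminant analysis).
#' @param imputation `"median"` (fitted on training folds only) or `"none"`.
#' @return list of class `start_cv_config`.
#' @export
cv_config <- function(folds = 5, repeats = 20, seed = 1L,
                      classifier = c("logistic_regression", "lda"),
                      imputation = c("median", "none")) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), classifier = match.arg(classifier),
                 imputation = match.arg(imputation)),
            class = "start_cv_config")
}

#' Assemble the design matrix for a block subset
#'
#' Columns are ordered by block then slot; the missingness mask is preserved.
#'
#' @param features a `start_features` data frame.
#' @param block_subset character vector of block ids (see
#'   [feature_blocks()]).
#' @return `list(x, y, mask)`: numeric matrix (children x slots), group
#'   factor, logical missingness matrix.
#' @export
assemble_matrix <- function(features, block_subset = names(feature_blocks())) {
  blocks <- feature_blocks()
  bad <- setdiff(block_subset, names(blocks))
  if (length(bad)) stopf("unknown block id(s): %s", paste(bad, collapse = ", "))
  slots <- unlist(blocks[block_subset], use.names = FALSE)
  x <- as.matrix(features[, slots, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- features$child_id
  empty <- colSums(!is.na(x)) == 0
  if (any(empty)) {
    off <- vapply(block_subset, function(b) all(blocks[[b]] %in% colnames(x)[empty]),
                  logical(1))
    if (any(off)) stopf("block(s) with no non-missing values: %s",
                        paste(block_subset[off], collapse = ", "))
  }
  y <- factor(features$group, GROUP_LEVELS)
  if (nlevels(droplevels(y)) < 2) stopf("need at least 2 classes")
  list(x = x, y = y, mask = is.na(x))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_predict <- function(xtr, ytr, xte, classifier) {
  ytr <- droplevels(ytr)
  if (nlevels(ytr) < 2) {
    return(factor(rep(levels(ytr)[1], nrow(xte)), levels = levels(ytr)))
  }
  if (classifier == "logistic_regression") {
    if (ncol(xtr) == 1) {  # glmnet needs >= 2 columns; duplication is a no-op
      xtr <- cbind(xtr, xtr)
      xte <- cbind(xte, xte)
    }
    fam <- if (nlevels(ytr) > 2) "multinomial" else "binomial"
    fit <- glmnet::glmnet(xtr, ytr, family = fam, alpha = 0, lambda = 0.05,
                          standardize = TRUE)
    pr <- stats::predict(fit, newx = xte, type = "class", s = 0.05)
    factor(as.character(pr), levels = levels(ytr))
  } else {
    fit <- MASS::lda(xtr, grouping = ytr)
    stats::predict(fit, xte)$class
  }
}

#' Evaluate a feature-block subset by repeated cross-validation
#'
#' Stratified k-fold cross-validation repeated `repeats` times. Imputation
#' statistics (column medians) are computed on the training folds only and
#' applied to the held-out fold; per-sample predictions are retained so the
#' TD-vs-NDD collapse can be recomputed exactly.
#'
#' @param features a `start_features` data frame (or a prebuilt
#'   [assemble_matrix()] result).
#' @param block_subset block ids to include.
#' @param cv a [cv_config()].
#' @param labels optional replacement label vector (e.g. permuted labels for
#'   a chance-level baseline).
#' @return A `start_classification`: per-class recall, overall accuracy,
#'   mean predicted-class proportions, per-repeat accuracy spread and the
#'   retained predictions.
#' @export
evaluate_blocks <- function(features, block_subset = names(feature_blocks()),
                            cv = cv_config(), labels = NULL) {
  am <- if (is.list(features) && !is.data.frame(features) && !is.null(features$x)) {
    features
  } else {
    assemble_matrix(features, block_subset)
  }
  x <- am$x
  y <- if (is.null(labels)) am$y else factor(labels, levels(am$y))
  y <- droplevels(y)
  n <- length(y)
  k <- cv$folds
  if (k > min(table(y))) stopf("folds (%d) exceed the smallest class count (%d)",
                               k, min(table(y)))
  preds <- matrix(NA_character_, n, cv$repeats)
  with_seed(cv$seed, function() {
    for (r in seq_len(cv$repeats)) {
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        te <- fold == f
        xtr <- x[!te, , drop = FALSE]
        xte <- x[te, , drop = FALSE]
        if (cv$imputation == "median") {
          med <- apply(xtr, 2, stats::median, na.rm = TRUE)
          med[!is.finite(med)] <- 0
          for (j in seq_len(ncol(xtr))) {
            xtr[is.na(xtr[, j]), j] <- med[j]
            xte[is.na(xte[, j]), j] <- med[j]
          }
        }
        preds[te, r] <<- as.character(fit_predict(xtr, y[!te], xte, cv$classifier))
      }
    }
  })
  acc_rep <- colMeans(preds == as.character(y))
  per_class <- vapply(levels(y), function(lev) {
    mean(preds[y == lev, , drop = FALSE] == lev)
  }, numeric(1))
  prop <- vapply(levels(y), function(lev) mean(preds == lev), numeric(1))
  structure(list(
    blocks = paste(block_subset, collapse = "+"),
    per_class_accuracy = per_class,
    overall_accuracy = mean(acc_rep),
    predicted_proportions = prop,
    accuracy_sd = stats::sd(acc_rep),
    accuracy_by_repeat = acc_rep,
    predictions = preds, truth = as.character(y),
    cv = cv), class = "start_classification")
}

#' @export
print.start_classification <- function(x, ...) {
  cat(sprintf("<start_classification> blocks: %s\n", x$blocks))
  cat(sprintf("  overall accuracy: %.1f%% (sd over repeats %.1f%%)\n",
              100 * x$overall_accuracy, 100 * x$accuracy_sd))
  cat("  per-class accuracy:",
      paste(sprintf("%s %.1f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  cat("  predicted proportions:",
      paste(sprintf("%s %.0f%%", names(x$predicted_proportions),
                    100 * x$predicted_proportions), collapse = ":"), "\n")
  invisible(x)
}

#' @export
as.data.frame.start_classification <- function(x, ...) {
  out <- data.frame(blocks = x$blocks, overall_accuracy = x$overall_accuracy,
                    accuracy_sd = x$accuracy_sd)
  for (lev in names(x$per_class_accuracy)) {
    out[[paste0("acc_", lev)]] <- x$per_class_accuracy[[lev]]
  }
  for (lev in names(x$predicted_proportions)) {
    out[[paste0("prop_", lev)]] <- x$predicted_proportions[[lev]]
  }
  out
}

#' Chance-level classification baseline
#'
#' Estimates the accuracy attainable with no class information: each repeat
#' draws a fresh random permutation of the group labels and runs one round
#' of stratified k-fold cross-validation. Averaging over permutations (not
#' just over folds of a single permutation) is essential: one permutation
#' can align by chance with structure in the features - missingness
#' patterns in particular - and bias the estimate by several points.
#'
#' @param features a `start_features` data frame.
#' @param block_subset block ids to include.
#' @param cv a [cv_config()]; `repeats` counts permutations.
#' @return list(accuracy, accuracy_by_repeat).
#' @export
chance_level <- function(features, block_subset = names(feature_blocks()),
                         cv = cv_config()) {
  am <- assemble_matrix(features, block_subset)
  perms <- with_seed(mix_seed(cv$seed, 5077), function() {
    lapply(seq_len(cv$repeats), function(r) sample(as.character(am$y)))
  })
  cv1 <- cv
  cv1$repeats <- 1L
  acc <- vapply(seq_len(cv$repeats), function(r) {
    cv1$seed <- mix_seed(cv$seed, r)
    evaluate_blocks(am, block_subset, cv1, labels = perms[[r]])$overall_accuracy
  }, numeric(1))
  list(accuracy = mean(acc), accuracy_by_repeat = acc)
}

#' Collapse a three-class report to TD vs NDD
#'
#' Relabels retained predictions and truth to TD vs NDD (AS or ID) and
#' recomputes accuracy, absorbing AS/ID confusions.
#'
#' @param report a `start_classification`.
#' @return list(accuracy, per_class_accuracy).
#' @export
collapse_binary <- function(report) {
  collapse <- function(v) ifelse(v == "TD", "TD", "NDD")
  truth <- collapse(report$truth)
  preds <- apply(report$predictions, 2, collapse)
  list(accuracy = mean(preds == truth),
       per_class_accuracy = vapply(c("TD", "NDD"), function(lev) {
         mean(preds[truth == lev, , drop = FALSE] == lev)
       }, numeric(1)))
}

#' Exhaustive feature-block combination search
#'
#' Evaluates every non-empty subset of the given blocks and ranks by mean
#' overall accuracy (ties: fewer blocks, then lexicographic id).
#'
#' @param features a `start_features` data frame.
#' @param blocks block ids to search over (at most 12).
#' @param cv a [cv_config()].
#' @return A data frame of class `start_block_ranking`, best first, with the
#'   full reports in `attr(, "reports")`.
#' @export
search_combinations <- function(features, blocks = names(feature_blocks()),
                                cv = cv_config()) {
  if (length(blocks) > 12) stopf("exhaustive search limited to 12 blocks")
  subsets <- unlist(lapply(seq_along(blocks), function(m) {
    utils::combn(blocks, m, simplify = FALSE)
  }), recursive = FALSE)
  reports <- lapply(subsets, function(bs) evaluate_blocks(features, bs, cv))
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  tab$n_blocks <- lengths(subsets)
  ord <- order(-tab$overall_accuracy, tab$n_blocks, tab$blocks)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, reports = reports[ord],
            class = c("start_block_ranking", "data.frame"))
}

#' Plot a block ranking or classification accuracies
#'
#' Bar plot of mean overall accuracy per evaluated block set, with the
#' chance level for the three-group problem (33.3%) marked.
#'
#' @param x a `start_block_ranking`.
#' @param top show at most this many rows.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.start_block_ranking <- function(x, top = 15, ...) {
  df <- utils::head(as.data.frame(x), top)
  graphics::barplot(rev(100 * df$overall_accuracy), names.arg = rev(df$blocks),
                    horiz = TRUE, las = 1, xlab = "mean overall accuracy (%)",
                    ...)
  graphics::abline(v = 100 / 3, lty = 2)
  invisible(x)
}
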