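# Statistical comparison of edge and node attributes between the true and
# false networks, and classifier-based ranking of node attributes.

EDGE_ATTRS <- c("jaccard", "preferential_attachment", "common_neighbors",
                "resource_allocation")
NODE_ATTRS <- c("degree", "closeness", "eigenvector", "betweenness",
                "clustering_coefficient", "eccentricity")

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero variance.
#' @param name_x,name_y Optional variable names for the result.
#' @return A one-row data frame: `variable_x`, `variable_y`, `r`, `n`.
#' @export
pearson_r <- function(x, y, name_x = "x", name_y = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("variable '", name_x, "' is constant", call. = FALSE)
  if (stats::var(y) == 0) stop("variable '", name_y, "' is constant", call. = FALSE)
  data.frame(variable_x = name_x, variable_y = name_y,
             r = stats::cor(x, y, method = "pearson"), n = length(x),
             stringsAsFactors = FALSE)
}

#' Correlate the STRING combined score with each topological edge attribute
#'
#' On the true network's edges only (false edges carry no interaction score):
#' Pearson r between the STRING combined score and each of the four
#' link-prediction scores. A weak correlation here means the topological
#' scores capture something other than the database's evidence channels.
#'
#' @param true_rows Edge-score rows of origin `TRUE_EDGE` (from
#'   [score_edge_set()]), with a `string_score` column.
#' @return Data frame of four correlation results.
#' @export
correlate_edge_attributes <- function(true_rows) {
  stopifnot(is.data.frame(true_rows))
  if (any(is.na(true_rows$string_score))) {
    stop("string_score missing: correlations need TRUE_EDGE rows", call. = FALSE)
  }
  do.call(rbind, lapply(EDGE_ATTRS, function(a) {
    pearson_r(true_rows$string_score, true_rows[[a]], "string_score", a)
  }))
}

#' Correlation matrix of the six node attributes
#'
#' 6x6 symmetric Pearson correlation matrix with unit diagonal. A constant
#' attribute yields NA in its row/column (reported, not fatal).
#'
#' @param rows Node-attribute rows of a single origin, >= 3 rows.
#' @return A 6x6 numeric matrix with dimnames the attribute names.
#' @export
correlate_node_attributes <- function(rows) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (length(unique(rows$origin)) > 1L) stop("rows must be of a single origin", call. = FALSE)
  m <- as.matrix(rows[, NODE_ATTRS])
  const <- apply(m, 2, function(col) stats::var(col) == 0)
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(r) <- 1
  if (any(const)) {
    warning("constant attribute(s): ", paste(NODE_ATTRS[const], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  r
}

#' Welch's unequal-variance two-sample t test
#'
#' Welch t statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. Used instead of the pooled-variance test because the
#' topological attributes of true and false networks have grossly unequal
#' spreads.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param attribute Optional attribute name carried into the result.
#' @return One-row data frame: `attribute`, `t_stat`, `df`, `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b, attribute = NA_character_) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("both samples are constant: t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  data.frame(attribute = attribute, t_stat = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Rank edge attributes by true-vs-false discrimination
#'
#' One Welch test per link-prediction attribute (4 tests), adjusted for
#' multiplicity, sorted by ascending adjusted p (ties broken by descending
#' |t|). The top attribute is the discriminating edge attribute. If every
#' adjusted p equals 1 the ranking is flagged inconclusive.
#'
#' @param true_rows,false_rows Edge-score rows from [score_edge_set()].
#' @param adjust Multiple-testing correction: `"bonferroni"` (default,
#'   conservative for m = 4) or `"BH"`.
#' @return Data frame of test results with an `adjusted_p` column, sorted;
#'   attributes `top_attribute` (character) and `inconclusive` (logical).
#' @export
rank_edge_attributes <- function(true_rows, false_rows,
                                 adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(nrow(true_rows) > 0L, nrow(false_rows) > 0L)
  res <- do.call(rbind, lapply(EDGE_ATTRS, function(a) {
    welch_t_test(true_rows[[a]], false_rows[[a]], attribute = a)
  }))
  res$adjusted_p <- stats::p.adjust(res$p_value, method = adjust)
  res <- res[order(res$adjusted_p, res$p_value, -abs(res$t_stat)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "top_attribute") <- res$attribute[1]
  attr(res, "inconclusive") <- all(res$adjusted_p >= 1)
  res
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

auc_score <- function(labels, scores) {
  resp <- factor(labels, levels = c(FALSE, TRUE))
  as.numeric(pROC::auc(pROC::roc(resp, scores, quiet = TRUE,
                                 levels = levels(resp), direction = "<")))
}

#' Rank node attributes with a linear and a tree-ensemble classifier
#'
#' Trains a ridge-penalized logistic model and a random forest to separate
#' true-network from false-network node-attribute rows. Per-attribute
#' importances are the absolute standardized ridge coefficients and the
#' forest's mean impurity decrease; attributes are ranked within each method
#' and aggregated by mean rank (ties broken by linear importance). A
#' stratified k-fold cross-validated ROC area for the combined model (average
#' of the two classifiers' fold probabilities) summarizes separability.
#'
#' @param true_rows,false_rows Node-attribute tables (see
#'   [node_attribute_table()]).
#' @param n_folds Number of stratified CV folds (default 5).
#' @param seed Integer seed controlling folds and the forest's bootstrap.
#' @param ridge_lambda Ridge penalty weight (default 1.0).
#' @param n_trees Trees in the ensemble (default 200).
#' @return A list of class `feature_importance_report`: `importance` data
#'   frame (`attribute`, `linear_importance`, `forest_importance`,
#'   `rank_linear`, `rank_forest`, `mean_rank`), `top_attribute`, and
#'   `cv_auc`.
#' @export
rank_node_attributes <- function(true_rows, false_rows, n_folds = 5L, seed = 1L,
                                 ridge_lambda = 1.0, n_trees = 200L) {
  stopifnot(n_folds >= 2L)
  if (nrow(true_rows) == 0L || nrow(false_rows) == 0L) {
    stop("both origins must be represented", call. = FALSE)
  }
  x <- as.matrix(rbind(true_rows[, NODE_ATTRS], false_rows[, NODE_ATTRS]))
  y <- c(rep(TRUE, nrow(true_rows)), rep(FALSE, nrow(false_rows)))
  withr::with_seed(seed, {
    # full-data importances (features standardized; constant columns -> 0)
    xs <- scale(x)
    xs[, attr(xs, "scaled:scale") == 0] <- 0
    fit_lin <- glmnet::glmnet(xs, factor(y), family = "binomial", alpha = 0,
                              lambda = ridge_lambda, standardize = FALSE)
    lin_imp <- abs(as.numeric(fit_lin$beta))
    fit_rf <- randomForest::randomForest(x, factor(y), ntree = n_trees)
    rf_imp <- as.numeric(randomForest::importance(fit_rf)[, 1])
    rank_lin <- rank(-lin_imp, ties.method = "first")
    rank_rf <- rank(-rf_imp, ties.method = "first")
    mean_rank <- (rank_lin + rank_rf) / 2
    ord <- order(mean_rank, -lin_imp)
    # stratified CV of the combined model
    fold <- stratified_folds(y, n_folds)
    prob <- numeric(length(y))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      mu <- colMeans(x[tr, , drop = FALSE])
      sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
      xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
      m1 <- glmnet::glmnet(xtr, factor(y[tr]), family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
      p1 <- as.numeric(predict(m1, xte, type = "response"))
      m2 <- randomForest::randomForest(x[tr, , drop = FALSE], factor(y[tr]),
                                       ntree = n_trees)
      p2 <- predict(m2, x[!tr, , drop = FALSE], type = "prob")[, "TRUE"]
      prob[!tr] <- (p1 + p2) / 2
    }
    cv_auc <- auc_score(y, prob)
  })
  imp <- data.frame(attribute = NODE_ATTRS, linear_importance = lin_imp,
                    forest_importance = rf_imp, rank_linear = rank_lin,
                    rank_forest = rank_rf, mean_rank = mean_rank,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(imp) <- NULL
  structure(list(importance = imp, top_attribute = imp$attribute[1],
                 cv_auc = cv_auc),
            class = "feature_importance_report")
}

#' @export
print.feature_importance_report <- function(x, ...) {
  cat("Node-attribute importance report\n")
  cat(sprintf("  top attribute: %s   cross-validated AUC: %.3f\n",
              x$top_attribute, x$cv_auc))
  print(x$importance, ...)
  invisible(x)
}
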