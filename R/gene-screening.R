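#' Cross-cohort gene intersection
#'
#' Deterministic sorted intersection of two gene-identifier lists, the
#' first step of the screening pipeline when expression comes from two
#' cohorts profiled on different platforms.
#'
#' @param genes_a,genes_b Character vectors of gene identifiers.
#' @return Sorted character vector of the common genes; an empty
#'   intersection is returned with a warning (downstream stages reject
#'   empty panels).
#' @export
intersect_genes <- function(genes_a, genes_b) {
  if (length(genes_a) == 0L || length(genes_b) == 0L) {
    stop("gene lists must be non-empty")
  }
  common <- sort(intersect(unique(genes_a), unique(genes_b)))
  if (length(common) == 0L) {
    warning("empty gene intersection between cohorts")
  }
  common
}

#' Univariate Cox screen over an expression matrix
#'
#' Fits one single-covariate proportional-hazards model per gene
#' (Newton-Raphson on the Breslow partial likelihood, see [cox_fit])
#' after per-gene z-scoring, and selects genes whose Wald p-value falls
#' below `alpha`.  Zero-variance and non-converging genes are marked
#' unestimable and never selected.
#'
#' @param expr Genes x patients numeric matrix with gene identifiers as
#'   row names and patient identifiers as column names.
#' @param data A [surv_data] aligned with (and matched by id to) the
#'   expression columns.
#' @param alpha Significance level for selection (default 0.0116).
#' @param standardize Z-score each gene before fitting (default TRUE).
#' @return A `gene_screen` data frame with one row per gene: `gene`,
#'   `coefficient`, `hazard_ratio`, `se`, `p_value`, `selected`,
#'   `unestimable`.
#' @export
univariate_cox_screen <- function(expr, data, alpha = 0.0116,
                                  standardize = TRUE) {
  expr <- as.matrix(expr)
  data <- as_surv_data(data)
  if (ncol(expr) != nrow(data)) stop("expression columns must match patients")
  if (!is.null(colnames(expr)) &&
      !identical(colnames(expr), data$patient_id)) {
    if (!all(data$patient_id %in% colnames(expr))) {
      stop("expression columns and survival ids do not match")
    }
    expr <- expr[, data$patient_id, drop = FALSE]
  }
  if (sum(data$event) < 1L) stop("at least one event is required")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(expr)))

  n <- nrow(expr)
  coefficient <- se <- p_value <- rep(NA_real_, n)
  unestimable <- rep(FALSE, n)
  for (g in seq_len(n)) {
    v <- expr[g, ]
    if (stats::var(v) == 0) { unestimable[g] <- TRUE; next }
    if (standardize) v <- (v - mean(v)) / stats::sd(v)
    fit <- tryCatch(cox_fit(v, data), error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$se[1])) {
      unestimable[g] <- TRUE
      next
    }
    coefficient[g] <- fit$coefficients[1]
    se[g] <- fit$se[1]
    p_value[g] <- fit$p_values[1]
  }
  out <- data.frame(gene = genes, coefficient = coefficient,
                    hazard_ratio = exp(coefficient), se = se,
                    p_value = p_value,
                    selected = !unestimable & !is.na(p_value) &
                      p_value < alpha,
                    unestimable = unestimable,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("gene_screen", "data.frame")
  out
}

#' Random-forest importance ranking of screened genes
#'
#' Fits a seeded random-forest classifier of event status on the
#' screened genes' expression and ranks genes by impurity (Gini)
#' importance, breaking ties by gene identifier.
#'
#' @param expr Genes x patients matrix restricted to the screened panel.
#' @param events 0/1 event indicators aligned with the columns.
#' @param n_top Number of top genes to keep (default: all).
#' @param seed RNG seed (default 1).
#' @param ntree Number of trees (default 500).
#' @return Data frame `gene`, `importance`, `rank`, ordered by rank,
#'   truncated to `n_top` rows.
#' @export
random_forest_select <- function(expr, events, n_top = NULL, seed = 1L,
                                 ntree = 500L) {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L) stop("screened gene set is empty")
  events <- as.integer(events)
  if (length(events) != ncol(expr)) stop("events must match patients")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(expr)))
  if (is.null(n_top)) n_top <- nrow(expr)
  if (n_top > nrow(expr)) {
    warning("n_top exceeds the number of screened genes; returning all")
    n_top <- nrow(expr)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  x <- t(expr)
  colnames(x) <- genes
  keep <- apply(x, 2, stats::var) > 0
  imp <- stats::setNames(rep(0, length(genes)), genes)
  if (any(keep) && length(unique(events)) > 1L) {
    rf <- randomForest::randomForest(x = x[, keep, drop = FALSE],
                                     y = factor(events, levels = c(0, 1)),
                                     ntree = ntree)
    gi <- rf$importance[, "MeanDecreaseGini"]
    imp[names(gi)] <- gi
  }
  ord <- order(-imp, names(imp))        # ties broken by gene identifier
  out <- data.frame(gene = names(imp)[ord], importance = unname(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  out[seq_len(n_top), , drop = FALSE]
}
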