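#' Disease omics dataset
#'
#' A samples x features numeric table over a [feature_set()], with an
#' optional case/control design used by [test_scores()]. Columns follow the
#' canonical genes-then-metabolites order.
#'
#' @param values numeric matrix, samples in rows, features in columns
#'   (column names must equal `feature_ids(features)` in order).
#' @param features a [feature_set()].
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to the rownames of `values` or `s1, s2, ...`.
#' @param design `"two_group"`, `"paired"` or `"none"`.
#' @param group for `two_group`/`paired` designs, a vector with exactly two
#'   levels (e.g. case/control) aligned with samples; for `paired`, samples
#'   are matched by position within each level, so both levels need equal
#'   counts and `pair` gives the pairing.
#' @param pair for the paired design, a vector identifying pairs (each pair
#'   id appearing once per group level).
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, features, sample_ids = NULL,
                          design = c("none", "two_group", "paired"),
                          group = NULL, pair = NULL) {
  stopifnot(inherits(features, "feature_set"))
  design <- match.arg(design)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- feature_ids(features)
  if (ncol(values) != length(ids))
    stop(sprintf("values has %d columns but the feature set has %d features",
                 ncol(values), length(ids)))
  if (!is.null(colnames(values)) && !identical(colnames(values), ids)) {
    if (!setequal(colnames(values), ids))
      stop("column names do not match the feature set")
    values <- values[, ids, drop = FALSE]
  }
  colnames(values) <- ids
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  rownames(values) <- sample_ids
  if (design %in% c("two_group", "paired")) {
    if (is.null(group) || length(group) != nrow(values))
      stop("design '", design, "' requires a 'group' vector, one per sample")
    group <- as.factor(group)
    if (nlevels(group) != 2L)
      stop("'group' must have exactly two levels")
    if (design == "paired") {
      if (is.null(pair) || length(pair) != nrow(values))
        stop("paired design requires a 'pair' vector, one per sample")
      tab <- table(pair, group)
      if (any(tab != 1L))
        stop("each pair id must appear exactly once per group")
    }
  }
  structure(list(sample_ids = as.character(sample_ids), features = features,
                 values = values, design = design, group = group,
                 pair = pair),
            class = "omics_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %d samples x %d features (%d genes, %d metabolites), design: %s\n",
              nrow(x$values), ncol(x$values), length(x$features$genes),
              length(x$features$metabolites), x$design))
  invisible(x)
}

#' Build the disease similarity matrix from omics profiles
#'
#' Entry (i, j) is the absolute pairwise correlation of feature columns i
#' and j across all samples (cases and controls pooled); the diagonal is 0.
#' The result is a [multi_omics_network()] with `weight_scale =
#' "similarity"`, partitioned into gene-gene, metabolite-metabolite and
#' gene-metabolite blocks. It encodes which interactions the disease data
#' actually supports and drives the network-enhancement walk.
#'
#' Constant feature columns have no defined correlation; they are reported
#' with a warning and given zero similarity to everything. Missing values
#' use pairwise-complete observations; pairs with fewer than 3 complete
#' observations get similarity 0 with a warning.
#'
#' @param data an [omics_dataset()] with at least 3 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A similarity [multi_omics_network()]; entries in `[0, 1]`.
#' @export
build_similarity <- function(data, method = c("pearson", "spearman")) {
  stopifnot(inherits(data, "omics_dataset"))
  method <- match.arg(method)
  X <- data$values
  if (nrow(X) < 3L)
    stop("at least 3 samples are required to estimate correlations")
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const))
    warning(sprintf(
      "%d constant feature column(s) excluded from similarity (e.g. %s)",
      sum(const), paste(utils::head(colnames(X)[const], 3L),
                        collapse = ", ")))
  C <- suppressWarnings(
    stats::cor(X, use = "pairwise.complete.obs", method = method))
  if (anyNA(X)) {
    # zero out pairs with < 3 complete observations
    obs <- crossprod(!is.na(X))
    few <- obs < 3L
    if (any(few & !is.na(C) & row(C) != col(C)))
      warning("feature pairs with fewer than 3 complete observations set to 0")
    C[few] <- 0
  }
  C[is.na(C)] <- 0
  C <- abs(C)
  diag(C) <- 0
  decompose(symmetrize(C), data$features, weight_scale = "similarity")
}

#' Restrict a network and a dataset to their shared features
#'
#' Keeps the intersection of gene identifiers and of metabolite identifiers,
#' in the order of the network's feature set, dropping network rows/columns
#' and data columns outside the intersection. Weights among retained
#' features are preserved exactly.
#'
#' @param net a [multi_omics_network()].
#' @param data an [omics_dataset()].
#' @return `list(net = , data = )` over the shared [feature_set()].
#' @export
harmonize <- function(net, data) {
  stopifnot(inherits(net, "multi_omics_network"),
            inherits(data, "omics_dataset"))
  keep_g <- intersect(net$features$genes, data$features$genes)
  keep_m <- intersect(net$features$metabolites, data$features$metabolites)
  for (side in list(list(keep_g, "gene", net$features$genes,
                         data$features$genes),
                    list(keep_m, "metabolite", net$features$metabolites,
                         data$features$metabolites))) {
    if (length(side[[1L]]) == 0L) {
      miss <- utils::head(setdiff(side[[3L]], side[[4L]]), 5L)
      stop(sprintf(
        "no shared %s identifiers; network-only examples: %s",
        side[[2L]], paste(miss, collapse = ", ")))
    }
  }
  fs <- feature_set(keep_g, keep_m)
  net2 <- subsample_network(net, keep_g, keep_m)
  vals <- data$values[, feature_ids(fs), drop = FALSE]
  data2 <- omics_dataset(vals, fs, sample_ids = data$sample_ids,
                         design = data$design, group = data$group,
                         pair = data$pair)
  list(net = net2, data = data2)
}
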