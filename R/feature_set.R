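#' Ordered gene + metabolite feature set
#'
#' A `feature_set` fixes the canonical index order used by every matrix and
#' vector in the package: genes first, then metabolites. All operations on
#' networks, similarity matrices and score vectors assume this order.
#'
#' @param genes character vector of gene identifiers (non-empty, unique).
#' @param metabolites character vector of metabolite identifiers (non-empty,
#'   unique, disjoint from `genes`).
#' @return An object of class `feature_set` with elements `genes`,
#'   `metabolites`.
#' @examples
#' fs <- feature_set(c("g1", "g2"), "m1")
#' feature_ids(fs)
#' @export
feature_set <- function(genes, metabolites) {
  genes <- as.character(genes)
  metabolites <- as.character(metabolites)
  if (length(genes) == 0L || length(metabolites) == 0L)
    stop("feature_set requires at least one gene and one metabolite")
  if (anyDuplicated(genes) || anyDuplicated(metabolites))
    stop("feature identifiers must be unique within each omics type")
  clash <- intersect(genes, metabolites)
  if (length(clash))
    stop("identifiers used as both gene and metabolite: ",
         paste(utils::head(clash, 5L), collapse = ", "))
  structure(list(genes = genes, metabolites = metabolites),
            class = "feature_set")
}

#' Combined identifiers in canonical (genes-then-metabolites) order
#' @param fs a [feature_set()].
#' @return character vector of length `n_genes + n_metabolites`.
#' @export
feature_ids <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  c(fs$genes, fs$metabolites)
}

#' Feature types in canonical order
#' @param fs a [feature_set()].
#' @return character vector of `"gene"` / `"metabolite"` per feature.
#' @export
feature_types <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  rep(c("gene", "metabolite"),
      c(length(fs$genes), length(fs$metabolites)))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes, %d metabolites\n",
              length(x$genes), length(x$metabolites)))
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$genes) + length(x$metabolites)

same_features <- function(a, b) {
  identical(a$genes, b$genes) && identical(a$metabolites, b$metabolites)
}
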