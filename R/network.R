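#' Block-structured multi-omics network
#'
#' A weighted undirected network over an ordered gene + metabolite feature
#' set, stored as its three blocks: gene-gene (`gg`), metabolite-metabolite
#' (`mm`) and gene-metabolite (`gm`). The full adjacency is the 2x2 block
#' composition `[[gg, gm], [t(gm), mm]]` in canonical (genes-then-
#' metabolites) order; see [compose()].
#'
#' `gg` and `mm` must be symmetric; their diagonals are forced to zero on
#' construction (interaction networks carry no self-edges). All weights are
#' nonnegative, and when `weight_scale = "raw_confidence"` they must not
#' exceed 999, the upper end of the STRING/STITCH confidence scale.
#'
#' @param features a [feature_set()].
#' @param gg genes x genes symmetric nonnegative matrix (or NULL for all
#'   zero).
#' @param mm metabolites x metabolites symmetric nonnegative matrix (or
#'   NULL).
#' @param gm genes x metabolites nonnegative matrix (or NULL).
#' @param mg metabolites x genes block; defaults to `t(gm)`. Only
#'   column-normalized networks may carry an `mg` different from `t(gm)`
#'   (normalization scales columns, breaking the symmetry of the full
#'   matrix).
#' @param weight_scale one of `"raw_confidence"` (0-999 database scores),
#'   `"normalized"` (column-stochastic), `"similarity"` (absolute
#'   correlations in `[0, 1]`). Informational except for range validation.
#' @return An object of class `multi_omics_network`.
#' @examples
#' fs <- feature_set(c("g1", "g2"), "m1")
#' gg <- matrix(c(0, 900, 900, 0), 2)
#' gm <- matrix(c(150, 0), 2, 1)
#' net <- multi_omics_network(fs, gg = gg, gm = gm)
#' compose(net)
#' @export
multi_omics_network <- function(features, gg = NULL, mm = NULL, gm = NULL,
                                mg = NULL,
                                weight_scale = c("raw_confidence",
                                                 "normalized",
                                                 "similarity")) {
  stopifnot(inherits(features, "feature_set"))
  weight_scale <- match.arg(weight_scale)
  ng <- length(features$genes)
  nm <- length(features$metabolites)
  if (is.null(gg)) gg <- matrix(0, ng, ng)
  if (is.null(mm)) mm <- matrix(0, nm, nm)
  if (is.null(gm)) gm <- matrix(0, ng, nm)
  if (is.null(mg)) mg <- t(gm)
  gg <- as_dense(gg); mm <- as_dense(mm); gm <- as_dense(gm)
  mg <- as_dense(mg)
  if (!identical(dim(gg), c(ng, ng)))
    stop(sprintf("gg must be %d x %d", ng, ng))
  if (!identical(dim(mm), c(nm, nm)))
    stop(sprintf("mm must be %d x %d", nm, nm))
  if (!identical(dim(gm), c(ng, nm)))
    stop(sprintf("gm must be %d x %d", ng, nm))
  if (!identical(dim(mg), c(nm, ng)))
    stop(sprintf("mg must be %d x %d", nm, ng))
  if (min(gg) < 0 || min(mm) < 0 || min(gm) < 0 || min(mg) < 0)
    stop("edge weights must be nonnegative")
  # column-normalized networks are legitimately asymmetric (column scaling
  # breaks the symmetry of the full matrix); all other scales must be
  # undirected
  if (weight_scale != "normalized") {
    if (!isSymmetric(unname(gg), tol = 1e-10) ||
        !isSymmetric(unname(mm), tol = 1e-10))
      stop("gg and mm blocks must be symmetric")
    if (max(abs(mg - t(gm))) > 1e-10)
      stop("mg must equal t(gm) for undirected weight scales")
  }
  diag(gg) <- 0
  diag(mm) <- 0
  if (weight_scale == "raw_confidence" &&
      max(gg, mm, gm) > 999)
    stop("raw confidence weights must lie in [0, 999]")
  if (weight_scale == "similarity" && max(gg, mm, gm) > 1 + 1e-12)
    stop("similarity weights must lie in [0, 1]")
  dimnames(gg) <- list(features$genes, features$genes)
  dimnames(mm) <- list(features$metabolites, features$metabolites)
  dimnames(gm) <- list(features$genes, features$metabolites)
  dimnames(mg) <- list(features$metabolites, features$genes)
  structure(list(features = features, gg = gg, mm = mm, gm = gm, mg = mg,
                 weight_scale = weight_scale),
            class = "multi_omics_network")
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) m <- as.matrix(m)
  if (!is.matrix(m)) stop("expected a matrix")
  storage.mode(m) <- "double"
  m
}

#' @export
print.multi_omics_network <- function(x, ...) {
  nz <- function(m) sum(m != 0)
  cat(sprintf(
    "<multi_omics_network> %d genes, %d metabolites (scale: %s)\n",
    length(x$features$genes), length(x$features$metabolites),
    x$weight_scale))
  cat(sprintf("  nonzero entries: gg %d, mm %d, gm %d\n",
              nz(x$gg), nz(x$mm), nz(x$gm)))
  invisible(x)
}

#' Compose a block network into its full adjacency matrix
#'
#' @param net a [multi_omics_network()].
#' @return Square matrix over genes-then-metabolites,
#'   `[[gg, gm], [t(gm), mm]]`, with feature identifiers as dimnames.
#' @export
compose <- function(net) {
  stopifnot(inherits(net, "multi_omics_network"))
  full <- rbind(cbind(net$gg, net$gm),
                cbind(net$mg, net$mm))
  ids <- feature_ids(net$features)
  dimnames(full) <- list(ids, ids)
  full
}

#' Decompose a full adjacency matrix into a block network
#'
#' Inverse of [compose()]: `compose(decompose(M, fs))` reproduces `M`
#' exactly when `M` has the expected block symmetry.
#'
#' @param full square matrix over the canonical feature order.
#' @param features the [feature_set()] defining the block boundaries.
#' @param weight_scale passed to [multi_omics_network()].
#' @return A [multi_omics_network()].
#' @export
decompose <- function(full, features, weight_scale = "raw_confidence") {
  stopifnot(inherits(features, "feature_set"))
  full <- as_dense(full)
  n <- length(features)
  if (!identical(dim(full), c(n, n)))
    stop(sprintf("matrix is %d x %d but the feature set has %d features",
                 nrow(full), ncol(full), n))
  ng <- length(features$genes)
  gi <- seq_len(ng)
  mi <- ng + seq_len(length(features$metabolites))
  multi_omics_network(features,
                      gg = full[gi, gi, drop = FALSE],
                      mm = full[mi, mi, drop = FALSE],
                      gm = full[gi, mi, drop = FALSE],
                      mg = full[mi, gi, drop = FALSE],
                      weight_scale = weight_scale)
}

#' Rebalance the within-omics blocks of a multi-omics network
#'
#' Multiplies the gene-gene block by `lambda_g` and the metabolite-
#' metabolite block by `lambda_m`, leaving the gene-metabolite block
#' untouched. With `lambda_g < 1` and `lambda_m > 1` this compensates for
#' the gene block dominating the network purely by size, so that cross-omics
#' edges can compete during propagation. `lambda_g = lambda_m = 1` is the
#' identity.
#'
#' @param net a [multi_omics_network()].
#' @param lambda_g,lambda_m positive scalars.
#' @return The rebalanced network. If scaling pushes weights outside the
#'   range implied by the `weight_scale` tag, the tag is relabelled
#'   `"normalized"`; the tag is informational only.
#' @export
reweight <- function(net, lambda_g, lambda_m) {
  stopifnot(inherits(net, "multi_omics_network"))
  if (!is.numeric(lambda_g) || length(lambda_g) != 1L || lambda_g <= 0 ||
      !is.numeric(lambda_m) || length(lambda_m) != 1L || lambda_m <= 0)
    stop("lambda_g and lambda_m must be positive scalars")
  out <- net
  out$gg <- net$gg * lambda_g
  out$mm <- net$mm * lambda_m
  # scaling can push weights outside the tagged range; the tag is
  # informational, so relabel rather than reject
  if (net$weight_scale == "raw_confidence" && max(out$gg, out$mm) > 999)
    out$weight_scale <- "normalized"
  if (net$weight_scale == "similarity" && max(out$gg, out$mm) > 1)
    out$weight_scale <- "normalized"
  out
}

#' Symmetrize a square matrix
#'
#' Returns `(M + t(M)) / 2`. Applied to the converged enhancement iterate,
#' whose left-multiplication by the similarity walk breaks the symmetry of
#' the starting network.
#'
#' @param M square numeric matrix.
#' @return Exactly symmetric matrix of the same dimension.
#' @export
symmetrize <- function(M) {
  M <- as_dense(M)
  if (nrow(M) != ncol(M)) stop("symmetrize requires a square matrix")
  (M + t(M)) / 2
}

#' Column-normalize a nonnegative matrix into a (sub)stochastic matrix
#'
#' Every column with a positive sum is divided by its sum. Columns that are
#' entirely zero are left as zero rather than being filled uniformly: an
#' isolated feature should not acquire fabricated interactions, and the
#' restart term of both recursions keeps them well-defined (column sums
#' <= 1 preserve the contraction).
#'
#' @param M nonnegative numeric matrix.
#' @return Matrix whose nonzero columns sum to 1 (within 1e-12).
#' @export
column_normalize <- function(M) {
  M <- as_dense(M)
  if (min(M) < 0) stop("column_normalize requires nonnegative entries")
  cs <- colSums(M)
  pos <- cs > 0
  M[, pos] <- sweep(M[, pos, drop = FALSE], 2L, cs[pos], "/")
  M
}

#' Sparsify a network by keeping only the strongest edges per block
#'
#' Within each block independently, retains the top `ceiling(keep * E)`
#' edges by weight, where `E` is the number of *nonzero* edges in that
#' block, and zeroes the rest. For the symmetric gg and mm blocks an edge is
#' an unordered pair: the cut operates on the upper triangle and is
#' mirrored, so symmetry is preserved. Ties at the cut are broken
#' deterministically by (weight descending, row index, column index).
#'
#' A block with no nonzero edges passes through unchanged with a message.
#'
#' @param net a [multi_omics_network()].
#' @param keep_gg,keep_mm,keep_gm retained fractions in `(0, 1]`.
#' @return The sparsified network. Retained weights are unchanged.
#' @export
denoise <- function(net, keep_gg = 0.05, keep_mm = 0.30, keep_gm = 0.15) {
  stopifnot(inherits(net, "multi_omics_network"))
  for (v in c(keep_gg, keep_mm, keep_gm))
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop("keep fractions must lie in (0, 1]")
  if (max(abs(net$mg - t(net$gm))) > 1e-10)
    stop("denoise requires an undirected network (mg = t(gm)); ",
         "apply it before column normalization")
  out <- net
  out$gg <- denoise_symmetric(net$gg, keep_gg, "gg")
  out$mm <- denoise_symmetric(net$mm, keep_mm, "mm")
  out$gm <- denoise_rectangular(net$gm, keep_gm, "gm")
  out$mg <- t(out$gm)
  out
}

# Top-fraction cut over the upper triangle of a symmetric block, mirrored.
denoise_symmetric <- function(M, keep, label) {
  ut <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) {
    message(sprintf("denoise: block %s has no nonzero edges; left unchanged",
                    label))
    return(M)
  }
  w <- M[ut]
  n_keep <- ceiling(keep * length(w))
  ord <- order(-w, ut[, 1L], ut[, 2L])
  drop <- ord[-seq_len(n_keep)]
  out <- M
  out[ut[drop, , drop = FALSE]] <- 0
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

denoise_rectangular <- function(M, keep, label) {
  nz <- which(M != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    message(sprintf("denoise: block %s has no nonzero edges; left unchanged",
                    label))
    return(M)
  }
  w <- M[nz]
  n_keep <- ceiling(keep * length(w))
  ord <- order(-w, nz[, 1L], nz[, 2L])
  drop <- ord[-seq_len(n_keep)]
  out <- M
  out[nz[drop, , drop = FALSE]] <- 0
  out
}
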