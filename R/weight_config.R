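#' Pipeline configuration: rebalancing weights, walk parameters, denoising
#'
#' Bundles every tunable of the enhancement + diffusion pipeline.
#'
#' The defaults are the values found optimal for a network of roughly 5000
#' genes and 60 metabolites: the gene-gene block is down-weighted
#' (`lambda_g = 0.05`) and the metabolite-metabolite block up-weighted
#' (`lambda_m = 20`) relative to the gene-metabolite block, so that the two
#' within-omics blocks contribute comparably despite the gene block being
#' orders of magnitude larger. More imbalanced networks call for smaller
#' `lambda_g` and larger `lambda_m`.
#'
#' @param lambda_g positive scalar; multiplier on the gene-gene block.
#' @param lambda_m positive scalar; multiplier on the metabolite-metabolite
#'   block.
#' @param alpha restart mixing of the network-enhancement walk, in `[0, 1)`.
#'   `alpha = 0` disables enhancement.
#' @param beta restart mixing of the score diffusion, in `[0, 1)`. `beta = 0`
#'   returns the initial scores unchanged.
#' @param tol convergence tolerance on the entrywise L1 norm of successive
#'   iterates, for both recursions.
#' @param max_iter iteration cap; exceeding it is an error, never a silent
#'   return.
#' @param keep_gg,keep_mm,keep_gm fractions in `(0, 1]` of nonzero edges
#'   retained per block when denoising the enhanced network (top edges by
#'   weight).
#' @param reweight_similarity if `TRUE` (default) the similarity matrix is
#'   rebalanced with the same `lambda_g`/`lambda_m` as the general network;
#'   `FALSE` gives the variant that reweights the general network only.
#' @return An object of class `weight_config`.
#' @examples
#' weight_config()
#' weight_config(lambda_g = 1, lambda_m = 1)  # no rebalancing
#' @export
weight_config <- function(lambda_g = 0.05, lambda_m = 20,
                          alpha = 0.75, beta = 0.75,
                          tol = 1e-6, max_iter = 1000L,
                          keep_gg = 0.05, keep_mm = 0.30, keep_gm = 0.15,
                          reweight_similarity = TRUE) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a positive finite scalar", nm))
  }
  chk_pos(lambda_g, "lambda_g"); chk_pos(lambda_m, "lambda_m")
  chk_pos(tol, "tol")
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1)
      stop(sprintf("'%s' must lie in [0, 1); values >= 1 break contraction",
                   nm))
  }
  for (nm in c("keep_gg", "keep_mm", "keep_gm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(sprintf("'%s' must lie in (0, 1]", nm))
  }
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("'max_iter' must be >= 1")
  structure(list(lambda_g = lambda_g, lambda_m = lambda_m,
                 alpha = alpha, beta = beta, tol = tol, max_iter = max_iter,
                 keep_gg = keep_gg, keep_mm = keep_mm, keep_gm = keep_gm,
                 reweight_similarity = isTRUE(reweight_similarity)),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>\n")
  cat(sprintf("  lambda_g = %g, lambda_m = %g (reweight similarity: %s)\n",
              x$lambda_g, x$lambda_m, x$reweight_similarity))
  cat(sprintf("  alpha = %g, beta = %g, tol = %g, max_iter = %d\n",
              x$alpha, x$beta, x$tol, x$max_iter))
  cat(sprintf("  keep fractions: gg %g, mm %g, gm %g\n",
              x$keep_gg, x$keep_mm, x$keep_gm))
  invisible(x)
}
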