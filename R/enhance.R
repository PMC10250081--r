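#' Random-walk-with-restart fixed point for a matrix-valued state
#'
#' Iterates `S_{t+1} = alpha * E_norm %*% S_t + (1 - alpha) * S0` from
#' `S_0 = S0` until the entrywise L1 norm of the difference of successive
#' iterates drops below `tol`. For `alpha < 1` and column sums of `E_norm`
#' at most 1 the map is a contraction with factor `alpha`, so convergence is
#' guaranteed; reaching `max_iter` first is an error carrying the last
#' residual.
#'
#' The fixed point solves `S* = (1 - alpha) * solve(I - alpha E_norm) %*%
#' S0`; `solver = "direct"` computes it that way in one linear solve, useful
#' for small problems and as an independent cross-check of the iteration.
#'
#' When `E_norm` is sparse (nonzero fraction below `sparse_threshold`) the
#' multiplications run through a `Matrix::dgCMatrix`; results agree with the
#' dense path to well below the convergence tolerance.
#'
#' @param E_norm column-(sub)stochastic square matrix driving the walk.
#' @param S0 matrix (or vector) of the same row dimension; the restart
#'   state.
#' @param alpha restart mixing in `[0, 1)`.
#' @param tol entrywise L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @param solver `"iterative"` (default) or `"direct"`.
#' @param sparse_threshold nonzero fraction below which the sparse
#'   representation is used for the iterative products.
#' @return The converged matrix, with attributes `iterations` and
#'   `residual` (iterative solver only).
#' @export
rwr_matrix <- function(E_norm, S0, alpha, tol = 1e-6, max_iter = 1000L,
                       solver = c("iterative", "direct"),
                       sparse_threshold = 0.05) {
  solver <- match.arg(solver)
  E_norm <- as_dense(E_norm)
  vec_in <- !is.matrix(S0)
  S0 <- if (vec_in) matrix(as.numeric(S0), ncol = 1L) else as_dense(S0)
  if (nrow(E_norm) != ncol(E_norm)) stop("E_norm must be square")
  if (nrow(S0) != nrow(E_norm)) stop("dimensions of E_norm and S0 disagree")
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  cs <- colSums(E_norm)
  if (any(cs > 1 + 1e-8))
    stop("E_norm column sums must not exceed 1")
  if (alpha == 0) {
    out <- S0
    attr(out, "iterations") <- 1L
    attr(out, "residual") <- 0
    return(finish_rwr(out, vec_in))
  }
  if (solver == "direct") {
    n <- nrow(E_norm)
    out <- (1 - alpha) * solve(diag(n) - alpha * E_norm, S0)
    return(finish_rwr(out, vec_in))
  }
  E_op <- if (mean(E_norm != 0) < sparse_threshold)
    Matrix::Matrix(E_norm, sparse = TRUE) else E_norm
  S <- S0
  restart <- (1 - alpha) * S0
  for (it in seq_len(max_iter)) {
    S_new <- as.matrix(alpha * (E_op %*% S)) + restart
    res <- sum(abs(S_new - S))
    S <- S_new
    if (res < tol) {
      attr(S, "iterations") <- it
      attr(S, "residual") <- res
      return(finish_rwr(S, vec_in))
    }
  }
  stop(sprintf(
    "random walk did not converge in %d iterations (last residual %.3e)",
    max_iter, res))
}

finish_rwr <- function(S, vec_in) {
  if (vec_in) {
    out <- drop(S[, 1L])
    attr(out, "iterations") <- attr(S, "iterations")
    attr(out, "residual") <- attr(S, "residual")
    out
  } else S
}

#' Enhance a general network into a disease-specific network
#'
#' Runs the full enhancement pipeline. In order: (1) rebalance the general
#' network with `(lambda_g, lambda_m)`; (2) rebalance the similarity matrix
#' the same way (skipped when `cfg$reweight_similarity` is off, giving the
#' general-network-only reweighting variant); (3) column-normalize the
#' composed similarity matrix; (4) run the random walk with restart,
#' driving the rebalanced general network toward the disease similarity
#' structure; (5) symmetrize the converged matrix; (6) sparsify each block,
#' keeping the `keep_gg`/`keep_mm`/`keep_gm` strongest edges; (7)
#' column-normalize the result.
#'
#' Normalization acts on the composed full matrix, not per block, so the
#' blocks compete within each column exactly as the rebalancing intends.
#'
#' @param net general [multi_omics_network()].
#' @param sim similarity [multi_omics_network()] over the same features.
#' @param cfg a [weight_config()].
#' @param solver passed to [rwr_matrix()].
#' @return The enhanced network with `weight_scale = "normalized"`, carrying
#'   attributes `iterations` and `residual` from the walk.
#' @export
enhance <- function(net, sim, cfg = weight_config(),
                    solver = c("iterative", "direct")) {
  stopifnot(inherits(net, "multi_omics_network"),
            inherits(sim, "multi_omics_network"),
            inherits(cfg, "weight_config"))
  solver <- match.arg(solver)
  if (!same_features(net$features, sim$features))
    stop("network and similarity matrix must share the same feature set; ",
         "run harmonize() first")
  s0t <- compose(reweight(net, cfg$lambda_g, cfg$lambda_m))
  sim_w <- if (cfg$reweight_similarity)
    reweight(sim, cfg$lambda_g, cfg$lambda_m) else sim
  e_norm <- column_normalize(compose(sim_w))
  st <- rwr_matrix(e_norm, s0t, cfg$alpha, tol = cfg$tol,
                   max_iter = cfg$max_iter, solver = solver)
  its <- attr(st, "iterations"); res <- attr(st, "residual")
  se <- decompose(symmetrize(st), net$features, weight_scale = "normalized")
  se <- denoise(se, cfg$keep_gg, cfg$keep_mm, cfg$keep_gm)
  se <- decompose(column_normalize(compose(se)), net$features,
                  weight_scale = "normalized")
  attr(se, "iterations") <- its
  attr(se, "residual") <- res
  se
}
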