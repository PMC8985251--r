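# Regularized latent factor model trained by stochastic gradient descent,
# plus the truncated-SVD baseline.

#' Latent factor model configuration
#'
#' @param n_factors Number of latent factors |F|.
#' @param reg_lambda L2 regularization weight lambda (>= 0).
#' @param learning_rate SGD step size alpha (> 0).
#' @param max_epochs Maximum number of full passes over the matrix cells.
#' @param tol Convergence threshold on the relative change of the cost
#'   between consecutive epochs.
#' @param seed Integer seed controlling initialization and cell shuffling.
#' @param init_scale Factor entries initialized uniformly on
#'   `(0, init_scale / sqrt(n_factors))`.
#' @param nonzero_only If TRUE, only nonzero cells of the training matrix
#'   are visited by SGD (ablation switch; default visits all cells).
#' @return A list of class `lfm_config`.
#' @export
lfm_config <- function(n_factors = 20L, reg_lambda = 0.01, learning_rate = 0.01,
                       max_epochs = 200L, tol = 1e-5, seed = 1L,
                       init_scale = 0.1, nonzero_only = FALSE) {
  stopifnot(n_factors >= 1L, reg_lambda >= 0, learning_rate > 0,
            max_epochs >= 1L, tol >= 0, init_scale >= 0)
  structure(list(n_factors = as.integer(n_factors), reg_lambda = reg_lambda,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed), init_scale = init_scale,
                 nonzero_only = isTRUE(nonzero_only)),
            class = "lfm_config")
}

# run expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Initialize latent factor matrices
#'
#' Entries are drawn uniformly from `(0, init_scale / sqrt(n_factors))`;
#' deterministic given the config seed.
#'
#' @param n_diseases,n_metabolites Dimensions.
#' @param config An [lfm_config()].
#' @return List with `dlf` (|D| x F) and `mlf` (|M| x F).
#' @export
init_factors <- function(n_diseases, n_metabolites, config) {
  stopifnot(n_diseases >= 1L, n_metabolites >= 1L)
  hi <- config$init_scale / sqrt(config$n_factors)
  .with_seed(config$seed, {
    list(dlf = matrix(stats::runif(n_diseases * config$n_factors, 0, hi),
                      n_diseases, config$n_factors),
         mlf = matrix(stats::runif(n_metabolites * config$n_factors, 0, hi),
                      n_metabolites, config$n_factors))
  })
}

#' Predicted association score for one cell
#'
#' Inner product of the disease and metabolite latent rows.
#'
#' @param factors List with `dlf` and `mlf`.
#' @param d,m Disease (column) and metabolite (row) indices.
#' @export
predict_cell <- function(factors, d, m) {
  stopifnot(d >= 1L, d <= nrow(factors$dlf), m >= 1L, m <= nrow(factors$mlf))
  sum(factors$dlf[d, ] * factors$mlf[m, ])
}

#' Cost of a factor pair on a training matrix
#'
#' Sum of squared residuals over all cells plus `lambda/2` times the total
#' squared Frobenius norm of both factor matrices (the regularizer is
#' accumulated once per row, not once per visited cell).
#'
#' @param values Training matrix (|M| x |D|).
#' @param factors List with `dlf`, `mlf`.
#' @param reg_lambda Regularization weight.
#' @export
lfm_cost <- function(values, factors, reg_lambda) {
  R <- values - factors$mlf %*% t(factors$dlf)
  sum(R^2) + reg_lambda / 2 * (sum(factors$dlf^2) + sum(factors$mlf^2))
}

#' Per-cell stochastic gradients
#'
#' Partial derivatives of the per-cell loss with respect to the disease and
#' metabolite latent rows: `-2 * err * other_row + lambda * row` where
#' `err = MDR[m,d] - prediction`.
#'
#' @param values Training matrix.
#' @param factors Factor pair.
#' @param d,m Cell indices.
#' @param reg_lambda Regularization weight.
#' @return List with `d_dlf` and `d_mlf` gradient vectors (length F).
#' @export
cell_gradients <- function(values, factors, d, m, reg_lambda) {
  err <- values[m, d] - predict_cell(factors, d, m)
  list(d_dlf = -2 * err * factors$mlf[m, ] + reg_lambda * factors$dlf[d, ],
       d_mlf = -2 * err * factors$dlf[d, ] + reg_lambda * factors$mlf[m, ])
}

#' Train the latent factor model by stochastic gradient descent
#'
#' Each epoch visits the training cells in a freshly shuffled (seeded) order
#' and updates the corresponding disease and metabolite latent rows by
#' stepping against the per-cell gradient.  By default all |M| x |D| cells of
#' the (completed) matrix are training targets — zeros included; with
#' `nonzero_only` in the config only nonzero cells are visited.  Training
#' stops at `max_epochs` or when the relative cost change between epochs
#' drops below `tol`.
#'
#' @param values Training matrix (|M| x |D|), e.g. the completed association
#'   matrix.
#' @param config An [lfm_config()].
#' @param factors Optional starting factor pair (defaults to
#'   [init_factors()] under the config seed).
#' @return List with `factors` (trained pair) and `trace` (list:
#'   `epoch_costs`, `converged`, `epochs_run`).
#' @export
lfm_train <- function(values, config = lfm_config(), factors = NULL) {
  stopifnot(is.matrix(values), nrow(values) >= 1L, ncol(values) >= 1L)
  if (is.null(factors))
    factors <- init_factors(ncol(values), nrow(values), config)
  dlf <- factors$dlf + 0   # force copies: the C++ kernel updates in place
  mlf <- factors$mlf + 0
  cells <- if (config$nonzero_only) which(values != 0) else seq_along(values)
  if (length(cells) == 0L) stop("no training cells (all-zero matrix with nonzero_only)")
  costs <- numeric(0)
  prev <- lfm_cost(values, list(dlf = dlf, mlf = mlf), config$reg_lambda)
  converged <- FALSE
  .with_seed(config$seed + 1L, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- cells[sample.int(length(cells))]
      ok <- .sgd_epoch(values, dlf, mlf, ord,
                       config$learning_rate, config$reg_lambda)
      if (!ok) stop("training diverged (non-finite factors); ",
                    "reduce learning_rate")
      cost <- lfm_cost(values, list(dlf = dlf, mlf = mlf), config$reg_lambda)
      if (!is.finite(cost)) stop("training diverged (non-finite cost); ",
                                 "reduce learning_rate")
      costs <- c(costs, cost)
      if (abs(cost - prev) / max(prev, 1e-12) < config$tol) {
        converged <- TRUE
        break
      }
      prev <- cost
    }
  })
  dimnames(dlf) <- list(colnames(values), paste0("F", seq_len(config$n_factors)))
  dimnames(mlf) <- list(rownames(values), paste0("F", seq_len(config$n_factors)))
  list(factors = list(dlf = dlf, mlf = mlf),
       trace = list(epoch_costs = costs, converged = converged,
                    epochs_run = length(costs)))
}

#' Final association predictions from trained factors
#'
#' Reconstructs the matrix as `MLF %*% t(DLF)` and forces initially-known
#' cells to exactly 1; optionally clamps the remaining cells to `[0, 1]`
#' (clamping never reorders two unclamped cells).
#'
#' @param factors Trained factor pair.
#' @param init The initial 0-1 `association_matrix`.
#' @param clip Clamp predictions into `[0, 1]`?
#' @return A matrix of class `prediction_matrix` with attributes `clipped`
#'   and `known` (logical mask of forced cells).
#' @export
finalize_predictions <- function(factors, init, clip = FALSE) {
  P <- factors$mlf %*% t(factors$dlf)
  dimnames(P) <- dimnames(init$values)
  known <- init$values == 1
  if (clip) P <- pmin(pmax(P, 0), 1)
  P[known] <- 1
  structure(P, clipped = clip, known = known, class = c("prediction_matrix", class(P)))
}

#' Truncated-SVD baseline predictions
#'
#' Rank-k singular value reconstruction of the completed matrix, with the
#' known-cell overlay applied as in [finalize_predictions()].
#'
#' @param mdr Completed `association_matrix`.
#' @param k Rank, `1 <= k <= min(|M|, |D|)`.
#' @param init Initial 0-1 matrix (defaults to the `initial` component of
#'   `mdr` when present).
#' @param clip Clamp predictions into `[0, 1]`?
#' @export
svd_baseline <- function(mdr, k, init = NULL, clip = FALSE) {
  V <- mdr$values
  if (k < 1L || k > min(dim(V))) stop("rank k out of range")
  s <- svd(V, nu = k, nv = k)
  R <- s$u %*% (diag(s$d[seq_len(k)], k, k)) %*% t(s$v)
  dimnames(R) <- dimnames(V)
  if (is.null(init))
    init <- list(values = if (!is.null(mdr$initial)) mdr$initial else (V == 1) * 1)
  known <- init$values == 1
  if (clip) R <- pmin(pmax(R, 0), 1)
  R[known] <- 1
  structure(R, clipped = clip, known = known, class = c("prediction_matrix", class(R)))
}
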