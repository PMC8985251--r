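# Central fit: similarity completion + latent factor factorization,
# presented as a classic R modelling object.

#' Fit a disease-metabolite association model
#'
#' Builds the initial 0-1 association matrix from the known pairs, completes
#' its unknown cells from disease similarity and metabolite literature
#' similarity (noisy-OR of the two channel fills), factorizes the completed
#' matrix with an L2-regularized latent factor model trained by stochastic
#' gradient descent, and forces known cells back to 1 in the final
#' predictions.
#'
#' Variants select which completion feeds the factorization: `"full"` uses
#' the noisy-OR of both channels, `"disease_only"` / `"metabolite_only"` use
#' a single channel, `"init"` factorizes the raw 0-1 matrix.  The backend
#' can be swapped for a truncated SVD (`backend = "svd"`); the unregularized
#' model is simply `reg_lambda = 0`.
#'
#' @param pairs data.frame of known (metabolite_id, disease_id) associations.
#' @param disease_sim Symmetric disease similarity matrix in `[0,1]` with
#'   dimnames (an external input, e.g. gene-network-based semantic
#'   similarity).  `NULL` disables the disease channel.
#' @param metabolite_sim Symmetric metabolite similarity matrix (e.g. from
#'   [metabolite_similarity_from_scores()]).  `NULL` disables the channel.
#' @param metabolite_labels,disease_labels Row/column universes; default to
#'   the identifiers occurring in `pairs`.
#' @param variant One of `"full"`, `"disease_only"`, `"metabolite_only"`,
#'   `"init"`.
#' @param backend `"sgd"` (latent factor model) or `"svd"`.
#' @param config An [lfm_config()]; for the SVD backend only `n_factors`
#'   (the rank) is used.
#' @param clip Clamp final predictions into `[0,1]`?
#' @return An object of class `dmlfm`: list with `initial`, `completed`
#'   (association matrices), `factors`, `trace`, `predictions`, `coverage`,
#'   `config`, `variant`, `backend`, `call`.
#' @examples
#' pairs <- data.frame(metabolite = c("m1", "m2"), disease = c("d1", "d2"))
#' fit <- dmlfm(pairs, metabolite_labels = c("m1", "m2", "m3"),
#'              disease_labels = c("d1", "d2"),
#'              config = lfm_config(n_factors = 2, max_epochs = 20))
#' print(fit)
#' @export
dmlfm <- function(pairs, disease_sim = NULL, metabolite_sim = NULL,
                  metabolite_labels = NULL, disease_labels = NULL,
                  variant = c("full", "disease_only", "metabolite_only", "init"),
                  backend = c("sgd", "svd"),
                  config = lfm_config(), clip = FALSE) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  if (is.null(metabolite_labels)) metabolite_labels <- sort(unique(as.character(pairs[[1]])))
  if (is.null(disease_labels)) disease_labels <- sort(unique(as.character(pairs[[2]])))
  init <- build_initial_matrix(pairs, metabolite_labels, disease_labels)

  zero <- function() matrix(0, nrow(init$values), ncol(init$values),
                            dimnames = dimnames(init$values))
  use_d <- variant %in% c("full", "disease_only") && !is.null(disease_sim)
  use_m <- variant %in% c("full", "metabolite_only") && !is.null(metabolite_sim)
  DF <- if (use_d) disease_fill(init, disease_sim) else init$values
  MF <- if (use_m) metabolite_fill(init, metabolite_sim) else zero()
  if (!use_d && use_m) DF <- zero()   # single metabolite channel
  if (!use_d && !use_m) { DF <- init$values; MF <- zero() }  # init variant
  completed <- combine_fills(DF, MF, init)

  if (backend == "sgd") {
    tr <- lfm_train(completed$values, config)
    factors <- tr$factors
    trace <- tr$trace
    predictions <- finalize_predictions(factors, init, clip = clip)
  } else {
    factors <- NULL
    trace <- NULL
    predictions <- svd_baseline(completed, k = config$n_factors,
                                init = init, clip = clip)
  }
  structure(list(initial = init, completed = completed, factors = factors,
                 trace = trace, predictions = predictions,
                 coverage = coverage_stats(completed), config = config,
                 variant = variant, backend = backend,
                 call = match.call()),
            class = "dmlfm")
}

#' @export
print.dmlfm <- function(x, ...) {
  cat("Disease-metabolite latent factor fit (variant:", x$variant,
      "| backend:", x$backend, ")\n")
  cat(sprintf("  %d metabolites x %d diseases, %d known associations\n",
              nrow(x$initial$values), ncol(x$initial$values),
              sum(x$initial$values == 1)))
  cat(sprintf("  completion coverage: %.2f%%\n", x$coverage$coverage_rate))
  if (!is.null(x$trace))
    cat(sprintf("  SGD: %d factors, %d epochs, final cost %.6g%s\n",
                x$config$n_factors, x$trace$epochs_run,
                utils::tail(x$trace$epoch_costs, 1),
                if (x$trace$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
summary.dmlfm <- function(object, ...) {
  structure(list(fit = object, coverage = object$coverage,
                 n_known = sum(object$initial$values == 1),
                 dims = dim(object$initial$values)),
            class = "summary.dmlfm")
}

#' @export
print.summary.dmlfm <- function(x, ...) {
  print(x$fit)
  cs <- x$coverage
  cat("Completion cell counts:\n")
  cat(sprintf("  known %d | disease-fill %d | metabolite-fill %d | both %d | empty %d\n",
              cs$n_known, cs$n_disease_only, cs$n_metabolite_only,
              cs$n_both, cs$n_empty))
  if (!is.null(x$fit$trace)) {
    tc <- x$fit$trace$epoch_costs
    cat(sprintf("Cost: first %.6g -> last %.6g over %d epochs\n",
                tc[1], utils::tail(tc, 1), length(tc)))
  }
  invisible(x)
}

#' Extract latent factor matrices
#'
#' @param object A `dmlfm` fit (SGD backend).
#' @param ... Unused.
#' @return List with `disease` (|D| x F) and `metabolite` (|M| x F) factors.
#' @export
coef.dmlfm <- function(object, ...) {
  if (is.null(object$factors)) return(NULL)
  list(disease = object$factors$dlf, metabolite = object$factors$mlf)
}

#' Reconstruction of the completed matrix
#' @param object A `dmlfm` fit.
#' @param ... Unused.
#' @export
fitted.dmlfm <- function(object, ...) {
  if (object$backend == "svd") return(unclass(object$predictions))
  R <- object$factors$mlf %*% t(object$factors$dlf)
  dimnames(R) <- dimnames(object$completed$values)
  R
}

#' Residuals of the factorization against the completed matrix
#' @param object A `dmlfm` fit.
#' @param ... Unused.
#' @export
residuals.dmlfm <- function(object, ...) {
  object$completed$values - fitted(object)
}

#' Predicted association scores or ranked candidates
#'
#' With `ranked = FALSE` returns the full prediction matrix (known cells
#' forced to 1).  With `ranked = TRUE` returns, per requested disease, the
#' candidate metabolites sorted by decreasing predicted score; metabolites
#' already known for the disease are excluded unless `include_known = TRUE`
#' (they then lead the ranking with score 1).  Ties are broken by metabolite
#' identifier for reproducibility.
#'
#' @param object A `dmlfm` fit.
#' @param diseases Disease identifiers (default: all).
#' @param ranked Return ranked candidate tables instead of the matrix?
#' @param include_known Keep known metabolites in the ranking?
#' @param ... Unused.
#' @return Matrix, or a data.frame with columns disease_id, metabolite_id,
#'   score, rank, known.
#' @export
predict.dmlfm <- function(object, diseases = NULL, ranked = FALSE,
                          include_known = FALSE, ...) {
  P <- object$predictions
  if (!ranked) return(P)
  if (is.null(diseases)) diseases <- colnames(P)
  missing <- setdiff(diseases, colnames(P))
  if (length(missing)) stop("unknown disease label: ", missing[1])
  out <- lapply(diseases, function(d) {
    known <- object$initial$values[, d] == 1
    keep <- if (include_known) rep(TRUE, nrow(P)) else !known
    df <- data.frame(disease_id = d,
                     metabolite_id = rownames(P)[keep],
                     score = P[keep, d],
                     known = known[keep], stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$metabolite_id), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot the training cost trace
#'
#' @param x A `dmlfm` fit with an SGD trace.
#' @param ... Passed to [plot()].
#' @export
plot.dmlfm <- function(x, ...) {
  if (is.null(x$trace)) stop("no training trace (SVD backend)")
  plot(seq_along(x$trace$epoch_costs), x$trace$epoch_costs, type = "b",
       xlab = "epoch", ylab = "cost", main = "SGD training cost", ...)
  invisible(x)
}
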