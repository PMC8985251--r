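# Validation: data-increment test sets over two association-map versions,
# per-disease AUC, leave-one-out cross-validation, ablation harness.

#' Construct an association-map version
#'
#' @param pairs data.frame of (metabolite_id, disease_id).
#' @param metabolites,diseases Entity universes (default: ids in `pairs`).
#' @param tag Version label.
#' @return A list of class `assoc_map_version`.
#' @export
assoc_map_version <- function(pairs, metabolites = NULL, diseases = NULL,
                              tag = "v") {
  m <- as.character(pairs[[1]]); d <- as.character(pairs[[2]])
  if (is.null(metabolites)) metabolites <- sort(unique(m))
  if (is.null(diseases)) diseases <- sort(unique(d))
  stopifnot(all(m %in% metabolites), all(d %in% diseases))
  structure(list(tag = tag, pairs = unique(paste(m, d, sep = "\r")),
                 pair_df = unique(data.frame(metabolite_id = m, disease_id = d,
                                             stringsAsFactors = FALSE)),
                 metabolites = metabolites, diseases = diseases),
            class = "assoc_map_version")
}

#' Extract data-increment test sets from two association-map versions
#'
#' A disease qualifies when at least one metabolite in the intersection of
#' the two metabolite universes is associated with it in BOTH versions (a
#' "detection target").  Its positives are metabolites in the intersection
#' associated in version 2 but not in version 1; its negatives are all
#' version-1 metabolites never associated with it in either version.
#' Diseases with no positive are dropped.
#'
#' @param v1,v2 `assoc_map_version` objects (older, newer).
#' @return List of test sets, each a list with `disease_id`, `positives`,
#'   `negatives`.
#' @export
extract_incremental_test_sets <- function(v1, v2) {
  stopifnot(inherits(v1, "assoc_map_version"), inherits(v2, "assoc_map_version"))
  common_m <- intersect(v1$metabolites, v2$metabolites)
  p1 <- v1$pair_df; p2 <- v2$pair_df
  out <- list()
  for (d in sort(unique(v1$diseases))) {
    m1d <- p1$metabolite_id[p1$disease_id == d]
    m2d <- p2$metabolite_id[p2$disease_id == d]
    # detection-target condition: some common metabolite in both versions
    if (!length(intersect(intersect(m1d, m2d), common_m))) next
    positives <- sort(setdiff(intersect(m2d, common_m), m1d))
    if (!length(positives)) next
    negatives <- sort(setdiff(v1$metabolites, union(m1d, m2d)))
    out[[length(out) + 1L]] <- list(disease_id = d, positives = positives,
                                    negatives = negatives)
  }
  out
}

#' Area under the ROC curve from score lists
#'
#' Normalized Mann-Whitney U: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties credited one half.
#'
#' @param positive_scores,negative_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_scores <- function(positive_scores, negative_scores) {
  np <- length(positive_scores); nn <- length(negative_scores)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: empty positive or negative score list")
  r <- rank(c(positive_scores, negative_scores), ties.method = "average")
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nn)
}

#' Evaluate predictions on a collection of test sets
#'
#' Scores each disease's positives and negatives from its prediction column
#' and reports the per-disease AUC and the unweighted mean.
#'
#' @param predictions A `prediction_matrix` (or plain labeled matrix).
#' @param test_sets Output of [extract_incremental_test_sets()].
#' @return A list of class `evaluation_report`: data.frame `per_disease`
#'   (disease_id, n_pos, n_neg, auc), `mean_auc`, `n_diseases`.
#' @export
evaluate_predictions <- function(predictions, test_sets) {
  rows <- lapply(test_sets, function(ts) {
    miss <- setdiff(c(ts$positives, ts$negatives), rownames(predictions))
    if (length(miss)) stop("metabolite missing from predictions: ", miss[1])
    if (!ts$disease_id %in% colnames(predictions))
      stop("disease missing from predictions: ", ts$disease_id)
    col <- predictions[, ts$disease_id]
    data.frame(disease_id = ts$disease_id,
               n_pos = length(ts$positives), n_neg = length(ts$negatives),
               auc = auc_scores(col[ts$positives], col[ts$negatives]),
               stringsAsFactors = FALSE)
  })
  per <- if (length(rows)) do.call(rbind, rows)
         else data.frame(disease_id = character(), n_pos = integer(),
                         n_neg = integer(), auc = numeric())
  structure(list(per_disease = per,
                 mean_auc = if (nrow(per)) mean(per$auc) else NA_real_,
                 n_diseases = nrow(per)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d diseases: mean AUC %.4f\n",
              x$n_diseases, x$mean_auc))
  invisible(x)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' Each known (metabolite, disease) pair is removed in turn; the completion
#' and factorization are rebuilt on the remaining pairs and the held-out
#' metabolite is scored against all metabolites never associated with that
#' disease.  Per-fold AUC (single positive vs. the negatives) and the
#' unweighted mean are reported.
#'
#' @param pairs Known association pairs (>= 2 rows).
#' @param disease_sim,metabolite_sim Similarity matrices as in [dmlfm()].
#' @param config An [lfm_config()].
#' @param variant,backend Passed to [dmlfm()].
#' @return An `evaluation_report` whose `per_disease` rows are folds
#'   (one per held-out pair, column `metabolite_id` added).
#' @export
loocv <- function(pairs, disease_sim = NULL, metabolite_sim = NULL,
                  config = lfm_config(), variant = "full", backend = "sgd") {
  pairs <- unique(data.frame(metabolite_id = as.character(pairs[[1]]),
                             disease_id = as.character(pairs[[2]]),
                             stringsAsFactors = FALSE))
  stopifnot(nrow(pairs) >= 2L)
  mlab <- sort(unique(pairs$metabolite_id))
  dlab <- sort(unique(pairs$disease_id))
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    held <- pairs[k, ]
    fit <- dmlfm(pairs[-k, ], disease_sim, metabolite_sim,
                 metabolite_labels = mlab, disease_labels = dlab,
                 variant = variant, backend = backend, config = config)
    col <- fit$predictions[, held$disease_id]
    neg <- setdiff(mlab, pairs$metabolite_id[pairs$disease_id == held$disease_id])
    if (!length(neg)) next   # disease linked to every metabolite: no fold
    rows[[k]] <- data.frame(disease_id = held$disease_id,
                            metabolite_id = held$metabolite_id,
                            n_pos = 1L, n_neg = length(neg),
                            auc = auc_scores(col[held$metabolite_id], col[neg]),
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(per_disease = per, mean_auc = mean(per$auc),
                 n_diseases = nrow(per)),
            class = "evaluation_report")
}

#' Run one ablation variant of the prediction pipeline
#'
#' Variants: `"init"` factorizes the raw 0-1 matrix; `"disease_only"` /
#' `"metabolite_only"` factorize a single-channel completion; `"full"` the
#' noisy-OR completion; `"svd"` swaps the factorization for a truncated SVD
#' of the full completion; `"lfm_nr"` is the full completion trained without
#' regularization.
#'
#' @param pairs Known association pairs.
#' @param disease_sim,metabolite_sim Similarity matrices.
#' @param config An [lfm_config()].
#' @param variant One of init, disease_only, metabolite_only, full, svd,
#'   lfm_nr.
#' @param ... Passed to [dmlfm()] (e.g. label universes).
#' @return The `prediction_matrix` of the fitted variant.
#' @export
run_ablation <- function(pairs, disease_sim = NULL, metabolite_sim = NULL,
                         config = lfm_config(),
                         variant = c("full", "init", "disease_only",
                                     "metabolite_only", "svd", "lfm_nr"),
                         ...) {
  variant <- match.arg(variant)
  fit <- switch(variant,
    full = dmlfm(pairs, disease_sim, metabolite_sim, variant = "full",
                 config = config, ...),
    init = dmlfm(pairs, disease_sim, metabolite_sim, variant = "init",
                 config = config, ...),
    disease_only = dmlfm(pairs, disease_sim, metabolite_sim,
                         variant = "disease_only", config = config, ...),
    metabolite_only = dmlfm(pairs, disease_sim, metabolite_sim,
                            variant = "metabolite_only", config = config, ...),
    svd = dmlfm(pairs, disease_sim, metabolite_sim, variant = "full",
                backend = "svd", config = config, ...),
    lfm_nr = {
      cfg <- config; cfg$reg_lambda <- 0
      dmlfm(pairs, disease_sim, metabolite_sim, variant = "full",
            config = cfg, ...)
    })
  fit$predictions
}
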