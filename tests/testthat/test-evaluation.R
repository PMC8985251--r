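test_that("data-increment extraction follows the two-version rules", {
  v1 <- assoc_map_version(data.frame(m = "m1", d = "d1"),
                          metabolites = c("m1", "m2"), diseases = "d1")
  v2 <- assoc_map_version(data.frame(m = c("m1", "m2"), d = c("d1", "d1")),
                          metabolites = c("m1", "m2"), diseases = "d1")
  ts <- extract_incremental_test_sets(v1, v2)
  expect_length(ts, 1L)
  expect_equal(ts[[1]]$disease_id, "d1")
  expect_equal(ts[[1]]$positives, "m2")
  expect_length(ts[[1]]$negatives, 0L)

  # a version-2 metabolite outside the version-1 universe is not a positive
  v2b <- assoc_map_version(data.frame(m = c("m1", "m3"), d = c("d1", "d1")),
                           metabolites = c("m1", "m2", "m3"), diseases = "d1")
  tsb <- extract_incremental_test_sets(v1, v2b)
  expect_length(tsb, 0L)

  # a version diffed against itself adds nothing
  expect_length(extract_incremental_test_sets(v2, v2), 0L)
})

test_that("extraction matches a set-comprehension oracle on random version pairs", {
  for (seed in 1:5) {
    vp <- random_version_pair(seed = seed)
    got <- extract_incremental_test_sets(vp$v1, vp$v2)
    want <- oracle_test_sets(vp$v1, vp$v2)
    expect_equal(got, want)
    for (ts in got) {
      expect_length(intersect(ts$positives, ts$negatives), 0L)
      # positives never overlap version-1 training pairs of this disease
      p1 <- vp$v1$pair_df
      expect_length(intersect(ts$positives,
                              p1$metabolite_id[p1$disease_id == ts$disease_id]),
                    0L)
    }
  }
})

test_that("AUC equals the normalized pairwise win count, ties at half", {
  expect_equal(auc_scores(0.9, c(0.1, 0.2)), 1.0)
  expect_equal(auc_scores(0.5, 0.5), 0.5)
  expect_equal(auc_scores(c(0.8, 0.4), c(0.6, 0.2, 0.4)),
               oracle_auc(c(0.8, 0.4), c(0.6, 0.2, 0.4)))
  for (seed in 1:5) {
    set.seed(seed)
    pos <- round(runif(7), 1); neg <- round(runif(11), 1)  # force some ties
    expect_equal(auc_scores(pos, neg), oracle_auc(pos, neg))
    # agreement with the rank-sum statistic of the standard test
    w <- suppressWarnings(stats::wilcox.test(pos, neg))
    expect_equal(auc_scores(pos, neg),
                 unname(w$statistic) / (length(pos) * length(neg)))
  }
  expect_error(auc_scores(numeric(0), 1), "empty")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  pos <- runif(6); neg <- runif(9)
  base <- auc_scores(pos, neg)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
    expect_equal(auc_scores(f(pos), f(neg)), base)
})

test_that("per-disease evaluation composes the AUC of each prediction column", {
  P <- matrix(c(0.9, 0.8, 0.1, 0.2,
                0.5, 0.5, 0.5, 0.5), 4, 2,
              dimnames = list(paste0("m", 1:4), c("d1", "d2")))
  ts <- list(list(disease_id = "d1", positives = c("m1", "m2"),
                  negatives = c("m3", "m4")),
             list(disease_id = "d2", positives = "m1",
                  negatives = c("m2", "m3")))
  rep <- evaluate_predictions(P, ts)
  expect_equal(rep$per_disease$auc, c(1.0, 0.5))
  expect_equal(rep$mean_auc, 0.75)
  expect_equal(rep$n_diseases, 2L)
  # compositional consistency with direct calls
  for (k in 1:2)
    expect_equal(rep$per_disease$auc[k],
                 auc_scores(P[ts[[k]]$positives, ts[[k]]$disease_id],
                            P[ts[[k]]$negatives, ts[[k]]$disease_id]))
  expect_error(evaluate_predictions(P, list(list(disease_id = "dX",
                                                 positives = "m1",
                                                 negatives = "m2"))),
               "missing")
})

test_that("LOOCV runs one fold per known pair and rebuilds the pipeline", {
  ds <- small_synth(seed = 3)
  pairs <- ds$version1$pair_df[1:10, ]
  cfg <- fast_cfg(seed = 2)
  rep <- loocv(pairs, ds$disease_similarity, ds$metabolite_similarity,
               config = cfg)
  expect_equal(rep$n_diseases, nrow(rep$per_disease))
  expect_equal(nrow(rep$per_disease), 10L)   # one fold per held-out pair
  expect_true(all(rep$per_disease$auc >= 0 & rep$per_disease$auc <= 1))

  # one fold reproduced from scratch with the public operations
  held <- pairs[4, ]
  mlab <- sort(unique(pairs$metabolite_id))
  dlab <- sort(unique(pairs$disease_id))
  fit <- dmlfm(pairs[-4, ], ds$disease_similarity, ds$metabolite_similarity,
               metabolite_labels = mlab, disease_labels = dlab, config = cfg)
  col <- fit$predictions[, held$disease_id]
  neg <- setdiff(mlab, pairs$metabolite_id[pairs$disease_id == held$disease_id])
  manual <- auc_scores(col[held$metabolite_id], col[neg])
  row <- rep$per_disease[rep$per_disease$metabolite_id == held$metabolite_id &
                           rep$per_disease$disease_id == held$disease_id, ]
  expect_equal(row$auc, manual)
})

test_that("a similarity-separable held-out pair is perfectly recovered", {
  # d2 is a near-clone of d1, so the held-out (m1, d2) pair should outrank
  # metabolites with no relation to either disease
  pairs <- data.frame(m = c("m1", "m1", "m2"), d = c("d1", "d2", "d3"))
  dsim <- diag(3); dimnames(dsim) <- list(paste0("d", 1:3), paste0("d", 1:3))
  dsim["d1", "d2"] <- dsim["d2", "d1"] <- 0.95
  rep <- loocv(pairs, disease_sim = dsim,
               config = lfm_config(n_factors = 2, learning_rate = 0.05,
                                   max_epochs = 300, seed = 5))
  fold <- rep$per_disease[rep$per_disease$disease_id == "d2", ]
  expect_equal(fold$auc, 1.0)
})

test_that("ablation variants compose the public operations as documented", {
  ds <- small_synth(seed = 4)
  pairs <- ds$version1$pair_df
  cfg <- fast_cfg(seed = 6)
  lab <- list(metabolite_labels = ds$metabolite_ids,
              disease_labels = ds$disease_ids)

  # identity similarities: completion is a no-op, so disease_only == init
  id_d <- diag(length(ds$disease_ids))
  dimnames(id_d) <- list(ds$disease_ids, ds$disease_ids)
  id_m <- diag(length(ds$metabolite_ids))
  dimnames(id_m) <- list(ds$metabolite_ids, ds$metabolite_ids)
  P_init <- do.call(run_ablation, c(list(pairs, id_d, id_m, config = cfg,
                                         variant = "init"), lab))
  P_do <- do.call(run_ablation, c(list(pairs, id_d, id_m, config = cfg,
                                       variant = "disease_only"), lab))
  P_full_id <- do.call(run_ablation, c(list(pairs, id_d, id_m, config = cfg,
                                            variant = "full"), lab))
  expect_equal(P_do, P_init)
  expect_equal(P_full_id, P_init)

  # all six variants on real similarities are distinct and reproducible
  variants <- c("init", "disease_only", "metabolite_only", "full", "svd", "lfm_nr")
  preds <- lapply(variants, function(v)
    do.call(run_ablation, c(list(pairs, ds$disease_similarity,
                                 ds$metabolite_similarity, config = cfg,
                                 variant = v), lab)))
  names(preds) <- variants
  for (i in seq_along(variants)) for (j in seq_len(i - 1))
    expect_false(isTRUE(all.equal(preds[[i]], preds[[j]])))

  # full == manual composition of the public operations
  init <- build_initial_matrix(pairs, ds$metabolite_ids, ds$disease_ids)
  completed <- combine_fills(disease_fill(init, ds$disease_similarity),
                             metabolite_fill(init, ds$metabolite_similarity),
                             init)
  manual <- finalize_predictions(lfm_train(completed$values, cfg)$factors, init)
  expect_equal(preds$full, manual)
  # svd == manual truncated decomposition of the same completion
  expect_equal(preds$svd, svd_baseline(completed, k = cfg$n_factors, init = init))
  # lfm_nr is exactly the zero-regularization fit
  cfg0 <- cfg; cfg0$reg_lambda <- 0
  manual_nr <- finalize_predictions(lfm_train(completed$values, cfg0)$factors, init)
  expect_equal(preds$lfm_nr, manual_nr)
})
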