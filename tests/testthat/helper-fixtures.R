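# Shared fixtures and independent oracles, all built in code.

toy_obo <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: DOID:9744", "name: type 1 diabetes mellitus",
  "synonym: \"juvenile diabetes\" EXACT []", "xref: MESH:D003922", "",
  "[Term]", "id: DOID:8659", "name: chickenpox", "xref: MESH:D002644", "",
  "[Term]", "id: DOID:8689", "name: anorexia nervosa",
  "synonym: \"AN\" EXACT []", "",
  "[Term]", "id: DOID:8692", "name: myeloid leukemia",
  "synonym: \"leukemia, myelocytic\" EXACT []", "",
  "[Term]", "id: DOID:8567", "name: Hodgkin disease", "",
  "[Term]", "id: DOID:0001", "name: retired entity", "is_obsolete: true", "")

toy_medic <- function() data.frame(
  DiseaseName = c("Chicken Pox", "Diabetes Mellitus, Type 1"),
  DiseaseID = c("MESH:D002644", "MESH:D003922"),
  Synonyms = c("", "IDDM|Insulin-Dependent Diabetes Mellitus"),
  stringsAsFactors = FALSE)

toy_vocab <- function() build_vocabulary(parse_ontology(toy_obo()),
                                         parse_medic(toy_medic()))

# random toy vocabulary with guaranteed-distinct surface forms
random_vocab_terms <- function(n_terms, seed) {
  set.seed(seed)
  words <- c("gastric", "renal", "hepatic", "cardiac", "neural", "ocular",
             "dermal", "lymphoid", "osseous", "thyroid")
  kinds <- c("atrophy", "fibrosis", "dysplasia", "stenosis", "carcinoma",
             "neuropathy", "sclerosis", "adenoma", "edema", "necrosis")
  combos <- expand.grid(w = words, k = kinds, stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos), n_terms), ]
  data.frame(term_id = sprintf("DOID:%05d", seq_len(n_terms)),
             name = paste(combos$w, combos$k),
             obsolete = FALSE,
             synonyms = I(lapply(seq_len(n_terms), function(i)
               paste(combos$k[i], combos$w[i], sep = ", "))),
             xrefs = I(rep(list(character(0)), n_terms)),
             stringsAsFactors = FALSE)
}

# small random 0-1 association instance with similarity matrices
random_instance <- function(nm, nd, density = 0.2, seed = 1) {
  set.seed(seed)
  mlab <- paste0("m", seq_len(nm)); dlab <- paste0("d", seq_len(nd))
  A <- matrix(rbinom(nm * nd, 1, density), nm, nd,
              dimnames = list(mlab, dlab))
  rsym <- function(n, lab) {
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(lab, lab)
    S
  }
  idx <- which(A == 1, arr.ind = TRUE)
  list(init = build_initial_matrix(
         data.frame(m = mlab[idx[, 1]], d = dlab[idx[, 2]]), mlab, dlab),
       dsim = rsym(nd, dlab), msim = rsym(nm, mlab))
}

# brute-force double-loop oracles for the similarity fills
oracle_disease_fill <- function(init, dsim) {
  A <- init$values
  DF <- A * 0
  for (m in seq_len(nrow(A))) for (d in seq_len(ncol(A))) {
    Dm <- which(A[m, ] == 1)
    DF[m, d] <- if (d %in% Dm) A[m, d]
                else if (length(Dm)) max(sapply(Dm, function(di)
                  dsim[colnames(A)[d], colnames(A)[di]]))
                else 0
  }
  DF
}

oracle_metabolite_fill <- function(init, msim) {
  A <- init$values
  MF <- A * 0
  for (m in seq_len(nrow(A))) for (d in seq_len(ncol(A))) {
    Md <- which(A[, d] == 1)
    MF[m, d] <- if (m %in% Md) A[m, d]
                else if (length(Md)) max(sapply(Md, function(mj)
                  msim[rownames(A)[m], rownames(A)[mj]]))
                else 0
  }
  MF
}

# literal two-term evaluation of the training cost
oracle_cost <- function(values, factors, lambda) {
  total <- 0
  for (m in seq_len(nrow(values))) for (d in seq_len(ncol(values))) {
    pred <- 0
    for (f in seq_len(ncol(factors$dlf)))
      pred <- pred + factors$dlf[d, f] * factors$mlf[m, f]
    total <- total + (values[m, d] - pred)^2
  }
  reg <- 0
  for (d in seq_len(nrow(factors$dlf))) reg <- reg + sum(factors$dlf[d, ]^2)
  for (m in seq_len(nrow(factors$mlf))) reg <- reg + sum(factors$mlf[m, ]^2)
  total + lambda / 2 * reg
}

# exhaustive pairwise AUC
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# set-comprehension oracle for data-increment test sets
oracle_test_sets <- function(v1, v2) {
  common <- intersect(v1$metabolites, v2$metabolites)
  has <- function(v, m, d) paste(m, d, sep = "\r") %in% v$pairs
  out <- list()
  for (d in sort(unique(v1$diseases))) {
    targets <- Filter(function(m) has(v1, m, d) && has(v2, m, d), common)
    if (!length(targets)) next
    pos <- sort(Filter(function(m) has(v2, m, d) && !has(v1, m, d), common))
    if (!length(pos)) next
    neg <- sort(Filter(function(m) !has(v1, m, d) && !has(v2, m, d),
                       v1$metabolites))
    out[[length(out) + 1L]] <- list(disease_id = d, positives = pos,
                                    negatives = neg)
  }
  out
}

random_version_pair <- function(nm = 30, nd = 10, seed = 1) {
  set.seed(seed)
  mlab <- paste0("m", seq_len(nm)); dlab <- paste0("d", seq_len(nd))
  all_cells <- expand.grid(m = mlab, d = dlab, stringsAsFactors = FALSE)
  i2 <- sample.int(nrow(all_cells), round(0.15 * nrow(all_cells)))
  i1 <- sample(i2, round(0.6 * length(i2)))
  # version-1 metabolite universe is a subset, so some v2 metabolites are new
  m1 <- union(unique(all_cells$m[i1]), sample(mlab, round(0.8 * nm)))
  list(v1 = assoc_map_version(all_cells[i1, ], metabolites = sort(m1),
                              diseases = dlab, tag = "v1"),
       v2 = assoc_map_version(all_cells[i2, ], metabolites = mlab,
                              diseases = dlab, tag = "v2"))
}

small_synth <- function(seed = 7, ...) {
  generate_synthetic(synthetic_config(n_diseases = 20, n_metabolites = 30,
                                      observation_density = 0.08,
                                      version2_extra_density = 0.05,
                                      seed = seed, ...))
}

fast_cfg <- function(seed = 1, ...) {
  lfm_config(n_factors = 6, max_epochs = 60, seed = seed, ...)
}
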