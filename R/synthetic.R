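# Seeded synthetic datasets emulating every external input: a toy disease
# ontology + MEDIC table, HMDB-style metabolite XML, STITCH-style literature
# scores, a precomputed disease similarity matrix, and two time-versions of
# the association map for data-increment validation.
#
# Associations and similarities derive from the SAME latent factors: this
# encodes the model's core assumption that metabolites with literature links
# tend to share diseases, in a controllable low-rank form.

#' Synthetic dataset configuration
#'
#' @param n_diseases,n_metabolites Entity counts.
#' @param true_rank Rank of the generating latent structure.
#' @param observation_density Fraction of cells observed in version 1.
#' @param version2_extra_density Additional fraction observed only in
#'   version 2 (the data increment).
#' @param similarity_noise Scale of the uniform perturbation added to the
#'   factor-cosine similarities.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_diseases = 40L, n_metabolites = 60L,
                             true_rank = 3L, observation_density = 0.05,
                             version2_extra_density = 0.03,
                             similarity_noise = 0.05, seed = 7L) {
  stopifnot(true_rank <= min(n_diseases, n_metabolites),
            observation_density > 0, observation_density <= 1,
            version2_extra_density >= 0, version2_extra_density < 1,
            similarity_noise >= 0)
  structure(list(n_diseases = as.integer(n_diseases),
                 n_metabolites = as.integer(n_metabolites),
                 true_rank = as.integer(true_rank),
                 observation_density = observation_density,
                 version2_extra_density = version2_extra_density,
                 similarity_noise = similarity_noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# cosine similarity between rows of X, diagonal 1
.row_cosine <- function(X) {
  n <- sqrt(rowSums(X^2))
  n[n == 0] <- 1
  S <- (X / n) %*% t(X / n)
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S
}

.perturb_sim <- function(S, scale) {
  if (scale == 0) return(S)
  n <- nrow(S)
  E <- matrix(stats::runif(n * n, -scale, scale), n, n)
  E <- (E + t(E)) / 2
  S2 <- pmin(pmax(S + E, 0), 1)
  diag(S2) <- 1
  S2
}

# toy ontology / MEDIC rows for one synthetic disease: canonical name
# "type k synthetic disease", MEDIC name "Synthetic Disease, Type k"
# (word-order variant), MEDIC abbreviation synonym "SD-k"
.toy_disease_table <- function(n) {
  data.frame(
    doid = sprintf("DOID:%d", 70000L + seq_len(n)),
    mesh = sprintf("MESH:D9%05d", seq_len(n)),
    name = sprintf("type %d synthetic disease", seq_len(n)),
    medic_name = sprintf("Synthetic Disease, Type %d", seq_len(n)),
    medic_syn = sprintf("SD-%d", seq_len(n)),
    stringsAsFactors = FALSE)
}

# additional ontology/MEDIC terms exercising the five naming-characteristic
# cases (plural/possessive, symbol, abbreviation, word order, synonym)
.naming_case_terms <- function() {
  list(
    obo = c(
      "[Term]", "id: DOID:8567", "name: Hodgkin disease",
      "xref: MESH:D006689", "",
      "[Term]", "id: DOID:8692", "name: myeloid leukemia",
      "xref: MESH:D007951", "",
      "[Term]", "id: DOID:8659", "name: chickenpox",
      "xref: MESH:D002644", "",
      "[Term]", "id: DOID:8689", "name: anorexia nervosa",
      "synonym: \"AN\" EXACT []", "xref: MESH:D000856", "",
      "[Term]", "id: DOID:9744", "name: type 1 diabetes mellitus",
      "xref: MESH:D003922", "",
      "[Term]", "id: DOID:4143", "name: orbital neoplasm",
      "xref: MESH:D009918", "",
      "[Term]", "id: DOID:8649",
      "name: malignant tumor of lingual tonsil",
      "synonym: \"malignant neoplasm of lingual tonsil\" EXACT []", ""),
    medic = data.frame(
      DiseaseName = c("Disease, Hodgkin's", "Leukemia, Myelocytic",
                      "Chicken Pox", "Anorexia Nervosa",
                      "Diabetes Mellitus, Type 1", "Neoplasm, Orbital"),
      DiseaseID = c("MESH:D006689", "MESH:D007951", "MESH:D002644",
                    "MESH:D000856", "MESH:D003922", "MESH:D009918"),
      Synonyms = c("Disease, Hodgkin|Hodgkin's Disease",
                   "Leukemias, Myelocytic", "", "AN", "", ""),
      stringsAsFactors = FALSE))
}

#' Generate a synthetic dataset
#'
#' Draws non-negative true factors of the configured rank; scales their
#' inner products into `[0, 1]` as association probabilities; derives
#' disease and metabolite similarities as (noise-perturbed) cosines of the
#' true factor rows; samples version-2 association pairs without replacement
#' from the top-quartile probability cells and version 1 as a subsample of
#' version 2; and builds a toy vocabulary covering all synthetic diseases
#' plus one instance of each of the five disease-naming cases.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with components
#'   `true_factors`, `true_probabilities`, `disease_similarity`,
#'   `metabolite_similarity`, `version1`, `version2`, `disease_table`,
#'   `metabolite_ids`, `disease_ids`, `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  nd <- config$n_diseases; nm <- config$n_metabolites; r <- config$true_rank
  mids <- sprintf("SMB%05d", seq_len(nm))
  tab <- .toy_disease_table(nd)
  dids <- tab$doid

  .with_seed(config$seed, {
    dlf <- matrix(stats::rgamma(nd * r, shape = 2, rate = 2), nd, r)
    mlf <- matrix(stats::rgamma(nm * r, shape = 2, rate = 2), nm, r)
    P <- mlf %*% t(dlf)
    P <- P / max(P)
    dimnames(P) <- list(mids, dids)

    dsim <- .perturb_sim(.row_cosine(dlf), config$similarity_noise)
    dimnames(dsim) <- list(dids, dids)
    msim <- .perturb_sim(.row_cosine(mlf), config$similarity_noise)
    dimnames(msim) <- list(mids, mids)

    ncells <- nm * nd
    n2 <- round((config$observation_density + config$version2_extra_density) * ncells)
    n1 <- round(config$observation_density * ncells)
    if (n1 < 1L) stop("configuration yields zero version-1 pairs")
    top <- order(P, decreasing = TRUE)[seq_len(max(ceiling(ncells / 4), n2))]
    idx2 <- sample(top, n2)
    idx1 <- sample(idx2, n1)
    to_pairs <- function(idx) data.frame(
      metabolite_id = mids[(idx - 1L) %% nm + 1L],
      disease_id = dids[(idx - 1L) %/% nm + 1L],
      stringsAsFactors = FALSE)
    v2 <- assoc_map_version(to_pairs(idx2), metabolites = mids,
                            diseases = dids, tag = "v2")
    v1 <- assoc_map_version(to_pairs(idx1), metabolites = mids,
                            diseases = dids, tag = "v1")

    structure(list(true_factors = list(dlf = dlf, mlf = mlf),
                   true_probabilities = P,
                   disease_similarity = dsim, metabolite_similarity = msim,
                   version1 = v1, version2 = v2,
                   disease_table = tab, metabolite_ids = mids,
                   disease_ids = dids, config = config),
              class = "synthetic_dataset")
  })
}

# disease-name variant used in the metabolite XML, rotated deterministically
# so the fixture exercises canonical, word-order and plural surface forms
.toy_name_variant <- function(tab, doid, slot) {
  k <- match(doid, tab$doid)
  switch((slot %% 3L) + 1L,
         tab$name[k],                                     # canonical
         tab$medic_name[k],                               # "Synthetic Disease, Type k"
         sub("disease$", "diseases", tab$name[k]))        # plural form
}

#' Write a synthetic dataset as an on-disk fixture
#'
#' Serializes every component in the exact external formats the production
#' readers consume: a toy OBO ontology, a MEDIC-style TSV, HMDB-style
#' metabolite XML whose disease lists encode the version-2 pairs through
#' varied surface forms, a STITCH-style score TSV (with a compound-id
#' mapping), the disease similarity matrix, version pair TSVs, a pipeline
#' config YAML, and a manifest.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (file, n_rows).
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tab <- ds$disease_table
  cases <- .naming_case_terms()

  # --- ontology.obo
  obo <- c("format-version: 1.2", "")
  for (k in seq_len(nrow(tab)))
    obo <- c(obo, "[Term]", paste0("id: ", tab$doid[k]),
             paste0("name: ", tab$name[k]),
             paste0("xref: ", tab$mesh[k]), "")
  obo <- c(obo, cases$obo)
  writeLines(obo, p("ontology.obo"))

  # --- medic.tsv
  medic <- rbind(
    data.frame(DiseaseName = tab$medic_name, DiseaseID = tab$mesh,
               Synonyms = tab$medic_syn, stringsAsFactors = FALSE),
    cases$medic)
  utils::write.table(medic, p("medic.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- metabolites.xml (disease lists = version-2 pairs, varied surfaces)
  v2 <- ds$version2$pair_df
  root <- xml2::xml_new_root("metabolites")
  for (i in seq_along(ds$metabolite_ids)) {
    mid <- ds$metabolite_ids[i]
    node <- xml2::xml_add_child(root, "metabolite")
    xml2::xml_add_child(node, "accession", mid)
    xml2::xml_add_child(node, "name", paste("synthetic metabolite", i))
    dl <- xml2::xml_add_child(node, "diseases")
    for (d in sort(v2$disease_id[v2$metabolite_id == mid])) {
      dn <- xml2::xml_add_child(dl, "disease")
      xml2::xml_add_child(dn, "name",
                          .toy_name_variant(tab, d, i + match(d, tab$doid)))
    }
  }
  xml2::write_xml(root, p("metabolites.xml"))

  # --- scores.tsv + mapping.tsv (ST = 150 + 750 * MSim for MSim > 0)
  S <- ds$metabolite_similarity
  iu <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  cid <- sprintf("CIDs%05d", seq_along(ds$metabolite_ids))
  scores <- data.frame(chemical1 = cid[iu[, 1]], chemical2 = cid[iu[, 2]],
                       textmining = round(150 + 750 * S[iu], 6))
  utils::write.table(scores, p("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(compound_id = cid,
                                metabolite_id = ds$metabolite_ids),
                     p("mapping.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- disease similarity, version pair lists
  write_labeled_matrix(ds$disease_similarity, p("disease_similarity.tsv"))
  utils::write.table(ds$version1$pair_df, p("version1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$version2$pair_df, p("version2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- pipeline config
  yaml::write_yaml(list(
    ontology = "ontology.obo", medic = "medic.tsv",
    metabolite_xml = "metabolites.xml",
    scores = "scores.tsv", score_mapping = "mapping.tsv",
    score_range = c(150, 900), msim_direction = "ascending",
    disease_similarity = "disease_similarity.tsv",
    seed = ds$config$seed), p("config.yaml"))

  files <- c("ontology.obo", "medic.tsv", "metabolites.xml", "scores.tsv",
             "mapping.tsv", "disease_similarity.tsv", "version1.tsv",
             "version2.tsv", "config.yaml")
  manifest <- data.frame(
    file = files,
    n_rows = vapply(files, function(f) length(readLines(p(f), warn = FALSE)),
                    integer(1)))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
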