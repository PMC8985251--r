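# External-format readers, labeled-matrix serialization, and the
# end-to-end pipeline.

#' Read metabolite records from HMDB-style XML
#'
#' One record per metabolite element, with its accession, name and the list
#' of free-text disease names.  Element paths are configurable to absorb
#' schema drift between database versions; the defaults follow the modern
#' nesting (`accession`, `name`, `diseases/disease/name`).
#'
#' @param path XML file path.
#' @param metabolite_xpath XPath selecting metabolite elements.
#' @param accession_xpath,name_xpath,disease_xpath XPaths relative to a
#'   metabolite element.
#' @return A data.frame with columns `accession`, `name` and list-column
#'   `disease_names`; records lacking an accession are skipped (their count
#'   is in attribute `n_skipped`).
#' @export
read_metabolite_xml <- function(path, metabolite_xpath = "//metabolite",
                                accession_xpath = "./accession",
                                name_xpath = "./name",
                                disease_xpath = "./diseases/disease/name") {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, metabolite_xpath)
  acc <- vapply(nodes, function(n)
    xml2::xml_text(xml2::xml_find_first(n, accession_xpath)), character(1))
  skipped <- is.na(acc) | !nzchar(acc)
  nodes <- nodes[!skipped]
  out <- data.frame(
    accession = acc[!skipped],
    name = vapply(nodes, function(n)
      xml2::xml_text(xml2::xml_find_first(n, name_xpath)), character(1)),
    stringsAsFactors = FALSE)
  out$disease_names <- I(lapply(nodes, function(n)
    xml2::xml_text(xml2::xml_find_all(n, disease_xpath))))
  if (anyDuplicated(out$accession))
    stop("duplicate metabolite accession: ",
         out$accession[duplicated(out$accession)][1])
  if (any(skipped)) warning(sum(skipped), " metabolite record(s) without accession skipped")
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Resolve metabolite disease names into association pairs
#'
#' Each free-text disease name is matched against the vocabulary
#' ([match_disease()] rules); resolved (metabolite, term id) pairs are
#' deduplicated.
#'
#' @param records Output of [read_metabolite_xml()].
#' @param vocab A `disease_vocabulary`.
#' @return A list with `pairs` (data.frame metabolite_id / disease_id) and
#'   `report` (matched / unmatched name counts, distinct entity tallies,
#'   unmatched name list).
#' @export
build_associations <- function(records, vocab) {
  stopifnot(inherits(vocab, "disease_vocabulary"))
  lookup <- vocab$entries$term_id
  names(lookup) <- vocab$entries$surface_form
  match1 <- function(raw) {
    for (form in normalize_term(raw, inventory = vocab$inventory)$variants) {
      hit <- lookup[form]
      if (!is.na(hit)) return(unname(hit))
    }
    NA_character_
  }
  m_id <- character(0); d_id <- character(0); unmatched <- character(0)
  n_names <- 0L
  for (k in seq_len(nrow(records))) {
    for (raw in records$disease_names[[k]]) {
      n_names <- n_names + 1L
      hit <- match1(raw)
      if (is.na(hit)) unmatched <- c(unmatched, raw)
      else { m_id <- c(m_id, records$accession[k]); d_id <- c(d_id, hit) }
    }
  }
  pairs <- unique(data.frame(metabolite_id = m_id, disease_id = d_id,
                             stringsAsFactors = FALSE))
  list(pairs = pairs,
       report = list(n_names = n_names, n_matched = n_names - length(unmatched),
                     n_unmatched = length(unmatched),
                     unmatched = unique(unmatched),
                     n_metabolites = length(unique(pairs$metabolite_id)),
                     n_diseases = length(unique(pairs$disease_id)),
                     n_pairs = nrow(pairs)))
}

#' Write a labeled numeric matrix as TSV
#'
#' First row holds the column labels, first column the row labels, so the
#' orientation is never implicit.  Numerics are serialized with 6 decimals.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_labeled_matrix <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(id = rownames(m),
                   formatC(m, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_labeled_matrix()]
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_labeled_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read an association pair list (metabolite_id, disease_id TSV)
#' @param path TSV path with a header.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("pair file needs two columns")
  data.frame(metabolite_id = as.character(df[[1]]),
             disease_id = as.character(df[[2]]), stringsAsFactors = FALSE)
}

#' Run the end-to-end prediction pipeline on external inputs
#'
#' vocabulary -> association pairs -> initial matrix -> similarity fills ->
#' noisy-OR completion -> latent-factor training -> final predictions ->
#' per-disease candidate rankings.  Every intermediate is written as labeled
#' TSV under `out_dir`, plus a YAML run log recording the inputs, seed and
#' summary counts; the run is deterministic given the config.
#'
#' @param config Either a YAML path or a list with elements `ontology`,
#'   `medic`, `metabolite_xml`, `scores`, `score_mapping` (optional),
#'   `score_range` (optional), `msim_direction`, `disease_similarity`,
#'   `seed`, and optionally `lfm` (a list of [lfm_config()] arguments) and
#'   `clip`.  Relative paths are resolved against the config file's
#'   directory (or `base_dir`).
#' @param out_dir Output directory.
#' @param base_dir Base for relative input paths.
#' @return Invisibly, a list with the `dmlfm` fit, the run `log`, and the
#'   output `manifest`.
#' @export
run_pipeline <- function(config, out_dir, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  rp <- function(f) if (file.exists(f)) f else file.path(base_dir, f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  terms <- parse_ontology(rp(config$ontology))
  medic <- parse_medic(rp(config$medic))
  vocab <- build_vocabulary(terms, medic)
  records <- read_metabolite_xml(rp(config$metabolite_xml))
  assoc <- build_associations(records, vocab)
  if (nrow(assoc$pairs) == 0L) stop("pipeline: no disease name matched the vocabulary")

  mapping <- if (!is.null(config$score_mapping)) rp(config$score_mapping)
  scores <- read_score_table(rp(config$scores), mapping = mapping)
  mlab <- sort(unique(assoc$pairs$metabolite_id))
  dlab <- sort(unique(assoc$pairs$disease_id))
  direction <- if (is.null(config$msim_direction)) "ascending" else config$msim_direction
  msim <- metabolite_similarity_from_scores(
    scores, labels = mlab, direction = direction,
    range = if (!is.null(config$score_range)) as.numeric(config$score_range))
  dsim <- read_labeled_matrix(rp(config$disease_similarity))

  lfm_args <- if (is.null(config$lfm)) list() else config$lfm
  if (!is.null(config$seed) && is.null(lfm_args$seed)) lfm_args$seed <- config$seed
  cfg <- do.call(lfm_config, lfm_args)
  fit <- dmlfm(assoc$pairs, disease_sim = dsim, metabolite_sim = msim,
               metabolite_labels = mlab, disease_labels = dlab,
               config = cfg, clip = isTRUE(config$clip))

  o <- function(f) file.path(out_dir, f)
  write_vocabulary(vocab, o("vocabulary.tsv"))
  utils::write.table(assoc$pairs, o("pairs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_labeled_matrix(fit$initial$values, o("initial_matrix.tsv"))
  write_labeled_matrix(fit$completed$values, o("completed_matrix.tsv"))
  prov <- fit$completed$provenance
  utils::write.table(
    data.frame(id = rownames(prov), prov, check.names = FALSE),
    o("provenance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_labeled_matrix(fit$factors$dlf, o("disease_factors.tsv"))
  write_labeled_matrix(fit$factors$mlf, o("metabolite_factors.tsv"))
  write_labeled_matrix(unclass(fit$predictions), o("predictions.tsv"))
  utils::write.table(
    data.frame(epoch = seq_along(fit$trace$epoch_costs),
               cost = formatC(fit$trace$epoch_costs, format = "f", digits = 6)),
    o("train_trace.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rankings <- predict(fit, ranked = TRUE)
  rankings$score <- round(rankings$score, 6)
  utils::write.table(rankings, o("rankings.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  log <- list(config = config, seed = cfg$seed,
              n_metabolites = length(mlab), n_diseases = length(dlab),
              n_known_pairs = nrow(assoc$pairs),
              vocabulary = as.list(vocab$stats),
              match_report = assoc$report[c("n_names", "n_matched", "n_unmatched")],
              coverage = fit$coverage[c("n_known", "n_disease_only",
                                        "n_metabolite_only", "n_both",
                                        "n_empty", "coverage_rate")],
              epochs_run = fit$trace$epochs_run,
              final_cost = utils::tail(fit$trace$epoch_costs, 1),
              converged = fit$trace$converged)
  yaml::write_yaml(log, o("run_log.yaml"))

  files <- c("vocabulary.tsv", "pairs.tsv", "initial_matrix.tsv",
             "completed_matrix.tsv", "provenance.tsv", "disease_factors.tsv",
             "metabolite_factors.tsv", "predictions.tsv", "train_trace.tsv",
             "rankings.tsv", "run_log.yaml")
  manifest <- data.frame(file = files, n_rows = vapply(
    files, function(f) length(readLines(o(f), warn = FALSE)), integer(1)))
  utils::write.table(manifest, o("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fit = fit, log = log, manifest = manifest))
}
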