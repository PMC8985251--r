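# Association-matrix construction and similarity-based completion.
#
# Orientation is fixed throughout: rows = metabolites, columns = diseases.
# Provenance codes: K known, D disease-fill, M metabolite-fill, B both, E empty.

#' Build the initial 0-1 disease-metabolite association matrix
#'
#' Cell (m, d) is 1 iff the pair is listed among the known associations.
#'
#' @param pairs data.frame (or 2-column matrix) with columns metabolite_id,
#'   disease_id.
#' @param metabolite_labels,disease_labels Ordered row/column identifiers.
#' @return A list of class `association_matrix`: `values` (|M| x |D| matrix,
#'   dimnames set), `provenance` (same shape, single characters).
#' @export
build_initial_matrix <- function(pairs, metabolite_labels, disease_labels) {
  stopifnot(!anyDuplicated(metabolite_labels), !anyDuplicated(disease_labels))
  A <- matrix(0, length(metabolite_labels), length(disease_labels),
              dimnames = list(metabolite_labels, disease_labels))
  if (NROW(pairs) > 0L) {
    m <- as.character(pairs[[1]]); d <- as.character(pairs[[2]])
    bad <- !(m %in% metabolite_labels) | !(d %in% disease_labels)
    if (any(bad))
      stop("association pair references unknown label: ",
           paste(m[bad][1], d[bad][1], sep = " / "))
    A[cbind(match(m, metabolite_labels), match(d, disease_labels))] <- 1
  }
  prov <- matrix(ifelse(A == 1, "K", "E"), nrow(A), ncol(A), dimnames = dimnames(A))
  structure(list(values = A, provenance = prov), class = "association_matrix")
}

#' Read a STITCH-style pairwise score table
#'
#' @param path TSV path or data.frame with id1, id2, score columns.
#' @param id1_col,id2_col,score_col Column names (defaults match STITCH
#'   chemical-chemical links: `chemical1`, `chemical2`, `textmining`).
#' @param mapping Optional two-column data.frame (or TSV path) mapping
#'   compound ids to metabolite ids; unmapped rows are dropped.
#' @return data.frame id1/id2/score; self-pairs removed, duplicate unordered
#'   pairs collapsed to their maximum score.
#' @export
read_score_table <- function(path, id1_col = "chemical1", id2_col = "chemical2",
                             score_col = "textmining", mapping = NULL) {
  tab <- if (is.data.frame(path)) path
         else utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id1_col, id2_col, score_col))
    if (!col %in% names(tab)) stop("score table lacks column '", col, "'")
  out <- data.frame(id1 = as.character(tab[[id1_col]]),
                    id2 = as.character(tab[[id2_col]]),
                    score = as.numeric(tab[[score_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    map <- if (is.data.frame(mapping)) mapping
           else utils::read.delim(mapping, stringsAsFactors = FALSE)
    key <- as.character(map[[1]]); val <- as.character(map[[2]])
    out$id1 <- val[match(out$id1, key)]
    out$id2 <- val[match(out$id2, key)]
    out <- out[!is.na(out$id1) & !is.na(out$id2), , drop = FALSE]
  }
  if (any(!is.finite(out$score))) stop("non-finite score in table")
  if (any(out$score < 0)) stop("negative raw score in table")
  out <- out[out$id1 != out$id2, , drop = FALSE]
  # unordered-unique: max score per pair
  a <- pmin(out$id1, out$id2); b <- pmax(out$id1, out$id2)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(out$score, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(id1 = vapply(parts, `[`, character(1), 1L),
             id2 = vapply(parts, `[`, character(1), 2L),
             score = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Metabolite literature similarity from co-occurrence scores
#'
#' Min-max standardizes raw literature co-occurrence scores into `[0, 1]`
#' similarities.  `direction = "ascending"` (default) maps the highest score
#' to similarity 1, i.e. `(ST - ST_min) / (ST_max - ST_min)`;
#' `direction = "as_printed"` applies the inverted form
#' `(ST_max - ST) / (ST_max - ST_min)`, which assigns similarity 1 to the
#' lowest score.  Pairs absent from the table get similarity 0; the diagonal
#' is 1.
#'
#' @param table Output of [read_score_table()].
#' @param labels Metabolite identifiers for the output matrix (defaults to
#'   the ids present in the table).
#' @param direction `"ascending"` or `"as_printed"`.
#' @param range Optional length-2 numeric `c(ST_min, ST_max)` overriding the
#'   observed score range (useful when the table is a subset of a larger
#'   corpus whose range is known).
#' @return A symmetric |labels| x |labels| matrix in `[0, 1]`.
#' @export
metabolite_similarity_from_scores <- function(table, labels = NULL,
                                              direction = c("ascending", "as_printed"),
                                              range = NULL) {
  direction <- match.arg(direction)
  if (is.null(labels)) labels <- sort(unique(c(table$id1, table$id2)))
  rng <- if (is.null(range)) c(min(table$score), max(table$score)) else range
  if (rng[2] <= rng[1])
    stop("score normalization undefined: ST_max equals ST_min")
  sim <- switch(direction,
                ascending  = (table$score - rng[1]) / (rng[2] - rng[1]),
                as_printed = (rng[2] - table$score) / (rng[2] - rng[1]))
  S <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  keep <- table$id1 %in% labels & table$id2 %in% labels
  i <- match(table$id1[keep], labels); j <- match(table$id2[keep], labels)
  S[cbind(i, j)] <- sim[keep]
  S[cbind(j, i)] <- sim[keep]
  diag(S) <- 1
  S
}

# max similarity to the reference set, per target index; 0 for an empty set
.max_sim <- function(sim_row, ref_idx) {
  if (length(ref_idx) == 0L) 0 else max(sim_row[ref_idx])
}

#' Disease-similarity fill of the association matrix
#'
#' For metabolite m and disease d: the initial value (1) when d is a known
#' disease of m; otherwise the maximum similarity between d and any known
#' disease of m; 0 when m has no known disease.
#'
#' @param init An `association_matrix` (the 0-1 initial matrix).
#' @param dsim Symmetric disease similarity matrix with dimnames; diseases
#'   missing from it are treated as all-zero similarity rows.
#' @return |M| x |D| fill matrix in `[0, 1]`.
#' @export
disease_fill <- function(init, dsim) {
  A <- init$values
  S <- .align_sim(dsim, colnames(A))
  DF <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (m in seq_len(nrow(A))) {
    Dm <- which(A[m, ] == 1)
    if (length(Dm) == 0L) next
    DF[m, ] <- apply(S[, Dm, drop = FALSE], 1L, max)
    DF[m, Dm] <- A[m, Dm]
  }
  DF
}

#' Metabolite-similarity fill of the association matrix
#'
#' Symmetric counterpart of [disease_fill()]: for disease d and metabolite m
#' not known for d, the maximum literature similarity between m and any
#' metabolite known for d; 0 when d has no known metabolite.
#'
#' @param init An `association_matrix`.
#' @param msim Symmetric metabolite similarity matrix with dimnames.
#' @return |M| x |D| fill matrix in `[0, 1]`.
#' @export
metabolite_fill <- function(init, msim) {
  A <- init$values
  S <- .align_sim(msim, rownames(A))
  MF <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (d in seq_len(ncol(A))) {
    Md <- which(A[, d] == 1)
    if (length(Md) == 0L) next
    MF[, d] <- apply(S[, Md, drop = FALSE], 1L, max)
    MF[Md, d] <- A[Md, d]
  }
  MF
}

# align a similarity matrix to a label set; absent labels get zero rows,
# self-similarity 1
.align_sim <- function(sim, labels) {
  stopifnot(is.matrix(sim), !is.null(dimnames(sim)))
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix is not symmetric")
  if (any(sim < -1e-12 | sim > 1 + 1e-12)) stop("similarity values outside [0, 1]")
  S <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  common <- intersect(labels, rownames(sim))
  S[common, common] <- sim[common, common]
  diag(S) <- 1
  S
}

#' Combine the two similarity fills into the completed matrix
#'
#' Noisy-OR per cell: `mdr = 1 - (1 - DF)(1 - MF)` — the probability that at
#' least one of the two independent evidence channels supports the
#' association.  Provenance is re-derived: K for initially known cells, D/M
#' for cells supported by one channel, B for both, E for neither.
#'
#' @param DF,MF Fill matrices from [disease_fill()] / [metabolite_fill()].
#' @param init The initial `association_matrix` (for the known mask).
#' @return A completed `association_matrix`.
#' @export
combine_fills <- function(DF, MF, init) {
  stopifnot(all(dim(DF) == dim(MF)))
  if (any(DF < 0 | DF > 1) || any(MF < 0 | MF > 1))
    stop("fill entries outside [0, 1]")
  V <- 1 - (1 - DF) * (1 - MF)
  known <- init$values == 1
  prov <- matrix("E", nrow(V), ncol(V), dimnames = dimnames(V))
  prov[DF > 0 & MF == 0] <- "D"
  prov[MF > 0 & DF == 0] <- "M"
  prov[DF > 0 & MF > 0] <- "B"
  prov[known] <- "K"
  structure(list(values = V, provenance = prov, initial = init$values),
            class = "association_matrix")
}

#' Coverage statistics of a completed association matrix
#'
#' Counts cells per provenance class and the coverage rate: the percentage of
#' initially-unknown cells assigned a nonzero predicted association,
#' `100 * (n_D + n_M + n_B) / (|M||D| - n_K)`.
#'
#' @param mdr A completed `association_matrix` (provenance populated).
#' @return A list with the class counts, `coverage_rate` (percent) and a
#'   `degenerate` flag (TRUE when there are no unknown cells; the rate is
#'   then reported as 100).
#' @export
coverage_stats <- function(mdr) {
  p <- mdr$provenance
  n <- c(n_known = sum(p == "K"), n_disease_only = sum(p == "D"),
         n_metabolite_only = sum(p == "M"), n_both = sum(p == "B"),
         n_empty = sum(p == "E"))
  stopifnot(sum(n) == length(p))
  denom <- length(p) - n[["n_known"]]
  degenerate <- denom == 0L
  rate <- if (degenerate) 100 else
    100 * (n[["n_disease_only"]] + n[["n_metabolite_only"]] + n[["n_both"]]) / denom
  c(as.list(n), list(n_cells = length(p), coverage_rate = rate,
                     degenerate = degenerate))
}

#' Coverage rate from category counts
#'
#' Arithmetic form of the coverage-rate definition, usable directly on
#' reported corpus counts: `100 * n_predicted / (n_cells - n_known)`.
#'
#' @param n_metabolites,n_diseases Matrix dimensions.
#' @param n_known Number of known (1) cells.
#' @param n_predicted Number of initially-unknown cells with a nonzero fill.
#' @return Coverage rate in percent.
#' @export
coverage_rate <- function(n_metabolites, n_diseases, n_known, n_predicted) {
  denom <- n_metabolites * n_diseases - n_known
  if (denom == 0) return(100)
  100 * n_predicted / denom
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix:", nrow(x$values), "metabolites x",
      ncol(x$values), "diseases;", sum(x$provenance == "K"), "known cells\n")
  if (any(x$provenance %in% c("D", "M", "B"))) {
    cs <- coverage_stats(x)
    cat(sprintf("  fills: D=%d M=%d B=%d; coverage %.2f%%\n",
                cs$n_disease_only, cs$n_metabolite_only, cs$n_both,
                cs$coverage_rate))
  }
  invisible(x)
}
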