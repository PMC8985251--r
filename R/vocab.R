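# Disease vocabulary: OBO + MEDIC ingestion, name normalization, matching.

#' Parse a disease ontology in OBO format
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 flat file and returns one row
#' per term with its name, synonyms and cross-references (MeSH, OMIM, ICD,
#' ...).  Obsolete terms are kept in the output but flagged, so that callers
#' can exclude them from matching.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @return A data.frame with columns `term_id`, `name`, `obsolete`, and
#'   list-columns `synonyms` and `xrefs`.
#' @examples
#' obo <- c("[Term]", "id: DOID:1", "name: toy disease")
#' parse_ontology(obo)
#' @export
parse_ontology <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    return(data.frame(term_id = character(), name = character(),
                      obsolete = logical(),
                      synonyms = I(list()), xrefs = I(list()),
                      stringsAsFactors = FALSE))
  }
  ends <- vapply(term_starts, function(s) {
    nxt <- starts[starts > s]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }, integer(1))

  ids <- character(length(term_starts))
  names_ <- character(length(term_starts))
  obsolete <- logical(length(term_starts))
  synonyms <- vector("list", length(term_starts))
  xrefs <- vector("list", length(term_starts))

  for (k in seq_along(term_starts)) {
    body <- lines[(term_starts[k] + 1L):ends[k]]
    body <- body[nzchar(body)]
    id_line <- grep("^id: ", body, value = TRUE)
    if (length(id_line) != 1L)
      stop("malformed [Term] stanza near line ", term_starts[k],
           ": expected exactly one 'id:' line")
    ids[k] <- sub("^id: ", "", id_line)
    name_line <- grep("^name: ", body, value = TRUE)
    names_[k] <- if (length(name_line)) sub("^name: ", "", name_line[1]) else ""
    obsolete[k] <- any(grepl("^is_obsolete: true", body))
    syn_lines <- grep("^synonym: ", body, value = TRUE)
    # synonym: "text" SCOPE [...]
    synonyms[[k]] <- unique(vapply(syn_lines, function(s) {
      m <- regmatches(s, regexpr('"[^"]*"', s))
      if (length(m)) substr(m, 2L, nchar(m) - 1L) else ""
    }, character(1), USE.NAMES = FALSE))
    synonyms[[k]] <- synonyms[[k]][nzchar(synonyms[[k]])]
    xr_lines <- grep("^xref: ", body, value = TRUE)
    xrefs[[k]] <- unique(sub("\\s.*$", "", sub("^xref: ", "", xr_lines)))
  }
  if (anyDuplicated(ids))
    stop("duplicate term id in ontology: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(names_) & !obsolete))
    stop("ontology term without a name: ",
         paste(ids[!nzchar(names_) & !obsolete], collapse = ", "))
  data.frame(term_id = ids, name = names_, obsolete = obsolete,
             synonyms = I(synonyms), xrefs = I(xrefs),
             stringsAsFactors = FALSE)
}

#' Parse a MEDIC-style disease vocabulary table
#'
#' @param path Path to a TSV/CSV file (or a data.frame already read).
#' @param id_col,name_col,syn_col Column names (defaults follow the CTD MEDIC
#'   export: `DiseaseID`, `DiseaseName`, `Synonyms`).
#' @param syn_sep Separator inside the synonym column.
#' @param sep Field separator when reading from a path.
#' @return A data.frame with columns `medic_id`, `name` and list-column
#'   `synonyms` (blank tokens dropped).
#' @export
parse_medic <- function(path, id_col = "DiseaseID", name_col = "DiseaseName",
                        syn_col = "Synonyms", syn_sep = "|", sep = "\t") {
  tab <- if (is.data.frame(path)) path
         else utils::read.delim(path, sep = sep, header = TRUE,
                                stringsAsFactors = FALSE, comment.char = "#",
                                quote = "", check.names = FALSE)
  if (!id_col %in% names(tab))
    stop("MEDIC table lacks id column '", id_col, "'")
  if (!name_col %in% names(tab))
    stop("MEDIC table lacks name column '", name_col, "'")
  syn_raw <- if (syn_col %in% names(tab)) as.character(tab[[syn_col]]) else rep("", nrow(tab))
  syn_raw[is.na(syn_raw)] <- ""
  synonyms <- lapply(strsplit(syn_raw, syn_sep, fixed = TRUE), function(s) {
    s <- trimws(s)
    unique(s[nzchar(s)])
  })
  data.frame(medic_id = as.character(tab[[id_col]]),
             name = as.character(tab[[name_col]]),
             synonyms = I(synonyms), stringsAsFactors = FALSE)
}

# strip possessives, special symbols; lowercase; collapse whitespace
.norm_basic <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("'s\\b", "", x)        # possessive marker
  x <- gsub("'", "", x)            # stray apostrophes / trailing '
  x <- gsub("[-_,.()]", " ", x)    # semantically irrelevant symbols
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# "A, B" -> "B A"; first comma only, two-segment reorder
.comma_invert <- function(x) {
  pos <- regexpr(",", x, fixed = TRUE)
  if (pos < 0L) return(NA_character_)
  a <- trimws(substr(x, 1L, pos - 1L))
  b <- trimws(substr(x, pos + 1L, nchar(x)))
  if (!nzchar(a) || !nzchar(b)) return(NA_character_)
  paste(b, a)
}

# depluralize each token by stripping one trailing "s", guarded by an
# optional token inventory (avoids mangling e.g. "diabetes")
.depluralize <- function(x, inventory = NULL) {
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  out <- vapply(toks, function(t) {
    if (nchar(t) > 3L && grepl("s$", t) && !grepl("ss$", t)) {
      stripped <- sub("s$", "", t)
      if (is.null(inventory) || stripped %in% inventory) return(stripped)
    }
    t
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = " ")
}

#' Normalize a disease name to canonical surface forms
#'
#' Deterministic pipeline: lowercase, strip possessive markers, replace
#' hyphens/underscores/commas/periods/parentheses with spaces and collapse
#' whitespace; then derive candidate variants by comma inversion (on the raw
#' form, first comma only: `"A, B"` also yields `"B A"`) and token
#' depluralization.  Singular/plural, possessive, symbol and word-order
#' variants of the same disease therefore normalize to a shared form.
#'
#' @param raw A single disease name.
#' @param inventory Optional character vector of known vocabulary tokens used
#'   to guard depluralization (a trailing "s" is only stripped when the
#'   stripped token is in the inventory); `NULL` disables the guard.
#' @return A list with `primary` (the normalized form) and `variants`
#'   (ordered unique candidate forms, primary first).
#' @examples
#' normalize_term("Diabetes Mellitus, Type 1")$variants
#' @export
normalize_term <- function(raw, inventory = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(trimws(raw)))
  primary <- .norm_basic(raw)
  variants <- primary
  inv <- .comma_invert(raw)
  if (!is.na(inv)) variants <- c(variants, .norm_basic(inv))
  # depluralized forms of every candidate so far
  variants <- c(variants,
                vapply(variants, .depluralize, character(1),
                       inventory = inventory, USE.NAMES = FALSE))
  variants <- unique(variants[nzchar(variants)])
  list(primary = primary, variants = variants)
}

#' Build an expanded disease vocabulary
#'
#' Combines an ontology's names and synonyms with MEDIC names/synonyms
#' attached to ontology terms through MeSH/OMIM cross-references.  All
#' surface forms are stored normalized; each maps to exactly one term id.
#' Collisions are resolved by source priority (ontology name > ontology
#' synonym > MEDIC-via-xref), ties by lexicographically smaller term id, and
#' are logged in the result.
#'
#' @param terms Output of [parse_ontology()].
#' @param medic Output of [parse_medic()], or `NULL` for ontology-only.
#' @return An object of class `disease_vocabulary`: a list with `entries`
#'   (data.frame surface_form/term_id/provenance), `collisions`,
#'   `n_unmatched_medic`, `stats`, and the token `inventory`.
#' @export
build_vocabulary <- function(terms, medic = NULL) {
  stopifnot(nrow(terms) > 0L)
  if (!is.null(medic) && !all(c("medic_id", "name", "synonyms") %in% names(medic)))
    stop("medic must be the output of parse_medic()")
  active <- terms[!terms$obsolete, , drop = FALSE]

  sf <- character(0); tid <- character(0); prov <- character(0)
  add <- function(surface, term_id, source) {
    sf <<- c(sf, surface); tid <<- c(tid, term_id); prov <<- c(prov, source)
  }
  for (k in seq_len(nrow(active))) {
    add(active$name[k], active$term_id[k], "ontology-name")
    for (s in active$synonyms[[k]]) add(s, active$term_id[k], "ontology-synonym")
  }
  n_unmatched <- 0L
  multi_xref <- 0L
  if (!is.null(medic) && nrow(medic) > 0L) {
    # xref accession -> term ids (an accession may be claimed by several terms)
    xref_map <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(active))) for (x in active$xrefs[[k]])
      assign(x, c(get0(x, envir = xref_map, ifnotfound = character(0)),
                  active$term_id[k]), envir = xref_map)
    for (k in seq_len(nrow(medic))) {
      hits <- get0(medic$medic_id[k], envir = xref_map, ifnotfound = character(0))
      if (length(hits) == 0L) { n_unmatched <- n_unmatched + 1L; next }
      if (length(hits) > 1L) multi_xref <- multi_xref + 1L
      for (h in hits) {
        add(medic$name[k], h, "medic-via-xref")
        for (s in medic$synonyms[[k]]) add(s, h, "medic-via-xref")
      }
    }
  }

  # token inventory from un-depluralized normalized forms
  basic <- vapply(sf, .norm_basic, character(1), USE.NAMES = FALSE)
  inventory <- unique(unlist(strsplit(basic, " ", fixed = TRUE)))

  prio <- c("ontology-name" = 1L, "ontology-synonym" = 2L, "medic-via-xref" = 3L)
  ent <- new.env(parent = emptyenv())   # surface -> c(term_id, provenance)
  collisions <- list()
  for (k in seq_along(sf)) {
    v <- normalize_term(sf[k], inventory = inventory)
    for (form in v$variants) {
      cur <- get0(form, envir = ent)
      if (is.null(cur)) {
        assign(form, c(tid[k], prov[k]), envir = ent)
      } else if (cur[1] != tid[k]) {
        collisions[[length(collisions) + 1L]] <-
          data.frame(surface_form = form, kept = NA_character_,
                     dropped = NA_character_, stringsAsFactors = FALSE)
        keep_new <- prio[[prov[k]]] < prio[[cur[2]]] ||
          (prio[[prov[k]]] == prio[[cur[2]]] && tid[k] < cur[1])
        if (keep_new) {
          collisions[[length(collisions)]]$kept <- tid[k]
          collisions[[length(collisions)]]$dropped <- cur[1]
          assign(form, c(tid[k], prov[k]), envir = ent)
        } else {
          collisions[[length(collisions)]]$kept <- cur[1]
          collisions[[length(collisions)]]$dropped <- tid[k]
        }
      }
    }
  }
  forms <- ls(ent)
  entries <- data.frame(
    surface_form = forms,
    term_id = vapply(forms, function(f) get(f, envir = ent)[1], character(1)),
    provenance = vapply(forms, function(f) get(f, envir = ent)[2], character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  collisions <- if (length(collisions)) do.call(rbind, collisions)
                else data.frame(surface_form = character(), kept = character(),
                                dropped = character(), stringsAsFactors = FALSE)
  structure(list(
    entries = entries,
    collisions = collisions,
    n_unmatched_medic = n_unmatched,
    n_multi_xref_medic = multi_xref,
    inventory = inventory,
    stats = c(n_terms = nrow(active),
              n_surface_forms = nrow(entries),
              n_from_ontology = sum(entries$provenance != "medic-via-xref"),
              n_from_medic = sum(entries$provenance == "medic-via-xref"))),
    class = "disease_vocabulary")
}

#' @export
print.disease_vocabulary <- function(x, ...) {
  cat("Disease vocabulary:", x$stats["n_surface_forms"], "surface forms over",
      x$stats["n_terms"], "ontology terms\n")
  cat("  from ontology:", x$stats["n_from_ontology"],
      "| via MEDIC xref:", x$stats["n_from_medic"],
      "| unmatched MEDIC entries:", x$n_unmatched_medic,
      "| collisions:", nrow(x$collisions), "\n")
  invisible(x)
}

#' Match a free-text disease name against a vocabulary
#'
#' Tries the normalized form first, then each normalization variant
#' (comma inversion, depluralization, combinations) in the fixed order
#' produced by [normalize_term()]; returns the first hit.
#'
#' @param raw A disease name.
#' @param vocab A `disease_vocabulary`.
#' @return The matched term id, or `NA_character_` for no-match.
#' @export
match_disease <- function(raw, vocab) {
  stopifnot(inherits(vocab, "disease_vocabulary"))
  lookup <- vocab$entries$term_id
  names(lookup) <- vocab$entries$surface_form
  for (form in normalize_term(raw, inventory = vocab$inventory)$variants) {
    hit <- lookup[form]
    if (!is.na(hit)) return(unname(hit))
  }
  NA_character_
}

#' Write a built vocabulary as TSV
#'
#' Three columns: surface_form, term_id, provenance.
#' @param vocab A `disease_vocabulary`.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(vocab$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
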