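#' Ontology graphs for annotation-closure queries
#'
#' An `ontology_graph` holds a term DAG in the style of the Gene Ontology
#' molecular-function branch: `is_a` edges (child to parent), optional
#' `part_of` edges, term labels, obsolescence flags, and Enzyme Commission
#' (EC) cross-references harvested from `xref` lines. Term identifiers are
#' opaque strings, so toy ontologies with ids like `"T:0001"` are legal.
#'
#' @param terms character vector of term identifiers.
#' @param names named character vector of term labels (names are term ids).
#' @param is_a named list, term id -> character vector of parent term ids.
#' @param part_of named list, term id -> character vector of parent term ids.
#' @param ec_xrefs named list, term id -> character vector of EC strings.
#' @param obsolete named logical vector of obsolescence flags.
#'
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, names = NULL, is_a = list(),
                           part_of = list(), ec_xrefs = list(),
                           obsolete = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    stop("duplicate term identifiers: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  if (is.null(names)) names <- stats::setNames(terms, terms)
  if (is.null(obsolete)) obsolete <- stats::setNames(rep(FALSE, length(terms)), terms)
  for (rel in list(is_a = is_a, part_of = part_of)) {
    ends <- unique(c(names(rel), unlist(rel, use.names = FALSE)))
    bad <- setdiff(ends, terms)
    if (length(bad)) {
      stop("edge endpoint(s) not declared as terms: ",
           paste(bad, collapse = ", "))
    }
  }
  g <- structure(
    list(terms = terms,
         names = names[terms],
         is_a = is_a,
         part_of = part_of,
         ec_xrefs = ec_xrefs,
         obsolete = obsolete[terms],
         children = list(is_a = .invert_edges(is_a),
                         part_of = .invert_edges(part_of))),
    class = "ontology_graph")
  cyc <- .find_cycle(g$is_a, terms)
  if (!is.null(cyc)) {
    stop("is_a relation is cyclic: ", paste(cyc, collapse = " -> "))
  }
  g
}

.invert_edges <- function(rel) {
  if (!length(rel)) return(list())
  child <- rep(names(rel), lengths(rel))
  parent <- unlist(rel, use.names = FALSE)
  split(child, parent)
}

# Kahn's algorithm; returns one cycle (as a term path) or NULL if acyclic.
.find_cycle <- function(is_a, terms) {
  outdeg <- stats::setNames(lengths(is_a[terms]), terms)
  outdeg[is.na(outdeg)] <- 0L
  incoming <- .invert_edges(is_a)   # parent -> children
  queue <- terms[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in incoming[[t]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk the residual graph to exhibit one cycle
  residual <- names(outdeg)[outdeg > 0L]
  cur <- residual[[1]]; path <- character()
  repeat {
    path <- c(path, cur)
    nxt <- intersect(is_a[[cur]], residual)[[1]]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    cur <- nxt
  }
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph> %d terms, %d is_a edges, %d part_of edges, %d EC-xref terms, %d obsolete\n",
    length(x$terms), sum(lengths(x$is_a)), sum(lengths(x$part_of)),
    sum(lengths(x$ec_xrefs) > 0), sum(x$obsolete)))
  invisible(x)
}

#' Read an OBO-format ontology
#'
#' Parses the OBO 1.2 subset used by annotation pipelines: `[Term]` stanzas
#' with `id`, `name`, `is_a`, `relationship: part_of`, `xref` and
#' `is_obsolete` tags. Trailing `! comment` text on tag lines is stripped.
#' EC cross-references are taken from `xref: EC:<code>` lines; xrefs with
#' other prefixes are ignored.
#'
#' @param path path to an OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  # split into stanzas
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("not an OBO file (no stanzas): ", path)
  terms <- character(); labels <- character()
  is_a <- list(); part_of <- list(); ec_xrefs <- list()
  obsolete <- logical()
  idx <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    head <- lines[stanza_starts[i]]
    if (head != "[Term]") next
    body <- lines[seq(stanza_starts[i] + 1L, idx[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    tags <- sub(":.*$", "", body)
    vals <- sub("^[^:]+: *", "", body)
    vals <- sub(" +! .*$", "", vals)   # inline comments
    id <- vals[tags == "id"][1]
    if (is.na(id)) stop("OBO [Term] stanza without an id near line ",
                        stanza_starts[i])
    terms <- c(terms, id)
    nm <- vals[tags == "name"][1]
    labels[id] <- if (is.na(nm)) id else nm
    parents <- vals[tags == "is_a"]
    if (length(parents)) is_a[[id]] <- parents
    rels <- vals[tags == "relationship"]
    po <- sub("^part_of +", "", rels[startsWith(rels, "part_of ")])
    if (length(po)) part_of[[id]] <- po
    xr <- vals[tags == "xref"]
    ec <- sub("^EC:", "", xr[startsWith(xr, "EC:")])
    if (length(ec)) ec_xrefs[[id]] <- ec
    obsolete[id] <- identical(vals[tags == "is_obsolete"][1], "true")
  }
  if (!length(terms)) stop("OBO file contains no [Term] stanzas: ", path)
  # edges may reference terms not declared in-file; declare them implicitly
  referenced <- unique(c(unlist(is_a, use.names = FALSE),
                         unlist(part_of, use.names = FALSE)))
  implicit <- setdiff(referenced, terms)
  if (length(implicit)) {
    terms <- c(terms, implicit)
    labels[implicit] <- implicit
    obsolete[implicit] <- FALSE
  }
  ontology_graph(terms, names = labels, is_a = is_a, part_of = part_of,
                 ec_xrefs = ec_xrefs, obsolete = obsolete)
}

#' Write an ontology back to OBO format
#'
#' Emits the same OBO 1.2 subset that [read_obo()] consumes, so a graph
#' round-trips: `read_obo(write_obo(g)) == g`.
#'
#' @param graph an [ontology_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, "wb")   # binary: LF endings regardless of platform
  on.exit(close(con))
  out <- c("format-version: 1.2", "")
  for (t in graph$terms) {
    stanza <- c("[Term]", paste0("id: ", t), paste0("name: ", graph$names[[t]]))
    for (p in graph$is_a[[t]]) stanza <- c(stanza, paste0("is_a: ", p))
    for (p in graph$part_of[[t]]) {
      stanza <- c(stanza, paste0("relationship: part_of ", p))
    }
    for (ec in graph$ec_xrefs[[t]]) stanza <- c(stanza, paste0("xref: EC:", ec))
    if (isTRUE(graph$obsolete[[t]])) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Descendant closure of a term
#'
#' Returns the term together with every term reachable from it in the
#' child-ward direction along the chosen relations — the "term or any of
#' its children" semantics used by ontology-aware annotation queries.
#' Obsolete terms are excluded by default (the query still returns the
#' focus term itself even if obsolete).
#'
#' @param graph an [ontology_graph()].
#' @param term focus term identifier.
#' @param relations character subset of `c("is_a", "part_of")`.
#' @param include_obsolete keep obsolete descendant terms?
#' @return character vector of term identifiers (always contains `term`).
#' @export
descendant_closure <- function(graph, term, relations = "is_a",
                               include_obsolete = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!term %in% graph$terms) stop("unknown term: ", term)
  bad <- setdiff(relations, c("is_a", "part_of"))
  if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "))
  seen <- stats::setNames(logical(length(graph$terms)), graph$terms)
  queue <- term
  seen[term] <- TRUE
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    for (rel in relations) {
      for (ch in graph$children[[rel]][[t]]) {
        if (!seen[[ch]]) {
          seen[[ch]] <- TRUE
          queue <- c(queue, ch)
        }
      }
    }
  }
  out <- names(seen)[seen]
  if (!include_obsolete) out <- out[!graph$obsolete[out] | out == term]
  out
}

#' Map genes to EC numbers through ontology cross-references
#'
#' Projects molecular-function annotations onto EC numbers using the EC
#' cross-references attached to ontology terms: a gene receives every EC
#' cross-referenced from any term it is positively annotated to. Negated
#' (`NOT`) annotations contribute nothing. Each derived EC carries the
#' evidence class of the annotation it came from, so experimentally
#' supported EC assignments can be told apart from predicted ones.
#'
#' @param annotations annotation data frame (see [read_gaf()]); rows with
#'   `aspect != "F"` are dropped with a warning.
#' @param graph an [ontology_graph()] with EC xrefs.
#' @return data frame with columns `gene_id`, `ec`, `evidence_class`
#'   (one row per distinct combination).
#' @export
derive_ec_annotations <- function(annotations, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (any(annotations$aspect != "F")) {
    warning("dropping ", sum(annotations$aspect != "F"),
            " non-molecular-function annotation(s)")
    annotations <- annotations[annotations$aspect == "F", , drop = FALSE]
  }
  pos <- annotations[!annotations$negated, , drop = FALSE]
  if (!nrow(pos)) {
    return(data.frame(gene_id = character(), ec = character(),
                      evidence_class = character()))
  }
  n_ec <- lengths(graph$ec_xrefs[pos$term])
  n_ec[is.na(n_ec)] <- 0L
  keep <- n_ec > 0L
  if (!any(keep)) {
    return(data.frame(gene_id = character(), ec = character(),
                      evidence_class = character()))
  }
  pos <- pos[keep, , drop = FALSE]
  n_ec <- n_ec[keep]
  out <- data.frame(
    gene_id = rep(pos$gene_id, n_ec),
    ec = unlist(graph$ec_xrefs[pos$term], use.names = FALSE),
    evidence_class = rep(as.character(evidence_class(pos$evidence_code)), n_ec),
    stringsAsFactors = FALSE)
  unique(out)
}
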