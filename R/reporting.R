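#' Build a hierarchical gene-group report
#'
#' Arranges a verified gene set into a gene group anchored on a class
#' term, with subgroups anchored on terms inside the class closure —
#' mirroring how curated gene-group pages are organised along the
#' ontology. Each gene is placed in every subgroup whose closure contains
#' one of its (most-specific) annotated terms, so a gene can sit in two
#' sibling subgroups; the report carries both the unique member count and
#' the total membership count with multiplicity.
#'
#' @param gene_terms data frame with columns `gene_id`, `term`: each
#'   verified gene with its most-specific in-closure term(s).
#' @param graph an [ontology_graph()].
#' @param class_term root anchor term.
#' @param subgroups subgroup specification: a character vector of anchor
#'   terms, or a named list `name = list(term =, children =)` for nested
#'   subgroups. All anchors must lie in the class closure.
#' @param name group display name (defaults to the class term's label).
#' @return object of class `gene_group`: list with `name`, `class_term`,
#'   `members`, `children` (list of `gene_group`), `n_unique`,
#'   `n_memberships`.
#' @export
build_groups <- function(gene_terms, graph, class_term, subgroups = NULL,
                         name = NULL) {
  stopifnot(all(c("gene_id", "term") %in% colnames(gene_terms)))
  root_closure <- descendant_closure(graph, class_term)
  outside <- setdiff(unique(gene_terms$term), root_closure)
  if (length(outside)) {
    stop("gene term(s) outside the class closure: ",
         paste(outside, collapse = ", "))
  }
  if (is.null(name)) name <- graph$names[[class_term]]
  specs <- .normalize_subgroups(subgroups, graph)
  for (s in specs) {
    if (!s$term %in% root_closure) {
      stop("subgroup anchor '", s$term, "' is outside the closure of '",
           class_term, "'")
    }
  }
  children <- lapply(specs, function(s) {
    sub_terms <- descendant_closure(graph, s$term)
    sub_genes <- gene_terms[gene_terms$term %in% sub_terms, , drop = FALSE]
    build_groups(sub_genes, graph, s$term, subgroups = s$children,
                 name = s$name)
  })
  members <- sort(unique(gene_terms$gene_id))
  n_memberships <- if (length(children)) {
    sum(vapply(children, function(ch) ch$n_unique, integer(1)))
  } else {
    length(members)
  }
  structure(list(name = name, class_term = class_term, members = members,
                 children = children, n_unique = length(members),
                 n_memberships = as.integer(n_memberships)),
            class = "gene_group")
}

.normalize_subgroups <- function(subgroups, graph) {
  if (is.null(subgroups) || !length(subgroups)) return(list())
  if (is.character(subgroups)) {
    return(lapply(subgroups, function(t) {
      list(name = graph$names[[t]], term = t, children = NULL)
    }))
  }
  lapply(seq_along(subgroups), function(i) {
    s <- subgroups[[i]]
    nm <- names(subgroups)[i]
    list(name = if (!is.null(nm) && nzchar(nm)) nm else
           graph$names[[s$term]],
         term = s$term, children = s$children)
  })
}

#' @export
print.gene_group <- function(x, indent = 0, ...) {
  cat(strrep("  ", indent),
      sprintf("%s [%s]: %d genes", x$name, x$class_term, x$n_unique),
      if (length(x$children)) {
        sprintf(" (%d memberships in subgroups)", x$n_memberships)
      } else "",
      "\n", sep = "")
  for (ch in x$children) print(ch, indent = indent + 1)
  invisible(x)
}

#' Serialise / read a gene group as JSON
#'
#' The JSON form round-trips: `read_groups_json(write_groups_json(g))`
#' reconstructs an identical group tree.
#'
#' @param group a `gene_group` from [build_groups()].
#' @param path output path.
#' @return `path` (writer) / a `gene_group` (reader).
#' @export
write_groups_json <- function(group, path) {
  jsonlite::write_json(.group_to_list(group), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.group_to_list <- function(g) {
  list(name = g$name, class_term = g$class_term,
       members = as.list(g$members),
       n_unique = g$n_unique, n_memberships = g$n_memberships,
       children = lapply(g$children, .group_to_list))
}

#' @rdname write_groups_json
#' @export
read_groups_json <- function(path) {
  .list_to_group(jsonlite::read_json(path))
}

.list_to_group <- function(l) {
  structure(list(name = l$name, class_term = l$class_term,
                 members = as.character(unlist(l$members)),
                 children = lapply(l$children, .list_to_group),
                 n_unique = as.integer(l$n_unique),
                 n_memberships = as.integer(l$n_memberships)),
            class = "gene_group")
}

#' Evidence strata of a verified set
#'
#' Assigns each verified gene to exactly one stratum by its strongest
#' supporting evidence class — experimental beats
#' computational/electronic beats author statement — and counts the
#' strata. This is the "how well is this activity actually known"
#' breakdown shown alongside gene-group reports.
#'
#' @param assessments data frame from [assess_genes()] (columns `n_exp`,
#'   `n_comp`, `n_elec`, `n_auth`).
#' @return named integer vector with entries `experimental`,
#'   `computational_electronic`, `author_statement`; sums to
#'   `nrow(assessments)`.
#' @export
evidence_strata <- function(assessments) {
  stratum <- ifelse(assessments$n_exp > 0, "experimental",
                    ifelse(assessments$n_comp + assessments$n_elec > 0,
                           "computational_electronic",
                           "author_statement"))
  out <- stats::setNames(integer(3), c("experimental",
                                       "computational_electronic",
                                       "author_statement"))
  tab <- table(stratum)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Write evidence strata as TSV
#'
#' @param strata named integer vector from [evidence_strata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strata <- function(strata, path) {
  utils::write.table(
    data.frame(stratum = names(strata), n_genes = as.integer(strata)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
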