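#' Source hit sets
#'
#' A `hit_set` records which genes a given source identifies for an
#' enzyme class, together with the supporting records (provenance) that
#' put each gene there.
#'
#' @param source source name.
#' @param genes character vector of gene identifiers.
#' @param provenance named list, gene -> data frame of supporting records.
#' @return object of class `hit_set`.
#' @export
hit_set <- function(source, genes, provenance = NULL) {
  genes <- sort(unique(as.character(genes)))
  if (is.null(provenance)) {
    provenance <- stats::setNames(
      lapply(genes, function(g) data.frame(gene_id = g)), genes)
  }
  if (length(genes) && !all(genes %in% names(provenance))) {
    stop("every hit gene needs at least one provenance record")
  }
  structure(list(source = source, genes = genes,
                 provenance = provenance[genes]),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set> source '%s': %d genes\n", x$source,
              length(x$genes)))
  invisible(x)
}

#' Genes hit by an ontology-class query
#'
#' Returns the genes carrying at least one non-negated annotation to the
#' class term or any of its descendants — the "term or any of its
#' children" query used by annotation browsers. Optional filters restrict
#' by assigning source (e.g. to exclude a database's electronic pipeline)
#' and by evidence code.
#'
#' @param annotations annotation data frame ([read_gaf()]).
#' @param graph an [ontology_graph()].
#' @param class_term the class anchor term (must be in `graph`).
#' @param name hit-set name (defaults to `class_term`).
#' @param sources keep only these assigning sources (NULL = all).
#' @param exclude_sources drop these assigning sources.
#' @param evidence keep only these evidence codes (NULL = all).
#' @param exclude_evidence drop these evidence codes.
#' @param relations closure relations, see [descendant_closure()].
#' @return a [hit_set()].
#' @export
hits_from_go <- function(annotations, graph, class_term, name = class_term,
                         sources = NULL, exclude_sources = NULL,
                         evidence = NULL, exclude_evidence = NULL,
                         relations = "is_a") {
  closure <- descendant_closure(graph, class_term, relations = relations)
  keep <- annotations$term %in% closure & !annotations$negated
  if (!is.null(sources)) keep <- keep & annotations$source %in% sources
  if (!is.null(exclude_sources)) {
    keep <- keep & !annotations$source %in% exclude_sources
  }
  if (!is.null(evidence)) {
    keep <- keep & annotations$evidence_code %in% evidence
  }
  if (!is.null(exclude_evidence)) {
    keep <- keep & !annotations$evidence_code %in% exclude_evidence
  }
  sel <- annotations[keep, , drop = FALSE]
  hit_set(name, sel$gene_id, split(sel, sel$gene_id))
}

#' Genes hit by an EC-number query
#'
#' Returns the genes with at least one EC record matching the (possibly
#' wildcarded) query under [ec_matches()], e.g. all of class 6 for query
#' `6.-.-.-`.
#'
#' @param ec_records data frame from [read_ec_table()].
#' @param query an EC string or `ec_number`, wildcards allowed.
#' @param name hit-set name.
#' @param reviewed_only restrict to manually reviewed records?
#' @return a [hit_set()].
#' @export
hits_from_ec <- function(ec_records, query, name = "ec",
                         reviewed_only = FALSE) {
  q <- parse_ec(query)
  df <- ec_records
  if (reviewed_only) df <- df[df$reviewed, , drop = FALSE]
  ok <- vapply(df$ec, function(e) {
    cand <- parse_ec(e)
    !anyNA(cand$levels) && ec_matches(q, cand)
  }, logical(1), USE.NAMES = FALSE)
  # wildcard records can never satisfy a concrete match; they only count
  # for queries they are at least as specific as
  wc <- vapply(df$ec, function(e) anyNA(parse_ec(e)$levels), logical(1),
               USE.NAMES = FALSE)
  ok[wc] <- vapply(df$ec[wc], function(e) {
    lv_c <- parse_ec(e)$levels
    lv_q <- q$levels
    all(mapply(function(qi, ci) is.na(qi) || (!is.na(ci) && qi == ci),
               lv_q, lv_c))
  }, logical(1), USE.NAMES = FALSE)
  sel <- df[ok, , drop = FALSE]
  hit_set(name, sel$gene_id, split(sel, sel$gene_id))
}

#' Genes hit by orthology transfer from a human gold set
#'
#' Filters orthology calls the way a curator triages DIOPT output: calls
#' from gold-set human genes with score above `hard_min` are considered;
#' of those, calls with score at least `retain_min` and the relevant
#' enzymatic domain present are retained automatically, while borderline
#' calls (score between the thresholds, or domain absent) are emitted to
#' a manual-review list (attribute `"review"`) rather than the hit set.
#' Named genes in `admit` reproduce curator decisions by promoting their
#' review-list calls into the hit set.
#'
#' @param calls data frame from [read_orthology_table()].
#' @param human_gold character vector of gold human genes.
#' @param hard_min scores must exceed this to be considered (default 2).
#' @param retain_min minimum score for automatic retention (default 5).
#' @param name hit-set name.
#' @param admit character vector of fly genes admitted from review.
#' @return a [hit_set()] with a `"review"` attribute (data frame of
#'   borderline calls).
#' @export
hits_from_orthology <- function(calls, human_gold, hard_min = 2L,
                                retain_min = 5L, name = "orthology",
                                admit = character()) {
  stopifnot(hard_min <= retain_min)
  considered <- calls[calls$human_gene %in% human_gold &
                        calls$score > hard_min, , drop = FALSE]
  auto <- considered$score >= retain_min & considered$domain_present
  review <- considered[!auto, , drop = FALSE]
  keep <- considered[auto | considered$fly_gene %in% admit, , drop = FALSE]
  hs <- hit_set(name, keep$fly_gene, split(keep, keep$fly_gene))
  attr(hs, "review") <- review[!review$fly_gene %in% admit, , drop = FALSE]
  hs
}

#' Merge hit sets into a gene-by-source membership matrix
#'
#' @param hitsets list of [hit_set()] objects (uniquely named sources).
#' @return data frame: `gene_id` plus one logical column per source; rows
#'   are the sorted union of all hit sets and every row has at least one
#'   `TRUE`.
#' @export
merge_sources <- function(hitsets) {
  stopifnot(length(hitsets) >= 1L)
  srcs <- vapply(hitsets, function(h) h$source, character(1))
  if (anyDuplicated(srcs)) stop("duplicate source names in hit sets")
  union_genes <- sort(unique(unlist(lapply(hitsets, `[[`, "genes"))))
  out <- data.frame(gene_id = union_genes, stringsAsFactors = FALSE)
  for (h in hitsets) out[[h$source]] <- union_genes %in% h$genes
  out
}

#' Venn region counts over hit sets
#'
#' Counts genes in every non-empty source-combination region. Regions are
#' keyed by their sorted source names joined with `"+"`, so the keys are
#' deterministic and independent of input order. Supports up to 6
#' sources (63 regions).
#'
#' @param hitsets list of [hit_set()] objects.
#' @return named integer vector over all non-empty source subsets (zero
#'   counts included); values sum to the union size.
#' @export
venn_counts <- function(hitsets) {
  srcs <- sort(vapply(hitsets, function(h) h$source, character(1)))
  if (length(srcs) > 6L) {
    stop("venn_counts() supports at most 6 sources; ",
         "use merge_sources() for larger collections")
  }
  m <- merge_sources(hitsets)
  sig <- apply(m[srcs], 1, function(row) paste(srcs[row], collapse = "+"))
  regions <- unlist(lapply(seq_along(srcs), function(k) {
    apply(utils::combn(srcs, k), 2, paste, collapse = "+")
  }))
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Categorise candidate genes against verified and discarded sets
#'
#' Candidates surfaced by EC- or orthology-based searches fall into three
#' categories: (i) already identified via verified annotations,
#' (ii) already identified and discarded via erroneous annotations, or
#' (iii) novel genes not previously identified. A gene present in both
#' the verified and discarded sets is an integrity error.
#'
#' @param candidates character vector of candidate genes.
#' @param verified character vector of verified genes.
#' @param discarded character vector of discarded genes.
#' @return data frame `gene_id`, `category` (`"verified"`, `"discarded"`,
#'   `"novel"`).
#' @export
categorize_novel <- function(candidates, verified, discarded) {
  both <- intersect(verified, discarded)
  if (length(both)) {
    stop("gene(s) in both verified and discarded sets: ",
         paste(both, collapse = ", "))
  }
  candidates <- unique(as.character(candidates))
  data.frame(
    gene_id = candidates,
    category = ifelse(candidates %in% verified, "verified",
                      ifelse(candidates %in% discarded, "discarded",
                             "novel")),
    stringsAsFactors = FALSE)
}

#' Write a membership matrix as TSV / venn counts as JSON
#'
#' @param matrix data frame from [merge_sources()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership_matrix <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_membership_matrix
#' @param counts named integer vector from [venn_counts()].
#' @export
write_venn_json <- function(counts, path) {
  jsonlite::write_json(as.list(counts), path, auto_unbox = TRUE)
  invisible(path)
}
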