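#' Run the reconciliation + evaluation pipeline over a fixture bundle
#'
#' Reads a bundle directory, rebuilds each source's hit set for an enzyme
#' class with the package's own query operations (ontology-closure GO
#' query, wildcard EC query with accession resolution, gold-restricted
#' orthology filtering), and scores every source against the bundle's
#' gold set.
#'
#' @param dir bundle directory (see [generate_bundle()]).
#' @param class enzyme class name; default: every class in the bundle.
#' @return named list per class: `hitsets`, `gold` (gene vector),
#'   `confusion` (named list of [confusion()] results per source),
#'   `report` (data frame from [evaluation_report()]).
#' @export
evaluate_bundle <- function(dir, class = NULL) {
  b <- read_bundle(dir)
  classes <- if (is.null(class)) names(b$truth$class_terms) else class
  out <- list()
  for (cl in classes) {
    ct <- b$truth$class_terms[[cl]]
    gold <- b$gold$gene_id[b$gold$class == cl]
    hitsets <- list()
    for (src in names(b$annotations)) {
      hitsets[[src]] <- hits_from_go(b$annotations[[src]], b$graph,
                                     ct$root, name = src)
    }
    for (src in unique(b$ec$source)) {
      recs <- b$ec[b$ec$source == src, , drop = FALSE]
      recs <- resolve_ids(recs, b$id_map)$resolved
      hitsets[[src]] <- hits_from_ec(recs, ct$ec, name = src)
    }
    if (nrow(b$orthology)) {
      hg <- b$human_gold$human_gene[b$human_gold$class == cl]
      hitsets$orthology <- hits_from_orthology(b$orthology, hg,
                                               name = "orthology")
    }
    out[[cl]] <- list(
      hitsets = hitsets, gold = gold,
      confusion = lapply(hitsets, confusion, gold = gold),
      report = evaluation_report(hitsets, gold))
  }
  if (!is.null(class) && length(class) == 1L) out[[class]] else out
}

#' Triage a bundle's pooled annotations for one class
#'
#' Pools every GAF source's in-closure annotations for the class and runs
#' the per-gene confidence assessment over them — the integration step of
#' the review workflow.
#'
#' @inheritParams evaluate_bundle
#' @param class enzyme class name.
#' @return data frame of per-gene assessments ([assess_genes()]).
#' @export
triage_bundle <- function(dir, class) {
  b <- read_bundle(dir)
  ct <- b$truth$class_terms[[class]]
  closure <- descendant_closure(b$graph, ct$root)
  pooled <- do.call(rbind, lapply(b$annotations, function(a) {
    a[a$term %in% closure, , drop = FALSE]
  }))
  rownames(pooled) <- NULL
  assess_genes(pooled, graph = b$graph)
}
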