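#' Classify evidence codes into evidence classes
#'
#' Evidence codes are grouped into four classes: experimental (IDA, IMP,
#' IGI), computational analysis (ISS and its child codes ISO/ISA/ISM,
#' plus IBA), author statement (TAS, NAS) and electronic (IEA).
#' Unrecognised codes are given author-statement-equivalent weight and
#' flagged via the `"unknown"` attribute, so they can never promote a
#' gene into the high or medium confidence tiers.
#'
#' @param code character vector of evidence-code abbreviations.
#' @return character vector of classes (`"experimental"`,
#'   `"computational"`, `"author_statement"`, `"electronic"`), with a
#'   logical attribute `"unknown"` marking unrecognised codes.
#' @export
evidence_class <- function(code) {
  map <- c(IDA = "experimental", IMP = "experimental", IGI = "experimental",
           ISS = "computational", ISO = "computational",
           ISA = "computational", ISM = "computational",
           IBA = "computational",
           TAS = "author_statement", NAS = "author_statement",
           IEA = "electronic")
  known <- code %in% names(map)
  out <- ifelse(known, map[code], "author_statement")
  structure(unname(out), unknown = !known)
}

.dedupe_annotations <- function(annotations) {
  key <- paste(annotations$term, annotations$negated,
               annotations$evidence_code, annotations$source,
               annotations$reference, sep = "\r")
  annotations[!duplicated(key), , drop = FALSE]
}

#' Detect conflicting annotations for one gene
#'
#' Flags a gene whose in-closure annotations contain both positive and
#' negated (`NOT`) statements on the same term, or on an
#' ancestor/descendant term pair when an ontology is supplied. With
#' `cross_activity = TRUE` (and a graph carrying EC cross-references),
#' positive annotations whose terms map to EC numbers in different
#' sub-subclasses (first three levels differ) are additionally flagged as
#' a cross-activity conflict.
#'
#' @param annotations annotation records for a single gene.
#' @param graph optional [ontology_graph()] for lineage and EC checks.
#' @param cross_activity enable the EC cross-activity check?
#' @return list with `conflict` (logical scalar) and `reasons`
#'   (character vector of rule codes).
#' @export
detect_conflicts <- function(annotations, graph = NULL,
                             cross_activity = FALSE) {
  reasons <- character()
  ann <- .dedupe_annotations(annotations)
  pos <- ann[!ann$negated, , drop = FALSE]
  neg <- ann[ann$negated, , drop = FALSE]
  if (nrow(pos) && nrow(neg)) {
    if (length(intersect(pos$term, neg$term))) {
      reasons <- c(reasons, "pos_neg_same_term")
    }
    if (!is.null(graph)) {
      for (nt in unique(neg$term)) {
        for (pt in unique(pos$term)) {
          if (nt == pt) next
          if (pt %in% descendant_closure(graph, nt) ||
              nt %in% descendant_closure(graph, pt)) {
            reasons <- c(reasons, "pos_neg_lineage")
          }
        }
      }
    }
  }
  if (cross_activity && !is.null(graph) && nrow(pos)) {
    ecs <- unique(unlist(graph$ec_xrefs[unique(pos$term)],
                         use.names = FALSE))
    ecs <- ecs[ec_is_valid(ecs)]
    prefix <- vapply(ecs, function(e) {
      lv <- parse_ec(e)$levels[1:3]
      paste(ifelse(is.na(lv), "-", lv), collapse = ".")
    }, character(1))
    concrete <- prefix[!grepl("-", prefix, fixed = TRUE)]
    if (length(unique(concrete)) > 1L) {
      reasons <- c(reasons, "cross_activity_ec")
    }
  }
  reasons <- unique(reasons)
  list(conflict = length(reasons) > 0L, reasons = reasons)
}

#' Assess confidence for one gene's in-closure annotations
#'
#' Applies the evidence-based confidence rules to the annotations a gene
#' holds within an activity-class closure:
#'
#' * **high** — at least two positive annotations with experimental
#'   evidence, or exactly one such annotation supported by at least one
#'   other positive annotation with computational or electronic evidence;
#' * **medium** — no experimental evidence, but at least two independent
#'   positive annotations with computational and/or electronic evidence
#'   (typically IBA plus an InterPro-derived IEA);
#' * **low** — any other gene with at least one positive annotation:
#'   single-annotation support, author-statement-only support, or a
#'   conflict between positive and negated statements (a conflict always
#'   demotes to low);
#' * **none** — no positive in-closure annotation at all.
#'
#' Two computational/electronic annotations count as independent iff they
#' differ in evidence code or in assigning source, so two IEA lines from
#' the same mapping pipeline count once. Identical annotation records
#' appearing via several databases (same term, evidence code, source and
#' reference) are deduplicated before counting.
#'
#' @param annotations annotation records for a single gene (all terms
#'   assumed to lie in the queried class closure).
#' @param graph optional [ontology_graph()] passed to
#'   [detect_conflicts()].
#' @param cross_activity enable the EC cross-activity conflict check.
#' @return one-row data frame: `gene_id`, `tier`, `n_exp`, `n_comp`,
#'   `n_elec`, `n_auth`, `conflict`, `rationale`.
#' @export
assess_gene <- function(annotations, graph = NULL, cross_activity = FALSE) {
  gid <- unique(annotations$gene_id)
  if (length(gid) > 1L) {
    stop("assess_gene() expects records for a single gene, got: ",
         paste(gid, collapse = ", "))
  }
  if (length(gid) == 0L) gid <- NA_character_
  ann <- .dedupe_annotations(annotations)
  conf <- detect_conflicts(ann, graph, cross_activity)
  pos <- ann[!ann$negated, , drop = FALSE]
  cls <- evidence_class(pos$evidence_code)
  unknown <- attr(cls, "unknown")
  n_exp <- sum(cls == "experimental")
  n_comp <- sum(cls == "computational" & !unknown)
  n_elec <- sum(cls == "electronic" & !unknown)
  n_auth <- sum(cls == "author_statement" | unknown)
  ce <- cls %in% c("computational", "electronic") & !unknown
  n_indep_ce <- length(unique(paste(pos$evidence_code[ce],
                                    pos$source[ce], sep = "\r")))
  if (nrow(pos) == 0L) {
    tier <- "none"
    rationale <- "no_positive_annotation"
  } else if (conf$conflict) {
    tier <- "low"
    rationale <- paste(c("conflict", conf$reasons), collapse = ";")
  } else if (n_exp >= 2L) {
    tier <- "high"
    rationale <- "multiple_experimental"
  } else if (n_exp == 1L && (n_comp + n_elec) >= 1L) {
    tier <- "high"
    rationale <- "experimental_plus_supporting"
  } else if (n_exp == 0L && n_indep_ce >= 2L) {
    tier <- "medium"
    rationale <- "independent_comp_elec"
  } else {
    tier <- "low"
    rationale <- if (nrow(pos) == 1L) {
      "single_annotation"
    } else if (n_comp + n_elec == 0L && n_exp == 0L) {
      "author_statement_only"
    } else {
      "insufficient_independent_support"
    }
  }
  data.frame(gene_id = gid, tier = tier, n_exp = n_exp, n_comp = n_comp,
             n_elec = n_elec, n_auth = n_auth, conflict = conf$conflict,
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Assess every gene in an annotation set
#'
#' Splits in-closure annotation records by gene and applies
#' [assess_gene()] to each, returning one assessment row per gene.
#'
#' @inheritParams assess_gene
#' @param annotations in-closure annotation records for any number of
#'   genes.
#' @return data frame of per-gene assessments, ordered by `gene_id`.
#' @export
assess_genes <- function(annotations, graph = NULL, cross_activity = FALSE) {
  if (!nrow(annotations)) {
    return(assess_gene(annotations)[0, , drop = FALSE])
  }
  parts <- split(annotations, annotations$gene_id)
  out <- do.call(rbind, lapply(parts, assess_gene, graph = graph,
                               cross_activity = cross_activity))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-gene assessment table as TSV
#'
#' @param assessments data frame from [assess_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  utils::write.table(assessments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
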