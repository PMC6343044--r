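#' Round half-up
#'
#' Reporting-boundary rounding that matches how curation tables are
#' printed: exact halves round away from zero (0.815 -> 0.82), unlike
#' base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Confusion counts and precision/recall/F1 for a hit set
#'
#' Compares a predicted gene set with a gold-standard set:
#' `TP = |predicted n gold|`, `FP = |predicted \ gold|`,
#' `FN = |gold \ predicted|`, then `P = TP/(TP+FP)`, `R = TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)`. Metrics with an empty denominator are `NA` and
#' flagged as undefined — never reported as 0 or 1. F1 is always computed
#' from the unrounded precision and recall; rounding happens only in the
#' reporting view ([format.confusion_result()]).
#'
#' @param predicted character vector (or [hit_set()]) of predicted genes.
#' @param gold character vector of gold-standard genes.
#' @return object of class `confusion_result`: list with `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1` and a logical `defined` vector.
#' @examples
#' confusion(c("a", "b", "c"), c("b", "c", "d"))
#' @export
confusion <- function(predicted, gold) {
  if (inherits(predicted, "hit_set")) predicted <- predicted$genes
  predicted <- unique(as.character(predicted))
  gold <- unique(as.character(gold))
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  confusion_from_counts(tp, fp, fn)
}

#' @rdname confusion
#' @param tp,fp,fn non-negative integer counts, for when the counts are
#'   known but the underlying sets are not.
#' @export
confusion_from_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 precision = precision, recall = recall, f1 = f1,
                 defined = c(precision = !is.na(precision),
                             recall = !is.na(recall), f1 = !is.na(f1))),
            class = "confusion_result")
}

#' @export
format.confusion_result <- function(x, digits = 2, ...) {
  fmt <- function(v) {
    if (is.na(v)) "undefined" else sprintf(paste0("%.", digits, "f"),
                                           round_half_up(v, digits))
  }
  c(tp = as.character(x$tp), fp = as.character(x$fp),
    fn = as.character(x$fn), precision = fmt(x$precision),
    recall = fmt(x$recall), f1 = fmt(x$f1))
}

#' @export
print.confusion_result <- function(x, ...) {
  v <- format(x, ...)
  cat(sprintf("<confusion> TP %s FP %s FN %s | P %s R %s F1 %s\n",
              v["tp"], v["fp"], v["fn"], v["precision"], v["recall"],
              v["f1"]))
  invisible(x)
}

#' Evaluation report across sources
#'
#' Scores each hit set against the gold set and assembles the table
#' reviewers expect: rows query results / TP / FP / FN / precision /
#' recall / F1, one column per source, metrics rounded half-up to 2
#' decimals at this reporting boundary.
#'
#' @param hitsets list of [hit_set()] objects.
#' @param gold character vector of gold genes.
#' @return data frame with a `metric` column and one column per source.
#' @export
evaluation_report <- function(hitsets, gold) {
  cols <- lapply(hitsets, function(h) {
    cr <- confusion(h, gold)
    v <- format(cr)
    c(length(h$genes), v["tp"], v["fp"], v["fn"], v["precision"],
      v["recall"], v["f1"])
  })
  out <- data.frame(metric = c("query_results", "tp", "fp", "fn",
                               "precision", "recall", "f1"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(hitsets)) out[[hitsets[[i]]$source]] <- cols[[i]]
  out
}

#' Release-diff ledger for one enzyme class
#'
#' Compares two release snapshots of a class's gene membership (and
#' optionally their annotations), reporting the gene counts before and
#' after, genes added/removed, and annotations added/removed.
#' Annotation identity for the deltas is the tuple
#' (gene, term, evidence code, source); dates are deliberately excluded
#' so a re-dated but otherwise identical annotation is not counted as a
#' change. The ledger satisfies
#' `after = before + genes_added - genes_removed` by construction.
#'
#' @param before,after character vectors of member genes in the two
#'   releases.
#' @param before_annotations,after_annotations optional annotation data
#'   frames for the two releases.
#' @param class_name label for the class.
#' @return object of class `release_ledger`.
#' @export
ledger <- function(before, after, before_annotations = NULL,
                   after_annotations = NULL, class_name = "") {
  before <- unique(as.character(before))
  after <- unique(as.character(after))
  ann_key <- function(a) {
    if (is.null(a) || !nrow(a)) return(character())
    unique(paste(a$gene_id, a$term, a$evidence_code, a$source, sep = "\r"))
  }
  kb <- ann_key(before_annotations)
  ka <- ann_key(after_annotations)
  structure(list(class_name = class_name,
                 before = length(before), after = length(after),
                 genes_added = length(setdiff(after, before)),
                 genes_removed = length(setdiff(before, after)),
                 annotations_added = length(setdiff(ka, kb)),
                 annotations_removed = length(setdiff(kb, ka))),
            class = "release_ledger")
}

#' @export
print.release_ledger <- function(x, ...) {
  cat(sprintf(
    "<release_ledger> %s: %d -> %d genes (+%d/-%d), annotations +%d/-%d\n",
    x$class_name, x$before, x$after, x$genes_added, x$genes_removed,
    x$annotations_added, x$annotations_removed))
  invisible(x)
}

#' Totals across release ledgers
#'
#' @param ledgers list of [ledger()] results.
#' @return named numeric vector: `genes_added`, `genes_removed`,
#'   `annotations_added`, `annotations_removed`.
#' @export
summarize_ledgers <- function(ledgers) {
  stopifnot(length(ledgers) >= 1L)
  fields <- c("genes_added", "genes_removed", "annotations_added",
              "annotations_removed")
  vapply(stats::setNames(fields, fields), function(f) {
    sum(vapply(ledgers, `[[`, numeric(1), f))
  }, numeric(1))
}

#' Write ledgers as a TSV table
#'
#' @param ledgers list of [ledger()] results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger_table <- function(ledgers, path) {
  df <- do.call(rbind, lapply(ledgers, function(l) {
    data.frame(class_name = l$class_name, before = l$before,
               after = l$after, genes_added = l$genes_added,
               genes_removed = l$genes_removed,
               annotations_added = l$annotations_added,
               annotations_removed = l$annotations_removed,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
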