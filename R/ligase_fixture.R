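#' Ligase case-study benchmark bundle
#'
#' Writes a fully deterministic five-database benchmark bundle modelled
#' on a comprehensive curation review of *D. melanogaster* ligases
#' (EC 6.-.-.-): two GO-annotation exports (`flybase`, `quickgo`), two
#' EC-annotation tables (`ncbi`, `uniprot`), an `orthology` pipeline, and
#' a `literature` source holding genes recovered only from uncurated
#' papers. The planted per-source confusion structure against the
#' 121-gene gold set is
#'
#' | source    | TP  | FP | FN |
#' |-----------|-----|----|----|
#' | flybase   | 94  | 18 | 27 |
#' | quickgo   | 101 | 37 | 20 |
#' | ncbi      | 82  | 13 | 39 |
#' | uniprot   | 89  | 17 | 32 |
#' | orthology | 104 | 12 | 17 |
#'
#' with the union of all hit sets containing 121 true and 46 false
#' members, the four database sources together surfacing 141 candidates
#' of which 40 are false, and the 101 GO-identified true positives
#' splitting 24 high / 36 medium / 41 low by planted evidence profile.
#' Gene identifiers are synthetic (`LIG0001`…, `FPG0001`…): the bundle
#' reproduces the arithmetic structure of such a review, not any real
#' gene list.
#'
#' @param dir output directory.
#' @return invisibly, a list with `dir` and `truth` (planted per-source
#'   gene sets and expected confusion counts).
#' @export
ligase_study_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gold <- sprintf("LIG%04d", 1:121)
  fpg <- sprintf("FPG%04d", 1:46)
  g <- function(i) gold[i]
  f <- function(i) fpg[i]

  # ontology: ligase class with the six EC 6.x subclasses, 2 leaves each
  terms <- c("T:0001", "T:0100")
  labels <- c("T:0001" = "catalytic activity", "T:0100" = "ligase activity")
  is_a <- list("T:0100" = "T:0001")
  ec_xrefs <- list("T:0100" = "6.-.-.-")
  sub_names <- c("carbon-oxygen ligase activity",
                 "carbon-sulfur ligase activity",
                 "carbon-nitrogen ligase activity",
                 "carbon-carbon ligase activity",
                 "phosphoric-ester ligase activity",
                 "nitrogen-metal ligase activity")
  subgroup_terms <- sprintf("T:%04d", 101:106)
  leaves <- list()
  tid <- 106L
  for (s in 1:6) {
    st <- subgroup_terms[s]
    labels[st] <- sub_names[s]
    is_a[[st]] <- "T:0100"
    ec_xrefs[[st]] <- sprintf("6.%d.-.-", s)
    leaves[[s]] <- character(2)
    for (l in 1:2) {
      tid <- tid + 1L
      lt <- sprintf("T:%04d", tid)
      labels[lt] <- sprintf("%s %d", sub_names[s], l)
      is_a[[lt]] <- st
      ec_xrefs[[lt]] <- sprintf("6.%d.%d.%d", s, l, l)
      leaves[[s]][l] <- lt
      terms <- c(terms, lt)
    }
    terms <- c(terms, st)
  }
  graph <- ontology_graph(sort(terms), names = labels, is_a = is_a,
                          ec_xrefs = ec_xrefs)
  write_obo(graph, file.path(dir, "ontology.obo"))

  # leaf assignment: gene i -> subclass (i mod 6) + 1; the first four
  # genes get a second term in a different subclass (dual membership)
  sub_of <- ((seq_along(gold) - 1L) %% 6L) + 1L
  leaf_of <- vapply(seq_along(gold), function(i) {
    leaves[[sub_of[i]]][((i - 1L) %/% 6L) %% 2L + 1L]
  }, character(1))
  names(leaf_of) <- gold
  dual <- gold[1:4]
  dual_leaf <- vapply(1:4, function(i) {
    leaves[[(sub_of[i] %% 6L) + 1L]][1]
  }, character(1))
  names(dual_leaf) <- dual
  fp_leaf <- vapply(seq_along(fpg), function(i) {
    leaves[[((i - 1L) %% 6L) + 1L]][1]
  }, character(1))
  names(fp_leaf) <- fpg

  # planted confidence tiers over the 101 GO-identified true positives
  tier_of <- stats::setNames(rep("none", 121), gold)
  tier_of[1:24] <- "high"
  tier_of[25:60] <- "medium"
  tier_of[61:101] <- "low"
  tier_of[112:121] <- "low"   # literature-recovered: one supporting line

  ann_row <- function(gene, term, code, source, reference,
                      negated = FALSE, date = "2018-01-15") {
    data.frame(gene_id = gene, symbol = tolower(gene), term = term,
               negated = negated,
               qualifiers = if (negated) "NOT|enables" else "enables",
               evidence_code = code, eco_id = NA_character_,
               reference = reference, source = source, date = date,
               aspect = "F", stringsAsFactors = FALSE)
  }

  # identical annotation tuples are emitted to every GO source carrying
  # the gene, so pooled assessment deduplicates them to one profile
  profile_of <- function(i) {
    gene <- g(i)
    term <- leaf_of[[gene]]
    extra <- if (gene %in% dual) {
      list(ann_row(gene, dual_leaf[[gene]], "ISS", "FlyBase",
                   sprintf("PMID:40%05d", i)))
    } else {
      list()
    }
    base <- switch(tier_of[[gene]],
      high = if (i %% 2L == 0L) {
        rbind(ann_row(gene, term, "IDA", "FlyBase",
                      sprintf("PMID:10%05d", i)),
              ann_row(gene, term, "IMP", "FlyBase",
                      sprintf("PMID:11%05d", i)))
      } else {
        rbind(ann_row(gene, term, "IDA", "FlyBase",
                      sprintf("PMID:10%05d", i)),
              ann_row(gene, term, "IEA", "InterPro", "GO_REF:0000002"))
      },
      medium = rbind(ann_row(gene, term, "IBA", "GO_Central",
                             "GO_REF:0000033"),
                     ann_row(gene, term, "IEA", "InterPro",
                             "GO_REF:0000002")),
      low = switch((i %% 3L) + 1L,
        ann_row(gene, term, "ISS", "FlyBase", sprintf("PMID:12%05d", i)),
        rbind(ann_row(gene, term, "TAS", "FlyBase",
                      sprintf("PMID:13%05d", i)),
              ann_row(gene, term, "NAS", "UniProt",
                      sprintf("PMID:14%05d", i))),
        rbind(ann_row(gene, term, "IDA", "FlyBase",
                      sprintf("PMID:15%05d", i)),
              ann_row(gene, term, "IDA", "FlyBase",
                      sprintf("PMID:16%05d", i), negated = TRUE))),
      none = ann_row(gene, term, "IDA", "FlyBase",
                     sprintf("PMID:30%05d", i)))
    do.call(rbind, c(list(base), extra))
  }
  fp_row <- function(i, src) {
    gene <- f(i)
    if (src == "quickgo" && i > 27) {
      # electronic keyword-mapping false positives, aggregator-only
      ann_row(gene, fp_leaf[[gene]], "IEA", "UniProtKB-KW",
              "GO_REF:0000043", date = "2017-06-01")
    } else {
      ann_row(gene, fp_leaf[[gene]], "IDA", src,
              sprintf("PMID:20%05d", i), date = "2016-03-01")
    }
  }

  planted <- list(
    flybase   = list(tp = 1:94, fp = 1:18),
    quickgo   = list(tp = 1:101, fp = 3:39),
    ncbi      = list(tp = 1:82, fp = 28:40),
    uniprot   = list(tp = 3:91, fp = 23:39),
    orthology = list(tp = 8:111, fp = 35:46),
    literature = list(tp = 112:121, fp = integer()))

  for (src in c("flybase", "quickgo", "literature")) {
    p <- planted[[src]]
    ann <- do.call(rbind, c(lapply(p$tp, profile_of),
                            lapply(p$fp, fp_row, src = src)))
    write_gaf(ann, file.path(dir, paste0("source_", src, ".gaf")))
  }

  accession <- function(genes) {
    sub("^LIG", "ACL", sub("^FPG", "ACF", genes))
  }
  ec_rows <- NULL
  for (src in c("ncbi", "uniprot")) {
    p <- planted[[src]]
    genes_tp <- g(p$tp); genes_fp <- f(p$fp)
    keyed <- function(x) if (src == "uniprot") accession(x) else x
    ec_rows <- rbind(
      ec_rows,
      data.frame(gene_or_accession = keyed(genes_tp),
                 ec = unlist(ec_xrefs[unname(leaf_of[genes_tp])]),
                 source = src, reviewed = src == "uniprot",
                 stringsAsFactors = FALSE),
      data.frame(gene_or_accession = keyed(genes_fp),
                 ec = unlist(ec_xrefs[unname(fp_leaf[genes_fp])]),
                 source = src, reviewed = src == "uniprot",
                 stringsAsFactors = FALSE))
  }
  rownames(ec_rows) <- NULL
  utils::write.table(ec_rows, file.path(dir, "ec.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")

  p <- planted$orthology
  called <- c(g(p$tp), f(p$fp))
  idx <- c(p$tp, p$fp)
  ortho <- data.frame(human_gene = paste0("HUM_", called),
                      fly_gene = called,
                      score = 8L + (idx %% 8L),
                      domain_present = TRUE, stringsAsFactors = FALSE)
  utils::write.table(ortho, file.path(dir, "orthology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(
    data.frame(human_gene = paste0("HUM_", called), class = "ligase"),
    file.path(dir, "human_gold.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, eol = "\n")

  all_genes <- c(gold, fpg)
  utils::write.table(
    data.frame(accession = accession(all_genes), gene_id = all_genes),
    file.path(dir, "id_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, eol = "\n")
  utils::write.table(
    data.frame(gene_id = gold, class = "ligase"),
    file.path(dir, "gold.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, eol = "\n")

  gene_terms <- rbind(
    data.frame(gene_id = gold, term = unname(leaf_of),
               stringsAsFactors = FALSE),
    data.frame(gene_id = dual, term = unname(dual_leaf),
               stringsAsFactors = FALSE))
  truth <- list(
    n_genes = length(all_genes),
    class_terms = list(ligase = list(root = "T:0100", ec = "6.-.-.-")),
    members = list(ligase = as.list(gold)),
    tiers = list(ligase = as.list(tier_of)),
    subgroup_terms = as.list(subgroup_terms),
    dual_membership_genes = as.list(dual),
    gene_terms = gene_terms,
    per_source = list(ligase = lapply(planted, function(pp) {
      list(tp = as.list(g(pp$tp)), fp = as.list(f(pp$fp)),
           fn = as.list(setdiff(gold, g(pp$tp))),
           expected = list(tp = length(pp$tp), fp = length(pp$fp),
                           fn = 121L - length(pp$tp)))
    })),
    errors = list(), seed = 0L)
  truth_json <- truth
  truth_json$gene_terms <- NULL   # data frame; keep JSON scalar-clean
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, truth = truth))
}
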