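#' Default simulated-source layout
#'
#' Five sources mirroring a multi-database enzyme-annotation review: two
#' GO-annotation exports (an authoritative curated database and a
#' broader aggregator), two EC-annotation tables (one gene-keyed and
#' automated, one accession-keyed and manually reviewed) and one
#' orthology-transfer pipeline.
#'
#' @return named list of source descriptors (`type`, plus per-type
#'   options).
#' @export
default_sources <- function() {
  list(
    flybase   = list(type = "gaf"),
    quickgo   = list(type = "gaf"),
    ncbi      = list(type = "ec", accession_keyed = FALSE, reviewed = FALSE),
    uniprot   = list(type = "ec", accession_keyed = TRUE, reviewed = TRUE),
    orthology = list(type = "orthology"))
}

#' Default per-source error-mode rates
#'
#' Rates are per eligible gene (Bernoulli draws), except
#' `dropped_relation`, which is the probability that the source's
#' ontology view has lost one `is_a` edge, and `missing_ec_xref`, the
#' per-term probability that a term's EC cross-reference is missing from
#' that EC provider's pipeline. The `global` entry applies to all
#' annotation sources at once (`uncurated_literature`: a true member
#' whose only support sits in unreviewed literature, so no annotation
#' source carries it).
#'
#' @return named list, source -> named numeric rate vector.
#' @export
default_error_profile <- function() {
  list(
    global    = c(uncurated_literature = 0.05),
    flybase   = c(erroneous_manual = 0.03, stale_release = 0.05),
    quickgo   = c(erroneous_manual = 0.03, bad_keyword_mapping = 0.05,
                  dropped_relation = 0.10),
    ncbi      = c(stale_release = 0.08, missing_ec_xref = 0.10),
    uniprot   = c(erroneous_manual = 0.03, stale_release = 0.05),
    orthology = c(erroneous_manual = 0.03, no_ortholog = 0.10))
}

.KNOWN_MODES <- c("erroneous_manual", "bad_keyword_mapping",
                  "stale_release", "dropped_relation",
                  "uncurated_literature", "no_ortholog", "missing_ec_xref")

#' Configuration for a synthetic fixture bundle
#'
#' Describes the simulated study: how many genes, how many true members
#' each enzyme class has, the mix of planted evidence tiers among
#' members, and the per-source error-mode rates.
#'
#' @param n_genes total number of simulated genes.
#' @param class_sizes named integer vector, enzyme class -> true member
#'   count; sizes must sum to at most `n_genes`.
#' @param tier_mix named proportions for planted `high`/`medium`/`low`
#'   evidence profiles (normalised internally).
#' @param error_profile named list of per-source rate vectors, see
#'   [default_error_profile()].
#' @param seed integer seed; together with the config it fully
#'   determines the bundle.
#' @param class_ec named integer vector, class -> EC class digit (1-7);
#'   defaults to 6, 5, 4, ... in class order.
#' @param sources source layout, see [default_sources()].
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 200,
                           class_sizes = c(ligase = 60, isomerase = 40),
                           tier_mix = c(high = 0.24, medium = 0.36,
                                        low = 0.40),
                           error_profile = default_error_profile(),
                           seed = 1, class_ec = NULL,
                           sources = default_sources()) {
  stopifnot(n_genes >= 1, length(class_sizes) >= 1,
            !is.null(names(class_sizes)))
  if (sum(class_sizes) > n_genes) {
    stop("class sizes (", sum(class_sizes), ") exceed n_genes (",
         n_genes, ")")
  }
  stopifnot(all(c("high", "medium", "low") %in% names(tier_mix)),
            all(tier_mix >= 0), sum(tier_mix) > 0)
  tier_mix <- tier_mix[c("high", "medium", "low")] /
    sum(tier_mix[c("high", "medium", "low")])
  for (src in names(error_profile)) {
    rates <- error_profile[[src]]
    bad <- setdiff(names(rates), .KNOWN_MODES)
    if (length(bad)) {
      stop("unknown error mode(s) for '", src, "': ",
           paste(bad, collapse = ", "))
    }
    if (any(rates < 0 | rates > 1)) {
      stop("error rates must lie in [0, 1] (source '", src, "')")
    }
  }
  if (is.null(class_ec)) {
    class_ec <- stats::setNames(
      ((6 - seq_along(class_sizes)) %% 7) + 1L, names(class_sizes))
  }
  stopifnot(all(class_ec >= 1 & class_ec <= 7))
  structure(list(n_genes = as.integer(n_genes), class_sizes = class_sizes,
                 tier_mix = tier_mix, error_profile = error_profile,
                 seed = as.integer(seed), class_ec = class_ec,
                 sources = sources),
            class = "fixture_config")
}

# deterministic sub-seed per draw context, so adding one error mode does
# not perturb the draws of another
.sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 100003
  as.integer((as.numeric(seed) * 100003 + h) %% 2147483587)
}

.with_sub_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(.sub_seed(seed, tag))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

# class ontology: shared root -> class roots -> 3 mid terms -> 2 leaves each
.build_class_ontology <- function(class_names, class_ec) {
  terms <- "T:0001"; labels <- c("T:0001" = "catalytic activity")
  is_a <- list(); ec_xrefs <- list()
  class_info <- list()
  tid <- 1L
  nxt <- function() {
    tid <<- tid + 1L
    sprintf("T:%04d", tid)
  }
  for (cl in class_names) {
    e <- class_ec[[cl]]
    root <- nxt()
    labels[root] <- paste0(cl, " activity")
    is_a[[root]] <- "T:0001"
    ec_xrefs[[root]] <- sprintf("%d.-.-.-", e)
    leaves <- character()
    for (m in 1:3) {
      mid <- nxt()
      labels[mid] <- sprintf("%s subclass %d activity", cl, m)
      is_a[[mid]] <- root
      ec_xrefs[[mid]] <- sprintf("%d.%d.-.-", e, m)
      for (l in 1:2) {
        leaf <- nxt()
        labels[leaf] <- sprintf("%s activity %d.%d", cl, m, l)
        is_a[[leaf]] <- mid
        ec_xrefs[[leaf]] <- sprintf("%d.%d.%d.%d", e, m, l, l)
        leaves <- c(leaves, leaf)
      }
      terms <- c(terms, mid)
    }
    terms <- c(terms, root, leaves)
    class_info[[cl]] <- list(root = root, leaves = leaves, ec = e)
  }
  terms <- unique(c("T:0001", setdiff(terms, "T:0001")))
  g <- ontology_graph(sort(terms), names = labels, is_a = is_a,
                      ec_xrefs = ec_xrefs)
  list(graph = g, classes = class_info)
}

# planted evidence profiles; variant chosen deterministically per member
.tier_profile <- function(tier, variant, term, gene, symbol) {
  row <- function(code, source, reference, negated = FALSE) {
    data.frame(gene_id = gene, symbol = symbol, term = term,
               negated = negated,
               qualifiers = if (negated) "NOT|enables" else "enables",
               evidence_code = code,
               eco_id = NA_character_, reference = reference,
               source = source, date = "2018-01-15", aspect = "F",
               stringsAsFactors = FALSE)
  }
  switch(tier,
    high = if (variant %% 2L == 0L) {
      rbind(row("IDA", "FlyBase", "PMID:1000001"),
            row("IMP", "FlyBase", "PMID:1000002"))
    } else {
      rbind(row("IDA", "FlyBase", "PMID:1000003"),
            row("IEA", "InterPro", "GO_REF:0000002"))
    },
    medium = rbind(row("IBA", "GO_Central", "GO_REF:0000033"),
                   row("IEA", "InterPro", "GO_REF:0000002")),
    low = switch((variant %% 3L) + 1L,
      row("ISS", "FlyBase", "PMID:1000004"),
      rbind(row("TAS", "FlyBase", "PMID:1000005"),
            row("NAS", "UniProt", "PMID:1000006")),
      rbind(row("IDA", "FlyBase", "PMID:1000007"),
            row("IDA", "FlyBase", "PMID:1000008", negated = TRUE))),
    stop("unknown tier: ", tier))
}

#' Generate a complete synthetic fixture bundle
#'
#' Emits, under `dir`: `ontology.obo`, one `source_<name>.gaf` per GAF
#' source (plus `ontology_<name>.obo` when that source's ontology view
#' lost an edge), `ec.tsv`, `orthology.tsv`, `id_map.tsv`, `gold.tsv`,
#' `human_gold.tsv` and `truth.json`. Every member gene carries a planted
#' evidence profile matching its planted confidence tier; every planted
#' false positive and false negative is drawn by a named error mode and
#' recorded in the bookkeeping, so pipeline-computed confusion can be
#' checked against the generator exactly. Identical `(config, seed)`
#' yield byte-identical bundles.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `truth` (bookkeeping) and
#'   `config`.
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  n <- config$n_genes
  genes <- sprintf("GENE%04d", seq_len(n))
  symbols <- sprintf("sym%04d", seq_len(n))
  accessions <- sprintf("ACC%04d", seq_len(n))
  names(symbols) <- genes

  ont <- .build_class_ontology(names(config$class_sizes), config$class_ec)
  write_obo(ont$graph, file.path(dir, "ontology.obo"))

  # membership, leaf terms, tiers
  members <- list()
  pool <- .with_sub_seed(seed, "structure:members", sample(genes))
  off <- 0L
  for (cl in names(config$class_sizes)) {
    k <- config$class_sizes[[cl]]
    members[[cl]] <- sort(pool[seq_len(k) + off])
    off <- off + k
  }
  leaf_of <- list(); tier_of <- list()
  for (cl in names(members)) {
    mg <- members[[cl]]
    leaf_of[[cl]] <- stats::setNames(
      .with_sub_seed(seed, paste0("structure:leaves:", cl),
                     sample(ont$classes[[cl]]$leaves, length(mg),
                            replace = TRUE)), mg)
    tier_of[[cl]] <- stats::setNames(
      .with_sub_seed(seed, paste0("structure:tiers:", cl),
                     sample(names(config$tier_mix), length(mg),
                            replace = TRUE, prob = config$tier_mix)), mg)
  }

  glob <- config$error_profile$global
  unc_rate <- if ("uncurated_literature" %in% names(glob)) {
    glob[["uncurated_literature"]]
  } else 0
  uncurated <- list()
  for (cl in names(members)) {
    mg <- members[[cl]]
    draw <- .with_sub_seed(seed, paste0("global:uncurated:", cl),
                           stats::runif(length(mg)) < unc_rate)
    uncurated[[cl]] <- mg[draw]
  }

  rate <- function(src, mode) {
    r <- config$error_profile[[src]]
    if (!is.null(r) && mode %in% names(r)) r[[mode]] else 0
  }
  draw_genes <- function(eligible, p, tag) {
    if (p <= 0 || !length(eligible)) return(character())
    sel <- .with_sub_seed(seed, tag, stats::runif(length(eligible)) < p)
    eligible[sel]
  }

  gaf_sources <- names(config$sources)[
    vapply(config$sources, function(s) s$type == "gaf", logical(1))]
  ec_sources <- names(config$sources)[
    vapply(config$sources, function(s) s$type == "ec", logical(1))]
  ortho_sources <- names(config$sources)[
    vapply(config$sources, function(s) s$type == "orthology", logical(1))]

  per_source <- list()
  errors <- list()
  gaf_presence <- list()   # class -> gene -> present in >=1 GAF source

  # --- GAF sources ------------------------------------------------------
  for (src in gaf_sources) {
    ann <- .empty_annotations()
    per_source_cl <- list()
    # dropped is_a edge in this source's ontology view?
    dropped_leaves <- character()
    p_drop <- rate(src, "dropped_relation")
    if (p_drop > 0 &&
        .with_sub_seed(seed, paste0(src, ":dropped_relation:trigger"),
                       stats::runif(1)) < p_drop) {
      mids <- unlist(lapply(ont$classes, function(ci) {
        unique(unlist(ont$graph$is_a[ci$leaves]))
      }), use.names = FALSE)
      mid <- .with_sub_seed(seed, paste0(src, ":dropped_relation:edge"),
                            sample(mids, 1))
      view <- ont$graph
      view$is_a[[mid]] <- character()
      view <- ontology_graph(view$terms, view$names, view$is_a,
                             view$part_of, view$ec_xrefs, view$obsolete)
      write_obo(view, file.path(dir, paste0("ontology_", src, ".obo")))
      dropped_leaves <- descendant_closure(ont$graph, mid)
      errors[[src]]$dropped_relation <- mid
    }
    for (cl in names(members)) {
      mg <- members[[cl]]
      fn <- union(uncurated[[cl]],
                  draw_genes(mg, rate(src, "stale_release"),
                             paste0(src, ":stale_release:", cl)))
      if (length(dropped_leaves)) {
        fn <- union(fn, mg[leaf_of[[cl]][mg] %in% dropped_leaves])
      }
      tp <- setdiff(mg, fn)
      non <- setdiff(genes, mg)
      fp <- union(
        draw_genes(non, rate(src, "erroneous_manual"),
                   paste0(src, ":erroneous_manual:", cl)),
        draw_genes(non, rate(src, "bad_keyword_mapping"),
                   paste0(src, ":bad_keyword_mapping:", cl)))
      for (g in tp) {
        idx <- match(g, mg)
        ann <- rbind(ann, .tier_profile(tier_of[[cl]][[g]], idx,
                                        leaf_of[[cl]][[g]], g,
                                        symbols[[g]]))
      }
      fp_term <- ont$classes[[cl]]$leaves[1]
      kw_set <- draw_genes(non, rate(src, "bad_keyword_mapping"),
                           paste0(src, ":bad_keyword_mapping:", cl))
      for (g in sort(fp)) {
        ann <- rbind(ann, if (g %in% kw_set) {
          data.frame(gene_id = g, symbol = symbols[[g]], term = fp_term,
                     negated = FALSE, qualifiers = "enables",
                     evidence_code = "IEA", eco_id = NA_character_,
                     reference = "GO_REF:0000043", source = "UniProtKB-KW",
                     date = "2017-06-01", aspect = "F",
                     stringsAsFactors = FALSE)
        } else {
          data.frame(gene_id = g, symbol = symbols[[g]], term = fp_term,
                     negated = FALSE, qualifiers = "enables",
                     evidence_code = "IDA", eco_id = NA_character_,
                     reference = "PMID:2000001", source = src,
                     date = "2016-03-01", aspect = "F",
                     stringsAsFactors = FALSE)
        })
      }
      per_source_cl[[cl]] <- list(tp = sort(tp), fp = sort(fp),
                                  fn = sort(intersect(mg, fn)))
      gaf_presence[[cl]] <- union(gaf_presence[[cl]], tp)
    }
    ord <- order(ann$gene_id, ann$term, ann$evidence_code, ann$negated)
    write_gaf(ann[ord, , drop = FALSE],
              file.path(dir, paste0("source_", src, ".gaf")))
    per_source[[src]] <- per_source_cl
  }

  # --- EC sources -------------------------------------------------------
  ec_rows <- NULL
  for (src in ec_sources) {
    opts <- config$sources[[src]]
    per_source_cl <- list()
    for (cl in names(members)) {
      mg <- members[[cl]]
      leaves <- ont$classes[[cl]]$leaves
      lost <- leaves[.with_sub_seed(
        seed, paste0(src, ":missing_ec_xref:", cl),
        stats::runif(length(leaves)) < rate(src, "missing_ec_xref"))]
      fn <- union(uncurated[[cl]],
                  draw_genes(mg, rate(src, "stale_release"),
                             paste0(src, ":stale_release:", cl)))
      fn <- union(fn, mg[leaf_of[[cl]][mg] %in% lost])
      tp <- setdiff(mg, fn)
      non <- setdiff(genes, mg)
      fp <- draw_genes(non, rate(src, "erroneous_manual"),
                       paste0(src, ":erroneous_manual:", cl))
      if (length(lost)) errors[[src]]$missing_ec_xref <- sort(lost)
      ec_for <- function(g, is_tp) {
        leaf <- if (is_tp) leaf_of[[cl]][[g]] else leaves[1]
        ont$graph$ec_xrefs[[leaf]][1]
      }
      for (g in sort(tp)) {
        key <- if (isTRUE(opts$accession_keyed)) {
          accessions[match(g, genes)]
        } else g
        ec_rows <- rbind(ec_rows, data.frame(
          gene_or_accession = key, ec = ec_for(g, TRUE), source = src,
          reviewed = isTRUE(opts$reviewed), stringsAsFactors = FALSE))
      }
      for (g in sort(fp)) {
        key <- if (isTRUE(opts$accession_keyed)) {
          accessions[match(g, genes)]
        } else g
        ec_rows <- rbind(ec_rows, data.frame(
          gene_or_accession = key, ec = ec_for(g, FALSE), source = src,
          reviewed = isTRUE(opts$reviewed), stringsAsFactors = FALSE))
      }
      per_source_cl[[cl]] <- list(tp = sort(tp), fp = sort(fp),
                                  fn = sort(intersect(mg, fn)))
    }
    per_source[[src]] <- per_source_cl
  }
  if (is.null(ec_rows)) {
    ec_rows <- data.frame(gene_or_accession = character(), ec = character(),
                          source = character(), reviewed = logical())
  }
  utils::write.table(ec_rows, file.path(dir, "ec.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")

  # --- orthology source -------------------------------------------------
  ortho_rows <- NULL
  human_gold <- NULL
  for (src in ortho_sources) {
    per_source_cl <- list()
    for (cl in names(members)) {
      mg <- members[[cl]]
      fn <- draw_genes(mg, rate(src, "no_ortholog"),
                       paste0(src, ":no_ortholog:", cl))
      tp <- setdiff(mg, fn)
      non <- setdiff(genes, mg)
      fp <- draw_genes(non, rate(src, "erroneous_manual"),
                       paste0(src, ":erroneous_manual:", cl))
      scores <- .with_sub_seed(
        seed, paste0(src, ":scores:", cl),
        sample(5:15, length(tp) + length(fp), replace = TRUE,
               prob = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3)))
      all_called <- c(sort(tp), sort(fp))
      hum <- sprintf("HUM_%s_%s", cl, all_called)
      ortho_rows <- rbind(ortho_rows, data.frame(
        human_gene = hum, fly_gene = all_called, score = scores,
        domain_present = TRUE, stringsAsFactors = FALSE))
      human_gold <- rbind(human_gold, data.frame(
        human_gene = hum, class = cl, stringsAsFactors = FALSE))
      # borderline second calls for the first two members: routed to the
      # manual-review list, never the hit set
      border <- utils::head(sort(tp), 2)
      if (length(border)) {
        ortho_rows <- rbind(ortho_rows, data.frame(
          human_gene = sprintf("HUM_%s_%s", cl, border), fly_gene = border,
          score = 4L, domain_present = FALSE, stringsAsFactors = FALSE))
      }
      per_source_cl[[cl]] <- list(tp = sort(tp), fp = sort(fp),
                                  fn = sort(fn))
    }
    per_source[[src]] <- per_source_cl
  }
  # distractor calls from non-gold human genes; filtered out by the gold
  # restriction in hits_from_orthology()
  ortho_rows <- rbind(ortho_rows, data.frame(
    human_gene = sprintf("HUMX%04d", 1:3),
    fly_gene = genes[seq_len(min(3, n))],
    score = 9L, domain_present = TRUE, stringsAsFactors = FALSE))
  utils::write.table(ortho_rows, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  if (is.null(human_gold)) {
    human_gold <- data.frame(human_gene = character(), class = character())
  }
  utils::write.table(human_gold, file.path(dir, "human_gold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")

  utils::write.table(
    data.frame(accession = accessions, gene_id = genes),
    file.path(dir, "id_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, eol = "\n")
  gold_df <- do.call(rbind, lapply(names(members), function(cl) {
    data.frame(gene_id = members[[cl]], class = cl,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(gold_df, file.path(dir, "gold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")

  # planted tier is "none" for members no annotation source carries
  tiers_out <- list()
  for (cl in names(members)) {
    t <- tier_of[[cl]]
    absent <- setdiff(members[[cl]], gaf_presence[[cl]])
    t[absent] <- "none"
    tiers_out[[cl]] <- as.list(t)
  }

  truth <- list(
    n_genes = n,
    class_terms = lapply(ont$classes, function(ci) {
      list(root = ci$root, ec = sprintf("%d.-.-.-", ci$ec))
    }),
    members = lapply(members, as.list),
    tiers = tiers_out,
    uncurated_literature = lapply(uncurated, as.list),
    per_source = lapply(per_source, function(cls) {
      lapply(cls, function(x) {
        list(tp = as.list(x$tp), fp = as.list(x$fp), fn = as.list(x$fn),
             expected = list(tp = length(x$tp), fp = length(x$fp),
                             fn = length(x$fn)))
      })
    }),
    errors = errors,
    seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, truth = truth, config = config))
}

#' Read a fixture bundle back from disk
#'
#' @param dir bundle directory written by [generate_bundle()].
#' @return list with `graph`, `annotations` (named list of per-source
#'   annotation data frames), `ec`, `orthology`, `id_map`, `gold` (data
#'   frame gene_id/class), `human_gold`, `truth`.
#' @export
read_bundle <- function(dir) {
  gaf_files <- list.files(dir, pattern = "^source_.*\\.gaf$",
                          full.names = TRUE)
  ann <- lapply(gaf_files, read_gaf)
  names(ann) <- sub("^source_(.*)\\.gaf$", "\\1", basename(gaf_files))
  list(
    graph = read_obo(file.path(dir, "ontology.obo")),
    annotations = ann,
    ec = read_ec_table(file.path(dir, "ec.tsv")),
    orthology = read_orthology_table(file.path(dir, "orthology.tsv")),
    id_map = read_id_map(file.path(dir, "id_map.tsv")),
    gold = .read_tsv(file.path(dir, "gold.tsv"), c("gene_id", "class")),
    human_gold = .read_tsv(file.path(dir, "human_gold.tsv"),
                           c("human_gene", "class")),
    truth = jsonlite::read_json(file.path(dir, "truth.json")))
}
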