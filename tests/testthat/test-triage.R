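test_that("evidence codes map to their classes; unknown codes are flagged weak", {
  cls <- evidence_class(c("IDA", "IMP", "IGI", "ISS", "ISO", "IBA",
                          "TAS", "NAS", "IEA", "XYZ"))
  expect_equal(cls[1:3], rep("experimental", 3))
  expect_equal(cls[4:6], rep("computational", 3))
  expect_equal(cls[7:8], rep("author_statement", 2))
  expect_equal(cls[9], "electronic")
  expect_equal(cls[10], "author_statement")
  expect_equal(attr(cls, "unknown"),
               c(rep(FALSE, 9), TRUE))
})

test_that("tier rules follow the high/medium/low definitions", {
  t <- function(ann) assess_gene(ann)$tier
  # multiple positive experimental -> high
  expect_equal(t(anns(make_ann("g", "T1", "IDA"),
                      make_ann("g", "T1", "IMP", reference = "REF:2"))),
               "high")
  # one experimental + one electronic supporter -> high
  expect_equal(t(anns(make_ann("g", "T1", "IDA"),
                      make_ann("g", "T1", "IEA", source = "InterPro"))),
               "high")
  # IBA + IEA from distinct pipelines -> medium
  expect_equal(t(anns(make_ann("g", "T1", "IBA", source = "GO_Central"),
                      make_ann("g", "T1", "IEA", source = "InterPro"))),
               "medium")
  # single computational annotation -> low
  expect_equal(t(make_ann("g", "T1", "ISS")), "low")
  # positive + NOT on the same term -> low with conflict
  a <- assess_gene(anns(make_ann("g", "T1", "IDA"),
                        make_ann("g", "T1", "IDA", reference = "REF:2",
                                 negated = TRUE)))
  expect_equal(a$tier, "low")
  expect_true(a$conflict)
  # no annotations -> none
  expect_equal(t(make_ann("g", "T1", "IDA")[0, ]), "none")
  # negated-only -> none (no positive support)
  expect_equal(t(make_ann("g", "T1", "IDA", negated = TRUE)), "none")
})

test_that("author statements never reach medium; independence needs a code or source difference", {
  t <- function(ann) assess_gene(ann)$tier
  expect_equal(t(anns(make_ann("g", "T1", "TAS"),
                      make_ann("g", "T1", "NAS", reference = "REF:2"),
                      make_ann("g", "T1", "TAS", reference = "REF:3"))),
               "low")
  # two IEA lines from the same mapping pipeline count once
  expect_equal(t(anns(make_ann("g", "T1", "IEA", source = "InterPro"),
                      make_ann("g", "T2", "IEA", source = "InterPro",
                               reference = "REF:2"))),
               "low")
  # same code, different pipelines -> independent
  expect_equal(t(anns(make_ann("g", "T1", "IEA", source = "InterPro"),
                      make_ann("g", "T1", "IEA", source = "UniProtKB-KW",
                               reference = "REF:2"))),
               "medium")
  # unknown codes carry author-statement weight only
  expect_equal(t(anns(make_ann("g", "T1", "XYZ"),
                      make_ann("g", "T1", "ABC", source = "other"))),
               "low")
})

test_that("identical annotation tuples imported twice are counted once", {
  dup <- anns(make_ann("g", "T1", "IDA"),
              make_ann("g", "T1", "IDA"))   # same tuple via two exports
  expect_equal(assess_gene(dup)$tier, "low")
  expect_equal(assess_gene(dup)$n_exp, 1)
})

test_that("mixed gene ids are a usage error; assess_genes partitions a set", {
  expect_error(assess_gene(anns(make_ann("g1", "T1", "IDA"),
                                make_ann("g2", "T1", "IDA"))),
               "single gene")
  ann <- anns(make_ann("g1", "T1", "IDA"),
              make_ann("g1", "T1", "IMP", reference = "REF:2"),
              make_ann("g2", "T1", "ISS"),
              make_ann("g3", "T1", "IDA", negated = TRUE))
  out <- assess_genes(ann)
  expect_equal(nrow(out), 3)
  expect_equal(out$tier[out$gene_id == "g1"], "high")
  expect_equal(out$tier[out$gene_id == "g2"], "low")
  expect_equal(out$tier[out$gene_id == "g3"], "none")
  expect_true(all(table(out$gene_id) == 1))   # exactly one tier per gene
})

test_that("adding a positive experimental annotation never lowers the tier", {
  set.seed(21)
  codes <- c("IDA", "IMP", "ISS", "IBA", "IEA", "TAS", "NAS")
  rank <- c(none = 0, low = 1, medium = 2, high = 3)
  for (rep in 1:40) {
    n <- sample(0:4, 1)
    ann <- if (n == 0) make_ann("g", "T1", "IDA")[0, ] else {
      do.call(rbind, lapply(seq_len(n), function(i) {
        make_ann("g", "T1", sample(codes, 1),
                 source = sample(c("FlyBase", "InterPro"), 1),
                 reference = sprintf("REF:%d", i))
      }))
    }
    before <- assess_gene(ann)$tier
    extra <- make_ann("g", "T1", "IDA", reference = "REF:new",
                      source = "NewLab")
    after <- assess_gene(rbind(ann, extra))$tier
    # absent new conflicts, the tier can only go up
    if (!assess_gene(rbind(ann, extra))$conflict) {
      expect_gte(rank[[after]], rank[[before]])
    }
  }
})

test_that("conflicts are detected on same-term and lineage pairs", {
  g <- toy_graph()   # A <- B <- C
  same <- detect_conflicts(anns(make_ann("g", "B", "IDA"),
                                make_ann("g", "B", "IDA", negated = TRUE,
                                         reference = "REF:2")))
  expect_true(same$conflict)
  expect_equal(same$reasons, "pos_neg_same_term")
  # positive on child, NOT on its parent
  lin <- detect_conflicts(anns(make_ann("g", "C", "IDA"),
                               make_ann("g", "B", "IDA", negated = TRUE,
                                        reference = "REF:2")), graph = g)
  expect_true(lin$conflict)
  expect_equal(lin$reasons, "pos_neg_lineage")
  # unrelated branches do not conflict
  unrel <- detect_conflicts(anns(make_ann("g", "C", "IDA"),
                                 make_ann("g", "D", "IDA", negated = TRUE,
                                          reference = "REF:2")), graph = g)
  expect_false(unrel$conflict)
})

test_that("cross-activity EC conflicts are off by default and need xrefs", {
  g <- ontology_graph(c("T1", "T2"),
                      ec_xrefs = list(T1 = "6.1.1.1", T2 = "6.3.2.19"))
  ann <- anns(make_ann("g", "T1", "IDA"),
              make_ann("g", "T2", "IDA", reference = "REF:2"))
  expect_false(detect_conflicts(ann, g)$conflict)
  on <- detect_conflicts(ann, g, cross_activity = TRUE)
  expect_true(on$conflict)
  expect_equal(on$reasons, "cross_activity_ec")
  # same sub-subclass is not a cross-activity conflict
  g2 <- ontology_graph(c("T1", "T2"),
                       ec_xrefs = list(T1 = "6.1.1.1", T2 = "6.1.1.2"))
  expect_false(detect_conflicts(ann, g2, cross_activity = TRUE)$conflict)
})

test_that("conflict flags equal a brute-force pairwise scan on random toys", {
  g <- toy_graph()
  closure <- list(A = c("A", "B", "C", "D"), B = c("B", "C"),
                  C = "C", D = "D")
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    ann <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_ann("g", sample(c("A", "B", "C", "D"), 1), "IDA",
               negated = stats::runif(1) < 0.4,
               reference = sprintf("REF:%d", i))
    }))
    got <- detect_conflicts(ann, graph = g)$conflict
    # oracle: scan every (positive, negated) pair for identity/lineage
    expected <- FALSE
    for (i in seq_len(nrow(ann))) {
      for (j in seq_len(nrow(ann))) {
        if (ann$negated[i] || !ann$negated[j]) next
        ti <- ann$term[i]; tj <- ann$term[j]
        if (ti == tj || ti %in% closure[[tj]] || tj %in% closure[[ti]]) {
          expected <- TRUE
        }
      }
    }
    expect_identical(got, expected)
  }
})

test_that("assessment tables serialise to TSV", {
  ann <- anns(make_ann("g1", "T1", "IDA"),
              make_ann("g1", "T1", "IMP", reference = "REF:2"))
  path <- tempfile(fileext = ".tsv")
  write_assessments(assess_genes(ann), path)
  back <- utils::read.delim(path)
  expect_equal(back$tier, "high")
  expect_equal(back$n_exp, 2)
})
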