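test_that("GO class queries include descendants and honour negation", {
  g <- toy_graph()   # A <- B <- C, A <- D
  ann <- anns(make_ann("g1", "C", "IDA"),              # child-only
              make_ann("g2", "A", "ISS"),
              make_ann("g3", "B", "IDA", negated = TRUE),
              make_ann("g4", "B", "IDA"),
              make_ann("g4", "B", "IEA", negated = TRUE,
                       reference = "REF:2"))
  hs <- hits_from_go(ann, g, "A")
  expect_setequal(hs$genes, c("g1", "g2", "g4"))   # NOT-only excluded
  hs_b <- hits_from_go(ann, g, "B")
  expect_setequal(hs_b$genes, c("g1", "g4"))
  expect_error(hits_from_go(ann, g, "missing"), "unknown term")
  expect_true(all(lengths(hs$provenance) >= 1))
})

test_that("source/evidence filters restrict hits and preserve subset structure", {
  g <- toy_graph()
  ann <- anns(make_ann("g1", "B", "IDA", source = "FlyBase"),
              make_ann("g2", "B", "IEA", source = "UniProtKB"),
              make_ann("g3", "B", "IEA", source = "InterPro"))
  all_hits <- hits_from_go(ann, g, "A")
  manual <- hits_from_go(ann, g, "A", exclude_sources = "UniProtKB")
  expect_setequal(manual$genes, c("g1", "g3"))
  expect_true(all(manual$genes %in% all_hits$genes))
  ev <- hits_from_go(ann, g, "A", evidence = "IDA")
  expect_equal(ev$genes, "g1")
})

test_that("GO hits equal a brute-force closure-membership scan on random toys", {
  set.seed(41)
  for (rep in 1:15) {
    g <- random_dag(sample(5:20, 1))
    ann <- do.call(rbind, lapply(1:30, function(i) {
      make_ann(sample(sprintf("g%d", 1:10), 1), sample(g$terms, 1),
               "IDA", negated = stats::runif(1) < 0.3,
               reference = sprintf("REF:%d", i))
    }))
    focus <- sample(g$terms, 1)
    got <- hits_from_go(ann, g, focus)$genes
    closure <- brute_closure(g, focus)
    expected <- sort(unique(ann$gene_id[
      !ann$negated & ann$term %in% closure]))
    expect_equal(got, expected)
  }
})

test_that("EC queries match wildcard prefixes with optional reviewed filter", {
  recs <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    ec = c("6.3.2.19", "5.1.1.1", "6.1.1.1", "6.3.-.-"),
    source = "src", reviewed = c(TRUE, TRUE, FALSE, TRUE))
  hs <- hits_from_ec(recs, "6.-.-.-")
  expect_setequal(hs$genes, c("g1", "g3", "g4"))
  expect_setequal(hits_from_ec(recs, "6.-.-.-", reviewed_only = TRUE)$genes,
                  c("g1", "g4"))
  expect_equal(hits_from_ec(recs, "6.3.2.19")$genes, "g1")
  # a wildcard record is no evidence for a more specific query
  expect_false("g4" %in% hits_from_ec(recs, "6.3.2.19")$genes)
})

test_that("EC hit membership equals the string-prefix oracle over an enumerated space", {
  codes <- apply(expand.grid(5:6, 1:2, 1:2, 1:2), 1, paste, collapse = ".")
  recs <- data.frame(gene_id = sprintf("g%02d", seq_along(codes)),
                     ec = codes, source = "s", reviewed = TRUE)
  for (q in c("6.-.-.-", "5.1.-.-", "6.2.1.-", "5.1.1.1")) {
    qprefix <- sub("(\\.-)+$", "", q)
    expected <- recs$gene_id[startsWith(paste0(codes, "."),
                                        paste0(qprefix, "."))]
    expect_setequal(hits_from_ec(recs, q)$genes, expected)
  }
})

test_that("orthology filtering applies score and domain thresholds", {
  calls <- data.frame(
    human_gene = c("h1", "h2", "h3", "h4", "h5", "hx"),
    fly_gene = c("f1", "f2", "f3", "f4", "f5", "f6"),
    score = c(12L, 2L, 4L, 8L, 9L, 15L),
    domain_present = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  gold <- c("h1", "h2", "h3", "h4", "h5")   # hx not characterised
  hs <- hits_from_orthology(calls, gold)
  expect_setequal(hs$genes, c("f1", "f5"))
  review <- attr(hs, "review")
  expect_setequal(review$fly_gene, c("f3", "f4"))   # borderline / no domain
  expect_false("f2" %in% c(hs$genes, review$fly_gene))  # hard-excluded
  expect_false("f6" %in% c(hs$genes, review$fly_gene))  # not gold
  # curator override admits a reviewed case
  hs2 <- hits_from_orthology(calls, gold, admit = "f3")
  expect_true("f3" %in% hs2$genes)
  expect_false("f3" %in% attr(hs2, "review")$fly_gene)
  expect_error(hits_from_orthology(calls, gold, hard_min = 6,
                                   retain_min = 5))
})

test_that("membership matrix covers the union with no all-FALSE rows", {
  hs <- list(hit_set("s1", c("a", "b")), hit_set("s2", c("b", "c")))
  m <- merge_sources(hs)
  expect_equal(m$gene_id, c("a", "b", "c"))
  expect_equal(m$s1, c(TRUE, TRUE, FALSE))
  expect_equal(m$s2, c(FALSE, TRUE, TRUE))
  expect_true(all(rowSums(m[, -1]) >= 1))
  expect_error(merge_sources(list(hit_set("s", "a"), hit_set("s", "b"))),
               "duplicate source")
})

test_that("venn regions count signatures and sum to the union size", {
  hs <- list(hit_set("s1", c("a", "b")), hit_set("s2", c("b", "c")))
  v <- venn_counts(hs)
  expect_equal(v[["s1"]], 1)
  expect_equal(v[["s2"]], 1)
  expect_equal(v[["s1+s2"]], 1)
  expect_equal(sum(v), 3)
})

test_that("venn counts are permutation-invariant and match per-gene tallies", {
  set.seed(51)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    hs <- lapply(seq_len(k), function(i) {
      hit_set(sprintf("s%d", i),
              sample(sprintf("g%02d", 1:25), sample(3:15, 1)))
    })
    v <- venn_counts(hs)
    v_perm <- venn_counts(rev(hs))
    expect_identical(v, v_perm)
    union_genes <- unique(unlist(lapply(hs, `[[`, "genes")))
    expect_equal(sum(v), length(union_genes))
    # brute-force: recount each gene's signature independently
    srcs <- sort(vapply(hs, `[[`, character(1), "source"))
    member <- lapply(hs, `[[`, "genes")
    names(member) <- vapply(hs, `[[`, character(1), "source")
    for (gene in union_genes) {
      sig <- paste(srcs[vapply(srcs, function(s) gene %in% member[[s]],
                               logical(1))], collapse = "+")
      expect_gte(v[[sig]], 1)
    }
    tally <- table(vapply(union_genes, function(gene) {
      paste(srcs[vapply(srcs, function(s) gene %in% member[[s]],
                        logical(1))], collapse = "+")
    }, character(1)))
    for (region in names(tally)) {
      expect_equal(v[[region]], as.integer(tally[[region]]))
    }
    expect_lte(length(union_genes), sum(lengths(member)))
  }
})

test_that("more than six sources is an unsupported arity for venn only", {
  hs <- lapply(1:7, function(i) hit_set(sprintf("s%d", i), "g1"))
  expect_error(venn_counts(hs), "at most 6")
  expect_equal(nrow(merge_sources(hs)), 1)   # matrix still available
})

test_that("candidates are categorised verified/discarded/novel exactly once", {
  out <- categorize_novel(c("a", "b", "c", "a"), verified = "a",
                          discarded = "b")
  expect_equal(nrow(out), 3)
  expect_equal(out$category[match(c("a", "b", "c"), out$gene_id)],
               c("verified", "discarded", "novel"))
  expect_error(categorize_novel("x", verified = c("a", "x"),
                                discarded = c("x")),
               "both verified and discarded")
})

test_that("membership and venn writers emit deterministic files", {
  hs <- list(hit_set("s1", c("a", "b")), hit_set("s2", "b"))
  p1 <- tempfile(fileext = ".tsv")
  write_membership_matrix(merge_sources(hs), p1)
  expect_equal(nrow(utils::read.delim(p1)), 2)
  p2 <- tempfile(fileext = ".json")
  write_venn_json(venn_counts(hs), p2)
  v <- jsonlite::read_json(p2)
  expect_equal(v[["s1+s2"]], 1)
})
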