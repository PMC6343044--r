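write_gaf_lines <- function(rows, path = tempfile(fileext = ".gaf"),
                            header = "!gaf-version: 2.2") {
  writeLines(c(header, rows), path)
  path
}

gaf_line <- function(gene = "FB0001", qual = "enables", term = "T:0001",
                     code = "IDA", date = "20180115", by = "FlyBase") {
  paste("DB", gene, tolower(gene), qual, term, "PMID:1", code, "",
        "F", "", "", "protein", "taxon:7227", date, by, "", "",
        sep = "\t")
}

test_that("GAF parsing handles NOT qualifiers, comments and dates", {
  path <- write_gaf_lines(c(
    gaf_line("FB0001"),
    "! a comment line",
    gaf_line("FB0002", qual = "NOT|enables"),
    gaf_line("FB0003", qual = "not|contributes_to")))
  ann <- read_gaf(path)
  expect_equal(nrow(ann), 3)
  expect_equal(sum(ann$negated), 2)   # NOT detected case-insensitively
  expect_equal(ann$date[1], "2018-01-15")
  expect_equal(ann$eco_id[1], "ECO:0000314")
  expect_equal(ann$aspect, rep("F", 3))
})

test_that("header-only GAF yields an empty record set", {
  ann <- read_gaf(write_gaf_lines(character()))
  expect_equal(nrow(ann), 0)
  expect_true(all(c("gene_id", "negated", "evidence_code") %in%
                    colnames(ann)))
})

test_that("bad column counts fail with the line number; missing header warns", {
  path <- write_gaf_lines(c(gaf_line(), "only\tthree\tcolumns"))
  expect_error(read_gaf(path), "line 3.*3 columns")
  path2 <- tempfile()
  writeLines(gaf_line(), path2)
  expect_warning(ann <- read_gaf(path2), "gaf-version")
  expect_equal(nrow(ann), 1)
})

test_that("annotations round-trip through write_gaf", {
  ann <- rbind(make_ann("G1", "T:0001", "IDA", source = "FlyBase",
                        date = "2018-01-15"),
               make_ann("G2", "T:0002", "IEA", source = "InterPro",
                        negated = TRUE, date = "2017-06-01"))
  path <- tempfile(fileext = ".gaf")
  write_gaf(ann, path)
  back <- read_gaf(path)
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$term, ann$term)
  expect_equal(back$negated, ann$negated)
  expect_equal(back$evidence_code, ann$evidence_code)
  expect_equal(back$source, ann$source)
  expect_equal(back$date, ann$date)
  # idempotence: parse(serialize(parse(x))) == parse(x)
  path2 <- tempfile(fileext = ".gaf")
  write_gaf(back, path2)
  back2 <- read_gaf(path2)
  expect_equal(back2, back)
})

test_that("EC tables load typed records and quarantine malformed codes", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_or_accession\tec\tsource\treviewed",
               "geneX\t6.1.1.1\tsrcA\tTRUE",
               "geneY\t6.1\tsrcA\tFALSE",
               "geneZ\t9.1.1.1\tsrcB\tFALSE",
               ""), path)
  recs <- read_ec_table(path)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$gene_id, "geneX")
  expect_true(recs$reviewed)
  rejects <- attr(recs, "rejects")
  expect_equal(nrow(rejects), 2)
  expect_match(rejects$reason, "malformed EC")
})

test_that("missing required columns are reported by name", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_or_accession\tec\tsource", "g\t1.1.1.1\ts"), path)
  expect_error(read_ec_table(path), "reviewed")
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("human_gene\tfly_gene\tscore", "h\tf\t3"), path2)
  expect_error(read_orthology_table(path2), "domain_present")
})

test_that("orthology tables enforce non-negative integer scores", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("human_gene\tfly_gene\tscore\tdomain_present",
               "h1\tf1\t12\tTRUE",
               "h2\tf2\t0\tFALSE"), path)
  calls <- read_orthology_table(path)
  expect_equal(calls$score, c(12L, 0L))
  expect_equal(calls$domain_present, c(TRUE, FALSE))
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("human_gene\tfly_gene\tscore\tdomain_present",
               "h1\tf1\t-2\tTRUE"), path2)
  expect_error(read_orthology_table(path2), "non-negative")
})

test_that("TSV readers tolerate CRLF endings and trailing blank lines", {
  path <- tempfile(fileext = ".tsv")
  con <- file(path, "wb")
  writeLines(c("accession\tgene_id", "ACC1\tG1", "", ""), con,
             sep = "\r\n")
  close(con)
  expect_equal(read_id_map(path)$gene_id, "G1")
})

test_that("ID resolution conserves records and quarantines ambiguity", {
  mapping <- data.frame(accession = c("A1", "A2", "A3", "AMB", "AMB"),
                        gene_id = c("G1", "G2", "G3", "G4", "G5"))
  recs <- data.frame(gene_id = c("A1", "A2", "A3", "AMB", "UNKNOWN"),
                     payload = 1:5)
  out <- resolve_ids(recs, mapping)
  expect_equal(nrow(out$resolved), 3)
  expect_equal(sort(out$resolved$gene_id), c("G1", "G2", "G3"))
  expect_equal(nrow(out$unmapped), 2)
  expect_setequal(out$unmapped$reason, c("ambiguous", "no_mapping"))
  # many-to-one is applied, not quarantined
  m2 <- data.frame(accession = c("X1", "X2"), gene_id = c("G9", "G9"))
  out2 <- resolve_ids(data.frame(gene_id = c("X1", "X2")), m2)
  expect_equal(out2$resolved$gene_id, c("G9", "G9"))
  # passthrough keeps already-stable ids
  out3 <- resolve_ids(data.frame(gene_id = "G1"), mapping)
  expect_equal(out3$resolved$gene_id, "G1")
  out4 <- resolve_ids(data.frame(gene_id = "G1"), mapping,
                      passthrough = FALSE)
  expect_equal(out4$unmapped$reason, "no_mapping")
})

test_that("record counts are conserved through resolution on random inputs", {
  set.seed(9)
  for (rep in 1:25) {
    accs <- sprintf("A%d", 1:20)
    mapping <- data.frame(
      accession = sample(accs, 15, replace = TRUE),
      gene_id = sample(sprintf("G%d", 1:10), 15, replace = TRUE))
    recs <- data.frame(gene_id = sample(c(accs, "ZZZ"), 12, TRUE))
    out <- resolve_ids(recs, mapping)
    expect_equal(nrow(out$resolved) + nrow(out$unmapped), nrow(recs))
  }
})
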