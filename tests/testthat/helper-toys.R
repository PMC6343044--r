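# shared in-code fixtures: tiny ontologies, annotation rows, random DAGs
# and brute-force oracles kept deliberately independent of the package's
# own traversal code

toy_graph <- function() {
  # A <- B <- C, A <- D
  ontology_graph(c("A", "B", "C", "D"),
                 is_a = list(B = "A", C = "B", D = "A"))
}

toy_obo_file <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: A", "name: alpha activity", "xref: EC:5.1.1.1", "",
    "[Term]", "id: B", "name: beta activity", "is_a: A ! alpha", "",
    "[Term]", "id: C", "name: gamma activity", "is_a: B", "",
    "[Term]", "id: D", "name: delta activity", "is_a: A",
    "xref: KEGG:R00001", ""), path)
  path
}

make_ann <- function(gene, term, code, source = "SRC",
                     reference = "REF:1", negated = FALSE,
                     date = "2018-01-01", aspect = "F",
                     symbol = tolower(gene)) {
  data.frame(gene_id = gene, symbol = symbol, term = term,
             negated = negated,
             qualifiers = if (negated) "NOT|enables" else "enables",
             evidence_code = code, eco_id = NA_character_,
             reference = reference, source = source, date = date,
             aspect = aspect, stringsAsFactors = FALSE)
}

anns <- function(...) do.call(rbind, list(...))

# random DAG: edges always point from higher index (child) to lower
# index (parent), so acyclicity holds by construction
random_dag <- function(n, p = 0.15) {
  terms <- sprintf("N%02d", seq_len(n))
  is_a <- list()
  for (i in seq_len(n)[-1]) {
    parents <- terms[seq_len(i - 1)][stats::runif(i - 1) < p]
    if (length(parents)) is_a[[terms[i]]] <- parents
  }
  ontology_graph(terms, is_a = is_a)
}

# reachability by boolean matrix closure; independent of the package BFS
brute_closure <- function(graph, term) {
  n <- length(graph$terms)
  idx <- stats::setNames(seq_len(n), graph$terms)
  m <- matrix(FALSE, n, n)
  for (child in names(graph$is_a)) {
    for (parent in graph$is_a[[child]]) {
      m[idx[[parent]], idx[[child]]] <- TRUE   # parent -> child
    }
  }
  reach <- diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% m) > 0
  graph$terms[reach[idx[[term]], ]]
}

small_config <- function(seed, n_genes = 50,
                         class_sizes = c(ligase = 15),
                         error_profile = default_error_profile()) {
  fixture_config(n_genes = n_genes, class_sizes = class_sizes,
                 error_profile = error_profile, seed = seed)
}

zero_error_profile <- function() {
  list(global = c(uncurated_literature = 0))
}
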