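#' @section GAF columns:
#' The GAF 2.2 body has 17 tab-separated columns; the ones this package
#' keeps are DB object id (as `gene_id`), symbol, qualifier, term id,
#' reference, evidence code, aspect, date and assigned-by (as `source`).
#' @name gaf-format
#' @keywords internal
NULL

# Evidence-code -> ECO identifier lookup for the codes this workflow uses.
.ECO_IDS <- c(IDA = "ECO:0000314", IMP = "ECO:0000315", IGI = "ECO:0000316",
              ISS = "ECO:0000250", IBA = "ECO:0000318",
              TAS = "ECO:0000304", NAS = "ECO:0000303", IEA = "ECO:0000501")

.empty_annotations <- function() {
  data.frame(gene_id = character(), symbol = character(), term = character(),
             negated = logical(), qualifiers = character(),
             evidence_code = character(), eco_id = character(),
             reference = character(), source = character(),
             date = character(), aspect = character(),
             stringsAsFactors = FALSE)
}

#' Read a gene-association file (GAF 2.x)
#'
#' Parses a GAF into one annotation record per body line. The `NOT`
#' qualifier (detected case-insensitively among the pipe-separated
#' qualifier values) sets `negated`; comment lines starting with `!` are
#' skipped; dates are normalised from the GAF `YYYYMMDD` convention to
#' ISO `YYYY-MM-DD`. A body line with the wrong column count aborts with
#' its line number; a missing `!gaf-version` header only warns.
#'
#' @param path path to a GAF file.
#' @return data frame with columns `gene_id`, `symbol`, `term`, `negated`,
#'   `qualifiers`, `evidence_code`, `eco_id`, `reference`, `source`,
#'   `date`, `aspect`.
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (!length(lines) || !grepl("^!gaf-version:", lines[1])) {
    warning("missing '!gaf-version' header in ", path,
            "; attempting best-effort parse")
  }
  body_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (!length(body_idx)) return(.empty_annotations())
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty 17th field is dropped by strsplit; pad 16 -> 17
  fields[nf == 16L] <- lapply(fields[nf == 16L], function(f) c(f, ""))
  nf <- lengths(fields)
  if (any(nf != 17L)) {
    bad <- which(nf != 17L)[1]
    stop(sprintf("GAF line %d of %s has %d columns, expected 17",
                 body_idx[bad], path, nf[bad]))
  }
  m <- do.call(rbind, fields)
  quals <- m[, 4]
  negated <- vapply(strsplit(quals, "|", fixed = TRUE),
                    function(q) any(tolower(q) == "not"), logical(1))
  code <- m[, 7]
  date <- m[, 14]
  iso <- ifelse(grepl("^[0-9]{8}$", date),
                paste(substr(date, 1, 4), substr(date, 5, 6),
                      substr(date, 7, 8), sep = "-"),
                date)
  data.frame(gene_id = m[, 2], symbol = m[, 3], term = m[, 5],
             negated = negated, qualifiers = quals,
             evidence_code = code,
             eco_id = unname(ifelse(code %in% names(.ECO_IDS),
                                    .ECO_IDS[code], NA_character_)),
             reference = m[, 6], source = m[, 15], date = iso,
             aspect = m[, 9], stringsAsFactors = FALSE)
}

#' Write annotation records as GAF 2.2
#'
#' Inverse of [read_gaf()] for the columns this package tracks; the other
#' GAF columns are filled with fixed placeholder values so the output is
#' structurally valid GAF 2.2.
#'
#' @param annotations annotation data frame as returned by [read_gaf()].
#' @param path output path.
#' @param db value for the DB column (default `"SIM"`).
#' @param taxon value for the taxon column.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, db = "SIM", taxon = "taxon:7227") {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- "!gaf-version: 2.2"
  if (!nrow(annotations)) {
    writeLines(header, con, sep = "\n")
    return(invisible(path))
  }
  qual <- ifelse(nzchar(annotations$qualifiers), annotations$qualifiers,
                 ifelse(annotations$negated, "NOT|enables", "enables"))
  date <- gsub("-", "", annotations$date, fixed = TRUE)
  rows <- paste(db, annotations$gene_id, annotations$symbol, qual,
                annotations$term, annotations$reference,
                annotations$evidence_code, "", annotations$aspect,
                "", "", "protein", taxon, date, annotations$source, "", "",
                sep = "\t")
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", blank.lines.skip = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  # tolerate trailing blank/whitespace-only lines
  df[rowSums(df[required] != "") > 0, , drop = FALSE]
}

#' Read an EC-annotation table
#'
#' Reads a TSV with header columns `gene_or_accession`, `ec`, `source`,
#' `reviewed`. Rows whose EC string is malformed are routed to a rejects
#' report (attached as the `"rejects"` attribute) rather than aborting.
#'
#' @param path path to the TSV.
#' @return data frame of valid records with columns `gene_id`, `ec`,
#'   `source`, `reviewed`; attribute `"rejects"` holds the rejected rows
#'   with a `reason` column.
#' @export
read_ec_table <- function(path) {
  df <- .read_tsv(path, c("gene_or_accession", "ec", "source", "reviewed"))
  ok <- ec_is_valid(df$ec)
  rejects <- df[!ok, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- "malformed EC number"
  out <- data.frame(gene_id = df$gene_or_accession[ok], ec = df$ec[ok],
                    source = df$source[ok],
                    reviewed = toupper(df$reviewed[ok]) %in%
                      c("TRUE", "T", "1", "YES"),
                    stringsAsFactors = FALSE)
  attr(out, "rejects") <- rejects
  out
}

#' Read an orthology-call table
#'
#' Reads a TSV with header columns `human_gene`, `fly_gene`, `score`,
#' `domain_present`. `score` is the integer count of orthology-prediction
#' algorithms supporting the pair (a DIOPT-style score) and must be >= 0.
#'
#' @param path path to the TSV.
#' @return data frame with columns `human_gene`, `fly_gene`, `score`
#'   (integer), `domain_present` (logical).
#' @export
read_orthology_table <- function(path) {
  df <- .read_tsv(path, c("human_gene", "fly_gene", "score",
                          "domain_present"))
  score <- suppressWarnings(as.integer(df$score))
  if (anyNA(score) || any(score < 0L)) {
    stop("orthology scores must be non-negative integers in ", path)
  }
  data.frame(human_gene = df$human_gene, fly_gene = df$fly_gene,
             score = score,
             domain_present = toupper(df$domain_present) %in%
               c("TRUE", "T", "1", "YES"),
             stringsAsFactors = FALSE)
}

#' Read an accession-to-gene ID mapping table
#'
#' @param path TSV with header columns `accession`, `gene_id`.
#' @return data frame with those two columns.
#' @export
read_id_map <- function(path) {
  .read_tsv(path, c("accession", "gene_id"))[c("accession", "gene_id")]
}

#' Resolve accessions to stable gene identifiers
#'
#' Rewrites the `gene_id` column of gene-keyed records through an
#' accession-to-gene mapping. Every input record ends up exactly once in
#' either the resolved output or the unmapped report — nothing is dropped
#' silently. A many-to-one mapping (several accessions, one gene) is
#' applied; a one-to-many mapping (an accession naming two genes) is
#' quarantined as ambiguous. With `passthrough = TRUE` (default), records
#' already keyed by a stable gene ID (a value of the mapping) are kept
#' as-is.
#'
#' @param records data frame with a `gene_id` column holding accessions
#'   and/or stable IDs.
#' @param mapping data frame with columns `accession`, `gene_id`.
#' @param passthrough treat ids already present among `mapping$gene_id`
#'   as resolved?
#' @return list with elements `resolved` (records, `gene_id` rewritten)
#'   and `unmapped` (records plus a `reason` column: `"no_mapping"` or
#'   `"ambiguous"`).
#' @export
resolve_ids <- function(records, mapping, passthrough = TRUE) {
  stopifnot("gene_id" %in% colnames(records),
            all(c("accession", "gene_id") %in% colnames(mapping)))
  targets <- split(mapping$gene_id, mapping$accession)
  n_targets <- lengths(lapply(targets, unique))
  key <- records$gene_id
  status <- ifelse(key %in% names(targets),
                   ifelse(n_targets[key] > 1L, "ambiguous", "mapped"),
                   ifelse(passthrough & key %in% mapping$gene_id,
                          "passthrough", "no_mapping"))
  resolved <- records[status %in% c("mapped", "passthrough"), , drop = FALSE]
  hit <- status[status %in% c("mapped", "passthrough")] == "mapped"
  resolved$gene_id[hit] <- vapply(targets[resolved$gene_id[hit]],
                                  function(g) unique(g)[[1]], character(1))
  unmapped <- records[status %in% c("ambiguous", "no_mapping"), , drop = FALSE]
  if (nrow(unmapped)) {
    unmapped$reason <- status[status %in% c("ambiguous", "no_mapping")]
  } else {
    unmapped$reason <- character()
  }
  stopifnot(nrow(resolved) + nrow(unmapped) == nrow(records))
  list(resolved = resolved, unmapped = unmapped)
}
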