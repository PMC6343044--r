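#' Parse an Enzyme Commission number
#'
#' EC numbers are four-level codes `class.subclass.sub-subclass.serial`
#' (e.g. `5.1.1.1` for alanine racemase). The class level is always
#' concrete and must be in 1–7; deeper levels may be the wildcard `-`,
#' and once a level is wildcard all deeper levels must be too (so
#' `6.-.-.-` denotes the whole ligase class, while `6.-.3.-` is invalid).
#'
#' @param text an EC string such as `"6.3.2.19"` or `"6.-.-.-"`.
#' @param wildcards allow wildcard levels? Set `FALSE` to require a fully
#'   concrete code.
#' @return An object of class `ec_number`: integer vector of 4 levels with
#'   `NA` marking wildcards.
#' @examples
#' parse_ec("6.-.-.-")
#' parse_ec("5.1.1.1")
#' @export
parse_ec <- function(text, wildcards = TRUE) {
  if (inherits(text, "ec_number")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(trimws(text), ".", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("EC number must have four levels, got ", length(parts), ": ", text)
  }
  lv <- suppressWarnings(ifelse(parts == "-", NA_integer_,
                                as.integer(parts)))
  concrete <- !is.na(lv)
  if (any(parts != "-" & !concrete)) {
    stop("EC levels must be positive integers or '-': ", text)
  }
  if (is.na(lv[1])) stop("EC class level cannot be a wildcard: ", text)
  if (lv[1] < 1L || lv[1] > 7L) {
    stop("EC class must be in 1..7, got ", lv[1], ": ", text)
  }
  if (any(lv[concrete] <= 0L)) {
    stop("EC levels must be positive integers or '-': ", text)
  }
  if (any(diff(concrete) > 0L)) {
    stop("concrete EC level after a wildcard: ", text)
  }
  if (!wildcards && any(!concrete)) {
    stop("wildcard EC levels not allowed here: ", text)
  }
  structure(list(levels = lv), class = "ec_number")
}

#' Is a string a well-formed EC number?
#'
#' Vectorised validity predicate used to route malformed codes to rejects
#' reports instead of aborting a load.
#'
#' @param text character vector of candidate EC strings.
#' @param wildcards allow wildcard levels?
#' @return logical vector.
#' @export
ec_is_valid <- function(text, wildcards = TRUE) {
  vapply(text, function(x) {
    !inherits(tryCatch(parse_ec(x, wildcards = wildcards),
                       error = identity), "error")
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
format.ec_number <- function(x, ...) {
  paste(ifelse(is.na(x$levels), "-", x$levels), collapse = ".")
}

#' @export
print.ec_number <- function(x, ...) {
  cat("<EC ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
as.character.ec_number <- function(x, ...) format(x)

#' Match an EC query against a concrete EC code
#'
#' A query with wildcard levels matches every code that agrees on all of
#' the query's concrete levels: `6.-.-.-` matches any ligase code, and
#' `5.1.-.-` matches every racemase/epimerase code but not `5.2.1.1`.
#'
#' @param query an `ec_number` or EC string, wildcards allowed.
#' @param candidate a fully concrete `ec_number` or EC string.
#' @return `TRUE` iff every concrete level of `query` equals the
#'   corresponding level of `candidate`.
#' @export
ec_matches <- function(query, candidate) {
  q <- parse_ec(query)
  cc <- parse_ec(candidate)
  if (anyNA(cc$levels)) {
    stop("candidate EC must be fully concrete: ", format(cc))
  }
  concrete <- !is.na(q$levels)
  all(q$levels[concrete] == cc$levels[concrete])
}
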