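# Subunit-level table for three-level hierarchical ROC analysis.
# Each record is one subunit: family / person / subunit labels, a continuous
# prediction score and a binary event indicator.  Person labels are resolved
# within family (the same person label under two families denotes two
# different persons); subunit labels within person.

#' Construct and validate a three-level hierarchical dataset
#'
#' Builds the subunit-level table used throughout the package: one row per
#' subunit, with family, person and subunit identifiers, a continuous
#' prediction score and a binary (0/1) event indicator.  Nesting is
#' label-based and resolved top-down: persons are identified by the pair
#' (family, person) and subunits by the triple (family, person, subunit), so
#' cluster sizes may vary at every level.
#'
#' @param data a data.frame containing the five columns below.
#' @param family,person,subunit,score,event column names in `data`.
#' @return A data.frame of class `"hier_data"` with standardized columns
#'   `family`, `person`, `subunit`, `score`, `event` (row order preserved).
#' @details Validation enforces: unique (family, person, subunit) triples,
#'   finite numeric scores, events in \{0, 1\}, and no missing values.
#'   Records with missing score or event are rejected rather than imputed.
#' @seealso [read_hier_data()], [pair_counts()], [hier_auc()]
#' @export
hier_data <- function(data, family = "family", person = "person",
                      subunit = "subunit", score = "score", event = "event") {
  cols <- c(family = family, person = person, subunit = subunit,
            score = score, event = event)
  missing_cols <- cols[!cols %in% names(data)]
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(family  = as.character(data[[family]]),
                    person  = as.character(data[[person]]),
                    subunit = as.character(data[[subunit]]),
                    score   = data[[score]],
                    event   = data[[event]],
                    stringsAsFactors = FALSE)
  if (!is.numeric(out$score))
    stop("score column must be numeric")
  bad <- which(!is.finite(out$score))
  if (length(bad))
    stop("non-finite or missing score in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  ev <- out$event
  if (is.logical(ev)) ev <- as.integer(ev)
  if (!is.numeric(ev))
    stop("event column must be numeric 0/1")
  bad <- which(is.na(ev) | !(ev %in% c(0, 1)))
  if (length(bad))
    stop("event must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  out$event <- as.integer(ev)
  key <- paste(out$family, out$person, out$subunit, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (family, person, subunit) triple in row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  class(out) <- c("hier_data", "data.frame")
  out
}

#' Read a hierarchical subunit table from a delimited file
#'
#' @param path path to a CSV or TSV file with a header row.
#' @param sep field delimiter; `NULL` (default) autodetects `","` vs `"\t"`
#'   from the header line.
#' @inheritParams hier_data
#' @return A validated [hier_data] data.frame, row order preserved.
#' @export
read_hier_data <- function(path, family = "family", person = "person",
                           subunit = "subunit", score = "score",
                           event = "event", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  hier_data(raw, family = family, person = person, subunit = subunit,
            score = score, event = event)
}

#' Write a hierarchical subunit table to a delimited file
#'
#' Inverse of [read_hier_data()]: `read_hier_data(write_hier_data(x, p))`
#' reproduces `x` record for record.
#'
#' @param x a [hier_data] object.
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_hier_data <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "hier_data"))
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Event and nonevent pair counts by person
#'
#' Computes, for every person, the number of event subunits \eqn{f_{ij}} and
#' nonevent subunits \eqn{g_{ij}}, together with the totals \eqn{F} and
#' \eqn{G}.  The product \eqn{F \cdot G} is the total number of discordant
#' (nonevent, event) subunit pairs, the denominator of the extended
#' Mann-Whitney AUC.
#'
#' @param data a [hier_data] object (or data.frame with its columns).
#' @return A list with components `persons` (data.frame: `family`, `person`,
#'   `f`, `g`), `F`, `G`.
#' @export
pair_counts <- function(data) {
  pid <- paste(data$family, data$person, sep = "\r")
  idx <- match(pid, unique(pid))
  f <- as.vector(rowsum(data$event, idx))
  g <- as.vector(rowsum(1L - data$event, idx))
  first <- !duplicated(pid)
  persons <- data.frame(family = data$family[first],
                        person = data$person[first],
                        f = f, g = g, stringsAsFactors = FALSE)
  list(persons = persons, F = sum(f), G = sum(g))
}

#' @export
print.hier_data <- function(x, ...) {
  pc <- pair_counts(x)
  cat(sprintf(
    "Three-level hierarchical dataset: %d subunits, %d persons, %d families\n",
    nrow(x), nrow(pc$persons), length(unique(x$family))))
  cat(sprintf("  events: %d, nonevents: %d (discordant pairs: %d)\n",
              pc$F, pc$G, pc$F * pc$G))
  NextMethod()
  invisible(x)
}
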