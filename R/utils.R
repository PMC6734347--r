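`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

## Guess the field separator from the first data lines: tab wins over comma,
## comma over generic whitespace.
.sniff_delim <- function(lines) {
  probe <- lines[nzchar(lines)][1]
  if (is.na(probe)) return("\t")
  if (grepl("\t", probe)) "\t" else if (grepl(",", probe)) "," else ""
}

.split_fields <- function(line, delim) {
  if (delim == "") strsplit(trimws(line), "[[:space:]]+")[[1]]
  else strsplit(line, delim, fixed = TRUE)[[1]]
}

## Header auto-detection: a first row whose fields look like column names
## (known keywords, or a non-numeric score field where one is expected).
.looks_like_header <- function(fields, expect_score = FALSE) {
  keywords <- c(
    "tumor", "tumour", "sample", "sample_id", "tumor_id", "gene", "gene1",
    "gene2", "gene_symbol", "symbol", "protein", "protein1", "protein2",
    "node", "node1", "node2", "source", "target", "from", "to", "id",
    "score", "weight", "combined_score"
  )
  if (any(tolower(fields) %in% keywords)) return(TRUE)
  if (expect_score && length(fields) >= 3) {
    return(is.na(suppressWarnings(as.numeric(fields[3]))))
  }
  FALSE
}

## Encode edges as scalar keys for O(1)-ish membership tests.
## `edges` is an m x 2 integer matrix; ncol2 is the size of the second index.
.edge_keys <- function(edges, ncol2) {
  (as.numeric(edges[, 1]) - 1) * ncol2 + as.numeric(edges[, 2])
}

## Dense rank of scores in descending order (1 = best; ties share a rank).
.dense_rank_desc <- function(x) {
  match(-x, sort(unique(-x)))
}

## sample() treats a length-1 numeric as 1:x; this does not.
.sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

.read_lines_any <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
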