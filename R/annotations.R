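#' Construct an annotation set
#'
#' Functional annotation (GO, MapMan, or custom) as a tibble with one row per
#' term: `term_id`, `description`, `genes` (list-column of gene id vectors),
#' `sub_ontology` (`"BP"`/`"CC"`/`"MF"` or `NA`).
#'
#' @param terms A data frame with at least `term_id` and `genes`; missing
#'   `description` / `sub_ontology` columns are filled with defaults.
#' @param source One of `"GO"`, `"MapMan"`, `"custom"`.
#' @return A tibble of class `annotation_set` with attribute `source`.
#' @export
annotation_set <- function(terms, source = c("custom", "GO", "MapMan")) {
  source <- match.arg(source)
  terms <- as_tibble(terms)
  if (!all(c("term_id", "genes") %in% names(terms))) {
    stop_validation("`terms` needs columns `term_id` and `genes`")
  }
  if (nrow(terms) == 0L) stop_parameter("annotation set is empty")
  if (!"description" %in% names(terms)) terms$description <- ""
  if (!"sub_ontology" %in% names(terms)) terms$sub_ontology <- NA_character_
  terms$genes <- lapply(terms$genes, function(g) unique(as.character(g)))
  if (any(lengths(terms$genes) == 0L)) {
    stop_validation("every term needs a non-empty gene set")
  }
  if (anyDuplicated(terms$term_id)) stop_validation("duplicate term ids")
  out <- terms[, c("term_id", "description", "genes", "sub_ontology")]
  attr(out, "source") <- source
  class(out) <- c("annotation_set", class(out))
  out
}

#' Read annotation in GMT format
#'
#' One term per line: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @param source Annotation source tag, see [annotation_set()].
#' @return An `annotation_set`.
#' @export
read_gmt <- function(path, source = "custom") {
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_parameter(sprintf("empty annotation file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop_parse(sprintf("GMT line %d has fewer than 3 fields in %s", short[1L], path))
  }
  annotation_set(
    tibble(term_id = vapply(parts, `[[`, "", 1L),
           description = vapply(parts, `[[`, "", 2L),
           genes = lapply(parts, function(p) p[-(1:2)])),
    source = source
  )
}

#' Read annotation in long (gene, term) TSV format
#'
#' Two columns, `gene_id<TAB>term_id` (optional header tolerated); repeated
#' pairs are deduplicated.
#'
#' @inheritParams read_gmt
#' @return An `annotation_set`.
#' @export
read_annotation_pairs <- function(path, source = "custom") {
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop_parse("annotation TSV needs two columns: gene_id, term_id")
  if (nrow(raw) > 0L && identical(tolower(raw[1L, 1L]), "gene_id")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop_parameter(sprintf("empty annotation file: %s", path))
  by_term <- split(raw[[1L]], raw[[2L]])
  annotation_set(
    tibble(term_id = names(by_term), genes = unname(by_term)),
    source = source
  )
}

#' All gene ids carrying at least one annotation
#'
#' @param ann An `annotation_set`.
#' @return Character vector of annotated gene ids.
#' @export
annotated_genes <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  unique(unlist(ann$genes, use.names = FALSE))
}
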