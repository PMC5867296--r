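# Cross-species integration: orthogroup tables link per-species candidate
# records into comparative networks (candidate nodes attached to a bait-set
# hub per species, orthology edges between same-family genes across species).

#' Read an orthogroup (gene family) table
#'
#' Three-column TSV `family_id<TAB>species_id<TAB>gene_id` (PLAZA-style gene
#' family export). A (species, gene) pair may belong to at most one family.
#'
#' @param path TSV path (optional header row tolerated).
#' @return A tibble of class `orthogroup_table` with columns `family_id`,
#'   `species_id`, `gene_id`.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  raw <- tryCatch(
    read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
               quote = "", comment.char = ""),
    error = function(e) data.frame()
  )
  if (nrow(raw) == 0L) {
    warn(sprintf("empty orthogroup file: %s", path))
    out <- tibble(family_id = character(), species_id = character(),
                  gene_id = character())
    class(out) <- c("orthogroup_table", class(out))
    return(out)
  }
  if (ncol(raw) < 3L) stop_parse("orthogroup TSV needs columns family_id, species_id, gene_id")
  if (identical(tolower(raw[1L, 1L]), "family_id")) raw <- raw[-1L, , drop = FALSE]
  out <- distinct(tibble(family_id = raw[[1L]], species_id = raw[[2L]],
                         gene_id = raw[[3L]]))
  key <- paste(out$species_id, out$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop_validation(sprintf(
      "gene(s) in more than one family: %s",
      paste(head(unique(paste0(dup$species_id, ":", dup$gene_id)), 5), collapse = ", ")))
  }
  class(out) <- c("orthogroup_table", class(out))
  out
}

#' Keyword-based regulatory classification of genes
#'
#' Maps free-text gene descriptions to coarse regulatory classes used for
#' node shapes in comparative networks: transcription factors, kinases and
#' receptors (signalling), transporters, everything else `"other"`, genes
#' without a description `"unknown"`. Matching is case-insensitive substring /
#' regex; rules are an ordered, user-editable list (first class whose pattern
#' matches wins).
#'
#' @param descriptions Data frame with columns `gene_id`, `description`, or a
#'   path to a two-column TSV.
#' @param rules Named list mapping class to character vector of regex
#'   patterns; default [default_regulatory_rules()].
#' @return Tibble `gene_id`, `regulatory_class`.
#' @export
classify_regulatory <- function(descriptions, rules = default_regulatory_rules()) {
  if (is.character(descriptions) && length(descriptions) == 1L) {
    raw <- read.delim(descriptions, header = FALSE, sep = "\t",
                      colClasses = "character", quote = "", comment.char = "")
    if (ncol(raw) < 2L) stop_parse("description TSV needs columns gene_id, description")
    if (identical(tolower(raw[1L, 1L]), "gene_id")) raw <- raw[-1L, , drop = FALSE]
    descriptions <- tibble(gene_id = raw[[1L]], description = raw[[2L]])
  }
  descriptions <- as_tibble(descriptions)
  stopifnot(all(c("gene_id", "description") %in% names(descriptions)))
  cls <- rep("other", nrow(descriptions))
  assigned <- rep(FALSE, nrow(descriptions))
  for (klass in names(rules)) {
    hit <- !assigned & Reduce(`|`, lapply(rules[[klass]], function(p) {
      grepl(p, descriptions$description, ignore.case = TRUE)
    }))
    cls[hit] <- klass
    assigned <- assigned | hit
  }
  tibble(gene_id = descriptions$gene_id, regulatory_class = cls)
}

#' Default regulatory-class keyword rules
#'
#' @return Named list of regex pattern vectors, in match-priority order.
#' @export
default_regulatory_rules <- function() {
  list(
    TF = c("transcription factor", "\\bWRKY\\b", "\\bMYB\\b", "\\bbZIP\\b",
           "\\bNAC domain\\b", "\\bAP2\\b", "homeobox", "zinc finger"),
    `kinase/receptor` = c("kinase", "receptor", "phosphatase"),
    transporter = c("transporter", "ATPase.*transporting", "\\bchannel\\b",
                    "permease")
  )
}

#' Build a cross-species comparative candidate network
#'
#' For one functional term, joins per-species candidate records (see
#' [morphdb_records()]) through orthogroups: a candidate node is included iff
#' it is stored for the term in its species AND its gene family contains, in
#' a different species, another stored candidate for the same term — or a
#' bait gene of that species' bait set, when `include_baits_as_partners` is
#' `TRUE` (the stricter candidates-only rule mirrors published network
#' figures). Each species contributing nodes gets one bait-set hub node;
#' candidates connect to their species' hub with `"member"` edges, and
#' cross-species same-family candidate pairs with `"orthology"` edges. Bait
#' genes themselves are not emitted as nodes.
#'
#' @param term_id The functional term.
#' @param records Named list (by species id) of record tibbles from
#'   [morphdb_records()].
#' @param baits Named list (by species id) of [bait_set()]s for the term.
#' @param orthogroups An [read_orthogroups()] table.
#' @param include_baits_as_partners Count baits as cross-species partners
#'   (default `TRUE`).
#' @param regulatory Optional classification tibble from
#'   [classify_regulatory()] with `gene_id`, `regulatory_class` (optionally
#'   `species_id`).
#' @return An object of class `comparative_network`: list with `term_id`,
#'   `nodes` (tibble: `node_id`, `type`, `species`, `gene_id`, `z`, `rank`,
#'   `family_id`, `regulatory_class`, `is_bait`), `edges` (tibble: `from`,
#'   `to`, `interaction`). Node order is (species, gene id) for diffability.
#' @export
build_network <- function(term_id, records, baits, orthogroups,
                          include_baits_as_partners = TRUE,
                          regulatory = NULL) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  if (length(records) < 2L || is.null(names(records))) {
    stop_parameter("`records` must be a named list covering at least 2 species")
  }
  species <- sort(names(records))
  fam_key <- setNames(orthogroups$family_id,
                      paste(orthogroups$species_id, orthogroups$gene_id, sep = "\r"))
  lookup_family <- function(sp, genes) {
    unname(fam_key[paste(sp, genes, sep = "\r")])
  }

  cand <- bind_rows(lapply(species, function(sp) {
    r <- records[[sp]]
    r <- r[r$term_id == term_id, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    tibble(species = sp, gene_id = r$gene_id, z = r$z, rank = r$rank,
           family_id = lookup_family(sp, r$gene_id))
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    warn(sprintf("term '%s' absent from all record tables: empty network", term_id))
    return(empty_network(term_id))
  }

  bait_fams <- bind_rows(lapply(species, function(sp) {
    b <- baits[[sp]]
    if (is.null(b)) return(NULL)
    g <- if (inherits(b, "bait_set")) b$genes else as.character(b)
    tibble(species = sp, family_id = lookup_family(sp, g))
  }))

  # inclusion: a cross-species partner (candidate, optionally bait) in the
  # same family
  has_partner <- vapply(seq_len(nrow(cand)), function(i) {
    f <- cand$family_id[i]
    if (is.na(f)) return(FALSE)
    other_cand <- any(cand$family_id == f & cand$species != cand$species[i],
                      na.rm = TRUE)
    other_bait <- include_baits_as_partners && !is.null(bait_fams) &&
      nrow(bait_fams) > 0L &&
      any(bait_fams$family_id == f & bait_fams$species != cand$species[i],
          na.rm = TRUE)
    other_cand || other_bait
  }, logical(1))
  cand <- cand[has_partner, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warn(sprintf("no candidate for term '%s' has a cross-species partner", term_id))
    return(empty_network(term_id))
  }
  cand <- arrange(cand, .data$species, .data$gene_id)
  cand$node_id <- paste(cand$species, cand$gene_id, sep = ":")

  cls <- rep("unknown", nrow(cand))
  if (!is.null(regulatory)) {
    reg <- as_tibble(regulatory)
    if ("species_id" %in% names(reg)) {
      idx <- match(paste(cand$species, cand$gene_id), paste(reg$species_id, reg$gene_id))
    } else {
      idx <- match(cand$gene_id, reg$gene_id)
    }
    cls <- ifelse(is.na(idx), "unknown", reg$regulatory_class[idx])
  }

  hubs <- tibble(
    node_id = paste(sort(unique(cand$species)), term_id, sep = ":"),
    type = "bait_set_hub",
    species = sort(unique(cand$species)),
    gene_id = NA_character_, z = NA_real_, rank = NA_integer_,
    family_id = NA_character_, regulatory_class = NA_character_,
    is_bait = FALSE
  )
  nodes <- bind_rows(
    tibble(node_id = cand$node_id, type = "candidate", species = cand$species,
           gene_id = cand$gene_id, z = cand$z, rank = cand$rank,
           family_id = cand$family_id, regulatory_class = cls,
           is_bait = FALSE),
    hubs
  )

  member_edges <- tibble(from = cand$node_id,
                         to = paste(cand$species, term_id, sep = ":"),
                         interaction = "member")
  ortho <- NULL
  if (nrow(cand) > 1L) {
    pairs <- expand.grid(i = seq_len(nrow(cand)), j = seq_len(nrow(cand)))
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    sel <- !is.na(cand$family_id[pairs$i]) &
      cand$family_id[pairs$i] == cand$family_id[pairs$j] &
      cand$species[pairs$i] != cand$species[pairs$j]
    pairs <- pairs[sel, , drop = FALSE]
    if (nrow(pairs) > 0L) {
      ortho <- tibble(from = cand$node_id[pairs$i], to = cand$node_id[pairs$j],
                      interaction = "orthology")
    }
  }
  edges <- bind_rows(member_edges, ortho)
  edges <- arrange(edges, .data$interaction, .data$from, .data$to)

  structure(list(term_id = term_id, nodes = nodes, edges = edges),
            class = "comparative_network")
}

empty_network <- function(term_id) {
  structure(
    list(term_id = term_id,
         nodes = tibble(node_id = character(), type = character(),
                        species = character(), gene_id = character(),
                        z = numeric(), rank = integer(), family_id = character(),
                        regulatory_class = character(), is_bait = logical()),
         edges = tibble(from = character(), to = character(),
                        interaction = character())),
    class = "comparative_network"
  )
}

#' @export
print.comparative_network <- function(x, ...) {
  cat(sprintf("<comparative_network> %s: %d nodes, %d edges\n",
              x$term_id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a comparative network
#'
#' Lossless attribute export in node-link JSON (Cytoscape-style `data` maps)
#' or GraphML (via igraph). Node ordering is stable (species, then gene id),
#' so exports are diffable.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("json", "graphml")) {
  stopifnot(inherits(net, "comparative_network"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      term_id = net$term_id,
      nodes = purrr::transpose(lapply(as.list(as.data.frame(net$nodes)), as.list)) |>
        lapply(function(d) list(data = d)),
      edges = purrr::transpose(lapply(as.list(as.data.frame(net$edges)), as.list)) |>
        lapply(function(d) list(data = d))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA, pretty = TRUE)
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
    nd <- net$nodes
    g <- igraph::add_vertices(g, nrow(nd),
                              name = nd$node_id, type = nd$type,
                              species = nd$species,
                              gene_id = nd$gene_id %na% "",
                              z = nd$z %na% NA_real_,
                              rank = as.numeric(nd$rank) %na% NA_real_,
                              family_id = nd$family_id %na% "",
                              regulatory_class = nd$regulatory_class %na% "",
                              is_bait = nd$is_bait)
    if (nrow(net$edges) > 0L) {
      g <- igraph::add_edges(
        g, rbind(match(net$edges$from, nd$node_id), match(net$edges$to, nd$node_id)),
        interaction = net$edges$interaction
      )
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a node-link JSON network export
#'
#' @param path JSON file produced by [export_network()].
#' @return A `comparative_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  to_tbl <- function(items, proto) {
    if (length(items) == 0L) return(proto)
    bind_rows(lapply(items, function(it) {
      d <- it$data
      d[vapply(d, is.null, logical(1))] <- NA
      as_tibble(d)
    }))
  }
  proto <- empty_network(obj$term_id)
  nodes <- to_tbl(obj$nodes, proto$nodes)
  edges <- to_tbl(obj$edges, proto$edges)
  if (nrow(nodes) > 0L) {
    nodes$rank <- as.integer(nodes$rank)
    nodes$z <- as.numeric(nodes$z)
  }
  structure(list(term_id = obj$term_id, nodes = nodes, edges = edges),
            class = "comparative_network")
}
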