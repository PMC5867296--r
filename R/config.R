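#' Load a species configuration from YAML
#'
#' The YAML lists, per species, the expression datasets and their clustering
#' solutions:
#'
#' ```yaml
#' species: ath
#' datasets:
#'   - dataset: ds01
#'     expression_path: ds01.expression.tsv
#'     platform: microarray
#'     clustering_paths: [ds01.clusters.tsv]
#' normalize: true        # optional, default true
#' sd_filter: 0.75        # optional retain fraction; null disables
#' filter_before_normalize: false   # optional order switch
#' ```
#'
#' Each dataset is read, optionally normalized according to its platform and
#' filtered by gene-wise standard deviation (default: normalize first, then
#' filter), and paired with each of its clustering solutions into
#' configurations.
#'
#' @param path YAML file path.
#' @param base_dir Directory relative paths are resolved against (default:
#'   the YAML's directory).
#' @return A list with `species`, `matrices`, `configurations`.
#' @export
load_species_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L) {
    stop_parameter("config lists no datasets")
  }
  normalize <- cfg$normalize %||% TRUE
  # an explicit `sd_filter: ~` disables filtering; an absent key means default
  sd_filter <- if ("sd_filter" %in% names(cfg)) cfg$sd_filter else 0.75
  filter_first <- cfg$filter_before_normalize %||% FALSE
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)

  matrices <- list()
  configurations <- list()
  for (ds in cfg$datasets) {
    m <- read_expression_matrix(resolve(ds$expression_path),
                                platform = ds$platform %||% "microarray",
                                dataset_id = ds$dataset)
    steps <- if (isTRUE(filter_first)) c("filter", "normalize") else c("normalize", "filter")
    for (st in steps) {
      if (st == "normalize" && isTRUE(normalize)) m <- normalize_expression(m)
      if (st == "filter" && !is.null(sd_filter)) m <- filter_by_sd(m, sd_filter)
    }
    matrices[[m$dataset_id]] <- m
    for (cp in ds$clustering_paths) {
      cl <- read_clustering(resolve(cp), m)
      configurations[[length(configurations) + 1L]] <- configuration(m, cl)
    }
  }
  list(species = cfg$species %||% "species", matrices = matrices,
       configurations = configurations)
}
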