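# Core containers and file formats.
#
# On-disk convention for count tables follows the common amplicon layout:
# rows = OTUs, columns = samples.  In memory the orientation is samples x
# OTUs (rows = samples), which is what vegan-style community functions
# expect.  All writers emit a '#'-prefixed header carrying the package
# version and the RNG seed of the run so every output is traceable.

#' Construct and validate a count table
#'
#' A count table is an integer matrix with samples as rows and OTUs as
#' columns.  Row names are sample identifiers, column names OTU
#' identifiers; both must be unique and non-empty.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs,
#'   with row and column names set.
#' @return the validated integer matrix, classed `htqs_counts`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table needs at least 1 sample and 1 OTU", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table requires sample (row) and OTU (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "counts must be non-negative integers; offending cell row '%s', column '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])), call. = FALSE)
  storage.mode(counts) <- "integer"
  class(counts) <- c("htqs_counts", class(counts))
  counts
}

#' @export
print.htqs_counts <- function(x, ...) {
  cat(sprintf("<htqs count table: %d samples x %d OTUs, %s reads>\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

.header_lines <- function(seed = NULL) {
  c(sprintf("# htqs %s", as.character(utils::packageVersion("htqs"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

.write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", ...)
}

#' Read a count table from TSV
#'
#' The reference dialect is tab-separated text with a header row of sample
#' identifiers and a first column of OTU identifiers (rows = OTUs).  Lines
#' starting with `#` are comments.  Use `transpose = TRUE` for files laid
#' out the other way (rows = samples).
#'
#' @param path file path.
#' @param transpose logical; set when the file has samples as rows.
#' @return an [count_table()] matrix (samples x OTUs).
#' @export
read_count_table <- function(path, transpose = FALSE) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("count table file needs an id column plus data",
                          call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count value near row ", ids[bad[1, 1]], call. = FALSE)
  }
  rownames(m) <- ids
  if (!transpose) m <- t(m)
  count_table(m)
}

#' Write a count table to TSV (rows = OTUs, columns = samples)
#' @param x count table (samples x OTUs).
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @export
write_count_table <- function(x, path, seed = NULL) {
  m <- t(unclass(x))
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path, seed)
}

#' Construct and validate a taxonomy table
#'
#' @param otu_id character OTU identifiers (unique).
#' @param lineage semicolon-separated ranked labels
#'   (`domain;phylum;class;order;family;genus`); shorter lineages allowed.
#' @param category one of `bacteria`, `archaea`, `chloroplast`,
#'   `spike_in`, `unassigned`.
#' @return data.frame with columns `otu_id`, `lineage`, `category`.
#' @export
taxonomy_table <- function(otu_id, lineage, category) {
  ok <- c("bacteria", "archaea", "chloroplast", "spike_in", "unassigned")
  if (anyDuplicated(otu_id))
    stop("duplicate OTU ids in taxonomy", call. = FALSE)
  if (any(is.na(category)) || !all(category %in% ok))
    stop("taxonomy category must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  data.frame(otu_id = as.character(otu_id), lineage = as.character(lineage),
             category = as.character(category), stringsAsFactors = FALSE)
}

#' @rdname taxonomy_table
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  df <- .read_tsv(path)
  taxonomy_table(df$otu_id, df$lineage, df$category)
}

#' @rdname taxonomy_table
#' @param x taxonomy table.
#' @param seed optional seed recorded in the header.
#' @export
write_taxonomy <- function(x, path, seed = NULL) .write_tsv(x, path, seed)

#' Spike-in design: identifier and copies added per sample
#'
#' @param spikein_id character identifiers.
#' @param added_copies positive copy numbers; at least two distinct
#'   concentration levels are required for a calibration line.
#' @return data.frame with columns `spikein_id`, `added_copies`.
#' @export
spikein_design <- function(spikein_id, added_copies) {
  added_copies <- as.numeric(added_copies)
  if (anyDuplicated(spikein_id))
    stop("duplicate spike-in ids", call. = FALSE)
  if (any(!is.finite(added_copies)) || any(added_copies <= 0))
    stop("added_copies must be positive", call. = FALSE)
  if (length(unique(added_copies)) < 2L)
    stop("spike-in design needs >= 2 distinct concentration levels",
         call. = FALSE)
  data.frame(spikein_id = as.character(spikein_id),
             added_copies = added_copies, stringsAsFactors = FALSE)
}

#' @rdname spikein_design
#' @param path file path.
#' @export
read_spikein_design <- function(path) {
  df <- .read_tsv(path)
  spikein_design(df$spikein_id, df$added_copies)
}

#' @rdname spikein_design
#' @param x spike-in design.
#' @param seed optional seed recorded in the header.
#' @export
write_spikein_design <- function(x, path, seed = NULL) .write_tsv(x, path, seed)

.meta_cols <- c("sample_id", "temperature", "salinity", "nox", "drp",
                "silicate", "chla", "bacterial_abundance", "longitude",
                "latitude", "recovery_ratio", "volume")

#' Validate per-sample metadata
#'
#' Environmental variables, coordinates, and the two calibration scalars:
#' `recovery_ratio` R (fraction of the DNA extract that was sequenced, in
#' (0,1]) and `volume` V (liters of seawater filtered).  Longitude is
#' normalized to \[-180, 180\] so that distance code sees one convention.
#' Missing values are rejected: downstream driver analyses assume complete
#' matrices.
#'
#' @param df data.frame with columns
#'   `sample_id, temperature, salinity, nox, drp, silicate, chla,
#'   bacterial_abundance, longitude, latitude, recovery_ratio, volume`.
#' @return validated data.frame, longitudes normalized.
#' @export
sample_metadata <- function(df) {
  miss <- setdiff(.meta_cols, names(df))
  if (length(miss) > 0L)
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, .meta_cols]
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  num <- df[, setdiff(.meta_cols, "sample_id")]
  if (any(!vapply(num, is.numeric, logical(1))) || anyNA(num))
    stop("metadata contains missing or non-numeric values; no imputation is done",
         call. = FALSE)
  if (any(df$recovery_ratio <= 0 | df$recovery_ratio > 1))
    stop("recovery_ratio must lie in (0, 1]", call. = FALSE)
  if (any(df$volume <= 0)) stop("volume must be positive", call. = FALSE)
  if (any(df$latitude < -90 | df$latitude > 90))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(df$longitude < -180 | df$longitude > 360))
    stop("longitude out of range", call. = FALSE)
  df$longitude <- ifelse(df$longitude > 180, df$longitude - 360,
                         df$longitude)
  df
}

#' @rdname sample_metadata
#' @param path file path.
#' @export
read_sample_metadata <- function(path) sample_metadata(.read_tsv(path))

#' @rdname sample_metadata
#' @param x metadata data.frame.
#' @param seed optional seed recorded in the header.
#' @export
write_sample_metadata <- function(x, path, seed = NULL) .write_tsv(x, path, seed)

#' Read a rooted phylogenetic tree (newick)
#'
#' Every edge must carry a branch length and tip labels must be unique.
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick: ", path, call. = FALSE)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree must have a branch length on every edge", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (!ape::is.rooted(tr)) stop("tree must be rooted", call. = FALSE)
  tr
}

#' Write a tree to newick
#' @param tree `phylo` object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Run configuration with the defaults used throughout the pipeline
#'
#' @param rarefaction_depth integer depth, or `"min"` to use the smallest
#'   sample total.
#' @param abundance_threshold overall relative-abundance cutoff for network
#'   inclusion (strict `>`).
#' @param corr_r_cutoff absolute Spearman r cutoff for network edges.
#' @param corr_alpha FDR-adjusted significance level.
#' @param n_permutations permutations for Monte-Carlo tests.
#' @param rng_seed integer seed recorded in every output header.
#' @param shannon_log_base logarithm base for the Shannon index.
#' @param distance_metric community distance; only `"bray-curtis"` is
#'   implemented.
#' @param mantel_method correlation method for Mantel tests.
#' @return classed list of settings.
#' @export
run_config <- function(rarefaction_depth = "min",
                       abundance_threshold = 0.001,
                       corr_r_cutoff = 0.6,
                       corr_alpha = 0.05,
                       n_permutations = 999L,
                       rng_seed = 1L,
                       shannon_log_base = 2,
                       distance_metric = "bray-curtis",
                       mantel_method = "spearman") {
  stopifnot(identical(rarefaction_depth, "min") ||
              (is.numeric(rarefaction_depth) && rarefaction_depth >= 1),
            abundance_threshold > 0, abundance_threshold < 1,
            corr_r_cutoff >= 0, corr_r_cutoff <= 1,
            corr_alpha > 0, corr_alpha < 1,
            n_permutations >= 1,
            shannon_log_base > 0, shannon_log_base != 1,
            distance_metric == "bray-curtis",
            mantel_method %in% c("spearman", "pearson"))
  structure(list(rarefaction_depth = rarefaction_depth,
                 abundance_threshold = abundance_threshold,
                 corr_r_cutoff = corr_r_cutoff,
                 corr_alpha = corr_alpha,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 shannon_log_base = shannon_log_base,
                 distance_metric = distance_metric,
                 mantel_method = mantel_method),
            class = "htqs_config")
}

#' Read a run configuration from YAML or JSON
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file
#'   whose keys match the arguments of [run_config()].
#' @return an `htqs_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}
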