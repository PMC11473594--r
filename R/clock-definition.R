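#' Construct a cluster-averaged linear clock definition
#'
#' A clock is a linear model over per-cluster mean methylation: correlated CpG
#' probes are collapsed into cluster averages, and the predicted age is
#' `intercept + sum_k weight_k * cluster_mean_k`. This is the form used by
#' cluster-averaged buccal clocks; the `form` tag is carried explicitly so that
#' other functional forms can be added later without ambiguity.
#'
#' @param probe_ids character vector of CpG identifiers (unique).
#' @param cluster_of character vector, same length as `probe_ids`, giving the
#'   cluster id of each probe.
#' @param cluster_weights named numeric vector of per-cluster weights; names
#'   are cluster ids and must cover exactly the clusters referenced by
#'   `cluster_of`.
#' @param intercept single finite numeric, in predicted-age units (years).
#' @param name clock name.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(probe_ids, cluster_of, cluster_weights,
                             intercept = 0, name = "unnamed_clock") {
  probe_ids <- as.character(probe_ids)
  cluster_of <- as.character(cluster_of)
  if (length(probe_ids) == 0L) stop("clock has no probes")
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids in clock definition: ",
         paste(unique(probe_ids[duplicated(probe_ids)])[1:min(3, sum(duplicated(probe_ids)))],
               collapse = ", "))
  }
  if (length(cluster_of) != length(probe_ids)) {
    stop("cluster_of must have one entry per probe")
  }
  if (anyNA(cluster_of) || any(cluster_of == "")) stop("missing cluster assignment")
  if (is.null(names(cluster_weights)) || anyDuplicated(names(cluster_weights))) {
    stop("cluster_weights must be uniquely named by cluster id")
  }
  cluster_weights <- vapply(cluster_weights, as.numeric, numeric(1))
  if (any(!is.finite(cluster_weights))) stop("non-finite cluster weight")
  if (!is.finite(intercept)) stop("non-finite intercept")
  used <- unique(cluster_of)
  unknown <- setdiff(used, names(cluster_weights))
  if (length(unknown)) {
    stop("probe mapped to unknown cluster: ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  empty <- setdiff(names(cluster_weights), used)
  if (length(empty)) {
    stop("cluster with no probes: ", paste(utils::head(empty, 3), collapse = ", "))
  }
  structure(
    list(name = as.character(name)[1],
         form = "linear_cluster_mean",
         intercept = as.numeric(intercept),
         probe_ids = probe_ids,
         cluster_of = stats::setNames(cluster_of, probe_ids),
         cluster_weights = cluster_weights),
    class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat("Cluster-averaged linear clock:", x$name, "\n")
  cat("  probes:   ", length(x$probe_ids), "\n")
  cat("  clusters: ", length(x$cluster_weights), "\n")
  cat("  intercept:", format(x$intercept), "\n")
  invisible(x)
}

#' Read a clock definition
#'
#' Two on-disk dialects are supported: a single JSON file holding
#' `{name, intercept, form, probes: {probe: cluster}, cluster_weights: {cluster: weight}}`,
#' or a TSV with header `probe_id<TAB>cluster_id` accompanied by a JSON sidecar
#' (same basename, extension `.json`) carrying
#' `{name, intercept, form, cluster_weights}`.
#'
#' @param path path to the `.json` clock file or the `.tsv` probe map.
#' @return A [clock_definition].
#' @export
read_clock_definition <- function(path) {
  if (!file.exists(path)) stop("clock file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(j$probes) || is.null(j$cluster_weights)) {
      stop("clock JSON must contain 'probes' and 'cluster_weights'")
    }
    check_clock_form(j$form)
    return(clock_definition(
      probe_ids = names(j$probes),
      cluster_of = unlist(j$probes, use.names = FALSE),
      cluster_weights = unlist(j$cluster_weights),
      intercept = if (is.null(j$intercept)) 0 else j$intercept,
      name = if (is.null(j$name)) "unnamed_clock" else j$name))
  }
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  if (!all(c("probe_id", "cluster_id") %in% names(map))) {
    stop("clock TSV needs columns probe_id, cluster_id")
  }
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(sidecar)) stop("clock JSON sidecar not found: ", sidecar)
  j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  check_clock_form(j$form)
  clock_definition(
    probe_ids = map$probe_id,
    cluster_of = map$cluster_id,
    cluster_weights = unlist(j$cluster_weights),
    intercept = if (is.null(j$intercept)) 0 else j$intercept,
    name = if (is.null(j$name)) "unnamed_clock" else j$name)
}

check_clock_form <- function(form) {
  if (!is.null(form) && !identical(form, "linear_cluster_mean")) {
    stop("unsupported clock form: ", form)
  }
  invisible(TRUE)
}

#' Write a clock definition as a single JSON file
#'
#' @param clock a [clock_definition].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_clock_definition <- function(clock, path) {
  stopifnot(inherits(clock, "clock_definition"))
  jsonlite::write_json(
    list(name = clock$name,
         form = clock$form,
         intercept = clock$intercept,
         probes = as.list(clock$cluster_of),
         cluster_weights = as.list(clock$cluster_weights)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
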