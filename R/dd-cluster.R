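#' Select the most discriminative movement features
#'
#' Top-n features by absolute coefficient of a fitted level-1 logistic
#' regression (canonically the T-cell vs B-cell task); the published
#' DD-cluster analysis uses the displacement and the standard deviation of
#' turning angles. `n = 2` is the default; `n = 8` is the figure-caption
#' variant.
#'
#' @param report Output of [coefficient_report()] (or a fitted level-1
#'   model).
#' @param n Number of features (default 2).
#' @return Character vector of feature names.
#' @export
select_features <- function(report, n = 2L) {
  if (inherits(report, "lm_model")) report <- coefficient_report(report)
  if (n > nrow(report)) {
    stop(sprintf("n = %d exceeds the number of features (%d)", n,
                 nrow(report)), call. = FALSE)
  }
  report$feature[seq_len(n)]
}

#' k-means DD-clustering of tracks into directed and undirected
#'
#' k-means (k = 2, multiple restarts, seed-deterministic) on the selected
#' standardized movement features. The cluster whose centre has the larger
#' net displacement is called "directed" (the labelling rule is applied post
#' hoc, so restarts can never flip the semantics). Per-phenotype cluster
#' compositions are reported.
#'
#' @param features Feature table ([track_feature_table()]); must contain the
#'   selected feature columns and (for compositions) a `phenotype` column.
#' @param selected Character vector of feature names (see
#'   [select_features()]); default `c("net_distance", "angle_std")`.
#' @param seed Seed.
#' @param n_init k-means restarts (>= 10).
#' @return `dd_cluster_result`: `cluster` (per track: "directed"/
#'   "undirected"), `centers` (in standardized feature space), `composition`
#'   (per phenotype proportions), `selected_features`.
#' @export
kmeans_dd <- function(features, selected = c("net_distance", "angle_std"),
                      seed = 1L, n_init = 10L) {
  stopifnot(all(selected %in% names(features)))
  if (nrow(features) < 2) stop("need at least 2 tracks", call. = FALSE)
  x <- scale(as.matrix(features[selected]))
  if (any(!is.finite(x))) {
    # constant column: scale() produced NaN
    stop("degenerate clustering: a selected feature is constant",
         call. = FALSE)
  }
  if (nrow(unique(x)) < 2) {
    stop("degenerate clustering: all feature vectors identical",
         call. = FALSE)
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2L, nstart = max(10L, n_init),
                      iter.max = 100L)
  # semantic labelling: higher net-displacement centre = directed
  disp_col <- if ("net_distance" %in% selected) "net_distance" else selected[1]
  directed_cluster <- which.max(km$centers[, disp_col])
  cluster <- ifelse(km$cluster == directed_cluster, "directed", "undirected")
  comp <- NULL
  if (!is.null(features$phenotype)) {
    tab <- table(features$phenotype, factor(cluster,
                                            c("undirected", "directed")))
    comp <- as.data.frame.matrix(prop.table(tab, 1))
    comp <- data.frame(phenotype = rownames(comp),
                       undirected = comp$undirected,
                       directed = comp$directed, row.names = NULL)
  }
  structure(list(cluster = cluster, centers = km$centers,
                 composition = comp, selected_features = selected,
                 track_id = features$track_id),
            class = "dd_cluster_result")
}

#' Per-phenotype DD-cluster composition table
#'
#' @param result A `dd_cluster_result`.
#' @param phenotypes Optional phenotype order; phenotypes with no tracks are
#'   omitted with a warning.
#' @param digits Rounding for the percentage columns.
#' @return `data.frame` `phenotype`, `undirected_pct`, `directed_pct`.
#' @export
composition_report <- function(result, phenotypes = NULL, digits = 1) {
  stopifnot(inherits(result, "dd_cluster_result"))
  comp <- result$composition
  if (is.null(comp)) stop("result carries no phenotype information",
                          call. = FALSE)
  if (!is.null(phenotypes)) {
    missing <- setdiff(phenotypes, comp$phenotype)
    if (length(missing)) {
      warning(sprintf("phenotype(s) with 0 tracks omitted: %s",
                      paste(missing, collapse = ", ")))
    }
    comp <- comp[comp$phenotype %in% phenotypes, ]
    comp <- comp[order(match(comp$phenotype, phenotypes)), ]
  }
  data.frame(phenotype = comp$phenotype,
             undirected_pct = round(100 * comp$undirected, digits),
             directed_pct = round(100 * comp$directed, digits),
             row.names = NULL)
}

#' Export tracks colored by DD-cluster
#'
#' Writes a simple SVG overlay of track polylines, full color for undirected
#' and pale color for directed tracks.
#'
#' @param result A `dd_cluster_result`.
#' @param tracks Track table (pixel coordinates).
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
export_cluster_tracks <- function(result, tracks, path) {
  cl <- setNames(result$cluster, result$track_id)
  lines <- c('<svg xmlns="http://www.w3.org/2000/svg">')
  for (d in split(tracks, tracks$track_id)) {
    d <- d[order(d$frame), ]
    cc <- cl[as.character(d$track_id[1])]
    if (is.na(cc)) next
    col <- if (cc == "directed") "#f4a6a6" else "#2e8b57"
    pts <- paste(sprintf("%.1f,%.1f", d$x_px %||% d$x, d$y_px %||% d$y),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '<polyline points="%s" fill="none" stroke="%s" stroke-width="1"/>',
      pts, col))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
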