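#' Fit the 2D manifold embedding on development features
#'
#' Learns a 2D UMAP representation of the normalized development feature
#' matrix and freezes the per-axis coordinate bounds of the fitted embedding,
#' so coordinates can be rescaled to the unit square. Patients close in
#' baseline clinical profile land close in the projection; survival structure
#' is then read off spatially by the zoning step.
#'
#' The fit is deterministic for a fixed seed, fixed inputs and fixed row
#' order (single-threaded optimisation); row permutation is not guaranteed
#' to reproduce coordinates.
#'
#' @param features Data frame or matrix of normalized features in `[0, 1]`
#'   (from [apply_normalizer()]); at least 50 rows.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param metric Distance metric (default `"euclidean"`).
#' @param seed Integer seed (default 42).
#' @return An object of class `als_embedding`: the fitted reducer, the
#'   embedding parameters, per-axis coordinate bounds, and the feature
#'   schema.
#' @export
fit_embedding <- function(features, n_neighbors = 15, min_dist = 0.1,
                          metric = "euclidean", seed = 42L) {
  x <- as.matrix(features)
  if (nrow(x) < 50)
    abort("At least 50 rows are required to fit the embedding; the neighbourhood graph is meaningless below that.")
  if (nrow(x) < n_neighbors)
    abort(sprintf(
      "n_neighbors = %d exceeds the number of rows (%d); use a smaller n_neighbors.",
      n_neighbors, nrow(x)))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort("Features must be finite and normalized to [0, 1].")
  set.seed(seed)
  model <- uwot::umap(
    x, n_components = 2, n_neighbors = n_neighbors, min_dist = min_dist,
    metric = metric, ret_model = TRUE, n_threads = 1, n_sgd_threads = 0
  )
  bounds <- apply(model$embedding, 2, range)
  structure(
    list(
      reducer = model,
      params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                    metric = metric, seed = as.integer(seed)),
      coordinate_bounds = bounds,
      feature_names = colnames(x),
      embedding = rescale_coords(model$embedding, bounds)
    ),
    class = "als_embedding"
  )
}

# Map raw embedding coordinates onto [0,1]^2 with the development bounds,
# clipping values that fall outside (validation points may exceed them).
rescale_coords <- function(coords, bounds) {
  out <- sweep(coords, 2, bounds[1, ], "-")
  out <- sweep(out, 2, bounds[2, ] - bounds[1, ], "/")
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- c("x", "y")
  tibble::as_tibble(out)
}

#' Project a cohort's features into a fitted embedding
#'
#' Transforms new normalized feature rows with the learnt UMAP mapping and
#' rescales the coordinates to the unit square using the development
#' coordinate bounds (clipped to `[0, 1]`).
#'
#' @param model An `als_embedding` from [fit_embedding()].
#' @param features Normalized feature data frame/matrix with the same columns
#'   as at fit time.
#' @return A tibble with columns `x`, `y` in `[0, 1]`.
#' @export
transform_cohort <- function(model, features) {
  stopifnot(inherits(model, "als_embedding"))
  x <- as.matrix(features)
  if (!identical(colnames(x), model$feature_names))
    abort(paste0(
      "Feature columns do not match the fitted embedding. Expected: ",
      paste(model$feature_names, collapse = ", ")))
  set.seed(model$params$seed)
  raw <- uwot::umap_transform(x, model$reducer, n_threads = 1,
                              n_sgd_threads = 0)
  rescale_coords(raw, model$coordinate_bounds)
}

#' @export
print.als_embedding <- function(x, ...) {
  cat("2D manifold embedding (UMAP)\n")
  cat(sprintf("  n = %d development patients, %d features\n",
              nrow(x$embedding), length(x$feature_names)))
  cat(sprintf("  n_neighbors = %d, min_dist = %g, metric = %s, seed = %d\n",
              x$params$n_neighbors, x$params$min_dist, x$params$metric,
              x$params$seed))
  invisible(x)
}

#' Persist a fitted embedding to a directory
#'
#' Writes the reducer state (implementation-native serialization) plus a
#' JSON sidecar carrying the parameters, coordinate bounds and feature
#' schema.
#'
#' @param model An `als_embedding`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_embedding <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reducer_path <- file.path(dir, "reducer.uwot")
  if (file.exists(reducer_path)) unlink(reducer_path)
  uwot::save_uwot(model$reducer, reducer_path)
  jsonlite::write_json(
    list(params = model$params,
         coordinate_bounds = model$coordinate_bounds,
         feature_names = model$feature_names),
    file.path(dir, "embedding.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(model$embedding, file.path(dir, "development_coords.csv"))
  invisible(dir)
}

#' Load a fitted embedding from a directory
#'
#' @param dir Directory written by [write_embedding()].
#' @return An `als_embedding`.
#' @export
read_embedding <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "embedding.json"),
                              simplifyVector = TRUE)
  structure(
    list(
      reducer = uwot::load_uwot(file.path(dir, "reducer.uwot")),
      params = meta$params,
      coordinate_bounds = matrix(meta$coordinate_bounds, nrow = 2),
      feature_names = meta$feature_names,
      embedding = tibble::as_tibble(
        readr::read_csv(file.path(dir, "development_coords.csv"),
                        col_types = "dd", progress = FALSE))
    ),
    class = "als_embedding"
  )
}
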