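#' Wald confidence width for a binomial survival rate
#'
#' Full width of the normal-approximation (Wald) confidence interval for a
#' binomial proportion:
#' \deqn{width = 2 z_{\alpha} \sqrt{P(1-P)/N}}
#' with \eqn{z_\alpha} the standard normal quantile at \eqn{1 - \alpha/2} and
#' \eqn{\alpha = 1 - confidence\_level}. The interval reported alongside a
#' prognosis is `[max(0, P - width/2), min(1, P + width/2)]`.
#'
#' @param p Observed proportion(s) in `[0, 1]`.
#' @param n Sample size(s), >= 1.
#' @param confidence_level Confidence level in (0, 1); default 0.95.
#' @return Width(s) on the probability scale.
#' @examples
#' ci_width(0.80, 1524)  # ~0.04: the intermediate-zone +/- 4%
#' @export
ci_width <- function(p, n, confidence_level = 0.95) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  if (any(n < 1)) abort("`n` must be >= 1; the width is undefined at N = 0.")
  if (confidence_level <= 0 || confidence_level >= 1)
    abort("`confidence_level` must lie in (0, 1).")
  alpha <- 1 - confidence_level
  2 * qnorm(1 - alpha / 2) * sqrt(p * (1 - p) / n)
}

#' Square-cell survival map of the projection space
#'
#' Divides the unit square into `1/cell_size` x `1/cell_size` cells and
#' computes the local 1-year survival rate and Wald width per cell. Cells
#' are half-open `[i s, (i+1) s)` on each axis with the last cell closed at
#' 1, so every patient lands in exactly one cell. Sparse cells carry wide
#' intervals; the map is diagnostic (it motivates the zone division) and is
#' never used for prognosis directly — empty cells have an undefined
#' (`NA`) rate, not 0.
#'
#' @param projected Tibble with columns `x`, `y` in `[0, 1]` and a logical
#'   `survived_12m` outcome for every row.
#' @param cell_size Side length of a cell; must divide `[0, 1]` into an
#'   integer grid (default 0.1).
#' @param confidence_level Confidence level for the Wald widths.
#' @return A tibble of class `als_cell_map`: one row per cell with
#'   `cell_x`, `cell_y` (0-based indices), `n`, `survivors`, `rate`,
#'   `width`.
#' @export
build_cell_map <- function(projected, cell_size = 0.1,
                           confidence_level = 0.95) {
  m <- 1 / cell_size
  if (abs(m - round(m)) > 1e-8)
    abort("`cell_size` must divide [0, 1] into an integer number of cells.")
  m <- as.integer(round(m))
  check_projected_outcomes(projected)
  idx <- function(v) pmin(floor(v / cell_size), m - 1L)
  counts <- tibble::tibble(
    cell_x = idx(projected$x),
    cell_y = idx(projected$y),
    survived = projected$survived_12m
  ) |>
    dplyr::group_by(.data$cell_x, .data$cell_y) |>
    dplyr::summarise(n = dplyr::n(), survivors = sum(.data$survived),
                     .groups = "drop")
  grid <- tidyr::expand_grid(cell_x = 0:(m - 1L), cell_y = 0:(m - 1L))
  map <- dplyr::left_join(grid, counts, by = c("cell_x", "cell_y")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      survivors = dplyr::coalesce(.data$survivors, 0L),
      rate = ifelse(.data$n > 0, .data$survivors / .data$n, NA_real_),
      width = ifelse(.data$n > 0,
                     ci_width(ifelse(.data$n > 0, .data$survivors / .data$n, 0),
                              pmax(.data$n, 1), confidence_level),
                     NA_real_)
    )
  structure(map, class = c("als_cell_map", class(map)),
            cell_size = cell_size, confidence_level = confidence_level)
}

check_projected_outcomes <- function(projected, call = rlang::caller_env()) {
  if (!all(c("x", "y") %in% names(projected)))
    abort("`projected` must have columns `x` and `y`.", call = call)
  if (any(projected$x < 0 | projected$x > 1 |
          projected$y < 0 | projected$y > 1, na.rm = TRUE))
    abort("Projected coordinates must lie in the unit square.", call = call)
  if (!"survived_12m" %in% names(projected) ||
      any(is.na(projected$survived_12m)))
    abort("`survived_12m` must be known for every projected patient; filter unknown outcomes first.",
          call = call)
  invisible(projected)
}

#' Segment the projection into equally populated survival-rate zones
#'
#' Divides the projection space along one axis into `k` zones of equal
#' population (sizes differing by at most 1), each carrying its empirical
#' 1-year survival rate and Wald confidence width. Cut points are empirical
#' quantiles of the axis coordinate at ranks `ceiling(j * n / k)`
#' (nearest-rank method); ties in coordinates are broken by stable input
#' order. Zones are ordered along the axis from 0 to 1.
#'
#' @inheritParams build_cell_map
#' @param axis `"y"` (default, the vertical axis) or `"x"`.
#' @param k Number of zones (>= 2), default 3.
#' @return An object of class `als_zones` with the axis, cut points,
#'   per-zone counts/rates/widths, the confidence level and membership of
#'   the development points.
#' @export
fit_zones <- function(projected, axis = c("y", "x"), k = 3,
                      confidence_level = 0.95) {
  axis <- match.arg(axis)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2.")
  check_projected_outcomes(projected)
  n <- nrow(projected)
  if (n < k)
    abort(sprintf("Cannot form %d zones from %d patients.", k, n))
  coord <- projected[[axis]]
  ord <- order(coord)  # stable: ties keep input order
  upper_ranks <- ceiling(seq_len(k) * n / k)
  lower_ranks <- c(0L, upper_ranks[-k])
  membership <- integer(n)
  zones <- purrr::map_dfr(seq_len(k), function(j) {
    rows <- ord[(lower_ranks[j] + 1L):upper_ranks[j]]
    membership[rows] <<- j
    s <- sum(projected$survived_12m[rows])
    m <- length(rows)
    tibble::tibble(
      zone = j, label = paste0("zone_", j), n = m, survivors = s,
      rate = s / m, width = ci_width(s / m, m, confidence_level)
    )
  })
  cuts <- sort(coord)[upper_ranks[-k]]
  structure(
    list(axis = axis, k = k, cuts = cuts, zones = zones,
         confidence_level = confidence_level,
         z_alpha = qnorm(1 - (1 - confidence_level) / 2),
         n = n, survivors = sum(projected$survived_12m),
         membership = membership),
    class = "als_zones"
  )
}

#' Assign a projected point to a survival zone (prognosis)
#'
#' Zone membership uses half-open intervals `[cut_j, cut_{j+1})` on the
#' model's axis, with the first interval closed at 0 and the last closed
#' at 1, so assignment is total and deterministic. The prognosis is the
#' zone's empirical survival rate with its Wald interval.
#'
#' @param model An `als_zones` from [fit_zones()].
#' @param x,y Coordinates in `[0, 1]` (vectors of equal length).
#' @return A tibble with one row per point: `zone`, `label`, `rate`,
#'   `width`, `lower`, `upper`.
#' @export
assign_zone <- function(model, x, y) {
  stopifnot(inherits(model, "als_zones"))
  if (any(x < 0 | x > 1 | y < 0 | y > 1))
    abort("Coordinates must lie in the unit square.")
  coord <- if (model$axis == "y") y else x
  zone <- findInterval(coord, model$cuts) + 1L
  tibble::tibble(
    x = x, y = y, zone = zone,
    label = model$zones$label[zone],
    rate = model$zones$rate[zone],
    width = model$zones$width[zone],
    lower = pmax(0, .data$rate - .data$width / 2),
    upper = pmin(1, .data$rate + .data$width / 2)
  )
}

#' @export
print.als_zones <- function(x, ...) {
  cat(sprintf(
    "Survival-rate zone model: %d equally populated zones along the %s axis\n",
    x$k, x$axis))
  cat(sprintf("  development n = %d (%d survivors), %.0f%% confidence\n",
              x$n, x$survivors, 100 * x$confidence_level))
  cat("  cuts:", paste(sprintf("%.4f", x$cuts), collapse = ", "), "\n")
  print(x$zones)
  invisible(x)
}

#' Tidy a zone model
#'
#' @param x An `als_zones`.
#' @param ... Unused.
#' @return The per-zone tibble (`zone`, `label`, `n`, `survivors`, `rate`,
#'   `width`) with the interval bounds added.
#' @method tidy als_zones
#' @export
tidy.als_zones <- function(x, ...) {
  dplyr::mutate(
    x$zones,
    lower = pmax(0, .data$rate - .data$width / 2),
    upper = pmin(1, .data$rate + .data$width / 2)
  )
}

#' One-row summary of a zone model
#'
#' @param x An `als_zones`.
#' @param ... Unused.
#' @return A tibble with the overall sample size, survivors, survival rate
#'   and its Wald width.
#' @method glance als_zones
#' @export
glance.als_zones <- function(x, ...) {
  tibble::tibble(
    n = x$n, survivors = x$survivors, rate = x$survivors / x$n,
    width = ci_width(x$survivors / x$n, x$n, x$confidence_level),
    k = x$k, axis = x$axis, confidence_level = x$confidence_level
  )
}

#' Serialize a zone model to JSON
#'
#' @param model An `als_zones`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_zones <- function(model, path) {
  jsonlite::write_json(
    list(axis = model$axis, k = model$k, cuts = model$cuts,
         zones = model$zones, confidence_level = model$confidence_level,
         z_alpha = model$z_alpha, n = model$n, survivors = model$survivors),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a zone model from JSON
#'
#' @param path JSON file written by [write_zones()].
#' @return An `als_zones` (without development membership).
#' @export
read_zones <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(axis = raw$axis, k = raw$k, cuts = raw$cuts,
         zones = tibble::as_tibble(raw$zones),
         confidence_level = raw$confidence_level, z_alpha = raw$z_alpha,
         n = raw$n, survivors = raw$survivors, membership = NULL),
    class = "als_zones"
  )
}
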