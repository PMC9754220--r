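# Sectorization: averaging fovea-centered thickness maps over the whole
# macula, the ETDRS grid, and the 20x20 fine square grid.

#' Whole-macula mean thickness
#'
#' Unweighted mean over grid nodes within `radius` mm of the foveal center
#' (non-missing values only).
#'
#' @param map a [interpolate_map()] thickness map.
#' @param radius disc radius (mm), default 3.
#' @param mask optional logical matrix (same shape as the map) restricting
#'   the computation to a node subset.
#' @return mean thickness (um).
#' @export
whole_macula_mean <- function(map, radius = 3, mask = NULL) {
  g <- map$grid$nodes
  r2 <- outer(g^2, g^2, "+")
  use <- r2 <= radius^2 & !is.na(map$values)
  if (!is.null(mask)) use <- use & mask
  if (!any(use)) stop("no usable nodes within ", radius, " mm")
  mean(map$values[use])
}

# Node-level ETDRS sector assignment for a grid: returns a character matrix
# of sector ids (NA outside the 3 mm circle). Rings: central disc r <= 0.5,
# inner 0.5 < r <= 1.5, outer 1.5 < r <= 3 (the nominal 6 mm diameter outer
# ring is clipped to the analyzed 3 mm radius disc). Quadrants split by the
# +/-45 degree diagonals with half-open angular wedges: nasal
# [-45, 45), superior [45, 135), temporal [135, 225), inferior [225, 315),
# so boundary nodes are assigned deterministically; nodes exactly on a ring
# circle go to the inner ring (<=).
etdrs_sector_ids <- function(grid) {
  g <- grid$nodes
  x <- matrix(g, grid$n_nodes, grid$n_nodes)
  y <- matrix(g, grid$n_nodes, grid$n_nodes, byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) * 180 / pi  # 0 = nasal (+x), CCW
  quad <- character(length(ang))
  a <- (ang + 45) %% 360        # [0,90): nasal, [90,180): superior, ...
  quad[a < 90] <- "N"
  quad[a >= 90 & a < 180] <- "S"
  quad[a >= 180 & a < 270] <- "T"
  quad[a >= 270] <- "I"
  ring <- ifelse(r <= 0.5, 0L, ifelse(r <= 1.5, 1L, ifelse(r <= 3, 2L, NA)))
  id <- ifelse(ring == 0L, "C0", paste0(quad, ring))
  id[is.na(ring)] <- NA_character_
  matrix(id, grid$n_nodes, grid$n_nodes)
}

ETDRS_SECTORS <- c("C0", "N1", "S1", "T1", "I1", "N2", "S2", "T2", "I2")

#' ETDRS sector means
#'
#' Averages a thickness map over the nine ETDRS sectors: a central disc of
#' 1 mm diameter, and inner (1-3 mm diameter) and outer (3-6 mm diameter)
#' rings split into nasal/superior/temporal/inferior quadrants by the
#' +/-45 degree diagonals. Outer-ring sectors only use nodes inside the
#' analyzed 3 mm radius circle. Empty sectors are flagged, not fatal.
#'
#' @param map a thickness map.
#' @return data.frame with columns `scheme`, `sector_id`, `layer`,
#'   `mean_um`, `n_nodes`, `excluded`, `reason`.
#' @export
etdrs_means <- function(map) {
  ids <- etdrs_sector_ids(map$grid)
  ids[is.na(map$values)] <- NA_character_
  out <- lapply(ETDRS_SECTORS, function(s) {
    use <- !is.na(ids) & ids == s
    n <- sum(use)
    data.frame(scheme = "etdrs", sector_id = s, layer = map$layer,
               mean_um = if (n) mean(map$values[use]) else NA_real_,
               n_nodes = n, excluded = n == 0L,
               reason = if (n == 0L) "empty" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Node-to-cell assignment for the 20x20 grid
#'
#' Pure geometry: assigns every grid node to one of the 400 cells of the
#' 6 x 6 mm, 0.3 mm square-cell sectorization, and flags which cells are
#' retained. A cell is retained when its center lies inside the 3 mm
#' fovea-centered circle (316 cells); for the inner layers (RNFL, GCIPL,
#' INL) the 4 x 4 centermost cells (centers with |x|, |y| < 0.6 mm) are
#' additionally excluded (300 cells). Cell ids are `g<row>_<col>` with
#' row 0 most superior (largest y) and column 0 most temporal (most
#' negative x in the right-eye frame); nodes on a cell's lower/left edge
#' belong to it.
#'
#' @param grid a [grid_spec()].
#' @param inner_exclusion apply the central 1.2 x 1.2 mm exclusion.
#' @return list with `cell_id` (character matrix over nodes) and `cells`
#'   (data.frame: `sector_id`, `cx`, `cy`, `retained`, `reason`).
#' @export
grid20_cells <- function(grid, inner_exclusion = FALSE) {
  g <- grid$nodes
  col_of <- pmin(pmax(floor((g + 3) / 0.3), 0), 19)       # x index
  row_of <- pmin(pmax(floor((3 - g) / 0.3), 0), 19)       # y index, row 0 top
  # node exactly at y = +3 belongs to row 0; at x = +3 to col 19
  cx <- -3 + 0.15 + 0.3 * (0:19)
  cy <- 3 - 0.15 - 0.3 * (0:19)
  cells <- expand.grid(row = 0:19, col = 0:19)
  cells$sector_id <- sprintf("g%d_%d", cells$row, cells$col)
  cells$cx <- cx[cells$col + 1L]
  cells$cy <- cy[cells$row + 1L]
  inside <- cells$cx^2 + cells$cy^2 <= 9
  central <- abs(cells$cx) < 0.6 & abs(cells$cy) < 0.6
  cells$retained <- inside & (!inner_exclusion | !central)
  cells$reason <- ifelse(!inside, "outside_3mm_circle",
                         ifelse(inner_exclusion & central,
                                "central_exclusion", ""))
  id <- outer(col_of, row_of,
              function(i, j) sprintf("g%d_%d", j, i))
  list(cell_id = id, cells = cells)
}

#' 20x20 grid sector means
#'
#' Mean thickness of each retained 0.3 mm cell (see [grid20_cells()]);
#' the central 1.2 x 1.2 mm exclusion is applied automatically for the
#' inner layers (RNFL, GCIPL, INL), whose central thickness is near zero.
#'
#' @param map a thickness map.
#' @return data.frame in the same format as [etdrs_means()], one row per
#'   cell (excluded cells carry `excluded = TRUE` and an `NA` mean).
#' @export
grid20_means <- function(map) {
  inner <- map$layer %in% c("RNFL", "GCIPL", "INL")
  gc <- grid20_cells(map$grid, inner_exclusion = inner)
  v <- as.vector(map$values)
  id <- as.vector(gc$cell_id)
  ok <- !is.na(v)
  sums <- tapply(v[ok], id[ok], sum)
  ns <- tapply(v[ok], id[ok], length)
  cells <- gc$cells
  n <- as.integer(ns[cells$sector_id])
  n[is.na(n)] <- 0L
  m <- as.numeric(sums[cells$sector_id]) / n
  keep <- cells$retained & n > 0L
  data.frame(
    scheme = "grid20", sector_id = cells$sector_id, layer = map$layer,
    mean_um = ifelse(keep, m, NA_real_),
    n_nodes = ifelse(cells$retained, n, 0L),
    excluded = !keep,
    reason = ifelse(cells$retained,
                    ifelse(n > 0L, "", "empty"), cells$reason),
    stringsAsFactors = FALSE
  )
}

#' Sector summary table for a set of layer maps
#'
#' Convenience wrapper producing a tidy table over schemes and layers,
#' ready for [write_sector_table()].
#'
#' @param maps named list of thickness maps (names are layers).
#' @param schemes subset of `c("whole", "etdrs", "grid20")`.
#' @return data.frame of sector summaries.
#' @export
sector_table <- function(maps, schemes = c("whole", "etdrs", "grid20")) {
  out <- list()
  for (map in maps) {
    if ("whole" %in% schemes) {
      out[[length(out) + 1L]] <- data.frame(
        scheme = "whole", sector_id = "ALL", layer = map$layer,
        mean_um = whole_macula_mean(map), n_nodes = NA_integer_,
        excluded = FALSE, reason = "", stringsAsFactors = FALSE)
    }
    if ("etdrs" %in% schemes) out[[length(out) + 1L]] <- etdrs_means(map)
    if ("grid20" %in% schemes) out[[length(out) + 1L]] <- grid20_means(map)
  }
  do.call(rbind, out)
}
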