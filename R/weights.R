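#' Spatial weights over areal units
#'
#' A `spatial_weights` object stores, for an ordered unit universe, each
#' unit's neighbor list and the matching weights, plus the standardization
#' state. Binary symmetric contiguity is the canonical input of both
#' Moran's I and Gi*; [row_standardize()] converts to row-stochastic form.
#'
#' @param unit_ids ordered character vector of unit identifiers.
#' @param neighbors list (same length) of character vectors of neighbor
#'   ids. Must be symmetric for binary input.
#' @param weights optional list of numeric weight vectors aligned with
#'   `neighbors`; default all 1 (binary).
#' @param standardization `"binary"` or `"row"`.
#' @param include_self logical; `TRUE` only for self-inclusive schemes
#'   (Gi* builds this internally).
#' @param check_symmetry validate symmetric neighbor structure (default
#'   `TRUE` for binary input).
#' @return a `spatial_weights` object.
#' @export
spatial_weights <- function(unit_ids, neighbors, weights = NULL,
                            standardization = c("binary", "row"),
                            include_self = FALSE,
                            check_symmetry = TRUE) {
  standardization <- match.arg(standardization)
  unit_ids <- as.character(unit_ids)
  assert_that(!anyDuplicated(unit_ids), "duplicate unit ids")
  assert_that(length(neighbors) == length(unit_ids),
              "one neighbor vector per unit required")
  names(neighbors) <- unit_ids
  neighbors <- lapply(neighbors, as.character)
  unknown <- setdiff(unique(unlist(neighbors)), unit_ids)
  assert_that(length(unknown) == 0,
              paste("neighbors reference unknown units:",
                    paste(unknown, collapse = ", ")))
  if (!include_self)
    for (u in unit_ids)
      assert_that(!(u %in% neighbors[[u]]),
                  sprintf("unit '%s' is its own neighbor", u))
  if (is.null(weights))
    weights <- lapply(neighbors, function(nb) rep(1, length(nb)))
  names(weights) <- unit_ids
  assert_that(all(lengths(weights) == lengths(neighbors)),
              "weights not aligned with neighbors")
  if (check_symmetry && standardization == "binary") {
    bad <- character()
    for (u in unit_ids)
      for (v in neighbors[[u]])
        if (!(u %in% neighbors[[v]]))
          bad <- c(bad, sprintf("%s->%s", u, v))
    assert_that(length(bad) == 0,
                paste("asymmetric neighbor pairs:",
                      paste(bad, collapse = ", ")))
  }
  islands <- unit_ids[lengths(neighbors) == 0]
  if (length(islands))
    warning("island units (no neighbors): ",
            paste(islands, collapse = ", "), call. = FALSE)
  structure(list(unit_ids = unit_ids, neighbors = neighbors,
                 weights = weights, standardization = standardization,
                 include_self = include_self),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, %d links, %s-standardized\n",
              length(x$unit_ids), sum(lengths(x$neighbors)),
              x$standardization))
  invisible(x)
}

#' Row-standardize spatial weights
#'
#' Rescales each unit's weights to sum to one. Islands keep an empty row
#' (with a warning); applying the operation twice is a no-op.
#'
#' @param W a [spatial_weights] object.
#' @return a row-standardized [spatial_weights].
#' @export
row_standardize <- function(W) {
  wts <- lapply(W$weights, function(w) {
    s <- sum(w)
    if (s > 0) w / s else w
  })
  islands <- W$unit_ids[lengths(W$neighbors) == 0]
  if (length(islands))
    warning("row_standardize: island rows left empty: ",
            paste(islands, collapse = ", "), call. = FALSE)
  out <- W
  out$weights <- wts
  out$standardization <- "row"
  out
}

#' Dense weight matrix (units x units) from a spatial_weights object
#' @param W a [spatial_weights] object.
#' @return numeric matrix with unit ids as dimnames.
#' @export
weights_matrix <- function(W) {
  n <- length(W$unit_ids)
  M <- matrix(0, n, n, dimnames = list(W$unit_ids, W$unit_ids))
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]
    if (length(nb)) M[i, nb] <- W$weights[[i]]
  }
  M
}

#' Read a GAL-format neighbor list
#'
#' Plain-text areal-weights format: a header line whose last numeric token
#' is the unit count, then per unit a line `id degree` followed by a line
#' of neighbor ids. The structure must be symmetric; islands are retained
#' with a warning.
#'
#' @param path path to the GAL file.
#' @return binary symmetric [spatial_weights].
#' @export
read_gal <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  head_tok <- strsplit(lines[1], "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head_tok[length(head_tok)]))
  if (is.na(n)) n <- suppressWarnings(as.integer(head_tok[1]))
  assert_that(!is.na(n) && n >= 1, "cannot parse GAL header line")
  ids <- character(n); nbrs <- vector("list", n)
  cur <- 2L
  for (i in seq_len(n)) {
    tok <- strsplit(lines[cur], "\\s+")[[1]]
    assert_that(length(tok) >= 2, sprintf("malformed GAL entry at line %d", cur))
    ids[i] <- tok[1]
    deg <- as.integer(tok[2])
    if (deg > 0) {
      nbrs[[i]] <- strsplit(lines[cur + 1L], "\\s+")[[1]]
      assert_that(length(nbrs[[i]]) == deg,
                  sprintf("unit '%s': declared degree %d but %d neighbors listed",
                          ids[i], deg, length(nbrs[[i]])))
      cur <- cur + 2L
    } else {
      nbrs[[i]] <- character()
      cur <- cur + 1L
    }
  }
  spatial_weights(ids, nbrs)
}

#' Write spatial weights as a GAL file
#' @param W a [spatial_weights] object (binary).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(W, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(length(W$unit_ids)), con)
  for (u in W$unit_ids) {
    nb <- W$neighbors[[u]]
    writeLines(sprintf("%s %d", u, length(nb)), con)
    if (length(nb)) writeLines(paste(nb, collapse = " "), con)
  }
  invisible(path)
}

# ---- polygon contiguity -----------------------------------------------

# canonical string key for a vertex, snapping to a tolerance grid
vertex_keys <- function(coords, digits = 8) {
  apply(round(coords, digits), 1, paste, collapse = ",")
}

# extract rings (matrices of x,y) from a GeoJSON geometry list
geojson_rings <- function(geom) {
  gtype <- geom$type
  pull_ring <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt)[1:2])))
  }
  if (identical(gtype, "Polygon")) {
    lapply(geom$coordinates, pull_ring)
  } else if (identical(gtype, "MultiPolygon")) {
    unlist(lapply(geom$coordinates,
                  function(poly) lapply(poly, pull_ring)),
           recursive = FALSE)
  } else {
    stop("unsupported geometry type: ", gtype, call. = FALSE)
  }
}

#' Contiguity weights from GeoJSON polygons
#'
#' Derives binary contiguity from a FeatureCollection of (Multi)Polygons.
#' Queen contiguity links polygons sharing at least one boundary vertex;
#' rook contiguity requires a shared edge (two consecutive vertices).
#' Vertices are snapped to `digits` decimals before comparison.
#'
#' @param path path to a GeoJSON FeatureCollection.
#' @param id_property feature property holding the unit id.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param digits coordinate snap precision.
#' @return binary symmetric [spatial_weights].
#' @export
read_geojson_weights <- function(path, id_property = "id",
                                 scheme = c("queen", "rook"),
                                 digits = 8) {
  scheme <- match.arg(scheme)
  gj <- jsonlite::read_json(path)
  assert_that(identical(gj$type, "FeatureCollection"),
              "expected a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_property]]
    assert_that(!is.null(v),
                paste("feature missing id property", id_property))
    as.character(v)
  }, character(1))
  assert_that(!anyDuplicated(ids), "duplicate feature ids")
  n <- length(ids)
  verts <- vector("list", n); edges <- vector("list", n)
  for (i in seq_len(n)) {
    rings <- geojson_rings(feats[[i]]$geometry)
    vk <- unlist(lapply(rings, vertex_keys, digits = digits))
    verts[[i]] <- unique(vk)
    ek <- unlist(lapply(rings, function(r) {
      k <- vertex_keys(r, digits)
      if (length(k) < 2) return(character())
      a <- k[-length(k)]; b <- k[-1]
      # undirected edge key: order endpoints lexicographically
      paste(pmin(a, b), pmax(a, b), sep = "|")
    }))
    edges[[i]] <- unique(ek)
  }
  nbrs <- lapply(seq_len(n), function(i) {
    hit <- vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      if (scheme == "queen") length(intersect(verts[[i]], verts[[j]])) > 0
      else length(intersect(edges[[i]], edges[[j]])) > 0
    }, logical(1))
    ids[hit]
  })
  spatial_weights(ids, nbrs)
}

#' Read spatial weights from GAL or GeoJSON
#'
#' Dispatches on the file extension: `.gal` files go through [read_gal()],
#' `.geojson`/`.json` through [read_geojson_weights()].
#'
#' @param path input file.
#' @param ... passed to the format-specific reader.
#' @return a [spatial_weights] object.
#' @export
read_weights <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gal") read_gal(path)
  else if (ext %in% c("geojson", "json")) read_geojson_weights(path, ...)
  else stop("unrecognized weights format: ", path, call. = FALSE)
}
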