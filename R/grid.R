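#' The nine ETDRS macular grid sectors
#'
#' The Early Treatment Diabetic Retinopathy Study grid partitions a 6 mm
#' macular field into a central 1 mm disc (`C`), an inner 1--3 mm ring and an
#' outer 3--6 mm ring, each ring split into superior, nasal, inferior and
#' temporal quadrants. This fixed order (`C, IS, IN, II, IT, OS, ON, OI, OT`)
#' is used for all serialization in the package.
#'
#' @return Character vector of the nine sector labels in canonical order.
#' @export
#' @examples
#' etdrs_sectors()
etdrs_sectors <- function() {
  c("C", "IS", "IN", "II", "IT", "OS", "ON", "OI", "OT")
}

#' Ring membership of an ETDRS sector
#'
#' @param sector Character vector of sector labels.
#' @return Character vector: `"center"`, `"inner"` or `"outer"`.
#' @export
#' @examples
#' sector_ring(c("C", "IS", "OT"))
sector_ring <- function(sector) {
  stopifnot(all(sector %in% etdrs_sectors()))
  dplyr::case_when(
    sector == "C" ~ "center",
    startsWith(sector, "I") ~ "inner",
    TRUE ~ "outer"
  )
}

#' Default contiguity graph of the ETDRS grid
#'
#' Two sectors are contiguous when they share a boundary arc on the printed
#' grid: the central disc touches all four inner quadrants, each ring is a
#' 4-cycle, and matching inner/outer quadrants are radially adjacent. The
#' result is an undirected graph with 16 edges in which every sector has
#' degree at least 2. Alternative conventions can be supplied to the
#' rule functions as an edge tibble of the same shape.
#'
#' @return A tibble with columns `from` and `to`, one row per undirected edge.
#' @export
#' @examples
#' etdrs_adjacency()
etdrs_adjacency <- function() {
  tibble::tribble(
    ~from, ~to,
    "C", "IS", "C", "IN", "C", "II", "C", "IT",
    "IS", "IN", "IN", "II", "II", "IT", "IT", "IS",
    "IS", "OS", "IN", "ON", "II", "OI", "IT", "OT",
    "OS", "ON", "ON", "OI", "OI", "OT", "OT", "OS"
  )
}

# igraph object from an edge tibble; vertices always all nine sectors
as_sector_graph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  bad <- setdiff(unique(c(edges$from, edges$to)), etdrs_sectors())
  if (length(bad) > 0) {
    stop("unknown sector label(s) in adjacency: ", paste(bad, collapse = ", "))
  }
  igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = etdrs_sectors())
  )
}

#' Neighbours of a sector under a contiguity convention
#'
#' @param sector A single sector label.
#' @param edges Edge tibble, by default [etdrs_adjacency()].
#' @return Character vector of adjacent sector labels.
#' @export
#' @examples
#' etdrs_neighbors("C")
#' etdrs_neighbors("OS")
etdrs_neighbors <- function(sector, edges = etdrs_adjacency()) {
  stopifnot(length(sector) == 1, sector %in% etdrs_sectors())
  with(edges, sort(c(to[from == sector], from[to == sector])))
}

#' Connected components of a marked sector set
#'
#' Partitions a subset of the nine grid sectors into maximal connected
#' subsets under the contiguity graph. The content of the partition is
#' order-independent; components are returned largest first.
#'
#' @param marked Character vector, a subset of [etdrs_sectors()].
#' @param edges Edge tibble, by default [etdrs_adjacency()].
#' @return A list of character vectors, one per component (empty list for an
#'   empty marked set).
#' @export
#' @examples
#' sector_components(c("OS", "ON", "OI"))
#' sector_components(c("OS", "OI")) # not adjacent: two singletons
sector_components <- function(marked, edges = etdrs_adjacency()) {
  marked <- unique(as.character(marked))
  stopifnot(all(marked %in% etdrs_sectors()))
  if (length(marked) == 0) {
    return(list())
  }
  g <- igraph::induced_subgraph(as_sector_graph(edges), marked)
  comp <- igraph::components(g)
  out <- split(names(comp$membership), comp$membership)
  out <- lapply(unname(out), sort)
  out[order(-lengths(out))]
}

#' Largest directional connected component of supra-threshold differences
#'
#' Finds the size of the largest contiguous set of sectors whose signed
#' interval differences all exceed the threshold in the stated direction
#' (`"+"`: difference >= +threshold; `"-"`: difference <= -threshold).
#' Differences are rounded to 0.01 um before the inclusive comparison, so a
#' difference of exactly the threshold qualifies and floating-point ties at
#' the boundary are unambiguous.
#'
#' @param diffs Named numeric vector over all nine sectors, um.
#' @param threshold Positive threshold, um.
#' @param direction `"+"` (thickening) or `"-"` (thinning).
#' @param edges Edge tibble, by default [etdrs_adjacency()].
#' @return Integer component size (0 when no sector qualifies).
#' @export
#' @examples
#' d <- stats::setNames(rep(0, 9), etdrs_sectors())
#' d[c("OS", "ON", "OI")] <- 4
#' largest_directional_component(d, 4, "+")
largest_directional_component <- function(diffs, threshold, direction = c("+", "-"),
                                          edges = etdrs_adjacency()) {
  direction <- match.arg(direction)
  diffs <- complete_sector_vector(diffs)
  if (any(!is.finite(diffs))) {
    stop("non-finite sector difference")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  d <- round(diffs, 2)
  marked <- if (direction == "+") {
    names(d)[d >= threshold]
  } else {
    names(d)[d <= -threshold]
  }
  comps <- sector_components(marked, edges)
  if (length(comps) == 0) 0L else max(lengths(comps))
}

# Coerce to a complete named numeric vector over the nine sectors, canonical
# order; errors on missing or extra sectors.
complete_sector_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[intersect(names(x), etdrs_sectors())])
  }
  if (is.null(names(x)) && length(x) == 9) {
    names(x) <- etdrs_sectors()
  }
  missing <- setdiff(etdrs_sectors(), names(x))
  if (length(missing) > 0) {
    stop("missing sector value(s): ", paste(missing, collapse = ", "))
  }
  out <- as.numeric(x[etdrs_sectors()])
  names(out) <- etdrs_sectors()
  out
}
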