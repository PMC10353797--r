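#' Region adjacency graph for administrative divisions
#'
#' A `region_graph` stores the division labels, the symmetric irreflexive
#' adjacency (regions sharing a common boundary are neighbours), and the
#' neighbour count of every region.  It is the support of the intrinsic
#' Gaussian Markov random field prior used for structured spatial effects.
#'
#' @param regions character vector of region labels (order is preserved and
#'   defines the row/column order of precision matrices built from the graph).
#' @param edges two-column character matrix or data frame of undirected edges.
#'   Duplicate edges (in either orientation) are collapsed to a single
#'   undirected edge.
#' @return An object of class `region_graph` with components `regions`,
#'   `edges` (deduplicated, lexicographically oriented), `neighbors` (named
#'   list of character vectors) and `neighbor_counts` (named integer vector).
#' @examples
#' g <- region_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' g$neighbor_counts
#' @export
region_graph <- function(regions, edges) {
  regions <- as.character(regions)
  if (anyDuplicated(regions)) {
    stop("duplicate region labels: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  unknown <- setdiff(c(edges), regions)
  if (length(unknown)) {
    stop("edge references undeclared region(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loop edge not allowed: ",
         paste(edges[edges[, 1L] == edges[, 2L], 1L], collapse = ", "))
  }
  # orient each undirected edge lexicographically, then dedupe
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, 2L:1L]
  edges <- unique(edges)
  dimnames(edges) <- list(NULL, c("from", "to"))

  neighbors <- lapply(regions, function(r) {
    sort(unique(c(edges[edges[, 1L] == r, 2L], edges[edges[, 2L] == r, 1L])))
  })
  names(neighbors) <- regions
  counts <- vapply(neighbors, length, integer(1))
  if (any(counts == 0L) && nrow(edges) > 0L) {
    warning("region(s) with no neighbours: ",
            paste(regions[counts == 0L], collapse = ", "))
  }
  structure(
    list(regions = regions, edges = edges, neighbors = neighbors,
         neighbor_counts = counts),
    class = "region_graph"
  )
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$regions), "regions,",
      nrow(x$edges), "edges\n")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}

#' Preset division graphs
#'
#' Builds one of the bundled region graphs:
#' \describe{
#'   \item{`"bdhs2014"`}{the 7 pre-2015 divisions of Bangladesh (Mymensingh
#'     still part of Dhaka) with an approximate shared-boundary adjacency.}
#'   \item{`"bdhs2018"`}{the 8 post-2015 divisions (Mymensingh separated
#'     from Dhaka), approximate adjacency.}
#'   \item{`"lattice2x2"`}{a 2 x 2 rook-adjacency toy lattice, handy for
#'     tests and examples.}
#' }
#' The two division presets are deliberate approximations for simulation and
#' testing: they capture the neighbour structure of the divisions at each
#' survey round, not surveyed boundary files.
#'
#' @param preset one of `"bdhs2014"`, `"bdhs2018"`, `"lattice2x2"`.
#' @return A [region_graph].
#' @examples
#' make_region_graph("lattice2x2")$neighbor_counts
#' @export
make_region_graph <- function(preset = c("bdhs2018", "bdhs2014", "lattice2x2")) {
  preset <- match.arg(preset)
  if (preset == "bdhs2014") {
    regions <- c("Barisal", "Chittagong", "Dhaka", "Khulna",
                 "Rajshahi", "Rangpur", "Sylhet")
    edges <- rbind(
      c("Barisal", "Chittagong"), c("Barisal", "Dhaka"),
      c("Barisal", "Khulna"), c("Chittagong", "Dhaka"),
      c("Chittagong", "Sylhet"), c("Dhaka", "Khulna"),
      c("Dhaka", "Rajshahi"), c("Dhaka", "Rangpur"),
      c("Dhaka", "Sylhet"), c("Khulna", "Rajshahi"),
      c("Rajshahi", "Rangpur")
    )
  } else if (preset == "bdhs2018") {
    regions <- c("Barisal", "Chittagong", "Dhaka", "Khulna", "Mymensingh",
                 "Rajshahi", "Rangpur", "Sylhet")
    edges <- rbind(
      c("Barisal", "Chittagong"), c("Barisal", "Dhaka"),
      c("Barisal", "Khulna"), c("Chittagong", "Dhaka"),
      c("Chittagong", "Sylhet"), c("Dhaka", "Khulna"),
      c("Dhaka", "Rajshahi"), c("Dhaka", "Mymensingh"),
      c("Dhaka", "Sylhet"), c("Khulna", "Rajshahi"),
      c("Mymensingh", "Rangpur"), c("Mymensingh", "Sylhet"),
      c("Rajshahi", "Rangpur")
    )
  } else {
    regions <- c("R11", "R12", "R21", "R22")
    edges <- rbind(
      c("R11", "R12"), c("R11", "R21"),
      c("R12", "R22"), c("R21", "R22")
    )
  }
  region_graph(regions, edges)
}

#' Read / write a region graph as plain text
#'
#' The on-disk format is a node file with one region label per line and an
#' edge file with two whitespace-separated labels per line.  If `node_path`
#' is `NULL` the region set is taken from the edge list (sorted), which
#' cannot represent isolated regions.
#'
#' @param edge_path path of the two-column edge-list text file.
#' @param node_path optional path of the one-label-per-line node file.
#' @return [read_adjacency()] returns a [region_graph];
#'   [write_adjacency()] returns the paths invisibly.
#' @export
read_adjacency <- function(edge_path, node_path = NULL) {
  lines <- readLines(edge_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:],]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) {
    stop("edge file line ", bad[1L], " does not have two fields: '",
         lines[bad[1L]], "'")
  }
  edges <- do.call(rbind, parts)
  if (is.null(node_path)) {
    regions <- sort(unique(c(edges)))
  } else {
    regions <- readLines(node_path)
    regions <- trimws(regions)
    regions <- regions[nzchar(regions) & !startsWith(regions, "#")]
  }
  region_graph(regions, edges)
}

#' @rdname read_adjacency
#' @param graph a [region_graph].
#' @export
write_adjacency <- function(graph, edge_path, node_path = NULL) {
  stopifnot(inherits(graph, "region_graph"))
  writeLines(paste(graph$edges[, 1L], graph$edges[, 2L]), edge_path)
  if (!is.null(node_path)) writeLines(graph$regions, node_path)
  invisible(c(edge_path, node_path))
}

#' Intrinsic GMRF (ICAR) precision matrix of a region graph
#'
#' Builds the precision matrix `Q` of the intrinsic conditional
#' autoregression implied by neighbour-average conditionals: each region's
#' effect, given all others, is Gaussian with mean the average of its
#' neighbours' effects and variance `delta / |N(k)|`.  Equivalently
#' `Q[k,k] = |N(k)| / delta` and `Q[k,l] = -1/delta` for neighbours.
#' `Q` is singular: `Q %*% 1 = 0` (one null dimension per connected
#' component).
#'
#' @param graph a [region_graph].
#' @param delta positive variance parameter of the GMRF prior.
#' @param isolated how to treat regions without neighbours: `"error"`
#'   (default, the prior is undefined for them) or `"zero"` (their row and
#'   column are zero, pinning the effect to its centred value, with a
#'   warning).
#' @return A symmetric `R x R` matrix with dimnames `graph$regions`.
#' @export
gmrf_precision <- function(graph, delta = 1,
                           isolated = c("error", "zero")) {
  stopifnot(inherits(graph, "region_graph"))
  isolated <- match.arg(isolated)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0) {
    stop("delta must be a positive scalar")
  }
  R <- length(graph$regions)
  if (any(graph$neighbor_counts == 0L)) {
    if (isolated == "error") {
      stop("isolated region(s): ",
           paste(graph$regions[graph$neighbor_counts == 0L], collapse = ", "),
           "; the structured spatial prior is undefined for them")
    }
    warning("isolated region(s) get a zero structured effect: ",
            paste(graph$regions[graph$neighbor_counts == 0L], collapse = ", "))
  }
  Q <- matrix(0, R, R, dimnames = list(graph$regions, graph$regions))
  diag(Q) <- graph$neighbor_counts
  if (nrow(graph$edges)) {
    idx_from <- match(graph$edges[, 1L], graph$regions)
    idx_to <- match(graph$edges[, 2L], graph$regions)
    Q[cbind(idx_from, idx_to)] <- -1
    Q[cbind(idx_to, idx_from)] <- -1
  }
  Q / delta
}
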