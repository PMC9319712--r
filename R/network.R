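#' Build a simple undirected network from endpoint vectors
#'
#' Node labels are opaque strings.  Duplicate edges (in either orientation)
#' collapse to one; the caller is responsible for removing self-loops.
#'
#' @param from,to character vectors of endpoint labels.
#' @param nodes optional character vector of node labels to declare in
#'   addition to the edge endpoints (isolated nodes).
#' @return an undirected simple [igraph::graph] with a `name` vertex
#'   attribute.
#' @export
make_network <- function(from, to, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  if (any(from == to)) stop("self-loops are not allowed in a simple network")
  vs <- sort(unique(c(from, to, as.character(nodes))), method = "radix")
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  keep <- !duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vs, stringsAsFactors = FALSE)
  )
  igraph::simplify(g)
}

#' Read an undirected edge list file
#'
#' Plain-text format: one edge per line, two whitespace-separated node labels;
#' `#` starts a comment line; blank lines are ignored.  Duplicate lines and
#' reversed duplicates collapse to a single edge; self-loop lines are dropped
#' with a warning.
#'
#' @param path path to the edge list file.
#' @return an undirected simple [igraph::graph].
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(body), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2)) {
    stop("parse error in ", path, ": line ", lineno[which(nt < 2)[1]],
         " has fewer than 2 tokens")
  }
  a <- vapply(toks, `[`, character(1), 1)
  b <- vapply(toks, `[`, character(1), 2)
  loop <- a == b
  if (any(loop)) {
    warning("dropped ", sum(loop), " self-loop line(s) in ", path)
  }
  if (all(loop)) {
    # declared nodes survive even if their only lines were self-loops
    return(make_network(character(0), character(0), nodes = unique(a)))
  }
  make_network(a[!loop], b[!loop], nodes = unique(c(a[loop], b[loop])))
}

#' Write a network as a plain-text edge list
#'
#' @param net an undirected [igraph::graph] with named vertices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Export a network in GML format (for visualisation tools)
#'
#' @inheritParams write_edge_list
#' @export
write_gml <- function(net, path) {
  igraph::write_graph(net, path, format = "gml")
  invisible(path)
}

#' Degree sequence of a network
#'
#' @param net an undirected [igraph::graph].
#' @return a named integer vector mapping every node (isolated nodes
#'   included, with degree 0) to its degree; the sum equals twice the edge
#'   count.
#' @export
degree_sequence <- function(net) {
  d <- igraph::degree(net, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Continuous maximum-likelihood estimate of a power-law degree exponent
#'
#' Fits `P(k) ~ k^-gamma` to the degree tail `k >= kmin` with the continuous
#' MLE and the -1/2 discreteness correction:
#' `gamma_hat = 1 + n / sum(log(k_i / (kmin - 1/2)))`.
#' Also returns the tail normalisation coefficient
#' `b = (gamma_hat - 1) * kmin^(gamma_hat - 1)` of the fitted density, used by
#' the analytic structural-hole-region bounds.
#'
#' @param degrees integer vector of node degrees.
#' @param kmin minimum degree included in the fit.  Defaults to 2; when the
#'   degrees come from an nPSO network the generator's `m` is the natural
#'   choice.
#' @return a list with elements `gamma`, `b`, `kmin` and `n_tail` (number of
#'   degrees used).
#' @export
#' @examples
#' k <- sample(2:500, 2000, replace = TRUE, prob = (2:500)^-2.5)
#' estimate_gamma(k, kmin = 2)$gamma
estimate_gamma <- function(degrees, kmin = 2) {
  stopifnot(is.numeric(degrees), kmin >= 1)
  ks <- degrees[degrees >= kmin]
  if (length(ks) < 10) {
    stop("gamma estimation needs at least 10 degrees >= kmin (got ",
         length(ks), ")")
  }
  if (length(unique(ks)) < 2) {
    stop("gamma estimation is degenerate: all usable degrees are equal")
  }
  gamma <- 1 + length(ks) / sum(log(ks / (kmin - 0.5)))
  list(gamma = gamma,
       b = (gamma - 1) * kmin^(gamma - 1),
       kmin = kmin,
       n_tail = length(ks))
}
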