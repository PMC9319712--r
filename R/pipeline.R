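#' Run the full generate/embed/detect/evaluate pipeline
#'
#' Composes the package stages: generate an nPSO benchmark network (or load
#' an edge list), embed it on the Poincare disk, detect communities with the
#' critical-gap sweep, rank structural hole spanners, and evaluate against
#' the baselines.  A single top-level seed fans out to per-stage seeds via
#' [derive_seed()], so each stage is individually reproducible.  When
#' `out_dir` is given, every artifact (edge list, truth table, coordinates,
#' communities, spanners, evaluation report) is written as TSV together with
#' the fully resolved configuration (JSON if the jsonlite package is
#' available, otherwise `dput`), stamped with a stable configuration hash.
#'
#' @param edges optional path to an edge list file; when `NULL`, a network
#'   is generated from the generator parameters below.
#' @param n,m,gamma,temperature,communities,sigma generator parameters (see
#'   [npso_params()]); `gamma` is also reused as the embedding exponent when
#'   `embed_gamma = "auto"` fails, and `sigma` defaults to
#'   `(2*pi/communities)/6`.
#' @param embed_gamma exponent for the embedding stage, `"auto"` (default)
#'   or a number `> 2`.
#' @param k top-k size for spanner detection and evaluation.
#' @param a,p spanner-region parameters (see [sdhe_detect()]).
#' @param methods evaluation methods (see [evaluate_methods()]).
#' @param seed top-level integer seed.
#' @param out_dir optional output directory.
#' @param plot if `TRUE` (and `out_dir` is given), also write a polar
#'   scatter of the embedded disk coloured by community.
#' @return a list with `network`, `truth` (or `NULL`), `coords`,
#'   `assignment`, `spanners`, `report`, `config` and `config_hash`.
#' @export
#' @examples
#' res <- run_pipeline(n = 150, m = 4, communities = 3, k = 5, seed = 1)
#' res$assignment
run_pipeline <- function(edges = NULL, n = 500, m = 4, gamma = 2.5,
                         temperature = 0.1, communities = 4, sigma = NULL,
                         embed_gamma = "auto", k = 10, a = 0.5, p = 0.9,
                         methods = c("sdhe", "pagerank", "betweenness",
                                     "two_step"),
                         seed = 1, out_dir = NULL, plot = FALSE) {
  config <- list(edges = edges, n = n, m = m, gamma = gamma,
                 temperature = temperature, communities = communities,
                 sigma = sigma, embed_gamma = embed_gamma, k = k, a = a,
                 p = p, methods = methods, seed = seed)
  hash <- config_hash(config)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[sdhe %s] stage %-11s %6.2f s", hash, name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  truth <- NULL
  if (is.null(edges)) {
    gen <- stage("generate", npso_generate(npso_params(
      n = n, m = m, gamma = gamma, temperature = temperature,
      communities = communities, sigma = sigma,
      seed = derive_seed(seed, "generate"))))
    net <- gen$network
    truth <- gen$truth
  } else {
    net <- stage("read", read_edge_list(edges))
    if (igraph::vcount(net) == 0) stop("usage error: empty network and no generator requested")
  }

  coords <- stage("embed", ee_embed(net, gamma = embed_gamma,
                                    temperature = temperature,
                                    seed = derive_seed(seed, "embed")))
  assignment <- stage("communities", critical_gap_sweep(net, coords))
  spanners <- stage("detect", sdhe_detect(net, coords, assignment, k = k,
                                          a = a, p = p))
  report <- stage("evaluate", evaluate_methods(net, coords, assignment,
                                               methods = methods, k = k,
                                               a = a, p = p))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(path) file.path(out_dir, path)
    write_edge_list(net, stamp("edges.tsv"))
    if (!is.null(truth)) {
      write.table(truth, stamp("truth.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    write_coordinates(coords, stamp("coordinates.tsv"))
    write.table(data.frame(node = names(assignment$membership),
                           community = as.integer(assignment$membership)),
                stamp("communities.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(as.data.frame(spanners), stamp("spanners.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report), stamp("report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg <- c(config, list(config_hash = hash,
                          Q = assignment$Q, gap = assignment$gap,
                          n_communities = assignment$n_communities))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(cfg, stamp("config.json"), auto_unbox = TRUE,
                           null = "null", digits = NA)
    } else {
      dput(cfg, stamp("config.txt"))
    }
    if (plot) {
      plot_disk(coords, assignment$membership,
                file = stamp("disk.png"))
    }
  }

  list(network = net, truth = truth, coords = coords,
       assignment = assignment, spanners = spanners, report = report,
       config = config, config_hash = hash)
}

#' Polar scatter plot of an embedded disk
#'
#' Draws every embedded node at `(r, theta)` on the disk, coloured by
#' community when a membership is supplied.
#'
#' @param coords a [disk_coordinates()] table.
#' @param membership optional community labels named by node.
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @param ... passed to [graphics::plot()].
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_disk <- function(coords, membership = NULL, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  x <- coords$r * cos(coords$theta)
  y <- coords$r * sin(coords$theta)
  col <- "grey30"
  if (!is.null(membership)) {
    m <- as.integer(factor(membership[coords$node]))
    col <- grDevices::hcl.colors(max(m), "Dark 3")[m]
  }
  lim <- max(coords$r) * 1.05
  graphics::plot(x, y, col = col, pch = 19, cex = 0.5, asp = 1,
                 xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "", ylab = "", axes = FALSE,
                 main = "Poincare disk embedding", ...)
  ang <- seq(0, 2 * pi, length.out = 256)
  graphics::lines(lim * cos(ang) / 1.05, lim * sin(ang) / 1.05,
                  col = "grey70")
  invisible(file)
}
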