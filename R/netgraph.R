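# RBFE network assembly, cycle-closure validation, indirect shortest-path
# estimates and comparison statistics.

.edge_key <- function(s, t) paste(s, t, sep = "\r")
.unordered_key <- function(s, t) paste(pmin(s, t), pmax(s, t), sep = "\r")

#' Assemble an RBFE network from edges with work samples
#'
#' Builds a network of compounds connected by alchemical edges and computes
#' the requested per-edge estimates.  Each unordered compound pair may be
#' stored in one orientation only; queries for the opposite orientation
#' return negated values transparently.  Disconnected components are
#' allowed (a message is emitted).
#'
#' @param edges List of [edge_data()] objects.
#' @param methods Character vector of method tags from
#'   [estimator_methods()].
#' @param bar_set,boot_set,max_products Passed to [edge_estimate()].
#' @return An object of class `rbfe_network`.
#' @seealso [network_from_table()] for starting from precomputed values.
#' @export
build_network <- function(edges, methods = "BAR",
                          bar_set = bar_settings(),
                          boot_set = bootstrap_settings(),
                          max_products = 1e6) {
  stopifnot(length(edges) >= 1)
  est <- list()
  for (e in edges) {
    for (m in methods) {
      fe <- edge_estimate(e, m, bar_set, boot_set, max_products)
      est[[length(est) + 1L]] <- data.frame(
        source = e$source, target = e$target, method = m,
        value = fe$value, stderr = fe$stderr, stringsAsFactors = FALSE)
    }
  }
  .make_network(edges, do.call(rbind, est), values_only = FALSE)
}

#' Assemble a values-only RBFE network from a table of estimates
#'
#' Builds a network directly from precomputed per-edge free energies (e.g.
#' a published results table), without any work samples.  The network is
#' marked values-only; estimators cannot be re-run on it, but cycle
#' closure, indirect estimates and comparison statistics all work.
#'
#' @param values Data frame with columns `source`, `target`, `method`,
#'   `value` and optionally `stderr` (kcal/mol).
#' @param edges Optional list of [edge_data()] carrying per-edge metadata
#'   (finite-size corrections, similarity records).  Defaults to bare
#'   edges derived from `values`.
#' @return An `rbfe_network` with `values_only = TRUE`.
#' @export
network_from_table <- function(values, edges = NULL) {
  stopifnot(is.data.frame(values),
            all(c("source", "target", "method", "value") %in% names(values)))
  if (is.null(values$stderr)) values$stderr <- NA_real_
  if (is.null(edges)) {
    pairs <- unique(values[c("source", "target")])
    edges <- lapply(seq_len(nrow(pairs)), function(i)
      edge_data(pairs$source[i], pairs$target[i]))
  }
  .make_network(edges, values, values_only = TRUE)
}

.make_network <- function(edges, estimates, values_only) {
  keys <- vapply(edges, function(e) .unordered_key(e$source, e$target), "")
  if (anyDuplicated(keys)) {
    d <- edges[[which(duplicated(keys))[1]]]
    stop("duplicate unordered pair in network: ", d$source, " / ", d$target)
  }
  names(edges) <- vapply(edges, function(e) .edge_key(e$source, e$target), "")
  nodes <- sort(unique(c(vapply(edges, `[[`, "", "source"),
                         vapply(edges, `[[`, "", "target"))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = vapply(edges, `[[`, "", "source"),
               to = vapply(edges, `[[`, "", "target")),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  nc <- igraph::components(g)$no
  if (nc > 1) message("rbfe_network: graph has ", nc,
                      " disconnected components")
  structure(list(nodes = nodes, edges = edges, estimates = estimates,
                 graph = g, values_only = values_only),
            class = "rbfe_network")
}

#' @export
print.rbfe_network <- function(x, ...) {
  cat(sprintf("<rbfe_network> %d compounds, %d edges, methods: %s%s\n",
              length(x$nodes), length(x$edges),
              paste(unique(x$estimates$method), collapse = ", "),
              if (x$values_only) " (values-only)" else ""))
  invisible(x)
}

# stored-orientation lookup; returns list(value, stderr, sign) or NULL
.lookup_edge_value <- function(net, a, b, method) {
  est <- net$estimates
  i <- which(est$source == a & est$target == b & est$method == method)
  if (length(i)) return(list(value = est$value[i[1]],
                             stderr = est$stderr[i[1]], sign = 1))
  i <- which(est$source == b & est$target == a & est$method == method)
  if (length(i)) return(list(value = -est$value[i[1]],
                             stderr = est$stderr[i[1]], sign = -1))
  NULL
}

#' Query an edge estimate in either orientation
#'
#' @param net An `rbfe_network`.
#' @param source,target Compound ids.  If the edge is stored in the
#'   opposite orientation the negated value is returned.
#' @param method Estimator tag.
#' @return List with `value`, `stderr` and `sign` (+1 along the stored
#'   orientation, -1 against it).
#' @export
edge_value <- function(net, source, target, method) {
  v <- .lookup_edge_value(net, source, target, method)
  if (is.null(v)) stop("edge_value: no ", method, " estimate for edge ",
                       source, " -> ", target)
  v
}

#' Cycle-closure sum around a closed path
#'
#' The free-energy change around any closed cycle of transmutations must
#' vanish; its deviation from zero, compared with the edge uncertainties
#' summed in quadrature, is a stringent self-consistency test of an RBFE
#' network.  Edges traversed against their stored orientation contribute
#' with negated sign.  Finite-size corrections are already inside the edge
#' values, so they cancel automatically around charge-balanced cycles.
#'
#' @param net An `rbfe_network`.
#' @param node_sequence Character vector of compound ids with
#'   `first == last` describing the traversal.
#' @param method Estimator tag.
#' @return An object of class `cycle_report` with `node_sequence`,
#'   `signed_sum`, `abs_sum`, `quadrature_error` and `method`.
#' @export
cycle_sum <- function(net, node_sequence, method = "BAR") {
  stopifnot(inherits(net, "rbfe_network"))
  if (length(node_sequence) < 4)
    stop("cycle_sum: a cycle needs at least 3 edges")
  if (node_sequence[1] != node_sequence[length(node_sequence)])
    stop("cycle_sum: node sequence must start and end at the same compound")
  total <- 0; q2 <- 0
  for (i in seq_len(length(node_sequence) - 1L)) {
    a <- node_sequence[i]; b <- node_sequence[i + 1L]
    v <- .lookup_edge_value(net, a, b, method)
    if (is.null(v)) stop("cycle_sum: no ", method, " estimate for step ",
                         a, " -> ", b)
    total <- total + v$value
    q2 <- q2 + v$stderr^2
  }
  structure(list(node_sequence = node_sequence, signed_sum = total,
                 abs_sum = abs(total), quadrature_error = sqrt(q2),
                 method = method),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle> %s [%s]: sum = %.1f +/- %.1f kcal/mol\n",
              paste(x$node_sequence, collapse = " -> "), x$method,
              x$signed_sum, x$quadrature_error))
  invisible(x)
}

#' Enumerate simple cycles of a network
#'
#' Lists every simple (no repeated node) undirected cycle with between 3
#' and `max_edges` edges, each reported exactly once in canonical form:
#' the lexicographically smallest node first and the traversal direction
#' chosen so that the second node is smaller than the second-to-last.
#' Sequences are closed (`first == last`) and returned in deterministic
#' (sorted) order, ready for [cycle_sum()].
#'
#' @param net An `rbfe_network`.
#' @param max_edges Maximum cycle length (>= 3).
#' @return List of character vectors.
#' @export
enumerate_cycles <- function(net, max_edges = 3) {
  stopifnot(inherits(net, "rbfe_network"), max_edges >= 3)
  adj <- lapply(stats::setNames(net$nodes, net$nodes), function(n) character(0))
  for (e in net$edges) {
    adj[[e$source]] <- c(adj[[e$source]], e$target)
    adj[[e$target]] <- c(adj[[e$target]], e$source)
  }
  adj <- lapply(adj, sort)
  out <- list()
  # DFS from each start node s, visiting only nodes > s, so every cycle is
  # found exactly once anchored at its smallest node.
  dfs <- function(s, path) {
    cur <- path[length(path)]
    for (nb in adj[[cur]]) {
      if (nb == s && length(path) >= 3) {
        if (path[2] < path[length(path)])   # canonical direction
          out[[length(out) + 1L]] <<- c(path, s)
      } else if (nb > s && !(nb %in% path) && length(path) < max_edges) {
        dfs(s, c(path, nb))
      }
    }
  }
  for (s in net$nodes) dfs(s, s)
  out[order(vapply(out, function(p)
    paste(formatC(length(p), width = 3, flag = "0"),
          paste(p, collapse = "\r")), ""))]
}

#' Indirect RBFE between two compounds via the shortest path
#'
#' When a pair of compounds is not connected by a direct edge, their RBFE
#' is obtained by summing the signed edge estimates along the shortest
#' path (fewest edges; ties broken by the lexicographically smallest node
#' sequence).  The uncertainty is the quadrature sum of the traversed edge
#' errors, so confidence intervals widen with the number of transmutations
#' `N_t`.
#'
#' @param net An `rbfe_network`.
#' @param reference,target Compound ids; must be connected.
#' @param method Estimator tag.
#' @return An [fe_estimate]; `diagnostics$n_transmutations` holds `N_t` and
#'   `diagnostics$path` the node sequence.
#' @export
indirect_rbfe <- function(net, reference, target, method = "BAR") {
  stopifnot(inherits(net, "rbfe_network"))
  if (!all(c(reference, target) %in% net$nodes))
    stop("indirect_rbfe: unknown compound id")
  if (reference == target)
    return(fe_estimate(0, stderr = 0, method = method,
                       diagnostics = list(n_transmutations = 0L,
                                          path = reference)))
  sp <- suppressWarnings(igraph::all_shortest_paths(
    net$graph, from = reference, to = target))$vpaths
  if (!length(sp))
    stop("indirect_rbfe: ", reference, " and ", target,
         " are not connected")
  paths <- lapply(sp, function(p) igraph::V(net$graph)$name[as.integer(p)])
  key <- vapply(paths, paste, "", collapse = "\r")
  path <- paths[[order(key)[1]]]
  total <- 0; q2 <- 0
  for (i in seq_len(length(path) - 1L)) {
    v <- .lookup_edge_value(net, path[i], path[i + 1L], method)
    if (is.null(v)) stop("indirect_rbfe: no ", method,
                         " estimate for step ", path[i], " -> ", path[i + 1L])
    total <- total + v$value
    q2 <- q2 + v$stderr^2
  }
  fe_estimate(total, stderr = sqrt(q2), method = method,
              diagnostics = list(n_transmutations = length(path) - 1L,
                                 path = path))
}

#' Agreement statistics between two sets of free energies
#'
#' Mean unsigned error, mean signed error, Pearson correlation and the
#' least-squares line of `predicted` on `observed`.  Pairs with a missing
#' entry in either vector are dropped and counted.
#'
#' @param predicted,observed Numeric vectors of equal length (kcal/mol).
#' @return An object of class `comparison_stats` with fields `mue`, `mse`,
#'   `pearson_r`, `slope`, `intercept`, `n`, `n_dropped`.
#' @export
compare_stats <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  ok <- is.finite(predicted) & is.finite(observed)
  n_dropped <- sum(!ok)
  p <- predicted[ok]; o <- observed[ok]
  if (length(p) < 2) stop("compare_stats: fewer than 2 complete pairs")
  fit <- stats::lm(p ~ o)
  structure(list(mue = mean(abs(p - o)), mse = mean(p - o),
                 pearson_r = stats::cor(p, o),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(p), n_dropped = n_dropped),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(paste0("<comparison> n = %d (%d dropped): MUE = %.2f, ",
                     "MSE = %.2f kcal/mol, R = %.2f, fit p = %.2f o %+.2f\n"),
              x$n, x$n_dropped, x$mue, x$mse, x$pearson_r,
              x$slope, x$intercept))
  invisible(x)
}

#' Correlation of estimator deviations with a dissimilarity metric
#'
#' Pearson correlation between the per-edge deviation
#' `estimate_a - estimate_b` and a chemical-dissimilarity metric stored on
#' the edges (a field of [similarity_record()]).  Used to probe whether
#' unidirectional estimators drift away from the bidirectional reference
#' as the two compounds become more dissimilar in charge, volume or
#' fingerprint.
#'
#' @param net An `rbfe_network`.
#' @param method_a,method_b Estimator tags; the deviation is a - b.
#' @param metric Field name of [similarity_record()], e.g.
#'   `"delta_volume"`, `"tanimoto"`, `"rel_charge_change"`.
#' @return The Pearson correlation coefficient.
#' @export
deviation_correlation <- function(net, method_a, method_b, metric) {
  stopifnot(inherits(net, "rbfe_network"))
  dev <- numeric(0); met <- numeric(0)
  for (e in net$edges) {
    va <- .lookup_edge_value(net, e$source, e$target, method_a)
    vb <- .lookup_edge_value(net, e$source, e$target, method_b)
    m <- e$similarity[[metric]]
    if (is.null(va) || is.null(vb) || is.null(m) || !is.finite(m) ||
        !is.finite(va$value) || !is.finite(vb$value)) next
    dev <- c(dev, va$value - vb$value)
    met <- c(met, m)
  }
  if (length(dev) < 3)
    stop("deviation_correlation: fewer than 3 edges carry both estimates ",
         "and the metric '", metric, "'")
  if (stats::sd(met) == 0)
    stop("deviation_correlation: zero variance in metric '", metric, "'")
  stats::cor(dev, met)
}

#' Tanimoto coefficient of two fingerprint bit vectors
#'
#' Set-overlap similarity `|a AND b| / |a OR b|` between two equal-length
#' binary fingerprints.
#'
#' @param fp_a,fp_b Logical or 0/1 numeric vectors of equal length.
#' @return The Tanimoto coefficient in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("tanimoto: fingerprints must have equal length")
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0) stop("tanimoto: both fingerprints are empty")
  sum(a & b) / un
}
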