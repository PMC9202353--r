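# Shared fixtures: all synthetic, generated in code under fixed seeds.

wp6_table_path <- function() {
  system.file("extdata", "wp6_sampl9_rbfe.tsv", package = "nebar")
}

wp6_network <- function() read_network(wp6_table_path())

# a random work_set (not Crooks-consistent; for parser/property tests)
random_work_set <- function(n, seed, direction = "forward", leg = "bound",
                            mu_range = c(-10, 10), sigma_range = c(0.1, 4)) {
  withr::with_seed(seed, {
    mu <- runif(1, mu_range[1], mu_range[2])
    sig <- runif(1, sigma_range[1], sigma_range[2])
    work_set(rnorm(n, mu, sig), direction, leg)
  })
}

# a synthetic bidirectional edge with Crooks-consistent Gaussian legs and
# known ground-truth RBFE dg_bound - dg_unbound
synthetic_edge <- function(dg_bound, dg_unbound, sigma_bound, sigma_unbound,
                           n_bound = 196, n_unbound = 96, seed = 1L,
                           fs_correction = 0) {
  b <- crooks_gaussian_sampler(dg_bound, sigma_bound, n_bound, n_bound,
                               seed = seed, leg = "bound")
  u <- crooks_gaussian_sampler(dg_unbound, sigma_unbound, n_unbound,
                               n_unbound, seed = seed + 1L, leg = "unbound")
  edge_data("A", "B",
            works = list(bound_forward = b$forward,
                         bound_reverse = b$reverse,
                         unbound_forward = u$forward,
                         unbound_reverse = u$reverse),
            fs_correction = fs_correction)
}

# values-only network whose edge values derive from node potentials, so
# that every cycle closes exactly and every path between two nodes sums
# to the same potential difference
potential_network <- function(n_nodes, n_extra_edges, seed,
                              method = "BAR") {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    phi <- setNames(rnorm(n_nodes, 0, 3), nodes)
    # random spanning tree + extra chords
    pairs <- list()
    for (i in 2:n_nodes)
      pairs[[length(pairs) + 1L]] <- c(nodes[sample.int(i - 1L, 1L)],
                                       nodes[i])
    all_pairs <- t(combn(nodes, 2))
    have <- vapply(pairs, function(p) paste(sort(p), collapse = "|"), "")
    avail <- which(!(paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                           pmax(all_pairs[, 1], all_pairs[, 2]),
                           sep = "|") %in% have))
    extra <- sample(avail, min(n_extra_edges, length(avail)))
    for (i in extra) pairs[[length(pairs) + 1L]] <- all_pairs[i, ]
    vals <- do.call(rbind, lapply(pairs, function(p)
      data.frame(source = p[1], target = p[2], method = method,
                 value = phi[[p[2]]] - phi[[p[1]]],
                 stderr = runif(1, 0.1, 1), stringsAsFactors = FALSE)))
    list(net = network_from_table(vals), phi = phi)
  })
}

# write a manifest + work files for one synthetic edge into dir
write_edge_manifest_fixture <- function(dir, edge, temperature = 298.15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (k in names(edge$works)) {
    p <- file.path(dir, paste0(k, ".work"))
    write_work_file(edge$works[[k]], p)
    files[[k]] <- basename(p)
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    temperature = temperature,
    edges = list(list(source = edge$source, target = edge$target,
                      fs_correction = edge$fs_correction,
                      files = files))), manifest)
  manifest
}
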