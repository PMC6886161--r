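# shared fixtures and independent oracles for the suite

# recovery RMSD against a known truth: reconstruction is blind to chirality,
# so take the better enantiomer under (optionally scaled) proper superposition
recovery_rmsd <- function(fit, truth, allow_scale = TRUE) {
  min(kabsch_superpose(fit, truth, allow_scale = allow_scale)$rmsd,
      kabsch_superpose(mirror_structure(fit), truth,
                       allow_scale = allow_scale)$rmsd)
}

# brute-force all-simple-paths shortest path oracle (independent of igraph);
# feasible for graphs with <= 8 nodes
brute_force_shortest_paths <- function(n, edges, weights) {
  adj <- matrix(Inf, n, n)
  diag(adj) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]
    j <- edges[k, 2]
    adj[i, j] <- adj[j, i] <- min(adj[i, j], weights[k])
  }
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  recurse <- function(path, len) {
    last <- path[length(path)]
    if (len < best[path[1], last]) {
      best[path[1], last] <<- len
      best[last, path[1]] <<- len
    }
    for (nxt in seq_len(n)) {
      if (is.finite(adj[last, nxt]) && nxt != last && !(nxt %in% path)) {
        recurse(c(path, nxt), len + adj[last, nxt])
      }
    }
  }
  for (s in seq_len(n)) recurse(s, 0)
  best
}

# central finite-difference gradient of an mds objective
fd_gradient <- function(coords, model, config, h = 1e-6) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (j in 1:3) {
      e <- coords * 0
      e[i, j] <- h
      g[i, j] <- (objective_value(coords + e, model, config) -
                    objective_value(coords - e, model, config)) / (2 * h)
    }
  }
  g
}

write_tmp <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# small noisy contact fixture with a nonempty C2 used across mds tests
noisy_fixture <- function(n = 5, seed = 3, dropout = 0.3) {
  s <- make_structure(random_walk_spec(n, seed = seed))
  structure_to_contacts(s, dropout_rate = dropout, seed = seed + 1)
}
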