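# Brute-force reference implementations used as independent oracles.
# All are deliberately naive (explicit loops, full adjacency matrices) so
# that they share no code path with the package estimators.

# univariate PCF by exhaustive pair enumeration
oracle_pcf <- function(pts, win, edges, correction = c("toroidal", "border")) {
  correction <- match.arg(correction)
  n <- nrow(pts)
  A <- (win$x_max - win$x_min) * (win$y_max - win$y_min)
  wx <- win$x_max - win$x_min
  wy <- win$y_max - win$y_min
  nb <- length(edges) - 1
  counts <- integer(nb)
  n_ref <- integer(nb)
  margin <- function(p) min(p[1] - win$x_min, win$x_max - p[1],
                            p[2] - win$y_min, win$y_max - p[2])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(pts[i, 1] - pts[j, 1]); dy <- abs(pts[i, 2] - pts[j, 2])
      if (correction == "toroidal") {
        dx <- min(dx, wx - dx); dy <- min(dy, wy - dy)
      }
      d <- sqrt(dx^2 + dy^2)
      for (k in seq_len(nb)) {
        if (d >= edges[k] && d < edges[k + 1]) {
          if (correction == "toroidal" || margin(pts[i, ]) >= edges[k + 1])
            counts[k] <- counts[k] + 1L
          break
        }
      }
    }
  }
  g <- numeric(nb)
  for (k in seq_len(nb)) {
    ann <- pi * (edges[k + 1]^2 - edges[k]^2)
    nr <- if (correction == "toroidal") n
          else sum(apply(pts, 1, margin) >= edges[k + 1])
    g[k] <- if (nr > 0) counts[k] / (nr * (n - 1) * ann / A) else NA_real_
  }
  list(g = g, counts = counts)
}

# cross-PCF by exhaustive enumeration (toroidal only)
oracle_cross_pcf <- function(p1, p2, win, edges) {
  A <- (win$x_max - win$x_min) * (win$y_max - win$y_min)
  wx <- win$x_max - win$x_min; wy <- win$y_max - win$y_min
  nb <- length(edges) - 1
  counts <- integer(nb)
  for (i in seq_len(nrow(p1))) {
    for (j in seq_len(nrow(p2))) {
      dx <- abs(p1[i, 1] - p2[j, 1]); dx <- min(dx, wx - dx)
      dy <- abs(p1[i, 2] - p2[j, 2]); dy <- min(dy, wy - dy)
      d <- sqrt(dx^2 + dy^2)
      for (k in seq_len(nb)) {
        if (d >= edges[k] && d < edges[k + 1]) {
          counts[k] <- counts[k] + 1L
          break
        }
      }
    }
  }
  ann <- pi * diff(edges^2)
  list(g = counts / (nrow(p1) * nrow(p2) * ann / A), counts = counts)
}

# connected components by BFS over an explicit adjacency matrix
bfs_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# spatiotemporal linkage components (merge oracle)
oracle_merge_components <- function(x, y, frame, eps, max_df) {
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && abs(frame[i] - frame[j]) <= max_df &&
        (x[i] - x[j])^2 + (y[i] - y[j])^2 <= eps^2)
      adj[i, j] <- TRUE
  }
  bfs_components(adj)
}

# eps-neighbourhood-graph components (DBSCAN minpts = 2 oracle);
# isolated vertices get label 0
oracle_eps_graph <- function(pts, eps) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        (pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2 <= eps^2)
      adj[i, j] <- TRUE
  }
  comp <- bfs_components(adj)
  sizes <- table(comp)
  lab <- integer(n)
  keep <- as.integer(names(sizes)[sizes >= 2])
  lab[comp %in% keep] <- match(comp[comp %in% keep], keep)
  lab
}

# canonical form of a labelling: relabel clusters by first appearance so
# two labelings can be compared up to permutation (0 stays 0)
canonical_labels <- function(lab) {
  pos <- lab > 0
  out <- integer(length(lab))
  out[pos] <- match(lab[pos], unique(lab[pos]))
  out
}

# write a small localization CSV in the default dialect
write_fixture_csv <- function(df, path, headers = c(frame = "frame",
                                                    x = "x [nm]",
                                                    y = "y [nm]")) {
  out <- df
  names(out) <- headers[names(df)]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  path
}

fixture_window <- function(side = 4000) roi(0, side, 0, side)
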