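# Fixture meshes and independent brute-force oracles. Every oracle here is a
# deliberately naive reference implementation, kept separate from the package
# code paths it checks.

tetra_surface <- function(edge = 1) {
  # regular tetrahedron with the given edge length
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    (2 * sqrt(2)) * edge
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  labeled_surface(v, f)
}

unit_cube_surface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  quads <- rbind(  # outward-oriented quads, split into triangles
    c(1, 3, 4, 2),  # z = 0
    c(5, 6, 8, 7),  # z = 1
    c(1, 2, 6, 5),  # y = 0
    c(3, 7, 8, 4),  # y = 1
    c(1, 5, 7, 3),  # x = 0
    c(2, 4, 8, 6))  # x = 1
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  labeled_surface(v, f)
}

# adjacency as a plain list of neighbor vectors (for oracle use)
adj_list <- function(surface) {
  n <- nrow(surface$vertices)
  e <- rbind(surface$faces[, c(1, 2)], surface$faces[, c(2, 3)],
             surface$faces[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  split(e[, 2], factor(e[, 1], levels = seq_len(n)))
}

# oracle: BFS ball of a vertex (<= radius edges), optionally region-confined
oracle_bfs_ball <- function(adj, v, radius, region = NULL) {
  ball <- v
  frontier <- v
  for (r in seq_len(radius)) {
    nxt <- unique(unlist(adj[frontier]))
    if (!is.null(region)) nxt <- nxt[region[nxt] == region[v]]
    frontier <- setdiff(nxt, ball)
    if (!length(frontier)) break
    ball <- c(ball, frontier)
  }
  ball
}

# oracle mode with the package's tie rule: keep current if tied, else
# smallest tied label
oracle_mode <- function(labels, current) {
  tab <- table(labels)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (current %in% top) current else min(top)
}

# oracle: surface mode filter
oracle_mode_filter_surface <- function(labels, adj, radius, iterations,
                                       region = NULL) {
  cur <- labels
  for (it in seq_len(iterations)) {
    nxt <- cur
    for (v in seq_along(cur)) {
      ball <- oracle_bfs_ball(adj, v, radius, region)
      nxt[v] <- oracle_mode(cur[ball], cur[v])
    }
    cur <- nxt
  }
  cur
}

# neighbor offsets for voxel connectivity
offsets_conn <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(g))
  g[m > 0 & ((connectivity == 6 & m <= 1) | (connectivity == 18 & m <= 2) |
               connectivity == 26), , drop = FALSE]
}

# oracle: volumetric mode filter
oracle_mode_filter_volume <- function(arr, iterations, connectivity,
                                      frozen = NULL, ignore_zero = FALSE) {
  d <- dim(arr)
  off <- offsets_conn(connectivity)
  cur <- arr
  for (it in seq_len(iterations)) {
    nxt <- cur
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (!is.null(frozen) && frozen[x, y, z]) next
      if (ignore_zero && cur[x, y, z] == 0) next
      labs <- cur[x, y, z]
      for (k in seq_len(nrow(off))) {
        p <- c(x, y, z) + off[k, ]
        if (any(p < 1) || any(p > d)) next
        l <- cur[p[1], p[2], p[3]]
        if (ignore_zero && l == 0) next
        labs <- c(labs, l)
      }
      nxt[x, y, z] <- oracle_mode(labs, cur[x, y, z])
    }
    cur <- nxt
  }
  cur
}

# oracle: multi-source BFS label expansion truncated at depth `iterations`
# through the target class; ties at equal distance go to the smallest label
oracle_expand_labels <- function(arr, iterations, sources, targets,
                                 connectivity, protect = NULL) {
  d <- dim(arr)
  off <- offsets_conn(connectivity)
  dist <- array(Inf, d)
  lab <- array(NA_integer_, d)
  src <- which(arr %in% sources)
  dist[src] <- 0
  lab[src] <- arr[src]
  frontier <- src
  depth <- 0
  while (length(frontier) && depth < iterations) {
    depth <- depth + 1
    newly <- integer(0)
    # collect candidate labels per voxel at this depth, then take the min
    cand <- list()
    for (v in frontier) {
      xyz <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        p <- xyz + off[k, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (!(arr[w] %in% targets)) next
        if (!is.null(protect) && protect[w]) next
        if (dist[w] < depth) next
        dist[w] <- depth
        key <- as.character(w)
        cand[[key]] <- c(cand[[key]], lab[v])
      }
    }
    for (key in names(cand)) {
      w <- as.integer(key)
      lab[w] <- min(cand[[key]])
      newly <- c(newly, w)
    }
    frontier <- newly
  }
  out <- arr
  reached <- which(is.finite(dist) & dist > 0)
  out[reached] <- lab[reached]
  out
}

# oracle: multi-source BFS patch growth with FIFO tie discipline
oracle_grow <- function(adj, region, seed_vertex, seed_patch) {
  patch <- integer(length(region))
  q <- seed_vertex
  patch[seed_vertex] <- seed_patch
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) {
      if (patch[w] == 0 && region[w] == region[v]) {
        patch[w] <- patch[v]
        q <- c(q, w)
      }
    }
  }
  patch
}

oracle_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

oracle_hausdorff <- function(A, B) {
  dmat <- as.matrix(dist(rbind(A, B)))[seq_len(nrow(A)),
                                       nrow(A) + seq_len(nrow(B)),
                                       drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# small labeled volume on an identity-ish grid
random_label_volume <- function(dim, n_labels, seed, affine = diag(4)) {
  set.seed(seed)
  label_volume(array(sample.int(n_labels, prod(dim), replace = TRUE), dim),
               affine)
}
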