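# Independent brute-force oracles used by the property tests. These are
# deliberately naive (explicit bp sets, O(n^2) closures, recursive DFS)
# and share no code with the implementation they check.

# Jaccard via explicit bp membership sets
ji_bitset <- function(s1, e1, s2, e2) {
  a <- seq.int(s1, e1); b <- seq.int(s2, e2)
  length(intersect(a, b)) / length(union(a, b))
}

# single-linkage components of an arbitrary boolean relation, by
# repeated flood fill over the full pairwise matrix
relation_components <- function(n, related) {
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nxt <- nxt + 1L
    frontier <- i
    comp[i] <- nxt
    while (length(frontier) > 0) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && related(cur, j)) {
          comp[j] <- nxt
          frontier <- c(frontier, j)
        }
      }
    }
  }
  comp
}

# exhaustive cluster + argmin oracle for scan-hit post-filtering
rfam_oracle <- function(hits, level, min_overlap = 40L) {
  keep <- switch(level,
    conservative = hits$e_value < 1e-6 & hits$bit_score >= hits$gathering_score,
    medium = hits$e_value < 1e-6,
    relaxed = hits$e_value < 1e-3
  )
  hits <- hits[which(keep), , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  related <- function(i, j) {
    if (hits$strand[i] != hits$strand[j]) return(FALSE)
    ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1
    ov >= min_overlap
  }
  comp <- relation_components(nrow(hits), related)
  out <- lapply(split(seq_len(nrow(hits)), comp), function(idx) {
    h <- hits[idx, , drop = FALSE]
    h <- h[h$e_value == min(h$e_value), , drop = FALSE]
    h <- h[h$bit_score == max(h$bit_score), , drop = FALSE]
    h[order(h$start, h$end), ][1, ]
  })
  res <- do.call(rbind, out)
  res[order(res$start, res$end), ]
}

# pairwise-closure oracle for resolution-window site grouping
site_group_oracle <- function(sites) {
  related <- function(i, j) {
    if (sites$strand[i] != sites$strand[j]) return(FALSE)
    w1 <- c(sites$position[i] - sites$halfwidth[i], sites$position[i] + sites$halfwidth[i])
    w2 <- c(sites$position[j] - sites$halfwidth[j], sites$position[j] + sites$halfwidth[j])
    w1[1] <= w2[2] && w2[1] <= w1[2]
  }
  relation_components(nrow(sites), related)
}

# recursive DFS path enumeration on an edge list
dfs_paths <- function(edges, from, to_set) {
  recurse <- function(node, path) {
    path <- c(path, node)
    found <- if (node %in% to_set) list(path) else list()
    nxt <- edges$to[edges$from == node]
    for (n in nxt) found <- c(found, recurse(n, path))
    found
  }
  recurse(from, character())
}

# plain union-find over explicit pairs
union_find <- function(items, pairs_a, pairs_b) {
  parent <- stats::setNames(items, items)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(pairs_a)) {
    ra <- find(pairs_a[[k]]); rb <- find(pairs_b[[k]])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(items, find, character(1))
}

# compact builder for annotation tables in tests
ann <- function(id, start, end, strand = "+", biotype = "CDS",
                resource = "r1", priority = 1L, names = NULL) {
  annotation_tbl(id, start, end, strand, biotype, resource, priority,
                 names = names)
}
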