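#' Median-joining haplotype network
#'
#' Bandelt-style median joining with epsilon = 0: build the minimum spanning
#' network (all edges belonging to some minimum spanning tree under Hamming
#' distance), then iteratively add column-wise-majority median (Steiner)
#' vectors of connected node triplets whenever they reduce the total
#' spanning-tree length, finally pruning unobserved nodes of degree < 3.
#'
#' @param table A `haplotype_table` (>= 1 haplotype), or a named character
#'   vector of distinct aligned sequences.
#' @return An [igraph::graph] with vertex attributes `name`, `sequence`,
#'   `observed`, `count`, and edge attribute `weight` (mutation count). A
#'   single haplotype yields a single-node network.
#' @export
median_joining_network <- function(table) {
  if (inherits(table, "haplotype_table")) {
    seqs <- table$haplotypes
    counts <- table$counts
  } else {
    seqs <- table
    if (is.null(names(seqs))) names(seqs) <- sprintf("H%02d", seq_along(seqs))
    counts <- stats::setNames(rep(1L, length(seqs)), names(seqs))
  }
  if (anyDuplicated(seqs)) stop("haplotype sequences must be distinct")
  n_obs <- length(seqs)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  if (n_obs == 1) {
    g <- igraph::make_empty_graph(1, directed = FALSE)
    igraph::V(g)$name <- names(seqs)
    igraph::V(g)$sequence <- unname(seqs)
    igraph::V(g)$observed <- TRUE
    igraph::V(g)$count <- unname(counts)
    return(g)
  }

  med_count <- 0L
  repeat {
    d <- hamming_matrix(mat)
    mst_len <- mst_total_length(d)
    edges <- msn_edges(d)
    # candidate medians from connected triplets (>= 2 of 3 links in the MSN)
    adj <- matrix(FALSE, nrow(mat), nrow(mat))
    adj[edges] <- TRUE; adj <- adj | t(adj)
    cand <- list()
    nn <- nrow(mat)
    for (u in seq_len(nn - 1)) for (v in seq(u + 1, nn)) {
      if (nn >= 3) for (w in setdiff(seq_len(nn), c(u, v))) {
        if (sum(adj[u, v], adj[u, w], adj[v, w]) >= 2) {
          m <- majority_median(mat[u, ], mat[v, ], mat[w, ])
          cand[[length(cand) + 1]] <- m
        }
      }
    }
    if (!length(cand)) break
    cand <- unique(do.call(rbind, cand))
    keys <- apply(cand, 1, paste, collapse = "")
    new <- !(keys %in% apply(mat, 1, paste, collapse = ""))
    cand <- cand[new, , drop = FALSE]
    if (!nrow(cand)) break
    # greedily add the single median that most reduces the MST length
    best <- NULL; best_len <- mst_len
    for (j in seq_len(nrow(cand))) {
      trial <- rbind(mat, cand[j, ])
      len <- mst_total_length(hamming_matrix(trial))
      if (len < best_len - 1e-9) { best_len <- len; best <- cand[j, ] }
    }
    if (is.null(best)) break
    med_count <- med_count + 1L
    mat <- rbind(mat, best)
    rownames(mat)[nrow(mat)] <- sprintf("mv%02d", med_count)
  }

  # prune obsolete medians (unobserved, degree < 3 in the MSN)
  repeat {
    d <- hamming_matrix(mat)
    edges <- msn_edges(d)
    deg <- tabulate(c(edges), nbins = nrow(mat))
    obsolete <- which(deg < 3 & !(rownames(mat) %in% names(seqs)))
    if (!length(obsolete)) break
    mat <- mat[-obsolete[1], , drop = FALSE]
  }

  d <- hamming_matrix(mat)
  edges <- msn_edges(d)
  g <- igraph::graph_from_edgelist(
    cbind(rownames(mat)[edges[, 1]], rownames(mat)[edges[, 2]]),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(rownames(mat), igraph::V(g)$name))
  igraph::E(g)$weight <- d[edges]
  vn <- igraph::V(g)$name
  igraph::V(g)$sequence <- apply(mat, 1, paste, collapse = "")[vn]
  igraph::V(g)$observed <- vn %in% names(seqs)
  igraph::V(g)$count <- ifelse(vn %in% names(seqs),
                               as.integer(counts[vn]), 0L)
  g
}

hamming_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  d
}

# total length of a minimum spanning tree (Kruskal with union-find)
mst_total_length <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  eu <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[eu])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  total <- 0; used <- 0L
  for (k in ord) {
    a <- find(eu[k, 1]); b <- find(eu[k, 2])
    if (a != b) { parent[a] <- b; total <- total + d[eu[k, 1], eu[k, 2]]; used <- used + 1L }
    if (used == n - 1L) break
  }
  total
}

# minimum spanning network: all edges that occur in at least one MST.
# Kruskal variant: at each distinct weight level, add every edge joining
# components that were distinct before any edge of this level was applied.
msn_edges <- function(d) {
  n <- nrow(d)
  eu <- which(upper.tri(d), arr.ind = TRUE)
  wts <- d[eu]
  keep <- matrix(integer(0), 0, 2)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (wl in sort(unique(wts))) {
    lev <- which(wts == wl)
    comp_before <- vapply(seq_len(n), find, 1L)
    joins <- lev[comp_before[eu[lev, 1]] != comp_before[eu[lev, 2]]]
    keep <- rbind(keep, eu[joins, , drop = FALSE])
    for (k in joins) {
      a <- find(eu[k, 1]); b <- find(eu[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  keep
}

# column-wise majority of three aligned sequences; ties resolved toward the
# first sequence (deterministic)
majority_median <- function(a, b, c_) {
  m <- a
  agree_bc <- b == c_
  m[agree_bc & b != a] <- b[agree_bc & b != a]
  m
}

#' Write a haplotype network as an edge-list TSV
#' @param g Network from [median_joining_network()].
#' @param path Output file.
#' @export
write_network_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = el[, 1], to = el[, 2],
                   mutations = igraph::E(g)$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a haplotype network in GML format
#' @param g Network from [median_joining_network()].
#' @param path Output file.
#' @export
write_network_gml <- function(g, path) {
  igraph::V(g)$observed <- as.integer(igraph::V(g)$observed)  # GML has no bool
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}
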