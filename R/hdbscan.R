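# Hierarchical density-based clustering (HDBSCAN): mutual-reachability
# distances -> single-linkage hierarchy -> condensed tree at the requested
# minimum cluster size -> excess-of-mass cluster extraction.  Points not
# inside any selected cluster are labelled noise (-1).

#' Density-based clustering of feature profiles
#'
#' @param d a `dist` object (see [distanceMatrix()]).
#' @param min_cluster_size smallest cluster size of interest.
#' @param min_samples neighbourhood size for the core-distance estimate
#'   (distance to the `min_samples`-th nearest other point); defaults to
#'   `min_cluster_size`, capped at n - 1.
#' @return integer labels (1..K, noise = -1), named as `d`'s labels.
#' @export
hdbscanLabels <- function(d, min_cluster_size, min_samples = NULL) {
  n <- attr(d, "Size")
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- min(min_samples, n - 1L)
  dm <- as.matrix(d)
  # core distance: distance to the min_samples-th nearest other point
  core <- vapply(seq_len(n), function(i) {
    sort(dm[i, -i])[min_samples]
  }, 0)
  mr <- pmax(dm, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  condensed <- condenseTree(hc, n, min_cluster_size)
  selected <- selectEOM(condensed)
  labels <- rep(-1L, n)
  names(labels) <- attr(d, "Labels")
  if (length(selected)) {
    sizes <- vapply(selected, function(id) length(condensed$members[[id]]), 0L)
    for (rank in seq_along(selected)) {
      id <- selected[order(-sizes)][rank]
      labels[condensed$members[[id]]] <- rank
    }
  }
  labels
}

# Walk the single-linkage dendrogram top-down, pruning undersized children:
# their points fall out of the current condensed cluster at the split level.
# A split into two children both >= mcs creates two new condensed clusters.
condenseTree <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  nodeSize <- function(node) {
    if (node < 0L) 1L else sizes[node]
  }
  sizes <- integer(nrow(merge))
  for (i in seq_len(nrow(merge)))
    sizes[i] <- nodeSize(merge[i, 1]) + nodeSize(merge[i, 2])
  nodePoints <- function(node) {
    if (node < 0L) return(-node)
    stack <- node; pts <- integer(0)
    while (length(stack)) {
      nd <- stack[1L]; stack <- stack[-1L]
      for (ch in merge[nd, ]) {
        if (ch < 0L) pts <- c(pts, -ch) else stack <- c(stack, ch)
      }
    }
    pts
  }
  members <- list(); birth <- numeric(0); parent <- integer(0)
  stability <- numeric(0); children <- list()
  newCluster <- function(pts, b, par) {
    members[[length(members) + 1L]] <<- pts
    birth[length(birth) + 1L] <<- b
    parent[length(parent) + 1L] <<- par
    stability[length(stability) + 1L] <<- 0
    children[[length(children) + 1L]] <<- integer(0)
    id <- length(members)
    if (par > 0L) children[[par]] <<- c(children[[par]], id)
    id
  }
  root_id <- newCluster(seq_len(n), 0, 0L)
  # tasks: dendrogram node to descend from, owning condensed cluster
  tasks <- list(list(node = nrow(merge), cid = root_id))
  while (length(tasks)) {
    task <- tasks[[length(tasks)]]; tasks[[length(tasks)]] <- NULL
    node <- task$node; cid <- task$cid
    repeat {
      lam <- 1 / max(height[node], 1e-12)
      ch <- merge[node, ]
      s <- vapply(ch, nodeSize, 0L)
      big <- s >= mcs
      if (all(big)) {
        # true split: remaining points leave cid, two children are born
        stability[cid] <- stability[cid] +
          sum(s) * (lam - birth[cid])
        for (k in 1:2) {
          sub <- newCluster(nodePoints(ch[k]), lam, cid)
          if (ch[k] > 0L) tasks[[length(tasks) + 1L]] <-
              list(node = ch[k], cid = sub)
        }
        break
      } else if (any(big)) {
        small <- which(!big)
        stability[cid] <- stability[cid] + s[small] * (lam - birth[cid])
        node <- ch[which(big)]
        if (node < 0L) break  # cannot happen: a leaf is never >= mcs >= 2
      } else {
        # cluster dissolves: everything left leaves at this level
        stability[cid] <- stability[cid] + sum(s) * (lam - birth[cid])
        break
      }
    }
  }
  list(members = members, birth = birth, parent = parent,
       stability = stability, children = children, root = root_id)
}

# Excess-of-mass cluster selection over the condensed tree: keep a cluster
# when it is more stable than the sum of its selected descendants.  The root
# is never selected.
selectEOM <- function(ct) {
  m <- length(ct$members)
  if (m <= 1L) return(integer(0))
  selected <- rep(FALSE, m)
  propagated <- numeric(m)
  descendants <- function(id) {
    out <- integer(0); stack <- ct$children[[id]]
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      out <- c(out, v); stack <- c(stack, ct$children[[v]])
    }
    out
  }
  for (id in rev(seq_len(m))) {  # children are created after their parents
    kids <- ct$children[[id]]
    if (id == ct$root) next
    if (!length(kids)) {
      selected[id] <- TRUE
      propagated[id] <- ct$stability[id]
    } else {
      cs <- sum(propagated[kids])
      if (ct$stability[id] >= cs) {
        selected[id] <- TRUE
        selected[descendants(id)] <- FALSE
        propagated[id] <- ct$stability[id]
      } else {
        propagated[id] <- cs
      }
    }
  }
  which(selected)
}
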