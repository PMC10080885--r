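# Ensemble clustering: combine base clustering solutions through their
# co-association (evidence) matrix.  Base clusters become nodes of a block
# graph; maximal cliques of sufficiently evidence-linked blocks propose
# consensus clusters; conflicts are resolved by mean evidence; undersized
# clusters are dropped and leftover features can be reattached.

#' Evidence (co-association) matrix of a set of clusterings
#'
#' Entry (i, j) is the fraction of base solutions that place features i and j
#' in the same cluster; a noise assignment counts as "not co-clustered".
#' The diagonal is 1 by convention.
#'
#' @param label_matrix integer matrix, solutions x features (noise = -1).
#' @return symmetric numeric matrix in \[0, 1\].
#' @export
evidenceMatrix <- function(label_matrix) {
  n <- ncol(label_matrix)
  E <- matrix(0, n, n)
  for (b in seq_len(nrow(label_matrix))) {
    lab <- label_matrix[b, ]
    same <- outer(lab, lab, "==") & lab != -1L &
      matrix(lab != -1L, n, n, byrow = TRUE)
    E <- E + same
  }
  E <- E / nrow(label_matrix)
  diag(E) <- 1
  colnames(E) <- rownames(E) <- colnames(label_matrix)
  E
}

# Core consensus procedure shared by clicomEnsemble and clusterReplicates.
consensusFromLabels <- function(label_matrix, cfg, feature_names) {
  n <- ncol(label_matrix)
  E <- evidenceMatrix(label_matrix)
  thr <- cfg@evidence_threshold
  # blocks: every base cluster from every solution
  blocks <- list()
  for (b in seq_len(nrow(label_matrix))) {
    lab <- label_matrix[b, ]
    for (cl in sort(unique(lab[lab != -1L])))
      blocks[[length(blocks) + 1L]] <- which(lab == cl)
  }
  nb <- length(blocks)
  if (nb > 5000L) stop("too many cluster blocks (", nb, " > 5000)")
  labels <- rep(-1L, n)
  names(labels) <- feature_names
  if (nb == 0L) {
    warning("no base clusters; empty solution")
    return(new("ClusteringSolution", labels = labels,
               setup = list(algorithm = "clicom", cfg = cfg)))
  }
  # block graph: edge when mean pairwise evidence between members >= threshold
  adj <- matrix(FALSE, nb, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)[-seq_len(i)]) {
      adj[i, j] <- adj[j, i] <-
        mean(E[blocks[[i]], blocks[[j]]]) >= thr
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  cliques <- lapply(cliques, function(q) sort(as.integer(q)))
  # canonical clique order: size desc, then lexicographic block indices
  keys <- vapply(cliques, function(q)
    paste(sprintf("%06d", q), collapse = ","), "")
  ord <- order(-vapply(cliques, length, 0L), keys)
  cliques <- cliques[ord]
  # candidate cluster per clique: features in >= threshold fraction of blocks
  candidates <- lapply(cliques, function(q) {
    cnt <- integer(n)
    for (bk in q) cnt[blocks[[bk]]] <- cnt[blocks[[bk]]] + 1L
    which(cnt / length(q) >= thr)
  })
  keep <- lengths(candidates) > 0L
  cliques <- cliques[keep]; candidates <- candidates[keep]
  # resolve multiply-claimed features: highest mean evidence to the
  # candidate's members; ties -> larger clique, then lower clique index
  claim <- integer(n)  # 0 = unclaimed
  for (f in seq_len(n)) {
    owners <- which(vapply(candidates, function(cc) f %in% cc, TRUE))
    if (length(owners) == 0L) next
    if (length(owners) > 1L) {
      score <- vapply(owners, function(ci) {
        others <- setdiff(candidates[[ci]], f)
        if (length(others)) mean(E[f, others]) else 0
      }, 0)
      qsize <- vapply(owners, function(ci) length(cliques[[ci]]), 0L)
      best <- order(-score, -qsize, owners)[1L]
      owners <- owners[best]
    }
    claim[f] <- owners
  }
  clusters <- split(seq_len(n), claim)
  clusters <- clusters[names(clusters) != "0"]
  # min-size filter
  clusters <- clusters[lengths(clusters) >= cfg@min_cluster_size]
  if (length(clusters) == 0L) {
    warning("all consensus clusters smaller than min_cluster_size; ",
            "empty solution")
    return(new("ClusteringSolution", labels = labels,
               setup = list(algorithm = "clicom", cfg = cfg)))
  }
  # optional reattachment of unclustered features
  if (cfg@attach_unclustered) {
    assigned <- unlist(clusters, use.names = FALSE)
    for (f in setdiff(seq_len(n), assigned)) {
      score <- vapply(clusters, function(cl)
        mean(E[f, setdiff(cl, f)]), 0)
      if (max(score) >= thr) {
        ci <- which.max(score)
        clusters[[ci]] <- c(clusters[[ci]], f)
      }
    }
  }
  # stable numbering: by decreasing size, ties by smallest member index
  ord <- order(-lengths(clusters),
               vapply(clusters, min, 0L))
  clusters <- clusters[ord]
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  new("ClusteringSolution", labels = labels,
      setup = list(algorithm = "clicom", cfg = cfg))
}

#' Ensemble clustering over multiple base setups
#'
#' Runs every setup in the configuration, builds the evidence matrix, and
#' extracts consensus clusters through maximal cliques of the block graph
#' (see the package vignette for the full procedure).  Clusters smaller than
#' `min_cluster_size` are dropped; when every cluster is dropped an empty
#' (all-noise) solution is returned with a warning.
#'
#' @param m a (transformed) [CountMatrix-class] or numeric matrix.
#' @param cfg an [EnsembleConfig-class].
#' @return A [ClusteringSolution-class] (noise = -1).
#' @export
clicomEnsemble <- function(m, cfg) {
  v <- if (is(m, "CountMatrix")) m@values else m
  sols <- lapply(cfg@setups, function(s) runClusterer(v, s)@labels)
  label_matrix <- do.call(rbind, sols)
  colnames(label_matrix) <- rownames(v)
  consensusFromLabels(label_matrix, cfg, rownames(v))
}

#' Ensemble clustering across replicate batches
#'
#' Each batch (e.g. a batch of replicates) is clustered separately with every
#' setup; all solutions are pooled into a single ensemble consensus.  Batches
#' must share the same feature universe.
#'
#' @param batches list of [CountMatrix-class] or numeric matrices over the
#'   same features.
#' @param cfg an [EnsembleConfig-class].
#' @return A [ClusteringSolution-class].
#' @export
clusterReplicates <- function(batches, cfg) {
  mats <- lapply(batches, function(b)
    if (is(b, "CountMatrix")) b@values else b)
  ref <- rownames(mats[[1L]])
  for (i in seq_along(mats)[-1L]) {
    extra <- setdiff(rownames(mats[[i]]), ref)
    miss <- setdiff(ref, rownames(mats[[i]]))
    if (length(extra) || length(miss))
      stop("batch ", i, " feature mismatch; missing: ",
           paste(utils::head(miss, 5), collapse = ", "),
           "; extra: ", paste(utils::head(extra, 5), collapse = ", "))
    mats[[i]] <- mats[[i]][ref, , drop = FALSE]
  }
  sols <- list()
  for (mt in mats) {
    for (s in cfg@setups)
      sols[[length(sols) + 1L]] <- runClusterer(mt, s)@labels
  }
  label_matrix <- do.call(rbind, sols)
  colnames(label_matrix) <- ref
  consensusFromLabels(label_matrix, cfg, ref)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two cluster assignments over the same
#' objects; 1 means identical partitions up to label permutation.
#'
#' @param a,b integer label vectors of equal length.
#' @return numeric in \[-1, 1\].
#' @export
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(length(a))
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
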