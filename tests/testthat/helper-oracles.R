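# Independent oracles and fixture builders. These deliberately use naive
# per-site loops / exhaustive enumeration, separate from the package's
# vectorized code paths.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_MISSING <- c("-", "N", "?", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# p-distance by per-site enumeration
naive_p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1L]]
  diff <- 0L; n <- 0L
  for (k in seq_along(a)) {
    ca <- toupper(a[[k]]); cb <- toupper(b[[k]])
    if (ca %in% ORACLE_BASES && cb %in% ORACLE_BASES) {
      n <- n + 1L
      if (ca != cb) diff <- diff + 1L
    }
  }
  list(p = if (n == 0L) NA_real_ else diff / n, overlap = n)
}

naive_distance_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d[i, j] <- naive_p_distance(mat[i, ], mat[j, ])$p
  }
  d
}

# pure-diagnostic detection by per-species, per-site loops
naive_diagnostics <- function(aln, scope = NULL, min_observed = 1) {
  records <- aln$records
  if (is.null(scope)) scope <- unique(records$species[records$role == "ingroup"])
  out <- list()
  for (s in scope) {
    own <- aln$matrix[records$species == s, , drop = FALSE]
    for (j in seq_len(ncol(aln$matrix))) {
      col <- own[, j]
      col <- col[col %in% ORACLE_BASES]
      if (length(col) < min_observed) next
      if (length(unique(col)) != 1L) next
      x <- col[[1L]]
      clash <- FALSE
      for (o in setdiff(scope, s)) {
        oc <- aln$matrix[records$species == o, j]
        if (any(oc[oc %in% ORACLE_BASES] == x)) { clash <- TRUE; break }
      }
      if (!clash) out[[length(out) + 1L]] <-
        data.frame(species = s, site = j, state = x, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), site = integer(0), state = character(0))
}

# exhaustive least-squares topology fit: enumerate all unrooted topologies for
# small n, fit branch lengths by OLS on path incidence, return the tree with
# minimal residual sum of squares
ls_best_topology <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
  pair_idx <- which(upper.tri(D), arr.ind = TRUE)
  y <- D[upper.tri(D)]
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]   # [[.multiPhylo restores the compressed tip labels
    if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
    nedge <- nrow(tr$edge)
    X <- matrix(0, length(y), nedge)
    # edges on the path between two tips, via node paths to a common point
    for (r in seq_len(nrow(pair_idx))) {
      t1 <- which(tr$tip.label == ids[pair_idx[r, 1L]])
      t2 <- which(tr$tip.label == ids[pair_idx[r, 2L]])
      p <- ape::nodepath(tr, t1, t2)
      for (k in seq_len(length(p) - 1L)) {
        e <- which((tr$edge[, 1L] == p[k] & tr$edge[, 2L] == p[k + 1L]) |
                     (tr$edge[, 1L] == p[k + 1L] & tr$edge[, 2L] == p[k]))
        X[r, e] <- 1
      }
    }
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      tr$edge.length <- fit$coefficients
      best <- tr
    }
  }
  list(tree = best, rss = best_rss)
}

# random alignment with optional missing symbols
rand_alignment <- function(n, L, miss_prob = 0.1, ids = sprintf("s%02d", seq_len(n))) {
  chars <- sample(ORACLE_BASES, n * L, replace = TRUE)
  if (miss_prob > 0) {
    miss <- runif(n * L) < miss_prob
    chars[miss] <- sample(ORACLE_MISSING, sum(miss), replace = TRUE)
  }
  mat <- matrix(chars, nrow = n, dimnames = list(ids, NULL))
  # keep the per-row "at least one determined base" invariant
  for (i in seq_len(n)) {
    if (!any(mat[i, ] %in% ORACLE_BASES)) mat[i, 1L] <- sample(ORACLE_BASES, 1L)
  }
  mat
}

# wrap a character matrix as a labeled alignment, one species per group
as_labeled <- function(mat, species, role = NULL) {
  if (is.null(role)) role <- rep("ingroup", nrow(mat))
  structure(list(matrix = mat,
                 records = data.frame(seq_id = rownames(mat),
                                      species = species, role = role,
                                      stringsAsFactors = FALSE)),
            class = "labeled_alignment")
}

# random additive distance matrix: path lengths of a random binary tree
rand_additive <- function(n, ids = sprintf("t%02d", seq_len(n))) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = ids)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[ids, ids])
}

split_set <- function(tr) sort(unname(barcodegap:::tree_splits(tr)))
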