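#' Neighbor-joining tree from a p-distance matrix
#'
#' Classical Saitou–Nei agglomeration: at each step the pair minimizing the
#' rate-corrected criterion Q(i,j) = (r-2) d(i,j) - R(i) - R(j) is joined,
#' with branch lengths from the standard two-point formulas. Ties in Q are
#' broken by the smallest (row, column) index pair in the current working
#' order, so the result is deterministic. On an additive distance matrix the
#' tree's path-length matrix reproduces the input.
#'
#' Negative branch lengths (legitimate NJ arithmetic on non-additive input)
#' are retained by default; `clamp_negative = TRUE` maps each negative edge to
#' zero and transfers the deficit to the adjacent edge created at the same
#' join, preserving path lengths through the new node.
#'
#' @param dm A `p_distmat` (no undefined entries allowed) or a plain symmetric
#'   numeric matrix with dimnames.
#' @param clamp_negative Clamp negative branch lengths to zero (default
#'   `FALSE`, matching the usual distance-software behaviour of reporting
#'   them as-is).
#' @return An unrooted `phylo` tree (class from \pkg{ape}) with tip labels
#'   equal to the matrix ids.
#' @export
neighbor_joining <- function(dm, clamp_negative = FALSE) {
  D <- if (inherits(dm, "p_distmat")) dm$d else as.matrix(dm)
  n <- nrow(D)
  if (n < 3L) stop("neighbor-joining needs at least 3 sequences, got ", n)
  if (any(is.na(D))) {
    bad <- which(is.na(D), arr.ind = TRUE)[1L, ]
    stop("distance matrix has undefined entries (e.g. ",
         rownames(D)[bad[[1L]]], " vs ", colnames(D)[bad[[2L]]],
         "); pairs with no shared determined sites cannot be joined")
  }
  ids <- rownames(D)
  frag <- ids                      # newick fragment per active node
  fmt <- function(x) sprintf("%.15g", x)

  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest (row, column) pair among the minima, in current working order
    qmin <- min(Q)
    hit <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (clamp_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
    n <- n - 1L
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) {
    for (k in 1:3) {
      ls <- c(l1, l2, l3)
      if (ls[k] < 0) {
        other <- which.max(ls)
        ls[other] <- ls[other] + ls[k]; ls[k] <- 0
        l1 <- ls[1]; l2 <- ls[2]; l3 <- ls[3]
      }
    }
  }
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2), ",",
                frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys for every internal edge of an unrooted tree.
# A split is keyed by the sorted tip labels of the block NOT containing the
# lexicographically smallest tip, so keys are comparable across trees with
# different tip orders/rootings. Returns a character vector named by the
# internal node number owning the edge (the child end); trivial splits are
# dropped.
tree_splits <- function(tr) {
  ntip <- length(tr$tip.label)
  ref <- sort(tr$tip.label)[[1L]]
  pp <- ape::prop.part(tr)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    node <- ntip + k
    tips <- tr$tip.label[pp[[k]]]
    if (ref %in% tips) tips <- setdiff(tr$tip.label, tips)
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    keys <- c(keys, paste(sort(tips), collapse = "\r"))
    nodes <- c(nodes, node)
  }
  names(keys) <- nodes
  keys
}

split_key <- function(tips, all_tips) {
  ref <- sort(all_tips)[[1L]]
  if (ref %in% tips) tips <- setdiff(all_tips, tips)
  paste(sort(tips), collapse = "\r")
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the NJ tree of the full alignment, then resamples alignment columns
#' with replacement `replicates` times; each replicate's p-distance matrix and
#' NJ tree are recomputed, and each internal edge of the original tree is
#' annotated with the percentage of replicate trees containing the same
#' bipartition. Replicates whose resampled matrix contains a pair with no
#' shared determined site are redrawn (the redraw count is capped at ten times
#' the replicate count).
#'
#' @param aln A `labeled_alignment`.
#' @param replicates Number of bootstrap replicates (default 1000, the field's
#'   customary default).
#' @param seed Integer seed; the whole computation is reproducible given
#'   (alignment, replicates, seed). `NULL` uses the current RNG state.
#' @param clamp_negative Passed to [neighbor_joining()].
#' @return The original NJ `phylo` tree with `node.label` holding rounded
#'   support percentages (empty at the root and for any edge never tested),
#'   plus attributes `replicates` and `redraws`.
#' @export
bootstrap_supports <- function(aln, replicates = 1000, seed = NULL,
                               clamp_negative = FALSE) {
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  code <- encode_alignment(aln)
  L <- ncol(code)
  tr <- neighbor_joining(distance_matrix(aln), clamp_negative = clamp_negative)
  orig <- tree_splits(tr)
  counts <- setNames(integer(length(orig)), orig)
  redraws <- 0L
  max_redraws <- 10L * replicates
  done <- 0L
  while (done < replicates) {
    cols <- sample.int(L, L, replace = TRUE)
    dmat <- dist_from_code(code[, cols, drop = FALSE])
    if (any(is.na(dmat))) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("bootstrap redraw cap exceeded: resampled alignments keep ",
             "producing pairs with no shared determined sites")
      }
      next
    }
    rep_tr <- neighbor_joining(dmat, clamp_negative = clamp_negative)
    rep_splits <- tree_splits(rep_tr)
    hit <- orig %in% rep_splits
    counts[hit] <- counts[hit] + 1L
    done <- done + 1L
  }
  lab <- rep("", tr$Nnode)
  node_idx <- as.integer(names(orig)) - length(tr$tip.label)
  lab[node_idx] <- as.character(round(100 * counts / replicates))
  tr$node.label <- lab
  attr(tr, "replicates") <- replicates
  attr(tr, "redraws") <- redraws
  tr
}

# p-distance matrix straight from an integer-coded alignment (NA = missing);
# used in the bootstrap inner loop.
dist_from_code <- function(code) {
  n <- nrow(code)
  det <- !is.na(code)
  d <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]; oki <- det[i, ]
    for (j in (i + 1L):n) {
      ok <- oki & det[j, ]
      m <- sum(ok)
      d[i, j] <- d[j, i] <-
        if (m == 0L) NA_real_ else sum(xi[ok] != code[j, ok]) / m
    }
  }
  d
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written in full precision; bootstrap supports (when
#' present as `node.label`) appear as internal node labels, the conventional
#' place identification software prints them.
#'
#' @param tr A `phylo` tree.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tr, path = NULL) {
  s <- ape::write.tree(tr, digits = 15)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Per-species monophyly report
#'
#' A species is monophyletic when the bipartition (its tips | everything
#' else) occurs in the tree; the reported support is that edge's bootstrap
#' label when available. Single-specimen species are trivially monophyletic
#' with support `NA`. A final row `"<ingroup>"` reports the monophyly of the
#' ingroup as a whole with respect to the outgroups (when any are present).
#'
#' @param tr A `phylo` tree, typically from [bootstrap_supports()].
#' @param records Specimen records data frame.
#' @return Data frame: `species`, `n_tips`, `monophyletic`, `support`.
#' @export
monophyly_report <- function(tr, records) {
  tips <- tr$tip.label
  all_species <- unique(records$species)
  records <- records[records$seq_id %in% tips, , drop = FALSE]
  skipped <- setdiff(all_species, unique(records$species))
  if (length(skipped)) warning("species with no tips in tree skipped: ",
                               paste(skipped, collapse = ", "))
  splits <- tree_splits(tr)
  supports <- if (!is.null(tr$node.label)) {
    setNames(suppressWarnings(as.numeric(
      tr$node.label[as.integer(names(splits)) - length(tips)])), splits)
  } else setNames(rep(NA_real_, length(splits)), splits)

  check_set <- function(members) {
    n <- length(members)
    if (n == 1L || n >= length(tips) - 1L) {
      return(list(mono = TRUE, sup = NA_real_))
    }
    key <- split_key(members, tips)
    if (key %in% splits) list(mono = TRUE, sup = unname(supports[key]))
    else list(mono = FALSE, sup = NA_real_)
  }

  species <- unique(records$species[records$role == "ingroup"])
  rows <- lapply(species, function(s) {
    members <- records$seq_id[records$species == s]
    r <- check_set(members)
    data.frame(species = s, n_tips = length(members),
               monophyletic = r$mono, support = r$sup,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ingroup <- records$seq_id[records$role == "ingroup"]
  if (length(ingroup) < length(tips) && length(ingroup) >= 1L) {
    r <- check_set(ingroup)
    out <- rbind(out, data.frame(species = "<ingroup>",
                                 n_tips = length(ingroup),
                                 monophyletic = r$mono, support = r$sup,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
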