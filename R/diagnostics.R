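#' Alignment site statistics
#'
#' Counts variable sites (at least two distinct determined states) and
#' parsimony-informative sites (at least two states each carried by at least
#' two sequences). Gaps, `N`, `?` and ambiguity codes never count as states.
#'
#' @param aln A `labeled_alignment` or character matrix.
#' @return A list: `L` (alignment length), `variable`,
#'   `parsimony_informative`.
#' @export
site_statistics <- function(aln) {
  code <- encode_alignment(aln)
  L <- ncol(code)
  variable <- 0L
  informative <- 0L
  for (j in seq_len(L)) {
    cnt <- tabulate(code[, j], nbins = 4L)
    states <- sum(cnt > 0L)
    if (states >= 2L) {
      variable <- variable + 1L
      if (sum(cnt >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  list(L = L, variable = variable, parsimony_informative = informative)
}

#' Pure diagnostic nucleotide sites per species
#'
#' A site is a pure diagnostic for a focal species when (a) every determined
#' base the focal species carries at that site is one and the same state, with
#' at least `min_observed` members actually determined there, and (b) no other
#' species in the comparison universe carries that state at that site among
#' its determined bases. Species wholly undetermined at a site cannot
#' contradict a diagnostic there. This is the character-based ("pure"
#' characters) species-delimitation criterion.
#'
#' @param aln A `labeled_alignment`.
#' @param scope Character vector of species forming the comparison universe;
#'   the default uses all ingroup species (outgroups excluded from the purity
#'   test, per the usual convention that they only anchor the tree).
#' @param min_observed Minimum number of determined focal bases required at a
#'   site (default 1, so single-specimen species can own diagnostics;
#'   fixation observed once is weak evidence, hence the knob).
#' @return An object of class `diagnostic_table`: list with `entries` (data
#'   frame `species`, `site` (1-based alignment column), `state`,
#'   `n_observed_focal`, `n_missing_focal`; zero-row for species with no
#'   diagnostics, but every scoped species appears in `species_levels`),
#'   `species_levels`, `per_species_count`, and `aln` (kept for matrix
#'   rendering).
#' @export
pure_diagnostic_sites <- function(aln, scope = NULL, min_observed = 1) {
  stopifnot(inherits(aln, "labeled_alignment"), min_observed >= 1)
  records <- aln$records
  if (is.null(scope)) {
    scope <- unique(records$species[records$role == "ingroup"])
  }
  absent <- setdiff(scope, unique(records$species))
  if (length(absent)) stop("species in scope but absent from alignment: ",
                           paste(absent, collapse = ", "))
  if (length(scope) < 2L) stop("need at least two species in scope")
  code <- encode_alignment(aln)
  L <- ncol(code)

  # per-species per-site state counts: counts[[s]] is 4 x L
  counts <- lapply(scope, function(s) {
    rows <- code[records$species == s, , drop = FALSE]
    vapply(seq_len(L), function(j) tabulate(rows[, j], nbins = 4L), integer(4))
  })
  names(counts) <- scope
  # L x S determined counts
  observed <- matrix(vapply(counts, colSums, numeric(L)), nrow = L,
                     dimnames = list(NULL, scope))
  n_members <- vapply(scope, function(s) sum(records$species == s), integer(1))

  entries <- list()
  for (s in scope) {
    cs <- counts[[s]]                    # 4 x L
    nstates <- colSums(cs > 0L)
    fixed <- nstates == 1L & observed[, s] >= min_observed
    if (!any(fixed)) next
    state_idx <- apply(cs[, fixed, drop = FALSE], 2L, which.max)
    sites <- which(fixed)
    # purity: no other scoped species carries the focal state
    others <- setdiff(scope, s)
    pure <- vapply(seq_along(sites), function(k) {
      j <- sites[[k]]; x <- state_idx[[k]]
      all(vapply(others, function(o) counts[[o]][x, j] == 0L, logical(1)))
    }, logical(1))
    if (!any(pure)) next
    sites <- sites[pure]; state_idx <- state_idx[pure]
    entries[[s]] <- data.frame(
      species = s, site = sites, state = BASES[state_idx],
      n_observed_focal = observed[sites, s],
      n_missing_focal = n_members[[s]] - observed[sites, s],
      stringsAsFactors = FALSE)
  }
  tab <- if (length(entries)) do.call(rbind, entries) else
    data.frame(species = character(0), site = integer(0), state = character(0),
               n_observed_focal = numeric(0), n_missing_focal = numeric(0))
  tab <- tab[order(match(tab$species, scope), tab$site), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(entries = tab, species_levels = scope,
                 per_species_count = setNames(
                   as.integer(table(factor(tab$species, levels = scope))),
                   scope),
                 aln = aln),
            class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat("Pure diagnostic sites: ", nrow(x$entries), " entries across ",
      length(x$species_levels), " species\n", sep = "")
  print(x$per_species_count)
  invisible(x)
}

#' Species-by-site diagnostic state matrix
#'
#' Renders the character-based delimitation result as a species x site grid:
#' columns are the union of all diagnostic sites in ascending order, each cell
#' is the state a species carries there (`-` when all its members are
#' undetermined, `*`-suffixed when polymorphic within the species), and
#' diagnostic cells are flagged. `as.data.frame` on the result gives the grid;
#' `format` gives the printable text.
#'
#' @param table A `diagnostic_table`.
#' @return A list with `grid` (character matrix, species x sites),
#'   `diagnostic` (logical matrix, same shape), `sites` (1-based columns).
#' @export
diagnostic_report <- function(table) {
  stopifnot(inherits(table, "diagnostic_table"))
  sites <- sort(unique(table$entries$site))
  species <- table$species_levels
  code <- encode_alignment(table$aln)
  records <- table$aln$records
  grid <- matrix("-", length(species), length(sites),
                 dimnames = list(species, as.character(sites)))
  flag <- matrix(FALSE, length(species), length(sites),
                 dimnames = dimnames(grid))
  for (si in seq_along(sites)) {
    j <- sites[[si]]
    for (sp in species) {
      col <- code[records$species == sp, j]
      col <- col[!is.na(col)]
      if (length(col) == 0L) next
      u <- unique(col)
      grid[sp, si] <- if (length(u) == 1L) BASES[u] else
        paste0(BASES[u[which.max(tabulate(col, 4L))]], "*")
    }
  }
  for (k in seq_len(nrow(table$entries))) {
    flag[table$entries$species[[k]],
         as.character(table$entries$site[[k]])] <- TRUE
  }
  list(grid = grid, diagnostic = flag, sites = sites)
}
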