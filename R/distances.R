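#' Pairwise p-distance under pairwise deletion
#'
#' Proportion of sites at which two aligned sequences differ, computed over
#' the sites where both carry an unambiguous base (pairwise deletion). Gaps,
#' `N`, `?` and IUPAC ambiguity codes never contribute.
#'
#' @param a,b Aligned sequences: character vectors of equal length, or
#'   single strings.
#' @return A list with `p` (proportion in \[0, 1\], `NA` when no site is
#'   determined in both sequences) and `overlap` (number of sites compared).
#' @examples
#' p_distance("AC-GT", "ACAGA")  # site 3 dropped, 1 difference in 4 -> 0.25
#' @export
p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) {
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  }
  ca <- match(toupper(a), BASES)
  cb <- match(toupper(b), BASES)
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  list(p = if (n == 0L) NA_real_ else sum(ca[ok] != cb[ok]) / n, overlap = n)
}

#' Full p-distance matrix for a labeled alignment
#'
#' @param aln A `labeled_alignment` (or a plain character matrix with row
#'   names).
#' @return An object of class `p_distmat`: a list with `ids`, `d` (symmetric
#'   matrix of proportions, `NA` where a pair shares no determined site, zero
#'   diagonal) and `overlap` (symmetric integer matrix of per-pair compared
#'   site counts; the diagonal holds each row's number of determined sites).
#' @export
distance_matrix <- function(aln) {
  code <- encode_alignment(aln)
  n <- nrow(code)
  ids <- rownames(code)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ov <- matrix(0L, n, n, dimnames = list(ids, ids))
  det <- !is.na(code)
  diag(ov) <- as.integer(rowSums(det))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      xi <- code[i, ]
      oki <- det[i, ]
      for (j in (i + 1L):n) {
        ok <- oki & det[j, ]
        m <- sum(ok)
        ov[i, j] <- ov[j, i] <- m
        d[i, j] <- d[j, i] <-
          if (m == 0L) NA_real_ else sum(xi[ok] != code[j, ok]) / m
      }
    }
  }
  structure(list(ids = ids, d = d, overlap = ov), class = "p_distmat")
}

#' @export
print.p_distmat <- function(x, ...) {
  n <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat("p-distance matrix: ", n, " sequences, ", sum(is.na(off)),
      " undefined pair(s)\n", sep = "")
  if (length(off) && any(!is.na(off))) {
    cat(sprintf("range of defined distances: %.4f .. %.4f\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-species intra- and interspecific distance summaries
#'
#' For each species, summarizes the set of intraspecific pairwise distances
#' (all unordered pairs within the species) and interspecific distances (all
#' pairs against members of every other in-scope species): minimum, maximum,
#' arithmetic mean, and sample standard deviation (n-1 denominator). Intra
#' fields are `NA` for single-specimen species; with exactly one pair in a set
#' the SD is reported as 0. Pairs with no shared determined site are excluded
#' (a message reports the count). Group-level aggregates report the overall
#' intraspecific maximum and the overall interspecific minimum/maximum, with
#' the species pair attaining the minimum.
#'
#' @param dm A `p_distmat`.
#' @param records Specimen records data frame (`seq_id`, `species`, `role`).
#' @param scope `"ingroup_only"` (default) restricts to ingroup species;
#'   `"all"` includes outgroup species as species of their own.
#' @return A list with `table` (one row per species: `species`, `n`,
#'   `n_intra_pairs`, `intra_min/max/mean/sd`, `n_inter_pairs`,
#'   `inter_min/max/mean/sd`) and `aggregates` (`intra_max`, `inter_min`,
#'   `inter_max`, `inter_min_pair`).
#' @export
species_summaries <- function(dm, records, scope = c("ingroup_only", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(dm, "p_distmat"))
  if (!all(dm$ids %in% records$seq_id)) {
    stop("distance matrix id(s) missing from records: ",
         paste(setdiff(dm$ids, records$seq_id), collapse = ", "))
  }
  records <- records[match(dm$ids, records$seq_id), , drop = FALSE]
  in_scope <- if (scope == "ingroup_only") records$role == "ingroup" else
    rep(TRUE, nrow(records))
  sp <- records$species
  species <- unique(sp[in_scope])
  if (length(species) < 2L) stop("need at least two species in scope")

  n_dropped <- 0L
  pair_set <- function(rows_a, rows_b, within = FALSE) {
    if (within) {
      if (length(rows_a) < 2L) return(numeric(0))
      v <- dm$d[rows_a, rows_a][upper.tri(diag(length(rows_a)))]
    } else {
      v <- as.vector(dm$d[rows_a, rows_b, drop = FALSE])
    }
    n_dropped <<- n_dropped + sum(is.na(v))
    v[!is.na(v)]
  }
  summ <- function(v) {
    if (length(v) == 0L) {
      return(c(min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_))
    }
    c(min = min(v), max = max(v), mean = mean(v),
      sd = if (length(v) == 1L) 0 else sd(v))
  }

  rows <- lapply(species, function(s) {
    own <- which(sp == s)
    others <- which(in_scope & sp != s)
    intra <- pair_set(own, within = TRUE)
    inter <- pair_set(own, others)
    if (length(inter) == 0L && length(intra) == 0L && length(own) >= 2L) {
      stop("all pairwise distances undefined for species ", s)
    }
    si <- summ(intra); se <- summ(inter)
    data.frame(species = s, n = length(own),
               n_intra_pairs = length(intra),
               intra_min = si[["min"]], intra_max = si[["max"]],
               intra_mean = si[["mean"]], intra_sd = si[["sd"]],
               n_inter_pairs = length(inter),
               inter_min = se[["min"]], inter_max = se[["max"]],
               inter_mean = se[["mean"]], inter_sd = se[["sd"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (n_dropped > 0L) {
    message("excluded ", n_dropped,
            " undefined (zero-overlap) pair distance(s) from summaries")
  }

  # group aggregates over in-scope pairs only
  idx <- which(in_scope)
  inter_min <- Inf; inter_max <- -Inf; inter_pair <- c(NA, NA)
  intra_max <- suppressWarnings(max(tab$intra_max, na.rm = TRUE))
  if (!is.finite(intra_max)) intra_max <- NA_real_
  for (i in idx) for (j in idx) {
    if (j <= i || sp[i] == sp[j]) next
    v <- dm$d[i, j]
    if (is.na(v)) next
    if (v < inter_min) { inter_min <- v; inter_pair <- sort(c(sp[i], sp[j])) }
    if (v > inter_max) inter_max <- v
  }
  list(table = tab,
       aggregates = list(intra_max = intra_max,
                         inter_min = if (is.finite(inter_min)) inter_min else NA_real_,
                         inter_max = if (is.finite(inter_max)) inter_max else NA_real_,
                         inter_min_pair = inter_pair))
}

#' Render a species summary table, optionally in percent
#'
#' @param summaries Result of [species_summaries()].
#' @param percent If `TRUE`, distance columns are multiplied by 100.
#' @param digits Rounding for the rendered values (default 3, matching the
#'   three-decimal proportions conventionally reported).
#' @return A data frame ready for writing.
#' @export
format_summary_table <- function(summaries, percent = FALSE, digits = 3) {
  tab <- summaries$table
  num <- grep("^(intra|inter)_(min|max|mean|sd)$", names(tab))
  if (percent) tab[num] <- lapply(tab[num], function(v) v * 100)
  tab[num] <- lapply(tab[num], round, digits = digits)
  tab
}
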