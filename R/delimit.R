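#' Distance- and character-based species delimitation
#'
#' The package's main analysis. From a labeled barcode alignment it computes
#' the pairwise p-distance matrix (pairwise deletion), the per-species intra-
#' and interspecific distance summaries, a neighbor-joining tree with
#' column-bootstrap supports, per-species monophyly, alignment site
#' statistics, and the pure diagnostic sites per species.
#'
#' @param aln A `labeled_alignment` from [bind_alignment()] or
#'   [simulate_barcodes()].
#' @param replicates Bootstrap replicate count (default 1000).
#' @param seed Integer seed for the bootstrap resampling; `NULL` uses the
#'   current RNG state.
#' @param scope Species scope for summaries and diagnostics:
#'   `"ingroup_only"` (default) or `"all"`.
#' @param min_observed Minimum determined focal bases for a diagnostic site
#'   (see [pure_diagnostic_sites()]).
#' @param clamp_negative Clamp negative NJ branch lengths (see
#'   [neighbor_joining()]).
#' @return An object of class `barcode_delim` with components `aln`, `dist`,
#'   `summary` (per-species table + group aggregates), `tree` (supports as
#'   node labels), `monophyly`, `sitestats`, `diagnostics`, `barcode_gap`
#'   (overall intra max, inter min, and whether max intra < min inter), and
#'   the matched `call`.
#' @examples
#' sim <- simulate_barcodes(barcode_sim_config(n_species = 4,
#'   specimens_per_species = c(3, 3, 2, 2), L = 200, seed = 7))
#' fit <- delimit_species(sim$aln, replicates = 20, seed = 7)
#' fit
#' @export
delimit_species <- function(aln, replicates = 1000, seed = NULL,
                            scope = c("ingroup_only", "all"),
                            min_observed = 1, clamp_negative = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(aln, "labeled_alignment"))
  if (!any(aln$records$role == "ingroup")) {
    stop("no ingroup sequences: nothing to delimit")
  }
  dm <- distance_matrix(aln)
  summ <- species_summaries(dm, aln$records, scope = scope)
  tr <- bootstrap_supports(aln, replicates = replicates, seed = seed,
                           clamp_negative = clamp_negative)
  mono <- monophyly_report(tr, aln$records)
  stats <- site_statistics(aln)
  diag_scope <- if (scope == "ingroup_only") NULL else
    unique(aln$records$species)
  diags <- pure_diagnostic_sites(aln, scope = diag_scope,
                                 min_observed = min_observed)
  gap <- list(intra_max = summ$aggregates$intra_max,
              inter_min = summ$aggregates$inter_min,
              present = isTRUE(summ$aggregates$intra_max <
                                 summ$aggregates$inter_min))
  structure(list(aln = aln, dist = dm, summary = summ, tree = tr,
                 monophyly = mono, sitestats = stats, diagnostics = diags,
                 barcode_gap = gap, replicates = replicates, seed = seed,
                 scope = scope, call = match.call()),
            class = "barcode_delim")
}

#' @export
print.barcode_delim <- function(x, ...) {
  cat("Barcode species delimitation\n")
  cat("  alignment: ", nrow(x$aln$matrix), " sequences x ", x$sitestats$L,
      " sites (", x$sitestats$variable, " variable, ",
      x$sitestats$parsimony_informative, " parsimony-informative)\n", sep = "")
  cat("  species:   ", nrow(x$summary$table), " in scope (",
      x$scope, ")\n", sep = "")
  gap <- x$barcode_gap
  cat(sprintf("  barcode gap: max intra %.4f %s min inter %.4f (%s)\n",
              gap$intra_max, if (isTRUE(gap$present)) "<" else ">=",
              gap$inter_min,
              if (isTRUE(gap$present)) "gap present" else "no gap"))
  n_mono <- sum(x$monophyly$monophyletic[x$monophyly$species != "<ingroup>"])
  cat("  monophyly: ", n_mono, "/",
      sum(x$monophyly$species != "<ingroup>"),
      " species monophyletic (", x$replicates, " bootstrap replicates)\n",
      sep = "")
  cat("  diagnostics: ", nrow(x$diagnostics$entries),
      " pure diagnostic site(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.barcode_delim <- function(object, percent = FALSE, ...) {
  out <- list(table = format_summary_table(object$summary, percent = percent),
              aggregates = object$summary$aggregates,
              barcode_gap = object$barcode_gap,
              monophyly = object$monophyly,
              sitestats = object$sitestats,
              diagnostics_per_species = object$diagnostics$per_species_count)
  class(out) <- "summary.barcode_delim"
  out
}

#' @export
print.summary.barcode_delim <- function(x, ...) {
  cat("Per-species p-distance summary:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("\nOverall: max intra %.4f, min inter %.4f (%s - %s)\n",
              x$aggregates$intra_max, x$aggregates$inter_min,
              x$aggregates$inter_min_pair[[1L]],
              x$aggregates$inter_min_pair[[2L]]))
  cat("\nMonophyly:\n")
  print(x$monophyly, row.names = FALSE)
  cat("\nPure diagnostic sites per species:\n")
  print(x$diagnostics_per_species)
  invisible(x)
}

#' @export
plot.barcode_delim <- function(x, show_support = TRUE, ...) {
  ape::plot.phylo(x$tree, ...)
  if (show_support && !is.null(x$tree$node.label)) {
    ape::nodelabels(text = x$tree$node.label, frame = "none", adj = c(1.2, -0.3),
                    cex = 0.7)
  }
  invisible(x)
}
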