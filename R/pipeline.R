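#' Run the full delimitation analysis from files to a report bundle
#'
#' Orchestrates the whole workflow: read and bind the alignment and metadata,
#' compute distances and summaries, build the bootstrapped NJ tree, test
#' monophyly, count site statistics, detect diagnostic sites, and write a
#' plain-text report bundle. Outputs are staged in a temporary directory and
#' moved into place only when every stage has succeeded, so a failed run
#' leaves no partial bundle; re-running with identical inputs and config
#' reproduces identical file contents.
#'
#' Bundle files: `distances.tsv` (long pairwise table), `summary.tsv`
#' (per-species intra/inter Min/Max/Mean/SD), `tree.nwk` (supports as node
#' labels), `monophyly.tsv`, `diagnostics.tsv`, `matrix.tsv` (species x site
#' diagnostic grid), `sitestats.json`, and `run_log.json` (input checksums,
#' config, package version).
#'
#' @param alignment Path to the aligned FASTA file.
#' @param metadata Path to the specimen TSV.
#' @param out_dir Output directory (created if needed).
#' @param replicates,seed,scope,min_observed,clamp_negative Passed to
#'   [delimit_species()]; `seed` defaults to 1 so a bundle is reproducible by
#'   default.
#' @param percent Render distance columns of `summary.tsv` as percentages.
#' @param binding `"strict"` (default) or `"lenient"` id matching between
#'   FASTA and metadata.
#' @return The `barcode_delim` object, invisibly, with attribute `bundle`
#'   naming the written files.
#' @export
run_analysis <- function(alignment, metadata, out_dir,
                         replicates = 1000, seed = 1,
                         scope = "ingroup_only", min_observed = 1,
                         clamp_negative = FALSE, percent = FALSE,
                         binding = "strict") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  aln <- stage("load", {
    mat <- read_fasta_alignment(alignment)
    recs <- read_metadata(metadata)
    bind_alignment(mat, recs, mode = binding)
  })
  fit <- stage("analysis",
    delimit_species(aln, replicates = replicates, seed = seed, scope = scope,
                    min_observed = min_observed,
                    clamp_negative = clamp_negative))

  staging <- tempfile("bundle_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(staging, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }

  files <- stage("report", {
    ids <- fit$dist$ids
    sp <- fit$aln$records$species[match(ids, fit$aln$records$seq_id)]
    pairs <- which(upper.tri(fit$dist$d), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    long <- data.frame(id_a = ids[pairs[, 1L]], id_b = ids[pairs[, 2L]],
                       species_a = sp[pairs[, 1L]], species_b = sp[pairs[, 2L]],
                       p_distance = fit$dist$d[pairs],
                       overlap = fit$dist$overlap[pairs],
                       stringsAsFactors = FALSE)
    rep <- diagnostic_report(fit$diagnostics)
    grid_df <- data.frame(species = rownames(rep$grid), rep$grid,
                          check.names = FALSE, stringsAsFactors = FALSE)
    stats <- fit$sitestats
    jsonlite::write_json(stats, file.path(staging, "sitestats.json"),
                         auto_unbox = TRUE)
    log <- list(
      inputs = list(alignment = unname(tools::md5sum(alignment)),
                    metadata = unname(tools::md5sum(metadata))),
      config = list(replicates = replicates, seed = seed, scope = scope,
                    min_observed = min_observed,
                    clamp_negative = clamp_negative, percent = percent,
                    binding = binding),
      package = list(name = "barcodegap",
                     version = as.character(utils::packageVersion("barcodegap"))))
    jsonlite::write_json(log, file.path(staging, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_newick(fit$tree, file.path(staging, "tree.nwk"))
    c(tsv(long, "distances.tsv"),
      tsv(format_summary_table(fit$summary, percent = percent), "summary.tsv"),
      "tree.nwk",
      tsv(fit$monophyly, "monophyly.tsv"),
      tsv(fit$diagnostics$entries, "diagnostics.tsv"),
      tsv(grid_df, "matrix.tsv"),
      "sitestats.json", "run_log.json")
  })

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in files) {
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }
  attr(fit, "bundle") <- file.path(out_dir, files)
  invisible(fit)
}

#' Write a simulated dataset to FASTA + metadata + truth files
#'
#' Companion to [simulate_barcodes()] for file-based workflows: writes the
#' alignment, the specimen table, and the generator truth (JSON) so the
#' outputs can feed [run_analysis()] or any external tool.
#'
#' @param sim Result of [simulate_barcodes()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta_alignment(sim$aln, paths[["alignment"]])
  write_metadata(sim$aln$records, paths[["metadata"]])
  truth <- sim$truth
  truth$specimen_mutations <- lapply(truth$specimen_mutations, as.integer)
  truth$missing_masks <- lapply(truth$missing_masks, as.integer)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
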