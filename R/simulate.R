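#' Configuration for the synthetic barcode generator
#'
#' Defaults emulate a typical COI barcoding study of a closely related species
#' group: ten species with one to nine specimens each (44 sequences), 664
#' aligned sites, intraspecific divergence well under 1%, interspecific
#' divergence around 10%, three planted diagnostic sites per species, and
#' occasional unsequenced leading/trailing runs shown as gaps.
#'
#' @param n_species Number of ingroup species (>= 2).
#' @param specimens_per_species Integer vector of per-species specimen counts
#'   (recycled to `n_species`); the default mirrors a realistic spread of 1-9
#'   specimens per species.
#' @param L Alignment length in sites.
#' @param inter_sub Expected per-site substitutions from the root to each
#'   species haplotype (default 0.05, putting typical between-species
#'   p-distances near 10%).
#' @param intra_sub Expected per-site substitutions from the species haplotype
#'   to each specimen (default 0.005, putting typical within-species
#'   p-distances near 1%).
#' @param planted_diagnostics Number `k` of diagnostic sites planted per
#'   species; planted sites are disjoint across species.
#' @param missing_end_prob Probability that a specimen has one truncated end.
#' @param missing_end_max Maximum truncation length in sites.
#' @param n_outgroups Number of outgroup sequences, generated at
#'   `outgroup_sub` divergence from the root.
#' @param outgroup_sub Expected per-site substitutions for outgroups.
#' @param seed Integer seed; the full dataset is reproducible from the config.
#' @return A list of class `barcode_sim_config`.
#' @export
barcode_sim_config <- function(n_species = 10,
                               specimens_per_species = c(1, 2, 9, 6, 6, 4, 3, 6, 4, 3),
                               L = 664,
                               inter_sub = 0.05,
                               intra_sub = 0.005,
                               planted_diagnostics = 3,
                               missing_end_prob = 0.2,
                               missing_end_max = 60,
                               n_outgroups = 2,
                               outgroup_sub = 0.15,
                               seed = 1) {
  stopifnot(n_species >= 2, L >= 1, n_outgroups >= 0,
            inter_sub >= 0, inter_sub <= 1, intra_sub >= 0, intra_sub <= 1,
            outgroup_sub >= 0, outgroup_sub <= 1,
            missing_end_prob >= 0, missing_end_prob <= 1,
            planted_diagnostics >= 0)
  specimens_per_species <- rep_len(specimens_per_species, n_species)
  stopifnot(all(specimens_per_species >= 1))
  if (L < n_species * planted_diagnostics) {
    stop("alignment too short: ", n_species, " species x ",
         planted_diagnostics, " planted sites need at least ",
         n_species * planted_diagnostics, " sites, have ", L)
  }
  structure(list(n_species = n_species,
                 specimens_per_species = specimens_per_species,
                 L = L, inter_sub = inter_sub, intra_sub = intra_sub,
                 planted_diagnostics = planted_diagnostics,
                 missing_end_prob = missing_end_prob,
                 missing_end_max = missing_end_max,
                 n_outgroups = n_outgroups, outgroup_sub = outgroup_sub,
                 seed = seed),
            class = "barcode_sim_config")
}

#' Simulate a labeled barcode alignment with known truth
#'
#' Generates a COI-like dataset by (1) drawing a uniform random root sequence;
#' (2) deriving each species haplotype by Binomial(L, `inter_sub`) random
#' substitutions (uniform over the three alternative bases); (3) planting `k`
#' disjoint diagnostic sites per species, where the owner carries a non-root
#' state and every other species keeps the root state; (4) deriving each
#' specimen by Binomial(L, `intra_sub`) substitutions that never touch any
#' planted site (so planted diagnostics survive by construction and recovery
#' tests isolate detector correctness from simulation noise); (5) masking,
#' with probability `missing_end_prob`, a uniform-length prefix or suffix
#' (at most `missing_end_max` sites) as `-`; (6) generating outgroups as in
#' step 2 at `outgroup_sub` divergence (no planted-site protection; outgroups
#' are not part of the default purity universe).
#'
#' @param cfg A `barcode_sim_config`.
#' @return A list: `aln` (a `labeled_alignment`) and `truth` (root and
#'   species haplotypes, planted sites/states per species, per-specimen
#'   mutated sites and missing masks, and the closed-form expected distances
#'   from [expected_distance()]).
#' @export
simulate_barcodes <- function(cfg = barcode_sim_config()) {
  stopifnot(inherits(cfg, "barcode_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$L
  S <- cfg$n_species
  species_names <- sprintf("species_%02d", seq_len(S))

  root <- sample(BASES, L, replace = TRUE)

  mutate <- function(seqv, rate, protect = integer(0)) {
    m <- rbinom(1L, L, rate)
    pool <- setdiff(seq_len(L), protect)
    m <- min(m, length(pool))
    sites <- if (m > 0L) pool[sample.int(length(pool), m)] else integer(0)
    for (j in sites) seqv[[j]] <- sample(setdiff(BASES, seqv[[j]]), 1L)
    list(seq = seqv, sites = sort(sites))
  }

  k <- cfg$planted_diagnostics
  planted_sites <- if (k > 0L) {
    matrix(sample(L, S * k), nrow = S)   # row s = species s's planted sites
  } else matrix(integer(0), nrow = S)

  haplos <- vector("list", S)
  planted <- vector("list", S)
  for (s in seq_len(S)) {
    h <- mutate(root, cfg$inter_sub)$seq
    haplos[[s]] <- h
  }
  # planting: non-owners keep the root state, the owner takes a non-root state
  all_planted <- as.integer(planted_sites)
  for (s in seq_len(S)) haplos[[s]][all_planted] <- root[all_planted]
  for (s in seq_len(S)) {
    sites <- sort(planted_sites[s, ])
    states <- character(length(sites))
    for (i in seq_along(sites)) {
      j <- sites[[i]]
      states[[i]] <- sample(setdiff(BASES, root[[j]]), 1L)
      haplos[[s]][[j]] <- states[[i]]
    }
    planted[[s]] <- data.frame(species = rep(species_names[[s]], length(sites)),
                               site = sites, state = states,
                               stringsAsFactors = FALSE)
  }
  names(haplos) <- names(planted) <- species_names

  rows <- list(); recs <- list(); muts <- list(); masks <- list()
  for (s in seq_len(S)) {
    for (i in seq_len(cfg$specimens_per_species[[s]])) {
      id <- sprintf("%s_sp%02d", species_names[[s]], i)
      mu <- mutate(haplos[[s]], cfg$intra_sub, protect = all_planted)
      v <- mu$seq
      mask <- integer(0)
      if (runif(1L) < cfg$missing_end_prob) {
        len <- sample.int(min(cfg$missing_end_max, L - 1L), 1L)
        mask <- if (runif(1L) < 0.5) seq_len(len) else (L - len + 1L):L
        v[mask] <- "-"
      }
      rows[[id]] <- v
      muts[[id]] <- mu$sites
      masks[[id]] <- mask
      recs[[id]] <- data.frame(seq_id = id, species = species_names[[s]],
                               role = "ingroup", stringsAsFactors = FALSE)
    }
  }
  for (o in seq_len(cfg$n_outgroups)) {
    id <- sprintf("outgroup_%02d", o)
    mu <- mutate(root, cfg$outgroup_sub)
    rows[[id]] <- mu$seq
    muts[[id]] <- mu$sites
    masks[[id]] <- integer(0)
    recs[[id]] <- data.frame(seq_id = id, species = sprintf("outsp_%02d", o),
                             role = "outgroup", stringsAsFactors = FALSE)
  }

  mat <- do.call(rbind, rows)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  aln <- structure(list(matrix = mat, records = records),
                   class = "labeled_alignment")
  truth <- list(root = paste(root, collapse = ""),
                haplotypes = vapply(haplos, paste, character(1), collapse = ""),
                planted = do.call(rbind, planted),
                specimen_mutations = muts,
                missing_masks = masks,
                expected = expected_distance(cfg))
  rownames(truth$planted) <- NULL
  list(aln = aln, truth = truth, config = cfg)
}

#' Closed-form expected p-distances for a simulation config
#'
#' Under the generator's scheme every site is hit with probability `r` per
#' round and, when hit, moves to one of the three alternative bases uniformly.
#' A round with rate `r` therefore has the 4x4 transition matrix
#' `(1 - 4r/3) I + (r/3) J`, and rounds compose by multiplying the
#' `(1 - 4r/3)` factors, exactly as in the Jukes-Cantor chain. Two sequences
#' separated by rounds with rates `r1, ..., rm` then differ at a site with
#' probability `3/4 * (1 - prod(1 - 4 r_i / 3))`. For two specimens of one
#' species the rates are (`intra_sub`, `intra_sub`), giving
#' `2 p (1 - p) + (2/3) p^2`; for specimens of two species they are
#' (`intra_sub`, `inter_sub`, `inter_sub`, `intra_sub`). Planted diagnostic
#' sites (guaranteed between-species differences, shielded from within-species
#' change) are not included in these baselines; they raise realized
#' interspecific distances by at most `2k/L`.
#'
#' @param cfg A `barcode_sim_config`.
#' @return A list with `intra` and `inter` expected p-distances.
#' @export
expected_distance <- function(cfg) {
  f <- function(r) 1 - 4 * r / 3
  p_diff <- function(rates) 3 / 4 * (1 - prod(f(rates)))
  list(intra = p_diff(c(cfg$intra_sub, cfg$intra_sub)),
       inter = p_diff(c(cfg$intra_sub, cfg$inter_sub,
                        cfg$inter_sub, cfg$intra_sub)))
}
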