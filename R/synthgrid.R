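## synthgrid: seeded generator of synthetic diced-crown datasets.
##
## The generator emulates the design of the study grid the analysis assumes:
## two molars (a forming M3 and a partially erupted M2) diced into 20 enamel /
## dentin blocks plus one bone reference location (21 locations total), with
## stage-structured protein mean log-abundances, per-peptide response offsets,
## multiplicative log-normal noise on peak areas, left-censoring at a fixed
## detection threshold, and spatially varying phospho-occupancy for the
## bundled marker peptides.

## Protein archetypes: which stages a protein class is elevated in, as
## additive offsets (natural-log units) on top of the protein's baseline.
## The defining-stage offset of 4 (~ 55-fold) matches the order-of-magnitude
## contrasts of stage-restricted enamel matrix proteins.
ARCHETYPES <- list(
  secretory_matrix   = c(secretory = 4, early_maturation = 1.5),
  maturation         = c(early_maturation = 4, late_maturation = 4),
  erupted_surface    = c(erupted = 4),
  dej_interface      = c(DEJ = 4),
  mineralized_tissue = c(dentin = 4, bone = 4),
  ubiquitous         = c(secretory = 1.5, early_maturation = 1.5,
                         late_maturation = 1.5, erupted = 1.5, DEJ = 1.5,
                         dentin = 1.5, bone = 1.5)
)
## Deterministic quota assignment (proportions 25/20/15/15/15/10 percent),
## interleaved so any prefix of proteins is class-balanced and adding
## proteins never reassigns existing ones.
ARCHETYPE_PATTERN <- c(
  "secretory_matrix", "maturation", "erupted_surface", "dej_interface",
  "mineralized_tissue", "ubiquitous",
  "secretory_matrix", "maturation", "erupted_surface", "dej_interface",
  "mineralized_tissue",
  "secretory_matrix", "maturation", "erupted_surface", "dej_interface",
  "mineralized_tissue",
  "secretory_matrix", "maturation",
  "secretory_matrix", "ubiquitous")

#' Default diced-crown grid layout
#'
#' A 21-location layout: two teeth of ten blocks each (two columns of five
#' rows; column 0 faces the crown surface, column 1 the dentin-enamel
#' junction; row 0 is cuspal, row 4 cervical) plus one alveolar bone
#' reference sample.  The forming tooth (M3) carries secretory and early
#' maturation enamel, DEJ and dentin blocks; the erupting tooth (M2) carries
#' erupted and late maturation enamel, DEJ and dentin blocks.
#'
#' @return `data.frame` with columns `location_id`, `tooth`, `grid_row`,
#'   `grid_col`, `stage`.
#' @export
#' @examples
#' table(default_stage_layout()$stage)
default_stage_layout <- function() {
  blk <- function(tooth, col, stages) {
    data.frame(location_id = sprintf("%s_r%d_c%d", tooth, 0:4, col),
               tooth = tooth, grid_row = 0:4, grid_col = col,
               stage = stages, stringsAsFactors = FALSE)
  }
  rbind(
    blk("M3", 0L, c("early_maturation", "secretory", "secretory",
                    "secretory", "secretory")),
    blk("M3", 1L, c("DEJ", "DEJ", "early_maturation", "early_maturation",
                    "dentin")),
    blk("M2", 0L, c("erupted", "erupted", "erupted", "erupted",
                    "late_maturation")),
    blk("M2", 1L, c("late_maturation", "late_maturation", "late_maturation",
                    "DEJ", "dentin")),
    data.frame(location_id = "bone", tooth = "bone", grid_row = 0L,
               grid_col = 0L, stage = "bone", stringsAsFactors = FALSE)
  )
}

#' Default stage-effect matrix for simulated proteins
#'
#' Assigns each protein an archetype (secretory-matrix, maturation-high,
#' erupted-surface, DEJ-interface, mineralized-tissue, ubiquitous) by a
#' deterministic interleaved quota, draws a baseline mean log peak area from
#' a per-protein sub-stream of `seed`, and adds the archetype's stage
#' offsets.  Adding proteins never reshuffles existing rows because the
#' quota is positional and each protein has its own random sub-stream.
#'
#' @param n_proteins Number of proteins.
#' @param seed Integer seed (shared global seed of the simulation).
#' @param base_mean,base_sd Baseline mean log peak area distribution
#'   (natural-log units of chromatographic peak area).
#' @return `n_proteins` x 7 matrix (stages as columns, natural-log scale)
#'   with an `archetypes` attribute naming each protein's class.
#' @export
default_stage_effects <- function(n_proteins, seed = 1L,
                                  base_mean = 14, base_sd = 1) {
  if (!is_count(n_proteins)) stop_validation("n_proteins must be a positive count")
  eff <- matrix(0, nrow = n_proteins, ncol = length(ENAMEL_STAGES),
                dimnames = list(sprintf("PROT%04d", seq_len(n_proteins)),
                                ENAMEL_STAGES))
  arch <- ARCHETYPE_PATTERN[(seq_len(n_proteins) - 1L) %%
                              length(ARCHETYPE_PATTERN) + 1L]
  for (i in seq_len(n_proteins)) {
    b <- with_seed(derive_seed(seed, i, 4), rnorm(1L, base_mean, base_sd))
    row <- rep(b, length(ENAMEL_STAGES))
    names(row) <- ENAMEL_STAGES
    on <- ARCHETYPES[[arch[i]]]
    row[names(on)] <- row[names(on)] + on
    eff[i, ] <- row
  }
  names(arch) <- rownames(eff)
  attr(eff, "archetypes") <- arch
  eff
}

#' Default spatial phospho-occupancy profiles for the bundled markers
#'
#' True per-location occupancy (fraction of marker abundance carried by the
#' phosphorylated form) assigned by stage: the amelogenin markers
#' (`P173_LRAP`, `P190`) start highly phosphorylated in secretory enamel and
#' decline toward erupted enamel; the ameloblastin marker (`AMBN_N`) shows
#' the opposite trend; the enamelin marker (`ENAM_32k`) is near-fully
#' phosphorylated everywhere.
#'
#' @param layout Grid layout (`default_stage_layout()` by default).
#' @return Long `data.frame` with columns `marker_id`, `location_id`,
#'   `occupancy`.
#' @export
default_phospho_profiles <- function(layout = default_stage_layout()) {
  by_stage <- list(
    P173_LRAP = c(secretory = 0.90, early_maturation = 0.85,
                  late_maturation = 0.55, erupted = 0.40, DEJ = 0.70,
                  dentin = 0.50, bone = 0.50),
    P190      = c(secretory = 0.90, early_maturation = 0.80,
                  late_maturation = 0.50, erupted = 0.35, DEJ = 0.60,
                  dentin = 0.50, bone = 0.50),
    AMBN_N    = c(secretory = 0.20, early_maturation = 0.35,
                  late_maturation = 0.70, erupted = 0.80, DEJ = 0.50,
                  dentin = 0.50, bone = 0.50),
    ENAM_32k  = c(secretory = 0.95, early_maturation = 0.95,
                  late_maturation = 0.95, erupted = 0.95, DEJ = 0.95,
                  dentin = 0.95, bone = 0.95)
  )
  do.call(rbind, lapply(names(by_stage), function(m) {
    data.frame(marker_id = m, location_id = layout$location_id,
               occupancy = unname(by_stage[[m]][layout$stage]),
               stringsAsFactors = FALSE)
  }))
}

#' Build and validate a simulation configuration
#'
#' Collects every knob of the synthetic diced-crown generator and validates
#' it.  Peak areas are generated as
#' `exp(stage mean + peptide response offset + noise)` and censored
#' (dropped) when strictly below `detection_threshold`; phospho marker
#' peptides are emitted as a phosphorylated/unphosphorylated pair whose
#' expected area split equals the configured true occupancy.
#'
#' @param n_locations Number of grid locations (must match the layout).
#' @param stage_layout Grid layout data frame (see [default_stage_layout()]).
#' @param n_proteins Number of simulated background proteins.
#' @param n_peptides_per_protein Integer range `c(min, max)` of peptides per
#'   protein.
#' @param stage_effects Protein x stage matrix of mean log peak areas;
#'   defaults to [default_stage_effects()].
#' @param peptide_response_sd SD of the per-peptide response offset
#'   (natural-log scale); ionization efficiency varies widely between
#'   peptides of one protein.
#' @param noise_sd SD of the multiplicative log-normal measurement noise
#'   (natural-log scale).
#' @param detection_threshold Peak-area detection limit; observations
#'   strictly below it are censored (missing).
#' @param volume_mean,volume_sd Block volume distribution in mm^3.
#' @param phospho_profiles Long data frame (`marker_id`, `location_id`,
#'   `occupancy` in `[0, 1]`); defaults to [default_phospho_profiles()].
#' @param seed Shared global integer seed; all randomness flows from
#'   deterministic sub-streams of it.
#' @return Object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_proteins = 10, seed = 7)
#' cfg$n_locations
simulation_config <- function(n_locations = 21L,
                              stage_layout = default_stage_layout(),
                              n_proteins = 100L,
                              n_peptides_per_protein = c(3L, 8L),
                              stage_effects = NULL,
                              peptide_response_sd = 0.8,
                              noise_sd = 0.3,
                              detection_threshold = 2e5,
                              volume_mean = 2.3,
                              volume_sd = 0.25,
                              phospho_profiles = NULL,
                              seed = 1L) {
  if (!is_count(n_locations)) stop_validation("n_locations must be a positive count")
  if (!is.data.frame(stage_layout) ||
      !all(c("location_id", "tooth", "grid_row", "grid_col", "stage") %in%
           names(stage_layout))) {
    stop_validation("stage_layout must have columns location_id, tooth, grid_row, grid_col, stage")
  }
  if (nrow(stage_layout) != n_locations) {
    stop_validation("n_locations (%d) does not match the layout (%d rows)",
                    n_locations, nrow(stage_layout))
  }
  if (anyDuplicated(stage_layout$location_id)) {
    stop_validation("duplicate location_id in stage_layout")
  }
  bad_stage <- setdiff(unique(stage_layout$stage), ENAMEL_STAGES)
  if (length(bad_stage)) {
    stop_validation("unknown stage label(s): %s", paste(bad_stage, collapse = ", "))
  }
  if (!is_count(n_proteins)) stop_validation("n_proteins must be a positive count")
  rng <- n_peptides_per_protein
  if (length(rng) != 2L || !all(vapply(rng, is_count, logical(1))) ||
      rng[1] > rng[2]) {
    stop_validation("n_peptides_per_protein must be an ascending pair of positive counts")
  }
  if (!is_number(peptide_response_sd) || peptide_response_sd < 0) {
    stop_validation("peptide_response_sd must be a non-negative number")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop_validation("noise_sd must be a non-negative number")
  }
  if (!is_number(detection_threshold) || detection_threshold < 0) {
    stop_validation("detection_threshold must be a non-negative number")
  }
  if (!is_number(volume_mean) || volume_mean <= 0) {
    stop_validation("volume_mean must be a positive number (mm^3)")
  }
  if (!is_number(volume_sd) || volume_sd < 0) {
    stop_validation("volume_sd must be a non-negative number")
  }
  if (is.null(stage_effects)) {
    stage_effects <- default_stage_effects(n_proteins, seed = seed)
  }
  if (!is.matrix(stage_effects) || nrow(stage_effects) != n_proteins ||
      !identical(colnames(stage_effects), ENAMEL_STAGES)) {
    stop_validation("stage_effects must be an n_proteins x 7 matrix with the stage vocabulary as columns")
  }
  if (is.null(phospho_profiles)) {
    phospho_profiles <- default_phospho_profiles(stage_layout)
  }
  pp <- phospho_profiles
  if (!is.data.frame(pp) ||
      !all(c("marker_id", "location_id", "occupancy") %in% names(pp))) {
    stop_validation("phospho_profiles must have columns marker_id, location_id, occupancy")
  }
  if (any(is.na(pp$occupancy)) || any(pp$occupancy < 0 | pp$occupancy > 1)) {
    stop_validation("occupancy values must lie in [0, 1]")
  }
  if (!all(pp$location_id %in% stage_layout$location_id)) {
    stop_validation("phospho_profiles reference unknown location_id(s)")
  }
  if (!is_number(seed) || seed != floor(seed)) {
    stop_validation("seed must be an integer")
  }
  structure(list(n_locations = as.integer(n_locations),
                 stage_layout = stage_layout,
                 n_proteins = as.integer(n_proteins),
                 n_peptides_per_protein = as.integer(rng),
                 stage_effects = stage_effects,
                 peptide_response_sd = peptide_response_sd,
                 noise_sd = noise_sd,
                 detection_threshold = detection_threshold,
                 volume_mean = volume_mean,
                 volume_sd = volume_sd,
                 phospho_profiles = pp,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration:",
      sprintf("  %d locations (%d teeth + %d non-tooth), %d proteins",
              x$n_locations,
              length(setdiff(unique(x$stage_layout$tooth), "bone")),
              sum(x$stage_layout$tooth == "bone"), x$n_proteins),
      sprintf("  peptides/protein %d-%d, response sd %.3g, noise sd %.3g (ln scale)",
              x$n_peptides_per_protein[1], x$n_peptides_per_protein[2],
              x$peptide_response_sd, x$noise_sd),
      sprintf("  detection threshold %.3g (area), volume %.3g +/- %.3g mm^3, seed %d",
              x$detection_threshold, x$volume_mean, x$volume_sd, x$seed),
      sep = "\n")
  invisible(x)
}

## Amino-acid alphabet used for synthetic peptides; internal K/R avoided so
## simulated background peptides are fully cleaved tryptic products.
.PEP_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
             "Q", "S", "T", "V", "W", "Y")

.random_peptides <- function(n, used) {
  out <- character(n)
  for (j in seq_len(n)) {
    repeat {
      len <- sample(8:16, 1L)
      body <- paste(sample(.PEP_AA, len, replace = TRUE), collapse = "")
      pep <- paste0(body, sample(c("K", "R"), 1L))
      if (is.null(used[[pep]])) {
        used[[pep]] <- TRUE
        out[j] <- pep
        break
      }
    }
  }
  out
}

#' Simulate a diced-crown peptide dataset
#'
#' Generates the sample grid (with volumes), the peptide-level quantification
#' records, and ground-truth tables for every latent value.  Identical
#' configuration and seed give identical output; all randomness is drawn from
#' deterministic per-protein / per-marker sub-streams of `config$seed`.
#'
#' Marker peptides listed in `config$phospho_profiles` are emitted as a
#' phosphorylated / unphosphorylated record pair at each location where the
#' marker's parent protein is expressed; the expected area split equals the
#' configured occupancy.  Two unmodified "support" peptides are emitted per
#' marker parent so parents pass the two-unique-peptide identification
#' filter.
#'
#' @param config A [simulation_config()].
#' @return Object of class `enamel_simulation`: list with elements `grid`
#'   (sample blocks incl. `volume_mm3`), `peptides` (quantification records),
#'   and `truth` (stage-effect matrix, archetypes, peptide offsets, true
#'   occupancies, volumes, per-protein significance).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_proteins = 5, seed = 1))
#' head(sim$peptides)
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_validation("config must be created by simulation_config()")
  }
  layout <- config$stage_layout
  n_loc <- nrow(layout)
  stage_of <- layout$stage
  loc_ids <- layout$location_id

  vols <- with_seed(derive_seed(config$seed, 0, 1),
                    pmax(0.25, rnorm(n_loc, config$volume_mean, config$volume_sd)))
  grid <- data.frame(location_id = loc_ids, tooth = layout$tooth,
                     grid_row = layout$grid_row, grid_col = layout$grid_col,
                     volume_mm3 = vols, stage = stage_of,
                     stringsAsFactors = FALSE)

  eff <- config$stage_effects
  used <- new.env(parent = emptyenv())
  rec <- vector("list", nrow(eff) + 64L)
  ri <- 0L
  truth_pep <- vector("list", nrow(eff))
  sig_tab <- data.frame(protein_accession = rownames(eff), significance = NA_real_)

  for (i in seq_len(nrow(eff))) {
    prot <- rownames(eff)[i]
    out <- with_seed(derive_seed(config$seed, i, 2), {
      npep <- sample(seq(config$n_peptides_per_protein[1],
                         config$n_peptides_per_protein[2]), 1L)
      seqs <- .random_peptides(npep, used)
      offs <- rnorm(npep, 0, config$peptide_response_sd)
      sig <- round(runif(1L, 40, 120), 1)
      noise <- matrix(rnorm(npep * n_loc, 0, config$noise_sd), npep, n_loc)
      list(seqs = seqs, offs = offs, sig = sig, noise = noise)
    })
    mu <- eff[i, stage_of]                       # per-location stage mean
    area <- exp(outer(out$offs, mu, "+") + out$noise)
    keep <- area >= config$detection_threshold   # strictly below => censored
    if (any(keep)) {
      idx <- which(keep, arr.ind = TRUE)
      ri <- ri + 1L
      rec[[ri]] <- data.frame(sequence = out$seqs[idx[, 1]],
                              modifications = "",
                              protein_accession = prot,
                              location_id = loc_ids[idx[, 2]],
                              peak_area = area[keep],
                              significance = out$sig,
                              is_unique = TRUE,
                              stringsAsFactors = FALSE)
    }
    sig_tab$significance[i] <- out$sig
    truth_pep[[i]] <- data.frame(protein_accession = prot,
                                 sequence = out$seqs,
                                 response_offset = out$offs,
                                 stringsAsFactors = FALSE)
  }

  ## marker peptide pairs + parent support peptides
  pp <- config$phospho_profiles
  marker_ids <- unique(pp$marker_id)
  markers <- builtin_markers()
  unknown <- setdiff(marker_ids, markers$marker_id)
  if (length(unknown)) {
    stop_validation("phospho_profiles reference unknown marker id(s): %s",
                    paste(unknown, collapse = ", "))
  }
  parent_sig <- list()
  for (j in seq_along(marker_ids)) {
    mk <- markers[markers$marker_id == marker_ids[j], ]
    occ <- pp$occupancy[pp$marker_id == mk$marker_id][
      match(loc_ids, pp$location_id[pp$marker_id == mk$marker_id])]
    out <- with_seed(derive_seed(config$seed, 10000 + j, 3), {
      mu <- ifelse(stage_of %in% c("dentin", "bone"), 6, 16)
      total <- exp(mu + rnorm(n_loc, 0, config$noise_sd))
      p_area <- occ * total * exp(rnorm(n_loc, 0, config$noise_sd))
      np_area <- (1 - occ) * total * exp(rnorm(n_loc, 0, config$noise_sd))
      list(p = p_area, np = np_area)
    })
    sig <- parent_sig[[mk$parent_accession]]
    if (is.null(sig)) {
      sig <- with_seed(derive_seed(config$seed, 20000 + j, 3),
                       round(runif(1L, 60, 120), 1))
      parent_sig[[mk$parent_accession]] <- sig
    }
    pk <- !is.na(out$p) & out$p >= config$detection_threshold
    nk <- !is.na(out$np) & out$np >= config$detection_threshold
    if (any(pk)) {
      ri <- ri + 1L
      rec[[ri]] <- data.frame(sequence = mk$sequence,
                              modifications = sprintf("%d:Phospho",
                                                      mk$phospho_position),
                              protein_accession = mk$parent_accession,
                              location_id = loc_ids[pk],
                              peak_area = out$p[pk],
                              significance = sig, is_unique = TRUE,
                              stringsAsFactors = FALSE)
    }
    if (any(nk)) {
      ri <- ri + 1L
      rec[[ri]] <- data.frame(sequence = mk$sequence, modifications = "",
                              protein_accession = mk$parent_accession,
                              location_id = loc_ids[nk],
                              peak_area = out$np[nk],
                              significance = sig, is_unique = TRUE,
                              stringsAsFactors = FALSE)
    }
  }
  parents <- unique(markers$parent_accession[markers$marker_id %in% marker_ids])
  for (j in seq_along(parents)) {
    out <- with_seed(derive_seed(config$seed, 30000 + j, 5), {
      seqs <- .random_peptides(2L, used)
      offs <- rnorm(2L, 0, config$peptide_response_sd)
      noise <- matrix(rnorm(2L * n_loc, 0, config$noise_sd), 2L, n_loc)
      list(seqs = seqs, offs = offs, noise = noise)
    })
    mu <- ifelse(stage_of %in% c("dentin", "bone"), 6, 15)
    area <- exp(outer(out$offs, mu, "+") + out$noise)
    keep <- area >= config$detection_threshold
    if (any(keep)) {
      idx <- which(keep, arr.ind = TRUE)
      ri <- ri + 1L
      rec[[ri]] <- data.frame(sequence = out$seqs[idx[, 1]],
                              modifications = "",
                              protein_accession = parents[j],
                              location_id = loc_ids[idx[, 2]],
                              peak_area = area[keep],
                              significance = parent_sig[[parents[j]]],
                              is_unique = TRUE, stringsAsFactors = FALSE)
    }
  }

  peptides <- do.call(rbind, rec[seq_len(ri)])
  rownames(peptides) <- NULL
  arch <- attr(eff, "archetypes")
  truth <- list(stage_effects = eff,
                archetypes = arch,
                peptides = do.call(rbind, truth_pep),
                occupancy = pp,
                volumes = grid[c("location_id", "volume_mm3")],
                significance = sig_tab)
  structure(list(grid = grid, peptides = peptides, truth = truth,
                 config = config),
            class = "enamel_simulation")
}

#' @export
print.enamel_simulation <- function(x, ...) {
  cat(sprintf("Synthetic diced-crown dataset: %d locations, %d proteins, %d peptide records\n",
              nrow(x$grid), nrow(x$truth$stage_effects), nrow(x$peptides)))
  cat(sprintf("  distinct peptide sequences: %d; markers: %s\n",
              length(unique(x$peptides$sequence)),
              paste(unique(x$truth$occupancy$marker_id), collapse = ", ")))
  invisible(x)
}
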