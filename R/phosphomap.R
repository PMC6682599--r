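## phosphomap: marker-peptide validation by in-silico tryptic digestion and
## spatial phospho-occupancy (P:P+NP) maps.

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R.  With `cleave_before_proline = FALSE`
#' (classical trypsin specificity) a K/R followed by proline is not a
#' cleavage site; with `TRUE` (the search configuration used for the marker
#' peptides) it is.  All products with `0..max_missed` internal missed
#' cleavage sites are returned.
#'
#' @param sequence Amino-acid string (20 standard residues).
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param cleave_before_proline Permit cleavage when the following residue
#'   is proline (default `TRUE`).
#' @return Data frame with columns `peptide`, `start`, `end`, `missed`.
#' @export
#' @examples
#' tryptic_digest("AKRPGK", cleave_before_proline = FALSE)$peptide
#' tryptic_digest("AKRPGK", cleave_before_proline = TRUE)$peptide
tryptic_digest <- function(sequence, max_missed = 2L,
                           cleave_before_proline = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)) {
    stop_validation("sequence must be a string over the 20 standard amino-acid letters")
  }
  if (!is.numeric(max_missed) || max_missed < 0) {
    stop_validation("max_missed must be a non-negative count")
  }
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  sites <- which(ch %in% c("K", "R"))
  sites <- sites[sites < n]
  if (!cleave_before_proline) sites <- sites[ch[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  out <- vector("list", nb)
  k <- 0L
  for (a in seq_len(nb - 1L)) {
    for (b in seq(a + 1L, min(a + 1L + max_missed, nb))) {
      k <- k + 1L
      out[[k]] <- c(bounds[a] + 1L, bounds[b], b - a - 1L)
    }
  }
  m <- do.call(rbind, out[seq_len(k)])
  data.frame(peptide = substring(sequence, m[, 1], m[, 2]),
             start = m[, 1], end = m[, 2], missed = m[, 3],
             stringsAsFactors = FALSE)
}

#' Bundled marker peptide definitions
#'
#' The four isoform-discriminating marker peptides: the amelogenin P173/LRAP
#' N-terminal peptide (Ser16), the exon-4-containing P190 peptide, the
#' ameloblastin N-terminal peptide (15/17 kDa products), and the enamelin
#' peptide representative of the 32 kDa cleavage product.  Definitions are
#' read from the packaged `markers.json`.
#'
#' @return Data frame with columns `marker_id`, `sequence`,
#'   `phospho_position`, `parent_accession`, `parent_products`.
#' @export
#' @examples
#' builtin_markers()[, c("marker_id", "sequence", "phospho_position")]
builtin_markers <- function() {
  read_markers(system.file("extdata", "markers.json", package = "enamelmap"))
}

#' Read marker peptide definitions from JSON
#'
#' @param path Path to a JSON array of objects with fields `marker_id`,
#'   `sequence`, `phospho_position`, `parent_accession` (and optionally
#'   `parent_products`).
#' @return Validated marker data frame.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  mk <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("marker_id", "sequence", "phospho_position", "parent_accession")
  miss <- setdiff(need, names(mk))
  if (length(miss)) {
    stop_validation("marker file lacks field(s): %s", paste(miss, collapse = ", "))
  }
  if (!"parent_products" %in% names(mk)) mk$parent_products <- ""
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", mk$sequence)
  if (any(bad)) {
    stop_validation("marker sequence(s) contain illegal residues: %s",
                    paste(mk$marker_id[bad], collapse = ", "))
  }
  res <- substring(mk$sequence, mk$phospho_position, mk$phospho_position)
  bad <- !(res %in% c("S", "T", "Y"))
  if (any(bad)) {
    stop_validation("phospho position of marker(s) %s is not S/T/Y",
                    paste(mk$marker_id[bad], collapse = ", "))
  }
  mk
}

#' Validate marker peptides against their parent sequences
#'
#' Confirms for each marker that the parent accession exists in the FASTA
#' map, that the marker sequence is a substring of the parent, and that it
#' is producible by tryptic digestion with at most two missed cleavages and
#' cleavage before proline permitted; also reports the phospho position in
#' parent coordinates.  Failures are reported as rows, never exceptions.
#'
#' @param markers Marker data frame (see [builtin_markers()]).
#' @param fasta Named character vector accession -> sequence
#'   (see [read_fasta()]).
#' @return Data frame with per-marker check flags, the parent-coordinate
#'   phospho position, and an overall `passed` flag.
#' @export
#' @examples
#' fasta <- read_fasta(system.file("extdata", "synthetic_parent_proteins.fasta",
#'                                 package = "enamelmap"))
#' validate_markers(builtin_markers(), fasta)
validate_markers <- function(markers, fasta) {
  out <- lapply(seq_len(nrow(markers)), function(i) {
    mk <- markers[i, ]
    parent_present <- mk$parent_accession %in% names(fasta)
    found <- FALSE
    producible <- FALSE
    parent_pos <- NA_integer_
    if (parent_present) {
      parent <- fasta[[mk$parent_accession]]
      at <- regexpr(mk$sequence, parent, fixed = TRUE)
      found <- at > 0L
      if (found) {
        parent_pos <- as.integer(at) + mk$phospho_position - 1L
        dig <- tryptic_digest(parent, max_missed = 2L,
                              cleave_before_proline = TRUE)
        producible <- mk$sequence %in% dig$peptide
      }
    }
    residue <- substring(mk$sequence, mk$phospho_position, mk$phospho_position)
    residue_ok <- residue %in% c("S", "T", "Y")
    data.frame(marker_id = mk$marker_id,
               parent_accession = mk$parent_accession,
               parent_present = parent_present,
               found_in_parent = found,
               producible_by_digest = producible,
               phospho_residue = residue,
               phospho_residue_ok = residue_ok,
               peptide_position = mk$phospho_position,
               parent_position = parent_pos,
               passed = parent_present && found && producible && residue_ok,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-location phosphorylated / unphosphorylated marker abundances
#'
#' At each location, `P_abundance` sums the areas of records matching the
#' marker sequence with a Phospho at the marker position; `NP_abundance`
#' sums matching records with no Phospho anywhere.  Other modifications
#' (e.g. deamidation) are ignored for pool assignment; records carrying a
#' Phospho at a different residue belong to neither pool and are audited.
#' Locations with no matching record at all are missing in both pools.
#'
#' @param records Identification-filtered peptide records.
#' @param marker One marker definition (single row of a marker data frame,
#'   or a list with `marker_id`, `sequence`, `phospho_position`).
#' @param grid Optional grid; when supplied, every location becomes a row of
#'   the map.
#' @return Object of class `phospho_pair_map` with elements `marker_id`,
#'   `data` (`location_id`, `P_abundance`, `NP_abundance`) and `audit`.
#' @export
pair_abundances <- function(records, marker, grid = NULL) {
  if (is.data.frame(marker)) {
    if (nrow(marker) != 1L) stop_validation("marker must be a single marker")
    marker <- as.list(marker)
  }
  hits <- records[records$sequence == marker$sequence, , drop = FALSE]
  locs <- if (!is.null(grid)) grid$location_id else sort(unique(records$location_id))
  pool <- character(nrow(hits))
  if (nrow(hits)) {
    mods <- lapply(hits$modifications, parse_modifications)
    bad_syntax <- vapply(mods, is.null, logical(1))
    if (any(bad_syntax)) {
      stop_validation("bad modification syntax in %d marker record(s)",
                      sum(bad_syntax))
    }
    phos_at <- vapply(mods, function(m) {
      any(m$name == "Phospho" & m$position == marker$phospho_position)
    }, logical(1))
    phos_any <- vapply(mods, function(m) any(m$name == "Phospho"), logical(1))
    pool <- ifelse(phos_at, "P", ifelse(!phos_any, "NP", "other"))
  }
  sum_pool <- function(which_pool, loc) {
    sel <- pool == which_pool & hits$location_id == loc
    if (any(sel)) sum(hits$peak_area[sel]) else 0
  }
  observed <- locs %in% hits$location_id[pool != "other"]
  p_ab <- ifelse(observed, vapply(locs, sum_pool, numeric(1),
                                  which_pool = "P"), NA_real_)
  np_ab <- ifelse(observed, vapply(locs, sum_pool, numeric(1),
                                   which_pool = "NP"), NA_real_)
  audit <- NULL
  if (any(pool == "other")) {
    audit <- data.frame(location_id = hits$location_id[pool == "other"],
                        reason = "Phospho at non-marker position; excluded from both pools")
  }
  structure(list(marker_id = marker$marker_id,
                 data = data.frame(location_id = locs,
                                   P_abundance = unname(p_ab),
                                   NP_abundance = unname(np_ab),
                                   stringsAsFactors = FALSE),
                 audit = audit),
            class = "phospho_pair_map")
}

#' Phospho-occupancy ratio P / (P + NP)
#'
#' Adds the per-location occupancy ratio to a pair map: the fraction of the
#' marker's total abundance carried by the phosphorylated form.  Undefined
#' (missing) where `P + NP` is zero or the marker was not observed.  The
#' ratio is scale-free, so volume normalization cancels out of it.
#'
#' @param pair_map A [pair_abundances()] result.
#' @param renormalize Divide each location's ratio by the crown-wide ratio
#'   (summed over all locations).  Off by default; the per-location ratio is
#'   reported as-is.
#' @return The `phospho_pair_map` with a `ratio` column added.
#' @export
occupancy_ratio <- function(pair_map, renormalize = FALSE) {
  if (!inherits(pair_map, "phospho_pair_map")) {
    stop_validation("pair_map must come from pair_abundances()")
  }
  d <- pair_map$data
  tot <- d$P_abundance + d$NP_abundance
  ratio <- ifelse(!is.na(tot) & tot > 0, d$P_abundance / tot, NA_real_)
  if (isTRUE(renormalize)) {
    overall <- sum(d$P_abundance, na.rm = TRUE) /
      sum(tot[!is.na(tot) & tot > 0])
    ratio <- ratio / overall
  }
  pair_map$data$ratio <- ratio
  pair_map$renormalized <- isTRUE(renormalize)
  pair_map
}

#' @export
print.phospho_pair_map <- function(x, ...) {
  n_obs <- sum(!is.na(x$data$P_abundance))
  cat(sprintf("Phospho pair map for %s: %d/%d locations observed%s\n",
              x$marker_id, n_obs, nrow(x$data),
              if (!is.null(x$data$ratio)) {
                sprintf("; occupancy %.2f-%.2f",
                        suppressWarnings(min(x$data$ratio, na.rm = TRUE)),
                        suppressWarnings(max(x$data$ratio, na.rm = TRUE)))
              } else ""))
  invisible(x)
}
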