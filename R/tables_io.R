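## tables_io: reading/writing the artifact file formats and the
## identification-level filters applied on import.
##
## Formats:
##  * peptide report - TSV with columns sequence, modifications,
##    protein_accession, location_id, peak_area, significance, is_unique;
##    leading '#' comment lines carry the tool version and seed.
##  * modifications dialect - semicolon-separated "pos:Name" with pos 1-based
##    within the peptide and one canonical name per modification
##    (e.g. "16:Phospho;2:Oxidation"); empty string = unmodified.
##  * grid - JSON object {meta, grid} where grid rows are sample blocks with
##    location_id, tooth, grid_row (0-based, cuspal -> cervical), grid_col
##    (0-based, surface -> DEJ), volume_mm3, stage.
##  * protein sequences - FASTA (accession = first header token).

REPORT_COLUMNS <- c("sequence", "modifications", "protein_accession",
                    "location_id", "peak_area", "significance", "is_unique")

## Parse one modification string; returns data.frame(position, name) or NULL
## on syntax error.
parse_modifications <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) {
    return(data.frame(position = integer(0), name = character(0)))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  ok <- grepl("^[0-9]+:[A-Za-z][A-Za-z0-9_-]*$", parts)
  if (!all(ok)) return(NULL)
  pos <- as.integer(sub(":.*", "", parts))
  nm <- sub("^[0-9]+:", "", parts)
  data.frame(position = pos, name = nm, stringsAsFactors = FALSE)
}

#' Write a peptide quantification report
#'
#' @param records Peptide record data frame (see [read_peptide_report()] for
#'   the columns).
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the file header comment.
#' @return The path, invisibly.
#' @export
write_peptide_report <- function(records, path, seed = NULL) {
  miss <- setdiff(REPORT_COLUMNS, names(records))
  if (length(miss)) {
    stop_validation("records lack column(s): %s", paste(miss, collapse = ", "))
  }
  write_tsv(records[REPORT_COLUMNS], path, seed = seed)
}

#' Read and validate a peptide quantification report
#'
#' Reads the TSV peptide report, types every column and validates each row:
#' the location must exist in `grid`, the peak area must be a non-negative
#' number, the modification string must parse and its positions must fall
#' inside the peptide.  All offending rows are reported together with their
#' file line numbers.
#'
#' @param path TSV path (leading `#` lines are ignored).
#' @param grid Sample grid data frame (see [read_grid()]).
#' @return Typed data frame of peptide records.
#' @export
read_peptide_report <- function(path, grid) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  lines <- readLines(path)
  n_comment <- 0L
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(REPORT_COLUMNS, names(df))
  if (length(miss)) {
    stop_validation("peptide report lacks column(s): %s",
                    paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    out <- data.frame(sequence = character(0), modifications = character(0),
                      protein_accession = character(0),
                      location_id = character(0), peak_area = numeric(0),
                      significance = numeric(0), is_unique = logical(0))
    return(out)
  }
  line_of <- n_comment + 1L + seq_len(nrow(df))   # +1 for the header line
  probs <- character(0)
  bad <- function(rows, what) {
    if (any(rows)) {
      probs <<- c(probs, sprintf("line %d: %s", line_of[rows], what[rows]))
    }
  }
  seq_ok <- grepl("^[A-Z]+$", df$sequence)
  bad(!seq_ok, rep("malformed peptide sequence", nrow(df)))
  area <- suppressWarnings(as.numeric(df$peak_area))
  bad(is.na(area), rep("peak_area is not a number", nrow(df)))
  bad(!is.na(area) & area < 0, rep("negative peak_area", nrow(df)))
  sig <- suppressWarnings(as.numeric(df$significance))
  bad(is.na(sig), rep("significance is not a number", nrow(df)))
  loc_ok <- df$location_id %in% grid$location_id
  bad(!loc_ok, sprintf("unknown location_id '%s'", df$location_id))
  uniq <- toupper(df$is_unique) %in% c("TRUE", "FALSE")
  bad(!uniq, rep("is_unique must be TRUE or FALSE", nrow(df)))
  mod_parsed <- lapply(df$modifications, parse_modifications)
  mod_bad <- vapply(mod_parsed, is.null, logical(1))
  bad(mod_bad, rep("bad modification syntax", nrow(df)))
  pos_bad <- mapply(function(m, s, ok) {
    if (is.null(m) || !ok) return(FALSE)
    nrow(m) > 0L && any(m$position < 1L | m$position > nchar(s))
  }, mod_parsed, df$sequence, seq_ok)
  bad(pos_bad, rep("modification position outside peptide", nrow(df)))
  if (length(probs)) {
    stop_validation("malformed peptide report rows:\n%s",
                    paste(probs, collapse = "\n"))
  }
  data.frame(sequence = df$sequence,
             modifications = df$modifications,
             protein_accession = df$protein_accession,
             location_id = df$location_id,
             peak_area = area,
             significance = sig,
             is_unique = toupper(df$is_unique) == "TRUE",
             stringsAsFactors = FALSE)
}

#' Write / read the sample grid as JSON
#'
#' @param grid Grid data frame (`location_id`, `tooth`, `grid_row`,
#'   `grid_col`, `volume_mm3`, `stage`).
#' @param path JSON path.
#' @param seed Optional seed recorded in the file's `meta` block.
#' @return `write_grid()` returns the path invisibly; `read_grid()` returns
#'   the validated grid data frame.
#' @export
write_grid <- function(grid, path, seed = NULL) {
  jsonlite::write_json(list(meta = list(tool = "enamelmap",
                                        version = as.character(utils::packageVersion("enamelmap")),
                                        seed = seed),
                            grid = grid),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- if (is.data.frame(obj)) obj else obj$grid
  need <- c("location_id", "tooth", "grid_row", "grid_col", "volume_mm3",
            "stage")
  miss <- setdiff(need, names(grid))
  if (length(miss)) {
    stop_validation("grid lacks field(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(grid$location_id)) {
    stop_validation("duplicate location_id in grid")
  }
  if (any(!is.finite(grid$volume_mm3)) || any(grid$volume_mm3 <= 0)) {
    stop_validation("block volumes must be positive (mm^3)")
  }
  bad <- setdiff(unique(grid$stage), ENAMEL_STAGES)
  if (length(bad)) {
    stop_validation("unknown stage label(s): %s", paste(bad, collapse = ", "))
  }
  grid[need]
}

#' Read protein sequences from FASTA
#'
#' Accessions are the first whitespace-delimited token of each header.
#' Sequences are upper-cased and checked against the 20 standard amino-acid
#' letters; duplicate accessions and illegal residues are errors.
#'
#' @param path FASTA path.
#' @return Named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  ## read without an alphabet so illegal residues reach our own check
  ## (the AA reader silently drops invalid letter codes)
  ss <- Biostrings::readBStringSet(path)
  acc <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup)) {
    stop_validation("duplicate accession(s) in FASTA: %s",
                    paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- acc
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(bad)) {
    stop_validation("illegal residue(s) in FASTA record(s): %s",
                    paste(acc[bad], collapse = ", "))
  }
  seqs
}

#' Identification-level protein filters
#'
#' A protein's records are retained iff the protein has at least
#' `min_unique_peptides` distinct unique peptide sequences dataset-wide and
#' its identification significance (-10lgP) reaches `min_significance`.
#' A peptide sequence counts as unique when it is flagged unique upstream
#' *and* maps to a single accession within the dataset.  The filter never
#' fails - it only excludes - and reports per-protein audit counts.
#'
#' @param records Typed peptide records (see [read_peptide_report()]).
#' @param min_unique_peptides Minimum distinct unique peptides per protein.
#' @param min_significance Minimum protein -10lgP significance.
#' @return List with `records` (retained rows) and `audit` (per-protein
#'   counts before/after with the retention decision).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_proteins = 5, seed = 1))
#' flt <- filter_identifications(sim$peptides)
#' head(flt$audit)
filter_identifications <- function(records, min_unique_peptides = 2,
                                   min_significance = 20) {
  if (nrow(records) == 0L) {
    audit <- data.frame(protein_accession = character(0),
                        n_records = integer(0),
                        n_unique_peptides = integer(0),
                        significance = numeric(0), retained = logical(0))
    return(list(records = records, audit = audit))
  }
  n_owners <- tapply(records$protein_accession, records$sequence,
                     function(p) length(unique(p)))
  rec_unique <- records$is_unique & n_owners[records$sequence] == 1L
  prot <- sort(unique(records$protein_accession))
  n_uni <- vapply(prot, function(p) {
    sel <- records$protein_accession == p & rec_unique
    length(unique(records$sequence[sel]))
  }, integer(1))
  sig <- vapply(prot, function(p) {
    max(records$significance[records$protein_accession == p])
  }, numeric(1))
  n_rec <- vapply(prot, function(p) sum(records$protein_accession == p),
                  integer(1))
  retained <- n_uni >= min_unique_peptides & sig >= min_significance
  audit <- data.frame(protein_accession = prot, n_records = n_rec,
                      n_unique_peptides = n_uni, significance = sig,
                      retained = retained, stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  keep <- records$protein_accession %in% prot[retained]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, audit = audit)
}
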