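## quantmap: peptide records -> volume-normalized, log- and percent-scaled
## spatial abundance maps.
##
## Canonical map pipeline (fixed and regression-tested):
##   top3_abundance -> volume_normalize -> log_transform -> percent_scale

#' Abundance matrix container
#'
#' A proteins (or peptides) x locations matrix of non-negative abundances
#' with missingness, tagged with the scale it is on: `raw_area` (summed
#' peak areas), `volume_normalized` (rescaled to the 2.14 mm^3 reference
#' volume), `natural_log`, or `percent` (each row scaled to its maximum =
#' 100).
#'
#' @param values Numeric matrix with row and column (location) names.
#' @param scale One of `"raw_area"`, `"volume_normalized"`, `"natural_log"`,
#'   `"percent"`.
#' @param audit Optional data frame of audit entries accumulated by the
#'   transforms.
#' @return Object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values,
                             scale = c("raw_area", "volume_normalized",
                                       "natural_log", "percent"),
                             audit = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("values must carry row and column (location) names")
  }
  if (scale != "natural_log" && any(values < 0, na.rm = TRUE)) {
    stop_validation("abundances must be non-negative on the %s scale", scale)
  }
  if (scale == "percent") {
    mx <- suppressWarnings(apply(values, 1L, max, na.rm = TRUE))
    mx <- mx[is.finite(mx)]
    if (length(mx) && any(abs(mx - 100) > 1e-6)) {
      stop_validation("percent scale requires every non-missing row maximum to equal 100")
    }
  }
  structure(list(values = values, scale = scale, audit = audit),
            class = "abundance_matrix")
}

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix [%s]: %d rows x %d locations, %.1f%% missing\n",
              x$scale, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  if (!is.null(x$audit) && nrow(x$audit)) {
    cat(sprintf("  audit entries: %d\n", nrow(x$audit)))
  }
  invisible(x)
}

.am_values <- function(x) {
  if (inherits(x, "abundance_matrix")) x$values else x
}

.add_audit <- function(old, new) {
  if (is.null(old)) return(new)
  if (is.null(new)) return(old)
  rbind(old, new)
}

## Effective unique peptides: flagged unique and mapping to one accession
## within the record set.
.unique_mask <- function(records) {
  n_owners <- tapply(records$protein_accession, records$sequence,
                     function(p) length(unique(p)))
  records$is_unique & n_owners[records$sequence] == 1L
}

#' Top-3 protein quantification
#'
#' Protein abundance at a location is the sum of the peak areas of the three
#' most abundant unique peptides of that protein at that location (summed
#' over records of the same sequence first, so modified and unmodified forms
#' of one peptide are pooled).  With fewer than three unique peptides
#' observed the available ones are summed; with none the cell is missing.
#' Peptide selection is per location; rank-3 ties are broken by
#' lexicographic peptide sequence so the sum always has a deterministic set
#' of at most `n_top` summands.
#'
#' @param records Identification-filtered peptide records.
#' @param grid Optional grid; when supplied, every grid location becomes a
#'   column (all-missing columns included).
#' @param n_top Number of peptides summed (3 by default).
#' @return `abundance_matrix` on the `raw_area` scale.
#' @export
top3_abundance <- function(records, grid = NULL, n_top = 3L) {
  locs <- if (!is.null(grid)) grid$location_id else sort(unique(records$location_id))
  if (nrow(records) == 0L) {
    stop_validation("no peptide records to quantify")
  }
  keep <- .unique_mask(records)
  rec <- records[keep, , drop = FALSE]
  agg <- stats::aggregate(peak_area ~ protein_accession + sequence + location_id,
                          data = rec, FUN = sum)
  prot <- sort(unique(agg$protein_accession))
  m <- matrix(NA_real_, length(prot), length(locs),
              dimnames = list(prot, locs))
  for (chunk in split(agg, agg$protein_accession)) {
    p <- chunk$protein_accession[1]
    for (loc_chunk in split(chunk, chunk$location_id)) {
      o <- order(-loc_chunk$peak_area, loc_chunk$sequence)
      m[p, loc_chunk$location_id[1]] <-
        sum(loc_chunk$peak_area[o][seq_len(min(n_top, length(o)))])
    }
  }
  abundance_matrix(m, "raw_area")
}

#' Volume normalization against the reference block volume
#'
#' Rescales every location's abundances by `reference_volume / block volume`
#' so that equal tissue concentrations yield equal normalized values
#' regardless of how much tissue a block contains.  The reference volume of
#' 2.14 mm^3 is the standard sample volume the abundances are expressed
#' against.
#'
#' @param x `abundance_matrix` (or plain matrix with location columns).
#' @param grid Grid data frame supplying `volume_mm3` per location.
#' @param reference_volume Reference standard volume in mm^3.
#' @return `abundance_matrix` on the `volume_normalized` scale.
#' @export
volume_normalize <- function(x, grid, reference_volume = 2.14) {
  v <- .am_values(x)
  vol <- grid$volume_mm3[match(colnames(v), grid$location_id)]
  if (any(is.na(vol))) {
    stop_validation("location(s) missing from grid: %s",
                    paste(colnames(v)[is.na(vol)], collapse = ", "))
  }
  if (any(vol <= 0)) {
    stop_validation("block volumes must be positive (mm^3)")
  }
  if (!is_number(reference_volume) || reference_volume <= 0) {
    stop_validation("reference_volume must be a positive number")
  }
  out <- sweep(v, 2L, reference_volume / vol, `*`)
  abundance_matrix(out, "volume_normalized",
                   audit = if (inherits(x, "abundance_matrix")) x$audit)
}

#' Natural-log transform
#'
#' Per-cell natural log.  Zeros become missing (counted in the audit);
#' negative values are an error.
#'
#' @param x `abundance_matrix` or matrix.
#' @return `abundance_matrix` on the `natural_log` scale.
#' @export
log_transform <- function(x) {
  v <- .am_values(x)
  if (any(v < 0, na.rm = TRUE)) {
    stop_validation("log transform of negative abundances")
  }
  zeros <- sum(v == 0, na.rm = TRUE)
  v[!is.na(v) & v == 0] <- NA_real_
  out <- log(v)
  audit <- if (zeros > 0) {
    data.frame(entity = "matrix", reason = sprintf("%d zero cell(s) set to missing before log", zeros))
  }
  abundance_matrix(out, "natural_log",
                   audit = .add_audit(if (inherits(x, "abundance_matrix")) x$audit, audit))
}

#' Percent scaling to each row's maximum
#'
#' Each row is divided by its maximum and multiplied by 100, so every
#' retained row's maximum is 100%.  With `grid` supplied, scaling is done
#' within each tooth crown separately (each tooth's sub-row peaks at 100);
#' without it, across all locations.  Rows that are entirely missing, or
#' whose maximum is not positive, are dropped with an audit entry.
#'
#' @param x `abundance_matrix` or matrix.
#' @param grid Optional grid; when given, scaling is per tooth.
#' @return `abundance_matrix` on the `percent` scale.
#' @export
percent_scale <- function(x, grid = NULL) {
  v <- .am_values(x)
  unit <- if (!is.null(grid)) {
    grid$tooth[match(colnames(v), grid$location_id)]
  } else {
    rep("all", ncol(v))
  }
  if (any(is.na(unit))) {
    stop_validation("location(s) missing from grid: %s",
                    paste(colnames(v)[is.na(unit)], collapse = ", "))
  }
  out <- v
  for (u in unique(unit)) {
    cols <- which(unit == u)
    sub <- v[, cols, drop = FALSE]
    mx <- suppressWarnings(apply(sub, 1L, max, na.rm = TRUE))
    ok <- is.finite(mx) & mx > 0
    out[ok, cols] <- 100 * sub[ok, , drop = FALSE] / mx[ok]
    out[!ok, cols] <- NA_real_
  }
  all_missing <- rowSums(!is.na(out)) == 0L
  audit <- NULL
  if (any(all_missing)) {
    audit <- data.frame(entity = rownames(v)[all_missing],
                        reason = "dropped by percent_scale: no positive values")
    out <- out[!all_missing, , drop = FALSE]
  }
  abundance_matrix(out, "percent",
                   audit = .add_audit(if (inherits(x, "abundance_matrix")) x$audit, audit))
}

#' Per-location amount and diversity summary
#'
#' "Amount" is the per-location sum of non-missing row values on the
#' matrix's scale; "diversity" is the count of non-missing rows (how many
#' proteins or peptides were observed there).
#'
#' @param x `abundance_matrix` or matrix.
#' @param grid Optional grid to annotate locations with tooth/row/col/stage.
#' @return Data frame with one row per location.
#' @export
summarize_grid <- function(x, grid = NULL) {
  v <- .am_values(x)
  out <- data.frame(location_id = colnames(v),
                    total_amount = colSums(v, na.rm = TRUE),
                    diversity = colSums(!is.na(v)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(grid)) {
    out <- cbind(out, grid[match(out$location_id, grid$location_id),
                           c("tooth", "grid_row", "grid_col", "stage")])
    rownames(out) <- NULL
  }
  out
}

#' Plot one row of an abundance matrix on the sample grid
#'
#' Draws each tooth as a grid of blocks (rows cuspal to cervical, columns
#' surface to DEJ) colored by the selected row's values.
#'
#' @param x `abundance_matrix`.
#' @param grid Grid data frame.
#' @param row_id Row (protein/peptide) to draw.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the per-tooth value matrices.
#' @export
plot.abundance_matrix <- function(x, grid, row_id = rownames(x$values)[1], ...) {
  v <- x$values[row_id, ]
  teeth <- setdiff(unique(grid$tooth), "bone")
  old <- graphics::par(mfrow = c(1, length(teeth)))
  on.exit(graphics::par(old))
  out <- list()
  for (tt in teeth) {
    g <- grid[grid$tooth == tt, ]
    m <- matrix(NA_real_, max(g$grid_row) + 1L, max(g$grid_col) + 1L)
    for (i in seq_len(nrow(g))) {
      m[g$grid_row[i] + 1L, g$grid_col[i] + 1L] <- v[g$location_id[i]]
    }
    graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                    col = grDevices::hcl.colors(32, "viridis"),
                    axes = FALSE, ...)
    graphics::title(main = sprintf("%s - %s (%s)", row_id, tt, x$scale))
    out[[tt]] <- m
  }
  invisible(out)
}

#' Write / read an abundance matrix as TSV
#'
#' Rows x locations TSV with a `row_id` first column; comment header lines
#' record the tool version, seed and scale tag so the matrix round-trips.
#'
#' @param x `abundance_matrix`.
#' @param path TSV path.
#' @param seed Optional seed for the header.
#' @return `write_matrix_tsv()` the path invisibly; `read_matrix_tsv()` the
#'   `abundance_matrix`.
#' @export
write_matrix_tsv <- function(x, path, seed = NULL) {
  v <- .am_values(x)
  scale <- if (inherits(x, "abundance_matrix")) x$scale else "raw_area"
  df <- data.frame(row_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, extra_header = paste0("# scale=", scale))
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  head_lines <- readLines(path, n = 10L)
  sc <- sub("^# scale=", "", grep("^# scale=", head_lines, value = TRUE))
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- df[[1L]]
  abundance_matrix(m, if (length(sc)) sc[1] else "raw_area")
}
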