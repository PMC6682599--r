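## Fixed vocabulary of a-priori developmental-stage labels for grid locations,
## and their mapping onto the named analysis groups.

ENAMEL_STAGES <- c("secretory", "early_maturation", "late_maturation",
                   "erupted", "DEJ", "dentin", "bone")

STAGE_GROUP <- c(secretory        = "Secretion",
                 early_maturation = "Maturation",
                 late_maturation  = "Maturation",
                 erupted          = "Cuspal",
                 DEJ              = "DEJ",
                 dentin           = "NonEnamel",
                 bone             = "NonEnamel")

## Developmental ordering used for tie-breaking when naming clusters:
## earlier stages first.
GROUP_ORDER <- c("Secretion", "Maturation", "Cuspal", "DEJ", "NonEnamel")

ENAMEL_GROUPS <- c("Secretion", "Maturation", "Cuspal", "DEJ")

#' Stage vocabulary for diced-crown sample locations
#'
#' The a-priori anatomical stage labels a sample block may carry: the three
#' phases of enamel formation (`secretory`, `early_maturation`,
#' `late_maturation`), post-eruptive enamel (`erupted`), the dentin-enamel
#' junction (`DEJ`), and the two non-enamel reference tissues (`dentin`,
#' `bone`).
#'
#' @return Character vector of the seven stage labels.
#' @export
#' @examples
#' enamel_stages()
enamel_stages <- function() ENAMEL_STAGES

#' Map stage labels onto named analysis groups
#'
#' Collapses the seven a-priori stage labels onto the five named groups used
#' by the clustering and differential-abundance stages: `Secretion`,
#' `Maturation` (early + late), `Cuspal` (erupted enamel), `DEJ`, and
#' `NonEnamel` (dentin + bone).
#'
#' @param stages Character vector of stage labels, or `NULL` for the full map.
#' @return Named character vector of group names.
#' @export
#' @examples
#' stage_groups(c("secretory", "bone"))
stage_groups <- function(stages = NULL) {
  if (is.null(stages)) return(STAGE_GROUP)
  bad <- setdiff(unique(stages), names(STAGE_GROUP))
  if (length(bad)) {
    stop_validation("unknown stage label(s): %s", paste(bad, collapse = ", "))
  }
  STAGE_GROUP[stages]
}
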