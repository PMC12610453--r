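#' Panel layout
#'
#' Describes a qPCR miRNA panel: which assays are quantified targets, which
#' are housekeeping references used for within-sample normalization, and
#' which are vendor controls (parsed but excluded from all statistics).
#' A Ct at or above `lod_ct` is retained but flagged undetected.
#'
#' @param assay_ids character vector of unique assay names.
#' @param roles character vector, same length, each one of `"target"`,
#'   `"housekeeping"`, `"control"`.
#' @param lod_ct limit of detection in cycles (default 35).
#' @return An object of class `panel_layout`.
#' @export
panel_layout <- function(assay_ids, roles, lod_ct = 35) {
  assay_ids <- as.character(assay_ids)
  roles <- as.character(roles)
  if (length(assay_ids) != length(roles))
    stop("assay_ids and roles must have the same length")
  if (anyDuplicated(assay_ids))
    stop("duplicate assay ids: ",
         paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "))
  bad <- setdiff(unique(roles), c("target", "housekeeping", "control"))
  if (length(bad))
    stop("unknown assay role(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(lod_ct) || length(lod_ct) != 1L || !is.finite(lod_ct))
    stop("lod_ct must be a single finite number")
  structure(
    list(assay_ids = assay_ids, roles = roles, lod_ct = lod_ct),
    class = "panel_layout"
  )
}

#' @export
print.panel_layout <- function(x, ...) {
  tab <- table(factor(x$roles, c("target", "housekeeping", "control")))
  cat("panel_layout:", length(x$assay_ids), "assays (",
      tab[["target"]], "target,", tab[["housekeeping"]], "housekeeping,",
      tab[["control"]], "control ), LOD", x$lod_ct, "cycles\n")
  invisible(x)
}

#' Assay ids of a given role
#' @param layout a `panel_layout`.
#' @param role one of `"target"`, `"housekeeping"`, `"control"`.
#' @return character vector of assay ids.
#' @export
assays_by_role <- function(layout, role) {
  stopifnot(inherits(layout, "panel_layout"))
  layout$assay_ids[layout$roles == role]
}

# Housekeeping references on the study panel.
STUDY_HOUSEKEEPING <- c("SNORD38B", "U6-snRNA", "SNORD49A")

# miRNAs named in the study results; used to seed the default layout so
# synthetic panels carry recognizable assay names.
STUDY_NAMED_MIRNAS <- c(
  "hsa-miR-181a-5p", "hsa-miR-23a-3p", "hsa-miR-20b-5p", "hsa-miR-100-5p",
  "hsa-miR-200c-3p", "hsa-miR-125b-5p", "hsa-miR-149-3p", "hsa-miR-24-3p",
  "hsa-miR-27b-3p", "hsa-miR-23b-3p", "hsa-let-7a-5p", "hsa-let-7c-5p",
  "hsa-let-7d-5p", "hsa-let-7i-5p", "hsa-miR-26b-5p", "hsa-miR-26a-5p",
  "hsa-miR-19b-3p", "hsa-miR-191-5p", "hsa-let-7f-5p", "hsa-miR-192-5p",
  "hsa-miR-10b-5p", "hsa-miR-34a-5p", "hsa-miR-200b-3p", "hsa-miR-15a-5p",
  "hsa-let-7g-5p", "hsa-miR-205-5p", "hsa-miR-221-3p", "hsa-miR-210-3p",
  "hsa-miR-10a-5p"
)

#' Default study-shaped panel layout
#'
#' 96 wells: `n_targets` target miRNAs (the miRNAs named in the study
#' results plus placeholder assays), three housekeeping references
#' (SNORD38B, U6 snRNA, SNORD49A) and the remainder as vendor controls.
#' The 84-target configuration gives the multiplicity m = 84 used
#' throughout the power analysis.
#'
#' @param n_targets number of target assays (default 84).
#' @param lod_ct limit of detection in cycles (default 35).
#' @return A `panel_layout`.
#' @export
default_panel_layout <- function(n_targets = 84, lod_ct = 35) {
  named <- STUDY_NAMED_MIRNAS
  if (n_targets < length(named)) named <- named[seq_len(n_targets)]
  n_fill <- n_targets - length(named)
  fill <- if (n_fill > 0)
    sprintf("hsa-miR-sim%02d-5p", seq_len(n_fill)) else character(0)
  targets <- c(named, fill)
  n_ctrl <- max(96 - n_targets - 3L, 0L)
  ctrl <- if (n_ctrl > 0) sprintf("CTRL-%02d", seq_len(n_ctrl)) else character(0)
  panel_layout(
    assay_ids = c(targets, STUDY_HOUSEKEEPING, ctrl),
    roles = c(rep("target", length(targets)),
              rep("housekeeping", length(STUDY_HOUSEKEEPING)),
              rep("control", length(ctrl))),
    lod_ct = lod_ct
  )
}

#' Read a panel layout from a TSV/CSV file
#'
#' Expects columns `assay_id` and `role`; an optional `lod_ct` column
#' (constant) overrides the default.
#'
#' @param path file path (`.tsv` or `.csv`).
#' @param lod_ct limit of detection used when the file has no lod_ct column.
#' @return A `panel_layout`.
#' @export
read_panel_layout <- function(path, lod_ct = 35) {
  df <- read_delim_auto(path)
  need <- c("assay_id", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("layout file missing column(s): ", paste(miss, collapse = ", "))
  if ("lod_ct" %in% names(df)) {
    lods <- unique(df$lod_ct)
    if (length(lods) != 1L) stop("lod_ct column must be constant")
    lod_ct <- as.numeric(lods)
  }
  panel_layout(df$assay_id, df$role, lod_ct = lod_ct)
}

#' Write a panel layout
#' @param layout a `panel_layout`.
#' @param path output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_panel_layout <- function(layout, path) {
  stopifnot(inherits(layout, "panel_layout"))
  df <- data.frame(assay_id = layout$assay_ids, role = layout$roles,
                   lod_ct = layout$lod_ct, stringsAsFactors = FALSE)
  write_delim_auto(df, path)
}
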