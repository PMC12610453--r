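# Tabular I/O for every artifact the pipeline consumes or emits.
# Dialect: UTF-8, delimiter chosen by extension (.tsv = tab, .csv = comma),
# decimal point only. All outputs are written at full double precision so
# write -> read round-trips exactly.

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("cannot infer delimiter from extension '.", ext,
              "' (use .tsv or .csv): ", path))
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = delim_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), quote = "\"",
                    comment.char = "", fileEncoding = "UTF-8")
}

write_delim_auto <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  # format(digits = 17) preserves doubles exactly through the round-trip
  out[num] <- lapply(df[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- NA
    s
  })
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a Ct table
#'
#' Couples a samples-by-assays matrix of raw Ct values with a
#' [panel_layout()]. Cells with `Ct >= lod_ct`, or missing, are flagged
#' undetected; values at or above the LOD are retained, not blanked, and
#' downstream operations decide exclusion.
#'
#' @param ct numeric matrix, samples in rows, assays in columns; dimnames
#'   give sample and assay ids.
#' @param layout a `panel_layout`; columns of `ct` must match
#'   `layout$assay_ids` exactly (order included).
#' @return An object of class `ct_table` with fields `sample_ids`, `layout`,
#'   `ct`, and logical mask `detected`.
#' @export
ct_table <- function(ct, layout) {
  stopifnot(inherits(layout, "panel_layout"), is.matrix(ct))
  if (is.null(rownames(ct))) stop("ct matrix must have sample ids as rownames")
  if (!identical(colnames(ct), layout$assay_ids))
    stop("ct matrix columns must match layout assay_ids")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  detected <- is.finite(ct) & ct < layout$lod_ct
  structure(
    list(sample_ids = rownames(ct), layout = layout, ct = ct,
         detected = detected),
    class = "ct_table"
  )
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", length(x$sample_ids), "samples x",
      length(x$layout$assay_ids), "assays;",
      sprintf("%.1f%%", 100 * mean(!x$detected)), "undetected (LOD",
      x$layout$lod_ct, ")\n")
  invisible(x)
}

#' Read a Ct table
#'
#' The file must have a sample-id first column and one column per assay in
#' the layout (extra columns are an error only if a layout assay is absent).
#'
#' @param path `.tsv`/`.csv` file; header row holds assay ids.
#' @param layout a `panel_layout`.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, layout) {
  stopifnot(inherits(layout, "panel_layout"))
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) stop("Ct table needs a sample-id column plus assays")
  sample_ids <- as.character(df[[1L]])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  miss <- setdiff(layout$assay_ids, names(df))
  if (length(miss))
    stop("Ct table missing assay column(s): ", paste(miss, collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(layout$assay_ids),
              dimnames = list(sample_ids, layout$assay_ids))
  for (a in layout$assay_ids) {
    col <- df[[a]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      stop("non-numeric Ct in assay '", a, "', sample(s) ",
           paste(sample_ids[bad], collapse = ", "))
    }
    m[, a] <- col
  }
  ct_table(m, layout)
}

#' Write a Ct table
#' @param x a `ct_table`.
#' @param path output `.tsv`/`.csv`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$ct, check.names = FALSE))
  write_delim_auto(df, path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `group` (cancer/healthy), `pole_status`
#' (mutant/wildtype/not_applicable), `age`, `bmi`, `grade`. Age, BMI and
#' grade may be missing. A healthy sample must have
#' `pole_status = not_applicable`, and vice versa.
#'
#' @param path `.tsv`/`.csv` file.
#' @return data.frame of class `sample_meta`, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delim_auto(path)
  need <- c("sample_id", "group", "pole_status", "age", "bmi", "grade")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  sample_meta(df[need])
}

#' Validate a sample-metadata data.frame
#' @param df data.frame with the columns of [read_sample_metadata()].
#' @return `df` with class `sample_meta` prepended.
#' @export
sample_meta <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  badg <- setdiff(unique(df$group), c("cancer", "healthy"))
  if (length(badg))
    stop("unknown group label(s): ", paste(badg, collapse = ", "))
  badp <- setdiff(unique(df$pole_status),
                  c("mutant", "wildtype", "not_applicable"))
  if (length(badp))
    stop("unknown pole_status label(s): ", paste(badp, collapse = ", "))
  mism <- (df$group == "healthy") != (df$pole_status == "not_applicable")
  if (any(mism))
    stop("pole_status must be 'not_applicable' exactly for healthy samples; ",
         "offending sample(s): ",
         paste(df$sample_id[mism], collapse = ", "))
  df$age <- as.numeric(df$age)
  df$bmi <- as.numeric(df$bmi)
  df$grade <- as.character(df$grade)
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Write pipeline result tables
#'
#' Serializes any set of pipeline outputs (DE tables, MDES results,
#' convergence rankings, enrichment tables, concordance pair tables) as TSV
#' with documented headers. Doubles are written at full precision so a
#' round-trip read returns identical values.
#'
#' @param tables named list of data.frames (names become file stems).
#' @param out_dir output directory, created if needed.
#' @return character vector of written file paths (named as `tables`).
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_delim_auto(as.data.frame(tables[[nm]], check.names = FALSE), p)
    paths[nm] <- p
  }
  paths
}
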