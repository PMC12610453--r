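# Cross-platform comparison of the panel DE table against an external
# (sequencing-derived) DE table: name matching, sign concordance, and the
# concordant-and-significant subset.

#' Read an external differential-expression table
#' @param path `.tsv`/`.csv` with columns mirna, log2fc, fdr.
#' @return data.frame of class `external_de`.
#' @export
read_external_de <- function(path) {
  df <- read_delim_auto(path)
  external_de(df)
}

#' @rdname read_external_de
#' @param df data.frame already in that layout.
#' @export
external_de <- function(df) {
  need <- c("mirna", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("external DE table missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[need]
  df$mirna <- as.character(df$mirna)
  if (!all(is.finite(df$log2fc))) stop("log2fc must be finite")
  norm <- normalize_mirna_name(df$mirna)
  if (anyDuplicated(norm))
    stop("duplicate miRNA names after normalization: ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "))
  class(df) <- c("external_de", "data.frame")
  df
}

# lowercase, species prefix stripped
normalize_mirna_name <- function(x) {
  sub("^hsa-", "", tolower(x))
}

# arm suffix (-5p/-3p) stripped from a normalized name
stem_mirna_name <- function(x) {
  sub("-(5p|3p)$", "", x)
}

#' Match miRNA names across platforms
#'
#' Two-stage matching: stage 1 pairs names that are exact matches after
#' normalization (lowercase, "hsa-" prefix stripped); stage 2 pairs
#' remaining names whose stems match after removing the arm suffix
#' (-5p/-3p). Pairing is one-to-one; a stem shared by several unmatched
#' arms on either side is ambiguous, and those names are left unmatched
#' and reported.
#'
#' @param panel_names,external_names character vectors.
#' @return list with `pairs` (data.frame: panel_name, external_name,
#'   match_stage in \{"exact", "stem"\}), `unmatched_panel`,
#'   `unmatched_external`, and `ambiguous_stems`.
#' @export
match_mirna_names <- function(panel_names, external_names) {
  panel_names <- unique(as.character(panel_names))
  external_names <- unique(as.character(external_names))
  pn <- normalize_mirna_name(panel_names)
  en <- normalize_mirna_name(external_names)
  hit <- match(pn, en)
  exact <- !is.na(hit)
  pairs <- data.frame(panel_name = panel_names[exact],
                      external_name = external_names[hit[exact]],
                      match_stage = rep("exact", sum(exact)),
                      stringsAsFactors = FALSE)
  rp <- panel_names[!exact]
  re <- setdiff(external_names, pairs$external_name)
  ambiguous <- character(0)
  if (length(rp) && length(re)) {
    sp <- stem_mirna_name(normalize_mirna_name(rp))
    se <- stem_mirna_name(normalize_mirna_name(re))
    for (stem in intersect(sp, se)) {
      ip <- which(sp == stem); ie <- which(se == stem)
      if (length(ip) == 1L && length(ie) == 1L) {
        pairs <- rbind(pairs, data.frame(
          panel_name = rp[ip], external_name = re[ie],
          match_stage = "stem", stringsAsFactors = FALSE))
      } else {
        ambiguous <- c(ambiguous, stem)
      }
    }
  }
  list(pairs = pairs,
       unmatched_panel = setdiff(panel_names, pairs$panel_name),
       unmatched_external = setdiff(external_names, pairs$external_name),
       ambiguous_stems = ambiguous)
}

#' Cross-platform sign-concordance report
#'
#' Matches panel against external miRNA names, scores each matched pair
#' as concordant when the log2 fold changes agree in sign (zero is
#' sign-indeterminate and never concordant), and extracts the subset that
#' is both concordant and significant on the panel side
#' (|log2 fold regulation| > lfc_threshold and FDR < fdr_threshold).
#'
#' @param panel_de a `de_table` from [run_contrast()].
#' @param ext an `external_de` table.
#' @param lfc_threshold,fdr_threshold panel-side significance thresholds
#'   (defaults 1 and 0.05).
#' @return list of class `concordance_report`: `pairs` (per-pair table
#'   with both log2FCs, concordance and panel significance),
#'   `concordant_significant` (subset), and `summary` (n_matched,
#'   n_concordant, percent_concordant — NA when nothing matched),
#'   plus the matching's unmatched/ambiguous name lists.
#' @export
concordance_report <- function(panel_de, ext, lfc_threshold = 1,
                               fdr_threshold = 0.05) {
  stopifnot(inherits(panel_de, "de_table"), inherits(ext, "external_de"))
  if (nrow(panel_de) == 0L || nrow(ext) == 0L)
    stop("both DE tables must be non-empty")
  mm <- match_mirna_names(panel_de$mirna, ext$mirna)
  pr <- mm$pairs
  if (nrow(pr)) {
    pi <- match(pr$panel_name, panel_de$mirna)
    ei <- match(pr$external_name, ext$mirna)
    pr$panel_log2fc <- panel_de$log2_fold_reg[pi]
    pr$panel_fdr <- panel_de$fdr[pi]
    pr$external_log2fc <- ext$log2fc[ei]
    pr$external_fdr <- ext$fdr[ei]
    pr$concordant <- !is.na(pr$panel_log2fc) &
      sign(pr$panel_log2fc) != 0 & sign(pr$external_log2fc) != 0 &
      sign(pr$panel_log2fc) == sign(pr$external_log2fc)
    pr$panel_significant <- !is.na(pr$panel_fdr) &
      abs(pr$panel_log2fc) > lfc_threshold & pr$panel_fdr < fdr_threshold
  } else {
    pr$panel_log2fc <- pr$panel_fdr <- numeric(0)
    pr$external_log2fc <- pr$external_fdr <- numeric(0)
    pr$concordant <- pr$panel_significant <- logical(0)
  }
  n_matched <- nrow(pr)
  n_conc <- sum(pr$concordant)
  structure(list(
    pairs = pr,
    concordant_significant = pr[pr$concordant & pr$panel_significant, ,
                                drop = FALSE],
    summary = data.frame(
      n_matched = n_matched, n_concordant = n_conc,
      percent_concordant = if (n_matched > 0)
        100 * n_conc / n_matched else NA_real_,
      n_concordant_significant = sum(pr$concordant & pr$panel_significant)),
    unmatched_panel = mm$unmatched_panel,
    unmatched_external = mm$unmatched_external,
    ambiguous_stems = mm$ambiguous_stems),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- x$summary
  cat("concordance_report:", s$n_matched, "matched,", s$n_concordant,
      "concordant",
      if (!is.na(s$percent_concordant))
        sprintf("(%.1f%%)", s$percent_concordant) else "(n/a)",
      ";", s$n_concordant_significant, "concordant & panel-significant\n")
  invisible(x)
}
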