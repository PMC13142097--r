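#' Read a heteronuclear NOE peak-intensity table
#'
#' TSV with columns `resno`, optional `resname`, `i_sat`, `i_unsat`: the
#' integrated peak intensities with and without proton saturation.
#' Unassigned or overlapped residues are absent rows, not zeros.
#'
#' @param path TSV path.
#' @return A `peak_table` tibble.
#' @export
read_peak_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("resno", "i_sat", "i_unsat") %in% names(tab))) {
    abort("peak table needs columns resno, i_sat, i_unsat",
          class = "conflex_parse_error")
  }
  as_peak_table(tab)
}

#' @rdname read_peak_table
#' @param tab Data frame with `resno`, `i_sat`, `i_unsat` (and optionally
#'   `resname`).
#' @export
as_peak_table <- function(tab) {
  tab <- as_tibble(tab)
  if (anyDuplicated(tab$resno)) {
    abort("duplicate residue numbers in peak table", class = "conflex_bad_input")
  }
  tab <- dplyr::arrange(tab, .data$resno)
  class(tab) <- c("peak_table", class(tab))
  tab
}

#' Steady-state heteronuclear NOE ratios
#'
#' Computes the per-residue ratio `I_sat / I_unsat`. Ratios near the rigid
#' limit (~0.8 at high field) indicate restricted backbone motion; reduced
#' ratios indicate sub-nanosecond flexibility. Rows with `I_unsat == 0`
#' cannot form a ratio and are excluded; they are reported in the `excluded`
#' attribute and via a warning.
#'
#' @param table A `peak_table` (or data frame with `resno`, `i_sat`,
#'   `i_unsat`).
#' @return A `residue_profile` (kind `"noe_ratio"`, unitless) with an
#'   `excluded` attribute listing dropped residue numbers.
#' @export
noe_ratio <- function(table) {
  if (nrow(table) == 0L) {
    abort("peak table is empty", class = "conflex_empty_profile")
  }
  bad <- table$i_unsat == 0
  if (all(bad)) {
    abort("all rows have I_unsat == 0; no ratios can be computed",
          class = "conflex_empty_profile")
  }
  if (any(bad)) {
    warn(paste0("excluding ", sum(bad), " row(s) with I_unsat == 0: residues ",
                paste(table$resno[bad], collapse = ", ")))
  }
  keep <- table[!bad, ]
  prof <- new_residue_profile(keep$resno, keep$i_sat / keep$i_unsat,
                              kind = "noe_ratio")
  attr(prof, "excluded") <- as.integer(table$resno[bad])
  prof
}

#' Flag low-NOE (flexible) regions
#'
#' Maximal contiguous runs of ratios strictly *below* the threshold; note the
#' inverted direction relative to the RMSD/RMSF/B-factor flags (fast local
#' motion lowers the NOE ratio).
#'
#' @param profile A `residue_profile` of NOE ratios.
#' @param threshold Ratio threshold, strict `<` (default 0.75).
#' @param min_length Minimum region length (default 2).
#' @return A `flex_regions` tibble.
#' @export
flag_low_noe <- function(profile, threshold = 0.75, min_length = 2L) {
  call_regions(profile, threshold = threshold, min_length = min_length,
               direction = "below")
}

#' Write an NOE ratio profile as TSV
#'
#' Columns: `resno`, `ratio`, `flagged` (below threshold).
#'
#' @param profile A `residue_profile` of NOE ratios.
#' @param path Output path.
#' @param threshold,min_length Flagging parameters.
#' @return `path`, invisibly.
#' @export
write_noe_tsv <- function(profile, path, threshold = 0.75, min_length = 2L) {
  regs <- flag_low_noe(profile, threshold, min_length)
  flagged <- rep(FALSE, nrow(profile))
  for (i in seq_len(nrow(regs))) {
    flagged <- flagged | (profile$resno >= regs$first[i] &
                            profile$resno <= regs$last[i])
  }
  readr::write_tsv(tibble(resno = profile$resno, ratio = profile$value,
                          flagged = flagged), path)
  invisible(path)
}
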