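#' Construct a per-residue profile
#'
#' A `residue_profile` is a tibble with one row per residue (`resno`, `value`)
#' and a `kind` attribute identifying the track: `"avg_pairwise_rmsd"`,
#' `"rmsf"`, `"bfactor"` or `"noe_ratio"`. All analysis stages return this
#' shape so that region calling and plotting are shared.
#'
#' @param resno Integer residue numbers (ascending, unique).
#' @param value Numeric track values (Angstrom, Angstrom^2 or unitless).
#' @param kind Track kind tag.
#' @param label Optional provenance label.
#' @return A `residue_profile` tibble.
#' @export
new_residue_profile <- function(resno, value, kind = "track", label = NULL) {
  stopifnot(length(resno) == length(value))
  if (is.unsorted(resno, strictly = TRUE)) {
    o <- order(resno)
    resno <- resno[o]; value <- value[o]
    if (anyDuplicated(resno)) abort("duplicate residue numbers in profile",
                                    class = "conflex_bad_input")
  }
  out <- tibble(resno = as.integer(resno), value = as.numeric(value))
  class(out) <- c("residue_profile", class(out))
  attr(out, "kind") <- kind
  attr(out, "label") <- label
  out
}

profile_kind <- function(x) attr(x, "kind") %||% "track"

#' Call threshold-exceeding regions on a residue profile
#'
#' Finds maximal contiguous runs of residues whose values are strictly above
#' (or, with `direction = "below"`, strictly below) the threshold. A break in
#' residue numbering breaks a run: unmodelled residues never bridge two
#' regions. Runs shorter than `min_length` are dropped, which separates
#' loop-scale flexible regions from single-residue minor peaks.
#'
#' @param profile A `residue_profile`, or any data frame with `resno` and
#'   `value` columns.
#' @param threshold Calling threshold (strict inequality), in the track's
#'   units. Must be positive.
#' @param min_length Minimum run length in residues (default 2).
#' @param direction `"above"` (default; flags high RMSD/RMSF/B) or `"below"`
#'   (flags low NOE ratios).
#' @return A `flex_regions` tibble: `first`, `last`, `n_res`, `peak`
#'   (extreme value in the region) and `mean_value`, with the threshold and
#'   direction stored as attributes. Zero rows when nothing exceeds the
#'   threshold.
#' @export
call_regions <- function(profile, threshold, min_length = 2L,
                         direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be a positive number", class = "conflex_bad_input")
  }
  resno <- as.integer(profile$resno)
  value <- as.numeric(profile$value)
  hit <- if (direction == "above") value > threshold else value < threshold
  hit[is.na(hit)] <- FALSE
  out <- tibble(first = integer(), last = integer(), n_res = integer(),
                peak = numeric(), mean_value = numeric())
  if (any(hit)) {
    # run id increments at every non-hit and at every numbering gap
    gap_break <- c(FALSE, diff(resno) != 1L)
    run_id <- cumsum(!hit | gap_break)
    runs <- split(which(hit), run_id[hit])
    rows <- purrr::map(runs, function(idx) {
      if (length(idx) < min_length) return(NULL)
      v <- value[idx]
      tibble(first = resno[idx[1]], last = resno[idx[length(idx)]],
             n_res = length(idx),
             peak = if (direction == "above") max(v) else min(v),
             mean_value = mean(v))
    })
    out <- dplyr::bind_rows(rows)
  }
  class(out) <- c("flex_regions", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "direction") <- direction
  attr(out, "kind") <- profile_kind(profile)
  out
}

#' Write a residue profile as TSV
#'
#' Columns: `resno`, `value`, `flagged` (whether the residue lies in a called
#' region at `threshold`).
#'
#' @param profile A `residue_profile`.
#' @param path Output path.
#' @param threshold,min_length,direction Passed to [call_regions()]; when
#'   `threshold` is `NULL` the `flagged` column is all `FALSE`.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, threshold = NULL,
                              min_length = 2L, direction = "above") {
  flagged <- rep(FALSE, nrow(profile))
  if (!is.null(threshold)) {
    regs <- call_regions(profile, threshold, min_length, direction)
    for (i in seq_len(nrow(regs))) {
      flagged <- flagged | (profile$resno >= regs$first[i] &
                              profile$resno <= regs$last[i])
    }
  }
  readr::write_tsv(tibble(resno = profile$resno, value = profile$value,
                          flagged = flagged), path)
  invisible(path)
}

#' Write called regions as TSV
#'
#' @param regions A `flex_regions` tibble from [call_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  readr::write_tsv(as_tibble(regions), path)
  invisible(path)
}

#' Plot a residue profile with its called regions
#'
#' Line plot of the track versus residue number, the calling threshold as a
#' dashed line, and called regions shaded.
#'
#' @param object A `residue_profile`.
#' @param threshold Optional threshold to draw and call regions at.
#' @param min_length,direction Passed to [call_regions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_profile <- function(object, threshold = NULL,
                                     min_length = 2L, direction = "above",
                                     ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue number", y = profile_kind(object)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    regs <- call_regions(object, threshold, min_length, direction)
    if (nrow(regs) > 0) {
      p <- p + ggplot2::geom_rect(
        data = as_tibble(regs), inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$first - 0.5, xmax = .data$last + 0.5,
                     ymin = -Inf, ymax = Inf),
        fill = "red", alpha = 0.15)
    }
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
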