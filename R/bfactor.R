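#' Cross-structure B-factor summary
#'
#' Aggregates the Calpha B-factor tracks of an ensemble: the member with the
#' highest overall B (mean over common residues), the per-residue mean over
#' all members, and the member with the lowest overall B. Contrasting the
#' three tracks shows which regions are mobile in every lattice environment
#' versus only in the loosest crystal.
#'
#' @param ensemble An `aligned_ensemble` whose members carry B-factors on all
#'   common residues.
#' @param normalize If `TRUE`, z-score each member's track (subtract its mean,
#'   divide by its SD) before aggregating, removing crystal-to-crystal offsets
#'   in overall B. Default `FALSE` (raw B-factors).
#' @return A `bfactor_summary`: list with `profile_max_structure`,
#'   `profile_mean`, `profile_min_structure` (each a `residue_profile`,
#'   Angstrom^2), `max_label`, `min_label`, `grand_mean` and `per_member`
#'   (tibble of member mean B used for the ranking).
#' @export
bfactor_summary <- function(ensemble, normalize = FALSE) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  bmat <- ensemble$b
  if (anyNA(bmat)) {
    bad <- which(is.na(bmat), arr.ind = TRUE)[1, ]
    abort(paste0("missing B-factor for member '",
                 ensemble$labels[bad[2]], "' at residue ",
                 ensemble$common_residues[bad[1]]),
          class = "conflex_missing_bfactor")
  }
  if (normalize) {
    bmat <- apply(bmat, 2, function(v) {
      s <- sd(v)
      (v - mean(v)) / (if (is.na(s) || s == 0) 1 else s)
    })
    if (is.null(dim(bmat))) bmat <- matrix(bmat, ncol = length(ensemble$labels))
    dimnames(bmat) <- dimnames(ensemble$b)
  }
  member_mean <- colMeans(bmat)
  i_max <- which.max(member_mean)
  i_min <- which.min(member_mean)
  mean_track <- rowMeans(bmat)
  resno <- ensemble$common_residues
  structure(
    list(
      profile_max_structure = new_residue_profile(resno, bmat[, i_max],
                                                  "bfactor",
                                                  ensemble$labels[i_max]),
      profile_mean = new_residue_profile(resno, mean_track, "bfactor",
                                         "mean over members"),
      profile_min_structure = new_residue_profile(resno, bmat[, i_min],
                                                  "bfactor",
                                                  ensemble$labels[i_min]),
      max_label = ensemble$labels[i_max],
      min_label = ensemble$labels[i_min],
      grand_mean = mean(mean_track),
      per_member = tibble(label = ensemble$labels, mean_b = unname(member_mean)),
      normalized = normalize
    ),
    class = "bfactor_summary"
  )
}

#' @export
print.bfactor_summary <- function(x, ...) {
  cat("<bfactor_summary> grand mean ", format(x$grand_mean, digits = 4),
      if (x$normalized) " (z)" else " A^2",
      "; highest: ", x$max_label, ", lowest: ", x$min_label, "\n", sep = "")
  invisible(x)
}

#' @describeIn bfactor_summary Long tibble of the three tracks
#'   (`resno`, `track`, `value`).
#' @param x A `bfactor_summary`.
#' @param ... Unused.
#' @export
tidy.bfactor_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(as_tibble(x$profile_max_structure), track = "max_structure"),
    dplyr::mutate(as_tibble(x$profile_mean), track = "mean"),
    dplyr::mutate(as_tibble(x$profile_min_structure), track = "min_structure")
  ) |>
    dplyr::select("resno", "track", "value")
}

#' @describeIn bfactor_summary One-row summary.
#' @export
glance.bfactor_summary <- function(x, ...) {
  tibble(grand_mean = x$grand_mean, max_label = x$max_label,
         min_label = x$min_label, n_members = nrow(x$per_member))
}

#' Flag regions with above-average B-factors
#'
#' Calls [call_regions()] on the cross-structure mean track with the grand
#' mean as threshold: the flagged regions are those whose average mobility
#' exceeds the domain-wide average.
#'
#' @param summary A `bfactor_summary`.
#' @param min_length Minimum region length (default 2).
#' @return A `flex_regions` tibble.
#' @export
flag_above_average <- function(summary, min_length = 2L) {
  stopifnot(inherits(summary, "bfactor_summary"))
  call_regions(summary$profile_mean, threshold = summary$grand_mean,
               min_length = min_length, direction = "above")
}

#' @describeIn bfactor_summary Plot the three tracks with the grand mean.
#' @param object A `bfactor_summary`.
#' @export
autoplot.bfactor_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$resno, .data$value, colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$grand_mean, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(max_structure = "orange",
                                            mean = "black",
                                            min_structure = "blue")) +
    ggplot2::labs(x = "Residue number",
                  y = if (object$normalized) "B-factor (z-score)"
                      else "B-factor (Å²)") +
    ggplot2::theme_minimal()
}

#' Write a B-factor summary as TSV
#'
#' Columns: `resno`, `b_max_structure`, `b_mean`, `b_min_structure`,
#' `flagged` (above grand mean, per [flag_above_average()]).
#'
#' @param summary A `bfactor_summary`.
#' @param path Output path.
#' @param min_length Minimum region length for flagging.
#' @return `path`, invisibly.
#' @export
write_bfactor_tsv <- function(summary, path, min_length = 2L) {
  regs <- flag_above_average(summary, min_length)
  resno <- summary$profile_mean$resno
  flagged <- rep(FALSE, length(resno))
  for (i in seq_len(nrow(regs))) {
    flagged <- flagged | (resno >= regs$first[i] & resno <= regs$last[i])
  }
  readr::write_tsv(tibble(resno = resno,
                          b_max_structure = summary$profile_max_structure$value,
                          b_mean = summary$profile_mean$value,
                          b_min_structure = summary$profile_min_structure$value,
                          flagged = flagged), path)
  invisible(path)
}
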