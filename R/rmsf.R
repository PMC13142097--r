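#' Construct a Calpha trajectory
#'
#' @param coords n_atoms x 3 x n_frames array of Calpha coordinates
#'   (Angstrom), or a list of n_atoms x 3 matrices.
#' @param times Frame times in picoseconds, strictly increasing.
#' @param resno Residue numbers (length n_atoms).
#' @param replicate_id Replicate label.
#' @return A `trajectory` object.
#' @export
new_trajectory <- function(coords, times, resno, replicate_id = "rep1") {
  if (is.list(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3L, length(coords)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (length(times) != dim(coords)[3]) {
    abort("length(times) must equal the number of frames",
          class = "conflex_bad_input")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("frame times must be strictly increasing", class = "conflex_bad_input")
  }
  if (length(resno) != dim(coords)[1]) {
    abort("length(resno) must equal the number of atoms",
          class = "conflex_bad_input")
  }
  structure(list(replicate_id = replicate_id, times = as.numeric(times),
                 coords = coords, resno = as.integer(resno)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$replicate_id, ": ", dim(x$coords)[3], " frames, ",
      dim(x$coords)[1], " atoms, t = ", min(x$times), "-", max(x$times),
      " ps\n", sep = "")
  invisible(x)
}

#' Convert trajectory coordinates from nanometres to Angstrom
#'
#' Multiplies all coordinates by 10. Trajectory post-processing pipelines
#' commonly emit nanometres; all analyses here are in Angstrom.
#'
#' @param traj A `trajectory` in nm.
#' @return The trajectory in Angstrom.
#' @export
nm_to_angstrom <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$coords <- traj$coords * 10
  traj
}

#' Select an analysis window and stride from a trajectory
#'
#' Keeps frames with `t_min <= t <= t_max`, then subsamples on a regular
#' stride grid starting at the first retained frame: for each grid time the
#' nearest retained frame is taken (ties to the earlier frame), so trajectories
#' whose native spacing already matches the stride are passed through
#' unchanged.
#'
#' @param traj A `trajectory`.
#' @param t_min,t_max Window bounds in ps (inclusive).
#' @param stride Sampling interval in ps (default: native spacing).
#' @return The windowed, strided `trajectory`.
#' @export
select_frames <- function(traj, t_min, t_max, stride = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (t_min >= t_max) abort("t_min must be < t_max", class = "conflex_bad_input")
  keep <- which(traj$times >= t_min & traj$times <= t_max)
  if (length(keep) == 0L) {
    abort(paste0("no frames in window [", t_min, ", ", t_max, "] ps"),
          class = "conflex_empty_selection")
  }
  times <- traj$times[keep]
  if (!is.null(stride)) {
    grid <- seq(times[1], times[length(times)], by = stride)
    picked <- vapply(grid, function(g) which.min(abs(times - g)), integer(1))
    keep <- keep[unique(picked)]
    times <- traj$times[keep]
  }
  new_trajectory(traj$coords[, , keep, drop = FALSE], times, traj$resno,
                 traj$replicate_id)
}

#' Per-residue RMSF of a trajectory
#'
#' Frames are superposed onto an iteratively refined mean structure: starting
#' from the first frame as reference, every frame is Kabsch-fitted on
#' `fit_selection`, the mean structure is recomputed, and the cycle repeats
#' until the mean moves by less than 1e-6 Angstrom (at most 10 iterations).
#' The fluctuation of atom i is then
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` over `measure_selection`.
#'
#' @param traj A `trajectory` with >= 2 frames.
#' @param fit_selection Atom indices used for superposition (default: all).
#' @param measure_selection Atom indices reported (default: all).
#' @return A `residue_profile` (kind `"rmsf"`, Angstrom) over
#'   `measure_selection`.
#' @export
rmsf <- function(traj, fit_selection = NULL, measure_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[3]
  if (nf < 2L) abort("need >= 2 frames", class = "conflex_bad_input")
  na <- dim(traj$coords)[1]
  fit_sel <- if (is.null(fit_selection)) seq_len(na) else as.integer(fit_selection)
  meas_sel <- if (is.null(measure_selection)) seq_len(na) else as.integer(measure_selection)
  fitted <- traj$coords
  ref <- fitted[, , 1]
  for (iter in seq_len(10L)) {
    for (f in seq_len(nf)) {
      fitted[, , f] <- kabsch_superpose(fitted[, , f], ref,
                                        fit_sel)$mobile_transformed
    }
    new_ref <- apply(fitted, c(1, 2), mean)
    shift <- sqrt(max(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < .tol$mean_conv) break
  }
  dev2 <- matrix(0, na, nf)
  for (f in seq_len(nf)) dev2[, f] <- rowSums((fitted[, , f] - ref)^2)
  vals <- sqrt(rowMeans(dev2))[meas_sel]
  new_residue_profile(traj$resno[meas_sel], vals, kind = "rmsf",
                      label = traj$replicate_id)
}

#' Aggregate per-replicate RMSF profiles
#'
#' Residue-wise mean and population standard deviation across independent
#' replicate runs.
#'
#' @param profiles List of `residue_profile` objects on identical residue
#'   sets (one per replicate).
#' @return An `rmsf_profile`: list with `per_replicate` (the inputs), `mean`
#'   and `sd` (`residue_profile`s) and `summary` (tibble `resno`,
#'   `mean_rmsf`, `sd_rmsf`). With a single replicate the SD is zero.
#' @export
aggregate_replicates <- function(profiles) {
  if (length(profiles) < 1L) abort("need >= 1 profile", class = "conflex_bad_input")
  resno <- profiles[[1]]$resno
  for (p in profiles[-1]) {
    if (!identical(p$resno, resno)) {
      abort("replicate profiles cover different residue sets",
            class = "conflex_bad_input")
    }
  }
  vals <- vapply(profiles, function(p) p$value, numeric(length(resno)))
  vals <- matrix(vals, nrow = length(resno))
  m <- rowMeans(vals)
  # population SD across replicates (0 for a single replicate)
  s <- sqrt(rowMeans((vals - m)^2))
  structure(
    list(per_replicate = profiles,
         mean = new_residue_profile(resno, m, "rmsf", "mean over replicates"),
         sd = new_residue_profile(resno, s, "rmsf_sd", "sd over replicates"),
         summary = tibble(resno = resno, mean_rmsf = m, sd_rmsf = s)),
    class = "rmsf_profile"
  )
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("<rmsf_profile> ", length(x$per_replicate), " replicate(s), ",
      nrow(x$summary), " residues; mean RMSF ",
      format(mean(x$summary$mean_rmsf), digits = 3), " A\n", sep = "")
  invisible(x)
}

#' @describeIn aggregate_replicates Tibble `resno`, `mean_rmsf`, `sd_rmsf`.
#' @param x An `rmsf_profile`.
#' @param ... Unused.
#' @export
tidy.rmsf_profile <- function(x, ...) x$summary

#' Flag high-RMSF regions
#'
#' @param profile A `residue_profile` of RMSF values (e.g. the `mean` track
#'   of an `rmsf_profile`).
#' @param threshold RMSF threshold in Angstrom, strict inequality
#'   (default 0.12).
#' @param min_length Minimum region length (default 2).
#' @return A `flex_regions` tibble.
#' @export
flag_high_rmsf <- function(profile, threshold = 0.12, min_length = 2L) {
  if (inherits(profile, "rmsf_profile")) profile <- profile$mean
  call_regions(profile, threshold = threshold, min_length = min_length,
               direction = "above")
}

#' @describeIn aggregate_replicates Mean RMSF with a +/- SD ribbon.
#' @param object An `rmsf_profile`.
#' @param threshold Optional threshold line.
#' @export
autoplot.rmsf_profile <- function(object, threshold = 0.12, ...) {
  p <- ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$resno)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rmsf - .data$sd_rmsf,
                                      ymax = .data$mean_rmsf + .data$sd_rmsf),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rmsf)) +
    ggplot2::labs(x = "Residue number", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Write an RMSF profile as TSV
#'
#' Columns: `resno`, `mean_rmsf`, `sd_rmsf`, `flagged`.
#'
#' @param x An `rmsf_profile`.
#' @param path Output path.
#' @param threshold,min_length Flagging parameters (strict `>`).
#' @return `path`, invisibly.
#' @export
write_rmsf_tsv <- function(x, path, threshold = 0.12, min_length = 2L) {
  regs <- flag_high_rmsf(x$mean, threshold, min_length)
  flagged <- rep(FALSE, nrow(x$summary))
  for (i in seq_len(nrow(regs))) {
    flagged <- flagged | (x$summary$resno >= regs$first[i] &
                            x$summary$resno <= regs$last[i])
  }
  readr::write_tsv(dplyr::mutate(x$summary, flagged = flagged), path)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB or a TSV frame table
#'
#' Multi-model PDB: each `MODEL` is one frame (times default to 0, 1, 2, ...
#' ps unless given). TSV: columns `time`, `resno`, `x`, `y`, `z`.
#'
#' @param path Input file.
#' @param format `"auto"`, `"pdb"` or `"tsv"`.
#' @param times Optional frame times (ps) overriding the defaults.
#' @param replicate_id Replicate label (default: file base name).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "tsv"),
                            times = NULL, replicate_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt|dat)$", path, ignore.case = TRUE)) "tsv" else "pdb"
  }
  replicate_id <- replicate_id %||% sub("\\.[^.]+$", "", basename(path))
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("time", "resno", "x", "y", "z")
    if (!all(need %in% names(tab))) {
      abort("trajectory TSV needs columns time, resno, x, y, z",
            class = "conflex_parse_error")
    }
    ts <- sort(unique(tab$time))
    resno <- tab$resno[tab$time == ts[1]]
    coords <- array(NA_real_, dim = c(length(resno), 3L, length(ts)))
    for (k in seq_along(ts)) {
      fr <- tab[tab$time == ts[k], ]
      fr <- fr[match(resno, fr$resno), ]
      coords[, , k] <- as.matrix(fr[, c("x", "y", "z")])
    }
    return(new_trajectory(coords, times %||% ts, resno, replicate_id))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) abort(conditionMessage(e),
                                            class = "conflex_parse_error"))
  ca <- which(pdb$atom$elety == "CA")
  resno <- as.integer(pdb$atom$resno[ca])
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, dim = c(length(ca), 3L, nf))
  for (f in seq_len(nf)) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[, , f] <- xyz[ca, , drop = FALSE]
  }
  new_trajectory(coords, times %||% (seq_len(nf) - 1), resno, replicate_id)
}
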