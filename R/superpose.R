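#' Optimal rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' distance from `mobile` to `target` over `fit_selection`, via singular value
#' decomposition of the cross-covariance matrix with reflection correction
#' (the sign of the smallest singular direction is flipped when needed so that
#' `det(rotation) = +1` always). The RMSD and per-site deviations are then
#' evaluated over *all* N sites after applying the fitted transform, which is
#' what per-residue deviation profiling needs when fitting on a rigid core.
#'
#' @param mobile,target N x 3 coordinate matrices (Angstrom), row i of one
#'   corresponding to row i of the other.
#' @param fit_selection Integer indices of the rows used for fitting
#'   (default: all rows). At least 3 non-collinear points are required.
#'
#' @return A `superposition` object: list with `rotation` (3 x 3, proper),
#'   `translation` (length-3), `rmsd` (Angstrom, over all sites),
#'   `per_site_deviation` (length N, Angstrom), `fit_selection`, and
#'   `mobile_transformed` (the superposed mobile coordinates).
#'   The transform maps mobile points as `x %*% t(rotation) + translation`.
#' @export
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' fit <- kabsch_superpose(a, a)
#' fit$rmsd  # 0
kabsch_superpose <- function(mobile, target, fit_selection = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L) {
    abort("mobile and target must be N x 3 matrices of equal size",
          class = "conflex_bad_input")
  }
  if (any(!is.finite(mobile)) || any(!is.finite(target))) {
    abort("coordinates must be finite", class = "conflex_bad_input")
  }
  n <- nrow(mobile)
  sel <- if (is.null(fit_selection)) seq_len(n) else as.integer(fit_selection)
  if (length(sel) < 3L || any(sel < 1L) || any(sel > n)) {
    abort("fit_selection must name >= 3 valid rows",
          class = "conflex_degenerate_fit")
  }
  mc <- colMeans(mobile[sel, , drop = FALSE])
  tc <- colMeans(target[sel, , drop = FALSE])
  P <- sweep(mobile[sel, , drop = FALSE], 2, mc)
  Q <- sweep(target[sel, , drop = FALSE], 2, tc)
  H <- crossprod(P, Q)  # 3 x 3 cross-covariance
  sv <- svd(H)
  # collinear fit set: rank of the centered points < 2
  pp <- svd(P, nu = 0, nv = 0)$d
  if (pp[2] <= .tol$degenerate * max(pp[1], 1)) {
    abort("fit selection is collinear or degenerate",
          class = "conflex_degenerate_fit")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(tc - mc %*% t(R))
  moved <- mobile %*% t(R) + matrix(translation, n, 3L, byrow = TRUE)
  dev <- sqrt(rowSums((moved - target)^2))
  structure(
    list(rotation = R, translation = translation,
         rmsd = sqrt(mean(dev^2)),
         per_site_deviation = dev,
         fit_selection = sel,
         mobile_transformed = moved),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd = ", format(x$rmsd, digits = 4), " A over ",
      length(x$per_site_deviation), " sites (fit on ",
      length(x$fit_selection), ")\n", sep = "")
  invisible(x)
}

#' @describeIn kabsch_superpose Per-site deviations as a tibble
#'   (`site`, `deviation`, `in_fit`).
#' @param x A `superposition`.
#' @param ... Unused.
#' @export
tidy.superposition <- function(x, ...) {
  tibble(site = seq_along(x$per_site_deviation),
         deviation = x$per_site_deviation,
         in_fit = seq_along(x$per_site_deviation) %in% x$fit_selection)
}

#' Calpha RMSD between two domain instances
#'
#' Restricts both instances to their shared author residue numbers, performs
#' Kabsch superposition and returns the RMSD. Symmetric to 1e-8 Angstrom.
#'
#' @param a,b `domain_instance` objects sharing >= 3 residue numbers, or bare
#'   N x 3 coordinate matrices (then used as-is, rows corresponding).
#' @param fit_selection Optional indices (into the common residues) used for
#'   fitting; deviations still span all common residues.
#' @return RMSD in Angstrom (single number).
#' @export
pair_rmsd <- function(a, b, fit_selection = NULL) {
  if (is.matrix(a) && is.matrix(b)) {
    return(kabsch_superpose(a, b, fit_selection)$rmsd)
  }
  stopifnot(inherits(a, "domain_instance"), inherits(b, "domain_instance"))
  common <- sort(intersect(a$resno, b$resno))
  if (length(common) < 3L) {
    abort(paste0(a$label, " and ", b$label, " share only ", length(common),
                 " residues; need >= 3"),
          class = "conflex_insufficient_overlap")
  }
  xa <- a$xyz[match(common, a$resno), , drop = FALSE]
  xb <- b$xyz[match(common, b$resno), , drop = FALSE]
  kabsch_superpose(xa, xb, fit_selection)$rmsd
}

#' Export a superposition transform as a 3 x 4 matrix TSV
#'
#' Rows are the rotation matrix with the translation as the fourth column.
#'
#' @param x A `superposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform_tsv <- function(x, path) {
  stopifnot(inherits(x, "superposition"))
  m <- cbind(x$rotation, x$translation)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = c("r1", "r2", "r3", "t"))
  invisible(path)
}
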