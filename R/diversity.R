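#' All-pairs Calpha RMSD matrix over an ensemble
#'
#' Computes the symmetric, zero-diagonal matrix of pairwise RMSDs between all
#' unordered member pairs, each pair superposed (Kabsch) on the ensemble's
#' common residues.
#'
#' @param ensemble An `aligned_ensemble` from [build_ensemble()].
#' @param fit_selection Optional indices into the common residues used for
#'   fitting each pair (default: all common residues).
#' @return An `rmsd_matrix`: list with `labels` and `values` (n x n matrix,
#'   Angstrom, dimnames = labels).
#' @export
pairwise_rmsd_matrix <- function(ensemble, fit_selection = NULL) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  n <- length(ensemble$labels)
  vals <- matrix(0, n, n, dimnames = list(ensemble$labels, ensemble$labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- tryCatch(
        kabsch_superpose(ensemble$coords[, , i], ensemble$coords[, , j],
                         fit_selection)$rmsd,
        error = function(e) {
          abort(paste0("superposition failed for pair ",
                       ensemble$labels[i], " / ", ensemble$labels[j], ": ",
                       conditionMessage(e)),
                class = "conflex_pair_error")
        })
      vals[i, j] <- vals[j, i] <- r
    }
  }
  structure(list(labels = ensemble$labels, values = vals),
            class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  n <- length(x$labels)
  off <- x$values[upper.tri(x$values)]
  cat("<rmsd_matrix> ", n, " members, ", length(off), " pairs; RMSD ",
      format(min(off), digits = 3), "-", format(max(off), digits = 3),
      " A (mean ", format(mean(off), digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @describeIn pairwise_rmsd_matrix Long-format pairs
#'   (`member_a`, `member_b`, `rmsd`), one row per unordered pair.
#' @param x An `rmsd_matrix`.
#' @param ... Unused.
#' @export
tidy.rmsd_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(member_a = x$labels[idx[, 1]], member_b = x$labels[idx[, 2]],
         rmsd = x$values[idx])
}

#' @describeIn pairwise_rmsd_matrix Summary statistics of the off-diagonal
#'   RMSDs.
#' @export
glance.rmsd_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble(n_members = length(x$labels), n_pairs = length(off),
         mean_rmsd = mean(off), median_rmsd = stats::median(off),
         max_rmsd = max(off), min_rmsd = min(off))
}

#' Write an RMSD matrix as TSV with header labels
#' @param x An `rmsd_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- as.data.frame(x$values)
  readr::write_tsv(dplyr::bind_cols(tibble(member = x$labels), df), path)
  invisible(path)
}

validate_rmsd_matrix <- function(x) {
  v <- x$values
  if (nrow(v) != ncol(v) || nrow(v) < 2L) {
    abort("distance matrix must be square with n >= 2",
          class = "conflex_invalid_distance")
  }
  if (any(v < 0) || max(abs(v - t(v))) > .tol$symmetry ||
      any(abs(diag(v)) > .tol$symmetry)) {
    abort("distance matrix must be symmetric, non-negative, zero-diagonal",
          class = "conflex_invalid_distance")
  }
  invisible(x)
}

#' Agglomerative clustering of an RMSD matrix
#'
#' Hierarchical clustering on the precomputed pairwise RMSD matrix. Members
#' are ordered lexicographically by label before merging so that equal-height
#' ties resolve to the smallest label pair, making the merge history
#' reproducible across input permutations.
#'
#' @param x An `rmsd_matrix` (or bare symmetric matrix with dimnames).
#' @param linkage `"average"` (UPGMA, default), `"single"` or `"complete"`.
#' @return A `cluster_tree`: list with `hclust` (the [stats::hclust()] fit on
#'   lexicographically ordered labels), `linkage` and `labels`.
#' @export
hierarchical_cluster <- function(x, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.matrix(x)) {
    labs <- rownames(x) %||% paste0("m", seq_len(nrow(x)))
    x <- structure(list(labels = labs,
                        values = `dimnames<-`(x, list(labs, labs))),
                   class = "rmsd_matrix")
  }
  validate_rmsd_matrix(x)
  o <- order(x$labels)
  v <- x$values[o, o, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(v), method = linkage)
  structure(list(hclust = hc, linkage = linkage, labels = hc$labels),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> ", length(x$labels), " members, ", x$linkage,
      " linkage; merge heights ",
      format(min(x$hclust$height), digits = 3), "-",
      format(max(x$hclust$height), digits = 3), " A\n", sep = "")
  invisible(x)
}

#' @export
as.hclust.cluster_tree <- function(x, ...) x$hclust

#' @describeIn hierarchical_cluster Merge history as a tibble
#'   (`step`, `height`, `members_a`, `members_b`: labels joined at each step).
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @export
tidy.cluster_tree <- function(x, ...) {
  hc <- x$hclust
  sets <- vector("list", nrow(hc$merge))
  members <- function(id, step) {
    if (id < 0) hc$labels[-id] else sets[[id]]
  }
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    a <- members(hc$merge[s, 1]); b <- members(hc$merge[s, 2])
    sets[[s]] <- c(a, b)
    out[[s]] <- tibble(step = s, height = hc$height[s],
                       members_a = paste(sort(a), collapse = ","),
                       members_b = paste(sort(b), collapse = ","))
  }
  dplyr::bind_rows(out)
}

#' Cut a cluster tree into k flat clusters
#'
#' @param tree A `cluster_tree`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector (names = member labels, values = cluster id);
#'   cluster ids follow [stats::cutree()] numbering. Stable across input
#'   permutation up to relabeling.
#' @export
flat_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  if (k < 1L || k > n) {
    abort(paste0("k must lie in [1, ", n, "]"), class = "conflex_range_error")
  }
  stats::cutree(tree$hclust, k = k)
}

#' Inter-cluster distances from an RMSD matrix and a flat clustering
#'
#' For every unordered cluster pair, aggregates the cross-pair RMSDs:
#' `"mean"` (average linkage-consistent, default), `"min"` (single) or
#' `"max"` (complete).
#'
#' @param x An `rmsd_matrix`.
#' @param clusters Named vector mapping member labels to cluster ids
#'   (as from [flat_clusters()]). At least two distinct clusters required.
#' @param aggregate Aggregation of cross-pair distances.
#' @return Tibble: `cluster_a`, `cluster_b`, `n_pairs`, `distance` (Angstrom).
#' @export
inter_cluster_distance <- function(x, clusters,
                                   aggregate = c("mean", "min", "max")) {
  aggregate <- match.arg(aggregate)
  validate_rmsd_matrix(x)
  if (is.null(names(clusters))) {
    abort("clusters must be a named vector over member labels",
          class = "conflex_bad_input")
  }
  ids <- sort(unique(clusters))
  if (length(ids) < 2L) {
    abort("need at least two clusters", class = "conflex_needs_two_clusters")
  }
  agg <- switch(aggregate, mean = mean, min = min, max = max)
  combs <- utils::combn(ids, 2L)
  purrr::map_dfr(seq_len(ncol(combs)), function(p) {
    a <- names(clusters)[clusters == combs[1, p]]
    b <- names(clusters)[clusters == combs[2, p]]
    cross <- x$values[a, b, drop = FALSE]
    tibble(cluster_a = combs[1, p], cluster_b = combs[2, p],
           n_pairs = length(cross), distance = agg(cross))
  })
}

#' Export a cluster tree as Newick with branch lengths
#'
#' @param tree A `cluster_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' Per-residue average pairwise RMSD profile
#'
#' For every unordered member pair in the chosen pair set, superposes the two
#' members (on `fit_selection`, default all common residues) and records the
#' per-residue deviation; the profile value at residue r is the mean deviation
#' at r over all pairs. High values localize the residues responsible for
#' ensemble diversity.
#'
#' @param ensemble An `aligned_ensemble`.
#' @param members Optional character vector of member labels restricting the
#'   averaged pair set to within-group pairs (default: all members).
#' @param fit_selection Optional indices into the common residues used for
#'   fitting each pair; deviations are always measured on all common residues.
#' @return A `residue_profile` (kind `"avg_pairwise_rmsd"`, Angstrom).
#' @export
per_residue_avg_rmsd <- function(ensemble, members = NULL, fit_selection = NULL) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  idx <- if (is.null(members)) seq_along(ensemble$labels)
         else match(members, ensemble$labels)
  if (anyNA(idx)) {
    abort(paste0("unknown member label(s): ",
                 paste(members[is.na(idx)], collapse = ", ")),
          class = "conflex_bad_input")
  }
  if (length(idx) < 2L) {
    abort("pair set needs at least 2 members", class = "conflex_bad_input")
  }
  nres <- length(ensemble$common_residues)
  acc <- numeric(nres)
  npairs <- 0L
  for (a in seq_along(idx)[-length(idx)]) {
    for (b in seq.int(a + 1L, length(idx))) {
      fit <- kabsch_superpose(ensemble$coords[, , idx[a]],
                              ensemble$coords[, , idx[b]], fit_selection)
      acc <- acc + fit$per_site_deviation
      npairs <- npairs + 1L
    }
  }
  new_residue_profile(ensemble$common_residues, acc / npairs,
                      kind = "avg_pairwise_rmsd",
                      label = if (is.null(members)) "all pairs"
                              else paste0("within-group (", length(idx), ")"))
}

#' Heatmap of an RMSD matrix in dendrogram leaf order
#'
#' @param object An `rmsd_matrix`.
#' @param tree Optional `cluster_tree` supplying the leaf order; computed
#'   with average linkage when omitted.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rmsd_matrix <- function(object, tree = NULL, ...) {
  tree <- tree %||% hierarchical_cluster(object)
  ord <- tree$labels[tree$hclust$order]
  long <- tidyr::expand_grid(member_a = ord, member_b = ord) |>
    dplyr::mutate(rmsd = object$values[cbind(.data$member_a, .data$member_b)],
                  member_a = factor(.data$member_a, levels = ord),
                  member_b = factor(.data$member_b, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(.data$member_a, .data$member_b,
                                     fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "cividis", name = "RMSD (Å)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
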