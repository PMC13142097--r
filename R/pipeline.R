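# Orchestration layer: each run_*() wires one analysis stage end-to-end
# (read inputs -> compute -> write canonical TSV/Newick/JSON outputs) and is
# what the command-line wrapper in inst/cli/conflex.R dispatches to.

log_msg <- function(..., quiet = FALSE) {
  if (!quiet) message("[conflex] ", ...)
}

#' Generate the full synthetic benchmark dataset
#'
#' Emits every input the downstream stages read: a crystal-like structure set
#' with ground truth, per-replicate trajectory tables for the flexible-loop
#' domain, and an NOE peak table, all deterministically from one seed.
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_ensemble_spec()].
#' @param n_frames Frames per trajectory replicate (default 2001: 0-200 ns
#'   at 100 ps spacing).
#' @param n_replicates Number of trajectory replicates (default 5).
#' @param traj_sigma Per-coordinate trajectory sigma: scaffold value and
#'   flexible-region value (Angstrom).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the written paths.
#' @export
run_simulate <- function(out_dir, spec = synthetic_ensemble_spec(),
                         n_frames = 2001L, n_replicates = 5L,
                         traj_sigma = c(scaffold = 0.05, flexible = 0.4),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- make_crystal_set(spec)
  crystal_dir <- file.path(out_dir, "crystals")
  paths <- write_crystal_set(cs, crystal_dir)
  log_msg("wrote ", length(paths), " crystal structures to ", crystal_dir,
          quiet = quiet)

  d1 <- spec$domains[1, ]
  resno <- seq.int(d1$first, d1$last)
  sigma <- rep(traj_sigma[["scaffold"]], length(resno))
  fr <- spec$flexible_regions[spec$flexible_regions$domain == d1$domain, ]
  for (i in seq_len(nrow(fr))) {
    sigma[resno >= fr$first[i] & resno <= fr$last[i]] <- traj_sigma[["flexible"]]
  }
  sigma_map <- tibble(resno = resno, sigma = sigma)
  traj_paths <- vapply(seq_len(n_replicates), function(r) {
    traj <- make_trajectory(n_frames, sigma_map,
                            seed = derive_seed(spec$seed, paste0("rep", r)),
                            replicate_id = paste0("rep", r))
    p <- file.path(out_dir, paste0("trajectory_rep", r, ".tsv"))
    write_trajectory_tsv(traj, p)
    p
  }, character(1))
  log_msg("wrote ", n_replicates, " trajectory replicates (", n_frames,
          " frames each)", quiet = quiet)

  noe <- make_noe_table(sigma_map, seed = derive_seed(spec$seed, "noe_table"))
  noe_path <- file.path(out_dir, "noe_peaks.tsv")
  readr::write_tsv(as_tibble(noe), noe_path)

  iface <- make_contact_structure(seed = spec$seed)
  iface_path <- file.path(out_dir, "interface.pdb")
  write_structure_pdb(iface, iface_path)
  log_msg("wrote NOE table and interface structure", quiet = quiet)
  invisible(list(crystals = paths, trajectories = traj_paths,
                 noe = noe_path, interface = iface_path,
                 ground_truth = file.path(crystal_dir, "ground_truth.json")))
}

#' Write a trajectory as a TSV frame table
#'
#' Long format: `time` (ps), `resno`, `x`, `y`, `z` (Angstrom).
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  nf <- dim(traj$coords)[3]
  n <- dim(traj$coords)[1]
  tab <- tibble(
    time = rep(traj$times, each = n),
    resno = rep(traj$resno, nf),
    x = as.vector(traj$coords[, 1, ]),
    y = as.vector(traj$coords[, 2, ]),
    z = as.vector(traj$coords[, 3, ])
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

read_structures <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|cif|ent)$",
                        full.names = TRUE)
  }
  if (length(paths) < 2L) {
    abort("need at least 2 structure files for an ensemble analysis",
          class = "conflex_insufficient_members")
  }
  lapply(paths, read_structure)
}

extract_all <- function(structures, domain, preset = "crystal",
                        chains = NULL, first = NULL, last = NULL) {
  pr <- domain_presets(preset)
  pr <- pr[pr$domain == domain, ]
  first <- first %||% pr$first
  last <- last %||% pr$last
  if (length(first) == 0L) {
    abort(paste0("unknown domain '", domain, "' and no explicit range given"),
          class = "conflex_bad_input")
  }
  out <- list()
  for (s in structures) {
    use_chains <- chains %||% sort(unique(s$atoms$chain))
    for (ch in use_chains) {
      out[[length(out) + 1L]] <- extract_domain(s, ch, first, last, domain)
    }
  }
  out
}

#' Ensemble conformational-diversity analysis, end to end
#'
#' Reads crystal structures, extracts the requested domain from every chain,
#' builds the aligned ensemble, and runs the core diversity analysis:
#' all-pairs RMSD matrix, hierarchical clustering with a flat cut and
#' inter-cluster distances, the per-residue average pairwise RMSD profile,
#' and flexible-region calls.
#'
#' @param inputs Structure file paths, or one directory of them.
#' @param domain Domain name matching a preset row (default `"PDZ1"`).
#' @param preset Domain boundary preset (see [domain_presets()]).
#' @param chains Chains to extract (default: all chains of each structure).
#' @param out_dir Optional output directory for TSV/Newick files.
#' @param linkage Clustering linkage (default `"average"`).
#' @param k Flat-cut cluster count (default 2).
#' @param threshold Region-calling threshold in Angstrom (default 1.0).
#' @param min_length Minimum region length (default 2).
#' @param quiet Suppress progress messages.
#' @return List with `ensemble`, `matrix`, `tree`, `clusters`,
#'   `inter_cluster`, `profile`, `regions` (and `paths` when `out_dir` is
#'   given).
#' @export
run_diversity <- function(inputs, domain = "PDZ1", preset = "crystal",
                          chains = NULL, out_dir = NULL,
                          linkage = "average", k = 2L, threshold = 1.0,
                          min_length = 2L, quiet = FALSE) {
  structures <- if (is.list(inputs) && inherits(inputs[[1]], "structure_model")) {
    inputs
  } else read_structures(inputs)
  instances <- extract_all(structures, domain, preset, chains)
  log_msg(length(structures), " structures -> ", length(instances), " ",
          domain, " members", quiet = quiet)
  ens <- build_ensemble(instances)
  dropped <- setdiff(seq.int(min(ens$common_residues), max(ens$common_residues)),
                     ens$common_residues)
  if (length(dropped) > 0) {
    log_msg("residues absent from >=1 member (dropped): ",
            paste(dropped, collapse = ", "), quiet = quiet)
  }
  mat <- pairwise_rmsd_matrix(ens)
  tree <- hierarchical_cluster(mat, linkage = linkage)
  clusters <- flat_clusters(tree, k = k)
  icd <- inter_cluster_distance(mat, clusters)
  prof <- per_residue_avg_rmsd(ens)
  regs <- call_regions(prof, threshold = threshold, min_length = min_length)
  log_msg(nrow(regs), " flexible region(s) above ", threshold, " A",
          quiet = quiet)
  out <- list(ensemble = ens, matrix = mat, tree = tree, clusters = clusters,
              inter_cluster = icd, profile = prof, regions = regs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      matrix = write_matrix_tsv(mat, file.path(out_dir, "rmsd_matrix.tsv")),
      tree = write_tree_newick(tree, file.path(out_dir, "cluster_tree.nwk")),
      clusters = {
        p <- file.path(out_dir, "clusters.tsv")
        readr::write_tsv(tibble(member = names(clusters),
                                cluster = unname(clusters)), p)
        p
      },
      inter_cluster = {
        p <- file.path(out_dir, "inter_cluster_distance.tsv")
        readr::write_tsv(icd, p)
        p
      },
      profile = write_profile_tsv(prof, file.path(out_dir, "avg_rmsd_profile.tsv"),
                                  threshold, min_length),
      regions = write_regions_tsv(regs, file.path(out_dir, "flexible_regions.tsv"))
    )
    out$paths <- paths
  }
  out
}

#' Cross-structure B-factor analysis, end to end
#'
#' @inheritParams run_diversity
#' @return List with `ensemble`, `summary`, `regions` (and `paths`).
#' @export
run_bfactor <- function(inputs, domain = "PDZ1", preset = "crystal",
                        chains = NULL, out_dir = NULL, min_length = 2L,
                        quiet = FALSE) {
  structures <- if (is.list(inputs) && inherits(inputs[[1]], "structure_model")) {
    inputs
  } else read_structures(inputs)
  instances <- extract_all(structures, domain, preset, chains)
  ens <- build_ensemble(instances)
  bs <- bfactor_summary(ens)
  regs <- flag_above_average(bs, min_length = min_length)
  log_msg(length(ens$labels), " members; grand mean B = ",
          format(bs$grand_mean, digits = 4), "; ", nrow(regs),
          " region(s) above average", quiet = quiet)
  out <- list(ensemble = ens, summary = bs, regions = regs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- list(
      tracks = write_bfactor_tsv(bs, file.path(out_dir, "bfactor_tracks.tsv"),
                                 min_length),
      regions = write_regions_tsv(regs, file.path(out_dir, "bfactor_regions.tsv"))
    )
  }
  out
}

#' Replicate-averaged trajectory RMSF analysis, end to end
#'
#' Applies the frame-selection protocol (analysis window and stride) to each
#' replicate, computes per-replicate RMSF profiles and aggregates them.
#'
#' @param inputs Per-replicate trajectory files (TSV or multi-model PDB).
#' @param t_min,t_max Analysis window in ps (defaults 40000-200000: the final
#'   160 ns of a 200 ns run).
#' @param stride Frame stride in ps (default 100).
#' @param fit_selection,measure_selection Atom index sets for [rmsf()].
#' @param threshold Flagging threshold in Angstrom (default 0.12).
#' @param min_length Minimum region length.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List with `profiles` (per replicate), `aggregate`, `regions`
#'   (and `paths`).
#' @export
run_rmsf <- function(inputs, t_min = 40000, t_max = 200000, stride = 100,
                     fit_selection = NULL, measure_selection = NULL,
                     threshold = 0.12, min_length = 2L, out_dir = NULL,
                     quiet = FALSE) {
  trajs <- if (is.list(inputs) && inherits(inputs[[1]], "trajectory")) {
    inputs
  } else lapply(inputs, read_trajectory)
  profiles <- lapply(trajs, function(tr) {
    win <- select_frames(tr, t_min, t_max, stride)
    log_msg(tr$replicate_id, ": ", dim(win$coords)[3], " frames in window",
            quiet = quiet)
    rmsf(win, fit_selection, measure_selection)
  })
  agg <- aggregate_replicates(profiles)
  regs <- flag_high_rmsf(agg$mean, threshold, min_length)
  log_msg(length(profiles), " replicate(s); ", nrow(regs),
          " region(s) above ", threshold, " A", quiet = quiet)
  out <- list(profiles = profiles, aggregate = agg, regions = regs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- list(
      rmsf = write_rmsf_tsv(agg, file.path(out_dir, "rmsf.tsv"), threshold,
                            min_length),
      regions = write_regions_tsv(regs, file.path(out_dir, "rmsf_regions.tsv"))
    )
  }
  out
}

#' Heteronuclear NOE ratio analysis, end to end
#'
#' @param input Peak-table TSV path or a `peak_table`.
#' @param threshold Low-ratio flag threshold (default 0.75, strict `<`).
#' @param min_length Minimum region length.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List with `profile`, `regions` (and `paths`).
#' @export
run_noe <- function(input, threshold = 0.75, min_length = 2L, out_dir = NULL,
                    quiet = FALSE) {
  tab <- if (inherits(input, "peak_table")) input else read_peak_table(input)
  prof <- noe_ratio(tab)
  excl <- attr(prof, "excluded")
  if (length(excl) > 0) {
    log_msg("excluded ", length(excl), " row(s) with I_unsat = 0",
            quiet = quiet)
  }
  regs <- flag_low_noe(prof, threshold, min_length)
  log_msg(nrow(prof), " ratios; ", nrow(regs), " region(s) below ",
          threshold, quiet = quiet)
  out <- list(profile = prof, regions = regs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- list(
      noe = write_noe_tsv(prof, file.path(out_dir, "noe_ratio.tsv"),
                          threshold, min_length),
      regions = write_regions_tsv(regs, file.path(out_dir, "noe_regions.tsv"))
    )
  }
  out
}

#' Interdomain contact analysis, end to end
#'
#' @param input Structure path or `structure_model`.
#' @param domain_a,domain_b Range specs (`list(chain=, first=, last=)`).
#' @param regions Optional tibble `first`, `last`, `side` of regions whose
#'   contact participation to report.
#' @param heavy_cutoff,polar_cutoff Contact cutoffs in Angstrom.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List with `contacts` and `fractions` (and `paths`).
#' @export
run_contacts <- function(input, domain_a, domain_b, regions = NULL,
                         heavy_cutoff = 4.5, polar_cutoff = 3.5,
                         out_dir = NULL, quiet = FALSE) {
  s <- if (inherits(input, "structure_model")) input else read_structure(input)
  cs <- find_contacts(s, domain_a, domain_b, heavy_cutoff, polar_cutoff)
  log_msg(nrow(cs), " contact pair(s), ", sum(cs$polar), " polar",
          quiet = quiet)
  fractions <- NULL
  if (!is.null(regions)) {
    fractions <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      tibble(first = regions$first[i], last = regions$last[i],
             side = regions$side[i],
             fraction = region_contact_fraction(
               cs, c(regions$first[i], regions$last[i]), regions$side[i]))
    })
  }
  out <- list(contacts = cs, fractions = fractions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- list(
      contacts = write_contacts_tsv(cs, file.path(out_dir, "contacts.tsv"))
    )
    if (!is.null(fractions)) {
      p <- file.path(out_dir, "contact_fractions.tsv")
      readr::write_tsv(fractions, p)
      out$paths$fractions <- p
    }
  }
  out
}
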