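# Seed policy: every generator derives an independent sub-seed from the user
# seed and a stream tag, so the crystal set, trajectories and NOE tables draw
# from separated RNG streams and adding one artifact never shifts another.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) %% 65521 * 48271 + h * 9973) %% 2147483629 + 1)
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

random_rotation <- function(max_angle_deg = 180) {
  axis <- stats::rnorm(3)
  angle <- stats::runif(1, 0, max_angle_deg * pi / 180)
  rotation_matrix(axis, angle)
}

#' Synthetic Calpha scaffold trace
#'
#' Deterministic smooth self-avoiding Calpha trace: an idealized alpha-helical
#' curve (radius 2.3 Angstrom, rise 1.5 Angstrom, 100 degrees per residue,
#' giving consecutive-Calpha distances of ~3.83 Angstrom) carrying a small
#' seeded smooth modulation and a seeded random orientation, so different
#' seeds give different but equally well-formed traces.
#'
#' @param n_residues Number of residues (>= 4).
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return n x 3 coordinate matrix (Angstrom) with consecutive-Calpha
#'   distances within \[3.7, 3.9\] Angstrom.
#' @export
make_scaffold <- function(n_residues, seed = 1L) {
  if (n_residues < 4L) {
    abort("need at least 4 residues", class = "conflex_bad_input")
  }
  with_seed_(derive_seed(seed, "scaffold"), {
    t <- seq_len(n_residues) - 1
    theta <- t * 100 * pi / 180
    base <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * t)
    # smooth low-amplitude modulation; too small to break Ca-Ca distances
    phase <- stats::runif(3, 0, 2 * pi)
    wobble <- 0.03 * cbind(sin(t / 9 + phase[1]), sin(t / 11 + phase[2]),
                           sin(t / 13 + phase[3]))
    xyz <- base + wobble
    R <- random_rotation()
    shift <- stats::runif(3, -20, 20)
    xyz %*% t(R) + matrix(shift, n_residues, 3, byrow = TRUE)
  })
}

#' Specification of a synthetic crystal ensemble
#'
#' Describes a set of crystal-like structures sharing per-domain scaffolds,
#' with controlled region-wise flexibility and chain asymmetry. The defaults
#' emulate a tandem-PDZ study setup: 10 structures, two chains (A, B) per
#' asymmetric unit, a PDZ1-like domain (residues 114-193) and a PDZ2-like
#' domain (197-273), with elevated flexibility confined to two chain-B PDZ1
#' loops (119-125 and 181-184, per-coordinate sigma 1.5 Angstrom) while
#' chain A is restrained to the scaffold noise level, emulating tighter
#' crystal-packing contacts.
#'
#' @param n_structures Number of crystal structures (default 10).
#' @param chains Chain identifiers (default `c("A", "B")`).
#' @param domains Tibble `domain`, `first`, `last` (default
#'   [domain_presets()] `"crystal"`).
#' @param flexible_regions Tibble `chain`, `domain`, `first`, `last`,
#'   `sigma`: per-coordinate Gaussian displacement sigma (Angstrom) applied
#'   to the region's residues.
#' @param scaffold_sigma Per-coordinate sigma for all other residues
#'   (default 0.05 Angstrom).
#' @param jitter_rotation Maximum rigid-body jitter rotation per structure
#'   and chain, degrees (default 5).
#' @param jitter_translation Maximum rigid-body jitter translation, Angstrom
#'   (default 2).
#' @param seed Integer seed.
#' @return A `synthetic_ensemble_spec` list.
#' @export
synthetic_ensemble_spec <- function(n_structures = 10L,
                                    chains = c("A", "B"),
                                    domains = domain_presets("crystal"),
                                    flexible_regions = tibble(
                                      chain = "B", domain = "PDZ1",
                                      first = c(119L, 181L),
                                      last = c(125L, 184L),
                                      sigma = 1.5),
                                    scaffold_sigma = 0.05,
                                    jitter_rotation = 5,
                                    jitter_translation = 2,
                                    seed = 1L) {
  if (nrow(flexible_regions) > 0) {
    for (i in seq_len(nrow(flexible_regions))) {
      d <- domains[domains$domain == flexible_regions$domain[i], ]
      if (nrow(d) == 0L ||
          flexible_regions$first[i] < d$first ||
          flexible_regions$last[i] > d$last) {
        abort(paste0("flexible region ", flexible_regions$first[i], "-",
                     flexible_regions$last[i], " lies outside domain ",
                     flexible_regions$domain[i]),
              class = "conflex_bad_input")
      }
    }
  }
  stopifnot(all(flexible_regions$sigma >= 0), scaffold_sigma >= 0)
  structure(
    list(n_structures = as.integer(n_structures), chains = chains,
         domains = domains, flexible_regions = flexible_regions,
         scaffold_sigma = scaffold_sigma,
         jitter_rotation = jitter_rotation,
         jitter_translation = jitter_translation,
         seed = as.integer(seed)),
    class = "synthetic_ensemble_spec"
  )
}

per_residue_sigma <- function(spec, chain, domain, resno) {
  sigma <- rep(spec$scaffold_sigma, length(resno))
  fr <- spec$flexible_regions
  fr <- fr[fr$chain == chain & fr$domain == domain, , drop = FALSE]
  for (i in seq_len(nrow(fr))) {
    sigma[resno >= fr$first[i] & resno <= fr$last[i]] <- fr$sigma[i]
  }
  sigma
}

#' Generate a synthetic crystal-structure set with known ground truth
#'
#' Each structure holds every chain and domain of the spec as a Calpha trace:
#' a per-domain scaffold shared by all structures and chains, plus iid
#' per-coordinate Gaussian displacements (region sigma inside flexible
#' regions, scaffold sigma elsewhere), plus a per-structure, per-chain
#' rigid-body jitter. Calpha B-factors are written from the generating sigma
#' via the isotropic relation `B = 8 pi^2 sigma^2`.
#'
#' @param spec A [synthetic_ensemble_spec()].
#' @return List with `structures` (list of `structure_model`, ids
#'   `S1`, `S2`, ...) and `truth` (the spec's flexible regions, sigmas and
#'   seed — the ground-truth record tests recover parameters against).
#' @export
make_crystal_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  scaffolds <- list()
  for (i in seq_len(nrow(spec$domains))) {
    d <- spec$domains[i, ]
    sc <- make_scaffold(d$last - d$first + 1L,
                        derive_seed(spec$seed, paste0("domain_", d$domain)))
    # separate the domains in space (tandem arrangement, no overlap)
    scaffolds[[d$domain]] <- sweep(sc, 2, c(35 * (i - 1), 0, 0), "+")
  }
  structures <- with_seed_(derive_seed(spec$seed, "crystals"), {
    lapply(seq_len(spec$n_structures), function(s) {
      rows <- list()
      for (ci in seq_along(spec$chains)) {
        chain <- spec$chains[ci]
        chain_offset <- c(0, 45 * (ci - 1), 0)
        xyz_all <- NULL; resno_all <- integer(); b_all <- numeric()
        for (i in seq_len(nrow(spec$domains))) {
          d <- spec$domains[i, ]
          resno <- seq.int(d$first, d$last)
          sigma <- per_residue_sigma(spec, chain, d$domain, resno)
          noise <- matrix(stats::rnorm(length(resno) * 3L), ncol = 3L) * sigma
          xyz_all <- rbind(xyz_all, scaffolds[[d$domain]] + noise)
          resno_all <- c(resno_all, resno)
          b_all <- c(b_all, 8 * pi^2 * sigma^2)
        }
        # rigid-body jitter of the whole chain about its centroid
        R <- random_rotation(spec$jitter_rotation)
        shift <- stats::runif(3, -spec$jitter_translation,
                              spec$jitter_translation)
        ctr <- colMeans(xyz_all)
        xyz_all <- sweep(xyz_all, 2, ctr) %*% t(R) +
          matrix(ctr + shift + chain_offset, nrow(xyz_all), 3, byrow = TRUE)
        rows[[ci]] <- tibble(
          chain = chain, resno = resno_all, icode = "", resid = "ALA",
          atom = "CA", element = "C",
          x = xyz_all[, 1], y = xyz_all[, 2], z = xyz_all[, 3],
          occ = 1, b = b_all, altloc = ""
        )
      }
      new_structure_model(dplyr::bind_rows(rows), paste0("S", s))
    })
  })
  list(structures = structures,
       truth = list(flexible_regions = spec$flexible_regions,
                    scaffold_sigma = spec$scaffold_sigma,
                    domains = spec$domains,
                    chains = spec$chains,
                    n_structures = spec$n_structures,
                    seed = spec$seed))
}

#' Generate a synthetic stationary-fluctuation trajectory
#'
#' Frames are a shared scaffold plus iid per-coordinate Gaussian noise with a
#' per-residue sigma. Residues inside `restrained_regions` have their sigma
#' divided by `restrain_factor`, emulating the damping of an interface region
#' by cross-domain restraints in a tandem construct.
#'
#' @param n_frames Number of frames (>= 2).
#' @param sigma_map Tibble `resno`, `sigma` (per-coordinate Angstrom), one
#'   row per residue.
#' @param restrained_regions Optional tibble `first`, `last`.
#' @param restrain_factor Sigma division factor inside restrained regions
#'   (default 3).
#' @param dt Frame spacing in ps (default 100).
#' @param seed Integer seed.
#' @param replicate_id Replicate label.
#' @return A `trajectory`; its `truth` attribute records the effective
#'   per-residue sigma.
#' @export
make_trajectory <- function(n_frames, sigma_map, restrained_regions = NULL,
                            restrain_factor = 3, dt = 100, seed = 1L,
                            replicate_id = "rep1") {
  if (n_frames < 2L) abort("need >= 2 frames", class = "conflex_bad_input")
  stopifnot(all(c("resno", "sigma") %in% names(sigma_map)))
  resno <- as.integer(sigma_map$resno)
  sigma <- as.numeric(sigma_map$sigma)
  if (!is.null(restrained_regions)) {
    for (i in seq_len(nrow(restrained_regions))) {
      sel <- resno >= restrained_regions$first[i] &
        resno <= restrained_regions$last[i]
      sigma[sel] <- sigma[sel] / restrain_factor
    }
  }
  n <- length(resno)
  scaffold <- make_scaffold(n, derive_seed(seed, "traj_scaffold"))
  coords <- with_seed_(derive_seed(seed, paste0("traj_", replicate_id)), {
    arr <- array(stats::rnorm(n * 3L * n_frames), dim = c(n, 3L, n_frames))
    arr <- arr * array(sigma, dim = c(n, 3L, n_frames))
    arr + array(scaffold, dim = c(n, 3L, n_frames))
  })
  traj <- new_trajectory(coords, (seq_len(n_frames) - 1) * dt, resno,
                         replicate_id)
  attr(traj, "truth") <- tibble(resno = resno, sigma = sigma)
  traj
}

#' Generate a synthetic heteronuclear NOE peak table
#'
#' NOE ratios are drawn anticorrelated with the injected flexibility:
#' `ratio = clip(base - k * sigma + eps, 0, 1)` with `eps ~ N(0, noise_sd)`;
#' intensities are back-computed with `I_unsat = 1`, so `I_sat = ratio`.
#'
#' @param sigma_map Tibble `resno`, `sigma` (Angstrom).
#' @param seed Integer seed.
#' @param base Rigid-limit ratio (default 0.85).
#' @param k Flexibility coupling in 1/Angstrom (default 0.2).
#' @param noise_sd SD of the additive ratio noise (default 0.02; use 0 for a
#'   noise-free table).
#' @return A `peak_table` with a `truth` attribute holding the noise-free
#'   ratios.
#' @export
make_noe_table <- function(sigma_map, seed = 1L, base = 0.85, k = 0.2,
                           noise_sd = 0.02) {
  stopifnot(all(c("resno", "sigma") %in% names(sigma_map)))
  clean <- pmin(pmax(base - k * sigma_map$sigma, 0), 1)
  ratio <- with_seed_(derive_seed(seed, "noe"), {
    pmin(pmax(clean + stats::rnorm(length(clean), 0, noise_sd), 0), 1)
  })
  tab <- as_peak_table(tibble(resno = as.integer(sigma_map$resno),
                              i_sat = ratio, i_unsat = 1))
  attr(tab, "truth") <- tibble(resno = as.integer(sigma_map$resno),
                               ratio = clean)
  tab
}

#' Generate a synthetic two-domain interface structure
#'
#' Builds an all-atom (N, CA, C, O backbone) stand-in for an interdomain
#' interface: two short facing strands, one per domain, separated so that
#' facing residues make heavy-atom contacts, including at least one O...N
#' pair within hydrogen-bonding distance. Used to exercise contact detection
#' without a deposited structure.
#'
#' @param resno_a,resno_b Residue numbers of the two facing segments.
#' @param gap Inter-strand backbone separation in Angstrom (default 4.0,
#'   within a 4.5 heavy-atom cutoff).
#' @param seed Integer seed for a small coordinate jitter (0.05 Angstrom).
#' @return A `structure_model` with chains holding both segments on chain
#'   `"A"` (a single-chain tandem interface).
#' @export
make_contact_structure <- function(resno_a = 130:136, resno_b = 230:236,
                                   gap = 4.0, seed = 1L) {
  with_seed_(derive_seed(seed, "contact"), {
    backbone <- function(resno, y, flip) {
      purrr::map_dfr(seq_along(resno), function(i) {
        x0 <- 3.5 * (i - 1)
        tibble(
          chain = "A", resno = resno[i], icode = "", resid = "GLY",
          atom = c("N", "CA", "C", "O"),
          element = c("N", "C", "C", "O"),
          x = x0 + c(0, 1.2, 2.4, 2.4),
          y = y + flip * c(0.3, 0, 0.3, 1.2),
          z = c(0, 0.4, 0, 0.4),
          occ = 1, b = 20, altloc = ""
        )
      })
    }
    a <- backbone(resno_a, 0, +1)
    b <- backbone(resno_b, gap, -1)
    at <- dplyr::bind_rows(a, b)
    at$x <- at$x + stats::rnorm(nrow(at), 0, 0.05)
    at$y <- at$y + stats::rnorm(nrow(at), 0, 0.05)
    at$z <- at$z + stats::rnorm(nrow(at), 0, 0.05)
    new_structure_model(at, "synthetic_interface")
  })
}

#' Write a structure model as a PDB file
#'
#' @param structure A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  pad_atom <- function(a) {
    ifelse(nchar(a) < 4L, sprintf(" %-3s", a), a)
  }
  lines <- sprintf(
    "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), pad_atom(at$atom),
    ifelse(at$altloc == "", " ", at$altloc),
    substr(at$resid, 1, 3), substr(at$chain, 1, 1), at$resno,
    ifelse(at$icode == "", " ", at$icode),
    at$x, at$y, at$z, at$occ, pmin(at$b, 999.99),
    toupper(at$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a synthetic crystal set to a directory
#'
#' Emits one PDB per structure (`S1.pdb`, ...) and the ground-truth record as
#' `ground_truth.json` beside them, so downstream tests never re-derive the
#' truth from the generator's internals.
#'
#' @param crystal_set Result of [make_crystal_set()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the PDB paths, invisibly.
#' @export
write_crystal_set <- function(crystal_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(crystal_set$structures, function(s) {
    p <- file.path(dir, paste0(s$structure_id, ".pdb"))
    write_structure_pdb(s, p)
    p
  }, character(1))
  jsonlite::write_json(crystal_set$truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
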