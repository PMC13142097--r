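#' Interdomain contact residues
#'
#' Records a residue pair as in contact when any heavy-atom (non-hydrogen)
#' pair across the two domains lies within `heavy_cutoff`. A pair is
#' additionally flagged polar when an N/O-N/O atom pair lies within
#' `polar_cutoff` — a donor/acceptor-agnostic, distance-only hydrogen-bond
#' proxy appropriate for crystal models without hydrogens.
#'
#' @param structure A `structure_model` with all-atom records.
#' @param domain_a,domain_b Range specifications: list with `chain`, `first`,
#'   `last` (and optionally `name`).
#' @param heavy_cutoff Heavy-atom contact cutoff in Angstrom (default 4.5).
#' @param polar_cutoff N/O-N/O polar-contact cutoff in Angstrom (default 3.5).
#' @return A `contact_set` tibble: `resno_a`, `resname_a`, `resno_b`,
#'   `resname_b`, `min_dist` (Angstrom), `polar`; cutoffs and domain specs
#'   stored as attributes.
#' @export
find_contacts <- function(structure, domain_a, domain_b,
                          heavy_cutoff = 4.5, polar_cutoff = 3.5) {
  stopifnot(inherits(structure, "structure_model"))
  get_atoms <- function(spec) {
    at <- structure$atoms |>
      dplyr::filter(.data$chain == spec$chain,
                    .data$resno >= spec$first, .data$resno <= spec$last,
                    !.data$resid %in% c("HOH", "WAT"),
                    toupper(.data$element) != "H")
    if (nrow(at) == 0L) {
      abort(paste0("no heavy atoms for domain on chain ", spec$chain,
                   " range ", spec$first, "-", spec$last),
            class = "conflex_missing_atoms")
    }
    at
  }
  a <- get_atoms(domain_a)
  b <- get_atoms(domain_b)
  dm <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
               outer(a$z, b$z, "-")^2)
  polar_a <- toupper(a$element) %in% c("N", "O")
  polar_b <- toupper(b$element) %in% c("N", "O")
  hit <- which(dm <= heavy_cutoff, arr.ind = TRUE)
  out <- tibble(resno_a = integer(), resname_a = character(),
                resno_b = integer(), resname_b = character(),
                min_dist = numeric(), polar = logical())
  if (nrow(hit) > 0L) {
    out <- tibble(
      resno_a = a$resno[hit[, 1]], resname_a = a$resid[hit[, 1]],
      resno_b = b$resno[hit[, 2]], resname_b = b$resid[hit[, 2]],
      dist = dm[hit],
      polar_pair = polar_a[hit[, 1]] & polar_b[hit[, 2]] &
        dm[hit] <= polar_cutoff
    ) |>
      dplyr::group_by(.data$resno_a, .data$resname_a,
                      .data$resno_b, .data$resname_b) |>
      dplyr::summarise(min_dist = min(.data$dist),
                       polar = any(.data$polar_pair), .groups = "drop") |>
      dplyr::arrange(.data$resno_a, .data$resno_b)
  }
  class(out) <- c("contact_set", class(out))
  attr(out, "heavy_cutoff") <- heavy_cutoff
  attr(out, "polar_cutoff") <- polar_cutoff
  attr(out, "domain_a") <- domain_a
  attr(out, "domain_b") <- domain_b
  out
}

#' Fraction of a region's residues participating in interdomain contacts
#'
#' @param contacts A `contact_set` from [find_contacts()].
#' @param region Length-2 vector `c(first, last)` of author residue numbers
#'   (inclusive), on the side given by `side`.
#' @param side `"A"` or `"B"`: which domain of the contact set the region
#'   belongs to.
#' @return Fraction in `[0, 1]` of region residues appearing in at least one
#'   contact pair.
#' @export
region_contact_fraction <- function(contacts, region, side = c("A", "B")) {
  side <- match.arg(side)
  if (length(region) != 2L || region[1] > region[2]) {
    abort("region must be c(first, last) with first <= last",
          class = "conflex_bad_input")
  }
  residues <- seq.int(region[1], region[2])
  in_contact <- if (side == "A") unique(contacts$resno_a) else unique(contacts$resno_b)
  mean(residues %in% in_contact)
}

#' Contact-fraction sensitivity to the heavy-atom cutoff
#'
#' Recomputes [region_contact_fraction()] over a sweep of heavy-atom cutoffs,
#' since participation figures can shift with the (unstandardized) contact
#' definition.
#'
#' @inheritParams find_contacts
#' @inheritParams region_contact_fraction
#' @param cutoffs Heavy-atom cutoffs to sweep (Angstrom).
#' @return Tibble: `heavy_cutoff`, `fraction`.
#' @export
contact_fraction_sweep <- function(structure, domain_a, domain_b, region,
                                   side = "A",
                                   cutoffs = seq(3.5, 5.5, by = 0.5),
                                   polar_cutoff = 3.5) {
  purrr::map_dfr(cutoffs, function(cc) {
    cs <- find_contacts(structure, domain_a, domain_b,
                        heavy_cutoff = cc, polar_cutoff = polar_cutoff)
    tibble(heavy_cutoff = cc,
           fraction = region_contact_fraction(cs, region, side))
  })
}

#' Write a contact set as TSV
#'
#' @param contacts A `contact_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  readr::write_tsv(as_tibble(contacts), path)
  invisible(path)
}
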