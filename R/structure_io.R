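#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a structure file into a `structure_model`: a light container holding
#' one model's atom records as a tibble. Alternate locations are resolved to a
#' single conformer per atom (highest occupancy, ties broken by lexicographic
#' altloc id), so every residue carries at most one Calpha.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param model Model index for multi-model files (default 1, the first).
#' @param structure_id Label for the structure; defaults to the file base name.
#'
#' @return A `structure_model` object: list with `structure_id` and `atoms`,
#'   a tibble with columns `chain`, `resno`, `icode`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`, `occ`, `b`, `altloc`.
#' @export
#' @examples
#' pdb <- system.file("extdata", "mini.pdb", package = "conflex")
#' read_structure(pdb)
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           model = 1L, structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path), class = "conflex_parse_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = TRUE, rm.alt = FALSE),
    error = function(e) {
      abort(paste0("cannot parse ", format, " file '", path, "': ",
                   conditionMessage(e)),
            class = "conflex_parse_error")
    }
  )
  atoms <- as_tibble(parsed$atom)
  n_models <- max(1L, nrow(parsed$xyz))
  if (model < 1L || model > n_models) {
    abort(paste0("model index ", model, " out of range (file has ",
                 n_models, " model(s))"),
          class = "conflex_parse_error")
  }
  if (model > 1L) {
    xyz <- matrix(parsed$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms <- tibble(
    chain   = as.character(atoms$chain),
    resno   = as.integer(atoms$resno),
    icode   = ifelse(is.na(atoms$insert) | atoms$insert == "", "", as.character(atoms$insert)),
    resid   = as.character(atoms$resid),
    atom    = as.character(atoms$elety),
    element = if ("elesy" %in% names(atoms)) as.character(atoms$elesy) else guess_element(atoms$elety),
    x = as.numeric(atoms$x), y = as.numeric(atoms$y), z = as.numeric(atoms$z),
    occ     = ifelse(is.na(atoms$o), 1, as.numeric(atoms$o)),
    b       = ifelse(is.na(atoms$b), 0, as.numeric(atoms$b)),
    altloc  = ifelse(is.na(atoms$alt) | atoms$alt == "", "", as.character(atoms$alt))
  )
  atoms <- resolve_altloc(atoms)
  if (!any(atoms$atom == "CA" & !atoms$resid %in% c("HOH", "WAT"))) {
    abort(paste0("no Calpha atoms in '", path, "'"),
          class = "conflex_empty_structure")
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in structure", class = "conflex_parse_error")
  }
  new_structure_model(atoms, structure_id %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' generator. The atom table must carry one row per atom with the columns
#' documented in [read_structure()]; missing `occ`/`b`/`altloc`/`element`
#' columns are filled with defaults.
#'
#' @param atoms Data frame of atom records.
#' @param structure_id Structure label.
#' @return A `structure_model`.
#' @export
new_structure_model <- function(atoms, structure_id) {
  atoms <- as_tibble(atoms)
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$atom)
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ca <- sum(x$atoms$atom == "CA")
  cat("<structure_model> ", x$structure_id, ": ",
      nrow(x$atoms), " atoms, ", ca, " Calpha, chains ",
      paste(sort(unique(x$atoms$chain)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# one conformer per (chain, resno, icode, atom): highest occupancy, tie ->
# lexicographically smallest altloc id
resolve_altloc <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "CA_"),
         two, toupper(substr(nm, 1, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one domain copy from a structure
#'
#' Pulls the Calpha trace of `domain_name` from one chain, keeping author
#' residue numbering and recording unmodelled residue numbers within the
#' requested inclusive range as gaps.
#'
#' @param structure A `structure_model`.
#' @param chain_id Chain identifier (e.g. `"A"`).
#' @param first,last First and last author residue numbers (inclusive).
#' @param domain_name Domain label (e.g. `"PDZ1"`).
#'
#' @return A `domain_instance`: list with `label`
#'   (`structure_id_chain_domain`), `structure_id`, `chain_id`, `domain`,
#'   `resno`, `icode`, `resid`, `xyz` (n x 3 matrix, Angstrom), `b`
#'   (Calpha B-factors, Angstrom^2) and `gaps` (missing residue numbers).
#' @export
extract_domain <- function(structure, chain_id, first, last, domain_name) {
  stopifnot(inherits(structure, "structure_model"))
  if (first > last) abort("first must be <= last", class = "conflex_bad_range")
  if (!chain_id %in% structure$atoms$chain) {
    abort(paste0("chain '", chain_id, "' not present in structure '",
                 structure$structure_id, "'"),
          class = "conflex_missing_chain")
  }
  ca <- structure$atoms |>
    dplyr::filter(.data$chain == chain_id, .data$atom == "CA",
                  !.data$resid %in% c("HOH", "WAT"),
                  .data$resno >= first, .data$resno <= last) |>
    dplyr::arrange(.data$resno, .data$icode)
  if (nrow(ca) == 0L) {
    abort(paste0("no Calpha residues in range ", first, "-", last,
                 " on chain ", chain_id, " of '", structure$structure_id, "'"),
          class = "conflex_empty_domain")
  }
  gaps <- setdiff(seq.int(first, last), ca$resno)
  structure(
    list(
      label = paste(structure$structure_id, chain_id, domain_name, sep = "_"),
      structure_id = structure$structure_id,
      chain_id = chain_id,
      domain = domain_name,
      resno = ca$resno,
      icode = ca$icode,
      resid = ca$resid,
      xyz = unname(as.matrix(ca[, c("x", "y", "z")])),
      b = ca$b,
      gaps = as.integer(gaps),
      range = c(first, last)
    ),
    class = "domain_instance"
  )
}

#' @export
print.domain_instance <- function(x, ...) {
  cat("<domain_instance> ", x$label, ": ", length(x$resno), " residues (",
      x$range[1], "-", x$range[2], "), ", length(x$gaps), " gap(s)\n", sep = "")
  invisible(x)
}

#' Domain boundary presets for the syntenin-1 PDZ tandem
#'
#' Two published residue-range conventions for the tandem: the
#' crystallographic assignment (PDZ1 Glu114-Arg193, PDZ2 Arg197-Phe273) and
#' the molecular-dynamics system definition (PDZ1 113-193, PDZ2 197-273).
#'
#' @param preset `"crystal"` (default) or `"md"`.
#' @return Tibble with columns `domain`, `first`, `last`.
#' @export
domain_presets <- function(preset = c("crystal", "md")) {
  preset <- match.arg(preset)
  switch(preset,
    crystal = tibble(domain = c("PDZ1", "PDZ2"),
                     first = c(114L, 197L), last = c(193L, 273L)),
    md      = tibble(domain = c("PDZ1", "PDZ2"),
                     first = c(113L, 197L), last = c(193L, 273L))
  )
}

#' Assemble comparable domain copies into an aligned ensemble
#'
#' Restricts every member to the residues (by author number) resolved in all
#' members, in ascending order, so that coordinate rows correspond across the
#' ensemble.
#'
#' @param instances List of `domain_instance` objects (>= 2).
#' @return An `aligned_ensemble`: list with `labels`, `common_residues`
#'   (ascending integer vector), `coords` (n_res x 3 x n_members array),
#'   `b` (n_res x n_members matrix) and `members` (the restricted instances).
#' @export
build_ensemble <- function(instances) {
  if (length(instances) < 2L) {
    abort("need at least 2 domain instances", class = "conflex_insufficient_members")
  }
  stopifnot(all(vapply(instances, inherits, logical(1), "domain_instance")))
  resno_sets <- lapply(instances, function(m) unique(m$resno))
  common <- sort(Reduce(intersect, resno_sets))
  if (length(common) < 3L) {
    cov <- vapply(seq_along(instances), function(i) {
      paste0(instances[[i]]$label, ": ", length(resno_sets[[i]]), " residues")
    }, character(1))
    abort(paste0("members share only ", length(common),
                 " residue(s); need >= 3. Coverage: ",
                 paste(cov, collapse = "; ")),
          class = "conflex_insufficient_overlap")
  }
  labels <- vapply(instances, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "#")
  }
  n <- length(common)
  coords <- array(NA_real_, dim = c(n, 3L, length(instances)),
                  dimnames = list(common, c("x", "y", "z"), labels))
  bmat <- matrix(NA_real_, n, length(instances), dimnames = list(common, labels))
  members <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    m <- instances[[i]]
    idx <- match(common, m$resno)  # first conformer if insertion codes duplicate a number
    coords[, , i] <- m$xyz[idx, , drop = FALSE]
    bmat[, i] <- m$b[idx]
    m$resno <- m$resno[idx]; m$icode <- m$icode[idx]; m$resid <- m$resid[idx]
    m$xyz <- m$xyz[idx, , drop = FALSE]; m$b <- m$b[idx]
    m$label <- labels[i]
    members[[i]] <- m
  }
  structure(
    list(labels = labels, common_residues = common,
         coords = coords, b = bmat, members = members),
    class = "aligned_ensemble"
  )
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat("<aligned_ensemble> ", length(x$labels), " members, ",
      length(x$common_residues), " common residues (",
      min(x$common_residues), "-", max(x$common_residues), ")\n", sep = "")
  invisible(x)
}

#' @describeIn build_ensemble Number of members and common residues.
#' @param x An `aligned_ensemble`.
#' @param ... Unused.
#' @export
glance.aligned_ensemble <- function(x, ...) {
  tibble(n_members = length(x$labels),
         n_common_residues = length(x$common_residues),
         first_residue = min(x$common_residues),
         last_residue = max(x$common_residues))
}

#' Write domain instances as a multi-model PDB file
#'
#' Each instance becomes one `MODEL` block holding its Calpha trace, with
#' author residue numbers and B-factors preserved at PDB field precision
#' (coordinates to 0.001 Angstrom).
#'
#' @param instances A `domain_instance` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_pdb <- function(instances, path) {
  if (inherits(instances, "domain_instance")) instances <- list(instances)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(instances)) {
    m <- instances[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_along(m$resno), substr(m$resid, 1, 3), substr(m$chain_id, 1, 1),
      m$resno, ifelse(m$icode == "", " ", m$icode),
      m$xyz[, 1], m$xyz[, 2], m$xyz[, 3], 1, pmin(m$b, 999.99)
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write domain instances as a TSV table
#'
#' One row per residue: `structure_id`, `chain`, `domain`, `resno`, `icode`,
#' `resname`, `x`, `y`, `z`, `b`.
#'
#' @inheritParams write_domain_pdb
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(instances, path) {
  if (inherits(instances, "domain_instance")) instances <- list(instances)
  tab <- purrr::map_dfr(instances, function(m) {
    tibble(structure_id = m$structure_id, chain = m$chain_id, domain = m$domain,
           resno = m$resno, icode = m$icode, resname = m$resid,
           x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3], b = m$b)
  })
  readr::write_tsv(tab, path)
  invisible(path)
}
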