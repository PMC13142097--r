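# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# structure_model holding a single-chain Calpha trace
make_ca_structure <- function(resno, xyz, chain = "A", b = NULL,
                              structure_id = "fix") {
  xyz <- as.matrix(xyz)
  new_structure_model(
    tibble::tibble(
      chain = chain, resno = as.integer(resno), icode = "", resid = "ALA",
      atom = "CA", element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = b %||% rep(0, length(resno)), altloc = ""
    ),
    structure_id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# domain_instance from raw coordinates via the public extraction path
make_instance <- function(resno, xyz, chain = "A", b = NULL, id = "fix",
                          domain = "D") {
  s <- make_ca_structure(resno, xyz, chain, b, id)
  extract_domain(s, chain, min(resno), max(resno), domain)
}

rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_proper_rotation <- function() {
  rotation_about(stats::rnorm(3), stats::runif(1, 0, pi))
}

apply_rigid <- function(xyz, R, t) {
  xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
}

# residue numbers / sigma map matching the default synthetic ensemble
default_sigma_map <- function(first = 114, last = 193,
                              loops = list(c(119, 125), c(181, 184)),
                              sigma_flex = 1.5, sigma_scaffold = 0.05) {
  resno <- seq.int(first, last)
  sigma <- rep(sigma_scaffold, length(resno))
  for (lp in loops) sigma[resno >= lp[1] & resno <= lp[2]] <- sigma_flex
  tibble::tibble(resno = resno, sigma = sigma)
}

flagged_residues <- function(regions) {
  if (nrow(regions) == 0) return(integer())
  unlist(lapply(seq_len(nrow(regions)),
                function(i) seq.int(regions$first[i], regions$last[i])))
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}
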