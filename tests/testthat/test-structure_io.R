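test_that("PDB fixture round-trips with altloc and missing-CA policies", {
  path <- system.file("extdata", "mini.pdb", package = "conflex")
  s <- read_structure(path)
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 3L)
  # altloc B (occupancy 0.6) beats A (0.4)
  r115 <- ca[ca$resno == 115, ]
  expect_equal(r115$altloc, "B")
  expect_equal(r115$x, 13.9)
})

test_that("altloc occupancy ties resolve to the lexicographically smaller id", {
  at <- tibble::tibble(
    chain = "A", resno = c(1L, 1L), icode = "", resid = "ALA", atom = "CA",
    element = "C", x = c(1, 2), y = 0, z = 0, occ = c(0.5, 0.5), b = 0,
    altloc = c("B", "A")
  )
  s <- new_structure_model(at, "tie")
  s2 <- make_ca_structure(1L, rbind(c(0, 0, 0)))
  resolved <- conflex:::resolve_altloc(s$atoms)
  expect_equal(nrow(resolved), 1L)
  expect_equal(resolved$altloc, "A")
  expect_equal(resolved$x, 2)
})

test_that("residues lacking a Calpha are skipped and reported as gaps", {
  resno <- c(114:119, 123:130)  # 120-122 unmodelled
  xyz <- matrix(seq_len(length(resno) * 3), ncol = 3) * 3.8
  s <- make_ca_structure(resno, xyz)
  d <- extract_domain(s, "A", 114, 130, "PDZ1")
  expect_equal(length(d$resno), 14L)
  expect_equal(d$gaps, c(120L, 121L, 122L))
})

test_that("extraction is inclusive and errors cover chain and range misuse", {
  resno <- 111:273
  xyz <- cbind(3.8 * seq_along(resno), 0, 0) + matrix(rnorm(length(resno) * 3, 0, 0.1), ncol = 3)
  s <- make_ca_structure(resno, xyz)
  d <- extract_domain(s, "A", 114, 193, "PDZ1")
  expect_equal(length(d$resno), 80L)  # 193 - 114 + 1
  expect_equal(d$gaps, integer())
  d2 <- extract_domain(s, "A", 197, 273, "PDZ2")
  expect_equal(length(d2$resno), 77L)
  expect_error(extract_domain(s, "Z", 114, 193, "PDZ1"),
               class = "conflex_missing_chain")
  expect_error(extract_domain(s, "A", 500, 600, "X"),
               class = "conflex_empty_domain")
  expect_error(extract_domain(s, "A", 200, 100, "X"),
               class = "conflex_bad_range")
})

test_that("inclusive-range law holds on complete chains", {
  set.seed(42)
  resno <- 50:200
  s <- make_ca_structure(resno, cbind(3.8 * seq_along(resno), 0, 0))
  for (i in 1:10) {
    first <- sample(50:150, 1)
    last <- first + sample(3:49, 1)
    d <- extract_domain(s, "A", first, last, "X")
    expect_equal(length(d$resno), last - first + 1)
  }
})

test_that("ensembles restrict members to the residue intersection", {
  xyz <- cbind(3.8 * (1:10), 0, 0)
  a <- make_instance(101:110, xyz, id = "a")
  b <- make_instance(setdiff(101:110, 105), xyz[-5, , drop = FALSE], id = "b")
  ens <- build_ensemble(list(a, b))
  expect_false(105 %in% ens$common_residues)
  expect_equal(ens$common_residues, setdiff(101:110, 105))
  expect_equal(dim(ens$coords), c(9L, 3L, 2L))
  # disjoint ranges cannot form an ensemble
  c_ <- make_instance(201:210, xyz, id = "c")
  expect_error(build_ensemble(list(a, c_)),
               class = "conflex_insufficient_overlap")
  expect_error(build_ensemble(list(a)),
               class = "conflex_insufficient_members")
})

test_that("the default two-chain crystal setup yields 20 members per domain", {
  cs <- make_crystal_set(synthetic_ensemble_spec(seed = 5))
  inst <- conflex:::extract_all(cs$structures, "PDZ1", "crystal")
  expect_length(inst, 20L)
  ens <- build_ensemble(inst)
  expect_equal(length(ens$labels), 20L)
  expect_equal(length(ens$common_residues), 80L)
})

test_that("build_ensemble is order-insensitive up to member permutation", {
  set.seed(9)
  xyz <- cbind(3.8 * (1:12), 0, 0) + matrix(rnorm(36, 0, 0.2), ncol = 3)
  inst <- lapply(1:4, function(i) {
    make_instance(1:12, xyz + matrix(rnorm(36, 0, 0.1), ncol = 3),
                  id = paste0("s", i))
  })
  e1 <- build_ensemble(inst)
  perm <- c(3, 1, 4, 2)
  e2 <- build_ensemble(inst[perm])
  expect_identical(e1$common_residues, e2$common_residues)
  expect_equal(e2$labels, e1$labels[perm])
  expect_equal(e2$coords[, , match(e1$labels, e2$labels)], e1$coords,
               ignore_attr = TRUE)
})

test_that("domain instances survive a PDB write/read round trip", {
  set.seed(3)
  xyz <- cbind(3.8 * (1:20), 0, 0) + matrix(rnorm(60, 0, 0.5), ncol = 3)
  b <- runif(20, 5, 90)
  inst <- list(make_instance(114:133, xyz, b = round(b, 2), id = "m1"),
               make_instance(114:133, xyz + 1, b = round(b, 2), id = "m2"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_domain_pdb(inst, path)
  for (k in 1:2) {
    rd <- read_structure(path, model = k, structure_id = paste0("m", k))
    d <- extract_domain(rd, "A", 114, 133, "D")
    expect_identical(d$resno, inst[[k]]$resno)
    expect_lt(max(abs(d$xyz - inst[[k]]$xyz)), 1e-3 + 1e-12)
    expect_equal(d$b, inst[[k]]$b, tolerance = 1e-6)
  }
})

test_that("domain presets expose both published boundary conventions", {
  cry <- domain_presets("crystal")
  md <- domain_presets("md")
  expect_equal(cry$first[cry$domain == "PDZ1"], 114L)
  expect_equal(md$first[md$domain == "PDZ1"], 113L)
  expect_equal(cry$last[cry$domain == "PDZ2"], 273L)
})
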