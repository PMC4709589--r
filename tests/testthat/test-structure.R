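test_that("PDB reading filters waters/heteroatoms and resolves altlocs", {
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 5))
  m <- read_structure(p)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(model_residues(m)), 5L)
  expect_equal(unique(m$chain), "A")

  # altloc A/B on one atom: keep the higher-occupancy record
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  O   HOH A   2       9.000   0.000   0.000  1.00  0.00           O",
    "END"), tmp)
  m2 <- read_structure(tmp)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$x, 5.0)

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "ATOM")
})

test_that("single-atom SASA matches the analytic sphere within 1%", {
  for (el in c("C", "N", "O", "S")) {
    p <- write_atoms_pdb(matrix(0, 1, 3), el)
    m <- read_structure(p)
    s <- compute_sasa(m, probe = 1.4, n_points = 960L)
    analytic <- 4 * pi * (m$radius[1] + 1.4)^2
    expect_lt(abs(s$sasa[1] - analytic) / analytic, 0.01)
  }
})

test_that("two overlapping spheres match the spherical-cap closed form within 2%", {
  R <- 1.70 + 1.4
  for (d in c(1.5, 2.5, 3.5, 4.5, 5.5)) {
    p <- write_atoms_pdb(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"))
    s <- compute_sasa(read_structure(p), probe = 1.4, n_points = 960L)
    total <- sum(s$sasa)
    oracle <- two_sphere_area_oracle(R, d)
    expect_lt(abs(total - oracle) / oracle, 0.02)
  }
})

test_that("SASA is deterministic, non-negative, and weakly decreases as atoms are added", {
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 6))
  m <- read_structure(p)
  s1 <- compute_sasa(m)
  s2 <- compute_sasa(m)
  expect_identical(s1$sasa, s2$sasa)
  expect_true(all(s1$sasa >= 0))

  a1 <- attr(compute_sasa(m[m$resno <= 3, ]), "atom_sasa")
  a2 <- attr(s1, "atom_sasa")[m$resno <= 3]
  expect_true(all(a2 <= a1 + 1e-9))
})

test_that("a caged residue is buried (relative SASA < 0.05)", {
  p <- make_structure_fixture(fixture_spec("cage"))
  s <- compute_sasa(read_structure(p))
  expect_lt(s$rel_sasa[s$resno == 1], 0.05)
})

test_that("planted disulfide and ionic pairs are detected as typed edges", {
  p <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "CYS", res2 = "CYS", atom1 = "SG", atom2 = "SG",
         distance = 2.04, resno1 = 201, resno2 = 208))))
  rin <- build_rin(read_structure(p))
  ss <- rin[rin$type == "disulfide", ]
  expect_equal(nrow(ss), 1L)
  expect_equal(c(ss$resno1, ss$resno2), c(201L, 208L))
  expect_equal(ss$distance, 2.04, tolerance = 0.01)

  p2 <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "ASP", res2 = "ARG", atom1 = "OD2", atom2 = "NH1", distance = 3.5))))
  rin2 <- build_rin(read_structure(p2))
  expect_equal(sum(rin2$type == "ionic"), 1L)
  expect_lte(rin2$distance[rin2$type == "ionic"], 4.0)

  # same charges do not form ionic edges
  p3 <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "ARG", res2 = "LYS", atom1 = "NH1", atom2 = "NZ", distance = 3.5))))
  rin3 <- build_rin(read_structure(p3))
  expect_equal(sum(rin3$type == "ionic"), 0L)
})

test_that("atoms beyond every cutoff give an empty network", {
  p <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "ALA", res2 = "ALA", atom1 = "CB", atom2 = "CB", distance = 30))))
  rin <- build_rin(read_structure(p))
  expect_equal(nrow(rin), 0L)
})

test_that("every edge respects its type cutoff and pairs are canonically ordered", {
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 12))
  rin <- build_rin(read_structure(p))
  co <- attr(rin, "cutoffs")
  type_key <- c("generic-contact" = "generic", "hydrogen-bond" = "hbond",
                ionic = "ionic", disulfide = "disulfide")
  expect_true(all(rin$distance <= co[type_key[rin$type]] + 1e-9))
  expect_true(all(rin$resno1 <= rin$resno2 | rin$chain1 != rin$chain2))
  # sequence-adjacent residues are not generic contacts
  gen <- rin[rin$type == "generic-contact", ]
  expect_true(all(abs(gen$resno1 - gen$resno2) >= 2))
  expect_false(any(duplicated(gen[, c("resno1", "resno2", "type")])))
})

test_that("network diffs are exact set subtraction on edge keys", {
  p1 <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "CYS", res2 = "CYS", atom1 = "SG", atom2 = "SG",
         distance = 2.04, resno1 = 201, resno2 = 208))))
  p2 <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "SER", res2 = "CYS", atom1 = "OG", atom2 = "SG",
         distance = 3.0, resno1 = 201, resno2 = 208))))
  a <- build_rin(read_structure(p1))
  b <- build_rin(read_structure(p2))
  d <- diff_rin(a, b)
  expect_true("disulfide" %in% d$lost$type)
  expect_false("disulfide" %in% d$gained$type)
  same <- diff_rin(a, a)
  expect_equal(nrow(same$lost), 0L)
  expect_equal(nrow(same$gained), 0L)

  # brute-force subtraction oracle on random edge tables
  set.seed(31)
  for (i in 1:10) {
    mk <- function() {
      n <- sample(3:12, 1)
      data.frame(chain1 = "A", resno1 = sample(1:6, n, TRUE), chain2 = "A",
                 resno2 = sample(7:12, n, TRUE),
                 type = sample(c("generic-contact", "ionic"), n, TRUE),
                 distance = runif(n, 2, 5), stringsAsFactors = FALSE)
    }
    x <- mk(); y <- mk()
    key <- function(t) paste(t$resno1, t$resno2, t$type)
    d2 <- diff_rin(x, y)
    expect_setequal(unique(key(d2$lost)), unique(setdiff(key(x), key(y))))
    expect_setequal(unique(key(d2$gained)), unique(setdiff(key(y), key(x))))
  }
})

test_that("backbone torsions are defined away from the termini", {
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 6))
  tor <- backbone_torsions(read_structure(p))
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[nrow(tor)]))
  expect_true(all(!is.na(tor$phi[-1])))
  expect_true(all(abs(tor$phi) <= 180, na.rm = TRUE))
})
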