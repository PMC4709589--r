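test_that("planted interfaces are recovered exactly", {
  p <- make_structure_fixture(fixture_spec("two-chain-complex",
    n_receptor = 8, n_ligand = 4, n_contact = 3, gap = 4))
  m <- read_structure(p)
  iface <- interface_residues(m, "B", 5.0)
  expect_equal(sort(iface$resno), 1:3)
  expect_equal(iface$min_distance, rep(4, 3), tolerance = 1e-6)

  expect_equal(nrow(interface_residues(m, "B", 0)), 0L)
  expect_error(interface_residues(m, "Z", 5.0), "chain")
})

test_that("interface extraction agrees with a brute-force scan on random complexes", {
  set.seed(37)
  for (i in 1:8) {
    n_rec <- sample(5:12, 1); n_lig <- sample(2:6, 1)
    p <- make_structure_fixture(fixture_spec("two-chain-complex",
      n_receptor = n_rec, n_ligand = n_lig,
      n_contact = sample(seq_len(min(n_rec, n_lig)), 1),
      gap = runif(1, 2.5, 6)))
    m <- read_structure(p)
    # jitter atoms deterministically to de-regularize the lattice
    m$x <- m$x + runif(nrow(m), -0.3, 0.3)
    m$y <- m$y + runif(nrow(m), -0.3, 0.3)
    m$z <- m$z + runif(nrow(m), -0.3, 0.3)
    cutoff <- runif(1, 3, 7)
    got <- interface_residues(m, "B", cutoff)
    expect_setequal(paste(got$chain, got$resno), brute_interface(m, "B", cutoff))
  }
})

test_that("neighbor analysis pairs panel positions with the cancer catalog", {
  catalog <- read_catalog(phd2_cancer_catalog_path())
  expect_equal(catalog$position, c(202L, 292L, 344L))

  p <- make_structure_fixture(fixture_spec("helix", n_residues = 150, start_resno = 200))
  m <- read_structure(p)
  pairs <- neighbor_analysis(m, c(203L, 291L), catalog, cutoff = 5.0)
  expect_true(any(pairs$query == 203 & pairs$catalog_position == 202))
  expect_true(any(pairs$query == 291 & pairs$catalog_position == 292))
  expect_equal(pairs$histology[pairs$query == 203 & pairs$catalog_position == 202],
               "Bladder")
  expect_equal(pairs$subtype[pairs$query == 291 & pairs$catalog_position == 292],
               "Adenocarcinoma")
  # adjacency holds even when the model does not resolve the positions
  small <- read_structure(make_structure_fixture(fixture_spec("helix", n_residues = 5)))
  pairs2 <- neighbor_analysis(small, c(203L, 291L), catalog)
  expect_true(any(pairs2$query == 203 & pairs2$catalog_position == 202))
  expect_true(all(is.na(pairs2$distance)))
  expect_setequal(attr(pairs2, "unresolved"), c(203L, 291L))

  empty <- neighbor_analysis(m, c(203L), catalog[integer(), ], cutoff = 5.0)
  expect_equal(nrow(empty), 0L)
})

test_that("exposed-patch clustering separates planted clusters from outliers", {
  # four mutually close exposed residues plus one far outlier, all on one helix
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 40))
  m <- read_structure(p)
  s <- compute_sasa(m)
  # helix rise 1.5 A: residues 10-13 span < 12 A; residue 39 is ~ 40 A away
  cl <- cluster_exposed_patch(m, c(10, 11, 12, 13, 39), s,
                              exposure_min = 0.2, link_cutoff = 12)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$clusters[[1]], c(10L, 11L, 12L, 13L))
  expect_equal(cl$clusters[[2]], 39L)
})

test_that("buried positions are excluded from patches", {
  p <- make_structure_fixture(fixture_spec("cage"))
  m <- read_structure(p)
  s <- compute_sasa(m)
  cl <- cluster_exposed_patch(m, 1L, s, exposure_min = 0.2, link_cutoff = 12)
  expect_length(cl$clusters, 0L)
  expect_equal(cl$buried, 1L)
})

test_that("single linkage equals union-find on random planted instances", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    coords <- matrix(runif(3 * n, 0, 60), ncol = 3)
    cutoff <- runif(1, 5, 25)
    # build a synthetic model: one CB atom per residue at the sampled coords
    df <- data.frame(chain = "A", resno = seq_len(n), resid = "ALA", elety = "CB",
                     element = "C", x = coords[, 1], y = coords[, 2], z = coords[, 3],
                     radius = 1.7, stringsAsFactors = FALSE)
    class(df) <- c("structure_model", "data.frame")
    sasa <- data.frame(chain = "A", resno = seq_len(n), resid = "ALA",
                       sasa = 100, rel_sasa = 1, exposed = TRUE,
                       stringsAsFactors = FALSE)
    class(sasa) <- c("sasa_profile", "data.frame")
    got <- cluster_exposed_patch(df, seq_len(n), sasa, exposure_min = 0.2,
                                 link_cutoff = cutoff)
    expect_equal(canon_clusters(got$clusters),
                 canon_clusters(union_find_clusters(coords, cutoff)))
  }
})

test_that("patch overlap reports the intersection with an interface set", {
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 20))
  m <- read_structure(p)
  s <- compute_sasa(m)
  cl <- cluster_exposed_patch(m, c(3, 4, 5), s, link_cutoff = 12,
                              interface = c(5, 6, 7))
  expect_equal(cl$overlap[[1]], 5L)
  cl2 <- cluster_exposed_patch(m, c(3, 4, 5), s, link_cutoff = 12,
                               interface = c(15, 16))
  expect_equal(cl2$overlap[[1]], integer(0))
})

test_that("structural flags fire on their defining geometries", {
  # catalytic site + charge inversion for an aspartate-to-histidine change
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 30, start_resno = 240))
  m <- read_structure(p)
  s <- compute_sasa(m)
  f <- derive_structural_flags(parse_variant("D254H"), m, s)
  expect_true(all(c("catalytic_site", "charge_inversion") %in% f))

  # exposed hydrophilic-to-hydrophobic change on a solvent-exposed helix
  p2 <- make_structure_fixture(fixture_spec("helix", n_residues = 10, start_resno = 288))
  m2 <- read_structure(p2)
  s2 <- compute_sasa(m2)
  f2 <- derive_structural_flags(parse_variant("K291I"), m2, s2)
  expect_true("exposed_hydrophobic" %in% f2)

  # proline loss
  p3 <- make_structure_fixture(fixture_spec("helix", n_residues = 10, start_resno = 314))
  m3 <- read_structure(p3)
  f3 <- derive_structural_flags(parse_variant("P317R"), m3, compute_sasa(m3))
  expect_true("proline_loss" %in% f3)

  # disulfide perturbation next to a planted Cys-Cys bond
  p4 <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
    list(res1 = "CYS", res2 = "CYS", atom1 = "SG", atom2 = "SG",
         distance = 2.04, resno1 = 201, resno2 = 208))))
  m4 <- read_structure(p4)
  s4 <- compute_sasa(m4)
  f4 <- derive_structural_flags(parse_variant("C201Y"), m4, s4)
  expect_true("disulfide_perturbation" %in% f4)

  # conservative change at a buried, non-functional position: no flags
  pc <- make_structure_fixture(fixture_spec("cage"))
  mc <- read_structure(pc)
  sc <- compute_sasa(mc)
  f5 <- derive_structural_flags(parse_variant("A1G"), mc, sc)
  expect_length(f5, 0L)
})

test_that("unresolvable positions fall back to sequence-only flags with a warning", {
  p <- make_structure_fixture(fixture_spec("helix", n_residues = 5))
  m <- read_structure(p)
  s <- compute_sasa(m)
  expect_warning(f <- derive_structural_flags(parse_variant("D254H"), m, s),
                 "not resolvable")
  expect_true(all(c("catalytic_site", "charge_inversion") %in% f))
})
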