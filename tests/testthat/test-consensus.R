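recs <- read_predictor_table(phd2_evidence_path())

classify_token <- function(tok, cfg = rule_config()) {
  rec <- recs[[tok]]
  classify_variant(normalize_and_count(rec), rec$conservation,
                   rec$structural_flags, rec, cfg)
}

test_that("the packaged evidence classifies in full agreement with the published verdicts", {
  expected <- phd2_published_verdicts()
  for (tok in names(expected)) {
    expect_equal(classify_token(tok)$label, unname(expected[tok]), info = tok)
  }
})

test_that("the discriminating cases fire the intended rules", {
  # full agreement across families -> Pathogenic
  expect_equal(classify_token("P317R")$rule, "full_agreement")
  # PolyPhen at Possibly damaging is what keeps D254H below Pathogenic
  d254h <- classify_token("D254H")
  expect_equal(d254h$label, "Likely Pathogenic")
  expect_equal(d254h$votes$n_deleterious, 8L)
  # strongly stabilizing ddG despite pathogenicity-tool votes -> Ambiguous
  p200q <- classify_token("P200Q")
  expect_equal(p200q$label, "Ambiguous")
  expect_equal(p200q$rule, "stability_conflict")
  # K291I's stabilizing ddG values are all weaker than -2 kcal/mol
  expect_equal(classify_token("K291I")$rule, "supported_majority")
  # nonsense variant has no predictor data
  expect_equal(classify_token("R398X")$rule, "no_predictor_data")
})

test_that("classification is total, deterministic, and fires exactly one rule", {
  set.seed(43)
  rules <- character(0)
  for (i in 1:60) {
    rec <- evidence_record(
      variant = parse_variant(random_variant_tokens(1)),
      snap = sample(list(NULL, "Neutral", "Non-Neutral"), 1)[[1]],
      pmut = sample(list(NULL, "Neutral", "Pathological"), 1)[[1]],
      snps3d = sample(list(NULL, list(label = "s", score = rnorm(1))), 1)[[1]],
      imutant = sample(list(NULL, list(direction = sample(c("Increase", "Decrease"), 1),
                                       reliability = 5L)), 1)[[1]],
      polyphen = sample(list(NULL, list(label = sample(c("Benign", "Possibly damaging",
                                                         "Probably damaging"), 1),
                                        score = runif(1))), 1)[[1]],
      eris_ddg = sample(c(NA, rnorm(1, 0, 3)), 1),
      foldx_ddg = sample(c(NA, rnorm(1, 0, 3)), 1),
      neemo_ddg = sample(c(NA, rnorm(1, 0, 3)), 1),
      conservation = sample(c(NA, "Variable", "Average", "Conserved"), 1))
    for (f in c("eris_ddg", "foldx_ddg", "neemo_ddg", "conservation"))
      if (length(rec[[f]]) && is.na(rec[[f]])) rec[[f]] <- NULL
    v1 <- classify_variant(normalize_and_count(rec), rec$conservation,
                           character(), rec)
    v2 <- classify_variant(normalize_and_count(rec), rec$conservation,
                           character(), rec)
    expect_identical(v1$label, v2$label)
    expect_true(v1$label %in% c("Pathogenic", "Likely Pathogenic", "Ambiguous",
                                "Likely Neutral"))
    expect_length(v1$rule, 1L)
    rules <- c(rules, v1$rule)
  }
  expect_gt(length(unique(rules)), 2L)
})

test_that("adding a deleterious vote escapes Likely Neutral except via the weak-minority rule", {
  rec <- recs[["V138A"]]
  base <- classify_variant(normalize_and_count(rec), rec$conservation,
                           character(), rec)
  expect_equal(base$label, "Likely Neutral")
  bumped <- rec
  bumped$snap <- "Non-Neutral"
  v <- classify_variant(normalize_and_count(bumped), bumped$conservation,
                        character(), bumped)
  expect_true(v$label != "Likely Neutral" || v$rule == "weak_minority")
})

test_that("rule thresholds are honored when reconfigured", {
  # raising the likely-pathogenic minimum pushes K423E (3 votes) to the fallback
  v <- classify_token("K423E", rule_config(likely_pathogenic_min = 4L))
  expect_equal(v$label, "Ambiguous")
  # weakening the strong-stabilization cutoff releases P200Q from the conflict rule
  v2 <- classify_token("P200Q", rule_config(strong_stabilization = -6))
  expect_equal(v2$label, "Likely Pathogenic")
})

test_that("run_pipeline reproduces the published verdict column end to end", {
  rep <- run_pipeline(phd2_panel_path(), phd2_evidence_path(),
                      catalog = phd2_cancer_catalog_path())
  expect_equal(nrow(rep$table), 12L)
  got <- setNames(rep$table$verdict, rep$table$variant)
  expected <- phd2_published_verdicts()
  expect_equal(got[names(expected)], expected)
  counts <- table(rep$table$verdict)
  expect_equal(unname(counts[["Likely Neutral"]]), 3L)
  expect_equal(unname(counts[["Likely Pathogenic"]]), 4L)
  expect_equal(unname(counts[["Pathogenic"]]), 3L)
  expect_equal(unname(counts[["Ambiguous"]]), 2L)
  expect_length(rep$uncovered, 0L)
})

test_that("uncovered panel variants and orphan evidence rows are reported", {
  tmp_panel <- tempfile()
  writeLines(c("D254H", "A99V"), tmp_panel)
  expect_warning(rep <- run_pipeline(tmp_panel, phd2_evidence_path()),
                 "without panel entry")
  expect_equal(rep$uncovered, "A99V")
  expect_equal(rep$table$variant, "D254H")

  empty_panel <- tempfile()
  writeLines("# nothing", empty_panel)
  rep2 <- suppressWarnings(run_pipeline(empty_panel, phd2_evidence_path()))
  expect_equal(nrow(rep2$table), 0L)
})

test_that("pipeline with structure attaches structural sections and stays deterministic", {
  pdb <- make_structure_fixture(fixture_spec("helix", n_residues = 230, start_resno = 195))
  rep1 <- suppressWarnings(run_pipeline(
    phd2_panel_path(), phd2_evidence_path(), structure = pdb,
    catalog = phd2_cancer_catalog_path()))
  rep2 <- suppressWarnings(run_pipeline(
    phd2_panel_path(), phd2_evidence_path(), structure = pdb,
    catalog = phd2_cancer_catalog_path()))
  expect_identical(rep1$table, rep2$table)
  expect_false(is.null(rep1$structural$patches))
  expect_true(any(rep1$structural$neighbor_pairs$query == 203 &
                    rep1$structural$neighbor_pairs$catalog_position == 202))
  # verdicts unchanged by the extra structural evidence on this panel
  expect_equal(setNames(rep1$table$verdict, rep1$table$variant),
               phd2_published_verdicts()[rep1$table$variant])
})

test_that("report serialization writes the verdict trail as JSON", {
  rep <- run_pipeline(phd2_panel_path(), phd2_evidence_path())
  out <- tempfile(fileext = ".json")
  write_report(rep, out)
  parsed <- jsonlite::read_json(out)
  expect_length(parsed$verdicts, 12L)
  expect_equal(parsed$verdicts$N203K$label, "Likely Pathogenic")
  expect_equal(parsed$verdicts$N203K$n_deleterious, 5L)
})
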