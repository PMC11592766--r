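# Synthetic study generator: structural contracts, determinism, and the
# tunable planted signal.

test_that("interactome generator enforces structure and determinism", {
  cfg <- simulation_config(n_proteins = 10L, n_functions = 5L,
                           ppi_attach_edges = 2L, seed = 7L)
  inter <- simulate_interactome(cfg)

  g <- igraph::graph_from_data_frame(inter$ppi, directed = FALSE,
                                     vertices = inter$proteins)
  expect_equal(igraph::vcount(g), 10L)
  expect_true(igraph::is_connected(g))

  hg <- igraph::graph_from_data_frame(inter$hierarchy, directed = TRUE)
  expect_true(igraph::is_dag(hg))

  expect_true(all(inter$annotations$protein %in% inter$proteins))
  expect_true(all(inter$annotations$func %in% inter$functions))

  again <- simulate_interactome(simulation_config(n_proteins = 10L,
                                                  n_functions = 5L,
                                                  ppi_attach_edges = 2L,
                                                  seed = 7L))
  expect_identical(inter$ppi, again$ppi)
  expect_identical(inter$hierarchy, again$hierarchy)
  expect_identical(inter$annotations, again$annotations)
})

test_that("degenerate layer sizes are rejected", {
  expect_error(simulation_config(n_proteins = 2L), "n_proteins")
  expect_error(simulation_config(n_functions = 1L), "n_functions")
  expect_error(simulation_config(planted_overlap_fraction = 1.2),
               "planted_overlap_fraction")
  expect_error(simulation_config(compounds_per_herb = c(5L, 3L)),
               "range")
})

test_that("connectivity and acyclicity hold across many seeds", {
  for (seed in 1:50) {
    cfg <- simulation_config(n_proteins = 20L, n_functions = 6L,
                             ppi_attach_edges = 2L, seed = seed)
    inter <- simulate_interactome(cfg)
    g <- igraph::graph_from_data_frame(inter$ppi, directed = FALSE,
                                       vertices = inter$proteins)
    expect_true(igraph::is_connected(g))
    hg <- igraph::graph_from_data_frame(inter$hierarchy, directed = TRUE)
    expect_true(igraph::is_dag(hg))
  }
})

test_that("disease table has the curated count, closed flag set, and is
           reproducible", {
  cfg <- simulation_config(n_proteins = 50L, n_disease_proteins = 15L,
                           seed = 3L)
  inter <- simulate_interactome(cfg)
  dz <- simulate_disease(cfg, inter)
  expect_identical(sum(dz$evidence == "curated"), 15L)
  expect_true(all(dz$evidence %in% c("curated", "animal_model",
                                     "literature_mined", "therapeutic")))
  expect_identical(dz, simulate_disease(cfg, inter))
})

test_that("herb panel respects ranges and marks exactly one planted herb", {
  cfg <- simulation_config(n_proteins = 100L, n_herbs = 20L,
                           compounds_per_herb = c(6L, 10L), seed = 11L)
  inter <- simulate_interactome(cfg)
  dz <- simulate_disease(cfg, inter)
  panel <- simulate_herb_panel(cfg, inter, dz)
  sizes <- table(panel$herb_compounds$herb)
  expect_length(sizes, 20L)
  expect_true(all(sizes >= 6L & sizes <= 10L))
  expect_length(panel$planted_herb, 1L)
  expect_true(panel$planted_herb %in% panel$herb_compounds$herb)
  # every compound has at least one target
  expect_true(all(panel$herb_compounds$compound %in%
                    panel$compound_targets$compound))
})

test_that("strong planting concentrates the planted herb's targets in the
           disease neighborhood", {
  cfg <- simulation_config(n_proteins = 150L, n_disease_proteins = 15L,
                           planted_overlap_fraction = 0.9, seed = 5L)
  inter <- simulate_interactome(cfg)
  dz <- simulate_disease(cfg, inter)
  panel <- simulate_herb_panel(cfg, inter, dz)
  curated <- dz$protein[dz$evidence == "curated"]
  nbhd <- unique(c(curated,
                   inter$ppi$protein_b[inter$ppi$protein_a %in% curated],
                   inter$ppi$protein_a[inter$ppi$protein_b %in% curated]))
  planted_compounds <- panel$herb_compounds$compound[
    panel$herb_compounds$herb == panel$planted_herb]
  targets <- unique(panel$compound_targets$protein[
    panel$compound_targets$compound %in% planted_compounds])
  expect_gte(mean(targets %in% nbhd), 0.5)
})

test_that("too-tight target range against a tiny disease neighborhood
           errors", {
  cfg <- simulation_config(n_proteins = 40L, n_functions = 4L,
                           n_disease_proteins = 1L,
                           targets_per_compound = c(30L, 39L), seed = 2L)
  inter <- simulate_interactome(cfg)
  dz <- simulate_disease(cfg, inter)
  expect_error(simulate_herb_panel(cfg, inter, dz), "neighborhood")
})

test_that("planted-signal overlap is monotone in the overlap fraction", {
  fractions <- c(0, 0.25, 0.5, 0.75, 1)
  mean_overlap <- vapply(fractions, function(f) {
    vals <- vapply(1:20, function(seed) {
      cfg <- simulation_config(n_proteins = 80L, n_functions = 10L,
                               n_herbs = 4L, n_disease_proteins = 10L,
                               planted_overlap_fraction = f, seed = seed)
      inter <- simulate_interactome(cfg)
      dz <- simulate_disease(cfg, inter)
      panel <- simulate_herb_panel(cfg, inter, dz)
      curated <- dz$protein[dz$evidence == "curated"]
      nbhd <- unique(c(curated,
                       inter$ppi$protein_b[inter$ppi$protein_a %in%
                                             curated],
                       inter$ppi$protein_a[inter$ppi$protein_b %in%
                                             curated]))
      pc <- panel$herb_compounds$compound[panel$herb_compounds$herb ==
                                            panel$planted_herb]
      tg <- unique(panel$compound_targets$protein[
        panel$compound_targets$compound %in% pc])
      mean(tg %in% nbhd)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gte(cor(fractions, mean_overlap, method = "spearman"), 0)
  # and the extremes are well separated
  expect_gt(mean_overlap[5], mean_overlap[1])
})

test_that("simulate_study writes all six tables plus a manifest", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_proteins = 30L, n_functions = 5L,
                           n_herbs = 3L, n_disease_proteins = 5L,
                           seed = 9L)
  res <- simulate_study(cfg, dir)
  expect_true(all(file.exists(res$paths)))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$planted_herb, res$planted_herb)
  expect_identical(manifest$seed, 9L)
})
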