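# One-command orchestration: simulate or load inputs, assemble the
# herb->target map and curated disease set, build the multiscale network,
# diffuse, rank herbs, score compounds of the top herbs, extract mechanism
# subnetworks, and write a manifest with file digests.

#' Pipeline configuration
#'
#' Exactly one of `simulation` or `inputs` must be given. `inputs` is a
#' named list of TSV paths: ppi, hierarchy, annotations, herb_compounds,
#' compound_targets, disease.
#'
#' @param simulation a [simulation_config()] for a synthetic study
#' @param inputs named list of input TSV paths for a real study
#' @param weights a [node_class_weights()]
#' @param walk a [walk_parameters()]
#' @param min_compounds herb inclusion threshold (default 6)
#' @param top_n_targets targets kept per herb (default 50)
#' @param k_top mechanism subnetwork size per profile (default 20)
#' @param n_top_herbs herbs taken forward to compound scoring (default 3)
#' @param max_active_compounds compounds flagged active per herb (default 3)
#' @param gmt optional GMT library path for over-representation analysis
#' @param out_dir output directory
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            weights = node_class_weights(),
                            walk = walk_parameters(),
                            min_compounds = 6L, top_n_targets = 50L,
                            k_top = 20L, n_top_herbs = 3L,
                            max_active_compounds = 3L,
                            gmt = NULL, out_dir = tempfile("herbnetdiff_")) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of `simulation` or `inputs` must be set",
         call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("ppi", "hierarchy", "annotations", "herb_compounds",
              "compound_targets", "disease")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0L) {
      stop("inputs is missing path(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(simulation = simulation, inputs = inputs,
                 weights = weights, walk = walk,
                 min_compounds = as.integer(min_compounds),
                 top_n_targets = as.integer(top_n_targets),
                 k_top = as.integer(k_top),
                 n_top_herbs = as.integer(n_top_herbs),
                 max_active_compounds = as.integer(max_active_compounds),
                 gmt = gmt, out_dir = out_dir),
            class = "pipeline_config")
}

# Load a yaml pipeline config written by hand; simulation block becomes a
# simulation_config, walk/weights blocks override the defaults.
#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognised blocks: `simulation`, `inputs`,
#'   `weights`, `walk`, plus the scalar options of [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$simulation)) {
    args$simulation <- do.call(simulation_config, y$simulation)
  }
  args$inputs <- y$inputs
  if (!is.null(y$weights)) args$weights <- do.call(node_class_weights,
                                                   y$weights)
  if (!is.null(y$walk)) args$walk <- do.call(walk_parameters, y$walk)
  for (nm in c("min_compounds", "top_n_targets", "k_top", "n_top_herbs",
               "max_active_compounds", "gmt", "out_dir")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(pipeline_config, args)
}

# Attach the disease and a set of drug-class entities to a base network and
# return profiles for all of them.
diffuse_entities <- function(base_net, disease_id, disease_proteins,
                             entity_sets, weights, walk) {
  net <- attach_entity(base_net, disease_id, disease_proteins,
                       "entity_disease")
  for (id in names(entity_sets)) {
    net <- attach_entity(net, id, entity_sets[[id]], "entity_drug")
  }
  tm <- build_transition_matrix(net, weights)
  profs <- batch_profiles(tm, c(disease_id, names(entity_sets)), walk)
  list(net = net, tm = tm,
       disease_profile = profs[[disease_id]],
       profiles = profs[names(entity_sets)])
}

#' Score the compounds of one herb against the disease
#'
#' Attaches each compound of the herb as its own entity on the multiscale
#' network (alongside the disease), computes diffusion profiles, and ranks
#' the compounds by correlation score; the top `max_active` are flagged as
#' the herb's putative active compounds. Compounds with no target in the
#' network are excluded with a warning.
#'
#' @param herb_id herb whose compounds are scored
#' @param herb_compounds named list herb -> compound ids
#' @param compound_targets named list compound -> protein ids
#' @param base_net the `multiscale_network` without entities
#' @param disease_id,disease_proteins the disease entity and its curated
#'   proteins
#' @param weights a [node_class_weights()]
#' @param walk a [walk_parameters()]
#' @param max_active compounds flagged active (default 3)
#' @return `ranked_candidates` data frame with an extra `active` column
#' @export
score_compounds_of_herb <- function(herb_id, herb_compounds,
                                    compound_targets, base_net,
                                    disease_id, disease_proteins,
                                    weights = node_class_weights(),
                                    walk = walk_parameters(),
                                    max_active = 3L) {
  if (!herb_id %in% names(herb_compounds)) {
    stop("unknown herb: ", herb_id, call. = FALSE)
  }
  comps <- unique(herb_compounds[[herb_id]])
  registry_proteins <- base_net$nodes$id[base_net$nodes$class == "protein"]
  sets <- lapply(comps, function(cmp) {
    intersect(unique(compound_targets[[cmp]]), registry_proteins)
  })
  names(sets) <- comps
  usable <- vapply(sets, length, integer(1)) > 0L
  note_drop("compound-scoring",
            paste0("compound(s) of ", herb_id, " without network targets"),
            sum(!usable))
  sets <- sets[usable]
  if (length(sets) == 0L) {
    stop("herb ", herb_id, " has no compound with targets in the network",
         call. = FALSE)
  }
  d <- diffuse_entities(base_net, disease_id, disease_proteins, sets,
                        weights, walk)
  tab <- rank_candidates(d$profiles, d$disease_profile, sets,
                         disease_proteins, registry_proteins)
  tab$active <- seq_len(nrow(tab)) <= max_active
  attr(tab, "network") <- d$net
  attr(tab, "profiles") <- d$profiles
  attr(tab, "disease_profile") <- d$disease_profile
  tab
}

#' Run the full analysis pipeline
#'
#' Figure of merit: the ranked herb table. Stages: obtain inputs (simulate
#' or load), assemble herb->target panels and the curated disease set,
#' build the multiscale network, diffuse all herbs and the disease, rank
#' herbs by correlation score, score the compounds of the top herbs,
#' extract the mechanism subnetwork of each top herb's best compound, run
#' over-representation analysis when a GMT library is given, and write all
#' artifacts plus a JSON manifest with md5 digests.
#'
#' @param cfg a [pipeline_config()]
#' @return object of class `herbnet_run` (ranked table, compound tables,
#'   subnetworks, shared-target summary, manifest), invisibly writing
#'   artifacts to `cfg$out_dir`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  paths <- stage("inputs", {
    if (!is.null(cfg$simulation)) {
      sim <- simulate_study(cfg$simulation, file.path(out, "sim"))
      sim$paths
    } else unlist(cfg$inputs)
  })

  asm <- stage("assembly", {
    tabs <- load_tables(paths[["herb_compounds"]],
                        paths[["compound_targets"]], paths[["disease"]])
    hc <- filter_herbs_min_compounds(tabs$herb_compounds,
                                     cfg$min_compounds)
    if (length(hc) == 0L) stop("no herb passes the compound-count filter")
    ht <- integrate_targets(hc, tabs$compound_targets, cfg$top_n_targets)
    dz <- curate_disease_proteins(tabs$disease)
    list(tables = tabs, herb_compounds = hc, herb_targets = ht,
         disease = dz)
  })

  base_net <- stage("network", {
    ppi <- read_tsv_checked(paths[["ppi"]], c("protein_a", "protein_b"))
    ann <- read_tsv_checked(paths[["annotations"]], c("protein", "func"))
    hier <- read_tsv_checked(paths[["hierarchy"]], c("child", "parent"))
    build_network(ppi, ann, hier)
  })

  ranked <- NULL; herb_diff <- NULL
  stage("diffusion+ranking", {
    ht <- as.data.frame(asm$herb_targets)
    herb_sets <- split(ht$protein, ht$herb)
    registry_proteins <- base_net$nodes$id[base_net$nodes$class ==
                                             "protein"]
    dz_in_net <- intersect(asm$disease$proteins, registry_proteins)
    herb_diff <- diffuse_entities(base_net, asm$disease$disease_id,
                                   dz_in_net, herb_sets,
                                   cfg$weights, cfg$walk)
    ranked <- rank_candidates(herb_diff$profiles,
                               herb_diff$disease_profile, herb_sets,
                               dz_in_net, registry_proteins)
    write_tsv(as.data.frame(ranked), file.path(out, "ranked_herbs.tsv"))
    ht$rank_within_herb <- ht$rank
    write_tsv(ht[c("herb", "protein", "support", "rank")],
              file.path(out, "herb_targets.tsv"))
  })

  top_herbs <- head(ranked$entity, cfg$n_top_herbs)
  shared <- stage("shared-targets", {
    shared_target_summary(asm$herb_targets, head(ranked$entity,
                                                 min(10L, nrow(ranked))))
  })

  dz_in_net <- intersect(asm$disease$proteins,
                         base_net$nodes$id[base_net$nodes$class ==
                                             "protein"])
  compound_tables <- list(); subnetworks <- list()
  stage("compound-scoring+subnetworks", {
    for (h in top_herbs) {
      ct <- score_compounds_of_herb(h, asm$herb_compounds,
                                    asm$tables$compound_targets, base_net,
                                    asm$disease$disease_id, dz_in_net,
                                    cfg$weights, cfg$walk,
                                    cfg$max_active_compounds)
      compound_tables[[h]] <- ct
      write_tsv(as.data.frame(ct),
                file.path(out, paste0("compounds_", h, ".tsv")))
      best <- ct$entity[1]
      sub <- extract_top_k(attr(ct, "profiles")[[best]],
                           attr(ct, "disease_profile"),
                           attr(ct, "network"), cfg$k_top)
      subnetworks[[best]] <- sub
      export_network(sub, file.path(out, paste0("subnetwork_", best,
                                                ".graphml")), "graphml")
      export_network(sub, file.path(out, paste0("subnetwork_", best,
                                                ".sif")), "sif")
    }
  })

  ora <- NULL
  if (!is.null(cfg$gmt)) {
    ora <- stage("ora", {
      query <- shared$shared_proteins
      if (length(query) == 0L) {
        query <- unique(as.data.frame(asm$herb_targets)$protein)
      }
      bg <- base_net$nodes$id[base_net$nodes$class == "protein"]
      res <- over_representation(query, read_gmt(cfg$gmt), bg)
      write_tsv(res, file.path(out, "ora.tsv"))
      res
    })
  }

  artifact_files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("herbnetdiff")),
    parameters = list(
      weights = unclass(cfg$weights), walk = unclass(cfg$walk),
      min_compounds = cfg$min_compounds,
      top_n_targets = cfg$top_n_targets, k_top = cfg$k_top,
      n_top_herbs = cfg$n_top_herbs),
    seed = if (!is.null(cfg$simulation)) cfg$simulation$seed else NULL,
    planted_herb = if (!is.null(cfg$simulation)) {
      jsonlite::read_json(file.path(out, "sim",
                                    "manifest.json"))$planted_herb
    } else NULL,
    top_herbs = as.list(top_herbs),
    files = lapply(setNames(artifact_files,
                            sub(paste0("^", out, "/?"), "",
                                artifact_files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(ranked = ranked, compound_tables = compound_tables,
                 subnetworks = subnetworks, shared_targets = shared,
                 ora = ora, manifest = manifest, out_dir = out,
                 disease_profile = herb_diff$disease_profile,
                 profiles = herb_diff$profiles, network = herb_diff$net),
            class = "herbnet_run")
}

#' @exportS3Method base::print
print.herbnet_run <- function(x, ...) {
  cat("herbnet_run:", nrow(x$ranked), "herbs ranked; artifacts in",
      x$out_dir, "\n")
  print(x$ranked, n = 5L)
  invisible(x)
}
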