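# Synthetic study generator: a connected scale-free PPI layer, a layered
# acyclic function hierarchy, sparse protein-function annotations, a curated
# disease gene set with decoy evidence classes, and herb panels with one
# planted positive-control herb whose targets concentrate in the disease
# 1-hop neighborhood. Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic study. Defaults
#' describe a toy interactome large enough for diffusion-based proximity to
#' be detectable yet small enough for exhaustive testing.
#'
#' @param n_proteins number of proteins in the PPI layer (>= 3)
#' @param n_functions number of biological-function nodes (>= 2)
#' @param ppi_attach_edges edges added per node during preferential
#'   attachment; controls density and the heavy-tailed degree distribution
#' @param annotation_rate mean annotations per protein (Poisson)
#' @param n_herbs number of herbs, one of which is the planted positive
#'   control
#' @param compounds_per_herb integer range `c(lo, hi)` of compounds per herb
#' @param targets_per_compound integer range `c(lo, hi)` of protein targets
#'   per compound
#' @param n_disease_proteins number of curated disease proteins; default
#'   one tenth of the proteins, capped at 25
#' @param planted_overlap_fraction probability in \[0, 1\] that each target of
#'   the planted herb's compounds is drawn from the disease 1-hop PPI
#'   neighborhood rather than uniformly
#' @param seed integer seed; identical seed gives byte-identical output
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(n_proteins = 300L,
                              n_functions = 60L,
                              ppi_attach_edges = 3L,
                              annotation_rate = 1.5,
                              n_herbs = 20L,
                              compounds_per_herb = c(6L, 10L),
                              targets_per_compound = c(2L, 5L),
                              n_disease_proteins = NULL,
                              planted_overlap_fraction = 0.8,
                              seed = 1L) {
  if (is.null(n_disease_proteins)) {
    n_disease_proteins <- min(25L, max(1L, as.integer(n_proteins) %/% 10L))
  }
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_functions = as.integer(n_functions),
              ppi_attach_edges = as.integer(ppi_attach_edges),
              annotation_rate = annotation_rate,
              n_herbs = as.integer(n_herbs),
              compounds_per_herb = as.integer(compounds_per_herb),
              targets_per_compound = as.integer(targets_per_compound),
              n_disease_proteins = as.integer(n_disease_proteins),
              planted_overlap_fraction = planted_overlap_fraction,
              seed = as.integer(seed))
  if (cfg$n_proteins < 3L) stop("n_proteins must be >= 3", call. = FALSE)
  if (cfg$n_functions < 2L) stop("n_functions must be >= 2", call. = FALSE)
  if (cfg$ppi_attach_edges < 1L) stop("ppi_attach_edges must be >= 1",
                                      call. = FALSE)
  if (cfg$annotation_rate < 0) stop("annotation_rate must be >= 0",
                                    call. = FALSE)
  if (cfg$n_herbs < 1L) stop("n_herbs must be >= 1", call. = FALSE)
  for (nm in c("compounds_per_herb", "targets_per_compound")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2]) {
      stop(nm, " must be a non-empty positive range c(lo, hi)",
           call. = FALSE)
    }
  }
  if (cfg$n_disease_proteins < 1L ||
      cfg$n_disease_proteins > cfg$n_proteins) {
    stop("n_disease_proteins must be in [1, n_proteins]", call. = FALSE)
  }
  if (cfg$planted_overlap_fraction < 0 || cfg$planted_overlap_fraction > 1) {
    stop("planted_overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Generate the synthetic multiscale interactome
#'
#' Builds the PPI layer by preferential attachment (single connected
#' component by construction, heavy-tailed degrees), a layered directed
#' acyclic function hierarchy (edges child -> parent, each non-top function
#' drawing 1-2 parents from the level above), and Poisson-sparse
#' protein-function annotations.
#'
#' @param config a [simulation_config()]
#' @return list with data frames `ppi` (protein_a, protein_b), `hierarchy`
#'   (child, parent), `annotations` (protein, func), and the id vectors
#'   `proteins`, `functions`
#' @export
simulate_interactome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  proteins <- make_ids("P", config$n_proteins)
  g <- igraph::sample_pa(config$n_proteins, m = config$ppi_attach_edges,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  # drop multi-edges sample_pa can emit, keep canonical a < b orientation
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  keep <- !duplicated(paste(a, b)) & a != b
  ppi <- data.frame(protein_a = proteins[a[keep]],
                    protein_b = proteins[b[keep]],
                    stringsAsFactors = FALSE)

  funcs <- make_ids("F", config$n_functions)
  n_levels <- max(2L, min(4L, config$n_functions %/% 2L))
  # guarantee each level non-empty, then spread the rest uniformly
  level <- c(seq_len(n_levels),
             sample(n_levels, config$n_functions - n_levels, replace = TRUE))
  child <- character(0); parent <- character(0)
  for (i in which(level > 1L)) {
    above <- funcs[level == level[i] - 1L]
    k <- min(length(above), sample(1:2, 1))
    p <- sample(above, k)
    child <- c(child, rep(funcs[i], k))
    parent <- c(parent, p)
  }
  hierarchy <- data.frame(child = child, parent = parent,
                          stringsAsFactors = FALSE)

  n_ann <- pmin(rpois(config$n_proteins, config$annotation_rate),
                config$n_functions)
  ann_protein <- rep(proteins, n_ann)
  ann_func <- unlist(lapply(n_ann, function(k) {
    if (k == 0L) character(0) else sample(funcs, k)
  }))
  annotations <- data.frame(protein = ann_protein, func = ann_func,
                            stringsAsFactors = FALSE)

  list(ppi = ppi, hierarchy = hierarchy, annotations = annotations,
       proteins = proteins, functions = funcs,
       function_levels = setNames(level, funcs))
}

#' Generate the synthetic disease-association table
#'
#' Emits exactly `n_disease_proteins` rows flagged `curated` plus decoy rows
#' flagged `animal_model`, `literature_mined` and `therapeutic`, so that the
#' evidence-based curation filters are exercised downstream.
#'
#' @param config a [simulation_config()]
#' @param interactome output of [simulate_interactome()]
#' @return data frame with columns disease, protein, evidence
#' @export
simulate_disease <- function(config, interactome) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  proteins <- interactome$proteins
  curated <- sample(proteins, config$n_disease_proteins)
  pool <- setdiff(proteins, curated)
  n_decoy <- max(1L, config$n_disease_proteins %/% 3L)
  decoy_flags <- c("animal_model", "literature_mined", "therapeutic")
  decoys <- lapply(decoy_flags, function(fl) {
    k <- min(n_decoy, length(pool))
    picked <- sample(pool, k)
    pool <<- setdiff(pool, picked)
    data.frame(disease = "DIS01", protein = picked, evidence = fl,
               stringsAsFactors = FALSE)
  })
  rbind(data.frame(disease = "DIS01", protein = curated,
                   evidence = "curated", stringsAsFactors = FALSE),
        do.call(rbind, decoys))
}

# Uniform draw from an integer range; avoids sample()'s scalar expansion
# when lo == hi.
sample_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1L)
}

# Disease proteins plus their direct PPI neighbors.
disease_neighborhood <- function(disease_proteins, ppi) {
  nb <- c(ppi$protein_b[ppi$protein_a %in% disease_proteins],
          ppi$protein_a[ppi$protein_b %in% disease_proteins])
  sort(unique(c(disease_proteins, nb)))
}

#' Generate herb panels with a planted positive-control herb
#'
#' Each herb receives a panel of compounds, each compound a protein target
#' set. Decoy herbs sample targets uniformly from the PPI layer; exactly one
#' planted herb draws each target from the disease 1-hop neighborhood with
#' probability `planted_overlap_fraction` and uniformly otherwise, so
#' diffusion-based proximity to the disease is tunable.
#'
#' @param config a [simulation_config()]
#' @param interactome output of [simulate_interactome()]
#' @param disease disease-association table from [simulate_disease()] (only
#'   rows flagged `curated` define the neighborhood)
#' @return list with `herb_compounds` (herb, compound), `compound_targets`
#'   (compound, protein) and `planted_herb`
#' @export
simulate_herb_panel <- function(config, interactome, disease) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  proteins <- interactome$proteins
  curated <- disease$protein[disease$evidence == "curated"]
  nbhd <- disease_neighborhood(curated, interactome$ppi)
  max_targets <- config$targets_per_compound[2]
  if (length(nbhd) < max_targets) {
    stop("disease 1-hop neighborhood (", length(nbhd), " proteins) is ",
         "smaller than the requested targets per compound (", max_targets,
         "); config too tight", call. = FALSE)
  }
  herbs <- make_ids("HERB", config$n_herbs, width = 2L)
  planted <- sample(herbs, 1L)
  herb_rows <- list(); target_rows <- list()
  cid <- 0L
  for (h in herbs) {
    n_comp <- sample_range(config$compounds_per_herb)
    comps <- make_ids("CID", cid + n_comp)[(cid + 1L):(cid + n_comp)]
    cid <- cid + n_comp
    herb_rows[[h]] <- data.frame(herb = h, compound = comps,
                                 stringsAsFactors = FALSE)
    for (cmp in comps) {
      n_t <- sample_range(config$targets_per_compound)
      if (h == planted) {
        from_nbhd <- runif(n_t) < config$planted_overlap_fraction
        tg <- character(n_t)
        if (any(from_nbhd)) tg[from_nbhd] <- sample(nbhd, sum(from_nbhd))
        if (any(!from_nbhd)) tg[!from_nbhd] <- sample(proteins,
                                                      sum(!from_nbhd))
        tg <- unique(tg)
      } else {
        tg <- sample(proteins, n_t)
      }
      target_rows[[cmp]] <- data.frame(compound = cmp, protein = tg,
                                       stringsAsFactors = FALSE)
    }
  }
  list(herb_compounds = do.call(rbind, c(herb_rows,
                                         make.row.names = FALSE)),
       compound_targets = do.call(rbind, c(target_rows,
                                           make.row.names = FALSE)),
       planted_herb = planted)
}

#' Generate and write a complete synthetic study
#'
#' Runs all three generators and writes the six TSV inputs plus a JSON
#' manifest (seed, config echo, planted herb id) to `dir`.
#'
#' @param config a [simulation_config()]
#' @param dir output directory (created if absent)
#' @return invisibly, a list with all generated tables, the planted herb id
#'   and the file paths
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inter <- simulate_interactome(config)
  disease <- simulate_disease(config, inter)
  panel <- simulate_herb_panel(config, inter, disease)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             herb_compounds = file.path(dir, "herb_compounds.tsv"),
             compound_targets = file.path(dir, "compound_targets.tsv"),
             disease = file.path(dir, "disease_associations.tsv"))
  write_tsv(inter$ppi, paths[["ppi"]])
  write_tsv(inter$hierarchy, paths[["hierarchy"]])
  write_tsv(inter$annotations, paths[["annotations"]])
  write_tsv(panel$herb_compounds, paths[["herb_compounds"]])
  write_tsv(panel$compound_targets, paths[["compound_targets"]])
  write_tsv(disease, paths[["disease"]])
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   planted_herb = panel$planted_herb,
                   files = as.list(setNames(basename(paths),
                                            names(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(interactome = inter, disease = disease, panel = panel,
                 paths = paths, planted_herb = panel$planted_herb))
}
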