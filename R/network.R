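# The multiscale network: a typed graph of proteins, hierarchically
# organised biological functions, and attached entity nodes (herbs,
# compounds, diseases), together with the biased row-stochastic transition
# matrix of the walk over it.

#' Build the multiscale network
#'
#' Joins three layers: undirected protein-protein edges, undirected
#' protein-function annotation edges, and directed function-function
#' hierarchy edges (child -> parent). The hierarchy must be acyclic.
#'
#' @param ppi data frame (protein_a, protein_b)
#' @param annotations data frame (protein, func)
#' @param hierarchy data frame (child, parent); may have zero rows
#' @return object of class `multiscale_network`: node registry plus typed
#'   edge table
#' @export
build_network <- function(ppi, annotations, hierarchy) {
  proteins <- sort(unique(c(ppi$protein_a, ppi$protein_b)))
  funcs <- sort(unique(c(hierarchy$child, hierarchy$parent,
                         annotations$func)))
  if (length(intersect(proteins, funcs)) > 0L) {
    stop("id used as both protein and function: ",
         paste(head(intersect(proteins, funcs), 3), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(annotations$protein, proteins)
  if (length(unknown) > 0L) {
    stop("annotation references unknown protein(s): ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  if (nrow(hierarchy) > 0L) {
    hg <- igraph::graph_from_data_frame(hierarchy[c("child", "parent")],
                                        directed = TRUE)
    if (!igraph::is_dag(hg)) {
      comp <- igraph::components(hg, mode = "strong")
      bad <- names(comp$membership)[comp$membership ==
                                      which(comp$csize > 1)[1]]
      stop("function hierarchy contains a directed cycle through: ",
           paste(head(bad, 5), collapse = " -> "), call. = FALSE)
    }
  }
  nodes <- data.frame(id = c(proteins, funcs),
                      class = c(rep("protein", length(proteins)),
                                rep("function", length(funcs))),
                      stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = ppi$protein_a, to = ppi$protein_b,
               type = rep("ppi", nrow(ppi)), stringsAsFactors = FALSE),
    data.frame(from = annotations$protein, to = annotations$func,
               type = rep("annotation", nrow(annotations)),
               stringsAsFactors = FALSE),
    data.frame(from = hierarchy$child, to = hierarchy$parent,
               type = rep("hierarchy", nrow(hierarchy)),
               stringsAsFactors = FALSE))
  # canonicalize undirected PPI orientation before deduplication
  is_ppi <- edges$type == "ppi"
  a <- pmin(edges$from[is_ppi], edges$to[is_ppi])
  b <- pmax(edges$from[is_ppi], edges$to[is_ppi])
  edges$from[is_ppi] <- a; edges$to[is_ppi] <- b
  edges <- edges[!duplicated(edges), , drop = FALSE]
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  structure(list(nodes = nodes, edges = edges,
                 entities = character(0)),
            class = "multiscale_network")
}

#' @exportS3Method base::print
print.multiscale_network <- function(x, ...) {
  tab <- table(x$nodes$class)
  cat("multiscale_network:", nrow(x$nodes), "nodes (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  et <- table(x$edges$type)
  cat("  edges:", paste(sprintf("%s: %d", names(et), et), collapse = ", "),
      "\n")
  invisible(x)
}

#' Attach an entity node (herb, compound or disease) to its proteins
#'
#' Adds one entity node with undirected attachment edges to each of its
#' proteins present in the registry; proteins absent from the network are
#' dropped with a warning. Attachment is bidirectional so walk mass can
#' return to the entity.
#'
#' @param net a `multiscale_network`
#' @param entity_id fresh node id
#' @param protein_ids proteins the entity acts on
#' @param entity_class `"entity_drug"` (herbs and compounds) or
#'   `"entity_disease"`
#' @return the augmented network
#' @export
attach_entity <- function(net, entity_id, protein_ids,
                          entity_class = c("entity_drug",
                                           "entity_disease")) {
  stopifnot(inherits(net, "multiscale_network"))
  entity_class <- match.arg(entity_class)
  if (entity_id %in% net$nodes$id) {
    stop("entity id already present in network: ", entity_id,
         call. = FALSE)
  }
  registry_proteins <- net$nodes$id[net$nodes$class == "protein"]
  present <- unique(protein_ids[protein_ids %in% registry_proteins])
  note_drop("attach", paste0("protein(s) of ", entity_id,
                             " absent from the interactome"),
            length(unique(protein_ids)) - length(present))
  if (length(present) == 0L) {
    stop("entity ", entity_id, " has no protein in the network; ",
         "cannot be walked", call. = FALSE)
  }
  net$nodes <- rbind(net$nodes,
                     data.frame(id = entity_id, class = entity_class,
                                stringsAsFactors = FALSE))
  net$edges <- rbind(net$edges,
                     data.frame(from = entity_id, to = present,
                                type = "attachment",
                                stringsAsFactors = FALSE))
  net$entities <- c(net$entities, entity_id)
  net
}

#' Node-class walk weights
#'
#' The biased walk weights each step by the class of the destination node
#' relative to the source: protein neighbors, function neighbors reached
#' from a protein, parent ("higher-level") and child ("lower-level")
#' functions reached from a function, and drug/disease entity neighbors.
#' Defaults follow established multiscale-interactome practice.
#'
#' @param w_drug,w_disease,w_protein,w_higher_function,w_lower_function,w_function
#'   positive class weights
#' @param alpha walker continuation probability in (0, 1)
#' @return object of class `node_class_weights`
#' @export
node_class_weights <- function(w_drug = 3.21, w_disease = 3.54,
                               w_protein = 4.40, w_higher_function = 2.10,
                               w_lower_function = 4.49, w_function = 6.58,
                               alpha = 0.860) {
  w <- list(w_drug = w_drug, w_disease = w_disease, w_protein = w_protein,
            w_higher_function = w_higher_function,
            w_lower_function = w_lower_function, w_function = w_function,
            alpha = alpha)
  if (any(unlist(w[1:6]) <= 0)) stop("all class weights must be > 0",
                                     call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  structure(w, class = "node_class_weights")
}

# Directed step table of the network: one row per ordered pair (from, to)
# a walker can traverse. Undirected layers contribute both directions;
# hierarchy edges are traversed upward (child -> parent) and downward.
directed_steps <- function(net) {
  e <- net$edges
  undirected <- e$type %in% c("ppi", "annotation", "attachment")
  rbind(data.frame(from = e$from, to = e$to, type = e$type,
                   up = e$type == "hierarchy", stringsAsFactors = FALSE),
        data.frame(from = e$to[undirected | e$type == "hierarchy"],
                   to = e$from[undirected | e$type == "hierarchy"],
                   type = e$type[undirected | e$type == "hierarchy"],
                   up = FALSE, stringsAsFactors = FALSE))
}

#' Build the biased row-stochastic transition matrix
#'
#' Each outgoing step (u, v) receives an unnormalized weight determined by
#' the class of the destination v relative to the source u: `w_protein` for
#' protein destinations, `w_function` for a function reached from a
#' protein, `w_higher_function` / `w_lower_function` for parent / child
#' functions reached from a function, and `w_drug` / `w_disease` for entity
#' destinations. Rows are then normalized to sum to one; nodes without
#' outgoing edges form the dangling set J.
#'
#' @param net a `multiscale_network`
#' @param weights a [node_class_weights()]
#' @return object of class `transition_matrix`: sparse matrix `M`, dangling
#'   index vector `J`, node `index`, node `class`
#' @export
build_transition_matrix <- function(net, weights = node_class_weights()) {
  stopifnot(inherits(net, "multiscale_network"),
            inherits(weights, "node_class_weights"))
  ids <- net$nodes$id
  cls <- setNames(net$nodes$class, ids)
  idx <- setNames(seq_along(ids), ids)
  steps <- directed_steps(net)
  dest_cls <- cls[steps$to]
  src_cls <- cls[steps$from]
  w <- numeric(nrow(steps))
  w[dest_cls == "protein"] <- weights$w_protein
  w[dest_cls == "entity_drug"] <- weights$w_drug
  w[dest_cls == "entity_disease"] <- weights$w_disease
  is_fun <- dest_cls == "function"
  w[is_fun & src_cls == "protein"] <- weights$w_function
  w[is_fun & steps$up] <- weights$w_higher_function
  w[is_fun & src_cls == "function" & !steps$up] <- weights$w_lower_function
  if (any(w <= 0)) stop("internal: unweighted step encountered")
  M <- Matrix::sparseMatrix(i = idx[steps$from], j = idx[steps$to], x = w,
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  rs <- Matrix::rowSums(M)
  dangling <- which(rs == 0)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  M <- Matrix::Diagonal(x = inv) %*% M
  dimnames(M) <- list(ids, ids)
  structure(list(M = M, J = dangling, index = idx, class = cls),
            class = "transition_matrix")
}

#' @exportS3Method base::print
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", length(x$index), "nodes,",
      length(x$M@x), "non-zero steps,", length(x$J), "dangling\n")
  invisible(x)
}
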