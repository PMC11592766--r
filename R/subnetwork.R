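# Mechanism subnetwork extraction: the top-k most-visited proteins and
# biological functions of the entity and disease diffusion profiles, with
# anchors, induced edges, and pruning of entity targets disconnected from
# the disease side. GraphML and SIF export with stable node ordering.

#' Extract the top-k mechanism subnetwork
#'
#' Selects the `k_top` highest-probability nodes of the requested classes
#' from the entity profile and from the disease profile (ties at the k-th
#' value are all included), unions them with the two anchor entity nodes,
#' induces the edges of the multiscale network on that node set, and prunes
#' entity targets that have no path (within the induced subnetwork) to any
#' disease-side node. Disease-side nodes are never pruned.
#'
#' @param r_c entity `diffusion_profile`
#' @param r_d disease `diffusion_profile`
#' @param net the `multiscale_network` both profiles were computed on
#' @param k_top nodes kept per profile (default 20)
#' @param include_classes node classes eligible for selection
#' @param entity_targets protein ids attached to the entity (used by the
#'   pruning rule); defaults to the entity's attachment edges in `net`
#' @return object of class `mechanism_subnetwork`: `nodes` (id, class,
#'   side, probability), `edges`, anchors
#' @export
extract_top_k <- function(r_c, r_d, net, k_top = 20L,
                          include_classes = c("protein", "function"),
                          entity_targets = NULL) {
  stopifnot(inherits(r_c, "diffusion_profile"),
            inherits(r_d, "diffusion_profile"),
            inherits(net, "multiscale_network"))
  if (k_top < 1L) stop("k_top must be >= 1", call. = FALSE)
  cls <- setNames(net$nodes$class, net$nodes$id)

  select_top <- function(prof) {
    p <- prof$p
    p <- p[names(p) %in% names(cls)[cls %in% include_classes]]
    if (length(p) == 0L) return(character(0))
    k <- k_top
    if (k > length(p)) {
      warning("k_top (", k_top, ") exceeds the ", length(p),
              " selectable nodes; clamped", call. = FALSE)
      k <- length(p)
    }
    ord <- order(-p, names(p))
    kth <- p[ord[k]]
    sel <- names(p)[p > kth | (p == kth)]  # all ties at the k-th value
    overflow <- length(sel) - k
    if (overflow > 0L) {
      message("top-k selection for ", prof$entity, ": ", overflow,
              " tie(s) at the k-th probability included")
    }
    sel
  }

  side_c <- select_top(r_c)
  side_d <- select_top(r_d)
  anchors <- c(r_c$entity, r_d$entity)
  ids <- unique(c(side_c, side_d, anchors))
  side <- ifelse(ids %in% side_d & ids %in% side_c, "both",
                 ifelse(ids %in% side_d, "disease", "compound"))
  side[ids == r_c$entity] <- "compound"
  side[ids == r_d$entity] <- "disease"

  steps <- net$edges
  keep <- steps$from %in% ids & steps$to %in% ids
  edges <- steps[keep, , drop = FALSE]

  if (is.null(entity_targets)) {
    att <- net$edges[net$edges$type == "attachment", , drop = FALSE]
    entity_targets <- unique(c(att$to[att$from == r_c$entity],
                               att$from[att$to == r_c$entity]))
  }

  # prune entity targets with no induced path to a disease-side node;
  # paths through the entity anchor itself do not count as mechanism links
  repeat {
    link_edges <- edges[edges$from != r_c$entity &
                          edges$to != r_c$entity, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      link_edges[c("from", "to")], directed = FALSE,
      vertices = data.frame(name = ids, stringsAsFactors = FALSE))
    comp <- igraph::components(g)$membership
    disease_side <- ids[side != "compound" & ids != r_c$entity]
    disease_comps <- unique(comp[disease_side])
    prune <- ids %in% entity_targets & side == "compound" &
      !(unname(comp[ids]) %in% disease_comps)
    if (!any(prune)) break
    ids <- ids[!prune]
    side <- side[!prune]
    edges <- edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE]
  }

  prob <- ifelse(ids %in% names(r_c$p), r_c$p[ids], NA_real_)
  prob_d <- ifelse(ids %in% names(r_d$p), r_d$p[ids], NA_real_)
  nodes <- data.frame(id = ids, class = unname(cls[ids]), side = side,
                      probability = pmax(prob, prob_d, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$from, edges$to, edges$type), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 entity = r_c$entity, disease = r_d$entity),
            class = "mechanism_subnetwork")
}

#' @exportS3Method base::print
print.mechanism_subnetwork <- function(x, ...) {
  cat("mechanism_subnetwork linking", x$entity, "to", x$disease, "\n")
  cat("  ", nrow(x$nodes), "nodes (",
      paste(sprintf("%s: %d", names(table(x$nodes$side)),
                    table(x$nodes$side)), collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Count proteins shared across herb target panels
#'
#' @param herb_targets a `herb_target_table` (herb, protein, ...)
#' @param herbs optional subset of herbs to consider
#' @return list with `edge_count` (herb-target pairs), `counts_at` (named
#'   vector: number of proteins targeted by >= m herbs, m = 1..max), and
#'   `shared_proteins` (targeted by >= 2 herbs)
#' @export
shared_target_summary <- function(herb_targets, herbs = NULL) {
  ht <- as.data.frame(herb_targets)
  if (!is.null(herbs)) ht <- ht[ht$herb %in% herbs, , drop = FALSE]
  if (nrow(ht) == 0L) stop("no herbs selected", call. = FALSE)
  ht <- unique(ht[c("herb", "protein")])
  per_protein <- table(ht$protein)
  max_m <- max(per_protein)
  counts <- vapply(seq_len(max_m),
                   function(m) sum(per_protein >= m), integer(1))
  names(counts) <- paste0(">=", seq_len(max_m))
  list(edge_count = nrow(ht), counts_at = counts,
       shared_proteins = sort(names(per_protein)[per_protein >= 2L]))
}

# igraph view of a mechanism subnetwork or multiscale network, with node
# attributes preserved.
as_igraph <- function(x) {
  if (inherits(x, "mechanism_subnetwork")) {
    v <- x$nodes
    v$probability[is.na(v$probability)] <- 0
    igraph::graph_from_data_frame(x$edges, directed = FALSE, vertices = v)
  } else if (inherits(x, "multiscale_network")) {
    igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                  vertices = x$nodes)
  } else stop("cannot convert to igraph: ", class(x)[1], call. = FALSE)
}

#' Export a network to GraphML or SIF
#'
#' GraphML carries node attributes (class, side, probability where
#' available); SIF writes one `source <tab> type <tab> target` line per
#' edge. Node and edge ordering is stable, so identical networks export to
#' byte-identical files.
#'
#' @param x a `mechanism_subnetwork` or `multiscale_network`
#' @param path output file
#' @param format `"graphml"` or `"sif"`
#' @return the path, invisibly
#' @export
export_network <- function(x, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  edges <- if (inherits(x, "mechanism_subnetwork")) x$edges else x$edges
  if (nrow(edges) == 0L) stop("refusing to export an empty network",
                              call. = FALSE)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to)
    writeLines(lines, path)
  } else {
    g <- as_igraph(x)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a SIF file back as an edge table
#'
#' @param path SIF file
#' @return data frame (from, type, to)
#' @export
read_sif <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("from", "type", "to"))
  df[c("from", "type", "to")]
}
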