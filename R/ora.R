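# Gene-set over-representation analysis against user-supplied GMT
# libraries: upper-tail hypergeometric p per term, BH adjustment, odds
# ratio from the 2x2 table, and a combined score joining the p-value with
# the hypergeometric-null z-score of the overlap.

#' Read a GMT gene-set library
#'
#' Standard format: one term per line, tab-separated
#' `term <tab> description <tab> id1 <tab> id2 ...`.
#'
#' @param path GMT file path
#' @return named list term -> character vector of member ids; descriptions
#'   kept in the `"descriptions"` attribute
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s) (need term, description, >=1 id): line ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  terms <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  attr(sets, "descriptions") <- setNames(desc, terms)
  sets
}

# z-score of the observed overlap under the hypergeometric null of drawing
# n ids from M containing K term members.
hypergeom_z <- function(k, n, K, M) {
  mu <- n * K / M
  v <- n * (K / M) * ((M - K) / M) * ((M - n) / max(M - 1, 1))
  if (v <= 0) return(0)
  (k - mu) / sqrt(v)
}

#' Over-representation analysis of a target set
#'
#' Tests each library term for enrichment of `target_ids` against
#' `background_ids`: upper-tail hypergeometric p, BH-adjusted p, odds ratio
#' of the 2x2 table (Haldane 0.5 correction when any cell is zero), the
#' z-score of the overlap under the hypergeometric null, and the combined
#' score `-ln(p) * z`.
#'
#' @param target_ids character vector of query ids
#' @param library named list term -> member ids (see [read_gmt()])
#' @param background_ids background universe, a superset of the targets
#' @return data frame (term, overlap, term_size, p_value, p_adjusted,
#'   odds_ratio, z, combined_score, overlap_ids) sorted by p then term
#' @export
over_representation <- function(target_ids, library, background_ids) {
  if (length(background_ids) == 0L) stop("empty background", call. = FALSE)
  if (length(library) == 0L) stop("empty gene-set library", call. = FALSE)
  background_ids <- unique(background_ids)
  target_ids <- unique(target_ids)
  outside <- setdiff(target_ids, background_ids)
  if (length(outside) > 0L) {
    stop("target id(s) outside the background: ",
         paste(head(outside, 3), collapse = ", "), call. = FALSE)
  }
  M <- length(background_ids)
  n <- length(target_ids)
  rows <- lapply(names(library), function(term) {
    members <- intersect(unique(library[[term]]), background_ids)
    K <- length(members)
    hits <- intersect(target_ids, members)
    k <- length(hits)
    p <- if (K == 0L) 1 else hypergeometric_overlap(k, n, K, M)
    a <- k; b <- n - k; c <- K - k; d <- M - K - n + k
    if (min(a, b, c, d) == 0L) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
    z <- hypergeom_z(k, n, K, M)
    combined <- if (k == 0L) 0 else -log(p) * z
    data.frame(term = term, overlap = k, term_size = K,
               p_value = p, odds_ratio = (a * d) / (b * c), z = z,
               combined_score = combined,
               overlap_ids = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[c("term", "overlap", "term_size", "p_value", "p_adjusted",
        "odds_ratio", "z", "combined_score", "overlap_ids")]
}
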