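# Entity-vs-disease scoring: Pearson correlation of diffusion profiles,
# upper-tail hypergeometric overlap with fold enrichment, BH adjustment,
# and the ranked candidate table.

#' Correlation score between two diffusion profiles
#'
#' Centered cosine (Pearson) similarity of the two probability vectors,
#' compared on a shared node index with entity coordinates excluded so both
#' profiles live in the same space.
#'
#' @param r_c entity `diffusion_profile` (or named numeric vector)
#' @param r_d disease `diffusion_profile` (or named numeric vector)
#' @param exclude node ids (typically all entity nodes) removed from both
#'   vectors before comparison
#' @return a number in \[-1, 1\]
#' @export
correlation_score <- function(r_c, r_d, exclude = character(0)) {
  v_c <- if (inherits(r_c, "diffusion_profile")) r_c$p else r_c
  v_d <- if (inherits(r_d, "diffusion_profile")) r_d$p else r_d
  if (!identical(names(v_c), names(v_d))) {
    stop("profiles do not share an identical node index", call. = FALSE)
  }
  keep <- !(names(v_c) %in% exclude)
  v_c <- v_c[keep]; v_d <- v_d[keep]
  if (stats::sd(v_c) == 0 || stats::sd(v_d) == 0) {
    stop("zero-variance profile: correlation score undefined",
         call. = FALSE)
  }
  x <- v_c - mean(v_c); y <- v_d - mean(v_d)
  sum(x * y) / (sqrt(sum(x * x)) * sqrt(sum(y * y)))
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` disease proteins when drawing `n`
#' targets from a background of `M_total` proteins containing `N` disease
#' proteins:
#' `p = 1 - sum_{i=0}^{k-1} C(N, i) C(M_total - N, n - i) / C(M_total, n)`.
#'
#' @param k observed overlap
#' @param n entity target count
#' @param N disease protein count
#' @param M_total background protein count
#' @return p-value in \[0, 1\]
#' @export
hypergeometric_overlap <- function(k, n, N, M_total) {
  if (n > M_total || N > M_total) {
    stop("n and N must not exceed M_total", call. = FALSE)
  }
  if (k < 0 || k > min(n, N)) {
    stop("impossible overlap: k must lie in [0, min(n, N)]", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, N, M_total - N, n, lower.tail = FALSE)
}

#' Fold enrichment of an overlap
#'
#' `(k / n) * rho` where the background ratio `rho = M_total / N` is either
#' given directly or derived from `N` and `M_total`. For table display use
#' [trunc_decimals()]: printed cells are truncated, not rounded.
#'
#' @param k observed overlap
#' @param n entity target count
#' @param N,M_total disease and background protein counts (used when
#'   `background_ratio` is missing)
#' @param background_ratio the ratio M_total / N directly
#' @return non-negative fold enrichment
#' @export
fold_enrichment <- function(k, n, N = NULL, M_total = NULL,
                            background_ratio = NULL) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  rho <- if (!is.null(background_ratio)) background_ratio
         else if (!is.null(N) && !is.null(M_total)) M_total / N
         else stop("supply background_ratio or both N and M_total",
                   call. = FALSE)
  if (rho <= 0) stop("background ratio must be > 0", call. = FALSE)
  (k / n) * rho
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p_values numeric vector in \[0, 1\]
#' @return adjusted p-values, same order
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Rank candidate entities against the disease
#'
#' Builds the prioritization table: one row per entity with the correlation
#' score of its diffusion profile against the disease profile, the
#' hypergeometric overlap of its targets with the curated disease proteins,
#' BH-adjusted p and fold enrichment; sorted by correlation score
#' descending with entity-id tie-break.
#'
#' @param profiles named list of entity `diffusion_profile`s
#' @param disease_profile the disease `diffusion_profile`
#' @param entity_targets named list entity id -> protein target ids
#' @param disease_proteins curated disease protein ids
#' @param background background protein ids (the interactome protein set)
#' @param exclude node ids excluded from profile comparison (all entity
#'   nodes); defaults to the profile names plus the disease entity
#' @param min_enrichment optional filter: drop rows below this fold
#'   enrichment (default NULL, off)
#' @return data frame of class `ranked_candidates` with columns entity,
#'   score, k, n, p_value, p_adjusted, enrichment
#' @export
rank_candidates <- function(profiles, disease_profile, entity_targets,
                            disease_proteins, background,
                            exclude = NULL, min_enrichment = NULL) {
  if (length(profiles) == 0L) {
    out <- data.frame(entity = character(0), score = numeric(0),
                      k = integer(0), n = integer(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      enrichment = numeric(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("ranked_candidates", "data.frame")))
  }
  if (is.null(exclude)) {
    exclude <- c(names(profiles), disease_profile$entity)
  }
  N <- length(unique(disease_proteins))
  M_total <- length(unique(background))
  rows <- lapply(names(profiles), function(id) {
    targets <- unique(entity_targets[[id]])
    targets <- targets[targets %in% background]
    k <- length(intersect(targets, disease_proteins))
    n <- length(targets)
    data.frame(entity = id,
               score = correlation_score(profiles[[id]], disease_profile,
                                         exclude = exclude),
               k = k, n = n,
               p_value = if (n > 0) hypergeometric_overlap(k, n, N, M_total)
                         else NA_real_,
               enrichment = if (n > 0) fold_enrichment(k, n, N = N,
                                                       M_total = M_total)
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(-out$score, out$entity), ,
             drop = FALSE]
  out <- out[c("entity", "score", "k", "n", "p_value", "p_adjusted",
               "enrichment")]
  if (!is.null(min_enrichment)) {
    out <- out[!is.na(out$enrichment) & out$enrichment >= min_enrichment, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("ranked_candidates", "data.frame"))
}

#' @exportS3Method base::print
print.ranked_candidates <- function(x, n = 10L, ...) {
  cat("ranked_candidates:", nrow(x), "entities\n")
  print.data.frame(head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.ranked_candidates <- function(object, ...) {
  cat("Candidate prioritization over", nrow(object), "entities\n")
  cat("  correlation score range: [",
      sprintf("%.4g", min(object$score)), ", ",
      sprintf("%.4g", max(object$score)), "]\n", sep = "")
  sig <- sum(object$p_adjusted < 0.05, na.rm = TRUE)
  cat("  entities with BH-adjusted overlap p < 0.05:", sig, "\n")
  cat("  top entity:", object$entity[1], "\n")
  invisible(object)
}

#' @exportS3Method
plot.ranked_candidates <- function(x, top = 10L, ...) {
  d <- head(x, top)
  graphics::barplot(rev(d$score), names.arg = rev(d$entity), horiz = TRUE,
                    las = 1, xlab = "correlation score",
                    main = "Top candidates", ...)
  invisible(x)
}
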