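# Diffusion profiles: biased random walk with restart over the multiscale
# network. The profile r is the fixed point of
#   r <- (1 - alpha) s + alpha (r M + s * sum(r[J]))
# where s is the restart indicator, M the biased row-stochastic transition
# matrix and J the dangling set whose mass restarts through s.

#' Walk parameters
#'
#' @param alpha continuation probability of the walker (default 0.860)
#' @param epsilon L1 convergence tolerance between successive iterates
#'   (default 1e-6)
#' @param max_iterations iteration cap (default 500)
#' @return object of class `walk_parameters`
#' @export
walk_parameters <- function(alpha = 0.860, epsilon = 1e-6,
                            max_iterations = 500L) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations)),
            class = "walk_parameters")
}

#' Compute a diffusion profile by power iteration
#'
#' Iterates the restart recursion from `r0 = s` until the L1 difference of
#' successive iterates drops to `epsilon` or the iteration cap is hit.
#' Probability mass reaching dangling nodes is rerouted through the restart
#' vector, so the profile stays a probability distribution at every step.
#'
#' @param tm a `transition_matrix`
#' @param restart_node node id the walker restarts at
#' @param params a [walk_parameters()]
#' @return object of class `diffusion_profile`: named probability vector
#'   `p`, `entity`, `iterations`, `converged`
#' @export
compute_diffusion_profile <- function(tm, restart_node,
                                      params = walk_parameters()) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (!restart_node %in% names(tm$index)) {
    stop("unknown restart node: ", restart_node, call. = FALSE)
  }
  n <- length(tm$index)
  rs <- Matrix::rowSums(tm$M)
  live <- setdiff(seq_len(n), tm$J)
  if (any(abs(rs[live] - 1) > 1e-9)) {
    stop("transition matrix is not row-stochastic on non-dangling rows",
         call. = FALSE)
  }
  alpha <- params$alpha
  s <- numeric(n)
  s[tm$index[[restart_node]]] <- 1
  r <- s
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    dangling_mass <- if (length(tm$J) > 0L) sum(r[tm$J]) else 0
    r_new <- (1 - alpha) * s +
      alpha * (as.numeric(Matrix::crossprod(tm$M, r)) + s * dangling_mass)
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta <= params$epsilon) { converged <- TRUE; break }
  }
  structure(list(entity = restart_node,
                 p = setNames(r, names(tm$index)),
                 iterations = iter, converged = converged),
            class = "diffusion_profile")
}

#' @exportS3Method base::print
print.diffusion_profile <- function(x, ...) {
  cat("diffusion_profile for", x$entity, "over", length(x$p), "nodes;",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  top <- head(sort(x$p, decreasing = TRUE), 5)
  cat("  top nodes:",
      paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Dense linear-solve oracle for the diffusion fixed point
#'
#' Solves `r (I - alpha M') = (1 - alpha) s` exactly, where M' equals the
#' transition matrix with every dangling row replaced by the restart vector
#' s. Intended as an independent correctness check for the power iteration
#' on small networks.
#'
#' @param tm a `transition_matrix`
#' @param restart_node node id of the restart
#' @param alpha continuation probability
#' @param dense_limit refuse networks larger than this (default 2000 nodes)
#' @return a `diffusion_profile` (iterations = NA)
#' @export
solve_stationary_oracle <- function(tm, restart_node, alpha = 0.860,
                                    dense_limit = 2000L) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- length(tm$index)
  if (n > dense_limit) {
    stop("network exceeds the dense-solve limit (", dense_limit,
         " nodes); use compute_diffusion_profile()", call. = FALSE)
  }
  if (!restart_node %in% names(tm$index)) {
    stop("unknown restart node: ", restart_node, call. = FALSE)
  }
  s <- numeric(n)
  s[tm$index[[restart_node]]] <- 1
  Mp <- as.matrix(tm$M)
  if (length(tm$J) > 0L) Mp[tm$J, ] <- matrix(s, nrow = length(tm$J),
                                              ncol = n, byrow = TRUE)
  # transpose the row-vector equation: (I - alpha M')^T r^T = (1-alpha) s^T
  A <- diag(n) - alpha * t(Mp)
  r <- solve(A, (1 - alpha) * s)
  structure(list(entity = restart_node,
                 p = setNames(as.numeric(r), names(tm$index)),
                 iterations = NA_integer_, converged = TRUE),
            class = "diffusion_profile")
}

#' Diffusion profiles for a batch of entities
#'
#' Applies [compute_diffusion_profile()] to each entity over a shared
#' transition matrix. Repeated ids are computed once and returned at each
#' occurrence; output order follows input order.
#'
#' @param tm a `transition_matrix`
#' @param entity_ids character vector of restart nodes
#' @param params a [walk_parameters()]
#' @return named list of `diffusion_profile`s, one per input id
#' @export
batch_profiles <- function(tm, entity_ids, params = walk_parameters()) {
  if (length(entity_ids) == 0L) return(list())
  cache <- new.env(parent = emptyenv())
  out <- lapply(entity_ids, function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    prof <- tryCatch(compute_diffusion_profile(tm, id, params),
                     error = function(e) {
                       stop("diffusion failed for entity ", id, ": ",
                            conditionMessage(e), call. = FALSE)
                     })
    cache[[id]] <- prof
    prof
  })
  names(out) <- entity_ids
  out
}
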