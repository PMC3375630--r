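# Patch weights, the weighted patch distance, thresholded bipartite
# matching, pocket scoring, database search and ligand prediction.

# scale a descriptor to unit Euclidean norm (zero vectors stay zero)
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

#' Per-patch property weights from equivalent patches
#'
#' Given the patches at the same ligand-atom position across pockets that
#' bind the same ligand, computes for each property the average and
#' standard deviation of the all-pairs Euclidean distances between the
#' (unit-normalized) descriptors, and weights each property by the inverse
#' of `avg + 2 std`, normalized so the four weights sum to 1.  Properties
#' whose distances vary little across equivalent patches are thereby
#' trusted more during matching.
#'
#' @param patches List of at least two `surface_patch` objects sharing an
#'   anchor position.
#' @return Named numeric vector (shape, hyd, ele, conc) summing to 1.
#' @export
compute_weights <- function(patches) {
  if (length(patches) < 2L) {
    stop("at least two equivalent patches are required; ",
         "singleton groups fall back to uniform weights upstream")
  }
  stats <- vapply(.channel_names, function(ch) {
    mats <- lapply(patches, function(p) .unit(p$descriptors[[ch]]))
    n <- length(mats)
    d <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- c(d, sqrt(sum((mats[[i]] - mats[[j]])^2)))
    }
    c(mean(d), sqrt(mean((d - mean(d))^2)))
  }, numeric(2L))
  .weights_from_stats(stats[1L, ], stats[2L, ])
}

# inverse-dispersion weighting: w_t = (1/(avg_t + 2 std_t)) normalized to
# sum 1; degenerate zero-dispersion channels are floored at 1e-12
.weights_from_stats <- function(avg, std) {
  denom <- avg + 2 * std
  denom[denom <= 0] <- 1e-12
  w <- (1 / denom) / sum(1 / denom)
  stats::setNames(w, .channel_names)
}

#' Weighted distance between two patches
#'
#' `pdist = sum_t w_t * L2(d_At, d_Bt)` over the four property channels,
#' with every channel descriptor scaled to unit Euclidean norm first so
#' that fixed matching thresholds are comparable across patches.  The
#' weights come from the database patch.
#'
#' @param query_patch,db_patch `surface_patch` objects with all four
#'   descriptors.
#' @param weights Optional weight override (named like the channels).
#' @param property_set `"all"` or `"shape"` (forces weights 1,0,0,0).
#' @return Nonnegative scalar distance.
#' @export
patch_distance <- function(query_patch, db_patch, weights = NULL,
                           property_set = c("all", "shape")) {
  property_set <- match.arg(property_set)
  if (is.null(weights)) weights <- db_patch$weights
  if (property_set == "shape") {
    weights <- stats::setNames(c(1, 0, 0, 0), .channel_names)
  }
  total <- 0
  for (ch in .channel_names) {
    w <- weights[[ch]]
    if (w == 0) next
    a <- query_patch$descriptors[[ch]]
    b <- db_patch$descriptors[[ch]]
    if (length(a) != length(b)) {
      stop(sprintf("descriptor length mismatch on channel %s (%d vs %d)",
                   ch, length(a), length(b)))
    }
    total <- total + w * sqrt(sum((.unit(a) - .unit(b))^2))
  }
  total
}

# all query x target patch distances
.pdist_matrix <- function(query, target, property_set = "all") {
  nq <- length(query$patches)
  nt <- length(target$patches)
  M <- matrix(0, nq, nt)
  for (i in seq_len(nq)) for (j in seq_len(nt)) {
    M[i, j] <- patch_distance(query$patches[[i]], target$patches[[j]],
                              property_set = property_set)
  }
  M
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Shortest-augmenting-path implementation for a square cost matrix.
#' Returns the column assigned to each row; the optimum is exact, which the
#' test suite checks against permutation enumeration.
#'
#' @param cost Square numeric matrix (finite values).
#' @return Integer vector: `result[i]` is the column matched to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(n + 1L)          # index 1 = virtual column
  p <- integer(n + 1L)          # row assigned to each column (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cand <- which(!used)
      cand <- cand[cand > 1L]
      cur <- cost[i0, cand - 1L] - u[i0] - v[cand]
      upd <- cur < minv[cand]
      minv[cand[upd]] <- cur[upd]
      way[cand[upd]] <- j0
      j1 <- cand[which.min(minv[cand])]
      delta <- minv[j1]
      us <- which(used)
      u[p[us]] <- u[p[us]] + delta
      v[us] <- v[us] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  out[p[2L:(n + 1L)]] <- seq_len(n)
  out
}

#' Match patches between two pockets
#'
#' One-to-one assignment between query and target patches minimizing total
#' patch distance.  Without a threshold every patch of the smaller pocket
#' is matched.  With threshold `tau`, pairs with `pdist > tau` are
#' forbidden and the matching first maximizes the number of pairs, then
#' minimizes total distance (achieved by augmenting the cost matrix with
#' per-patch unmatch slots whose cost dominates any real total).
#'
#' @param query,target `pocket` objects.
#' @param threshold Patch-distance threshold, or `NULL` for none.
#' @param property_set `"all"` or `"shape"`.
#' @return A `patch_matching`: data frame `pairs` (query, target, distance)
#'   plus `unmatched_query` and `unmatched_target` index vectors.
#' @export
match_patches <- function(query, target, threshold = NULL,
                          property_set = c("all", "shape")) {
  property_set <- match.arg(property_set)
  if (length(query$patches) == 0L || length(target$patches) == 0L) {
    stop("both pockets must contain at least one patch")
  }
  M <- .pdist_matrix(query, target, property_set)
  nq <- nrow(M)
  nt <- ncol(M)
  allowed <- if (is.null(threshold)) M >= 0 else M <= threshold
  thr_part <- if (!is.null(threshold) && is.finite(threshold)) threshold else 0
  base <- max(M, thr_part, 1e-6, na.rm = TRUE)
  K <- (nq + nt + 1) * base          # unmatch cost: dominates real costs
  FORBID <- 4 * (nq + nt + 1) * K    # never part of an optimal solution
  n <- nq + nt
  C <- matrix(0, n, n)
  C[seq_len(nq), seq_len(nt)] <- ifelse(allowed, M, FORBID)
  C[seq_len(nq), nt + seq_len(nq)] <- FORBID
  C[cbind(seq_len(nq), nt + seq_len(nq))] <- K
  C[nq + seq_len(nt), seq_len(nt)] <- FORBID
  C[cbind(nq + seq_len(nt), seq_len(nt))] <- K
  a <- solve_assignment(C)
  qi <- seq_len(nq)
  matched <- qi[a[qi] <= nt & C[cbind(qi, a[qi])] < K]
  pairs <- data.frame(query = matched, target = a[matched],
                      distance = M[cbind(matched, a[matched])])
  pairs <- pairs[order(pairs$query), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_query = setdiff(seq_len(nq), pairs$query),
                 unmatched_target = setdiff(seq_len(nt), pairs$target),
                 threshold = threshold),
            class = "patch_matching")
}

#' @export
print.patch_matching <- function(x, ...) {
  cat(sprintf("<patch_matching: %d pairs, %d/%d unmatched (query/target)>\n",
              nrow(x$pairs), length(x$unmatched_query),
              length(x$unmatched_target)))
  invisible(x)
}

#' Pocket similarity score from a patch matching
#'
#' Linear combination of three terms (lower is more similar):
#' `c1 * mean matched distance + c2 * fraction of query patches unmatched +
#' c3 * |n_q - n_t| / max(n_q, n_t)`.  An empty matching scores
#' `c1 * tau + c2 + c3 * size term`, placing unmatched pockets behind every
#' matched one.
#'
#' @param matching A `patch_matching`.
#' @param query,target The matched `pocket` objects.
#' @param term_weights Coefficients (c1, c2, c3), default (1, 0.5, 0.5).
#' @return Nonnegative scalar score.
#' @export
pocket_score <- function(matching, query, target,
                         term_weights = c(1.0, 0.5, 0.5)) {
  nq <- length(query$patches)
  nt <- length(target$patches)
  size_term <- abs(nq - nt) / max(nq, nt)
  c1 <- term_weights[1L]; c2 <- term_weights[2L]; c3 <- term_weights[3L]
  if (nrow(matching$pairs) == 0L) {
    tau <- if (is.null(matching$threshold)) 1 else matching$threshold
    return(c1 * tau + c2 + c3 * size_term)
  }
  c1 * mean(matching$pairs$distance) +
    c2 * (length(matching$unmatched_query) / nq) +
    c3 * size_term
}

#' Search a pocket database with a query pocket
#'
#' Scores the query against every database entry with
#' [match_patches()] + [pocket_score()] and returns the ascending ranking.
#' Ties are broken lexicographically by pocket ID, so search is fully
#' deterministic.
#'
#' @param query A `pocket`.
#' @param db A `pocket_database`.
#' @param threshold Patch-distance threshold (`NULL` = none); defaults to
#'   the database build configuration.
#' @param property_set `"all"` (four properties) or `"shape"`.
#' @param term_weights Pocket-score coefficients.
#' @return A `retrieval_result` data frame: rank, pocket_id, ligand_code,
#'   score.
#' @export
search_database <- function(query, db, threshold = db$metadata$threshold,
                            property_set = c("all", "shape"),
                            term_weights = c(1.0, 0.5, 0.5)) {
  property_set <- match.arg(property_set)
  if (length(db$entries) == 0L) stop("database is empty")
  if (query$order != db$metadata$order) {
    stop(sprintf("query order %d does not match database order %d",
                 query$order, db$metadata$order))
  }
  scores <- vapply(db$entries, function(entry) {
    m <- match_patches(query, entry, threshold, property_set)
    pocket_score(m, query, entry, term_weights)
  }, numeric(1L))
  ids <- vapply(db$entries, `[[`, "", "source_id")
  ligs <- vapply(db$entries, `[[`, "", "ligand_code")
  ord <- order(scores, ids)
  out <- data.frame(rank = seq_along(ord), pocket_id = ids[ord],
                    ligand_code = ligs[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "query_id") <- query$source_id
  class(out) <- c("retrieval_result", "data.frame")
  out
}

#' Predict the binding ligand from a retrieval ranking
#'
#' Aggregates the top `k` retrieved pockets: each ligand type scores the
#' sum of `1 / rank` over its entries, and types are returned in descending
#' score order (ties broken by ligand code).
#'
#' @param result A `retrieval_result`.
#' @param k Number of top-ranked entries to aggregate.
#' @return Data frame (ligand_code, score) sorted by decreasing score.
#' @export
predict_ligand <- function(result, k = 10L) {
  if (k < 1L) stop("`k` must be at least 1")
  if (k > nrow(result)) {
    warning(sprintf("k = %d exceeds ranking size %d; clamped", k,
                    nrow(result)))
    k <- nrow(result)
  }
  top <- result[seq_len(k), , drop = FALSE]
  agg <- rowsum(1 / top$rank, top$ligand_code)
  out <- data.frame(ligand_code = rownames(agg), score = agg[, 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$ligand_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}
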