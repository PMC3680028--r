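#' Jaccard match score between two complexes
#'
#' \eqn{|K \cap R| / |K \cup R|}; 1 for identical membership, 0 for
#' disjoint complexes.
#'
#' @param k,r non-empty protein-ID sets (character vectors).
#' @return the score in `[0, 1]`.
#' @export
match_score <- function(k, r) {
  k <- unique(as.character(k))
  r <- unique(as.character(r))
  if (!length(k) || !length(r)) {
    stop("match score undefined for empty complexes", call. = FALSE)
  }
  length(intersect(k, r)) / length(union(k, r))
}

# n x m Jaccard matrix (rows = references, cols = predictions)
pairwise_match <- function(refs, preds) {
  M <- base::matrix(0, length(refs), length(preds))
  for (i in seq_along(refs)) {
    for (j in seq_along(preds)) {
      M[i, j] <- match_score(preds[[j]], refs[[i]])
    }
  }
  M
}

#' Complex-level recall, precision and F1
#'
#' A predicted complex matches a reference when their Jaccard score reaches
#' `alpha`. Recall is the fraction of reference complexes matched by some
#' prediction, precision the fraction of predictions matching some
#' reference, F1 their harmonic mean.
#'
#' @param refs,preds complex catalogs (`complex_set` or list of character
#'   vectors).
#' @param alpha match threshold in `(0, 1]`; 0.25 and 0.5 are the
#'   conventional operating points.
#' @return a list: `rec`, `prec`, `f1`, `matched_ref`, `matched_pred`.
#'   An empty catalog on either side makes the corresponding metrics 0
#'   (with a message).
#' @export
recall_precision <- function(refs, preds, alpha = 0.25) {
  stopifnot(alpha > 0, alpha <= 1)
  refs <- as_complex_set(refs)
  preds <- as_complex_set(preds)
  n <- length(refs)
  m <- length(preds)
  if (n == 0L || m == 0L) {
    message("empty catalog: recall/precision reported as 0")
    return(list(rec = 0, prec = 0, f1 = 0, matched_ref = 0L, matched_pred = 0L))
  }
  M <- pairwise_match(refs, preds)
  matched_ref <- sum(apply(M, 1L, max) >= alpha)
  matched_pred <- sum(apply(M, 2L, max) >= alpha)
  rec <- matched_ref / n
  prec <- matched_pred / m
  f1 <- if (rec + prec > 0) 2 * prec * rec / (prec + rec) else 0
  list(rec = rec, prec = prec, f1 = f1,
       matched_ref = matched_ref, matched_pred = matched_pred)
}

#' Reference-by-prediction confusion matrix
#'
#' Entry `t[i, j]` counts the proteins shared by reference complex `i` and
#' predicted complex `j`.
#'
#' @inheritParams recall_precision
#' @return an object of class `complex_confusion`: list with the integer
#'   matrix `t` and `ref_sizes` (reference complex sizes).
#' @export
complex_confusion <- function(refs, preds) {
  refs <- as_complex_set(refs)
  preds <- as_complex_set(preds)
  t_ij <- base::matrix(0L, length(refs), length(preds))
  for (i in seq_along(refs)) {
    for (j in seq_along(preds)) {
      t_ij[i, j] <- length(intersect(refs[[i]], preds[[j]]))
    }
  }
  structure(list(t = t_ij, ref_sizes = lengths(refs)),
            class = "complex_confusion")
}

#' Clustering-wise sensitivity, PPV and accuracy
#'
#' From the confusion matrix `T`:
#' \deqn{Sn = \frac{\sum_i \max_j t_{ij}}{\sum_i n_i}, \quad
#'       PPV = \frac{\sum_j \max_i t_{ij}}{\sum_j \sum_i t_{ij}}, \quad
#'       Acc = \sqrt{Sn \cdot PPV}}
#' Sn is inflated by one giant cluster, PPV by singleton clusters; their
#' geometric mean Acc balances the two. When no prediction overlaps any
#' reference the PPV denominator vanishes and PPV and Acc are reported
#' as 0.
#'
#' @param cm a `complex_confusion` from [complex_confusion()].
#' @return a list: `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(cm) {
  stopifnot(inherits(cm, "complex_confusion"))
  t_ij <- cm$t
  if (nrow(t_ij) == 0L || ncol(t_ij) == 0L) {
    message("empty catalog: Sn/PPV/Acc reported as 0")
    return(list(sn = 0, ppv = 0, acc = 0))
  }
  sn <- sum(apply(t_ij, 1L, max)) / sum(cm$ref_sizes)
  tot <- sum(t_ij)
  if (tot == 0) {
    message("no reference/prediction overlap: PPV reported as 0")
    ppv <- 0
  } else {
    ppv <- sum(apply(t_ij, 2L, max)) / tot
  }
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio (MMR)
#'
#' Builds the bipartite graph between reference and predicted complexes
#' with edge weight equal to the Jaccard match score (zero-score pairs get
#' no edge and can never be matched), computes a maximum-total-weight
#' one-to-one matching, and divides the matched weight by the number of
#' reference complexes. Unlike PPV, MMR does not penalize predictions for
#' overlapping one another.
#'
#' @inheritParams recall_precision
#' @return the ratio in `[0, 1]`; 0 when there are no predictions.
#' @export
mmr <- function(refs, preds) {
  refs <- as_complex_set(refs)
  preds <- as_complex_set(preds)
  n <- length(refs)
  if (n == 0L) stop("MMR undefined without reference complexes", call. = FALSE)
  m <- length(preds)
  if (m == 0L) return(0)
  M <- pairwise_match(refs, preds)
  idx <- which(M > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  vnames <- c(paste0("R", seq_len(n)), paste0("P", seq_len(m)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("R", idx[, 1L]), to = paste0("P", idx[, 2L]),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE))
  igraph::V(g)$type <- igraph::V(g)$name %in% paste0("P", seq_len(m))
  res <- igraph::max_bipartite_match(g, weights = M[idx])
  res$matching_weight / n
}

#' Score a predicted complex catalog against a reference catalog
#'
#' One call computing the full evaluation report: matched counts and
#' recall/precision/F1 at threshold `alpha`, clustering-wise Sn/PPV/Acc,
#' and the maximum matching ratio.
#'
#' @inheritParams recall_precision
#' @param min_size if not `NULL`, complexes smaller than this are dropped
#'   from both catalogs before scoring (conventionally 4 when comparing
#'   against hand-curated catalogs).
#' @return a one-row data frame with columns `alpha`, `n_ref`, `n_pred`,
#'   `matched_ref`, `matched_pred`, `rec`, `prec`, `f1`, `sn`, `ppv`,
#'   `acc`, `mmr`.
#' @export
evaluate_complexes <- function(refs, preds, alpha = 0.25, min_size = NULL) {
  refs <- as_complex_set(refs)
  preds <- as_complex_set(preds)
  if (!is.null(min_size)) {
    refs <- complex_set(unclass(refs)[lengths(refs) >= min_size])
    preds <- complex_set(unclass(preds)[lengths(preds) >= min_size])
  }
  rp <- recall_precision(refs, preds, alpha)
  spa <- sn_ppv_acc(complex_confusion(refs, preds))
  mm <- if (length(refs) == 0L) 0 else mmr(refs, preds)
  data.frame(alpha = alpha, n_ref = length(refs), n_pred = length(preds),
             matched_ref = rp$matched_ref, matched_pred = rp$matched_pred,
             rec = rp$rec, prec = rp$prec, f1 = rp$f1,
             sn = spa$sn, ppv = spa$ppv, acc = spa$acc, mmr = mm)
}
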