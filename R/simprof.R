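## SIMPROF: similarity-profile permutation test (Clarke-style) on
## Bray-Curtis resemblance profiles.

## sorted dissimilarity profile of an accessions x loci matrix; binary
## data uses the closed form d = 1 - 2*shared/(r_i + r_j) (equal to
## Bray-Curtis on 0/1 data) for speed in the permutation loop, with the
## all-zero-pair convention d = 1
.bc_profile <- function(x, binary = all(x == 0L | x == 1L)) {
  if (binary) {
    s <- tcrossprod(x)
    r <- rowSums(x)
    denom <- outer(r, r, "+")
    d <- 1 - 2 * s / denom
    d[denom == 0] <- 1
    sort(d[lower.tri(d)])
  } else {
    d <- vegan::vegdist(x, method = "bray")
    d[is.nan(d)] <- 1
    sort(as.numeric(d))
  }
}

## permute each locus column independently across accessions
.permute_columns <- function(x) {
  n <- nrow(x)
  for (j in seq_len(ncol(x))) x[, j] <- x[sample.int(n), j]
  x
}

#' SIMPROF test for internal structure of an accession set
#'
#' Tests whether a set of accessions has real multivariate structure in
#' its presence/absence profiles.  The actual resemblance profile is the
#' sorted vector of pairwise Bray-Curtis dissimilarities.  Null profiles
#' are generated by independently permuting each locus column across the
#' accessions; the mean profile is the rank-wise mean of `n_mean_perms`
#' such null profiles, and the test statistic
#' `pi = sum_ranks |actual - mean|` measures the deviation of the actual
#' profile from it.  Significance comes from `n_null_perms` further null
#' profiles: `p = (1 + #\{null pi >= observed pi\}) / (1 + n_null_perms)`.
#'
#' Accessions are put into a canonical order (by profile content) before
#' any permutation is drawn, so the p-value does not depend on input row
#' order for a fixed seed.  Sets with fewer than 3 accessions auto-pass
#' as non-significant.
#'
#' @param x Accessions x loci matrix (rows are the node's members).
#' @param n_mean_perms Permutations used for the mean profile (default
#'   1000).
#' @param n_null_perms Permutations used for the null pi distribution
#'   (default 999).
#' @param seed Optional integer seed.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `simprof_result`: `n_members`, `pi`,
#'   `p_value`, `significant`, `n_mean_perms`, `n_null_perms`.
#' @export
simprof <- function(x, n_mean_perms = 1000L, n_null_perms = 999L,
                    seed = NULL, alpha = 0.05) {
  x <- as.matrix(x)
  if (nrow(x) < 3L)
    return(structure(list(n_members = nrow(x), pi = NA_real_,
                          p_value = 1, significant = FALSE,
                          n_mean_perms = 0L, n_null_perms = 0L),
                     class = "simprof_result"))
  if (!is.null(seed)) set.seed(seed)
  ## canonical row order: p-value invariant to accession ordering
  x <- x[order(apply(x, 1, paste, collapse = "\r")), , drop = FALSE]
  binary <- all(x == 0L | x == 1L)
  actual <- .bc_profile(x, binary)
  n_pair <- length(actual)
  profs <- matrix(0, n_mean_perms + n_null_perms, n_pair)
  for (b in seq_len(nrow(profs)))
    profs[b, ] <- .bc_profile(.permute_columns(x), binary)
  mean_profile <- colMeans(profs[seq_len(n_mean_perms), , drop = FALSE])
  pi_obs <- sum(abs(actual - mean_profile))
  null_rows <- profs[n_mean_perms + seq_len(n_null_perms), , drop = FALSE]
  pi_null <- rowSums(abs(sweep(null_rows, 2, mean_profile)))
  p <- (1 + sum(pi_null >= pi_obs)) / (1 + n_null_perms)
  structure(list(n_members = nrow(x), pi = pi_obs, p_value = p,
                 significant = p < alpha,
                 n_mean_perms = as.integer(n_mean_perms),
                 n_null_perms = as.integer(n_null_perms)),
            class = "simprof_result")
}

## leaf indices under a merge-tree node (hclust convention)
.node_members <- function(merge, node) {
  if (node < 0L) return(-node)
  c(.node_members(merge, merge[node, 1L]),
    .node_members(merge, merge[node, 2L]))
}

#' Bray-Curtis dendrogram with top-down SIMPROF tests
#'
#' Clusters accessions by group-average linkage on Bray-Curtis
#' dissimilarities, then walks the dendrogram from the root applying
#' [simprof()] to each node's members.  Children of a non-significant
#' node are not tested (the standard SIMPROF stopping rule), so the
#' significant nodes delimit the statistically supported groups.
#'
#' @param x Accessions x loci presence/absence matrix (rownames are
#'   accession ids).
#' @param alpha Significance level (default 0.05).
#' @param n_mean_perms,n_null_perms Permutation counts per node (defaults
#'   1000 and 999).
#' @param seed Optional integer seed (per-node seeds are derived from
#'   it).
#' @param method Linkage for [cluster_accessions()].
#' @return A list of class `simprof_clustering`: `hclust`, `tests`
#'   (data.frame: `node_id`, `n_members`, `pi`, `p_value`, `significant`,
#'   `members`), and `groups` (named integer vector: the partition
#'   obtained by cutting at non-significant nodes).
#' @export
simprof_dendrogram <- function(x, alpha = 0.05, n_mean_perms = 1000L,
                               n_null_perms = 999L, seed = NULL,
                               method = "average") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("acc%d", seq_len(nrow(x)))
  d <- bray_curtis(x)
  hc <- cluster_accessions(d, method = method)
  n <- nrow(x)
  tests <- list()
  groups <- rep(NA_integer_, n)
  names(groups) <- rownames(x)
  next_group <- 0L
  assign_group <- function(members) {
    next_group <<- next_group + 1L
    groups[members] <<- next_group
  }
  visit <- function(node) {
    members <- .node_members(hc$merge, node)
    res <- simprof(x[members, , drop = FALSE],
                   n_mean_perms = n_mean_perms,
                   n_null_perms = n_null_perms,
                   seed = if (is.null(seed)) NULL
                          else (seed + 7919L * abs(node)) %% 2147483647L,
                   alpha = alpha)
    tests[[length(tests) + 1L]] <<- data.frame(
      node_id = node, n_members = length(members),
      pi = res$pi, p_value = res$p_value, significant = res$significant,
      members = paste(rownames(x)[members], collapse = ","),
      stringsAsFactors = FALSE)
    if (res$significant) {
      for (child in hc$merge[node, ]) {
        if (child < 0L) assign_group(-child)
        else visit(child)
      }
    } else {
      assign_group(members)
    }
  }
  visit(n - 1L)
  structure(list(hclust = hc, tests = do.call(rbind, tests),
                 groups = groups),
            class = "simprof_clustering")
}
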