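#' Per-node projection profile
#'
#' Each node's feature vector is the concatenation of its afferent count
#' profile (cells it receives from every other node) and its efferent count
#' profile (cells it sends to every other node), ipsi + contra summed, over
#' a fixed node order. Nodes with similar structural connectivity patterns
#' end up close in Euclidean distance, which is what the dendrogram-based
#' module detection clusters on.
#'
#' @param counts Count table (see [validate_counts()]).
#' @param node_set Ordered character vector of nodes; every region in
#'   `counts` must appear.
#' @return Numeric matrix, one row per node (rownames = `node_set`),
#'   `2 * (length(node_set) - 1)` columns: afferent profile then efferent
#'   profile.
#' @export
projection_profile <- function(counts, node_set = vsb_regions()) {
  counts <- validate_counts(counts)
  unknown <- setdiff(unique(c(counts$injection, counts$source)), node_set)
  if (length(unknown)) {
    stop_input("regions absent from the node set: ",
               paste(unknown, collapse = ", "))
  }
  n <- length(node_set)
  W <- matrix(0, n, n, dimnames = list(node_set, node_set))
  agg <- tapply(counts$count, list(counts$source, counts$injection), sum)
  W[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  # W[a, b] = projection a -> b; afferent profile of i is column i,
  # efferent profile is row i, each dropping the self entry
  prof <- t(vapply(seq_len(n), function(i) {
    c(W[-i, i], W[i, -i])
  }, numeric(2 * (n - 1))))
  rownames(prof) <- node_set
  colnames(prof) <- c(paste0("aff_", seq_len(n - 1)),
                      paste0("eff_", seq_len(n - 1)))
  prof
}

#' Detect modules by hierarchical clustering of projection profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance) of the
#' per-node projection profiles, cut either at a fixed dendrogram height
#' `h` or into exactly `k` flat clusters. Module ids are renumbered
#' contiguously from 1 in order of first appearance over the node order.
#'
#' @param profiles Profile matrix from [projection_profile()] (rows =
#'   nodes).
#' @param h Dendrogram cut height (Euclidean).
#' @param k Number of modules; exactly one of `h`, `k` must be given.
#' @param linkage Agglomeration method: `"complete"` (default),
#'   `"average"`, or `"ward.D2"`.
#' @return An object of class `module_partition`:
#'   \describe{
#'     \item{assignment}{Named integer vector node -> module id.}
#'     \item{tree}{The [stats::hclust] object (merge table, heights).}
#'     \item{method}{Record of distance, linkage and cut rule.}
#'   }
#' @export
detect_modules <- function(profiles, h = NULL, k = NULL,
                           linkage = c("complete", "average", "ward.D2")) {
  linkage <- match.arg(linkage)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop_input("need at least 2 nodes to cluster")
  if (is.null(h) == is.null(k)) {
    stop_input("give exactly one of 'h' (cut height) or 'k' (module count)")
  }
  if (!is.null(k)) {
    check_scalar_number(k, "k", min = 1, max = n)
  }
  tree <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                        method = linkage)
  raw <- if (is.null(k)) stats::cutree(tree, h = h) else
    stats::cutree(tree, k = k)
  assignment <- match(raw, unique(raw))
  names(assignment) <- rownames(profiles)
  structure(
    list(assignment = assignment, tree = tree,
         method = list(distance = "euclidean", linkage = linkage,
                       cut = if (is.null(k)) list(h = h) else list(k = k))),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("module_partition: %d nodes in %d modules (%s linkage, cut %s)\n",
              length(x$assignment), k, x$method$linkage,
              paste(names(x$method$cut), unlist(x$method$cut),
                    sep = " = ")))
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

# Accept a module_partition or a bare named/unnamed assignment vector,
# aligned to `nodes`.
partition_assignment <- function(partition, nodes) {
  a <- if (inherits(partition, "module_partition")) partition$assignment
       else partition
  if (!is.null(names(a))) {
    if (!all(nodes %in% names(a))) {
      stop_input("partition does not cover node(s): ",
                 paste(setdiff(nodes, names(a)), collapse = ", "))
    }
    a <- a[nodes]
  } else if (length(a) != length(nodes)) {
    stop_input("partition must cover all ", length(nodes), " nodes")
  }
  as.integer(a)
}

#' Adjusted agreement between two partitions
#'
#' Adjusted Rand index between two module assignments (1 = identical up to
#' relabeling, ~0 = chance agreement); used to score recovery of planted
#' module structure.
#'
#' @param a,b Integer module assignments over the same nodes.
#' @return The adjusted Rand index.
#' @export
partition_agreement <- function(a, b) {
  if (length(a) != length(b)) stop_input("partitions differ in length")
  mclust::adjustedRandIndex(a, b)
}
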