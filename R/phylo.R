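#' Pairwise p-distance matrix
#'
#' For every pair, aligns the sequences and computes the fraction of
#' mismatched residues over gap-free aligned columns, optionally with the
#' Poisson multiple-hit correction `-ln(1 - p)`. A distance surrogate for
#' likelihood-based trees: clade assignment depends on separation, not on
#' branch-length optimality.
#'
#' @param sequences named character vector (at least 3 sequences).
#' @param params an [alignment_params()].
#' @param correction `"none"` or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
pdistance_matrix <- function(sequences, params = alignment_params(),
                             correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- length(sequences)
  if (n < 3L) stop("need at least 3 sequences")
  if (is.null(names(sequences))) stop("sequences must be named")
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- align_pair(sequences[[i]], sequences[[j]], params)
    qa <- strsplit(a$query_aln, "")[[1]]
    ra <- strsplit(a$ref_aln, "")[[1]]
    keep <- qa != "-" & ra != "-"
    if (!any(keep))
      stop("no gap-free aligned columns between ", names(sequences)[i],
           " and ", names(sequences)[j])
    p <- mean(qa[keep] != ra[keep])
    d[i, j] <- d[j, i] <- apply_correction(p, correction)
  }
  d
}

apply_correction <- function(p, correction) {
  if (correction == "none") return(p)
  if (p >= 1) stop("p-distance of 1 cannot be Poisson-corrected")
  -log(1 - p)
}

#' Reference-anchored stacked alignment
#'
#' Aligns every sequence to one anchor reference and stacks the results into
#' a character matrix whose columns are the anchor's positions (query
#' insertions relative to the anchor are dropped). This gives the
#' alignment-columns view used for column-bootstrap resampling. Adequate for
#' indel-light data; a progressive multiple alignment should replace it on
#' indel-rich real data.
#'
#' @param sequences named character vector.
#' @param anchor name of the anchor sequence (must be in `sequences`).
#' @param params an [alignment_params()].
#' @return Character matrix, rows = sequences, columns = anchor positions;
#'   `"-"` where a sequence has no residue in an anchor column.
#' @export
anchored_alignment <- function(sequences, anchor, params = alignment_params()) {
  if (!anchor %in% names(sequences)) stop("anchor not found among sequences")
  ref <- sequences[[anchor]]
  L <- nchar(ref)
  out <- matrix("-", length(sequences), L,
                dimnames = list(names(sequences), NULL))
  for (id in names(sequences)) {
    if (id == anchor) { out[id, ] <- strsplit(ref, "")[[1]]; next }
    a <- align_pair(sequences[[id]], ref, params)
    qa <- strsplit(a$query_aln, "")[[1]]
    ra <- strsplit(a$ref_aln, "")[[1]]
    rpos <- a$ref_start - 1L
    for (k in seq_along(qa)) {
      if (ra[k] != "-") {
        rpos <- rpos + 1L
        out[id, rpos] <- qa[k]
      }
    }
  }
  out
}

#' p-distances from a stacked alignment matrix
#'
#' @param aln character matrix from [anchored_alignment()] (or any aligned
#'   character matrix with `"-"` gaps).
#' @param correction `"none"` or `"poisson"`.
#' @param on_empty_overlap what to do for a pair with no gap-free shared
#'   columns: `"error"` (default), or `"max"` -- substitute 1.5 times the
#'   largest finite distance in the matrix (used by bootstrap replicates,
#'   where resampling can drop the entire overlap of a distant pair).
#' @return Symmetric distance matrix over the row names.
#' @export
matrix_pdistance <- function(aln, correction = c("none", "poisson"),
                             on_empty_overlap = c("error", "max")) {
  correction <- match.arg(correction)
  on_empty_overlap <- match.arg(on_empty_overlap)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- aln[i, ] != "-" & aln[j, ] != "-"
    if (!any(keep)) {
      if (on_empty_overlap == "error")
        stop("no gap-free aligned columns between ", rownames(aln)[i],
             " and ", rownames(aln)[j])
      d[i, j] <- d[j, i] <- NA_real_
      next
    }
    p <- mean(aln[i, keep] != aln[j, keep])
    if (correction == "poisson" && p > 0.95) p <- 0.95  # cap for correctability
    d[i, j] <- d[j, i] <- apply_correction(p, correction)
  }
  if (anyNA(d)) {
    cap <- if (all(is.na(d[upper.tri(d)]))) 1 else 1.5 * max(d, na.rm = TRUE)
    d[is.na(d)] <- cap
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix. Negative branch
#' lengths (a known NJ artefact on non-additive input) are clamped to zero
#' with the total deficit reported as a warning.
#'
#' @param d symmetric distance matrix with zero diagonal (at least 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_build <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warning(sprintf("clamped %d negative NJ branch length(s); total deficit %.3g",
                    sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Column-bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and writes the percentage of replicates containing each
#' internal bipartition onto the tree's node labels (classical Felsenstein
#' column bootstrap; 100 replicates by default).
#'
#' @param aln stacked alignment matrix from [anchored_alignment()].
#' @param n_replicates bootstrap replicates (at least 1; default 100).
#' @param seed RNG seed.
#' @param correction distance correction passed to [matrix_pdistance()].
#' @return The NJ tree built from the full alignment, with internal-node
#'   labels holding support percentages in `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              correction = "none") {
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  aln <- aln[order(rownames(aln)), , drop = FALSE]  # canonical leaf order
  tr <- nj_build(matrix_pdistance(aln, correction))
  reps <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    suppressWarnings(nj_build(matrix_pdistance(aln[, cols, drop = FALSE],
                                               correction,
                                               on_empty_overlap = "max")))
  }))
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round(100 * counts / n_replicates, 1)
  tr$node.label <- as.character(supports)
  tr$node.label[1] <- ""  # root of the unrooted representation carries no split
  tr
}

# Every internal edge of an unrooted tree splits the tips in two. For one
# clade's reference set, the smallest split side containing all its
# references is the clade's spanning-subtree tip set; the defining edge's
# bootstrap support qualifies the clade.
clade_span <- function(tree, ref_tips, min_support = 50) {
  # edgelabel = TRUE keeps support values attached to their edges on re-rooting
  rt <- ape::root(tree, outgroup = setdiff(tree$tip.label, ref_tips)[1],
                  resolve.root = TRUE, edgelabel = TRUE)
  pp <- ape::prop.part(rt)
  labels <- attr(pp, "labels")
  node_labels <- rt$node.label
  if (is.null(node_labels)) node_labels <- rep(NA_character_, length(pp))
  best <- list(tips = tree$tip.label, support = NA_real_)  # trivial side
  for (i in seq_along(pp)) {
    below <- labels[pp[[i]]]
    lab <- node_labels[i]
    sup <- if (is.na(lab) || !nzchar(lab)) NA_real_ else
      suppressWarnings(as.numeric(lab))
    if (!is.na(sup) && sup < min_support) next  # unsupported edges define no clade
    for (side in list(below, setdiff(labels, below))) {
      if (all(ref_tips %in% side) && length(side) < length(best$tips)) {
        best <- list(tips = side, support = sup)
      }
    }
  }
  best
}

#' Assign query sequences to reference clades
#'
#' A query is assigned to the clade of its nearest reference (by corrected
#' distance) when three checks pass: (i) no distance tie with another clade;
#' (ii) the NJ tree contains a bipartition side holding the clade's
#' references and the query, no reference of any other clade, and bootstrap
#' support of at least `min_support` on its subtending edge (an unlabelled
#' edge passes) -- the query falls inside the clade's spanning subtree;
#' (iii) the query's distance to the clade is commensurate with the clade's
#' own spread (at most `max_stretch` times the reference diameter plus a
#' small floor), which rejects unrelated sequences that merely attach as a
#' long-branch sister of the clade. Anything else is `"unassigned"`.
#'
#' @param query_ids ids of the query tips.
#' @param ref_clades named character vector: reference tip id -> clade label
#'   (at least 2 references per clade).
#' @param tree `phylo` tree over queries and references, node labels holding
#'   bootstrap supports.
#' @param d distance matrix over the same tips.
#' @param min_support support threshold in percent (default 50).
#' @param max_stretch allowed ratio of query-to-clade distance over the
#'   clade's reference diameter (default 2.5, plus an absolute floor of 0.05
#'   to keep near-identical reference panels usable).
#' @return data.frame: `query_id`, `clade_label`, `support`,
#'   `nearest_reference`, `nearest_distance`, `in_clade_subtree`.
#' @export
assign_clade <- function(query_ids, ref_clades, tree, d, min_support = 50,
                         max_stretch = 2.5) {
  clades <- unique(ref_clades)
  if (any(table(ref_clades) < 2L)) stop("need at least 2 references per clade")
  rows <- lapply(query_ids, function(q) {
    dq <- d[q, names(ref_clades)]
    per_clade <- vapply(clades, function(cl)
      min(dq[names(ref_clades)[ref_clades == cl]]), numeric(1))
    o <- order(per_clade)
    best <- clades[o[1]]
    tied <- length(clades) > 1L && per_clade[o[2]] - per_clade[o[1]] < 1e-12
    ref_tips <- names(ref_clades)[ref_clades == best]
    span <- clade_span(tree, c(ref_tips, q), min_support)
    pure <- !any(setdiff(names(ref_clades), ref_tips) %in% span$tips)
    diam <- max(d[ref_tips, ref_tips])
    close_enough <- per_clade[o[1]] <= max_stretch * diam + 0.05
    ok <- !tied && pure && close_enough
    data.frame(query_id = q,
               clade_label = if (ok) best else "unassigned",
               support = span$support, nearest_reference = names(which.min(dq)),
               nearest_distance = unname(per_clade[o[1]]),
               in_clade_subtree = pure)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
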