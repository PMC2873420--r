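#' Poisson-corrected distance between two DBD peptides
#'
#' Globally aligns the two peptides, computes the p-distance over aligned
#' residue columns (gap columns excluded), and applies the Poisson correction
#' `-ln(1 - p)`. To keep neighbor-joining numerically stable for highly
#' divergent domains, p is capped at `cap_p` (default 0.95, distance about
#' 3.0); a pair with no shared residue columns gets the capped maximum and is
#' flagged via the `"capped"` attribute.
#'
#' @param a,b peptide strings.
#' @param scheme a [substitution_scheme()].
#' @param cap_p cap on the p-distance before the log transform.
#' @return non-negative distance (symmetric in its arguments).
#' @export
dbd_distance <- function(a, b, scheme = substitution_scheme(), cap_p = 0.95) {
  aln <- global_align(a, b, scheme)
  aq <- strsplit(aln$aligned_query, "")[[1]]
  at <- strsplit(aln$aligned_target, "")[[1]]
  res_cols <- aq != "-" & at != "-"
  n <- sum(res_cols)
  capped <- FALSE
  if (n == 0) {
    p <- cap_p
    capped <- TRUE
  } else {
    p <- sum(aq[res_cols] != at[res_cols]) / n
    if (p >= cap_p) {
      p <- cap_p
      capped <- TRUE
    }
  }
  structure(-log(1 - p), capped = capped)
}

#' Pairwise distance matrix over a set of domain sequences
#'
#' @param seqs named character vector of peptides (names become labels).
#' @param scheme a [substitution_scheme()].
#' @param cap_p passed to [dbd_distance()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, scheme = substitution_scheme(),
                            cap_p = 0.95) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must have unique names")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- as.numeric(
          dbd_distance(seqs[[i]], seqs[[j]], scheme, cap_p))
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion with deterministic
#' tie-breaking (lowest index pair in the current label ordering). Negative
#' branch lengths are set to zero with the deficit transferred to the sister
#' branch, so all output branch lengths are non-negative. NJ is exact on
#' additive matrices, which is the module's correctness oracle.
#'
#' @param dm symmetric numeric matrix with labels as dimnames (>= 3 labels).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("dm must be a square matrix")
  labels <- rownames(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor-joining needs at least 3 labels")
  if (is.null(labels)) stop("dm must carry labels as dimnames")
  if (max(abs(dm - t(dm))) > 1e-12) stop("dm must be symmetric")
  if (any(diag(dm) != 0)) stop("dm must have a zero diagonal")

  ntip <- n
  # node ids: tips 1..ntip, internals ntip+1 ... ; root-less construction
  active_id <- seq_len(ntip) # phylo node id per active cluster
  D <- dm
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  next_internal <- ntip + 2L # reserve ntip+1 for the final join (ape root id)

  transfer <- list() # per active cluster: pending edge index to absorb deficit
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
    length(lens)
  }

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest-index pair among minima, scanning column-major upper triangle
    best <- Inf
    bi <- bj <- 0L
    for (j in 2:r) {
      for (i in 1:(j - 1)) {
        if (Q[i, j] < best) {
          best <- Q[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    vi <- D[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (r - 2))
    vj <- D[bi, bj] - vi
    # clamp negatives, transferring the deficit to the sister branch
    if (vi < 0) {
      vj <- vj + vi
      vi <- 0
    }
    if (vj < 0) {
      vi <- vi + vj
      vj <- 0
    }
    u <- next_internal
    next_internal <- next_internal + 1L
    ei <- add_edge(u, active_id[bi], vi)
    ej <- add_edge(u, active_id[bj], vj)
    newd <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(r), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    D <- D2
    active_id <- c(active_id[keep], u)
  }

  # resolve the final three clusters around one internal node (ape's root id)
  u <- ntip + 1L
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(va, vb, vc)
  # clamp negatives; spread the deficit over the other two terminal branches
  for (k in 1:3) {
    if (v[k] < 0) {
      others <- setdiff(1:3, k)
      v[others] <- v[others] + v[k] / 2
      v[k] <- 0
    }
  }
  v <- pmax(v, 0)
  for (k in 1:3) add_edge(u, active_id[k], v[k])

  Nnode <- next_internal - ntip - 1L
  tree <- list(edge = edges, edge.length = lens, tip.label = labels,
               Nnode = as.integer(Nnode))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Assign query leaves to reference clades by tree proximity
#'
#' Each non-reference leaf receives the group of its nearest reference leaf
#' by path length in the tree; exact ties yield `UNASSIGNED`.
#'
#' @param tree an `ape::phylo` containing all reference leaves.
#' @param references named character vector: reference leaf -> group label.
#' @return named character vector: query leaf -> group (or `UNASSIGNED`).
#' @export
assign_clades <- function(tree, references) {
  refs <- names(references)
  missing <- setdiff(refs, tree$tip.label)
  if (length(missing))
    stop("reference leaf/leaves missing from the tree: ",
         paste(missing, collapse = ","))
  groups <- unique(references)
  if (any(table(references) < 2))
    warning("each reference group should have at least 2 leaves")
  pd <- ape::cophenetic.phylo(tree)
  queries <- setdiff(tree$tip.label, refs)
  out <- setNames(character(length(queries)), queries)
  for (q in queries) {
    dref <- pd[q, refs]
    bygroup <- vapply(groups, function(g) min(dref[references == g]),
                      numeric(1))
    o <- order(bygroup)
    if (length(bygroup) > 1 &&
        abs(bygroup[o[1]] - bygroup[o[2]]) < 1e-12) {
      out[q] <- "UNASSIGNED"
    } else {
      out[q] <- groups[o[1]]
    }
  }
  out
}

#' Write a tree as Newick
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
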