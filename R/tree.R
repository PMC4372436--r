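#' Parse a Newick string into a phylogeny
#'
#' Reads a rooted Newick tree (quoted labels and polytomies supported) and
#' validates it for downstream diversity calculations: unique leaf labels,
#' branch lengths on every non-root edge, and non-negative lengths. A root
#' edge length, if present, is dropped; rooting of Faith's PD is handled by
#' the diversity functions themselves.
#'
#' @param text Newick string (must end in ";").
#' @param missing_lengths One of "error" (default) or "zero". With "zero",
#'   absent branch lengths are substituted by 0 instead of raising an error.
#' @return An object of class \code{phylo} (see \pkg{ape}).
#' @export
parse_newick <- function(text, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable string", call. = FALSE)
  validate_tree(tree, missing_lengths = missing_lengths)
}

# Cheap structural scan so malformed input is reported with a character
# position, which ape::read.tree does not provide.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (quoted)
    stop("Newick parse error: unterminated quoted label", call. = FALSE)
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of string",
         call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing terminal ';' at character ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

validate_tree <- function(tree, missing_lengths = "error") {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty leaf labels are not allowed", call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "zero") {
      tree$edge.length <- rep(0, nrow(tree$edge))
    } else {
      stop("tree has no branch lengths (use missing_lengths = \"zero\" to ",
           "substitute 0)", call. = FALSE)
    }
  }
  if (anyNA(tree$edge.length)) {
    if (missing_lengths == "zero") {
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      stop("missing branch lengths on ", sum(is.na(tree$edge.length)),
           " edges", call. = FALSE)
    }
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  # drop a root edge if one was read
  tree$root.edge <- NULL
  tree
}

#' Write a phylogeny to Newick
#'
#' Branch lengths are emitted with 12 significant digits so that a
#' parse/write round trip preserves lengths to printed precision.
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; if \code{NULL} the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, con = file)
  invisible(txt)
}

#' Node depths (distance from the root) for every node
#'
#' @param tree A \code{phylo} object.
#' @return Numeric vector over node ids 1..(Ntip+Nnode); root depth 0.
#' @keywords internal
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- numeric(n_all)
  root <- n_tip + 1L
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]
    c <- ord$edge[k, 2L]
    depth[c] <- depth[p] + ord$edge.length[k]
  }
  depth
}

#' Test whether a tree is ultrametric
#'
#' All root-to-leaf path sums must agree within a relative tolerance
#' (absolute when the tree height is zero).
#'
#' @param tree A \code{phylo} object.
#' @param tol Relative tolerance, default \code{1e-6}.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  n_tip <- length(tree$tip.label)
  d <- node_depths(tree)[seq_len(n_tip)]
  h <- max(d)
  if (h == 0) return(TRUE)
  (max(d) - min(d)) / h <= tol
}

#' Tree height (maximum root-to-leaf distance)
#'
#' @param tree A \code{phylo} object.
#' @return Non-negative numeric scalar.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(length(tree$tip.label))])
}

#' Total branch length of a tree
#'
#' @param tree A \code{phylo} object.
#' @return Sum of all branch lengths (0 for a single-node tree).
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

#' Prune a tree to a subset of leaves
#'
#' Unifurcating internal nodes created by the pruning are suppressed with
#' their branch lengths summed, so root-to-leaf depths of retained taxa --
#' and hence all pairwise patristic distances among them -- are unchanged.
#'
#' @param tree A \code{phylo} object.
#' @param taxa Character vector of leaf labels to keep (non-empty subset).
#' @return The pruned \code{phylo}.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxon set", call. = FALSE)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Patristic distance matrix over leaves
#'
#' @param tree A \code{phylo} object.
#' @return Symmetric matrix of path-length distances with zero diagonal,
#'   dimnames = leaf labels.
#' @export
patristic_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' A node-age calibration for tree dating
#'
#' @param mrca_of Character vector of two leaf labels; the calibration
#'   applies to their most recent common ancestor.
#' @param age Positive age (time units before present).
#' @return A list of class \code{calibration}.
#' @export
calibration <- function(mrca_of, age) {
  stopifnot(length(mrca_of) == 2L, is.numeric(age), length(age) == 1L)
  if (age <= 0) stop("calibration age must be > 0", call. = FALSE)
  structure(list(mrca_of = as.character(mrca_of), age = as.numeric(age)),
            class = "calibration")
}

#' Mean-path-length tree dating ("MPL-lite")
#'
#' Converts a phylogram with arbitrary branch lengths into an ultrametric
#' chronogram. Node ages are first estimated bottom-up as the mean over
#' children of (child age + child branch length); calibrated nodes are then
#' pinned to their assigned ages and intervening nodes rescaled linearly
#' within each calibrated segment (anchored at age 0 at the leaves when no
#' calibrated node lies below). Age reversals left by rescaling are resolved
#' by clamping each child's age to at most its parent's. Rate-deviation
#' smoothing used by full path-length dating programs is deliberately not
#' reproduced; this routine exists to obtain an ultrametric tree.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @param calibrations List of \code{\link{calibration}} objects. The root
#'   must be calibrated, either by a calibration whose MRCA is the root or
#'   via \code{root_age}.
#' @param root_age Optional positive age for the root, used when no supplied
#'   calibration pins the root.
#' @return An ultrametric \code{phylo} with the same topology.
#' @export
mpl_ultrametricize <- function(tree, calibrations = list(), root_age = NULL) {
  if (inherits(calibrations, "calibration")) calibrations <- list(calibrations)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)

  # resolve calibrations to node ids
  cal_age <- rep(NA_real_, n_all)
  for (cal in calibrations) {
    miss <- setdiff(cal$mrca_of, tree$tip.label)
    if (length(miss))
      stop("calibration refers to unknown taxa: ",
           paste(miss, collapse = ", "), call. = FALSE)
    node <- if (cal$mrca_of[1] == cal$mrca_of[2]) {
      match(cal$mrca_of[1], tree$tip.label)
    } else {
      ape::getMRCA(tree, cal$mrca_of)
    }
    if (!is.na(cal_age[node]) && cal_age[node] != cal$age)
      stop("conflicting calibrations at node ", node, call. = FALSE)
    cal_age[node] <- cal$age
  }
  if (is.na(cal_age[root])) {
    if (is.null(root_age))
      stop("the root must be calibrated (supply root_age or a calibration ",
           "spanning the root)", call. = FALSE)
    cal_age[root] <- root_age
  }

  parent <- integer(n_all)
  parent[root] <- 0L
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  # conflicting calibrations: a calibrated descendant older than a
  # calibrated ancestor is an error
  for (v in which(!is.na(cal_age))) {
    a <- parent[v]
    while (a != 0L) {
      if (!is.na(cal_age[a]) && cal_age[a] < cal_age[v])
        stop("conflicting calibrations: node ", v, " (age ", cal_age[v],
             ") is older than its ancestor node ", a, " (age ", cal_age[a],
             ")", call. = FALSE)
      a <- parent[a]
    }
  }

  # raw mean-path-length ages, bottom-up (postorder)
  edge_len <- numeric(n_all)
  edge_len[tree$edge[, 2L]] <- tree$edge.length
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  mpl <- numeric(n_all) # leaves 0
  post <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2L])
  for (v in c(post[post > n_tip], root)) {
    ch <- kids[[as.character(v)]]
    mpl[v] <- mean(mpl[ch] + edge_len[ch])
  }

  # nearest calibrated ancestor-or-self, and nearest calibrated node on the
  # path below (if any), then linear rescale between the two anchors; leaves
  # (age 0, mpl 0) are the lower anchor otherwise.
  age <- rep(NA_real_, n_all)
  age[seq_len(n_tip)] <- 0
  age[!is.na(cal_age)] <- cal_age[!is.na(cal_age)]

  has_cal_below <- logical(n_all)
  max_cal_below_age <- rep(-Inf, n_all)
  max_cal_below_mpl <- rep(0, n_all)
  for (v in post[post > n_tip]) {
    ch <- kids[[as.character(v)]]
    for (c in ch) {
      c_age <- if (!is.na(cal_age[c])) cal_age[c] else max_cal_below_age[c]
      c_mpl <- if (!is.na(cal_age[c])) mpl[c] else max_cal_below_mpl[c]
      if (is.finite(c_age) && c_age > max_cal_below_age[v]) {
        has_cal_below[v] <- TRUE
        max_cal_below_age[v] <- c_age
        max_cal_below_mpl[v] <- c_mpl
      }
    }
  }

  pre <- c(root, ape::reorder.phylo(tree, "cladewise")$edge[, 2L])
  anc_cal_age <- rep(NA_real_, n_all)
  anc_cal_mpl <- rep(NA_real_, n_all)
  for (v in pre) {
    if (!is.na(cal_age[v])) {
      anc_cal_age[v] <- cal_age[v]
      anc_cal_mpl[v] <- mpl[v]
    } else if (v != root) {
      anc_cal_age[v] <- anc_cal_age[parent[v]]
      anc_cal_mpl[v] <- anc_cal_mpl[parent[v]]
    }
    if (v > n_tip && is.na(cal_age[v])) {
      tA <- anc_cal_age[v]; mA <- anc_cal_mpl[v]
      if (has_cal_below[v]) {
        tD <- max_cal_below_age[v]; mD <- max_cal_below_mpl[v]
      } else {
        tD <- 0; mD <- 0
      }
      age[v] <- if (mA > mD) {
        tD + (mpl[v] - mD) * (tA - tD) / (mA - mD)
      } else {
        tA
      }
    }
  }

  # clamp age reversals top-down (calibrated nodes keep their ages; the
  # conflict check above guarantees they never need clamping)
  for (v in pre) {
    if (v == root) next
    if (is.na(cal_age[v]) && age[v] > age[parent[v]]) age[v] <- age[parent[v]]
  }

  out <- tree
  out$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  out$edge.length[out$edge.length < 0] <- 0
  out
}
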