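#' Assign anatomical labels to an airway tree
#'
#' Labels follow the 26-label bronchial scheme: Trachea, left and right
#' main bronchus, Bronint (bronchus intermedius), the four lobar
#' trifurcations (TriRUL, TriRLL, TriLUL, TriLLB) and segmental leaves
#' grouped into the five lobe subgroups (sRUL, sRML, sRLL, sLUL, sLLL).
#' Assignment is rule-based on generation order and the laterality /
#' inclination of branch direction vectors (+x is the patient's left, +z
#' superior): the trachea's left-pointing child is the LMB; the RMB child
#' that points superiorly is TriRUL, the inferior one Bronint; Bronint's
#' inferior child is TriRLL and the other the (unlabeled) middle-lobe
#' stem; the LMB's superior child is TriLUL and the inferior TriLLB.
#' Leaf branches of each lobar subtree get subgroup labels numbered in a
#' deterministic traversal order.  Branches that no rule reaches keep an
#' `NA` label ("unlabeled") and are never dropped.
#'
#' @param tree an `airway_tree` from [skeletonize()].
#' @return The tree with `label` (and `subgroup`) fields filled.
#' @export
label_branches <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  br <- tree$branches
  n <- length(br)
  parent <- vapply(br, function(b) b$parent, integer(1))
  kids <- function(i) which(parent == i)
  dirmat <- t(vapply(br, function(b) b$direction, numeric(3)))
  for (i in seq_len(n)) {
    br[[i]]$label <- NA_character_
    br[[i]]$subgroup <- NA_character_
  }

  root <- which(parent == 0L)
  if (length(root) != 1) stop("tree must have a single root")
  br[[root]]$label <- "Trachea"
  ch <- kids(root)
  if (length(ch) != 2)
    stop("cannot orient tree: trachea must have exactly two children ",
         "(LMB and RMB), found ", length(ch))
  lmb <- ch[which.max(dirmat[ch, 1])]
  rmb <- setdiff(ch, lmb)
  br[[lmb]]$label <- "LMB"
  br[[rmb]]$label <- "RMB"

  # deterministic sibling order for subgroup numbering
  ord_kids <- function(i) {
    k <- kids(i)
    k[order(dirmat[k, 1], dirmat[k, 2], dirmat[k, 3])]
  }
  label_leaves <- function(top, subgroup) {
    cnt <- 0L
    walk <- function(i) {
      k <- ord_kids(i)
      if (!length(k)) {
        cnt <<- cnt + 1L
        br[[i]]$label <<- paste0(subgroup, "_", cnt)
        br[[i]]$subgroup <<- subgroup
      } else for (j in k) walk(j)
    }
    for (j in ord_kids(top)) walk(j)
  }

  rch <- kids(rmb)
  if (length(rch) == 2) {
    bronint <- rch[which.min(dirmat[rch, 3])]
    trirul <- setdiff(rch, bronint)
    br[[bronint]]$label <- "Bronint"
    br[[trirul]]$label <- "TriRUL"
    label_leaves(trirul, "sRUL")
    bch <- kids(bronint)
    if (length(bch) == 2) {
      trirll <- bch[which.min(dirmat[bch, 3])]
      rml <- setdiff(bch, trirll)
      br[[trirll]]$label <- "TriRLL"
      label_leaves(trirll, "sRLL")
      label_leaves(rml, "sRML")
    }
  }
  lch <- kids(lmb)
  if (length(lch) == 2) {
    trilul <- lch[which.max(dirmat[lch, 3])]
    trillb <- setdiff(lch, trilul)
    br[[trilul]]$label <- "TriLUL"
    br[[trillb]]$label <- "TriLLB"
    label_leaves(trilul, "sLUL")
    label_leaves(trillb, "sLLL")
  }

  labs <- vapply(br, function(b) b$label, character(1))
  dup <- labs[!is.na(labs)][duplicated(labs[!is.na(labs)])]
  if (length(dup)) stop("duplicate labels assigned: ",
                        paste(unique(dup), collapse = ", "))
  tree$branches <- br
  tree
}
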