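# Constrained constructive optimization (CCO) tree growth.
#
# A growing tree is a compact arrays-of-vectors structure ("cco_tree"):
# node 1 is the root; each segment stores tail/head node indices, its parent
# segment (0 at the root segment), children, the Murray power-sum
# s = sum of terminal d^gamma below it (so diameter = s^(1/gamma)), and its
# terminal count. Geometry is straight during growth; tortuosity is imposed
# afterwards.

cco_new <- function(root_pos, gamma = 3) {
  list(pos = matrix(root_pos, ncol = 3), n_nodes = 1L,
       tail = integer(0), head = integer(0), parent = integer(0),
       children = list(), s = numeric(0), nterm = integer(0),
       is_leaf = logical(0), term_nodes = integer(0), term_segs = integer(0),
       gamma = gamma)
}

.cco_add_node <- function(tree, p) {
  tree$pos <- rbind(tree$pos, p)
  tree$n_nodes <- tree$n_nodes + 1L
  tree
}

cco_seg_lengths <- function(tree, idx = seq_along(tree$tail)) {
  a <- tree$pos[tree$tail[idx], , drop = FALSE]
  b <- tree$pos[tree$head[idx], , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

cco_diameters <- function(tree) tree$s^(1 / tree$gamma)

cco_volume <- function(tree) {
  sum(pi / 4 * tree$s^(2 / tree$gamma) * cco_seg_lengths(tree)) # um^3
}

# Weighted Fermat point of triangle (a, b, t) with weights w = (w1, w2, w3):
# minimizes w1|x-a| + w2|x-b| + w3|x-t| by safeguarded Weiszfeld iteration,
# clamped into the domain box. Positions in micrometers; tol in micrometers.
weiszfeld_point <- function(a, b, t, w, domain, tol = 0.1, maxit = 60L) {
  P <- rbind(a, b, t)
  x <- colSums(P * w) / sum(w)
  lo <- c(domain$x[1], domain$y[1], -domain$depth)
  hi <- c(domain$x[2], domain$y[2], 0)
  for (i in seq_len(maxit)) {
    r <- sqrt(rowSums((P - rep(x, each = 3L))^2))
    r <- pmax(r, 1e-9)
    wi <- w / r
    x_new <- colSums(P * wi) / sum(wi)
    x_new <- pmin(pmax(x_new, lo), hi)
    if (sqrt(sum((x_new - x)^2)) < tol) { x <- x_new; break }
    x <- x_new
  }
  x
}

# Candidate evaluation: optimal bifurcation point and volume increase for
# attaching a terminal (position t, Murray power dtg = d_t^gamma) onto
# segment j. Returns list(x, dvol_local, dvol_up).
.cco_eval_candidate <- function(tree, j, t, dtg, domain, tol = 0.1) {
  a <- tree$pos[tree$tail[j], ]
  b <- tree$pos[tree$head[j], ]
  g2 <- 2 / tree$gamma
  w <- c((tree$s[j] + dtg)^g2, tree$s[j]^g2, dtg^g2)
  ab <- b - a; at <- t - a
  cr <- c(ab[2] * at[3] - ab[3] * at[2],
          ab[3] * at[1] - ab[1] * at[3],
          ab[1] * at[2] - ab[2] * at[1])
  degenerate <- sum(cr^2) < (1e-6 * sum(ab^2) * max(sum(at^2), 1e-12))
  if (degenerate) {
    x <- (a + b) / 2
  } else {
    x <- weiszfeld_point(a, b, t, w, domain, tol = tol)
  }
  # keep the bifurcation off the parent/child nodes
  for (p in list(a, b)) {
    if (sqrt(sum((x - p)^2)) < 1.0) {
      x <- a + (b - a) * if (identical(p, a)) 0.02 else 0.98
      break
    }
  }
  Lab <- sqrt(sum((b - a)^2))
  vol_new <- w[1] * sqrt(sum((x - a)^2)) + w[2] * sqrt(sum((x - b)^2)) +
    w[3] * sqrt(sum((x - t)^2))
  vol_old <- tree$s[j]^g2 * Lab
  dvol_local <- pi / 4 * (vol_new - vol_old)
  # upstream inflation: ancestors gain dtg in their power sum
  dvol_up <- 0
  anc <- tree$parent[j]
  while (anc != 0L) {
    L <- sqrt(sum((tree$pos[tree$tail[anc], ] - tree$pos[tree$head[anc], ])^2))
    dvol_up <- dvol_up + pi / 4 * L * ((tree$s[anc] + dtg)^g2 - tree$s[anc]^g2)
    anc <- tree$parent[anc]
  }
  list(x = x, dvol_local = dvol_local, dvol_up = dvol_up,
       degenerate = degenerate)
}

#' Optimal bifurcation point for a new terminal
#'
#' Returns the in-domain point minimizing the total tree volume after
#' connecting a new terminal to a candidate segment, with diameters
#' re-balanced through the Murray power sums, together with the resulting
#' volume increase. The volume objective over the bifurcation position is a
#' weighted Fermat problem over the triangle (segment tail, segment head,
#' terminal), solved by safeguarded Weiszfeld iteration (tolerance 0.1 um).
#' Degenerate geometry (terminal collinear with the segment) falls back to
#' the segment midpoint with a warning.
#'
#' @param tree A `cco_tree` growth state (see [grow_tree()]).
#' @param segment Index of the candidate segment.
#' @param terminal Position of the new terminal (length-3, micrometers).
#' @param terminal_diameter Terminal diameter, micrometers.
#' @param domain A [domain_descriptor()].
#' @return List with `position` (the bifurcation point) and `dvolume`
#'   (total tree volume increase, um^3, always > 0).
#' @export
optimize_bifurcation <- function(tree, segment, terminal, terminal_diameter,
                                 domain = domain_descriptor()) {
  stopifnot(inherits(tree, "cco_tree") || is.list(tree),
            segment >= 1, segment <= length(tree$tail))
  dtg <- terminal_diameter^tree$gamma
  ev <- .cco_eval_candidate(tree, segment, as.numeric(terminal), dtg, domain)
  if (ev$degenerate) {
    warning("terminal collinear with candidate segment; using midpoint")
  }
  list(position = ev$x, dvolume = ev$dvol_local + ev$dvol_up)
}

# Insert a terminal into the tree at the volume-minimizing attachment among
# the k nearest candidate segments.
cco_insert <- function(tree, t, d_t, domain, k = 20L) {
  t <- as.numeric(t)
  dtg <- d_t^tree$gamma
  ns <- length(tree$tail)
  if (ns == 0L) {
    tree <- .cco_add_node(tree, t)
    tree$tail <- 1L; tree$head <- 2L; tree$parent <- 0L
    tree$children <- list(integer(0))
    tree$s <- dtg; tree$nterm <- 1L; tree$is_leaf <- TRUE
    tree$term_nodes <- 2L; tree$term_segs <- 1L
    return(tree)
  }
  mid <- (tree$pos[tree$tail, , drop = FALSE] +
          tree$pos[tree$head, , drop = FALSE]) / 2
  d2 <- (mid[, 1] - t[1])^2 + (mid[, 2] - t[2])^2 + (mid[, 3] - t[3])^2
  cand <- order(d2)[seq_len(min(k, ns))]
  best <- NULL; best_dv <- Inf
  for (j in cand) {
    ev <- .cco_eval_candidate(tree, j, t, dtg, domain)
    dv <- ev$dvol_local + ev$dvol_up
    if (dv < best_dv) { best_dv <- dv; best <- list(j = j, x = ev$x) }
  }
  j <- best$j; x <- best$x
  tree <- .cco_add_node(tree, x); nx <- tree$n_nodes
  tree <- .cco_add_node(tree, t); nt <- tree$n_nodes
  b_node <- tree$head[j]
  j2 <- ns + 1L   # (x, b): carries j's old subtree
  jt <- ns + 2L   # (x, t): the new terminal segment
  tree$tail[j2] <- nx; tree$head[j2] <- b_node
  tree$tail[jt] <- nx; tree$head[jt] <- nt
  tree$head[j] <- nx
  tree$parent[j2] <- j; tree$parent[jt] <- j
  tree$children[[j2]] <- tree$children[[j]]
  for (ch in tree$children[[j2]]) tree$parent[ch] <- j2
  tree$children[[jt]] <- integer(0)
  tree$children[[j]] <- c(j2, jt)
  tree$s[j2] <- tree$s[j]; tree$nterm[j2] <- tree$nterm[j]
  tree$is_leaf[j2] <- tree$is_leaf[j]
  tree$s[jt] <- dtg; tree$nterm[jt] <- 1L; tree$is_leaf[jt] <- TRUE
  tree$is_leaf[j] <- FALSE
  # terminal bookkeeping: a split leaf's record moves to its continuation
  w <- which(tree$term_segs == j)
  if (length(w)) tree$term_segs[w] <- j2
  tree$term_nodes <- c(tree$term_nodes, nt)
  tree$term_segs <- c(tree$term_segs, jt)
  # inflate j and its ancestors
  anc <- j
  while (anc != 0L) {
    tree$s[anc] <- tree$s[anc] + dtg
    tree$nterm[anc] <- tree$nterm[anc] + 1L
    anc <- tree$parent[anc]
  }
  tree
}

# Segments ordered root-to-leaves (parents before children).
.cco_toporder <- function(tree) {
  ns <- length(tree$tail)
  ord <- integer(ns); qi <- 1L; qn <- 0L
  roots <- which(tree$parent == 0L)
  ord[seq_along(roots)] <- roots; qn <- length(roots)
  while (qi <= qn) {
    ch <- tree$children[[ord[qi]]]
    if (length(ch)) { ord[qn + seq_along(ch)] <- ch; qn <- qn + length(ch) }
    qi <- qi + 1L
  }
  ord
}

# Hydraulic balancing: reallocate Murray power between sibling subtrees
# (preserving each parent's power sum exactly) so that subtree conductances
# become proportional to terminal counts -> equal terminal outflows. A few
# passes suffice; each pass is a bottom-up resistance sweep followed by a
# top-down reallocation.
cco_balance <- function(tree, rheology = rheology_params(), h = 0.35,
                        passes = 3L) {
  gamma <- tree$gamma
  ord <- .cco_toporder(tree)
  rev_ord <- rev(ord)
  L <- cco_seg_lengths(tree)
  for (p in seq_len(passes)) {
    d <- tree$s^(1 / gamma)
    Rseg <- segment_resistance(d, pmax(L, 1e-3), h, rheology)
    Rsub <- numeric(length(Rseg))
    for (j in rev_ord) {
      ch <- tree$children[[j]]
      Rsub[j] <- Rseg[j] + if (length(ch)) 1 / sum(1 / Rsub[ch]) else 0
    }
    accum <- rep(1, length(Rseg))
    beta <- gamma / 4
    for (j in ord) {
      ch <- tree$children[[j]]
      if (length(ch) >= 2L) {
        gcond <- 1 / Rsub[ch]
        Nt <- tree$nterm[ch]
        S <- sum(tree$s[ch])
        base <- (Nt / gcond)^beta
        cb <- S / sum(tree$s[ch] * base)       # c^beta
        f <- (cb * base)^(1 / gamma)           # per-child diameter factor
        accum[ch] <- accum[j] * f
      } else if (length(ch) == 1L) {
        accum[ch] <- accum[j]
      }
    }
    tree$s <- tree$s * accum^gamma
  }
  tree
}

#' Grow a vascular tree by constrained constructive optimization
#'
#' Sequentially connects terminal sites to a growing tree rooted at
#' `root`. Each insertion evaluates the `k` nearest segments and commits the
#' attachment with the minimal total volume increase, with the bifurcation
#' position optimized as in [optimize_bifurcation()]. Diameters follow the
#' Murray power rule `d_parent^gamma = sum(d_child^gamma)` by construction
#' (power sums are maintained incrementally). When `balance = TRUE`, a
#' hydraulic balancing pass reallocates power between sibling subtrees —
#' preserving every parent's power sum, hence Murray closure — until subtree
#' conductances are proportional to terminal counts, which enforces the
#' equal-terminal-outflow growth constraint.
#'
#' @param root Root position (length-3, micrometers).
#' @param terminals Matrix of terminal positions (n x 3).
#' @param terminal_diameters Terminal diameters (recycled), micrometers.
#' @param gamma Murray exponent in `[2, 4]`.
#' @param domain A [domain_descriptor()].
#' @param k Number of nearest candidate segments evaluated per insertion.
#' @param balance Apply the equal-outflow balancing pass?
#' @param rheology Rheology used for the balancing resistance sweep.
#' @return A `cco_tree` object; convert with [cco_as_network()].
#' @export
grow_tree <- function(root, terminals, terminal_diameters, gamma = 3,
                      domain = domain_descriptor(), k = 20L, balance = TRUE,
                      rheology = rheology_params()) {
  stopifnot(gamma >= 2, gamma <= 4)
  terminals <- matrix(as.numeric(terminals), ncol = 3)
  nd <- rep_len(terminal_diameters, nrow(terminals))
  tree <- cco_new(as.numeric(root), gamma)
  for (i in seq_len(nrow(terminals))) {
    tree <- cco_insert(tree, terminals[i, ], nd[i], domain, k = k)
  }
  if (balance && length(tree$tail) > 1L) {
    tree <- cco_balance(tree, rheology)
  }
  class(tree) <- "cco_tree"
  tree
}

#' Materialize a CCO tree as a vascular network fragment
#'
#' @param tree A `cco_tree`.
#' @param side `"arterial"` (root becomes an inlet) or `"venous"` (root
#'   becomes an outlet; the venous tree is grown in reverse).
#' @param compartment_internal,compartment_leaf Compartment labels for
#'   internal and leaf segments.
#' @param domain A [domain_descriptor()].
#' @param id_offset Node/segment id offset for later merging.
#' @param check Validate the fragment (leaf terminals are dangling interior
#'   nodes, so full validation normally fails until closure; default FALSE).
#' @return A `vascular_network` (unchecked fragment unless `check = TRUE`).
#' @export
cco_as_network <- function(tree, side = c("arterial", "venous"),
                           compartment_internal = "PEA",
                           compartment_leaf = "PEC",
                           domain = domain_descriptor(), id_offset = 0L,
                           check = FALSE) {
  side <- match.arg(side)
  d <- cco_diameters(tree)
  L <- cco_seg_lengths(tree)
  roles <- rep("interior", tree$n_nodes)
  roles[1] <- if (side == "arterial") "arterial_inlet" else "venous_outlet"
  nodes <- data.frame(id = seq_len(tree$n_nodes) + id_offset,
                      x = tree$pos[, 1], y = tree$pos[, 2], z = tree$pos[, 3],
                      role = roles)
  # reference orientation: arterial flows root->leaf, venous leaf->root
  tl <- tree$tail; hd <- tree$head
  if (side == "venous") { tmp <- tl; tl <- hd; hd <- tmp }
  segs <- data.frame(id = seq_along(tl) + id_offset,
                     tail = tl + id_offset, head = hd + id_offset,
                     diameter = d, length = pmax(L, 1e-3),
                     compartment = ifelse(tree$is_leaf, compartment_leaf,
                                          compartment_internal))
  segs$cp <- vector("list", nrow(segs))
  vascular_network(nodes, segs, domain, check = check)
}

#' Recompute tree diameters by the Murray power rule
#'
#' Leaf-to-root pass over a tree-shaped network enforcing
#' `d_parent^gamma = sum(d_child^gamma)` while keeping leaf diameters fixed.
#' The network must be a rooted tree (the root is the unique boundary node);
#' cycles are an error since the recursion is defined on trees only.
#'
#' @param net A tree-shaped `vascular_network` fragment (boundary root).
#' @param gamma Murray exponent.
#' @return `net` with updated internal diameters.
#' @export
recompute_diameters <- function(net, gamma = 3) {
  g <- network_igraph(net)
  if (igraph::gsize(g) != igraph::vcount(g) - 1L || !igraph::is_connected(g)) {
    stop("cycle detected: diameter recursion is defined on trees only")
  }
  root <- which(net$nodes$role != "interior")[1]
  if (is.na(root)) root <- 1L
  bfs <- igraph::bfs(g, root = root, father = TRUE)
  father <- as.integer(bfs$father)
  ord <- as.integer(bfs$order)
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  # map each non-root node to the segment joining it to its father
  seg_of <- integer(nrow(net$nodes))
  key <- paste(pmin(it, ih), pmax(it, ih))
  for (v in ord) {
    f <- father[v]
    if (!is.na(f) && f > 0) {
      seg_of[v] <- match(paste(min(v, f), max(v, f)), key)
    }
  }
  s <- numeric(nrow(net$segments))
  deg <- node_degree(net)
  for (v in rev(ord)) {
    f <- father[v]
    if (is.na(f) || f == 0) next
    sj <- seg_of[v]
    kids <- which(father == v & seg_of > 0)
    ksegs <- seg_of[kids]
    s[sj] <- if (length(ksegs) == 0L) net$segments$diameter[sj]^gamma
             else sum(s[ksegs])
  }
  net$segments$diameter <- s^(1 / gamma)
  net
}
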