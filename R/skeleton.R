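# Topology-preserving thinning and skeleton-graph morphometry: chains,
# geodesic lengths, spur pruning, distal tips.

#' Guo-Hall topology-preserving thinning of a binary mask
#'
#' Parallel two-subiteration thinning; unlike Zhang-Suen it does not erase
#' two-pixel-wide diagonal strips, which curvilinear processes frequently
#' produce.
#'
#' @param mask logical matrix.
#' @return logical matrix: one-pixel-wide 8-connected skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask & TRUE
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- m_shift(m,  1,  0, FALSE); p3 <- m_shift(m,  1, -1, FALSE)
      p4 <- m_shift(m,  0, -1, FALSE); p5 <- m_shift(m, -1, -1, FALSE)
      p6 <- m_shift(m, -1,  0, FALSE); p7 <- m_shift(m, -1,  1, FALSE)
      p8 <- m_shift(m,  0,  1, FALSE); p9 <- m_shift(m,  1,  1, FALSE)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      mcond <- if (sub == 1) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      cond <- m & C == 1 & N >= 2 & N <= 3 & !mcond
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Reduced skeleton adjacency: 8-neighbour edges, dropping a diagonal edge when
# the two pixels share an orthogonal skeleton neighbour (so straight runs and
# junction degrees are not inflated by chain-code triangles).
# Returns list(rows, cols, adj, wt, degree); adj/wt are per-node neighbour and
# step-length (px) lists.
skeleton_adjacency <- function(sk) {
  idx <- which(sk)
  n <- length(idx)
  nr <- nrow(sk)
  id <- matrix(0L, nr, ncol(sk)); id[idx] <- seq_len(n)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(sk)
    j <- integer(n); j[ok] <- id[cbind(r2[ok], c2[ok])]
    sel <- j > 0L
    diag_off <- o[1] != 0L && o[2] != 0L
    if (diag_off && any(sel)) {
      s <- which(sel)
      cn <- sk[cbind(rows[s] + o[1], cols[s])] | sk[cbind(rows[s], cols[s] + o[2])]
      sel[s[cn]] <- FALSE
    }
    if (any(sel)) {
      ef <- c(ef, which(sel)); et <- c(et, j[sel])
      ew <- c(ew, rep(if (diag_off) sqrt(2) else 1, sum(sel)))
    }
  }
  adj <- vector("list", n); wt <- vector("list", n)
  allf <- c(ef, et); allt <- c(et, ef); allw <- c(ew, ew)
  if (length(allf)) {
    ord <- order(allf)
    sp <- split(seq_along(allf)[ord], allf[ord])
    for (k in names(sp)) {
      i <- as.integer(k)
      adj[[i]] <- allt[sp[[k]]]
      wt[[i]] <- allw[sp[[k]]]
    }
  }
  list(rows = rows, cols = cols, adj = adj, wt = wt,
       degree = lengths(adj), n = n)
}

# Decompose a skeleton graph into maximal chains between nodes of degree != 2
# (isolated cycles are traversed from an arbitrary node). Returns a list of
# integer node-index paths.
skeleton_chains <- function(g) {
  if (g$n == 0) return(list())
  seen <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(a, "_", b)
  chains <- list()
  walk <- function(from, nxt) {
    path <- c(from, nxt)
    assign(ekey(from, nxt), TRUE, envir = seen)
    assign(ekey(nxt, from), TRUE, envir = seen)
    prev <- from; cur <- nxt
    while (g$degree[cur] == 2L) {
      nb <- g$adj[[cur]]
      nxt2 <- nb[nb != prev]
      if (length(nxt2) != 1L) break
      if (exists(ekey(cur, nxt2), envir = seen)) break
      assign(ekey(cur, nxt2), TRUE, envir = seen)
      assign(ekey(nxt2, cur), TRUE, envir = seen)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    path
  }
  ends <- which(g$degree != 2L & g$degree > 0L)
  for (v in ends) for (u in g$adj[[v]]) {
    if (!exists(ekey(v, u), envir = seen))
      chains[[length(chains) + 1L]] <- walk(v, u)
  }
  # isolated cycles (every node degree 2)
  for (v in which(g$degree == 2L)) {
    u <- g$adj[[v]][1]
    if (!exists(ekey(v, u), envir = seen))
      chains[[length(chains) + 1L]] <- walk(v, u)
  }
  chains
}

# Geodesic length of a chain: moving-average smoothing of the pixel polyline
# (ends anchored) removes the orientation-dependent chain-code overestimate.
chain_length_um <- function(g, path, pixel_size) {
  k <- length(path)
  if (k < 2) return(0)
  p <- cbind(g$rows[path], g$cols[path])
  q <- p
  if (k > 2) for (i in 2:(k - 1)) {
    w <- min(i - 1L, k - i, 2L)
    q[i, ] <- colMeans(p[(i - w):(i + w), , drop = FALSE])
  }
  sum(sqrt(rowSums((q[-1, , drop = FALSE] - q[-k, , drop = FALSE])^2))) * pixel_size
}

#' Extract the process skeleton of one cell from a MIP image
#'
#' The cell foreground is segmented in a window around the soma by a
#' deterministic per-cell cut at `background + process_threshold * (soma
#' level - background)` (background = window median, soma level = 0.9
#' quantile of the soma mask), restricted to pixels nearer this soma than
#' any other when neighbouring cell centroids are supplied, morphologically
#' closed, and reduced to a one-pixel skeleton by topology-preserving
#' thinning. Anchoring the cut to each cell's soma brightness keeps the
#' dimmer process ridges in the mask, which a window Otsu cut (dominated by
#' the bright soma mode) does not. The
#' skeleton outside the soma mask is decomposed into chains; spur chains
#' shorter than `prune_um` hanging off a branch node are removed. Distal tips
#' are chain endpoints of degree 1 off the soma; with `tip_snap` each tip is
#' advanced along its local direction to the foreground boundary and pulled
#' back by the estimated stroke half-width, correcting the endpoint erosion
#' of thinning.
#'
#' @param mip numeric matrix.
#' @param soma a `soma_region` from [segment_soma()].
#' @param pixel_size um per pixel.
#' @param window_um half-width of the analysis window around the soma (um).
#' @param prune_um spur prune length (um).
#' @param other_centroids optional matrix (x, y um) of the other somata in
#'   the field, used to keep neighbouring arbors out of this cell's mask.
#' @param process_threshold foreground cut as a fraction of the soma
#'   peak-to-background range.
#' @param tip_snap logical; correct tip positions for endpoint erosion.
#' @return An object of class `cell_skeleton`: node table, chains with
#'   lengths and end types, attachment nodes, `tips` (data.frame x, y um),
#'   and bookkeeping needed by [primary_process_lengths()] and
#'   [total_process_length()].
#' @export
extract_skeleton <- function(mip, soma, pixel_size, window_um = 40,
                             prune_um = 2, other_centroids = NULL,
                             process_threshold = 0.2, tip_snap = TRUE) {
  stopifnot(inherits(soma, "soma_region"))
  nr <- nrow(mip); nc <- ncol(mip)
  crow <- soma$centroid["y"] / pixel_size + 1
  ccol <- soma$centroid["x"] / pixel_size + 1
  half <- ceiling(window_um / pixel_size)
  rs <- max(1L, floor(crow - half)):min(nr, ceiling(crow + half))
  cs <- max(1L, floor(ccol - half)):min(nc, ceiling(ccol + half))
  crop <- mip[rs, cs]
  soma_mask <- matrix(FALSE, nr, nc)
  soma_mask[soma$mask_idx] <- TRUE
  soma_crop <- soma_mask[rs, cs]
  bg <- stats::median(crop)
  soma_level <- stats::quantile(crop[soma_crop], 0.9, names = FALSE)
  if (soma_level <= bg) stop("soma is not above the window background")
  fg <- crop >= bg + process_threshold * (soma_level - bg)
  fg <- fg | soma_crop
  fg <- EBImage::closing(fg * 1, EBImage::makeBrush(3, "box")) > 0
  lab <- EBImage::bwlabel(fg)
  ks <- unique(lab[soma_crop])
  ks <- ks[ks > 0]
  if (!length(ks)) stop("foreground not connected to the soma")
  comp <- matrix(lab %in% ks, nrow(fg), ncol(fg))
  if (!is.null(other_centroids) && NROW(other_centroids) > 0) {
    ci <- which(comp)
    pr <- (ci - 1L) %% nrow(comp) + 1L
    pc <- (ci - 1L) %/% nrow(comp) + 1L
    gx <- (cs[pc] - 1) * pixel_size
    gy <- (rs[pr] - 1) * pixel_size
    d0 <- (gx - soma$centroid["x"])^2 + (gy - soma$centroid["y"])^2
    dmin <- rep(Inf, length(ci))
    for (i in seq_len(NROW(other_centroids))) {
      dmin <- pmin(dmin, (gx - other_centroids[i, 1])^2 +
                           (gy - other_centroids[i, 2])^2)
    }
    drop <- ci[d0 > dmin & !soma_crop[ci]]
    comp[drop] <- FALSE
  }
  sk_full <- thin_mask(comp)
  sk <- sk_full & !soma_crop
  build <- function(skm) {
    g <- skeleton_adjacency(skm)
    # attachments: skeleton pixels 8-adjacent to the soma mask
    att <- logical(g$n)
    if (g$n > 0) {
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- g$rows + dr; c2 <- g$cols + dc
        ok <- r2 >= 1 & r2 <= nrow(skm) & c2 >= 1 & c2 <= ncol(skm)
        att[ok] <- att[ok] | soma_crop[cbind(r2[ok], c2[ok])]
      }
    }
    list(g = g, att = att, chains = skeleton_chains(g))
  }
  b <- build(sk)
  # spur pruning: drop tip chains shorter than prune_um whose far end is a
  # branch node; repeat because removals can linearise junctions
  for (pass in 1:5) {
    if (!length(b$chains)) break
    remove_nodes <- integer(0)
    for (ch in b$chains) {
      e1 <- ch[1]; e2 <- ch[length(ch)]
      d1 <- b$g$degree[e1]; d2 <- b$g$degree[e2]
      len <- chain_length_um(b$g, ch, pixel_size)
      tip_end <- (d1 == 1L && !b$att[e1] && d2 >= 3L) ||
                 (d2 == 1L && !b$att[e2] && d1 >= 3L)
      if (tip_end && len < prune_um) {
        inner <- if (d1 >= 3L) ch[-1] else ch[-length(ch)]
        remove_nodes <- c(remove_nodes, inner)
      }
    }
    if (!length(remove_nodes)) break
    keep <- setdiff(seq_len(b$g$n), unique(remove_nodes))
    sk_new <- matrix(FALSE, nrow(sk), ncol(sk))
    sk_new[cbind(b$g$rows[keep], b$g$cols[keep])] <- TRUE
    sk <- sk_new
    b <- build(sk)
  }
  g <- b$g
  chains <- b$chains
  chain_info <- if (length(chains)) data.frame(
    chain = seq_along(chains),
    end1 = vapply(chains, `[`, integer(1), 1L),
    end2 = vapply(chains, function(ch) ch[length(ch)], integer(1)),
    length_um = vapply(chains, function(ch) chain_length_um(g, ch, pixel_size),
                       numeric(1)))
  else data.frame(chain = integer(0), end1 = integer(0), end2 = integer(0),
                  length_um = numeric(0))
  tip_nodes <- which(g$degree == 1L & !b$att)
  # isolated single nodes (degree 0, not attachments) are not tips
  tips <- if (length(tip_nodes)) {
    tx <- (cs[g$cols[tip_nodes]] - 1) * pixel_size
    ty <- (rs[g$rows[tip_nodes]] - 1) * pixel_size
    data.frame(node = tip_nodes, x = tx, y = ty)
  } else data.frame(node = integer(0), x = numeric(0), y = numeric(0))
  # sub-pixel march along direction d from p while the bilinear foreground
  # stays above 0.5 (i.e. up to the mask contour); returns the distance
  comp_num <- comp * 1
  march <- function(p, d, maxs = 6, img = comp_num, inside = TRUE) {
    s <- 0
    repeat {
      q <- p + (s + 0.1) * d
      if (q[1] < 1 || q[1] > nrow(img) || q[2] < 1 || q[2] > ncol(img)) break
      v <- bilinear_at(img, q[1], q[2]) >= 0.5
      if (v != inside) break
      s <- s + 0.1
      if (s >= maxs) break
    }
    s
  }
  if (tip_snap && nrow(tips) > 0 && g$n > 1 && length(chains)) {
    for (i in seq_len(nrow(tips))) {
      tn <- tips$node[i]
      ch <- NULL; chi <- NA_integer_
      for (k in seq_along(chains)) {
        cc <- chains[[k]]
        if (cc[1] == tn) { ch <- cc; chi <- k; break }
        if (cc[length(cc)] == tn) { ch <- rev(cc); chi <- k; break }
      }
      if (is.null(ch) || length(ch) < 2) next
      back <- ch[min(4L, length(ch))]
      pt <- c(g$rows[tn], g$cols[tn])
      pb <- c(g$rows[back], g$cols[back])
      dirv <- pt - pb
      nv <- sqrt(sum(dirv^2))
      if (nv < 1e-9) next
      dirv <- dirv / nv
      # the mask contour is where the process signal ends: for a stroke whose
      # intensity is the line integral of its cross-section, the threshold
      # contour closes at the stroke endpoint, so the contour point ahead of
      # the (erosion-shortened) skeleton end IS the distal tip
      ext <- march(pt, dirv)
      p <- pt + ext * dirv
      tips$x[i] <- (cs[1] - 1 + p[2] - 1) * pixel_size
      tips$y[i] <- (rs[1] - 1 + p[1] - 1) * pixel_size
      chain_info$length_um[chi] <- chain_info$length_um[chi] + ext * pixel_size
    }
  }
  # account for the gap between each attachment node and the soma contour
  if (length(b$att) && any(b$att) && nrow(chain_info)) {
    soma_num <- soma_crop * 1
    scent <- c(crow - rs[1] + 1, ccol - cs[1] + 1)
    for (k in seq_len(nrow(chain_info))) {
      for (endn in c(chain_info$end1[k], chain_info$end2[k])) {
        if (!b$att[endn]) next
        pa <- c(g$rows[endn], g$cols[endn])
        dirv <- scent - pa
        nv <- sqrt(sum(dirv^2))
        if (nv < 1e-9) next
        gap <- march(pa, dirv / nv, maxs = 3, img = soma_num, inside = FALSE)
        chain_info$length_um[k] <- chain_info$length_um[k] + gap * pixel_size
      }
    }
  }
  structure(list(
    g = g, chains = chains, chain_info = chain_info,
    attachments = which(b$att), tips = tips,
    pixel_size = pixel_size, soma_centroid = soma$centroid,
    window = list(rows = rs, cols = cs)),
    class = "cell_skeleton")
}

#' @export
print.cell_skeleton <- function(x, ...) {
  cat(sprintf("cell_skeleton: %d px, %d chains, %d primary processes, %d tips, total %.1f um\n",
              x$g$n, length(x$chains), length(primary_process_lengths(x)),
              nrow(x$tips), total_process_length(x)))
  invisible(x)
}

#' Primary process lengths of a cell skeleton
#'
#' One length per soma attachment: the geodesic distance from the soma
#' boundary to the first branch node, or to the tip for an unbranched
#' process.
#'
#' @param skel a `cell_skeleton`.
#' @return numeric vector (um); empty for a process-less cell.
#' @export
primary_process_lengths <- function(skel) {
  stopifnot(inherits(skel, "cell_skeleton"))
  ci <- skel$chain_info
  if (!nrow(ci)) return(numeric(0))
  att <- skel$attachments
  lens <- c(ci$length_um[ci$end1 %in% att], ci$length_um[ci$end2 %in% att])
  # a chain with both ends attached contributes once per attachment, which is
  # correct: two primary stubs merging outside the soma
  lens
}

#' Total process length of a cell skeleton
#'
#' Sum of the geodesic lengths of all skeleton chains outside the soma, each
#' chain counted once.
#'
#' @param skel a `cell_skeleton`.
#' @return total length in um (0 for a process-less cell).
#' @export
total_process_length <- function(skel) {
  stopifnot(inherits(skel, "cell_skeleton"))
  sum(skel$chain_info$length_um)
}
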